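#' Differential expression of panel genes, worst cluster vs rest
#'
#' Per panel gene, a two-sided Wilcoxon rank-sum test of cluster-3 samples
#' against clusters 1+2, Benjamini-Hochberg FDR across the tested genes, and
#' a log2 fold change defined as mean log2(TPM+1) in cluster 3 minus the mean
#' in clusters 1+2 (a difference of means on the log scale). Direction is
#' `up`/`down` only when both the fold-change and FDR thresholds are met.
#'
#' @param m `expr_matrix`, log2(TPM+1) scale.
#' @param assign `cluster_assignment` with a designated worst cluster.
#' @param panel character vector of genes to test (intersected with the
#'   matrix).
#' @param fc_threshold |log2FC| threshold for calling direction (default 1).
#' @param q_threshold FDR threshold for calling direction (default 0.05).
#' @return data.frame of class `de_table`: gene, log2_fold_change, p, fdr,
#'   direction.
#' @export
differential_expression <- function(m, assign, panel,
                                    fc_threshold = 1, q_threshold = 0.05) {
  stopifnot_log2p1(m)
  stopifnot(inherits(assign, "cluster_assignment"))
  if (is.na(assign$worst))
    stop("worst cluster not designated; run designate_worst() first")
  genes <- intersect(panel, rownames(m))
  if (length(genes) == 0L) stop("no panel genes present in the matrix")
  labels <- assign$labels[colnames(m)]
  if (any(is.na(labels))) stop("assignment lacks labels for some samples")
  g3 <- labels == assign$worst
  if (sum(g3) < 2L || sum(!g3) < 2L)
    stop("need >= 2 samples per group for differential expression")
  x <- unclass(m)[genes, , drop = FALSE]
  lfc <- rowMeans(x[, g3, drop = FALSE]) - rowMeans(x[, !g3, drop = FALSE])
  p <- vapply(genes, function(g) {
    if (stats::sd(x[g, ]) == 0) return(1)
    suppressWarnings(
      stats::wilcox.test(x[g, g3], x[g, !g3], exact = FALSE)$p.value)
  }, numeric(1L))
  fdr <- stats::p.adjust(p, method = "BH")
  direction <- rep("ns", length(genes))
  direction[lfc >= fc_threshold & fdr < q_threshold] <- "up"
  direction[lfc <= -fc_threshold & fdr < q_threshold] <- "down"
  structure(data.frame(gene = genes, log2_fold_change = unname(lfc),
                       p = unname(p), fdr = unname(fdr),
                       direction = direction, stringsAsFactors = FALSE),
            class = c("de_table", "data.frame"))
}

#' Median dichotomization of one gene
#'
#' `hi` iff expression strictly exceeds the cohort median of that gene;
#' values equal to the median are `lo`, so the hi set never exceeds half the
#' cohort and the rule is deterministic.
#'
#' @param m `expr_matrix`, log2(TPM+1) scale.
#' @param gene gene identifier.
#' @param cutoff optional frozen cut-off; default is the median computed on
#'   `m` (pass a stored median when applying a trained signature to a new
#'   cohort).
#' @return Named character vector of `"hi"`/`"lo"` per sample.
#' @export
median_dichotomize <- function(m, gene, cutoff = NULL) {
  stopifnot_log2p1(m)
  if (!gene %in% rownames(m)) stop("gene '", gene, "' absent from matrix")
  v <- unclass(m)[gene, ]
  if (is.null(cutoff)) cutoff <- stats::median(v)
  stats::setNames(ifelse(v > cutoff, "hi", "lo"), colnames(m))
}

#' Elect a two-gene pair by concordance with the worst cluster
#'
#' Every (up-regulated, down-regulated) gene pair from the differential
#' expression table defines a binary call: a sample is pair-positive iff the
#' up gene is `hi` and the down gene is `lo` under median dichotomization.
#' `overall_consistency` is the fraction of samples where pair-positivity
#' agrees with membership of the worst cluster; `target_consistency` is the
#' precision of the pair-positive set for the worst cluster (0 when the set
#' is empty, which is flagged). The elected pair maximizes overall
#' consistency, with ties broken by target consistency and then
#' lexicographically by (up, down).
#'
#' @param m `expr_matrix`, log2(TPM+1) scale.
#' @param de a `de_table` from [differential_expression()].
#' @param assign `cluster_assignment` with designated worst cluster.
#' @return list of class `pair_signature`: `up_gene`, `down_gene`,
#'   `overall_consistency`, `target_consistency`, `calls` (per-sample
#'   positive/negative for the elected pair), `cutoffs` (the two medians, for
#'   frozen application), and `table` (every evaluated pair, ranked).
#' @export
pair_search <- function(m, de, assign) {
  stopifnot_log2p1(m)
  ups <- de$gene[de$direction == "up"]
  downs <- de$gene[de$direction == "down"]
  if (length(ups) == 0L || length(downs) == 0L)
    stop("need at least one up- and one down-regulated gene (got ",
         length(ups), " up, ", length(downs), " down)")
  labels <- assign$labels[colnames(m)]
  is3 <- labels == assign$worst
  dich <- lapply(stats::setNames(nm = union(ups, downs)),
                 function(g) median_dichotomize(m, g))
  grid <- expand.grid(up = ups, down = downs, stringsAsFactors = FALSE)
  grid <- grid[order(grid$up, grid$down), , drop = FALSE]
  res <- lapply(seq_len(nrow(grid)), function(i) {
    pos <- dich[[grid$up[i]]] == "hi" & dich[[grid$down[i]]] == "lo"
    overall <- mean(pos == is3)
    target <- if (any(pos)) mean(is3[pos]) else 0
    recall <- if (any(is3)) mean(pos[is3]) else NA_real_
    c(overall = overall, target = target, recall = recall,
      n_positive = sum(pos))
  })
  res <- do.call(rbind, res)
  tab <- data.frame(up = grid$up, down = grid$down,
                    overall_consistency = res[, "overall"],
                    target_consistency = res[, "target"],
                    recall = res[, "recall"],
                    n_positive = as.integer(res[, "n_positive"]),
                    stringsAsFactors = FALSE)
  if (any(tab$n_positive == 0L))
    warning(sum(tab$n_positive == 0L),
            " pair(s) with empty positive set; target consistency set to 0")
  ord <- order(-tab$overall_consistency, -tab$target_consistency,
               tab$up, tab$down)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  best <- tab[1L, ]
  pos <- dich[[best$up]] == "hi" & dich[[best$down]] == "lo"
  structure(list(up_gene = best$up, down_gene = best$down,
                 overall_consistency = best$overall_consistency,
                 target_consistency = best$target_consistency,
                 calls = stats::setNames(ifelse(pos, "positive", "negative"),
                                         colnames(m)),
                 cutoffs = c(up = stats::median(unclass(m)[best$up, ]),
                             down = stats::median(unclass(m)[best$down, ])),
                 table = tab),
            class = "pair_signature")
}

#' @export
print.pair_signature <- function(x, ...) {
  cat(sprintf(
    "pair_signature: %s-high / %s-low\n  overall consistency %.1f%%, target consistency %.1f%%, %d positive\n",
    x$up_gene, x$down_gene, 100 * x$overall_consistency,
    100 * x$target_consistency, sum(x$calls == "positive")))
  invisible(x)
}

#' Spearman correlation between the two signature genes
#'
#' @param m `expr_matrix`, log2(TPM+1) scale.
#' @param up,down gene identifiers.
#' @return list with `rho`, `p`, and `flag` (`"ok"`, or `"constant"` /
#'   `"too_few_samples"` when the correlation is undefined).
#' @export
correlate_pair <- function(m, up, down) {
  stopifnot_log2p1(m)
  for (g in c(up, down))
    if (!g %in% rownames(m)) stop("gene '", g, "' absent from matrix")
  x <- unclass(m)[up, ]; y <- unclass(m)[down, ]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, flag = "constant"))
  if (length(x) < 3L)
    return(list(rho = suppressWarnings(stats::cor(x, y, method = "spearman")),
                p = NA_real_, flag = "too_few_samples"))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, flag = "ok")
}

#' Classify samples by a frozen two-gene signature
#'
#' A sample is signature-positive iff the up gene is `hi` and the down gene
#' is `lo`. Medians default to the supplied cohort; pass `cutoffs` (named
#' `up`, `down`) to apply a signature trained elsewhere (frozen-threshold
#' mode).
#'
#' @param m `expr_matrix`, log2(TPM+1) scale.
#' @param up,down gene identifiers.
#' @param cutoffs optional named numeric vector `c(up = , down = )` of frozen
#'   medians.
#' @return Named character vector `"positive"`/`"negative"` per sample.
#' @export
classify_by_expression <- function(m, up, down, cutoffs = NULL) {
  hi <- median_dichotomize(m, up, cutoff = cutoffs[["up"]])
  lo <- median_dichotomize(m, down, cutoff = cutoffs[["down"]])
  stats::setNames(ifelse(hi == "hi" & lo == "lo", "positive", "negative"),
                  colnames(m))
}

#' Immunohistochemistry composite score
#'
#' Composite = staining intensity (0-3) + staining extensity (0-3);
#' composites 0-2 are `low`, 3-6 are `high`.
#'
#' @param intensity,extensity integer scores in 0..3 (vectorized).
#' @return data.frame with intensity, extensity, composite, level.
#' @export
ihc_score <- function(intensity, extensity) {
  if (any(!(intensity %in% 0:3)) || any(!(extensity %in% 0:3)))
    stop("IHC intensity and extensity must be integers in 0..3")
  composite <- intensity + extensity
  data.frame(intensity = intensity, extensity = extensity,
             composite = composite,
             level = ifelse(composite <= 2L, "low", "high"),
             stringsAsFactors = FALSE)
}

#' Classify samples by IHC scores of the two signature genes
#'
#' Positive iff the up gene scores `high` and the down gene scores `low`
#' under the composite rule of [ihc_score()].
#'
#' @param up_scores,down_scores data.frames from [ihc_score()] (row order =
#'   sample order).
#' @return Character vector `"positive"`/`"negative"`.
#' @export
classify_by_ihc <- function(up_scores, down_scores) {
  if (nrow(up_scores) != nrow(down_scores))
    stop("IHC score tables differ in length")
  ifelse(up_scores$level == "high" & down_scores$level == "low",
         "positive", "negative")
}

#' PD-L1 combined positive score (CPS)
#'
#' CPS = stained cells / total tumor cells x 100; positive iff CPS >= 10.
#'
#' @param stained_cells,tumor_cells nonnegative counts (vectorized).
#' @param cutoff positivity cut-off on the CPS scale (default 10).
#' @return data.frame with stained_cells, tumor_cells, cps, status.
#' @export
cps_score <- function(stained_cells, tumor_cells, cutoff = 10) {
  if (any(stained_cells < 0) || any(tumor_cells <= 0))
    stop("stained cells must be >= 0 and tumor cells > 0")
  cps <- stained_cells / tumor_cells * 100
  data.frame(stained_cells = stained_cells, tumor_cells = tumor_cells,
             cps = cps,
             status = ifelse(cps >= cutoff, "positive", "negative"),
             stringsAsFactors = FALSE)
}
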