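#' Unsupervised hierarchical clustering on a gene panel
#'
#' Panel genes are z-scored across samples, sample-sample distance is
#' 1 - Pearson correlation over the z-scored panel, and average-linkage
#' hierarchical clustering is cut at `k` groups. Deterministic: no random
#' initialization is involved.
#'
#' @param m `expr_matrix` on the log2(TPM+1) scale.
#' @param panel character vector of panel gene identifiers; genes absent from
#'   the matrix are dropped (at least 2 must remain).
#' @param k number of clusters (default 3).
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return list of class `cluster_assignment`: `labels` (named integer
#'   vector), `tree` (the hclust merge tree), `params`, and `worst`
#'   (NA until [designate_worst()] is applied).
#' @export
hierarchical_cluster <- function(m, panel, k = 3L, linkage = "average") {
  stopifnot_log2p1(m)
  if (k < 2L) stop("k must be >= 2")
  if (ncol(m) < k) stop("fewer samples (", ncol(m), ") than clusters (", k, ")")
  genes <- intersect(panel, rownames(m))
  if (length(genes) < 2L)
    stop("panel overlaps the matrix by ", length(genes), " gene(s); need >= 2")
  x <- unclass(m)[genes, , drop = FALSE]
  sds <- apply(x, 1L, stats::sd)
  keep <- sds > 0
  if (sum(keep) < 2L) stop("fewer than 2 non-constant panel genes")
  z <- (x[keep, , drop = FALSE] - rowMeans(x[keep, , drop = FALSE])) / sds[keep]
  d <- stats::as.dist(1 - stats::cor(z))
  tree <- stats::hclust(d, method = linkage)
  labels <- stats::cutree(tree, k = k)
  structure(list(labels = labels, tree = tree,
                 params = list(distance = "1 - Pearson", linkage = linkage,
                               k = k, n_panel_genes = sum(keep)),
                 worst = NA_integer_),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d samples, k = %d (%s linkage)\n",
              length(x$labels), x$params$k, x$params$linkage))
  print(table(cluster = x$labels))
  if (!is.na(x$worst))
    cat("worst-prognosis cluster designated as label", x$params$k, "\n")
  invisible(x)
}

# KM median per cluster; NA when the curve never crosses 0.5
km_median_by_group <- function(time, event, group) {
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  tab <- summary(fit)$table
  if (is.null(dim(tab))) tab <- matrix(tab, nrow = 1L,
                                       dimnames = list("all", names(tab)))
  med <- tab[, "median"]
  names(med) <- sub("^group=", "", rownames(tab))
  med
}

#' Designate the worst-prognosis cluster
#'
#' Relabels clusters so that label `k` (3 in the default three-cluster
#' analysis) is the cluster with the shortest Kaplan-Meier median overall
#' survival. Ties, or medians undefined in every cluster, fall back to the
#' restricted mean survival, and finally to the lowest original label, with
#' the relabeling recorded in `relabel_log`. The remaining clusters keep
#' their relative original order.
#'
#' @param assign a `cluster_assignment`.
#' @param clinical a `clinical_table` with `sample`, `os_time`, `os_event`.
#' @return The assignment with relabeled `labels`, `worst = k`, and a
#'   `relabel_log` entry.
#' @export
designate_worst <- function(assign, clinical) {
  stopifnot(inherits(assign, "cluster_assignment"))
  k <- assign$params$k
  if (length(unique(assign$labels)) < 2L)
    stop("need at least two clusters to designate a worst cluster")
  idx <- match(names(assign$labels), clinical$sample)
  if (any(is.na(idx)))
    stop("clinical table lacks ", sum(is.na(idx)), " clustered sample(s)")
  time <- clinical$os_time[idx]; event <- clinical$os_event[idx]
  ok <- !is.na(time) & !is.na(event)
  grp <- assign$labels[ok]
  if (length(unique(grp)) < length(unique(assign$labels)))
    stop("overall survival missing for an entire cluster")
  med <- km_median_by_group(time[ok], event[ok], grp)
  med <- med[as.character(sort(unique(grp)))]
  rule <- "KM median OS"
  if (all(is.na(med)) || (sum(med == min(med, na.rm = TRUE), na.rm = TRUE) > 1)) {
    # fall back to restricted mean survival over the observed follow-up
    fit <- survival::survfit(survival::Surv(time[ok], event[ok]) ~ grp)
    tab <- summary(fit, rmean = "common")$table
    rmean <- tab[, "rmean"]
    names(rmean) <- sub("^grp=", "", rownames(tab))
    cand <- rmean[as.character(sort(unique(grp)))]
    rule <- "restricted mean survival (median tie/undefined)"
    if (all(!is.finite(cand)) ||
        sum(cand == min(cand)) > 1) {
      worst_old <- min(as.integer(names(cand)[cand == min(cand)]))
      rule <- "lowest original label (complete tie)"
    } else {
      worst_old <- as.integer(names(which.min(cand)))
    }
  } else {
    worst_old <- as.integer(names(which.min(med)))
  }
  old <- sort(unique(assign$labels))
  others <- setdiff(old, worst_old)
  map <- stats::setNames(c(seq_along(others), k), c(others, worst_old))
  assign$labels <- stats::setNames(map[as.character(assign$labels)],
                                   names(assign$labels))
  assign$worst <- k
  assign$relabel_log <- sprintf(
    "cluster %d designated worst (label %d) by %s; medians: %s",
    worst_old, k, rule,
    paste(sprintf("%s=%.1f", names(med), med), collapse = ", "))
  assign
}

#' Single-sample gene set enrichment (ssGSEA)
#'
#' For each sample, genes are ranked in decreasing expression order (ties
#' broken by matrix row order for determinism). The running-sum statistic
#' steps up at in-set genes in proportion to rank-weight^`alpha` (rank weight
#' = number of genes minus position + 1) and down by 1/(#out-of-set genes)
#' otherwise; the enrichment score ES is the sum of the running difference
#' over all positions. NES is ES divided by the range (max - min) of ES
#' across samples for that set. Significance is assessed by gene-label
#' permutation (two-sided on |ES|) with Benjamini-Hochberg FDR across all
#' sample-by-set comparisons performed in the call.
#'
#' @param m `expr_matrix`, log2(TPM+1) scale.
#' @param sets named list of gene identifier vectors (or a
#'   `gene_set_collection`).
#' @param alpha rank-weight exponent; 0.25 by convention.
#' @param n_perm permutation count for p-values; 0 disables p/FDR.
#' @param seed integer seed for the permutations.
#' @return data.frame of class `ssgsea_result` with columns set, sample, es,
#'   nes, p, fdr. Sets overlapping the matrix by fewer than 2 genes are
#'   flagged missing (NA scores) with a warning.
#' @export
ssgsea <- function(m, sets, alpha = 0.25, n_perm = 1000L, seed = 1L) {
  stopifnot_log2p1(m)
  x <- unclass(m)
  ng <- nrow(x)
  out <- list()
  set.seed(seed)
  for (nm in names(sets)) {
    in_set <- rownames(x) %in% sets[[nm]]
    n_in <- sum(in_set)
    if (n_in < 2L) {
      warning("set '", nm, "' overlaps the matrix by ", n_in,
              " gene(s); flagged missing")
      out[[nm]] <- data.frame(set = nm, sample = colnames(x),
                              es = NA_real_, nes = NA_real_,
                              p = NA_real_, fdr = NA_real_)
      next
    }
    if (n_in == ng)
      stop("set '", nm, "' covers the whole matrix; out-of-set decrement undefined")
    es <- vapply(seq_len(ncol(x)), function(j)
      es_running_sum(x[, j], in_set, alpha), numeric(1L))
    rng <- max(es) - min(es)
    nes <- if (rng > 0) es / rng else rep(NA_real_, length(es))
    p <- rep(NA_real_, length(es))
    if (n_perm > 0L) {
      perm_es <- matrix(NA_real_, n_perm, ncol(x))
      for (b in seq_len(n_perm)) {
        perm_set <- logical(ng)
        perm_set[sample.int(ng, n_in)] <- TRUE
        perm_es[b, ] <- vapply(seq_len(ncol(x)), function(j)
          es_running_sum(x[, j], perm_set, alpha), numeric(1L))
      }
      for (j in seq_len(ncol(x)))
        p[j] <- (1 + sum(abs(perm_es[, j]) >= abs(es[j]))) / (n_perm + 1)
    }
    out[[nm]] <- data.frame(set = nm, sample = colnames(x),
                            es = es, nes = nes, p = p, fdr = NA_real_)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  ok <- !is.na(res$p)
  res$fdr[ok] <- stats::p.adjust(res$p[ok], method = "BH")
  structure(res, class = c("ssgsea_result", "data.frame"))
}

#' Running-sum enrichment score for one sample
#'
#' The ssGSEA kernel: genes sorted by decreasing expression (ties keep input
#' order), in-set steps proportional to rank-weight^alpha, out-of-set steps
#' uniform, ES = sum of the running difference. With `alpha = 0` on a 4-gene
#' universe whose top gene forms the set, the running values are
#' 1, 2/3, 1/3, 0, so ES = 2.
#'
#' @param expr numeric expression vector for one sample.
#' @param in_set logical vector marking set membership, same gene order.
#' @param alpha rank-weight exponent.
#' @return The enrichment score (a single number).
#' @export
ssgsea_es <- function(expr, in_set, alpha = 0.25) {
  if (!any(in_set)) stop("empty gene set")
  if (all(in_set)) stop("set covers the whole universe; decrement undefined")
  es_running_sum(expr, in_set, alpha)
}

# Running-sum enrichment score for one sample. expr: named expression vector;
# in_set: logical over the same gene order; alpha: rank-weight exponent.
es_running_sum <- function(expr, in_set, alpha) {
  ord <- order(expr, decreasing = TRUE)  # stable: ties keep row order
  n <- length(expr)
  in_ord <- in_set[ord]
  w <- (n - seq_len(n) + 1)^alpha
  inc <- ifelse(in_ord, w, 0)
  inc <- inc / sum(inc)
  dec <- ifelse(in_ord, 0, 1 / sum(!in_ord))
  sum(cumsum(inc - dec))
}

#' Screen gene sets for significant enrichment
#'
#' Retains comparisons passing all three thresholds: p below `p_max`, FDR
#' below `fdr_max`, and |NES| above `nes_min`.
#'
#' @param results an `ssgsea_result` (or any data.frame with p, fdr, nes).
#' @param p_max p-value threshold (default 0.05).
#' @param fdr_max FDR threshold (default 0.25).
#' @param nes_min |NES| threshold (default 1).
#' @return The subset of rows passing all thresholds.
#' @export
gene_set_screen <- function(results, p_max = 0.05, fdr_max = 0.25,
                            nes_min = 1) {
  if (nrow(results) == 0L) return(results)
  keep <- !is.na(results$p) & !is.na(results$fdr) & !is.na(results$nes) &
    results$p < p_max & results$fdr < fdr_max & abs(results$nes) > nes_min
  results[keep, , drop = FALSE]
}
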