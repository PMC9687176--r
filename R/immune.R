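#' Marker-based immune population scores
#'
#' Per sample and population, the arithmetic mean of the population's marker
#' genes on the log2(TPM+1) scale (the marker-mean construction popularized
#' by MCP-counter-style scoring). Markers absent from the matrix are dropped
#' and logged; a population with zero overlap is flagged missing (NA).
#'
#' @param m `expr_matrix`, log2(TPM+1) scale.
#' @param panel named list: population -> marker gene identifiers.
#' @return matrix of scores, populations x samples, with a
#'   `missing_markers` attribute naming dropped markers per population.
#' @export
population_scores <- function(m, panel) {
  stopifnot_log2p1(m)
  if (anyDuplicated(names(panel))) stop("population names must be unique")
  if (any(lengths(panel) == 0L)) stop("marker lists must be non-empty")
  x <- unclass(m)
  missing_log <- list()
  scores <- t(vapply(names(panel), function(pop) {
    present <- intersect(panel[[pop]], rownames(x))
    dropped <- setdiff(panel[[pop]], present)
    if (length(dropped)) missing_log[[pop]] <<- dropped
    if (length(present) == 0L) {
      warning("population '", pop, "' has no markers in the matrix; flagged missing")
      return(rep(NA_real_, ncol(x)))
    }
    colMeans(x[present, , drop = FALSE])
  }, numeric(ncol(x))))
  colnames(scores) <- colnames(x)
  attr(scores, "missing_markers") <- missing_log
  scores
}

#' Compare population scores between two groups
#'
#' Per population: mean, SD per group and a two-sided p-value from Welch's
#' t-test (default) or the Wilcoxon rank-sum test; paired mode for matched
#' pre/post designs.
#'
#' @param scores population x sample score matrix from
#'   [population_scores()].
#' @param grouping named group vector over the samples (exactly 2 levels).
#' @param test `"welch"` or `"ranksum"`.
#' @param paired match samples by name across the two groups (requires equal
#'   group sizes with identical sample-name suffixes after stripping the
#'   group; here, identical ordering of the two groups' columns).
#' @return data.frame: population, group means and SDs, p.
#' @export
compare_groups <- function(scores, grouping, test = c("welch", "ranksum"),
                           paired = FALSE) {
  test <- match.arg(test)
  grouping <- grouping[colnames(scores)]
  if (any(is.na(grouping))) stop("grouping lacks some samples")
  lv <- unique(as.character(grouping))
  if (length(lv) != 2L) stop("grouping must have exactly 2 levels")
  a <- colnames(scores)[grouping == lv[1L]]
  b <- colnames(scores)[grouping == lv[2L]]
  if (length(a) < 2L || length(b) < 2L) stop("need >= 2 samples per group")
  if (paired && length(a) != length(b))
    stop("paired comparison requires matched groups of equal size")
  out <- lapply(rownames(scores), function(pop) {
    xa <- scores[pop, a]; xb <- scores[pop, b]
    p <- if (test == "welch") {
      stats::t.test(xa, xb, paired = paired)$p.value
    } else {
      suppressWarnings(stats::wilcox.test(xa, xb, paired = paired,
                                          exact = FALSE)$p.value)
    }
    data.frame(population = pop,
               group1 = lv[1L], mean1 = mean(xa), sd1 = stats::sd(xa),
               group2 = lv[2L], mean2 = mean(xb), sd2 = stats::sd(xb),
               p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Clonotype richness and Shannon diversity
#'
#' Per sample and receptor: richness = number of distinct clonotypes;
#' Shannon score = -sum p_i log p_i with natural log (so k equal clonotypes
#' score log k, and a single clonotype scores 0).
#'
#' @param clonotypes a `clonotype_table`.
#' @return data.frame: sample, receptor, richness, shannon.
#' @export
clonotype_stats <- function(clonotypes) {
  if (any(clonotypes$count < 1)) stop("clonotype counts must be positive")
  key <- interaction(clonotypes$sample, clonotypes$receptor, drop = TRUE)
  out <- lapply(split(clonotypes, key), function(d) {
    p <- d$count / sum(d$count)
    data.frame(sample = d$sample[1L], receptor = d$receptor[1L],
               richness = nrow(d), shannon = -sum(p * log(p)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$sample, res$receptor), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Compare a list of genes between two groups
#'
#' Per listed gene present in the matrix: two-sided Wilcoxon rank-sum
#' comparison with Benjamini-Hochberg correction across the listed genes.
#' Absent genes are reported and skipped.
#'
#' @param m `expr_matrix`, log2(TPM+1) scale.
#' @param genes character vector of gene identifiers (e.g., immunoregulatory
#'   genes).
#' @param grouping named 2-level group vector over samples.
#' @return data.frame: gene, group means, p, fdr; with a `skipped` attribute
#'   naming absent genes.
#' @export
gene_panel_compare <- function(m, genes, grouping) {
  stopifnot_log2p1(m)
  present <- intersect(genes, rownames(m))
  skipped <- setdiff(genes, present)
  if (length(skipped))
    message("skipping ", length(skipped), " absent gene(s): ",
            paste(utils::head(skipped, 5L), collapse = ", "))
  if (length(present) == 0L) {
    res <- data.frame(gene = character(), mean1 = numeric(),
                      mean2 = numeric(), p = numeric(), fdr = numeric())
    attr(res, "skipped") <- skipped
    return(res)
  }
  grouping <- grouping[colnames(m)]
  lv <- unique(as.character(grouping))
  if (length(lv) != 2L) stop("grouping must have exactly 2 levels")
  x <- unclass(m)
  ga <- grouping == lv[1L]; gb <- grouping == lv[2L]
  res <- do.call(rbind, lapply(present, function(g) {
    p <- suppressWarnings(
      stats::wilcox.test(x[g, ga], x[g, gb], exact = FALSE)$p.value)
    data.frame(gene = g, mean1 = mean(x[g, ga]), mean2 = mean(x[g, gb]),
               p = p, stringsAsFactors = FALSE)
  }))
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}
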