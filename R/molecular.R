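#' Tumor mutational burden
#'
#' Mutations per megabase: the sample's mutation count (all record classes,
#' substitutions and indels alike) divided by the callable exome size.
#'
#' @param catalog a `mutation_catalog`.
#' @param sample sample identifier.
#' @param callable_mb callable megabases (default 38, a conventional exome).
#' @return Mutations per Mb. A sample absent from the catalog scores 0 with
#'   a warning (absence is not distinguishable from zero mutations here).
#' @export
tmb <- function(catalog, sample, callable_mb = 38) {
  if (callable_mb <= 0) stop("callable_mb must be positive")
  k <- sum(catalog$sample == sample)
  if (k == 0L) warning("sample '", sample,
                       "' absent from catalog; TMB reported as 0")
  k / callable_mb
}

#' MATH intratumor-heterogeneity score
#'
#' Mutant-allele tumor heterogeneity: 100 x 1.4826 x median absolute
#' deviation of the variant allele fractions divided by their median. The
#' 1.4826 factor is the Gaussian consistency constant of the standard MATH
#' definition; `consistency = FALSE` drops it.
#'
#' @param vafs variant allele fractions in (0, 1].
#' @param consistency include the 1.4826 factor (default TRUE).
#' @return The MATH score, or NA (with a warning) for fewer than 3 VAFs.
#' @export
math_score <- function(vafs, consistency = TRUE) {
  vafs <- vafs[!is.na(vafs)]
  if (any(vafs <= 0 | vafs > 1)) stop("VAFs must be in (0, 1]")
  if (length(vafs) < 3L) {
    warning("MATH undefined for fewer than 3 VAFs")
    return(NA_real_)
  }
  med <- stats::median(vafs)
  mad_raw <- stats::median(abs(vafs - med))
  k <- if (consistency) 1.4826 else 1
  100 * k * mad_raw / med
}

#' Per-gene mutation frequency by subtype
#'
#' For each gene and subtype call, the fraction of samples of that subtype
#' with at least one mutation in the gene. Genes are ranked by pooled
#' frequency.
#'
#' @param catalog a `mutation_catalog`.
#' @param subtype_calls named `"positive"`/`"negative"` (or any grouping)
#'   vector with one call per cataloged sample.
#' @return data.frame: gene, one frequency column per subtype level, pooled
#'   frequency; ranked by pooled frequency, decreasing.
#' @export
mutation_frequency <- function(catalog, subtype_calls) {
  miss <- setdiff(unique(catalog$sample), names(subtype_calls))
  if (length(miss))
    stop("no subtype call for sample(s): ",
         paste(utils::head(miss, 5L), collapse = ", "))
  levels <- sort(unique(as.character(subtype_calls)))
  genes <- sort(unique(catalog$gene))
  hit <- unique(catalog[, c("sample", "gene")])
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (lv in levels) {
    members <- names(subtype_calls)[subtype_calls == lv]
    nlv <- length(members)
    cnt <- table(factor(hit$gene[hit$sample %in% members], levels = genes))
    out[[lv]] <- if (nlv > 0L) as.numeric(cnt) / nlv else NA_real_
  }
  n_all <- length(subtype_calls)
  cnt_all <- table(factor(hit$gene[hit$sample %in% names(subtype_calls)],
                          levels = genes))
  out$pooled <- as.numeric(cnt_all) / n_all
  out <- out[order(-out$pooled, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' 96-context catalog for one sample
#'
#' Counts the sample's single-base substitutions over the canonical
#' pyrimidine-strand 96-category ordering of [context_labels()]. Records
#' without a context (e.g., indels) are excluded: signature analysis uses
#' substitutions only, while [tmb()] counts every record.
#'
#' @param catalog a `mutation_catalog`.
#' @param sample sample identifier.
#' @return Named integer vector of length 96.
#' @export
context_catalog <- function(catalog, sample) {
  sel <- catalog$sample == sample & !is.na(catalog$context) &
    nzchar(catalog$context)
  tab <- table(factor(catalog$context[sel], levels = context_labels()))
  stats::setNames(as.integer(tab), context_labels())
}

#' Refit mutational-signature exposures by non-negative least squares
#'
#' Fits a 96-context count vector as a nonnegative combination of
#' column-stochastic signature profiles (NNLS via
#' [pracma::lsqnonneg()]); exposures are normalized to fractions and the
#' residual is the Euclidean norm of the unexplained counts.
#'
#' @param vector named 96-vector of context counts.
#' @param sigs 96 x k column-stochastic signature matrix, rows in
#'   [context_labels()] order.
#' @return list of class `signature_refit`: `exposures` (fractions summing
#'   to 1), `residual`, `flag` (`"ok"` or `"empty_catalog"`).
#' @export
refit_signatures <- function(vector, sigs) {
  sigs <- as.matrix(sigs)
  if (nrow(sigs) != 96L) stop("signature matrix must have 96 rows")
  csum <- colSums(sigs)
  if (any(abs(csum - 1) > 1e-6))
    stop("signature columns must each sum to 1")
  if (any(sigs < 0)) stop("signature entries must be nonnegative")
  if (length(vector) != 96L) stop("context vector must have length 96")
  if (!is.null(names(vector)) &&
      !identical(names(vector), rownames(sigs)) &&
      !is.null(rownames(sigs)))
    vector <- vector[rownames(sigs)]
  if (sum(vector) == 0) {
    warning("all-zero context vector; exposures undefined")
    return(structure(list(exposures = stats::setNames(
      rep(NA_real_, ncol(sigs)), colnames(sigs)),
      residual = NA_real_, flag = "empty_catalog"),
      class = "signature_refit"))
  }
  fit <- pracma::lsqnonneg(sigs, as.numeric(vector))
  x <- fit$x
  exposures <- x / sum(x)
  residual <- sqrt(sum((sigs %*% x - vector)^2))
  structure(list(exposures = stats::setNames(exposures, colnames(sigs)),
                 residual = residual, flag = "ok"),
            class = "signature_refit")
}

#' Per-sample molecular profile
#'
#' Convenience wrapper computing TMB, MATH and signature exposures for every
#' sample in a catalog.
#'
#' @param catalog a `mutation_catalog`.
#' @param sigs optional signature matrix for refitting.
#' @param callable_mb callable megabases for TMB.
#' @return data.frame with sample, tmb, math, and one exposure column per
#'   signature when `sigs` is supplied.
#' @export
molecular_profile <- function(catalog, sigs = NULL, callable_mb = 38) {
  samples <- sort(unique(catalog$sample))
  out <- data.frame(sample = samples, stringsAsFactors = FALSE)
  out$tmb <- vapply(samples, function(s) tmb(catalog, s, callable_mb),
                    numeric(1L))
  out$math <- vapply(samples, function(s) {
    v <- catalog$vaf[catalog$sample == s]
    if (length(v) < 3L) NA_real_ else math_score(v)
  }, numeric(1L))
  if (!is.null(sigs)) {
    ex <- t(vapply(samples, function(s)
      refit_signatures(context_catalog(catalog, s), sigs)$exposures,
      numeric(ncol(sigs))))
    colnames(ex) <- colnames(sigs)
    out <- cbind(out, as.data.frame(ex))
  }
  rownames(out) <- NULL
  out
}
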