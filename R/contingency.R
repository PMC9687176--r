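#' Exact and asymptotic contingency-table tests
#'
#' Two-sided test of independence for an r x c table of counts, with the
#' dispatch rule used throughout clinical tables of this kind:
#' \itemize{
#'   \item 2 x 2 with any expected count < 5 or total n < 40: Fisher's exact
#'     test, two-sided p = sum of hypergeometric probabilities of all tables
#'     (fixed margins) no more probable than the observed one;
#'   \item larger tables with small counts (same smallness rule):
#'     Freeman-Halton exact test by full enumeration of fixed-margin tables
#'     when their number is at most `enumeration_limit`, else seeded
#'     Monte-Carlo;
#'   \item otherwise: Pearson chi-square (no continuity correction).
#' }
#' "No more probable" uses the standard relative tolerance (1 + 1e-7) so
#' ties in floating point are counted.
#'
#' @param table integer matrix of nonnegative counts, at least 2 x 2.
#' @param enumeration_limit max number of fixed-margin tables enumerated
#'   exactly (default 1e6).
#' @param mc_draws Monte-Carlo draws beyond the limit (default 1e5).
#' @param seed seed for the Monte-Carlo fallback.
#' @return list of class `contingency_result`: `table`, `test_used`
#'   (`"fisher_2x2"`, `"freeman_halton"`, `"chi_square"`), `statistic`
#'   (chi-square statistic, NA for exact tests), `p`, and `method_detail`.
#' @export
contingency_test <- function(table, enumeration_limit = 1e6,
                             mc_draws = 1e5, seed = 1L) {
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != round(tab)) || any(!is.finite(tab)))
    stop("table must contain nonnegative integer counts")
  if (nrow(tab) < 2L || ncol(tab) < 2L) stop("table must be at least 2 x 2")
  storage.mode(tab) <- "double"
  n <- sum(tab)
  if (n == 0) stop("table is all zeros")
  rs <- rowSums(tab); cs <- colSums(tab)
  expected <- outer(rs, cs) / n
  small <- any(expected < 5) || n < 40
  if (nrow(tab) == 2L && ncol(tab) == 2L && small) {
    p <- fisher_2x2_p(tab)
    return(structure(list(table = tab, test_used = "fisher_2x2",
                          statistic = NA_real_, p = p,
                          method_detail = "full hypergeometric enumeration"),
                     class = "contingency_result"))
  }
  if (small) {
    res <- freeman_halton_p(tab, enumeration_limit, mc_draws, seed)
    return(structure(list(table = tab, test_used = "freeman_halton",
                          statistic = NA_real_, p = res$p,
                          method_detail = res$detail),
                     class = "contingency_result"))
  }
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  structure(list(table = tab, test_used = "chi_square",
                 statistic = stat,
                 p = stats::pchisq(stat, df, lower.tail = FALSE),
                 method_detail = sprintf("Pearson chi-square, df = %d", df)),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("contingency_test: %s, p = %.4g (%s)\n",
              x$test_used, x$p, x$method_detail))
  invisible(x)
}

# Two-sided Fisher exact p for a 2x2 table: enumerate the hypergeometric
# support of cell (1,1) at fixed margins and sum probabilities <= observed.
fisher_2x2_p <- function(tab) {
  r1 <- sum(tab[1L, ]); c1 <- sum(tab[, 1L]); n <- sum(tab)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  support <- lo:hi
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1L, 1L], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# log multivariate-hypergeometric probability of a fixed-margin table
log_table_prob <- function(tab, rs, cs, n) {
  sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(n + 1) -
    sum(lgamma(tab + 1))
}

# Freeman-Halton exact p for an r x c table: enumerate all tables with the
# observed margins (row-major recursion) and sum probabilities <= observed.
# Beyond enumeration_limit tables, fall back to seeded Monte-Carlo using
# r2dtable (uniform over fixed-margin tables via Patefield's algorithm).
freeman_halton_p <- function(tab, enumeration_limit, mc_draws, seed) {
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  lp_obs <- log_table_prob(tab, rs, cs, n)
  tol <- log(1 + 1e-7)
  env <- new.env()
  env$p <- 0; env$count <- 0L; env$overflow <- FALSE
  nr <- length(rs); nc <- length(cs)
  # fill rows 1..nr-1 cell by cell; last row forced by column remainders
  recurse <- function(row, col, col_left, row_left, lp_acc) {
    if (env$overflow) return(invisible())
    if (row == nr) {
      # last row determined
      env$count <- env$count + 1L
      if (env$count > enumeration_limit) { env$overflow <- TRUE; return(invisible()) }
      lp <- lp_acc - sum(lgamma(col_left + 1))
      if (lp <= lp_obs + tol) env$p <- env$p + exp(lp)
      return(invisible())
    }
    if (col == nc) {
      # last cell of the row is forced by the row remainder
      if (row_left > col_left[nc]) return(invisible())
      cl <- col_left; cl[nc] <- cl[nc] - row_left
      recurse(row + 1L, 1L, cl, rs[row + 1L],
              lp_acc - lgamma(row_left + 1))
      return(invisible())
    }
    # cell (row, col): bounded by the column remainder and by having to fit
    # the rest of the row into the later columns
    lo <- max(0, row_left - if (col < nc) sum(col_left[(col + 1L):nc]) else 0)
    hi <- min(row_left, col_left[col])
    if (lo > hi) return(invisible())
    for (x in lo:hi) {
      cl <- col_left; cl[col] <- cl[col] - x
      recurse(row, col + 1L, cl, row_left - x, lp_acc - lgamma(x + 1))
    }
    invisible()
  }
  lp_base <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(n + 1)
  recurse(1L, 1L, cs, rs[1L], lp_base)
  if (!env$overflow)
    return(list(p = min(env$p, 1),
                detail = sprintf("full enumeration of %d fixed-margin tables",
                                 env$count)))
  # Monte-Carlo fallback
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  draws <- stats::r2dtable(mc_draws, rs, cs)
  lps <- vapply(draws, log_table_prob, numeric(1L), rs = rs, cs = cs, n = n)
  hits <- sum(lps <= lp_obs + tol)
  list(p = (1 + hits) / (mc_draws + 1),
       detail = sprintf("Monte-Carlo over %d fixed-margin tables", mc_draws))
}
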