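# Small in-code fixtures shared across test files.

# tiny expression matrix on the log2(TPM+1) scale
tiny_expr <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  if (!is.null(genes)) rownames(m) <- genes
  if (!is.null(samples)) colnames(m) <- samples
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  expr_matrix(m, transform = "log2p1")
}

# a quick small calibration cohort for unit tests (defaults are the study
# conditions; shrink only the background so tests stay fast)
small_cohort <- function(seed = 1, n = 120) {
  spec <- cohort_spec(n_samples = n, n_background_genes = 20, seed = seed)
  list(spec = spec, cohort = generate_cohort(spec))
}

# the BJIM counts table shipped as plain text with the package
bjim_counts <- function() {
  path <- system.file("extdata", "bjim_table1.tsv", package = "pairsig")
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

bjim_matrix <- function(tab, what) {
  sub <- tab[tab$characteristic == what, ]
  m <- as.matrix(sub[, c("positive", "negative")])
  rownames(m) <- sub$level
  m
}

# independent brute-force oracle for the two-sided Fisher 2x2 p-value:
# binomial-coefficient route over the hypergeometric support
oracle_fisher_2x2 <- function(a, r1, c1, n) {
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  x <- lo:hi
  lp <- lchoose(r1, x) + lchoose(n - r1, c1 - x) - lchoose(n, c1)
  p_obs <- lp[x == a]
  sum(exp(lp[lp <= p_obs + log(1 + 1e-7)]))
}

# independent brute-force oracle for r x c exact p: expand.grid over every
# cell of the first r-1 rows, filter to the observed margins, sum
# multivariate hypergeometric probabilities <= observed
oracle_exact_rxc <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  nr <- nrow(tab); nc <- ncol(tab)
  free <- expand.grid(rep(list(0:max(rs[-nr])), (nr - 1L) * nc))
  logp <- function(m) {
    sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(n + 1) -
      sum(lgamma(m + 1))
  }
  lp_obs <- logp(tab)
  total <- 0
  for (i in seq_len(nrow(free))) {
    top <- matrix(as.numeric(free[i, ]), nrow = nr - 1L, ncol = nc)
    if (any(rowSums(top) != rs[-nr])) next
    last <- cs - colSums(top)
    if (any(last < 0)) next
    m <- rbind(top, last)
    lp <- logp(m)
    if (lp <= lp_obs + log(1 + 1e-7)) total <- total + exp(lp)
  }
  total
}
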