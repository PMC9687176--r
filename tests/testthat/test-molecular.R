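make_catalog <- function(samples, genes, vafs, contexts = NULL) {
  n <- length(samples)
  if (is.null(contexts)) contexts <- rep("A[C>T]G", n)
  structure(data.frame(sample = samples, gene = genes, vaf = vafs,
                       ref = "C", alt = "T", context = contexts,
                       substitution = substr(contexts, 3, 5),
                       is_coding = 1L, stringsAsFactors = FALSE),
            class = c("mutation_catalog", "data.frame"))
}

test_that("TMB is the per-Mb count, additive, and guards its denominator", {
  cat_ <- make_catalog(rep("S1", 76), "TP53", rep(0.3, 76))
  expect_equal(tmb(cat_, "S1", 38), 2.0)
  expect_warning(z <- tmb(cat_, "S2", 38), "absent")
  expect_equal(z, 0)
  expect_error(tmb(cat_, "S1", 0), "positive")
  # additivity over disjoint catalogs
  a <- make_catalog(rep("S1", 10), "A", rep(0.2, 10))
  b <- make_catalog(rep("S1", 5), "B", rep(0.4, 5))
  ab <- make_catalog(rep("S1", 15), c(rep("A", 10), rep("B", 5)),
                     c(rep(0.2, 10), rep(0.4, 5)))
  expect_equal(tmb(ab, "S1", 38), tmb(a, "S1", 38) + tmb(b, "S1", 38))
})

test_that("MATH matches the scaled-MAD formula and its invariances", {
  expect_equal(round(math_score(c(0.1, 0.2, 0.3, 0.4, 0.5)), 2), 49.42)
  expect_equal(math_score(rep(0.3, 5)), 0)
  set.seed(20)
  for (i in 1:50) {
    v <- stats::runif(sample(3:30, 1), 0.01, 0.99)
    direct <- 100 * 1.4826 * stats::median(abs(v - stats::median(v))) /
      stats::median(v)
    expect_equal(math_score(v), direct, tolerance = 1e-12)
    c_ <- stats::runif(1, 0.1, 1 / max(v))
    expect_equal(math_score(c_ * v), math_score(v), tolerance = 1e-9)
  }
  expect_warning(out <- math_score(c(0.2, 0.3)), "fewer than 3")
  expect_true(is.na(out))
  expect_error(math_score(c(0.2, 1.5, 0.1)), "VAFs")
})

test_that("mutation frequency is the per-subtype mutated fraction, ranked", {
  # MUC16 mutated in 9 of 55 positive samples -> 16.4%
  pos <- sprintf("P%02d", 1:55)
  neg <- sprintf("N%02d", 1:48)
  calls <- stats::setNames(c(rep("positive", 55), rep("negative", 48)),
                           c(pos, neg))
  muts <- make_catalog(c(pos[1:9], neg[1:5], pos[1:20]),
                       c(rep("MUC16", 14), rep("TP53", 20)),
                       rep(0.3, 34))
  freq <- mutation_frequency(muts, calls)
  muc <- freq[freq$gene == "MUC16", ]
  expect_equal(round(100 * muc$positive, 1), 16.4)
  expect_equal(round(100 * muc$negative, 1), 10.4)
  # ranked by pooled frequency: TP53 (20/103) above MUC16 (14/103)
  expect_identical(freq$gene, c("TP53", "MUC16"))
  # a gene absent from the catalog scores 0 in both groups
  muts2 <- rbind(muts, make_catalog("P01", "RARE", 0.2))
  class(muts2) <- class(muts)
  freq2 <- mutation_frequency(muts2, calls)
  expect_equal(freq2$negative[freq2$gene == "RARE"], 0)
  # every sample mutated -> 100% in both groups
  all_mut <- make_catalog(c(pos, neg), "TTN", rep(0.5, 103))
  f3 <- mutation_frequency(all_mut, calls)
  expect_equal(f3$positive, 1)
  expect_equal(f3$negative, 1)
})

test_that("signature refitting recovers mixtures and is scale invariant", {
  sigs <- pairsig:::synthetic_signature_matrix()
  # degenerate single-signature catalog
  v <- round(100 * sigs[, "SigA"])
  names(v) <- rownames(sigs)
  fit <- refit_signatures(v, sigs)
  expect_equal(unname(fit$exposures["SigA"]), 1, tolerance = 1e-9)
  # exact 60/40 mixture
  v2 <- 1000 * (0.6 * sigs[, "SigA"] + 0.4 * sigs[, "SigB"])
  fit2 <- refit_signatures(v2, sigs)
  expect_equal(unname(fit2$exposures), c(0.6, 0.4), tolerance = 1e-6)
  expect_lt(fit2$residual, 1e-8)
  # scaling the counts leaves exposures unchanged
  fit3 <- refit_signatures(7.3 * v2, sigs)
  expect_equal(fit3$exposures, fit2$exposures, tolerance = 1e-9)
  # all-zero vector flagged
  expect_warning(z <- refit_signatures(rep(0, 96), sigs), "all-zero")
  expect_identical(z$flag, "empty_catalog")
  expect_error(refit_signatures(v2, sigs * 2), "sum to 1")
})

test_that("context catalog counts substitutions in the canonical order", {
  ctx <- context_labels()
  expect_length(ctx, 96)
  expect_false(anyDuplicated(ctx) > 0)
  cat_ <- make_catalog(rep("S1", 3), "X", rep(0.3, 3),
                       contexts = c("A[C>T]G", "A[C>T]G", "T[T>G]C"))
  v <- context_catalog(cat_, "S1")
  expect_equal(sum(v), 3)
  expect_equal(unname(v["A[C>T]G"]), 2L)
  expect_equal(unname(v["T[T>G]C"]), 1L)
})
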