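test_that("well-separated synthetic clusters are recovered", {
  skip_if_not_installed("mclust")
  spec <- cohort_spec(n_samples = 150, panel_cluster_shift = 3,
                      noise_sd = 0.3, seed = 2)
  ge <- generate_expression(spec)
  a <- hierarchical_cluster(ge$expr, panel_genes(spec), k = 3)
  expect_gte(mclust::adjustedRandIndex(a$labels, ge$labels), 0.9)
})

test_that("clustering degenerate cases and equivariance hold", {
  co <- small_cohort(seed = 4, n = 12)
  m <- co$cohort$expr
  pg <- panel_genes(co$spec)
  # k = n: every sample its own cluster
  a <- hierarchical_cluster(m, pg, k = ncol(m))
  expect_equal(sort(unname(a$labels)), 1:ncol(m))
  # duplicated columns co-cluster (zero-distance pairs merge first)
  x <- unclass(m)
  dup <- cbind(x, x)
  colnames(dup) <- c(paste0(colnames(x), "_a"), paste0(colnames(x), "_b"))
  ad <- hierarchical_cluster(expr_matrix(dup, "log2p1"), pg, k = ncol(x))
  expect_identical(unname(ad$labels[paste0(colnames(x), "_a")]),
                   unname(ad$labels[paste0(colnames(x), "_b")]))
  # permuting sample order permutes the partition identically
  skip_if_not_installed("mclust")
  perm <- rev(seq_len(ncol(m)))
  ap <- hierarchical_cluster(expr_matrix(x[, perm], "log2p1"), pg, k = 3)
  a3 <- hierarchical_cluster(m, pg, k = 3)
  expect_equal(mclust::adjustedRandIndex(ap$labels[colnames(m)],
                                         a3$labels), 1)
  # error contracts
  expect_error(hierarchical_cluster(m, pg, k = ncol(m) + 1), "fewer samples")
  expect_error(hierarchical_cluster(m, c("absent1", "absent2"), k = 2),
               "overlap")
})

test_that("worst cluster is designated by shortest KM median survival", {
  # three clusters with medians 9.4 (A), 13.6 (B), 13.0 (C), all events
  mk <- function(med, n = 20) med * stats::qexp(stats::ppoints(n)) / log(2)
  labels <- rep(c(1, 2, 3), each = 20)
  names(labels) <- sprintf("P%02d", 1:60)
  clin <- as_clinical(data.frame(
    sample = names(labels),
    os_time = c(mk(9.4), mk(13.6), mk(13.0)),
    os_event = 1L))
  assign <- structure(list(labels = labels, tree = NULL,
                           params = list(k = 3), worst = NA_integer_),
                      class = "cluster_assignment")
  out <- designate_worst(assign, clin)
  expect_true(all(out$labels[1:20] == 3))
  expect_match(out$relabel_log, "cluster 1 designated worst")
  # complete tie: lowest original label becomes the worst label
  clin2 <- clin; clin2$os_time <- rep(mk(10), 3)
  out2 <- designate_worst(assign, clin2)
  expect_true(all(out2$labels[1:20] == 3))
  # single cluster is an error
  assign1 <- assign; assign1$labels[] <- 1
  expect_error(designate_worst(assign1, clin), "two clusters")
})

test_that("ssGSEA matches the hand-enumerated toy and is rank-invariant", {
  # 4-gene universe, set = top-ranked gene, alpha = 0:
  # running values 1, 2/3, 1/3, 0 so ES = 2
  expect_equal(ssgsea_es(c(4, 3, 2, 1), c(TRUE, FALSE, FALSE, FALSE),
                         alpha = 0), 2)
  expect_error(ssgsea_es(c(1, 2), c(TRUE, TRUE), 0), "whole universe")

  m <- tiny_expr(matrix(c(5, 4, 3, 2, 1, 8, 2, 7, 1, 3), 5, 2),
                 genes = paste0("g", 1:5))
  sets <- list(top = c("g1", "g2"))
  r1 <- ssgsea(m, sets, alpha = 0.25, n_perm = 0)
  # monotone transform of one sample leaves its ES unchanged
  x <- unclass(m); x[, 2] <- x[, 2]^3
  r2 <- ssgsea(expr_matrix(x, "log2p1"), sets, alpha = 0.25, n_perm = 0)
  expect_equal(r1$es, r2$es)
  # whole-universe set is an error; sub-overlap set flagged missing
  expect_error(ssgsea(m, list(all = paste0("g", 1:5)), n_perm = 0),
               "whole matrix")
  expect_warning(r3 <- ssgsea(m, list(tiny = "g1"), n_perm = 0), "flagged")
  expect_true(all(is.na(r3$es)))
})

test_that("ssGSEA permutation p-values are seeded and screened correctly", {
  co <- small_cohort(seed = 8, n = 30)
  m <- co$cohort$expr
  sets <- list(panel = panel_genes(co$spec)[1:10])
  r1 <- ssgsea(m, sets, n_perm = 50, seed = 3)
  r2 <- ssgsea(m, sets, n_perm = 50, seed = 3)
  expect_identical(r1, r2)
  expect_true(all(r1$fdr >= r1$p, na.rm = TRUE))

  screen_in <- data.frame(set = "a", sample = "s", es = 1,
                          nes = 1.5, p = 0.01, fdr = 0.10)
  screen_out <- data.frame(set = "b", sample = "s", es = 1,
                           nes = 0.5, p = 0.01, fdr = 0.10)
  expect_equal(nrow(gene_set_screen(rbind(screen_in, screen_out))), 1L)
  expect_identical(gene_set_screen(rbind(screen_in, screen_out))$set, "a")
  empty <- screen_in[0, ]
  expect_equal(nrow(gene_set_screen(empty)), 0L)
})
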