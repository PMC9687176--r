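test_that("median dichotomization follows the strict-exceedance tie rule", {
  m <- tiny_expr(matrix(c(1, 2, 3, 4), 1, 4), genes = "g")
  expect_equal(unname(median_dichotomize(m, "g")), c("lo", "lo", "hi", "hi"))
  m2 <- tiny_expr(matrix(c(5, 5, 5), 1, 3), genes = "g")
  expect_equal(unname(median_dichotomize(m2, "g")), rep("lo", 3))
  m3 <- tiny_expr(matrix(c(1, 2, 3), 1, 3), genes = "g")
  expect_equal(unname(median_dichotomize(m3, "g")), c("lo", "lo", "hi"))
  expect_error(median_dichotomize(m, "absent"), "absent")
})

test_that("differential expression flags planted markers and nulls", {
  co <- small_cohort(seed = 6, n = 150)
  ch <- co$cohort
  a <- designate_worst(hierarchical_cluster(ch$expr, panel_genes(co$spec)),
                       ch$clinical)
  de <- differential_expression(ch$expr, a, panel_genes(co$spec))
  expect_identical(de$direction[de$gene == "MARKER_UP"], "up")
  expect_identical(de$direction[de$gene == "MARKER_DN"], "down")
  ups <- de[de$direction == "up", ]
  expect_identical(ups$gene[which.min(ups$fdr)], "MARKER_UP")
  # a constant gene: zero fold change, ns
  x <- unclass(ch$expr); x["BG0001", ] <- 3
  de2 <- differential_expression(expr_matrix(x, "log2p1"), a, "BG0001")
  expect_equal(de2$log2_fold_change, 0)
  expect_identical(de2$direction, "ns")
  # shuffled labels: no fdr-significant panel genes for a fixed seed
  set.seed(1)
  a_null <- a; a_null$labels[] <- sample(a$labels)
  de3 <- differential_expression(ch$expr, a_null, panel_genes(co$spec))
  expect_lte(mean(de3$fdr < 0.05), 0.02)
})

test_that("pair search maximizes concordance with the worst cluster", {
  co <- small_cohort(seed = 2, n = 150)
  ch <- co$cohort
  a <- designate_worst(hierarchical_cluster(ch$expr, panel_genes(co$spec)),
                       ch$clinical)
  de <- differential_expression(ch$expr, a, panel_genes(co$spec))
  sig <- pair_search(ch$expr, de, a)
  expect_identical(sig$up_gene, "MARKER_UP")
  expect_identical(sig$down_gene, "MARKER_DN")
  expect_gte(sig$overall_consistency, 0.9)
  # row order of the DE table does not change the election
  set.seed(7)
  de_shuf <- de[sample(nrow(de)), ]
  sig2 <- pair_search(ch$expr, de_shuf, a)
  expect_identical(sig2$up_gene, sig$up_gene)
  expect_identical(sig2$down_gene, sig$down_gene)
  expect_equal(sig2$overall_consistency, sig$overall_consistency)
  # complement property: a call vector and its complement have
  # overall consistencies summing to 1
  is3 <- a$labels[names(sig$calls)] == a$worst
  pos <- sig$calls == "positive"
  expect_equal(mean(pos == is3) + mean(!pos == is3), 1)
  # errors
  de_no_up <- de; de_no_up$direction[de_no_up$direction == "up"] <- "ns"
  expect_error(pair_search(ch$expr, de_no_up, a), "at least one up")
})

test_that("a pair identical to the worst-cluster indicator scores 1.0", {
  is3 <- c(rep(FALSE, 6), rep(TRUE, 3))
  up <- ifelse(is3, 9, 1)         # hi exactly on cluster 3
  dn <- ifelse(is3, 1, 9)         # lo exactly on cluster 3
  m <- tiny_expr(rbind(UP = up, DN = dn, OTHER = seq(1, 2, length.out = 9)))
  labels <- ifelse(is3, 3L, 1L)
  names(labels) <- colnames(m)
  assign <- structure(list(labels = labels, params = list(k = 3), worst = 3L),
                      class = "cluster_assignment")
  de <- data.frame(gene = c("UP", "DN"), log2_fold_change = c(4, -4),
                   p = c(1e-5, 1e-5), fdr = c(1e-4, 1e-4),
                   direction = c("up", "down"))
  sig <- pair_search(m, de, assign)
  expect_equal(sig$overall_consistency, 1.0)
  expect_equal(sig$target_consistency, 1.0)
  # degenerate pair with empty positive set stays in the table at target 0
  de2 <- rbind(de, data.frame(gene = "OTHER", log2_fold_change = 2,
                              p = 1e-5, fdr = 1e-4, direction = "up"))
  x <- unclass(m); x["OTHER", ] <- ifelse(is3, 1, 9)  # hi never with DN lo
  expect_warning(sig2 <- pair_search(expr_matrix(x, "log2p1"), de2, assign),
                 "empty positive")
  row <- sig2$table[sig2$table$up == "OTHER", ]
  expect_equal(row$target_consistency, 0)
})

test_that("pair correlation and classification behave as documented", {
  set.seed(3)
  up <- stats::runif(50, 1, 9)
  m <- tiny_expr(rbind(UP = up, DN = 10 - up, CONST = rep(2, 50)))
  cp <- correlate_pair(m, "UP", "DN")
  expect_equal(cp$rho, -1)
  expect_identical(correlate_pair(m, "UP", "CONST")$flag, "constant")
  m2 <- tiny_expr(rbind(UP = c(1, 2), DN = c(2, 1)))
  expect_identical(correlate_pair(m2, "UP", "DN")$flag, "too_few_samples")

  calls <- classify_by_expression(m, "UP", "DN")
  expect_true(all(calls %in% c("positive", "negative")))
  # monotone: raising the up gene of a positive sample never flips it
  pos_sample <- names(calls)[calls == "positive"][1]
  cuts <- c(up = stats::median(up), down = stats::median(10 - up))
  x <- unclass(m); x["UP", pos_sample] <- x["UP", pos_sample] + 5
  calls2 <- classify_by_expression(expr_matrix(x, "log2p1"), "UP", "DN",
                                   cutoffs = cuts)
  expect_identical(unname(calls2[pos_sample]), "positive")
})

test_that("IHC composite and CPS scoring follow the clinical cut-offs", {
  up <- ihc_score(2, 3)    # composite 5 -> high
  dn <- ihc_score(1, 1)    # composite 2 -> low
  expect_identical(up$level, "high")
  expect_identical(dn$level, "low")
  expect_identical(classify_by_ihc(up, dn), "positive")
  # boundary: composite 3 is high
  expect_identical(ihc_score(1, 2)$level, "high")
  expect_error(ihc_score(4, 0), "0..3")

  cps <- cps_score(50, 200)
  expect_equal(cps$cps, 25)
  expect_identical(cps$status, "positive")
  expect_identical(cps_score(5, 200)$status, "negative")
  expect_identical(cps_score(20, 200)$status, "positive")  # cps = 10 boundary
})
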