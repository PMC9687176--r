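test_that("Kaplan-Meier estimator matches closed forms", {
  km <- km_fit(1:5, rep(1, 5))
  expect_equal(km$curves$surv, c(0.8, 0.6, 0.4, 0.2, 0))
  expect_equal(unname(km$medians), 3)
  # no censoring: S(t) equals the empirical fraction surviving beyond t
  set.seed(10)
  t <- stats::rexp(40)
  km2 <- km_fit(t, rep(1, 40))
  emp <- vapply(km2$curves$time, function(u) mean(t > u), numeric(1))
  expect_equal(km2$curves$surv, emp, tolerance = 1e-12)
  # two identical groups: log-rank statistic 0, p = 1
  km3 <- km_fit(c(t, t), rep(1, 80), rep(c("a", "b"), each = 40))
  expect_equal(km3$logrank_chisq, 0, tolerance = 1e-12)
  expect_equal(km3$logrank_p, 1)
  expect_error(km_fit(c(-1, 2), c(1, 1)), "negative")
})

test_that("contingency dispatch reproduces printed clinical p-values", {
  resp <- contingency_test(matrix(c(7, 7, 0, 7), 2, byrow = TRUE))
  expect_identical(resp$test_used, "fisher_2x2")
  expect_equal(round(resp$p, 3), 0.047)
  age <- contingency_test(matrix(c(3, 9, 4, 5), 2, byrow = TRUE))
  expect_equal(round(age$p, 3), 0.397)
  diff <- contingency_test(matrix(c(2, 6, 5, 7, 0, 1), 3, byrow = TRUE))
  expect_identical(diff$test_used, "freeman_halton")
  expect_equal(round(diff$p, 3), 0.762)
  expect_equal(contingency_test(matrix(c(2, 1, 1, 2), 2))$p, 1.0)
  # large balanced table goes asymptotic
  big <- contingency_test(matrix(c(30, 20, 20, 30), 2))
  expect_identical(big$test_used, "chi_square")
  expect_error(contingency_test(matrix(c(-1, 2, 3, 4), 2)), "nonnegative")
})

test_that("Fisher p is invariant under row/column swap and transpose", {
  set.seed(4)
  for (i in 1:20) {
    tab <- matrix(stats::rpois(4, 4), 2)
    if (sum(tab) == 0) next
    p <- contingency_test(tab)$p
    expect_equal(contingency_test(tab[2:1, ])$p, p, tolerance = 1e-12)
    expect_equal(contingency_test(tab[, 2:1])$p, p, tolerance = 1e-12)
    expect_equal(contingency_test(t(tab))$p, p, tolerance = 1e-12)
  }
})

test_that("Monte-Carlo fallback engages beyond the enumeration limit", {
  tab <- matrix(c(2, 6, 5, 7, 0, 1), 3, byrow = TRUE)
  mc <- contingency_test(tab, enumeration_limit = 3, mc_draws = 20000,
                         seed = 42)
  expect_match(mc$method_detail, "Monte-Carlo")
  expect_lt(abs(mc$p - 0.7616), 0.02)
})

test_that("binary AUC equals the rank statistic and trapezoid area", {
  # positives: 7 responders / 0 non; negatives: 7 / 7
  pred <- c(rep("positive", 7), rep("negative", 14))
  lab <- c(rep(1, 7), rep(1, 7), rep(0, 7))
  roc <- binary_auc(pred, lab)
  expect_equal(roc$auc, 0.750)
  expect_equal(binary_auc(rep(1, 21), lab)$auc, 0.5)
  expect_equal(binary_auc(lab, lab)$auc, 1.0)
  expect_error(binary_auc(pred, rep(1, 21)), "both label classes")
  # trapezoidal area under the operating points equals the rank AUC
  set.seed(5)
  score <- stats::rnorm(60)
  lab2 <- stats::rbinom(60, 1, 0.4)
  r <- binary_auc(score, lab2)
  pts <- r$points[order(r$points$fpr, r$points$tpr), ]
  trap <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                 utils::tail(pts$tpr, -1)) / 2)
  expect_equal(trap, r$auc, tolerance = 1e-12)
})

test_that("forward-LR Cox recovers signal and matches univariate fits", {
  set.seed(12)
  n <- 500
  x_true <- stats::rbinom(n, 1, 0.4)
  nulls <- matrix(stats::rnorm(n * 3), n,
                  dimnames = list(NULL, paste0("null", 1:3)))
  t <- stats::rexp(n, rate = 0.05 * exp(log(3) * x_true))
  clin <- as_clinical(data.frame(sample = paste0("P", 1:n),
                                 os_time = t, os_event = 1L,
                                 x_true = x_true, nulls))
  fit <- cox_forward_lr(clin, c("x_true", paste0("null", 1:3)), "OS")
  expect_true("x_true" %in% fit$variables)
  hr <- fit$summary$hr[fit$summary$term == "x_true"]
  expect_lt(abs(hr - 3) / 3, 0.2)
  # single binary covariate reproduces the univariate Cox HR
  uni <- cox_forward_lr(clin, "x_true", "OS")
  ref <- survival::coxph(survival::Surv(t, rep(1, n)) ~ x_true)
  expect_equal(uni$summary$hr, unname(exp(stats::coef(ref))),
               tolerance = 1e-8)
  # all-null candidates: empty model for this seed
  fit0 <- cox_forward_lr(clin, paste0("null", 1:3), "OS")
  expect_length(fit0$variables, 0)
  expect_equal(nrow(fit0$summary), 0L)
})

test_that("a covariate with exactly no effect is excluded at large n", {
  set.seed(99)
  n <- 5000
  x <- stats::rbinom(n, 1, 0.5)
  t <- stats::rexp(n, 0.05)   # hazard free of x
  clin <- as_clinical(data.frame(sample = paste0("P", 1:n),
                                 os_time = t, os_event = 1L, x = x))
  fit <- cox_forward_lr(clin, "x", "OS")
  expect_length(fit$variables, 0)
})

test_that("treated-vs-untreated comparison restricts to signature positives", {
  set.seed(31)
  mk <- function(n, prefix) {
    treated <- stats::rbinom(n, 1, 0.5)
    as_clinical(data.frame(
      sample = paste0(prefix, 1:n),
      rfs_time = stats::rexp(n, 0.08 * ifelse(treated == 1, 0.4, 1)),
      rfs_event = 1L, treated = treated))
  }
  a <- mk(60, "A"); b <- mk(60, "B")
  calls <- stats::setNames(rep(c("positive", "negative"), 60),
                           c(a$sample, b$sample))
  km <- compare_treated_untreated(a, b, calls)
  expect_s3_class(km, "km_fit")
  expect_equal(sum(km$curves$n_event), sum(calls == "positive"))
  # schema error when the treated flag is missing
  a2 <- a; a2$treated <- NULL
  expect_error(compare_treated_untreated(a2, b, calls), "treated")
  # no positives in one cohort
  calls2 <- calls; calls2[a$sample] <- "negative"
  expect_error(compare_treated_untreated(a, b, calls2), "no signature-positive")
})
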