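#' Kaplan-Meier fit with log-rank comparison
#'
#' Product-limit estimator per group via [survival::survfit()], group medians
#' (earliest time with survival <= 0.5; NA when the curve never crosses 0.5),
#' and, for two or more groups, the log-rank test via
#' [survival::survdiff()].
#'
#' @param times nonnegative follow-up times.
#' @param events 0/1 event indicators.
#' @param groups optional grouping vector; NULL fits a single curve.
#' @return list of class `km_fit`: `curves` (data.frame group, time, n_risk,
#'   n_event, surv), `medians` (named), `logrank_chisq`, `logrank_p` (NA for
#'   a single group), and the underlying `fit`.
#' @export
km_fit <- function(times, events, groups = NULL) {
  if (any(times < 0, na.rm = TRUE)) stop("negative survival times")
  if (!all(events %in% c(0, 1, NA))) stop("events must be 0/1")
  if (is.null(groups)) groups <- rep("all", length(times))
  if (length(times) != length(events) || length(times) != length(groups))
    stop("times, events and groups must have equal length")
  ok <- !is.na(times) & !is.na(events) & !is.na(groups)
  times <- times[ok]; events <- events[ok]; groups <- as.factor(groups[ok])
  if (any(table(groups) < 1L)) stop("empty group")
  df <- data.frame(times = times, events = events, groups = groups)
  fit <- survival::survfit(survival::Surv(times, events) ~ groups, data = df)
  strata <- if (is.null(fit$strata)) {
    rep(levels(groups)[1L], length(fit$time))
  } else {
    rep(sub("^groups=", "", names(fit$strata)), fit$strata)
  }
  curves <- data.frame(group = strata, time = fit$time,
                       n_risk = fit$n.risk, n_event = fit$n.event,
                       surv = fit$surv, stringsAsFactors = FALSE)
  tab <- summary(fit)$table
  if (is.null(dim(tab))) {
    medians <- stats::setNames(tab[["median"]], levels(groups)[1L])
  } else {
    medians <- stats::setNames(tab[, "median"],
                               sub("^groups=", "", rownames(tab)))
  }
  chisq <- NA_real_; p <- NA_real_
  if (nlevels(groups) >= 2L) {
    sd <- survival::survdiff(survival::Surv(times, events) ~ groups, data = df)
    chisq <- sd$chisq
    p <- stats::pchisq(chisq, df = nlevels(groups) - 1L, lower.tail = FALSE)
  }
  structure(list(curves = curves, medians = medians,
                 logrank_chisq = chisq, logrank_p = p, fit = fit),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat("km_fit medians:",
      paste(sprintf("%s = %.2f", names(x$medians), x$medians),
            collapse = ", "), "\n")
  if (!is.na(x$logrank_p))
    cat(sprintf("log-rank chi-square = %.3f, p = %.4g\n",
                x$logrank_chisq, x$logrank_p))
  invisible(x)
}

# fit a Cox model on selected variables; returns coxph fit or stops with step
fit_cox <- function(data, vars, step_label) {
  rhs <- if (length(vars)) paste(sprintf("`%s`", vars), collapse = " + ") else "1"
  f <- stats::as.formula(paste("survival::Surv(.time, .event) ~", rhs))
  fit <- tryCatch(
    survival::coxph(f, data = data),
    error = function(e) stop("Cox fit failed at ", step_label, ": ",
                             conditionMessage(e)),
    warning = function(w) {
      if (grepl("did not converge|infinite", conditionMessage(w)))
        stop("Cox fit did not converge at ", step_label)
      suppressWarnings(survival::coxph(f, data = data))
    })
  fit
}

model_ll <- function(fit) fit$loglik[length(fit$loglik)]
model_df <- function(fit) if (is.null(fit$coefficients)) 0L else length(fit$coefficients)

#' Forward stepwise Cox regression with likelihood-ratio entry and removal
#'
#' The "Forward:LR" procedure: starting from the empty model, at each step
#' the candidate with the smallest likelihood-ratio p-value enters if below
#' `p_enter`; after every entry, any included variable whose
#' likelihood-ratio removal p-value is at least `p_remove` leaves (worst
#' first); iterate to a fixed point. The final model reports hazard ratios
#' with Wald 95% confidence intervals and p-values; the full selection trace
#' is kept.
#'
#' @param clinical a `clinical_table` (or data.frame) with outcome columns
#'   and candidate covariates.
#' @param candidates character vector of covariate column names.
#' @param outcome `"OS"` (os_time/os_event) or `"RFS"` (rfs_time/rfs_event).
#' @param p_enter entry threshold (default 0.05, the SPSS Forward:LR
#'   convention).
#' @param p_remove removal threshold (default 0.10).
#' @return list of class `cox_model`: `variables`, `summary` (term, hr,
#'   ci_lower, ci_upper, p), `trace` (step, action, variable, lr_stat, df,
#'   p), `n_used`, and the final `fit` (NULL for an empty model).
#' @export
cox_forward_lr <- function(clinical, candidates, outcome = c("OS", "RFS"),
                           p_enter = 0.05, p_remove = 0.10) {
  outcome <- match.arg(outcome)
  if (length(candidates) < 1L) stop("need at least one candidate covariate")
  tm <- if (outcome == "OS") "os_time" else "rfs_time"
  ev <- if (outcome == "OS") "os_event" else "rfs_event"
  miss <- setdiff(c(tm, ev, candidates), names(clinical))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  data <- as.data.frame(clinical)[, c(tm, ev, candidates), drop = FALSE]
  names(data)[1:2] <- c(".time", ".event")
  cc <- stats::complete.cases(data)
  if (sum(!cc)) message(sum(!cc), " sample(s) dropped for missing values")
  data <- data[cc, , drop = FALSE]
  data[] <- lapply(data, function(col)
    if (is.character(col)) factor(col) else col)
  if (sum(data$.event) < 1L) stop("no events in the data")
  included <- character(0)
  trace <- list()
  step <- 0L
  cur_fit <- fit_cox(data, included, "null model")
  repeat {
    step <- step + 1L
    pool <- setdiff(candidates, included)
    if (length(pool) == 0L) break
    ll_cur <- model_ll(cur_fit); df_cur <- model_df(cur_fit)
    entry <- t(vapply(pool, function(v) {
      fit <- fit_cox(data, c(included, v), paste("entry of", v))
      lr <- 2 * (model_ll(fit) - ll_cur)
      df <- model_df(fit) - df_cur
      c(lr = lr, df = df, p = stats::pchisq(lr, df, lower.tail = FALSE))
    }, numeric(3L)))
    best <- which.min(entry[, "p"])
    if (entry[best, "p"] >= p_enter) break
    v_in <- pool[best]
    included <- c(included, v_in)
    cur_fit <- fit_cox(data, included, paste("entry of", v_in))
    trace[[length(trace) + 1L]] <-
      data.frame(step = step, action = "enter", variable = v_in,
                 lr_stat = entry[best, "lr"], df = entry[best, "df"],
                 p = entry[best, "p"], stringsAsFactors = FALSE)
    # backward removal sweep
    repeat {
      if (length(included) == 0L) break
      ll_full <- model_ll(cur_fit); df_full <- model_df(cur_fit)
      removal <- t(vapply(included, function(v) {
        fit <- fit_cox(data, setdiff(included, v), paste("removal of", v))
        lr <- 2 * (ll_full - model_ll(fit))
        df <- df_full - model_df(fit)
        c(lr = lr, df = df, p = stats::pchisq(lr, df, lower.tail = FALSE))
      }, numeric(3L)))
      worst <- which.max(removal[, "p"])
      if (removal[worst, "p"] < p_remove) break
      v_out <- included[worst]
      included <- setdiff(included, v_out)
      cur_fit <- fit_cox(data, included, paste("removal of", v_out))
      trace[[length(trace) + 1L]] <-
        data.frame(step = step, action = "remove", variable = v_out,
                   lr_stat = removal[worst, "lr"], df = removal[worst, "df"],
                   p = removal[worst, "p"], stringsAsFactors = FALSE)
    }
  }
  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(step = integer(), action = character(),
               variable = character(), lr_stat = numeric(),
               df = numeric(), p = numeric())
  if (length(included)) {
    sm <- summary(cur_fit)
    coefs <- sm$coefficients
    ci <- sm$conf.int
    tab <- data.frame(term = rownames(coefs),
                      hr = unname(coefs[, "exp(coef)"]),
                      ci_lower = unname(ci[, "lower .95"]),
                      ci_upper = unname(ci[, "upper .95"]),
                      p = unname(coefs[, "Pr(>|z|)"]),
                      stringsAsFactors = FALSE)
  } else {
    tab <- data.frame(term = character(), hr = numeric(),
                      ci_lower = numeric(), ci_upper = numeric(),
                      p = numeric())
    cur_fit <- NULL
  }
  structure(list(variables = included, summary = tab, trace = trace,
                 n_used = nrow(data), outcome = outcome, fit = cur_fit),
            class = "cox_model")
}

#' @export
print.cox_model <- function(x, ...) {
  cat(sprintf("cox_model (%s, forward LR): %d variable(s) retained, n = %d\n",
              x$outcome, length(x$variables), x$n_used))
  if (nrow(x$summary)) print(x$summary, digits = 3)
  invisible(x)
}

#' ROC and AUC for a predictor against a binary label
#'
#' AUC by the rank statistic with tie correction: the probability a random
#' positive scores above a random negative, plus half the probability of a
#' tie. For a binary predictor this equals (sensitivity + specificity) / 2
#' and the trapezoidal area under the two-point ROC.
#'
#' @param predictor per-sample scores; numeric, or character
#'   `"positive"`/`"negative"` (positive scored 1).
#' @param label 0/1 outcome (e.g., responder).
#' @return list of class `roc_result`: `points` (data.frame fpr, tpr
#'   including (0,0) and (1,1)) and `auc`.
#' @export
binary_auc <- function(predictor, label) {
  if (is.character(predictor) || is.factor(predictor)) {
    predictor <- as.character(predictor)
    if (!all(predictor %in% c("positive", "negative")))
      stop("character predictor must be 'positive'/'negative'")
    score <- as.numeric(predictor == "positive")
  } else score <- as.numeric(predictor)
  label <- as.integer(label)
  ok <- !is.na(score) & !is.na(label)
  score <- score[ok]; label <- label[ok]
  if (!all(label %in% c(0L, 1L))) stop("label must be 0/1")
  n1 <- sum(label == 1L); n0 <- sum(label == 0L)
  if (n1 == 0L || n0 == 0L) stop("both label classes must be present")
  r <- rank(score)
  auc <- (sum(r[label == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(score), decreasing = TRUE)
  pts <- t(vapply(thr, function(t) {
    pos <- score >= t
    c(fpr = sum(pos & label == 0L) / n0, tpr = sum(pos & label == 1L) / n1)
  }, numeric(2L)))
  points <- rbind(data.frame(fpr = 0, tpr = 0),
                  as.data.frame(pts),
                  data.frame(fpr = 1, tpr = 1))
  points <- unique(points[order(points$fpr, points$tpr), , drop = FALSE])
  rownames(points) <- NULL
  structure(list(points = points, auc = auc), class = "roc_result")
}

#' Relapse-free survival of signature-positive patients, treated vs untreated
#'
#' Pools two cohorts, restricts to signature-positive samples, groups by the
#' `treated` flag and runs [km_fit()] on relapse-free survival.
#'
#' @param clinical_a,clinical_b `clinical_table`s carrying `rfs_time`,
#'   `rfs_event` and a 0/1 `treated` column.
#' @param calls named `"positive"`/`"negative"` vector covering the samples
#'   of both cohorts.
#' @return A `km_fit` comparing treated vs untreated signature-positive
#'   patients.
#' @export
compare_treated_untreated <- function(clinical_a, clinical_b, calls) {
  for (nm in c("rfs_time", "rfs_event", "treated")) {
    if (!nm %in% names(clinical_a) || !nm %in% names(clinical_b))
      stop("both cohorts must carry column '", nm, "'")
  }
  for (cl in list(clinical_a, clinical_b)) {
    pos <- calls[cl$sample] == "positive"
    if (!any(pos, na.rm = TRUE))
      stop("a cohort has no signature-positive samples")
  }
  pooled <- rbind(as.data.frame(clinical_a)[, c("sample", "rfs_time",
                                                "rfs_event", "treated")],
                  as.data.frame(clinical_b)[, c("sample", "rfs_time",
                                                "rfs_event", "treated")])
  keep <- calls[pooled$sample] == "positive"
  pooled <- pooled[keep & !is.na(keep), , drop = FALSE]
  km_fit(pooled$rfs_time, pooled$rfs_event,
         ifelse(pooled$treated == 1, "treated", "untreated"))
}
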