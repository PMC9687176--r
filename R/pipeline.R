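#' Pipeline configuration
#'
#' Collects every tunable the discovery and validation runs use, with the
#' package defaults. All stochastic steps derive their seeds
#' deterministically from the single top-level `seed`.
#'
#' @param k number of expression clusters.
#' @param linkage hierarchical-clustering linkage.
#' @param fc_threshold,q_threshold differential-expression direction
#'   thresholds.
#' @param p_enter,p_remove forward-LR Cox entry/removal thresholds.
#' @param alpha ssGSEA rank-weight exponent.
#' @param n_perm ssGSEA permutation count.
#' @param callable_mb callable exome megabases for TMB.
#' @param seed top-level seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(k = 3L, linkage = "average",
                            fc_threshold = 1, q_threshold = 0.05,
                            p_enter = 0.05, p_remove = 0.10,
                            alpha = 0.25, n_perm = 1000L,
                            callable_mb = 38, seed = 1L) {
  structure(list(k = as.integer(k), linkage = linkage,
                 fc_threshold = fc_threshold, q_threshold = q_threshold,
                 p_enter = p_enter, p_remove = p_remove,
                 alpha = alpha, n_perm = as.integer(n_perm),
                 callable_mb = callable_mb, seed = as.integer(seed)),
            class = "pipeline_config")
}

write_stage_tsv <- function(df, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  utils::write.table(df, file.path(out_dir, paste0(name, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the discovery analysis end to end
#'
#' Subtype by hierarchical clustering on the panel, designate the
#' worst-prognosis cluster by Kaplan-Meier median overall survival, test
#' panel genes for differential expression against that cluster, elect the
#' two-gene pair by concordance maximization, and characterize the elected
#' signature against survival (log-rank by signature call, forward-LR Cox
#' over supplied covariates). When `out_dir` is given, per-stage TSVs and a
#' JSON manifest (config, seeds, stage list, package version) are written.
#'
#' @param expr `expr_matrix`, log2(TPM+1) scale.
#' @param clinical a `clinical_table` covering the expression samples.
#' @param panel character vector of panel gene identifiers.
#' @param covariates optional covariate column names for the Cox stage
#'   (signature call is always included as `signature`).
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return list of class `discovery_report`: `assignment`, `de`,
#'   `signature`, `km_by_signature`, `cox` (NULL when no covariates and too
#'   few events), `stages` (completed stage names), `manifest`.
#' @export
run_discovery <- function(expr, clinical, panel, covariates = character(0),
                          config = pipeline_config(), out_dir = NULL) {
  stopifnot_log2p1(expr)
  if (!inherits(clinical, "clinical_table")) clinical <- as_clinical(clinical)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  stages <- character(0)
  assign <- hierarchical_cluster(expr, panel, k = config$k,
                                 linkage = config$linkage)
  stages <- c(stages, "cluster")
  assign <- designate_worst(assign, clinical)
  stages <- c(stages, "designate_worst")
  de <- differential_expression(expr, assign, panel,
                                fc_threshold = config$fc_threshold,
                                q_threshold = config$q_threshold)
  stages <- c(stages, "differential_expression")
  sig <- pair_search(expr, de, assign)
  stages <- c(stages, "pair_search")
  idx <- match(names(sig$calls), clinical$sample)
  km <- km_fit(clinical$os_time[idx], clinical$os_event[idx], sig$calls)
  stages <- c(stages, "km_by_signature")
  cox <- NULL
  cl2 <- as.data.frame(clinical)
  cl2$signature <- as.character(sig$calls[match(cl2$sample,
                                                names(sig$calls))])
  cox <- cox_forward_lr(as_clinical(cl2), c("signature", covariates),
                        outcome = "OS",
                        p_enter = config$p_enter, p_remove = config$p_remove)
  stages <- c(stages, "cox_forward_lr")
  manifest <- list(config = unclass(config), stages = stages,
                   n_samples = ncol(expr),
                   elected_pair = c(up = sig$up_gene, down = sig$down_gene),
                   package_version = as.character(utils::packageVersion("pairsig")))
  if (!is.null(out_dir)) {
    write_stage_tsv(data.frame(sample = names(assign$labels),
                               cluster = assign$labels),
                    out_dir, "clusters")
    write_stage_tsv(de, out_dir, "differential_expression")
    write_stage_tsv(sig$table, out_dir, "pair_table")
    write_stage_tsv(data.frame(sample = names(sig$calls),
                               call = sig$calls),
                    out_dir, "signature_calls")
    write_stage_tsv(km$curves, out_dir, "km_by_signature")
    if (!is.null(cox)) write_stage_tsv(cox$summary, out_dir, "cox_summary")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  structure(list(assignment = assign, de = de, signature = sig,
                 km_by_signature = km, cox = cox, stages = stages,
                 manifest = manifest),
            class = "discovery_report")
}

#' Apply a frozen signature to a validation cohort
#'
#' Classifies samples with the trained pair (frozen medians when supplied,
#' else cohort medians), then runs whatever downstream stages the inputs
#' permit: response contingency table and AUC (when `response` is present),
#' Kaplan-Meier RFS by signature, molecular characterization (when a
#' mutation catalog is supplied) and immune comparisons (when immune inputs
#' are supplied). Stages skipped for missing inputs are listed in
#' `skipped`, never silently dropped.
#'
#' @param expr `expr_matrix`, log2(TPM+1) scale.
#' @param clinical a `clinical_table`.
#' @param up_gene,down_gene the frozen signature genes.
#' @param cutoffs optional frozen medians `c(up = , down = )`.
#' @param mutations optional `mutation_catalog`.
#' @param sigs optional signature matrix for refitting.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return list of class `validation_report`: `calls`, `response_test`,
#'   `auc`, `km_rfs`, `molecular`, `stages`, `skipped`.
#' @export
run_validation <- function(expr, clinical, up_gene, down_gene,
                           cutoffs = NULL, mutations = NULL, sigs = NULL,
                           config = pipeline_config(), out_dir = NULL) {
  stopifnot_log2p1(expr)
  for (g in c(up_gene, down_gene))
    if (!g %in% rownames(expr))
      stop("frozen signature gene '", g, "' absent from expression matrix")
  if (!inherits(clinical, "clinical_table")) clinical <- as_clinical(clinical)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  stages <- "classify"; skipped <- character(0)
  calls <- classify_by_expression(expr, up_gene, down_gene, cutoffs = cutoffs)
  idx <- match(names(calls), clinical$sample)
  response_test <- NULL; auc <- NULL
  if ("responder" %in% names(clinical) &&
      any(!is.na(clinical$responder[idx]))) {
    resp <- clinical$responder[idx]
    ok <- !is.na(resp)
    tab <- table(call = factor(calls[ok], c("positive", "negative")),
                 responder = factor(resp[ok], c(1, 0)))
    response_test <- contingency_test(unclass(tab))
    auc <- binary_auc(calls[ok], resp[ok])
    stages <- c(stages, "response", "auc")
  } else skipped <- c(skipped, "response", "auc")
  km_rfs <- NULL
  if (all(c("rfs_time", "rfs_event") %in% names(clinical))) {
    km_rfs <- km_fit(clinical$rfs_time[idx], clinical$rfs_event[idx], calls)
    stages <- c(stages, "km_rfs")
  } else skipped <- c(skipped, "km_rfs")
  molecular <- NULL
  if (!is.null(mutations)) {
    molecular <- molecular_profile(mutations, sigs = sigs,
                                   callable_mb = config$callable_mb)
    stages <- c(stages, "molecular")
  } else skipped <- c(skipped, "molecular")
  if (!is.null(out_dir)) {
    write_stage_tsv(data.frame(sample = names(calls), call = calls),
                    out_dir, "validation_calls")
    if (!is.null(molecular)) write_stage_tsv(molecular, out_dir, "molecular")
    jsonlite::write_json(
      list(config = unclass(config), stages = stages, skipped = skipped,
           signature = c(up = up_gene, down = down_gene)),
      file.path(out_dir, "validation_manifest.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  structure(list(calls = calls, response_test = response_test, auc = auc,
                 km_rfs = km_rfs, molecular = molecular,
                 stages = stages, skipped = skipped),
            class = "validation_report")
}
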