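#' Synthetic cohort specification
#'
#' Parameterizes the statistical structure the discovery analysis assumes:
#' three expression clusters over a ~55-gene pathway panel, one strongly
#' up-regulated and one strongly down-regulated marker gene in the
#' worst-prognosis cluster (cluster 3), proportional-hazards survival
#' differences by cluster, cluster-dependent binary treatment response,
#' per-sample mutation catalogs whose VAF dispersion and 96-context
#' composition differ by cluster, and immune marker / clonotype tables.
#'
#' Defaults are the calibration conditions used throughout the package's
#' tests: n = 300 samples, marker shifts of 4 log2 units against noise SD 0.5,
#' a within-panel cluster shift of 2 log2 units, a cluster-3 hazard ratio of
#' 3, and responder probabilities 1.0 (cluster 3) vs 0.5 (others).
#'
#' @param n_samples cohort size.
#' @param n_panel_genes pathway panel size (default 55).
#' @param n_background_genes shift-free noise genes.
#' @param cluster_proportions length-3 simplex of cluster sizes.
#' @param marker_up_shift log2 mean shift of the designated up-marker
#'   (`MARKER_UP`) in cluster 3.
#' @param marker_down_shift log2 mean shift (downwards) of the designated
#'   down-marker (`MARKER_DN`) in cluster 3.
#' @param panel_cluster_shift log2 shift applied to panel-gene blocks by
#'   cluster (block design: half the non-marker panel elevated in cluster 1,
#'   half in cluster 2; cluster 3 stays at panel baseline).
#' @param noise_sd Gaussian noise SD on the log2 scale.
#' @param hazard_ratio_cluster3 multiplicative hazard for cluster-3 samples.
#' @param median_os_months baseline median overall survival (months) for
#'   clusters 1 and 2.
#' @param censoring_rate target fraction of censored subjects.
#' @param response_prob_positive responder probability in cluster 3.
#' @param response_prob_negative responder probability in clusters 1 and 2.
#' @param mutation_rate_per_mb somatic mutations per megabase.
#' @param exome_mb callable exome size in Mb.
#' @param math_dispersion_by_subtype Beta precision (pseudo-count) of the VAF
#'   distribution for (clusters 1+2, cluster 3); the smaller cluster-3 value
#'   widens VAFs so MATH is higher.
#' @param dc_post_shift additive log2 shift of dendritic-cell markers in
#'   cluster-3 samples after therapy.
#' @param richness_by_subtype expected distinct clonotypes for
#'   (clusters 1+2, cluster 3).
#' @param seed integer seed; every generator output is a pure function of
#'   (spec, seed).
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 300L,
                        n_panel_genes = 55L,
                        n_background_genes = 200L,
                        cluster_proportions = c(1 / 3, 1 / 3, 1 / 3),
                        marker_up_shift = 4,
                        marker_down_shift = 4,
                        panel_cluster_shift = 2,
                        noise_sd = 0.5,
                        hazard_ratio_cluster3 = 3,
                        median_os_months = 20,
                        censoring_rate = 0.3,
                        response_prob_positive = 1.0,
                        response_prob_negative = 0.5,
                        mutation_rate_per_mb = 2,
                        exome_mb = 38,
                        math_dispersion_by_subtype = c(12, 4),
                        dc_post_shift = 0.3,
                        richness_by_subtype = c(60, 30),
                        seed = 1L) {
  spec <- list(n_samples = as.integer(n_samples),
               n_panel_genes = as.integer(n_panel_genes),
               n_background_genes = as.integer(n_background_genes),
               cluster_proportions = as.numeric(cluster_proportions),
               marker_up_shift = marker_up_shift,
               marker_down_shift = marker_down_shift,
               panel_cluster_shift = panel_cluster_shift,
               noise_sd = noise_sd,
               hazard_ratio_cluster3 = hazard_ratio_cluster3,
               median_os_months = median_os_months,
               censoring_rate = censoring_rate,
               response_prob_positive = response_prob_positive,
               response_prob_negative = response_prob_negative,
               mutation_rate_per_mb = mutation_rate_per_mb,
               exome_mb = exome_mb,
               math_dispersion_by_subtype = as.numeric(math_dispersion_by_subtype),
               dc_post_shift = dc_post_shift,
               richness_by_subtype = as.numeric(richness_by_subtype),
               seed = as.integer(seed))
  if (spec$n_samples < 3L) stop("n_samples must be >= 3")
  if (spec$n_panel_genes < 3L) stop("n_panel_genes must be >= 3")
  if (length(spec$cluster_proportions) != 3L ||
      any(spec$cluster_proportions <= 0) ||
      abs(sum(spec$cluster_proportions) - 1) > 1e-8)
    stop("cluster_proportions must be a positive length-3 simplex")
  probs <- c(spec$censoring_rate, spec$response_prob_positive,
             spec$response_prob_negative)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (spec$hazard_ratio_cluster3 <= 0 || spec$mutation_rate_per_mb <= 0 ||
      spec$exome_mb <= 0 || any(spec$math_dispersion_by_subtype <= 0))
    stop("rates, hazard ratio and dispersions must be positive")
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0")
  structure(spec, class = "cohort_spec")
}

# Deterministic sub-seed per generator stage; kept below 2^31.
sub_seed <- function(spec, offset) (spec$seed * 101L + offset) %% .Machine$integer.max

#' Panel gene names used by the generator
#' @param spec a `cohort_spec`.
#' @return character vector: `MARKER_UP`, `MARKER_DN`, `PANEL3..`.
#' @export
panel_genes <- function(spec) {
  c("MARKER_UP", "MARKER_DN",
    sprintf("PANEL%02d", seq_len(spec$n_panel_genes - 2L)))
}

#' Generate a clustered expression matrix
#'
#' Draws a log2(TPM+1)-scale matrix in which panel genes receive
#' cluster-dependent block mean shifts, the designated up-marker gains
#' `marker_up_shift` and the down-marker loses `marker_down_shift` in
#' cluster 3, and background genes are shift-free noise. The planted labels
#' are returned for evaluation only and are never consumed by the analysis.
#'
#' @param spec a [cohort_spec()].
#' @return list with `expr` (an `expr_matrix`, `transform = "log2p1"`) and
#'   `labels` (integer cluster per sample, 3 = planted worst cluster).
#' @export
generate_expression <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(sub_seed(spec, 1L))
  n <- spec$n_samples
  labels <- rep(1:3, times = round(spec$cluster_proportions * n))
  labels <- c(labels, rep(3L, n - length(labels)))[seq_len(n)]
  genes <- c(panel_genes(spec),
             sprintf("BG%04d", seq_len(spec$n_background_genes)))
  g <- length(genes)
  base_mean <- 5
  mu <- matrix(base_mean, nrow = g, ncol = n,
               dimnames = list(genes, sprintf("S%03d", seq_len(n))))
  # block design over the non-marker panel genes: half elevated in cluster 1,
  # half in cluster 2; cluster 3 stays at panel baseline (a pathway-suppressed
  # worst cluster), so only the two markers separate cluster 3 cleanly
  p_idx <- seq(3L, spec$n_panel_genes)
  block <- rep(1:2, length.out = length(p_idx))
  for (cl in 1:2) {
    rows <- p_idx[block == cl]
    mu[rows, labels == cl] <- mu[rows, labels == cl] + spec$panel_cluster_shift
  }
  mu["MARKER_UP", labels == 3L] <- base_mean + spec$marker_up_shift
  mu["MARKER_DN", labels == 3L] <- base_mean - spec$marker_down_shift
  vals <- mu + matrix(stats::rnorm(g * n, sd = spec$noise_sd), g, n)
  list(expr = expr_matrix(vals, transform = "log2p1"), labels = labels)
}

#' Generate survival, response and covariates for planted labels
#'
#' Survival times follow an exponential proportional-hazards model: baseline
#' hazard log(2)/`median_os_months`, multiplied by `hazard_ratio_cluster3`
#' for cluster-3 samples. Censoring is an independent exponential calibrated
#' so the expected censored fraction equals `censoring_rate`. Responder
#' status is Bernoulli with cluster-dependent probability, reported as
#' CR/PR vs SD/PD. Covariates are drawn from fixed categorical distributions
#' typical of an esophageal-cancer surgical cohort (mostly male, majority
#' smokers/drinkers, stage III+).
#'
#' @param spec a [cohort_spec()].
#' @param labels integer cluster labels from [generate_expression()].
#' @return A `clinical_table` with os/rfs outcomes, response, responder,
#'   treated flag and covariates.
#' @export
generate_outcomes <- function(spec, labels) {
  stopifnot(inherits(spec, "cohort_spec"), length(labels) == spec$n_samples)
  set.seed(sub_seed(spec, 2L))
  n <- spec$n_samples
  lambda0 <- log(2) / spec$median_os_months
  lambda <- lambda0 * ifelse(labels == 3L, spec$hazard_ratio_cluster3, 1)
  t_event <- stats::rexp(n, rate = lambda)
  cr <- spec$censoring_rate
  if (cr > 0) {
    mu_c <- mean(lambda) * cr / (1 - cr)
    t_cens <- stats::rexp(n, rate = mu_c)
  } else {
    t_cens <- rep(Inf, n)
  }
  os_time <- pmin(t_event, t_cens)
  os_event <- as.integer(t_event <= t_cens)
  # relapse precedes death: RFS drawn with a higher hazard, same structure
  r_event <- stats::rexp(n, rate = lambda * 1.6)
  rfs_time <- pmin(r_event, t_cens)
  rfs_event <- as.integer(r_event <= t_cens)
  p_resp <- ifelse(labels == 3L, spec$response_prob_positive,
                   spec$response_prob_negative)
  responder <- stats::rbinom(n, 1L, p_resp)
  response <- ifelse(responder == 1L,
                     sample(c("CR", "PR"), n, replace = TRUE, prob = c(.3, .7)),
                     sample(c("SD", "PD"), n, replace = TRUE, prob = c(.6, .4)))
  df <- data.frame(
    sample = sprintf("S%03d", seq_len(n)),
    os_time = os_time, os_event = os_event,
    rfs_time = rfs_time, rfs_event = rfs_event,
    response = response,
    treated = stats::rbinom(n, 1L, 0.5),
    age = round(stats::rnorm(n, 62, 8)),
    sex = sample(c("male", "female"), n, replace = TRUE, prob = c(.9, .1)),
    smoking = stats::rbinom(n, 1L, 0.75),
    drinking = stats::rbinom(n, 1L, 0.7),
    family_history = stats::rbinom(n, 1L, 0.1),
    tumor_length = round(stats::rlnorm(n, log(3.5), 0.4), 1),
    differentiation = sample(c("low", "middle", "high"), n, replace = TRUE,
                             prob = c(.4, .55, .05)),
    stage = sample(c("I+II", "III+IV"), n, replace = TRUE, prob = c(.1, .9)),
    stringsAsFactors = FALSE)
  as_clinical(df)
}

# Two synthetic 96-context signature profiles: one concentrated on C>T (a
# deamination-like profile), one on T>G contexts. Columns sum to 1.
synthetic_signature_matrix <- function() {
  ctx <- context_labels()
  sub <- substr(ctx, 3L, 5L)
  sigA <- ifelse(sub == "C>T", 4, 0.2)
  sigB <- ifelse(sub == "T>G", 4, 0.2)
  m <- cbind(SigA = sigA / sum(sigA), SigB = sigB / sum(sigB))
  rownames(m) <- ctx
  m
}

#' Generate per-sample mutation catalogs
#'
#' Per-sample mutation counts are Poisson(`mutation_rate_per_mb` x
#' `exome_mb`). VAFs are Beta(mu = 0.3) with a subtype-specific precision so
#' cluster-3 VAFs are over-dispersed (higher MATH). Trinucleotide contexts
#' are drawn from a two-signature mixture whose weights depend on the
#' subtype. The true signature matrix and per-sample weights are attached as
#' attributes `signatures` and `true_weights` for refit testing. Gene labels
#' include a high-frequency TP53/TTN/MUC16 trio, with MUC16 enriched in
#' cluster-3 samples.
#'
#' @param spec a [cohort_spec()].
#' @param labels planted cluster labels.
#' @return A `mutation_catalog` data.frame.
#' @export
generate_mutations <- function(spec, labels) {
  stopifnot(inherits(spec, "cohort_spec"), length(labels) == spec$n_samples)
  set.seed(sub_seed(spec, 3L))
  n <- spec$n_samples
  sigs <- synthetic_signature_matrix()
  ctx <- rownames(sigs)
  counts <- stats::rpois(n, spec$mutation_rate_per_mb * spec$exome_mb)
  w3 <- c(0.7, 0.3); w12 <- c(0.3, 0.7)
  true_w <- matrix(NA_real_, n, 2L, dimnames = list(NULL, colnames(sigs)))
  recs <- vector("list", n)
  genes_pool <- sprintf("G%03d", 1:60)
  mu_vaf <- 0.3
  for (i in seq_len(n)) {
    k <- counts[i]
    if (k == 0L) { recs[[i]] <- NULL; true_w[i, ] <- w12; next }
    is3 <- labels[i] == 3L
    w <- if (is3) w3 else w12
    true_w[i, ] <- w
    disp <- spec$math_dispersion_by_subtype[if (is3) 2L else 1L]
    vaf <- stats::rbeta(k, mu_vaf * disp, (1 - mu_vaf) * disp)
    vaf <- pmin(pmax(vaf, 1e-4), 1)
    mix <- as.vector(sigs %*% w)
    ctx_i <- sample(ctx, k, replace = TRUE, prob = mix)
    p_muc16 <- if (is3) 0.0035 else 0.002
    gene <- sample(c("TP53", "TTN", "MUC16", genes_pool), k, replace = TRUE,
                   prob = c(0.01, 0.006, p_muc16, rep(0.9 / 60, 60)))
    recs[[i]] <- data.frame(sample = sprintf("S%03d", i), gene = gene,
                            vaf = vaf,
                            ref = substr(ctx_i, 3L, 3L),
                            alt = substr(ctx_i, 5L, 5L),
                            context = ctx_i, is_coding = 1L,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs)
  out$substitution <- substr(out$context, 3L, 5L)
  rownames(out) <- NULL
  structure(out, signatures = sigs, true_weights = true_w,
            class = c("mutation_catalog", "data.frame"))
}

# Marker panel used by the immune generator: 10 populations x 4 markers.
synthetic_marker_panel <- function() {
  pops <- c("T_cells", "CD8_T_cells", "cytotoxic", "B_cells", "NK_cells",
            "monocytes", "DC", "neutrophils", "endothelial", "fibroblasts")
  panel <- lapply(pops, function(p) paste0(toupper(p), "_M", 1:4))
  names(panel) <- pops
  panel
}

#' Generate immune marker expression and clonotype tables
#'
#' Marker-gene expression is Gaussian noise around a common baseline; in the
#' `"post"` phase, dendritic-cell (DC) markers of cluster-3 samples gain
#' `dc_post_shift` log2 units, emulating increased DC infiltration after
#' therapy in the signature-positive subtype. Clonotype counts follow a
#' log-series abundance model with subtype-dependent richness.
#'
#' @param spec a [cohort_spec()].
#' @param labels planted cluster labels.
#' @param phase `"pre"` or `"post"` therapy.
#' @return list with `expr` (marker `expr_matrix`, log2p1 scale), `panel`
#'   (named marker list) and `clonotypes` (a `clonotype_table`).
#' @export
generate_immune <- function(spec, labels, phase = c("pre", "post")) {
  phase <- match.arg(phase)
  stopifnot(inherits(spec, "cohort_spec"), length(labels) == spec$n_samples)
  set.seed(sub_seed(spec, if (phase == "pre") 4L else 5L))
  n <- spec$n_samples
  panel <- synthetic_marker_panel()
  genes <- unlist(panel, use.names = FALSE)
  mu <- matrix(1.6, length(genes), n,
               dimnames = list(genes, sprintf("S%03d", seq_len(n))))
  if (phase == "post") {
    dc <- panel$DC
    mu[dc, labels == 3L] <- mu[dc, labels == 3L] + spec$dc_post_shift
  }
  vals <- mu + matrix(stats::rnorm(length(mu), sd = 0.3),
                      nrow(mu), ncol(mu))
  expr <- expr_matrix(vals, transform = "log2p1")
  # log-series clonotype abundances, richness set by subtype
  theta <- 0.95
  kmax <- 200L
  pk <- theta^(1:kmax) / (1:kmax)
  recs <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    rich_mu <- spec$richness_by_subtype[if (labels[i] == 3L) 2L else 1L]
    for (r in c("BCR", "TCR")) {
      rich <- max(1L, stats::rpois(1L, rich_mu))
      cnt <- sample.int(kmax, rich, replace = TRUE, prob = pk)
      recs[[(i - 1L) * 2L + (r == "TCR") + 1L]] <-
        data.frame(sample = sprintf("S%03d", i), receptor = r,
                   clonotype = sprintf("%s_C%04d", r, seq_len(rich)),
                   count = cnt, stringsAsFactors = FALSE)
    }
  }
  clono <- do.call(rbind, recs)
  rownames(clono) <- NULL
  list(expr = expr, panel = panel,
       clonotypes = structure(clono,
                              class = c("clonotype_table", "data.frame")))
}

#' Generate a full synthetic cohort
#'
#' Convenience wrapper running every generator under one spec.
#'
#' @param spec a [cohort_spec()].
#' @return list with `expr`, `labels`, `clinical`, `mutations`, `immune_pre`,
#'   `immune_post`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  ge <- generate_expression(spec)
  list(expr = ge$expr,
       labels = ge$labels,
       clinical = generate_outcomes(spec, ge$labels),
       mutations = generate_mutations(spec, ge$labels),
       immune_pre = generate_immune(spec, ge$labels, "pre"),
       immune_post = generate_immune(spec, ge$labels, "post"))
}
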