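#' Configure a synthetic transplant cohort
#'
#' Builds the configuration object consumed by [simulate_cohort()],
#' [simulate_expression()] and [simulate_longitudinal()]. Defaults emulate a
#' cross-sectional kidney-transplant tolerance study: 14 operationally
#' tolerant recipients (off all drugs), 190 stable and 36 chronic-rejector
#' recipients on immunosuppression, and 12 healthy controls. Treated patients
#' receive at most one calcineurin inhibitor (ciclosporin or tacrolimus), at
#' most one antiproliferative (azathioprine or mycophenolate mofetil), and
#' optionally prednisone; regimen frequencies default to those observed in a
#' large stable cohort (CNI none/Cyc/Tac roughly 38/85/50 out of 173, AP
#' none/Aza/MMF roughly 33/58/82, about 45% on steroids).
#'
#' Expression is simulated on the log2(2^-dCt) scale as
#' `y_ij = alpha_j + sum_d X_id * beta_dj + 1[tolerant_i] * delta_j + eps_ij`
#' with `eps ~ N(0, noise_sd^2)`: additive per-gene drug effects, an additive
#' tolerance effect on a configurable gene subset, and Gaussian noise.
#'
#' @param n_tolerant,n_stable,n_chronic,n_healthy group sizes.
#' @param regimen_probs named list with elements `cni` (probabilities for
#'   none/Cyc/Tac), `ap` (none/Aza/MMF) and `pred` (probability of steroid
#'   intake), applied to stable and chronic-rejector patients. Tolerant and
#'   healthy subjects never receive drugs.
#' @param n_genes number of genes.
#' @param frac_drug_affected per-drug fraction of genes with a nonzero drug
#'   coefficient; a single number is recycled over the five drugs.
#' @param drug_effect_sd SD (log2 units) of nonzero drug coefficients.
#' @param frac_tolerance_genes fraction of genes carrying a tolerance effect.
#' @param tolerance_effect_sd SD (log2 units) of tolerance effects `delta_j`.
#' @param overlap_mode how tolerance-informative genes relate to drug-affected
#'   genes: `"independent"` (sets drawn independently), `"forced"` (every
#'   tolerance gene is also affected by every drug with a nonzero fraction —
#'   the worst case for confounding), or `"disjoint"`.
#' @param align_drug_effects if `TRUE`, drug effects on tolerance-informative
#'   genes point away from the tolerance direction (`beta_dj` takes the sign
#'   of `-delta_j`), so immunosuppression consistently pushes treated
#'   patients' profiles away from the tolerant one — the coherent confounding
#'   seen when drugs suppress the same immune programs that mark tolerance.
#'   Default `FALSE` (independent random signs).
#' @param noise_sd residual SD (log2 units).
#' @param within_subject_corr correlation of the residual component between
#'   repeat samples of the same patient, in `[0, 1]`.
#' @param baseline_mean,baseline_sd distribution of per-gene intercepts
#'   `alpha_j` on the log2(2^-dCt) scale.
#' @param healthy_offset_sd SD of an optional additive healthy-control offset
#'   (default 0: healthy controls share the treated baseline, so the
#'   tolerant-vs-healthy contrast is driven by `delta_j` alone).
#' @param rejection_effect_sd SD of an optional chronic-rejection effect
#'   (default 0: chronic rejectors follow the stable-patient model).
#' @param missing_rate probability that an expression value is missing
#'   completely at random (for exercising imputation).
#' @param drug_r2_target optional fraction in `(0, 1)`: rescale each
#'   drug-affected gene's coefficient vector so that the population variance
#'   explained by drugs among treated patients equals this fraction of the
#'   total (drug + noise) variance.
#' @param seed integer seed; fixes every output bit of the generator.
#'
#' @return an object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_tolerant = 14, n_stable = 190, n_chronic = 36,
                          n_healthy = 12,
                          regimen_probs = list(
                            cni  = c(none = 38, cyc = 85, tac = 50) / 173,
                            ap   = c(none = 33, aza = 58, mmf = 82) / 173,
                            pred = 0.45),
                          n_genes = 100,
                          frac_drug_affected = 0.3,
                          drug_effect_sd = 0.6,
                          frac_tolerance_genes = 0.1,
                          tolerance_effect_sd = 1.5,
                          overlap_mode = c("independent", "forced", "disjoint"),
                          align_drug_effects = FALSE,
                          noise_sd = 1,
                          within_subject_corr = 0.8,
                          baseline_mean = -3, baseline_sd = 2,
                          healthy_offset_sd = 0,
                          rejection_effect_sd = 0,
                          missing_rate = 0,
                          drug_r2_target = NULL,
                          seed = NULL) {
  overlap_mode <- match.arg(overlap_mode)
  counts <- c(n_tolerant = n_tolerant, n_stable = n_stable,
              n_chronic = n_chronic, n_healthy = n_healthy, n_genes = n_genes)
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("group sizes and n_genes must be non-negative integers")
  if (!is.list(regimen_probs) ||
      !all(c("cni", "ap", "pred") %in% names(regimen_probs)))
    stopf("regimen_probs must be a list with elements 'cni', 'ap', 'pred'")
  for (fac in c("cni", "ap")) {
    p <- regimen_probs[[fac]]
    if (length(p) != 3) stopf("regimen_probs$%s must have 3 levels", fac)
    check_fraction(p, paste0("regimen_probs$", fac))
    if (abs(sum(p) - 1) > 1e-8)
      stopf("regimen_probs$%s must sum to 1 (got %g)", fac, sum(p))
  }
  check_fraction(regimen_probs$pred, "regimen_probs$pred")
  if (length(frac_drug_affected) == 1)
    frac_drug_affected <- setNames(rep(frac_drug_affected, 5), DRUGS)
  if (!all(DRUGS %in% names(frac_drug_affected)))
    stopf("frac_drug_affected must be a single number or named over %s",
          paste(DRUGS, collapse = ", "))
  frac_drug_affected <- frac_drug_affected[DRUGS]
  check_fraction(frac_drug_affected, "frac_drug_affected")
  check_fraction(frac_tolerance_genes, "frac_tolerance_genes")
  check_fraction(missing_rate, "missing_rate")
  check_fraction(within_subject_corr, "within_subject_corr")
  for (s in c("drug_effect_sd", "tolerance_effect_sd", "noise_sd",
              "baseline_sd", "healthy_offset_sd", "rejection_effect_sd")) {
    v <- get(s)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0)
      stopf("'%s' must be a single non-negative number", s)
  }
  if (!is.null(drug_r2_target))
    check_fraction(drug_r2_target, "drug_r2_target", lo = 1e-6, hi = 1 - 1e-6)
  if (!is.null(seed)) seed <- as.integer(seed)

  structure(list(
    n_tolerant = as.integer(n_tolerant), n_stable = as.integer(n_stable),
    n_chronic = as.integer(n_chronic), n_healthy = as.integer(n_healthy),
    regimen_probs = regimen_probs, n_genes = as.integer(n_genes),
    frac_drug_affected = frac_drug_affected, drug_effect_sd = drug_effect_sd,
    frac_tolerance_genes = frac_tolerance_genes,
    tolerance_effect_sd = tolerance_effect_sd, overlap_mode = overlap_mode,
    align_drug_effects = isTRUE(align_drug_effects),
    noise_sd = noise_sd, within_subject_corr = within_subject_corr,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    healthy_offset_sd = healthy_offset_sd,
    rejection_effect_sd = rejection_effect_sd,
    missing_rate = missing_rate, drug_r2_target = drug_r2_target,
    seed = seed), class = "cohort_config")
}

set_stage_seed <- function(config, offset) {
  if (!is.null(config$seed)) set.seed(config$seed + offset)
}

#' Simulate cohort metadata and the drug design matrix
#'
#' Draws one sample per patient with the configured group sizes and drug
#' regimens. Calcineurin-inhibitor and antiproliferative assignments are
#' mutually exclusive within their factor; tolerant patients and healthy
#' controls carry all-zero drug flags by construction.
#'
#' @param config a [cohort_config()].
#' @return list with `metadata` (a [SampleMetadata][read_metadata] data
#'   frame, timepoint 1) and `design` (binary sample x drug matrix over the
#'   treated patients, see [encode_drug_design()]).
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    stopf("config must be created by cohort_config()")
  set_stage_seed(config, 0L)
  n <- config$n_tolerant + config$n_stable + config$n_chronic + config$n_healthy
  group <- rep(c("tolerant", "stable", "chronic_rejector", "healthy"),
               c(config$n_tolerant, config$n_stable, config$n_chronic,
                 config$n_healthy))
  patient_id <- sprintf("P%04d", seq_len(n))
  md <- data.frame(
    sample_id = paste0(patient_id, "_t1"), patient_id = patient_id,
    group = group, timepoint = "1",
    pred = 0L, cyc = 0L, tac = 0L, aza = 0L, mmf = 0L,
    stringsAsFactors = FALSE)
  treated <- group %in% TREATED_GROUPS
  nt <- sum(treated)
  if (nt > 0) {
    rp <- config$regimen_probs
    cni <- sample(c("none", "cyc", "tac"), nt, replace = TRUE, prob = rp$cni)
    ap <- sample(c("none", "aza", "mmf"), nt, replace = TRUE, prob = rp$ap)
    md$pred[treated] <- rbinom(nt, 1, rp$pred)
    md$cyc[treated] <- as.integer(cni == "cyc")
    md$tac[treated] <- as.integer(cni == "tac")
    md$aza[treated] <- as.integer(ap == "aza")
    md$mmf[treated] <- as.integer(ap == "mmf")
  }
  validate_metadata(md)
  list(metadata = md, design = encode_drug_design(md))
}

draw_affected <- function(n_genes, frac, tolerance_idx, mode) {
  affected <- matrix(FALSE, n_genes, 5, dimnames = list(NULL, DRUGS))
  pool <- seq_len(n_genes)
  if (mode == "disjoint") pool <- setdiff(pool, tolerance_idx)
  for (d in DRUGS) {
    k <- round(frac[[d]] * n_genes)
    if (mode == "disjoint") k <- min(k, length(pool))
    if (k > 0 && length(pool) > 0)
      affected[sample(pool, k), d] <- TRUE
    if (mode == "forced" && frac[[d]] > 0)
      affected[tolerance_idx, d] <- TRUE
  }
  affected
}

#' Simulate an expression matrix with known ground truth
#'
#' Generates log2-scale expression under the additive model
#' `y_ij = alpha_j + sum_d X_id beta_dj + 1[tolerant_i] delta_j + eps_ij`.
#' Drug coefficients are nonzero only for the drug-affected gene sets,
#' tolerance effects only for the tolerance-informative set; both sets are
#' reported in the returned truth object, together with the systematic
#' (noise-free) component used by [simulate_longitudinal()].
#'
#' @param metadata,design output of [simulate_cohort()].
#' @param config the same [cohort_config()].
#' @return list with `expr` (gene x sample matrix, possibly with `NA`s when
#'   `missing_rate > 0`) and `truth` (class `simulation_truth`: intercepts,
#'   gene x drug beta matrix, tolerance deltas, logical gene labels, and the
#'   systematic component `mu`).
#' @export
simulate_expression <- function(metadata, design, config) {
  if (!inherits(config, "cohort_config"))
    stopf("config must be created by cohort_config()")
  validate_metadata(metadata)
  if (!all(rownames(design) %in% metadata$sample_id))
    stopf("design rows must be samples present in metadata")
  set_stage_seed(config, 1L)
  p <- config$n_genes
  n <- nrow(metadata)
  genes <- sprintf("g%04d", seq_len(p))

  alpha <- rnorm(p, config$baseline_mean, config$baseline_sd)
  n_tol_genes <- round(config$frac_tolerance_genes * p)
  tolerance_idx <- if (n_tol_genes > 0) sort(sample(p, n_tol_genes)) else integer()
  affected <- draw_affected(p, config$frac_drug_affected, tolerance_idx,
                            config$overlap_mode)
  beta <- matrix(0, p, 5, dimnames = list(genes, DRUGS))
  beta[affected] <- rnorm(sum(affected), 0, config$drug_effect_sd)
  delta <- numeric(p)
  delta[tolerance_idx] <- rnorm(n_tol_genes, 0, config$tolerance_effect_sd)
  if (config$align_drug_effects && length(tolerance_idx)) {
    # coherent confounding: drugs shift tolerance genes away from the
    # tolerant profile
    sgn <- sign(delta[tolerance_idx])
    beta[tolerance_idx, ] <- -abs(beta[tolerance_idx, , drop = FALSE]) * sgn
  }

  # full-cohort design (zeros for untreated samples)
  X <- matrix(0, n, 5, dimnames = list(metadata$sample_id, DRUGS))
  X[rownames(design), ] <- design

  if (!is.null(config$drug_r2_target)) {
    # rescale each affected gene's beta so drug variance / (drug + noise)
    # variance equals the target among treated patients
    tgt <- config$drug_r2_target
    Xt <- X[metadata$group %in% TREATED_GROUPS, , drop = FALSE]
    for (j in which(rowSums(beta != 0) > 0)) {
      v <- var(drop(Xt %*% beta[j, ]))
      if (v > 0)
        beta[j, ] <- beta[j, ] * sqrt(tgt / (1 - tgt)) * config$noise_sd / sqrt(v)
    }
  }

  mu <- matrix(alpha, p, n) + beta %*% t(X) +
    outer(delta, as.numeric(metadata$group == "tolerant"))
  if (config$healthy_offset_sd > 0) {
    h_off <- rnorm(p, 0, config$healthy_offset_sd)
    mu <- mu + outer(h_off, as.numeric(metadata$group == "healthy"))
  }
  if (config$rejection_effect_sd > 0) {
    r_off <- rnorm(p, 0, config$rejection_effect_sd)
    mu <- mu + outer(r_off, as.numeric(metadata$group == "chronic_rejector"))
  }
  dimnames(mu) <- list(genes, metadata$sample_id)
  y <- mu + matrix(rnorm(p * n, 0, config$noise_sd), p, n)
  if (config$missing_rate > 0)
    y[runif(p * n) < config$missing_rate] <- NA_real_

  truth <- structure(list(
    intercepts = setNames(alpha, genes),
    betas = beta,
    tolerance_delta = setNames(delta, genes),
    drug_affected = affected,
    tolerance_genes = genes[tolerance_idx],
    mu = mu), class = "simulation_truth")
  list(expr = y, truth = truth)
}

#' Simulate repeat or post-steroid-withdrawal samples
#'
#' `mode = "timepoint2"` draws a second sample per patient whose residual
#' component correlates with the first at `within_subject_corr` while drug
#' flags and systematic effects are unchanged. `mode = "steroid_withdrawal"`
#' produces paired pre/post samples for prednisone-taking stable patients:
#' the post sample loses the per-gene prednisone contribution `beta_Pred`,
#' has its Pred flag cleared, and — because it is drawn months after
#' withdrawal — carries a fresh residual correlated with the pre sample at
#' `within_subject_corr` (with `noise_sd = 0` the post sample is exactly the
#' pre sample minus `beta_Pred`).
#'
#' @param metadata,expr,truth baseline cohort from [simulate_cohort()] and
#'   [simulate_expression()].
#' @param mode `"timepoint2"` or `"steroid_withdrawal"`.
#' @param config the [cohort_config()].
#' @return list with `expr` (gene x sample matrix of the new samples) and
#'   `metadata` (rows for the new samples, timepoint `"2"` or `"post"`, with
#'   baseline rows relabelled `"pre"` in the withdrawal mode returned as
#'   `metadata_pre`).
#' @export
simulate_longitudinal <- function(metadata, expr, truth,
                                  mode = c("timepoint2", "steroid_withdrawal"),
                                  config) {
  mode <- match.arg(mode)
  if (!inherits(truth, "simulation_truth"))
    stopf("truth must come from simulate_expression()")
  set_stage_seed(config, 2L)
  if (mode == "timepoint2") {
    rho <- config$within_subject_corr
    eps1 <- expr - truth$mu
    eps2 <- rho * eps1 +
      sqrt(1 - rho^2) * matrix(rnorm(length(expr), 0, config$noise_sd),
                               nrow(expr), ncol(expr))
    y2 <- truth$mu + eps2
    md2 <- metadata
    md2$timepoint <- "2"
    md2$sample_id <- paste0(metadata$patient_id, "_t2")
    colnames(y2) <- md2$sample_id
    list(expr = y2, metadata = md2)
  } else {
    on_pred <- metadata$group == "stable" & metadata$pred == 1
    if (!any(on_pred))
      stopf("steroid_withdrawal mode requires prednisone-taking stable patients")
    pre_md <- metadata[on_pred, , drop = FALSE]
    pre_md$timepoint <- "pre"
    post_md <- pre_md
    post_md$timepoint <- "post"
    post_md$pred <- 0L
    post_md$sample_id <- paste0(pre_md$patient_id, "_post")
    rho <- config$within_subject_corr
    mu_pre <- truth$mu[, pre_md$sample_id, drop = FALSE]
    eps_pre <- expr[, pre_md$sample_id, drop = FALSE] - mu_pre
    eps_post <- rho * eps_pre +
      sqrt(1 - rho^2) * matrix(rnorm(length(eps_pre), 0, config$noise_sd),
                               nrow(eps_pre), ncol(eps_pre))
    y_post <- mu_pre - outer(truth$betas[, "Pred"], rep(1, nrow(pre_md))) +
      eps_post
    colnames(y_post) <- post_md$sample_id
    list(expr = y_post, metadata = post_md, metadata_pre = pre_md)
  }
}

#' Simulate a complete study in one call
#'
#' Convenience wrapper running [simulate_cohort()] then
#' [simulate_expression()].
#'
#' @param config a [cohort_config()].
#' @return list with `metadata`, `design`, `expr`, `truth`.
#' @export
simulate_study <- function(config) {
  cohort <- simulate_cohort(config)
  sim <- simulate_expression(cohort$metadata, cohort$design, config)
  c(cohort, sim)
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf("simulation_truth: %d genes, %d drug-affected, %d tolerance-informative\n",
              length(x$intercepts), sum(rowSums(x$drug_affected) > 0),
              length(x$tolerance_genes)))
  invisible(x)
}

#' Write simulation truth to JSON
#'
#' @param truth a `simulation_truth` object.
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(list(
    intercepts = as.list(truth$intercepts),
    betas = as.data.frame(truth$betas),
    tolerance_delta = as.list(truth$tolerance_delta),
    tolerance_genes = truth$tolerance_genes),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
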