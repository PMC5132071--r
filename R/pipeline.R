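#' Configure an end-to-end pipeline run
#'
#' Validates and bundles everything [run_pipeline()] needs: a cohort
#' generator configuration (or paths to an expression matrix and metadata),
#' the background-filter threshold, the tuning scheme, the cutoff
#' constraints and the analysis mode.
#'
#' @param cohort a [cohort_config()] for simulation mode, or `NULL` when
#'   `expression_path`/`metadata_path` are given.
#' @param expression_path,metadata_path optional input files (see
#'   [read_expression()], [read_metadata()]).
#' @param gmt_path optional GMT file enabling the gene-set analysis stage.
#' @param mode `"isie"` (residualize drug effects before training) or
#'   `"raw"` (train on raw expression — the confounded baseline).
#' @param min_detect_frac optional background-filter threshold in `(0, 1]`;
#'   `NULL` skips the filter (detection calls require Ct-scale input).
#' @param alpha_grid,n_lambda,train_frac,iters,max_genes,k_impute tuning
#'   scheme, see [tune_signature()].
#' @param spec_min,sens_min cutoff constraints, see [select_cutoff()].
#' @param n_perm_gsa permutations for [gsa_permutation_fdr()].
#' @param seed integer seed driving every stochastic stage (mandatory).
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            expression_path = NULL, metadata_path = NULL,
                            gmt_path = NULL,
                            mode = c("isie", "raw"),
                            min_detect_frac = NULL,
                            alpha_grid = c(0.2, 0.5, 0.8, 1),
                            n_lambda = 30, train_frac = 0.65, iters = 100,
                            max_genes = 30, k_impute = 5,
                            spec_min = 0.85, sens_min = 0.70,
                            n_perm_gsa = 1000, seed) {
  mode <- match.arg(mode)
  if (missing(seed) || is.null(seed))
    stopf("a seed is mandatory: the tuning resamples are stochastic")
  if (is.null(cohort) && (is.null(expression_path) || is.null(metadata_path)))
    stopf("either a cohort config or expression + metadata paths are required")
  if (!is.null(cohort) && !inherits(cohort, "cohort_config"))
    stopf("cohort must be created by cohort_config()")
  check_fraction(train_frac, "train_frac", lo = 0.1, hi = 0.95)
  check_fraction(spec_min, "spec_min")
  check_fraction(sens_min, "sens_min")
  if (!is.null(min_detect_frac))
    check_fraction(min_detect_frac, "min_detect_frac", lo = 1e-9)
  if (max_genes < 1) stopf("max_genes must be >= 1")
  structure(list(cohort = cohort, expression_path = expression_path,
                 metadata_path = metadata_path, gmt_path = gmt_path,
                 mode = mode, min_detect_frac = min_detect_frac,
                 alpha_grid = alpha_grid, n_lambda = n_lambda,
                 train_frac = train_frac, iters = iters,
                 max_genes = max_genes, k_impute = k_impute,
                 spec_min = spec_min, sens_min = sens_min,
                 n_perm_gsa = n_perm_gsa, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the tolerance-signature pipeline end to end
#'
#' Executes the stages in their canonical order — simulate (or load),
#' optional background filter, drug-design encoding, per-gene drug-effect
#' models, IS-IE residualization (in `"isie"` mode), imputation, signature
#' tuning, prediction, cutoff selection, evaluation, and optional gene-set
#' analysis — writing every artifact plus a run log into `outdir`.
#' Rerunning with the same config and seed reproduces every output.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory; must not exist unless `overwrite = TRUE`
#'   (one immutable directory per invocation).
#' @param overwrite allow writing into an existing directory.
#' @return invisibly, a list with the in-memory results (`model`,
#'   `signature`, `probabilities`, `cutoff`, `report`, `gsa`, `paths`).
#' @export
run_pipeline <- function(config, outdir, overwrite = FALSE) {
  if (!inherits(config, "pipeline_config"))
    stopf("config must be created by pipeline_config()")
  if (dir.exists(outdir) && !overwrite)
    stopf("output directory exists: %s (use overwrite = TRUE)", outdir)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log <- c(sprintf("tolsig %s", as.character(packageVersion("tolsig"))),
           sprintf("seed %d, mode %s", config$seed, config$mode))
  note <- function(fmt, ...) log <<- c(log, sprintf(fmt, ...))

  # -- stage: acquire data ---------------------------------------------------
  if (!is.null(config$cohort)) {
    cohort <- config$cohort
    cohort$seed <- cohort$seed %||% config$seed
    sim <- simulate_study(cohort)
    metadata <- sim$metadata
    expr <- sim$expr
    write_truth(sim$truth, file.path(outdir, "truth.json"))
    note("simulated %d genes x %d samples", nrow(expr), ncol(expr))
  } else {
    expr <- read_expression(config$expression_path)
    metadata <- read_metadata(config$metadata_path)
    note("loaded %d genes x %d samples", nrow(expr), ncol(expr))
  }
  write_expression(expr, file.path(outdir, "expression.tsv"))
  write_metadata(metadata, file.path(outdir, "metadata.csv"))

  # -- stage: background filter ---------------------------------------------
  if (!is.null(config$min_detect_frac)) {
    flt <- background_filter(expr, !is.na(expr), config$min_detect_frac)
    expr <- flt$expr
    note("background filter kept %d / %d genes",
         flt$report$n_retained, flt$report$n_input)
  }

  # -- stage: drug models + IS-IE -------------------------------------------
  design <- encode_drug_design(metadata)
  note("drug design: %d treated samples, %d excluded for missing flags",
       nrow(design), length(attr(design, "excluded")))
  model <- fit_drug_models(expr, design)
  write_drug_effect_model(model, file.path(outdir, "drug_effect_model.json"))
  train_expr <- if (config$mode == "isie")
    isie_transform(expr, metadata, model) else expr
  note("mode %s: median drug R^2 = %.3f", config$mode,
       median(model$r_squared))

  # -- stage: signature -----------------------------------------------------
  in_training <- metadata$group %in% c("tolerant", TREATED_GROUPS) &
    metadata$sample_id %in% colnames(train_expr)
  train_ids <- metadata$sample_id[in_training]
  labels <- setNames(metadata$group[in_training] == "tolerant", train_ids)
  tuned <- tune_signature(train_expr[, train_ids, drop = FALSE], labels,
                          alpha_grid = config$alpha_grid,
                          n_lambda = config$n_lambda,
                          train_frac = config$train_frac,
                          iters = config$iters,
                          max_genes = config$max_genes,
                          k_impute = config$k_impute, seed = config$seed)
  sig <- tuned$signature
  note("signature: %d genes, alpha %.2f, lambda %.4g, resampled AUC %.3f",
       length(sig$genes), sig$alpha, sig$lambda, sig$mean_cv_auc)

  probs <- predict_probability(
    sig, knn_impute(train_expr[, train_ids, drop = FALSE],
                    k = config$k_impute))
  cut <- select_cutoff(probs, labels, config$spec_min, config$sens_min)
  sig$cutoff <- cut$cutoff
  write_signature(sig, file.path(outdir, "signature.json"))
  note(if (cut$feasible)
    sprintf("cutoff %.3f (sens %.2f, spec %.2f)", cut$cutoff,
            cut$sensitivity, cut$specificity)
    else "no cutoff satisfies the sensitivity/specificity constraints")
  write.table(data.frame(sample_id = names(probs), probability = probs,
                         classified_tolerant =
                           if (cut$feasible) probs >= cut$cutoff else NA),
              file.path(outdir, "predictions.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)

  # -- stage: evaluation -----------------------------------------------------
  report <- evaluate_probabilities(probs, metadata[in_training, ],
                                   cutoff = cut$cutoff)
  jsonlite::write_json(list(
    mode = config$mode, auc = report$auc, auc_ci = report$auc_ci,
    auc_adjusted = report$auc_adjusted,
    drug_association = report$drug_association,
    cutoff = cut, counts = report$counts,
    n_signature_genes = length(sig$genes)),
    file.path(outdir, "report.json"), auto_unbox = TRUE, digits = NA)
  note("AUC %.3f, adjusted AUC %.3f", report$auc, report$auc_adjusted)

  # -- stage: gene-set analysis ---------------------------------------------
  gsa <- NULL
  if (!is.null(config$gmt_path)) {
    collection <- read_gmt(config$gmt_path)
    gsa_expr <- knn_impute(train_expr[, train_ids, drop = FALSE],
                           k = config$k_impute)
    gsa <- gsa_permutation_fdr(gsa_expr, labels, collection,
                               n_perm = config$n_perm_gsa,
                               seed = config$seed)
    write.table(as.data.frame(gsa), file.path(outdir, "gsa.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    note("GSA: %d sets, %d at q < 0.10", nrow(gsa), sum(gsa$q_value < 0.10))
  }

  writeLines(log, file.path(outdir, "run.log"))
  invisible(list(model = model, signature = sig, probabilities = probs,
                 cutoff = cut, report = report, gsa = gsa,
                 metadata = metadata, outdir = outdir))
}
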