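# Per-gene ordinary-least-squares machinery shared by the drug-effect model
# and the drug-association tests. X includes the intercept column; Y is
# samples x genes and may not contain NAs (complete cases are handled by the
# callers, gene-wise).
ols_block <- function(X, Y) {
  Y <- as.matrix(Y)
  fit <- lm.fit(X, Y)
  r <- fit$rank
  piv <- fit$qr$pivot
  cu <- rep(NA_real_, ncol(X))
  R1 <- qr.R(fit$qr)[seq_len(r), seq_len(r), drop = FALSE]
  cu[piv[seq_len(r)]] <- diag(chol2inv(R1))
  cf <- as.matrix(fit$coefficients)
  res <- as.matrix(fit$residuals)
  rownames(cf) <- colnames(X)
  n <- nrow(X)
  df <- n - r
  rss <- colSums(res^2)
  sigma2 <- if (df > 0) rss / df else rep(NA_real_, ncol(Y))
  se <- sqrt(outer(cu, sigma2))
  rownames(se) <- colnames(X)
  tss <- colSums(sweep(Y, 2, colMeans(Y))^2)
  r2 <- ifelse(tss > 0, 1 - rss / tss, 0)
  list(coef = cf, se = se, sigma = sqrt(sigma2), df = df, n = n,
       r2 = pmin(pmax(r2, 0), 1), residuals = res)
}

#' Fit per-gene linear drug-effect models on treated patients
#'
#' For every gene, fits by ordinary least squares
#' `y_ij = alpha_j + Pred_i b_Pred,j + Cyc_i b_Cyc,j + Tac_i b_Tac,j +
#' Aza_i b_Aza,j + MMF_i b_MMF,j + e_ij`
#' using the treated (stable + chronic rejector) samples in `design`.
#' Samples with missing expression are dropped gene-wise (complete-case per
#' gene, no imputation at this stage). Coefficient standard errors use the
#' unbiased residual variance. Coefficients that are not estimable on a
#' rank-deficient design (e.g. every patient on prednisone) are flagged `NA`
#' rather than silently zeroed.
#'
#' @param expr gene x sample expression matrix (log2 scale).
#' @param design binary sample x drug matrix from [encode_drug_design()];
#'   its rows define the fitting population and must be columns of `expr`.
#' @return object of class `drug_effect_model`: per-gene `coefficients`
#'   (genes x 6: `(Intercept)` then the five drugs), `se`, residual `sigma`,
#'   `df_residual`, `n_used`, and `r_squared` (variance explained by drugs).
#' @export
fit_drug_models <- function(expr, design) {
  missing_samp <- setdiff(rownames(design), colnames(expr))
  if (length(missing_samp))
    stopf("design sample(s) absent from expression matrix: %s",
          paste(missing_samp, collapse = ", "))
  X <- cbind(`(Intercept)` = 1, design[, DRUGS, drop = FALSE])
  Y <- t(expr[, rownames(design), drop = FALSE])
  genes <- colnames(Y)
  p <- ncol(X)

  n_obs <- colSums(!is.na(Y))
  too_few <- genes[n_obs < p + 1]
  if (length(too_few))
    stopf("gene(s) with fewer than %d non-missing treated samples: %s",
          p + 1, paste(too_few, collapse = ", "))

  coefs <- matrix(NA_real_, length(genes), p, dimnames = list(genes, colnames(X)))
  ses <- coefs
  sigma <- setNames(rep(NA_real_, length(genes)), genes)
  r2 <- sigma
  dfres <- sigma

  complete <- !apply(is.na(Y), 2, any)
  if (any(complete)) {
    blk <- ols_block(X, Y[, complete, drop = FALSE])
    coefs[complete, ] <- t(blk$coef)
    ses[complete, ] <- t(blk$se)
    sigma[complete] <- blk$sigma
    r2[complete] <- blk$r2
    dfres[complete] <- blk$df
  }
  for (g in genes[!complete]) {
    ok <- !is.na(Y[, g])
    blk <- ols_block(X[ok, , drop = FALSE], Y[ok, g, drop = FALSE])
    coefs[g, ] <- blk$coef[, 1]
    ses[g, ] <- blk$se[, 1]
    sigma[g] <- blk$sigma
    r2[g] <- blk$r2
    dfres[g] <- blk$df
  }
  structure(list(coefficients = coefs, se = ses, sigma = sigma,
                 df_residual = dfres, n_used = n_obs, r_squared = r2,
                 drugs = DRUGS), class = "drug_effect_model")
}

#' @export
print.drug_effect_model <- function(x, ...) {
  cat(sprintf("drug_effect_model: %d genes, median n = %d, median R^2 = %.3f\n",
              nrow(x$coefficients), as.integer(median(x$n_used)),
              median(x$r_squared)))
  invisible(x)
}

# betas with NA (non-estimable) are treated as 0 downstream, loudly
model_betas <- function(model) {
  B <- model$coefficients[, DRUGS, drop = FALSE]
  if (anyNA(B)) {
    warnf("%d non-estimable drug coefficient(s) treated as 0 in the transform",
          sum(is.na(B)))
    B[is.na(B)] <- 0
  }
  B
}

model_alpha <- function(model) {
  a <- model$coefficients[, "(Intercept)"]
  if (anyNA(a)) stopf("non-estimable intercept(s); cannot rescale")
  a
}

#' Immunosuppression-independent expression (IS-IE)
#'
#' Rescales an expression matrix with a fitted [drug-effect
#' model][fit_drug_models]: treated samples (stable, chronic rejector) become
#' the model residual `y - (alpha + X beta)`, i.e. the expression free of
#' additive drug effects; untreated samples (tolerant, healthy) are rescaled
#' by subtracting the intercept `alpha` only, putting them on the same
#' drug-free scale. Missing values stay missing.
#'
#' `isie_transform_heldout()` is the held-out variant for repeat samples: it
#' applies a model trained at time point 1 to time-point-2 data with the same
#' treated/untreated rule and never refits.
#'
#' @param expr gene x sample matrix; all genes must be in the model.
#' @param metadata validated metadata covering the samples of `expr`
#'   (supplies group and drug flags).
#' @param model a `drug_effect_model` fitted on the same genes.
#' @return matrix of IS-IE values, same dimnames as `expr`.
#' @export
isie_transform <- function(expr, metadata, model) {
  metadata <- validate_metadata(metadata)
  absent <- setdiff(rownames(expr), rownames(model$coefficients))
  if (length(absent))
    stopf("gene(s) absent from the drug-effect model: %s",
          paste(absent, collapse = ", "))
  md <- metadata[match(colnames(expr), metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id))
    stopf("sample(s) missing from metadata: %s",
          paste(setdiff(colnames(expr), metadata$sample_id), collapse = ", "))
  genes <- rownames(expr)
  alpha <- model_alpha(model)[genes]
  B <- model_betas(model)[genes, , drop = FALSE]

  treated <- md$group %in% TREATED_GROUPS
  X <- matrix(0, ncol(expr), 5, dimnames = list(colnames(expr), DRUGS))
  if (any(treated)) {
    flags <- as.matrix(md[treated, c("pred", "cyc", "tac", "aza", "mmf")])
    if (anyNA(flags))
      stopf("treated sample(s) with missing drug flags cannot be rescaled: %s",
            paste(md$sample_id[treated][rowSums(is.na(flags)) > 0],
                  collapse = ", "))
    X[treated, ] <- flags
  }
  expr - (matrix(alpha, nrow(expr), ncol(expr)) + B %*% t(X))
}

#' @rdname isie_transform
#' @param expr_t2,metadata_t2 held-out (e.g. time point 2) data.
#' @param model_t1 the model trained on the baseline samples.
#' @export
isie_transform_heldout <- function(expr_t2, metadata_t2, model_t1) {
  isie_transform(expr_t2, metadata_t2, model_t1)
}

# shared per-coefficient t-tests with family-wise Bonferroni correction
coef_tests <- function(blk_coef, blk_se, df, family_sizes) {
  est <- blk_coef[DRUGS]
  se <- blk_se[DRUGS]
  tval <- est / se
  p <- 2 * pt(-abs(tval), df)
  adj <- pmin(1, p * family_sizes[DRUGS])
  data.frame(drug = DRUGS, estimate = unname(est), se = unname(se),
             p_value = unname(p), p_adjusted = unname(adj),
             stringsAsFactors = FALSE)
}

#' Per-gene, per-drug association tests
#'
#' Two-sided t-tests on the OLS drug coefficients of [fit_drug_models()],
#' each adjusted for all other drugs by construction of the joint model.
#' Within the calcineurin-inhibitor family (Cyc, Tac) and the
#' antiproliferative family (Aza, MMF) the p-values are Bonferroni-multiplied
#' by the family size (default 2; prednisone stands alone), capped at 1.
#'
#' @inheritParams fit_drug_models
#' @param family_sizes named multipliers per drug for the Bonferroni step.
#' @return data frame with one row per gene x drug: `gene_id`, `drug`,
#'   `estimate`, `se`, `p_value`, `p_adjusted`, and `computable` (`FALSE`
#'   when the residual variance is zero or the coefficient non-estimable).
#' @export
drug_effect_tests <- function(expr, design,
                              family_sizes = DEFAULT_FAMILY_SIZES) {
  model <- fit_drug_models(expr, design)
  genes <- rownames(model$coefficients)
  est <- model$coefficients[, DRUGS, drop = FALSE]
  se <- model$se[, DRUGS, drop = FALSE]
  df <- model$df_residual
  tval <- est / se
  p <- 2 * pt(-abs(tval), df)
  # (near-)zero residual variance relative to the fitted scale: the t-test
  # is not computable; flag rather than report rounding noise
  fit_scale <- 1 + sqrt(rowSums(model$coefficients^2, na.rm = TRUE))
  p[model$sigma <= 1e-8 * fit_scale, ] <- NA_real_
  adj <- sweep(p, 2, family_sizes[DRUGS], "*")
  adj[adj > 1] <- 1   # pmin(1, .) would drop the dim attribute
  out <- data.frame(
    gene_id = rep(genes, each = 5),
    drug = rep(DRUGS, times = length(genes)),
    estimate = as.vector(t(est)), se = as.vector(t(se)),
    p_value = as.vector(t(p)), p_adjusted = as.vector(t(adj)),
    stringsAsFactors = FALSE)
  out$computable <- !is.na(out$p_value)
  out
}

#' Variance in gene expression explained by drug regimen
#'
#' R-squared of the full five-indicator drug model per gene, the quantity
#' used to gauge how strongly immunosuppression drives each gene (values up
#' to roughly 25-30% are seen for drug-responsive tolerance-signature genes).
#' Constant genes are reported as 0.
#'
#' @inheritParams fit_drug_models
#' @return data frame `gene_id`, `r_squared` (fraction), `pct` (percentage).
#' @export
drug_variance_explained <- function(expr, design) {
  model <- fit_drug_models(expr, design)
  data.frame(gene_id = rownames(model$coefficients),
             r_squared = unname(model$r_squared),
             pct = 100 * unname(model$r_squared),
             stringsAsFactors = FALSE)
}

#' Serialize / read a drug-effect model as JSON
#' @param model a `drug_effect_model`.
#' @param path file path.
#' @export
write_drug_effect_model <- function(model, path) {
  jsonlite::write_json(list(
    genes = rownames(model$coefficients),
    coefficients = as.data.frame(model$coefficients),
    se = as.data.frame(model$se),
    sigma = unname(model$sigma), df_residual = unname(model$df_residual),
    n_used = unname(model$n_used), r_squared = unname(model$r_squared)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_drug_effect_model
#' @export
read_drug_effect_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cf <- as.matrix(j$coefficients)
  rownames(cf) <- j$genes
  se <- as.matrix(j$se)
  rownames(se) <- j$genes
  structure(list(coefficients = cf, se = se,
                 sigma = setNames(j$sigma, j$genes),
                 df_residual = setNames(j$df_residual, j$genes),
                 n_used = setNames(j$n_used, j$genes),
                 r_squared = setNames(j$r_squared, j$genes),
                 drugs = DRUGS), class = "drug_effect_model")
}
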