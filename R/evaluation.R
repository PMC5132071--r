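#' AUC with a DeLong 95% confidence interval
#'
#' The AUC is the Mann-Whitney pair statistic (ties credited 1/2); the
#' confidence interval uses the DeLong structural-components variance
#' estimator with a normal approximation, truncated to `[0, 1]`.
#'
#' @param scores numeric scores (higher = more tolerant-like).
#' @param labels logical, `TRUE` = positive (tolerant) class.
#' @param conf_level confidence level, default 0.95.
#' @return list: `auc`, `ci` (lower, upper), `se`.
#' @export
roc_auc_ci <- function(scores, labels, conf_level = 0.95) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) stopf("both classes required")
  pos <- scores[labels]
  neg <- scores[!labels]
  m <- length(pos)
  n <- length(neg)
  # psi(x, y) = 1 if x > y, 1/2 if tied
  psi <- outer(pos, neg, function(x, y) (x > y) + 0.5 * (x == y))
  auc <- mean(psi)
  v10 <- rowMeans(psi)   # per-positive structural components
  v01 <- colMeans(psi)   # per-negative
  se <- sqrt(var(v10) / m + var(v01) / n)
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(pmax(auc + c(-1, 1) * z * se, 0), 1)
  list(auc = auc, ci = ci, se = se)
}

#' Drug-regimen-adjusted AUC
#'
#' Removes confounding of the predicted probability of tolerance by the drug
#' regimen before measuring discrimination: the probability is regressed by
#' OLS on the five drug indicators among IS-treated patients; treated
#' patients are replaced by their residuals, and untreated (tolerant)
#' patients by their probability minus the model intercept — the prediction
#' for an all-zero regimen, mirroring the IS-IE rescaling convention. The
#' adjusted AUC is the AUC of these residuals against the labels. A
#' classifier that discriminates only through drug effects collapses to
#' chance after adjustment.
#'
#' @param probabilities named per-sample probabilities (tolerant + treated).
#' @param labels logical, `TRUE` = tolerant.
#' @param design binary sample x drug matrix over the treated samples
#'   ([encode_drug_design()]); tolerant samples must not appear in it.
#' @return list: `auc_adjusted`, `auc_raw`, `residuals`.
#' @export
adjusted_auc <- function(probabilities, labels, design) {
  labels <- as.logical(labels)
  ids <- names(probabilities)
  if (is.null(ids)) stopf("probabilities must be named by sample id")
  is_ids <- rownames(design)
  if (!all(is_ids %in% ids))
    stopf("design contains samples without probabilities")
  X <- cbind(`(Intercept)` = 1, design[, DRUGS, drop = FALSE])
  fit <- lm.fit(X, probabilities[is_ids])
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  resid <- probabilities
  # same arithmetic for both strata so degenerate inputs stay exactly tied
  resid[is_ids] <- probabilities[is_ids] - drop(X %*% cf)
  untreated <- setdiff(ids, is_ids)
  resid[untreated] <- probabilities[untreated] - cf[1]
  # zap rounding noise so degenerate (drug-determined or constant) inputs
  # give exact ties rather than arbitrary orderings
  resid[abs(resid) < 1e-10] <- 0
  list(auc_adjusted = auc_mw(resid, labels),
       auc_raw = auc_mw(probabilities, labels),
       residuals = resid)
}

#' Association of a per-sample quantity with drug intake
#'
#' OLS of the value (predicted probability of tolerance, a gene's
#' expression, a cell-subset size, ...) on all five drug indicators
#' simultaneously, so each drug's test is adjusted for the others; two-sided
#' t-tests per coefficient with Bonferroni correction inside the
#' calcineurin-inhibitor and antiproliferative families.
#'
#' @param values named numeric vector over the samples of `design`.
#' @param design binary sample x drug matrix.
#' @param family_sizes Bonferroni multipliers per drug.
#' @return data frame: `drug`, `estimate`, `se`, `p_value`, `p_adjusted`,
#'   `computable` (`FALSE` for non-estimable coefficients).
#' @export
probability_drug_association <- function(values, design,
                                         family_sizes = DEFAULT_FAMILY_SIZES) {
  ids <- rownames(design)
  if (!is.null(names(values))) {
    miss <- setdiff(ids, names(values))
    if (length(miss))
      stopf("values missing for sample(s): %s", paste(miss, collapse = ", "))
    values <- values[ids]
  } else if (length(values) != nrow(design)) {
    stopf("values must align with the rows of design")
  }
  X <- cbind(`(Intercept)` = 1, design[, DRUGS, drop = FALSE])
  blk <- ols_block(X, matrix(values, ncol = 1))
  est <- blk$coef[DRUGS, 1]
  se <- blk$se[DRUGS, 1]
  p <- 2 * pt(-abs(est / se), blk$df)
  fit_scale <- 1 + sqrt(sum(blk$coef[, 1]^2, na.rm = TRUE))
  if (!is.na(blk$sigma[1]) && blk$sigma[1] <= 1e-8 * fit_scale) {
    # exact linear dependence on the regimen: a zero coefficient is fully
    # consistent (p = 1), a nonzero one is exactly determined (p = 0)
    p <- ifelse(abs(est) > 1e-8 * fit_scale, 0, 1)
  }
  adj <- pmin(1, p * family_sizes[DRUGS])
  data.frame(drug = DRUGS, estimate = unname(est), se = unname(se),
             p_value = unname(p), p_adjusted = unname(adj),
             computable = !is.na(p), stringsAsFactors = FALSE)
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Two-sided signed-rank test on paired values (e.g. the predicted
#' probability of tolerance before and after steroid withdrawal). Zero
#' differences are dropped; the exact distribution is used for up to 25
#' nonzero pairs without ties, otherwise the normal approximation with tie
#' correction. All-zero differences give p = 1 with a degenerate flag.
#'
#' @param pre,post equal-length paired numeric vectors.
#' @return list: `statistic` (V), `p_value`, `n_pairs` (nonzero),
#'   `degenerate`.
#' @export
paired_wilcoxon <- function(pre, post) {
  if (length(pre) != length(post)) stopf("pre and post must be paired")
  d <- post - pre
  d <- d[!is.na(d)]
  if (!length(d)) stopf("no complete pairs")
  d <- d[d != 0]
  if (!length(d))
    return(list(statistic = NA_real_, p_value = 1, n_pairs = 0L,
                degenerate = TRUE))
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  wt <- suppressWarnings(wilcox.test(d, mu = 0, exact = exact,
                                     correct = FALSE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_pairs = length(d), degenerate = FALSE)
}

#' Exact McNemar test of classification stability
#'
#' Tests whether binary tolerant/non-tolerant classifications change between
#' two time points using the exact binomial McNemar test on the discordant
#' pairs: with `b` patients switching 1 to 0 and `c` switching 0 to 1,
#' `p = min(1, 2 * P(X <= min(b, c)))` for `X ~ Binomial(b + c, 1/2)`.
#' A nonsignificant result indicates classification stability.
#'
#' @param class_t1,class_t2 paired binary (logical or 0/1) classifications.
#' @return list: `b`, `c`, `p_value`, `n_pairs`.
#' @export
mcnemar_stability <- function(class_t1, class_t2) {
  if (length(class_t1) != length(class_t2) || length(class_t1) == 0)
    stopf("paired classifications of equal positive length required")
  t1 <- as.logical(class_t1)
  t2 <- as.logical(class_t2)
  b <- sum(t1 & !t2)
  cc <- sum(!t1 & t2)
  p <- if (b + cc == 0) 1 else min(1, 2 * pbinom(min(b, cc), b + cc, 0.5))
  list(b = b, c = cc, p_value = p, n_pairs = length(t1))
}

#' Full classifier evaluation report
#'
#' Bundles the discrimination and confounding diagnostics for a signature on
#' one cohort: raw AUC with DeLong CI, drug-adjusted AUC, per-drug
#' association tests of the predicted probability (among stable patients, as
#' in the confounding analyses), and counts classified tolerant at the
#' signature cutoff.
#'
#' @param probabilities named probabilities for tolerant + treated samples.
#' @param metadata validated metadata covering those samples.
#' @param cutoff classification cutoff (may be `NA` to skip counts).
#' @param assoc_groups groups over which the drug-association regression
#'   runs, default stable patients only.
#' @return list of class `evaluation_report`.
#' @export
evaluate_probabilities <- function(probabilities, metadata, cutoff = NA,
                                   assoc_groups = "stable") {
  metadata <- validate_metadata(metadata)
  md <- metadata[match(names(probabilities), metadata$sample_id), ]
  labels <- md$group == "tolerant"
  design <- encode_drug_design(md)
  design <- design[rownames(design) %in% names(probabilities), , drop = FALSE]
  raw <- roc_auc_ci(probabilities, labels)
  adj <- adjusted_auc(probabilities, labels, design)
  assoc_design <- encode_drug_design(md, groups = assoc_groups)
  assoc <- probability_drug_association(probabilities, assoc_design)
  counts <- if (is.na(cutoff)) NULL else list(
    n_classified_tolerant = sum(probabilities >= cutoff),
    n_treated_classified_tolerant =
      sum(probabilities >= cutoff & !labels),
    n_total = length(probabilities))
  structure(list(auc = raw$auc, auc_ci = raw$ci,
                 auc_adjusted = adj$auc_adjusted,
                 drug_association = assoc, cutoff = cutoff, counts = counts),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f), adjusted AUC %.3f\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], x$auc_adjusted))
  sig <- x$drug_association$drug[x$drug_association$p_adjusted < 0.05 &
                                   x$drug_association$computable]
  cat("drug associations (adj p < 0.05): ",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n", sep = "")
  invisible(x)
}
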