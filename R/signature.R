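#' K-nearest-neighbor imputation of missing expression values
#'
#' Each missing entry of a gene x sample matrix is replaced by the mean of
#' that gene's values in the `k` nearest samples. Sample-to-sample distance
#' is the Euclidean distance over mutually observed genes, normalized by the
#' number of shared genes so samples with different missingness patterns are
#' comparable. Only samples in which the gene is observed are eligible
#' neighbors; distance ties are broken by column order, so the result is
#' deterministic. A complete matrix is returned unchanged.
#'
#' @param expr gene x sample matrix with `NA` for missing entries.
#' @param k number of neighbors, default 5; must be smaller than the number
#'   of reference samples.
#' @param reference optional gene x sample matrix supplying the neighbor pool
#'   (e.g. the training split when imputing held-out samples); defaults to
#'   `expr` itself, excluding the sample being imputed.
#' @return complete gene x sample matrix.
#' @export
knn_impute <- function(expr, k = 5, reference = NULL) {
  if (!anyNA(expr)) return(expr)
  self <- is.null(reference)
  ref <- if (self) expr else reference
  if (!identical(rownames(ref), rownames(expr)))
    stopf("reference must cover the same genes in the same order")
  all_missing <- rownames(expr)[rowSums(!is.na(ref)) == 0]
  if (length(all_missing))
    stopf("gene(s) missing in every reference sample: %s",
          paste(all_missing, collapse = ", "))
  n_ref <- ncol(ref) - as.integer(self)
  if (k >= n_ref + as.integer(self) && self)
    stopf("k (%d) must be smaller than the number of samples (%d)", k, ncol(ref))
  if (!self && k > n_ref)
    stopf("k (%d) exceeds the number of reference samples (%d)", k, n_ref)

  out <- expr
  for (s in which(colSums(is.na(expr)) > 0)) {
    x <- expr[, s]
    cand <- seq_len(ncol(ref))
    if (self) cand <- cand[cand != s]
    # normalized Euclidean distance over mutually observed genes
    d <- vapply(cand, function(j) {
      shared <- !is.na(x) & !is.na(ref[, j])
      if (!any(shared)) return(Inf)
      sqrt(mean((x[shared] - ref[shared, j])^2))
    }, 0)
    ord <- cand[order(d)]
    for (g in which(is.na(x))) {
      avail <- ord[!is.na(ref[g, ord])]
      if (!length(avail))
        stopf("no neighbor with observed value for gene '%s'", rownames(expr)[g])
      out[g, s] <- mean(ref[g, avail[seq_len(min(k, length(avail)))]])
    }
  }
  out
}

std_constants <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

std_apply <- function(x, cs) {
  scale(x, center = cs$center, scale = cs$scale)
}

# largest penalty with all slopes zero, for building a lambda path
lambda_max_logistic <- function(x_std, y, alpha) {
  n <- length(y)
  max(abs(crossprod(x_std, y - mean(y)))) / (n * max(alpha, 1e-3))
}

default_lambda_path <- function(x_std, y, alpha, n_lambda = 50, decades = 4) {
  lmax <- lambda_max_logistic(x_std, y, alpha)
  lmax * 10^seq(0, -decades, length.out = n_lambda)
}

#' Elastic-net penalized logistic regression at fixed hyperparameters
#'
#' Minimizes the mean negative binomial log-likelihood plus
#' `lambda * (alpha * ||b||_1 + (1 - alpha)/2 * ||b||_2^2)` over the slopes
#' (intercept unpenalized), via `glmnet`. At `alpha > 0` excluded genes get
#' exact zero coefficients. The solver is warm-started along a decreasing
#' lambda path ending at the requested value, so small penalties (including
#' `lambda = 0`, the unpenalized maximum-likelihood fit) are solved
#' accurately.
#'
#' @param x samples x genes numeric matrix, complete; no internal
#'   standardization is applied (standardize beforehand, see
#'   [tune_signature()]).
#' @param y binary outcome (logical or 0/1), both classes present.
#' @param alpha elastic-net mixing parameter in `[0, 1]` (1 = lasso).
#' @param lambda penalty strength, `>= 0`.
#' @param weights optional per-sample observation weights.
#' @param thresh glmnet convergence threshold.
#' @return list with named `coefficients` (length = genes, exact zeros for
#'   excluded genes), `intercept`, `alpha`, `lambda`.
#' @export
fit_elastic_net_logistic <- function(x, y, alpha, lambda, weights = NULL,
                                     thresh = 1e-10) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stopf("y must contain both classes")
  if (any(!is.finite(x))) stopf("x must be complete and finite")
  if (lambda < 0 || alpha < 0 || alpha > 1)
    stopf("require lambda >= 0 and alpha in [0, 1]")
  path <- default_lambda_path(x, y, alpha, n_lambda = 30)
  path <- sort(unique(c(path[path > lambda], lambda)), decreasing = TRUE)
  fit <- suppressWarnings(
    glmnet::glmnet(x, y, family = "binomial", alpha = alpha,
                   lambda = path, standardize = FALSE, thresh = thresh,
                   weights = weights, maxit = 1e6))
  i <- which.min(abs(fit$lambda - lambda))
  beta <- as.numeric(fit$beta[, i])
  names(beta) <- rownames(fit$beta)
  list(coefficients = beta, intercept = unname(fit$a0[i]),
       alpha = alpha, lambda = lambda)
}

# Mann-Whitney AUC with ties counted 1/2 (midranks)
auc_mw <- function(scores, labels) {
  labels <- as.logical(labels)
  r <- rank(scores)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stopf("both classes required for AUC")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# stratified random train/test splits, fixed across the tuning grid
make_splits <- function(labels, train_frac, iters) {
  idx_pos <- which(labels)
  idx_neg <- which(!labels)
  lapply(seq_len(iters), function(i) {
    c(sample(idx_pos, max(1, round(train_frac * length(idx_pos)))),
      sample(idx_neg, max(1, round(train_frac * length(idx_neg)))))
  })
}

#' Tune and fit the tolerance signature
#'
#' Derives a penalized-logistic tolerance signature (tolerant vs IS-treated)
#' from IS-IE (or raw) expression. Hyperparameters are tuned by leave-group-
#' out resampling: `iters` stratified random splits with `train_frac` of each
#' class in training, mean held-out AUC per grid point, and the winning point
#' chosen among those whose full-data refit selects at most `max_genes` genes.
#' Genes are centered and scaled to unit SD on the training data before
#' penalization; the constants travel with the signature. Missing values are
#' imputed once up front with [knn_impute()].
#'
#' @param expr gene x sample matrix (typically the [isie_transform()] output
#'   restricted to tolerant + treated samples).
#' @param labels logical per sample, `TRUE` = tolerant; healthy controls must
#'   be excluded from training.
#' @param alpha_grid mixing parameters to scan.
#' @param n_lambda,lambda_decades per-alpha penalty path: `n_lambda` points
#'   log-spaced over `lambda_decades` decades below the smallest
#'   all-zero-slope penalty.
#' @param train_frac,iters resampling scheme (default 65% training, 100
#'   iterations).
#' @param max_genes signature size cap (default 30).
#' @param k_impute neighbors for [knn_impute()].
#' @param seed integer seed; the same seed reproduces the result bit for bit.
#' @return list with `tuning` (data frame over the grid: `alpha`, `lambda`,
#'   `mean_auc`, `n_nonzero`, `eligible`) and `signature` (class
#'   `tolerance_signature`).
#' @export
tune_signature <- function(expr, labels,
                           alpha_grid = seq(0.1, 1, by = 0.1),
                           n_lambda = 50, lambda_decades = 4,
                           train_frac = 0.65, iters = 100,
                           max_genes = 30, k_impute = 5, seed = 1L) {
  labels <- as.logical(labels)
  if (length(labels) != ncol(expr))
    stopf("labels must align with the columns of expr")
  if (!any(labels) || all(labels)) stopf("both classes required")
  expr <- knn_impute(expr, k = k_impute)
  x <- t(expr)
  set.seed(seed)
  splits <- make_splits(labels, train_frac, iters)

  grid <- list()
  for (a in alpha_grid) {
    cs_full <- std_constants(x)
    path <- default_lambda_path(std_apply(x, cs_full), labels, a,
                                n_lambda = n_lambda, decades = lambda_decades)
    auc_mat <- matrix(NA_real_, iters, length(path))
    for (i in seq_len(iters)) {
      tr <- splits[[i]]
      te <- setdiff(seq_len(nrow(x)), tr)
      if (length(unique(labels[te])) < 2) next
      cs <- std_constants(x[tr, , drop = FALSE])
      # the tiny tolerant class trips glmnet's small-class warning every split
      fit <- suppressWarnings(
        glmnet::glmnet(std_apply(x[tr, , drop = FALSE], cs), labels[tr],
                       family = "binomial", alpha = a, lambda = path,
                       standardize = FALSE, maxit = 1e6))
      lp <- predict(fit, std_apply(x[te, , drop = FALSE], cs), s = path,
                    type = "link")
      auc_mat[i, ] <- apply(lp, 2, auc_mw, labels = labels[te])
    }
    full <- suppressWarnings(
      glmnet::glmnet(std_apply(x, cs_full), labels, family = "binomial",
                     alpha = a, lambda = path, standardize = FALSE,
                     maxit = 1e6))
    grid[[length(grid) + 1]] <- data.frame(
      alpha = a, lambda = path,
      mean_auc = colMeans(auc_mat, na.rm = TRUE),
      n_nonzero = full$df, eligible = full$df <= max_genes)
  }
  tuning <- do.call(rbind, grid)
  if (!any(tuning$eligible))
    stopf("no grid point selects <= %d genes; widen the lambda range upward",
          max_genes)
  elig <- tuning[tuning$eligible, ]
  # max mean AUC; ties -> sparser (larger lambda), then smaller alpha
  best <- elig[order(-elig$mean_auc, -elig$lambda, elig$alpha), ][1, ]

  cs <- std_constants(x)
  fit <- fit_elastic_net_logistic(std_apply(x, cs), labels,
                                  alpha = best$alpha, lambda = best$lambda)
  nz <- fit$coefficients != 0
  signature <- structure(list(
    genes = names(fit$coefficients)[nz],
    coefficients = fit$coefficients[nz],
    intercept = fit$intercept,
    alpha = best$alpha, lambda = best$lambda,
    center = cs$center[nz], scale = cs$scale[nz],
    cutoff = NA_real_, max_genes = max_genes,
    mean_cv_auc = best$mean_auc,
    train_frac = train_frac, iters = iters, seed = seed),
    class = "tolerance_signature")
  stopifnot(length(signature$genes) <= max_genes)  # hard gene-cap assertion
  list(tuning = tuning, signature = signature)
}

#' @export
print.tolerance_signature <- function(x, ...) {
  cat(sprintf(
    "tolerance_signature: %d genes (alpha = %.2f, lambda = %.4g, resampled AUC = %.3f, cutoff = %s)\n",
    length(x$genes), x$alpha, x$lambda, x$mean_cv_auc,
    ifelse(is.na(x$cutoff), "unset", format(x$cutoff))))
  invisible(x)
}

#' Predicted probability of tolerance
#'
#' Applies a fitted [tolerance signature][tune_signature]: each signature
#' gene is standardized with the training centering/scaling constants and the
#' probability is the inverse logit of `intercept + sum(coef * z)`.
#'
#' @param signature a `tolerance_signature`.
#' @param expr gene x sample matrix containing every signature gene, with no
#'   missing values in those genes (impute first, see [knn_impute()]).
#' @return named numeric vector of probabilities in `[0, 1]`.
#' @export
predict_probability <- function(signature, expr) {
  miss <- setdiff(signature$genes, rownames(expr))
  if (length(miss))
    stopf("signature gene(s) absent from expression matrix: %s",
          paste(miss, collapse = ", "))
  xg <- expr[signature$genes, , drop = FALSE]
  if (anyNA(xg))
    stopf("missing values in signature genes; run knn_impute() first")
  if (length(signature$genes) == 0)
    return(setNames(rep(plogis(signature$intercept), ncol(expr)),
                    colnames(expr)))
  z <- (xg - signature$center) / signature$scale
  lp <- signature$intercept + drop(crossprod(z, signature$coefficients))
  setNames(plogis(lp), colnames(expr))
}

#' Select a classification cutoff under sensitivity/specificity constraints
#'
#' Candidate cutoffs are the midpoints between adjacent sorted unique
#' probabilities. Among candidates achieving specificity `>= spec_min` and
#' sensitivity `>= sens_min`, the one maximizing specificity is returned
#' (ties broken by higher sensitivity, then by lower cutoff — safety first:
#' misclassifying a non-tolerant patient as tolerant risks graft loss).
#' When no candidate qualifies the result is flagged infeasible; there is no
#' silent fallback.
#'
#' @param probabilities predicted probabilities of tolerance.
#' @param labels logical, `TRUE` = tolerant.
#' @param spec_min,sens_min constraints (defaults 0.85 and 0.70).
#' @return list: `cutoff`, `sensitivity`, `specificity`, `feasible`.
#' @export
select_cutoff <- function(probabilities, labels, spec_min = 0.85,
                          sens_min = 0.70) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) stopf("both classes required")
  u <- sort(unique(probabilities))
  if (length(u) < 2)
    return(list(cutoff = NA_real_, sensitivity = NA_real_,
                specificity = NA_real_, feasible = FALSE))
  cand <- (u[-1] + u[-length(u)]) / 2
  sens <- vapply(cand, function(c) mean(probabilities[labels] >= c), 0)
  spec <- vapply(cand, function(c) mean(probabilities[!labels] < c), 0)
  ok <- spec >= spec_min & sens >= sens_min
  if (!any(ok))
    return(list(cutoff = NA_real_, sensitivity = NA_real_,
                specificity = NA_real_, feasible = FALSE))
  i <- which(ok)[order(-spec[ok], -sens[ok], cand[ok])][1]
  list(cutoff = cand[i], sensitivity = sens[i], specificity = spec[i],
       feasible = TRUE)
}

#' Optimism-corrected (cross-validated) AUC
#'
#' Mean held-out AUC over stratified random splits, with the full prediction
#' pipeline — KNN imputation (neighbors restricted to the training split),
#' standardization constants and the penalized fit — re-estimated inside each
#' training split, so the estimate is free of resubstitution optimism.
#' Held-out sets lacking one of the classes are skipped and counted.
#'
#' @inheritParams tune_signature
#' @param alpha,lambda hyperparameters of the penalized fit (typically the
#'   tuned values of the signature).
#' @return list: `cv_auc` (mean), `per_iteration`, `n_skipped`.
#' @export
cross_validated_auc <- function(expr, labels, alpha, lambda,
                                train_frac = 0.65, iters = 100,
                                k_impute = 5, seed = 1L) {
  labels <- as.logical(labels)
  set.seed(seed)
  splits <- make_splits(labels, train_frac, iters)
  aucs <- rep(NA_real_, iters)
  for (i in seq_len(iters)) {
    tr <- splits[[i]]
    te <- setdiff(seq_len(ncol(expr)), tr)
    if (length(unique(labels[te])) < 2) next
    etr <- knn_impute(expr[, tr, drop = FALSE], k = k_impute)
    ete <- knn_impute(expr[, te, drop = FALSE], k = k_impute, reference = etr)
    cs <- std_constants(t(etr))
    fit <- fit_elastic_net_logistic(std_apply(t(etr), cs), labels[tr],
                                    alpha = alpha, lambda = lambda,
                                    thresh = 1e-8)
    lp <- drop(std_apply(t(ete), cs) %*% fit$coefficients) + fit$intercept
    aucs[i] <- auc_mw(lp, labels[te])
  }
  list(cv_auc = mean(aucs, na.rm = TRUE), per_iteration = aucs,
       n_skipped = sum(is.na(aucs)))
}

#' Serialize / read a tolerance signature as JSON
#' @param signature a `tolerance_signature`.
#' @param path file path.
#' @export
write_signature <- function(signature, path) {
  jsonlite::write_json(unclass(signature), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("coefficients", "center", "scale"))
    j[[f]] <- setNames(as.numeric(j[[f]]), j$genes)
  j$genes <- as.character(j$genes)
  structure(j, class = "tolerance_signature")
}
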