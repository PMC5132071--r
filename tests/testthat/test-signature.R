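test_that("KNN imputation averages the nearest samples' values", {
  # s3 misses gA; its two nearest neighbors are s1 (value 3) and s2 (value 5)
  expr <- rbind(gA = c(3, 5, NA, 40),
                gB = c(1, 1, 1, 30),
                gC = c(2, 2, 2, 35))
  colnames(expr) <- paste0("s", 1:4)
  out <- knn_impute(expr, k = 2)
  expect_equal(out["gA", "s3"], 4.0)

  complete <- matrix(rnorm(20), 4, 5,
                     dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
  expect_identical(knn_impute(complete, k = 2), complete)
})

test_that("KNN imputation matches the exhaustive neighbor-search oracle", {
  set.seed(20)
  expr <- matrix(rnorm(300), 20, 15,
                 dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:15)))
  expr[sample(300, 15)] <- NA
  expect_equal(knn_impute(expr, k = 5), knn_oracle(expr, k = 5),
               tolerance = 1e-12)
})

test_that("KNN imputation rejects degenerate inputs", {
  expr <- rbind(gA = c(NA_real_, NA_real_), gB = c(1, 2))
  colnames(expr) <- c("s1", "s2")
  expect_error(knn_impute(expr, k = 1), "gA")
  expr2 <- rbind(gA = c(1, 2), gB = c(NA, 3))
  colnames(expr2) <- c("s1", "s2")
  expect_error(knn_impute(expr2, k = 5), "smaller than")
})

test_that("fully penalized logistic fit collapses to the intercept-only model", {
  set.seed(21)
  x <- matrix(rnorm(200), 40, 5, dimnames = list(NULL, paste0("g", 1:5)))
  y <- rep(c(1, 0), c(15, 25))
  fit <- fit_elastic_net_logistic(x, y, alpha = 0.5, lambda = 10)
  expect_equal(unname(fit$coefficients), rep(0, 5))
  expect_equal(fit$intercept, log(15 / 25), tolerance = 1e-6)
})

test_that("unpenalized fit matches the IRLS maximum-likelihood oracle", {
  set.seed(22)
  x <- matrix(rnorm(160), 80, 2, dimnames = list(NULL, c("g1", "g2")))
  y <- rbinom(80, 1, plogis(0.3 + 0.8 * x[, 1] - 0.5 * x[, 2]))
  fit <- fit_elastic_net_logistic(x, y, alpha = 1, lambda = 0)
  oracle <- irls_logistic(x, y)
  expect_equal(unname(c(fit$intercept, fit$coefficients)), unname(oracle),
               tolerance = 1e-4)
})

test_that("ridge shares the coefficient equally across duplicated genes", {
  set.seed(23)
  x1 <- rnorm(60)
  x <- cbind(gA = x1, gB = x1, gC = rnorm(60))
  y <- rbinom(60, 1, plogis(x1))
  fit <- fit_elastic_net_logistic(x, y, alpha = 0, lambda = 0.1,
                                  thresh = 1e-13)
  expect_lt(abs(fit$coefficients["gA"] - fit$coefficients["gB"]), 1e-6)
})

test_that("lasso support is monotone along an increasing penalty on orthonormal predictors", {
  set.seed(24)
  x <- qr.Q(qr(matrix(rnorm(50 * 10), 50, 10))) * sqrt(50)
  colnames(x) <- paste0("g", 1:10)
  y <- rbinom(50, 1, plogis(x[, 1] - x[, 2]))
  lambdas <- 10^seq(-4, 0, length.out = 12)
  nnz <- vapply(lambdas, function(l)
    sum(fit_elastic_net_logistic(x, y, alpha = 1, lambda = l,
                                 thresh = 1e-9)$coefficients != 0), 0L)
  expect_true(all(diff(nnz) <= 0))
})

test_that("predicted probabilities equal the dot-product inverse-logit oracle", {
  set.seed(25)
  genes <- paste0("g", 1:6)
  sig <- structure(list(
    genes = genes, coefficients = setNames(rnorm(6), genes),
    intercept = 0.4, alpha = 0.5, lambda = 0.1,
    center = setNames(rnorm(6), genes),
    scale = setNames(runif(6, 0.5, 2), genes), cutoff = NA_real_),
    class = "tolerance_signature")
  expr <- matrix(rnorm(60), 6, 10, dimnames = list(genes, paste0("s", 1:10)))
  p <- predict_probability(sig, expr)
  oracle <- vapply(seq_len(10), function(i) {
    z <- (expr[, i] - sig$center) / sig$scale
    1 / (1 + exp(-(sig$intercept + sum(sig$coefficients * z))))
  }, 0)
  expect_equal(unname(p), oracle, tolerance = 1e-12)

  # centering identity: a sample at the training mean scores plogis(intercept)
  at_mean <- matrix(sig$center, 6, 1, dimnames = list(genes, "m"))
  expect_equal(unname(predict_probability(sig, at_mean)),
               plogis(0.4), tolerance = 1e-12)

  # null model: zero coefficients, zero intercept -> probability 0.5
  sig0 <- sig
  sig0$coefficients[] <- 0
  sig0$intercept <- 0
  expect_equal(unname(predict_probability(sig0, expr)), rep(0.5, 10))

  expect_error(predict_probability(sig, expr[1:5, ]), "g6")
})

test_that("prediction is invariant to affine rescaling of gene units", {
  set.seed(26)
  genes <- paste0("g", 1:4)
  sig <- structure(list(
    genes = genes, coefficients = setNames(rnorm(4), genes),
    intercept = -0.2, center = setNames(rnorm(4), genes),
    scale = setNames(runif(4, 0.5, 2), genes), cutoff = NA_real_),
    class = "tolerance_signature")
  expr <- matrix(rnorm(40), 4, 10, dimnames = list(genes, paste0("s", 1:10)))
  a <- runif(4, 0.5, 3)
  b <- rnorm(4)
  sig2 <- sig
  sig2$center <- a * sig$center + b
  sig2$scale <- a * sig$scale
  expect_equal(predict_probability(sig2, expr * a + b),
               predict_probability(sig, expr), tolerance = 1e-12)
})

test_that("cutoff selection obeys the constrained-maximization contract", {
  # perfectly separated probabilities -> midpoint 0.5, perfect operating point
  res <- select_cutoff(c(0.9, 0.9, 0.9, 0.1, 0.1, 0.1),
                       c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(res$cutoff, 0.5)
  expect_equal(res$sensitivity, 1.0)
  expect_equal(res$specificity, 1.0)
  expect_true(res$feasible)

  # agreement with exhaustive enumeration on random 10-sample sets
  set.seed(27)
  for (i in 1:50) {
    prob <- round(runif(10), 2)
    lab <- sample(c(TRUE, FALSE), 10, TRUE)
    if (!any(lab) || all(lab)) next
    got <- select_cutoff(prob, lab, spec_min = 0.6, sens_min = 0.5)
    want <- cutoff_oracle(prob, lab, spec_min = 0.6, sens_min = 0.5)
    if (is.na(want)) expect_false(got$feasible)
    else expect_equal(got$cutoff, want)
  }

  # infeasible constraints are reported, never silently relaxed
  res2 <- select_cutoff(c(0.4, 0.6, 0.5, 0.5), c(TRUE, FALSE, TRUE, FALSE))
  expect_false(res2$feasible)
  expect_true(is.na(res2$cutoff))
})

test_that("tuning is deterministic and respects the gene cap", {
  set.seed(28)
  expr <- matrix(rnorm(40 * 60), 40, 60,
                 dimnames = list(sprintf("g%02d", 1:40), sprintf("s%02d", 1:60)))
  lab <- rep(c(TRUE, FALSE), c(15, 45))
  expr[1:3, lab] <- expr[1:3, lab] + 2
  a <- tune_signature(expr, lab, alpha_grid = c(0.5, 1), n_lambda = 12,
                      iters = 10, max_genes = 10, seed = 99)
  b <- tune_signature(expr, lab, alpha_grid = c(0.5, 1), n_lambda = 12,
                      iters = 10, max_genes = 10, seed = 99)
  expect_identical(a$tuning, b$tuning)
  expect_identical(a$signature, b$signature)
  expect_lte(length(a$signature$genes), 10)
  expect_true(all(a$signature$coefficients != 0))
})

test_that("strongly informative genes are recovered by the tuned signature", {
  set.seed(29)
  hits <- replicate(10, {
    expr <- matrix(rnorm(40 * 200), 40, 200,
                   dimnames = list(sprintf("g%02d", 1:40),
                                   sprintf("s%03d", 1:200)))
    lab <- rep(c(TRUE, FALSE), each = 100)
    expr[1:5, lab] <- expr[1:5, lab] + 3
    sig <- quick_tune(expr, lab, seed = sample.int(1e6, 1))$signature
    all(sprintf("g%02d", 1:5) %in% sig$genes)
  })
  expect_gte(mean(hits), 0.9)
})

test_that("cross-validated AUC is calibrated at chance for permuted labels", {
  # conditional CV-AUC on one dataset has SD ~0.08 under the null, so the
  # calibration check averages over 20 replicate datasets
  set.seed(30)
  cvs <- replicate(20, {
    expr <- matrix(rnorm(20 * 100), 20, 100,
                   dimnames = list(paste0("g", 1:20), paste0("s", 1:100)))
    lab <- sample(rep(c(TRUE, FALSE), c(20, 80)))
    cross_validated_auc(expr, lab, alpha = 0.5, lambda = 0.05,
                        iters = 10, seed = sample.int(1e6, 1))$cv_auc
  })
  expect_gt(mean(cvs), 0.42)
  expect_lt(mean(cvs), 0.58)
})

test_that("cross-validated AUC is high for strong signal and below the apparent AUC", {
  set.seed(32)
  expr <- matrix(rnorm(20 * 120), 20, 120,
                 dimnames = list(paste0("g", 1:20), paste0("s", 1:120)))
  lab <- rep(c(TRUE, FALSE), c(30, 90))
  expr[1:4, lab] <- expr[1:4, lab] + 4
  cv <- cross_validated_auc(expr, lab, alpha = 0.5, lambda = 0.05,
                            iters = 25, seed = 33)
  expect_gte(cv$cv_auc, 0.95)

  # optimism direction: resubstitution AUC >= held-out AUC in most draws
  direction <- replicate(10, {
    e <- matrix(rnorm(15 * 60), 15, 60,
                dimnames = list(paste0("g", 1:15), paste0("s", 1:60)))
    l <- rep(c(TRUE, FALSE), c(15, 45))
    e[1, l] <- e[1, l] + 1
    cs <- tolsig:::std_constants(t(e))
    f <- fit_elastic_net_logistic(tolsig:::std_apply(t(e), cs), l,
                                  alpha = 0.5, lambda = 0.05)
    apparent <- tolsig:::auc_mw(
      drop(tolsig:::std_apply(t(e), cs) %*% f$coefficients), l)
    heldout <- cross_validated_auc(e, l, alpha = 0.5, lambda = 0.05,
                                   iters = 15, seed = 1)$cv_auc
    apparent >= heldout
  })
  expect_gte(mean(direction), 0.9)
})

test_that("signatures survive a JSON round trip", {
  set.seed(34)
  expr <- matrix(rnorm(30 * 50), 30, 50,
                 dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:50)))
  lab <- rep(c(TRUE, FALSE), c(12, 38))
  expr[1:2, lab] <- expr[1:2, lab] + 2.5
  sig <- quick_tune(expr, lab)$signature
  sig$cutoff <- 0.54
  f <- withr::local_tempfile(fileext = ".json")
  write_signature(sig, f)
  back <- read_signature(f)
  expect_equal(back$coefficients, sig$coefficients)
  expect_equal(back$center, sig$center)
  expect_equal(back$cutoff, 0.54)
  expect_equal(predict_probability(back, expr), predict_probability(sig, expr))
})
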