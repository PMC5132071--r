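test_that("OLS on a single binary covariate reduces to group means", {
  md <- data.frame(
    sample_id = sprintf("s%d", 1:10), patient_id = sprintf("p%d", 1:10),
    group = "stable", timepoint = "1",
    pred = rep(c(1L, 0L), each = 5), cyc = 0L, tac = 0L, aza = 0L, mmf = 0L,
    stringsAsFactors = FALSE)
  X <- encode_drug_design(md)
  expr <- matrix(rep(c(4, 2), each = 5), 1, 10,
                 dimnames = list("gA", md$sample_id))
  fit <- fit_drug_models(expr, X)
  expect_equal(fit$coefficients["gA", "(Intercept)"], 2)
  expect_equal(fit$coefficients["gA", "Pred"], 2)
  # the other drugs never vary: flagged non-estimable, not silently zero
  expect_true(all(is.na(fit$coefficients["gA", c("Cyc", "Tac", "Aza", "MMF")])))
  expect_equal(unname(fit$sigma["gA"]), 0)
})

test_that("constant expression gives intercept-only fit with zero R^2", {
  md <- make_treated_metadata(40, seed = 4)
  X <- encode_drug_design(md)
  expr <- matrix(5, 1, 40, dimnames = list("gA", md$sample_id))
  fit <- fit_drug_models(expr, X)
  expect_equal(fit$coefficients["gA", "(Intercept)"], 5)
  expect_equal(unname(fit$coefficients["gA", tolsig:::DRUGS]),
               rep(0, 5), ignore_attr = TRUE)
  expect_equal(unname(fit$r_squared["gA"]), 0)
})

test_that("gene-wise complete-case fitting handles missing expression", {
  md <- make_treated_metadata(60, seed = 5)
  X <- encode_drug_design(md)
  set.seed(5)
  expr <- matrix(rnorm(120), 2, 60,
                 dimnames = list(c("gA", "gB"), md$sample_id))
  expr["gB", 1:10] <- NA
  fit <- fit_drug_models(expr, X)
  expect_equal(unname(fit$n_used), c(60L, 50L))
  sub <- fit_drug_models(expr["gB", 11:60, drop = FALSE], X[11:60, ])
  expect_equal(fit$coefficients["gB", ], sub$coefficients["gB", ])

  expr2 <- expr
  expr2["gB", 1:55] <- NA
  expect_error(fit_drug_models(expr2, X), "gB")
})

test_that("IS-IE rescaling subtracts the intercept for untreated samples and the fitted value for treated", {
  md <- make_treated_metadata(30, seed = 6)
  X <- encode_drug_design(md)
  set.seed(6)
  expr <- matrix(rnorm(90, mean = 2), 3, 30,
                 dimnames = list(c("gA", "gB", "gC"), md$sample_id))
  fit <- fit_drug_models(expr, X)

  md_tol <- data.frame(sample_id = "t1", patient_id = "pt1",
                       group = "tolerant", timepoint = "1", pred = 0L,
                       cyc = 0L, tac = 0L, aza = 0L, mmf = 0L,
                       stringsAsFactors = FALSE)
  y_tol <- matrix(5, 3, 1, dimnames = list(rownames(expr), "t1"))
  out_tol <- isie_transform(y_tol, md_tol, fit)
  expect_equal(out_tol[, "t1"], 5 - fit$coefficients[, "(Intercept)"])

  # a treated sample lying exactly on the fitted plane has IS-IE zero
  x1 <- c(1, X[1, ])
  on_plane <- matrix(drop(fit$coefficients %*% x1), 3, 1,
                     dimnames = list(rownames(expr), md$sample_id[1]))
  out_pl <- isie_transform(on_plane, md[1, ], fit)
  expect_equal(unname(out_pl[, 1]), rep(0, 3), tolerance = 1e-12)

  expect_error(isie_transform(rbind(expr, gZ = expr[1, ]), md, fit), "gZ")
})

test_that("double residualization is idempotent: refit on IS-IE gives alpha = beta = 0", {
  sim <- simulate_study(cohort_config(n_genes = 25, seed = 8))
  fit <- fit_drug_models(sim$expr, sim$design)
  isie <- isie_transform(sim$expr, sim$metadata, fit)
  refit <- fit_drug_models(isie, sim$design)
  expect_lt(max(abs(refit$coefficients)), 1e-8)
})

test_that("in-sample residuals are orthogonal to every drug indicator", {
  sim <- simulate_study(cohort_config(n_genes = 30, seed = 9))
  fit <- fit_drug_models(sim$expr, sim$design)
  isie <- isie_transform(sim$expr, sim$metadata, fit)
  res <- isie[, rownames(sim$design)]
  Xc <- scale(sim$design, scale = FALSE)
  expect_lt(max(abs(res %*% Xc)), 1e-8)
  expect_lt(max(abs(rowSums(res))), 1e-8)
})

test_that("IS-IE is a pure shift for untreated samples", {
  sim <- simulate_study(cohort_config(n_genes = 15, seed = 10))
  fit <- fit_drug_models(sim$expr, sim$design)
  isie <- isie_transform(sim$expr, sim$metadata, fit)
  unt <- sim$metadata$sample_id[sim$metadata$group %in% c("tolerant", "healthy")]
  expect_equal(apply(isie[, unt], 1, var), apply(sim$expr[, unt], 1, var),
               tolerance = 1e-12)
})

test_that("held-out rescaling applies the time-point-1 model without refitting", {
  cfg <- cohort_config(n_genes = 12, seed = 12)
  sim <- simulate_study(cfg)
  fit <- fit_drug_models(sim$expr, sim$design)
  same <- isie_transform_heldout(sim$expr, sim$metadata, fit)
  expect_identical(same, isie_transform(sim$expr, sim$metadata, fit))

  # stopping prednisone changes the correction by exactly beta_Pred
  treated <- sim$metadata[sim$metadata$group == "stable" &
                            sim$metadata$pred == 1, ][1, ]
  y <- sim$expr[, treated$sample_id, drop = FALSE]
  md_off <- treated
  md_off$pred <- 0L
  on <- isie_transform_heldout(y, treated, fit)
  off <- isie_transform_heldout(y, md_off, fit)
  expect_equal(off[, 1] - on[, 1], fit$coefficients[, "Pred"])
})

test_that("out-of-sample residuals are only approximately orthogonal to the design", {
  cfg <- cohort_config(n_genes = 20, within_subject_corr = 0.8, seed = 14)
  sim <- simulate_study(cfg)
  fit <- fit_drug_models(sim$expr, sim$design)
  t2 <- simulate_longitudinal(sim$metadata, sim$expr, sim$truth,
                              mode = "timepoint2", config = cfg)
  isie2 <- isie_transform_heldout(t2$expr, t2$metadata, fit)
  res2 <- isie2[, t2$metadata$sample_id[t2$metadata$group %in%
                                          c("stable", "chronic_rejector")]]
  Xc <- scale(sim$design, scale = FALSE)
  dots <- abs(res2 %*% Xc)
  expect_gt(max(dots), 1e-6)   # not exactly orthogonal out of sample
  expect_lt(max(dots) / ncol(res2), 1)  # but small per sample on average
})

test_that("per-drug tests apply family-wise Bonferroni correction", {
  md <- make_treated_metadata(200, seed = 15)
  X <- encode_drug_design(md)
  set.seed(15)
  expr <- matrix(rnorm(10 * 200), 10, 200,
                 dimnames = list(sprintf("g%02d", 1:10), md$sample_id))
  tab <- drug_effect_tests(expr, X)
  expect_true(all(tab$p_adjusted >= tab$p_value, na.rm = TRUE))
  expect_true(all(tab$p_adjusted <= 1, na.rm = TRUE))
  cni_ap <- tab$drug %in% c("Cyc", "Tac", "Aza", "MMF")
  expect_equal(tab$p_adjusted[cni_ap], pmin(1, 2 * tab$p_value[cni_ap]))
  expect_equal(tab$p_adjusted[tab$drug == "Pred"],
               tab$p_value[tab$drug == "Pred"])

  # zero residual variance is flagged, not reported as a p-value
  expr0 <- matrix(3, 1, 200, dimnames = list("gflat", md$sample_id))
  tab0 <- drug_effect_tests(expr0, X)
  expect_true(all(!tab0$computable))
})

test_that("null genes keep per-drug type-I error near the nominal 5%", {
  md <- make_treated_metadata(200, seed = 16)
  X <- encode_drug_design(md)
  set.seed(16)
  expr <- matrix(rnorm(1000 * 200), 1000, 200,
                 dimnames = list(sprintf("g%04d", 1:1000), md$sample_id))
  tab <- drug_effect_tests(expr, X)
  se3 <- 3 * sqrt(0.05 * 0.95 / 1000)
  for (d in tolsig:::DRUGS) {
    rate <- mean(tab$p_value[tab$drug == d] < 0.05)
    expect_lt(abs(rate - 0.05), se3)
  }
})

test_that("a strong prednisone effect is detected with high power", {
  md <- make_treated_metadata(200, seed = 17)
  X <- encode_drug_design(md)
  set.seed(17)
  hits <- replicate(40, {
    y <- 1.5 * X[, "Pred"] + rnorm(200)
    expr <- matrix(y, 1, 200, dimnames = list("gA", md$sample_id))
    tab <- drug_effect_tests(expr, X)
    tab$p_adjusted[tab$drug == "Pred"] < 0.001
  })
  expect_gte(mean(hits), 0.95)
})

test_that("drug variance explained matches the fit and its boundary cases", {
  md <- make_treated_metadata(100, seed = 18)
  X <- encode_drug_design(md)
  y_det <- 2 * X[, "Pred"] - 1 * X[, "Aza"]          # fully drug-determined
  set.seed(18)
  y_null <- rnorm(100)
  expr <- rbind(gdet = y_det, gnull = y_null)
  colnames(expr) <- md$sample_id
  r2 <- drug_variance_explained(expr, X)
  expect_equal(r2$r_squared[r2$gene_id == "gdet"], 1.0)
  expect_lt(r2$r_squared[r2$gene_id == "gnull"], 0.15)
  expect_equal(r2$pct, 100 * r2$r_squared)
})

test_that("drug-effect models survive a JSON round trip", {
  sim <- simulate_study(cohort_config(n_genes = 8, seed = 19))
  fit <- fit_drug_models(sim$expr, sim$design)
  f <- withr::local_tempfile(fileext = ".json")
  write_drug_effect_model(fit, f)
  back <- read_drug_effect_model(f)
  expect_equal(back$coefficients, fit$coefficients)
  expect_equal(back$r_squared, fit$r_squared)
})
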