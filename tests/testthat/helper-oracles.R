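# Independent oracles used to validate the package implementations.

# brute-force Mann-Whitney AUC: all positive/negative pairs, ties = 1/2
auc_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (x in pos) for (y in neg)
    tot <- tot + if (x > y) 1 else if (x == y) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# unpenalized logistic regression by Newton-Raphson (IRLS)
irls_logistic <- function(x, y, tol = 1e-12, maxit = 100) {
  X <- cbind(1, x)
  b <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% b)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    b_new <- solve(crossprod(X, w * X), crossprod(X, w * z))
    if (max(abs(b_new - b)) < tol) {
      b <- b_new
      break
    }
    b <- b_new
  }
  drop(b)
}

# exhaustive nearest-neighbor imputation: for each missing (gene, sample),
# rank every other sample by RMS distance over shared observed genes,
# keep the first k with that gene observed, average
knn_oracle <- function(expr, k) {
  out <- expr
  for (s in seq_len(ncol(expr))) {
    miss <- which(is.na(expr[, s]))
    if (!length(miss)) next
    d <- rep(Inf, ncol(expr))
    for (j in seq_len(ncol(expr))) {
      if (j == s) next
      shared <- which(!is.na(expr[, s]) & !is.na(expr[, j]))
      if (length(shared))
        d[j] <- sqrt(mean((expr[shared, s] - expr[shared, j])^2))
    }
    ord <- order(d)
    for (g in miss) {
      have <- ord[!is.na(expr[g, ord]) & is.finite(d[ord])]
      out[g, s] <- mean(expr[g, have[seq_len(min(k, length(have)))]])
    }
  }
  out
}

# exhaustive cutoff search mirroring the select_cutoff contract
cutoff_oracle <- function(prob, labels, spec_min = 0.85, sens_min = 0.70) {
  labels <- as.logical(labels)
  u <- sort(unique(prob))
  if (length(u) < 2) return(NA_real_)
  cand <- (u[-1] + u[-length(u)]) / 2
  best <- NULL
  for (c in cand) {
    sens <- mean(prob[labels] >= c)
    spec <- mean(prob[!labels] < c)
    if (spec < spec_min || sens < sens_min) next
    if (is.null(best) || spec > best$spec ||
        (spec == best$spec && sens > best$sens) ||
        (spec == best$spec && sens == best$sens && c < best$c))
      best <- list(c = c, sens = sens, spec = spec)
  }
  if (is.null(best)) NA_real_ else best$c
}

# small treated-only metadata with all five drugs varying, for OLS tests
make_treated_metadata <- function(n, seed = 1) {
  set.seed(seed)
  cni <- sample(c("none", "cyc", "tac"), n, TRUE)
  ap <- sample(c("none", "aza", "mmf"), n, TRUE)
  data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    patient_id = sprintf("P%03d", seq_len(n)),
    group = "stable", timepoint = "1",
    pred = rbinom(n, 1, 0.45),
    cyc = as.integer(cni == "cyc"), tac = as.integer(cni == "tac"),
    aza = as.integer(ap == "aza"), mmf = as.integer(ap == "mmf"),
    stringsAsFactors = FALSE)
}

# fast tuning settings for tests that need a trained signature
quick_tune <- function(expr, labels, seed = 1) {
  tune_signature(expr, labels, alpha_grid = 0.5, n_lambda = 15,
                 iters = 15, seed = seed)
}
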