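# Independent oracles and small fixture builders used across the suite.
# Everything here is deliberately naive (direct summation, exhaustive
# enumeration, textbook Newton-Raphson) and never calls the package's own
# fitting or metric code paths.

# Unpenalized weighted logistic MLE by Newton-Raphson on (intercept, theta).
newton_logistic <- function(X, y, w, tol = 1e-12, maxit = 100) {
  v <- w / mean(w)
  Z <- cbind(1, X)
  b <- rep(0, ncol(Z))
  for (i in seq_len(maxit)) {
    eta <- as.numeric(Z %*% b)
    p <- 1 / (1 + exp(-eta))
    g <- colSums(v * Z * (y - p))
    H <- crossprod(Z, v * p * (1 - p) * Z)
    step <- solve(H, g)
    b <- b + step
    if (max(abs(step)) < tol) break
  }
  list(intercept = unname(b[1]), theta = unname(b[-1]))
}

# Term-by-term weighted Bernoulli log-likelihood (naive; can overflow only
# for |eta| far beyond the fixtures used here).
loglik_direct <- function(theta, intercept, X, y, w) {
  v <- w / mean(w)
  eta <- intercept + as.numeric(X %*% theta)
  sum(v * (y * eta - log(1 + exp(eta))))
}

# AUC by exhaustive pair enumeration, ties counted 1/2.
auc_pairs <- function(y, p, w = NULL) {
  if (is.null(w)) w <- rep(1, length(y))
  pos <- which(y == 1); neg <- which(y == 0)
  num <- 0; den <- 0
  for (i in pos) for (j in neg) {
    ww <- w[i] * w[j]
    num <- num + ww * (if (p[i] > p[j]) 1 else if (p[i] == p[j]) 0.5 else 0)
    den <- den + ww
  }
  num / den
}

# Knee as the point of maximum perpendicular distance from the chord joining
# the curve's endpoints (classic discrete-curvature surrogate).
knee_chord <- function(values) {
  n <- length(values)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (values - min(values)) / (max(values) - min(values))
  x0 <- c(x[1], y[1]); x1 <- c(x[n], y[n])
  d <- abs((x1[1] - x0[1]) * (x0[2] - y) - (x0[1] - x) * (x1[2] - x0[2])) /
    sqrt(sum((x1 - x0)^2))
  which.max(d)
}

# KKT residual of the L1-penalized weighted objective at a fit, computed on
# the standardized scale from first principles.
kkt_residual_l1 <- function(fit, ds, lam) {
  v <- ds$w / mean(ds$w)
  n <- nrow(ds$X)
  mu <- colSums(v * ds$X) / n
  Xc <- sweep(ds$X, 2, mu)
  sd <- sqrt(colSums(v * Xc * Xc) / n); sd[sd < 1e-12] <- 1
  Xs <- sweep(Xc, 2, sd, "/")
  th <- fit$theta_std
  eta <- fit$intercept_std + as.numeric(Xs %*% th)
  p <- 1 / (1 + exp(-eta))
  g <- colSums(v * Xs * (ds$y - p))
  active <- th != 0
  res_active <- if (any(active)) max(abs(g[active] - lam * sign(th[active]))) else 0
  res_inactive <- if (any(!active)) max(0, max(abs(g[!active])) - lam) else 0
  res_int <- abs(sum(v * (ds$y - p)))
  max(res_active, res_inactive, res_int)
}

# Implied phi (Pearson) correlation of two binaries from thresholding a
# bivariate standard normal with correlation rho at threshold t, by 1-D
# numerical integration of P(Z1 > t, Z2 > t).
phi_implied <- function(rho, marginal) {
  t <- qnorm(1 - marginal)
  p11 <- integrate(function(z)
    dnorm(z) * pnorm((rho * z - t) / sqrt(1 - rho^2)),
    lower = t, upper = Inf, rel.tol = 1e-10)$value
  q <- marginal
  (p11 - q^2) / (q * (1 - q))
}

# Small planted-signal binary dataset for fitting tests: ncol columns, the
# first `n_signal` with log-odds effect `beta`, the rest pure noise.
make_planted <- function(n = 400, p = 12, n_signal = 3, beta = 1.2,
                         prevalence = 0.3, seed = 42, weights = TRUE) {
  set.seed(seed)
  X <- matrix(rbinom(n * p, 1, 0.4), n, p)
  colnames(X) <- sprintf("v%02d", seq_len(p))
  eta <- qlogis(prevalence) + X[, seq_len(n_signal), drop = FALSE] %*%
    rep(beta, n_signal)
  y <- rbinom(n, 1, plogis(eta))
  if (sum(y) < 2) y[sample(n, 2)] <- 1
  if (sum(1 - y) < 2) y[sample(n, 2)] <- 0
  w <- if (weights) rlnorm(n, 0, 0.4) else rep(1, n)
  encoded_dataset(X, y, w / mean(w))
}

# Tiny raw survey table + metadata written to a temp dir; returns the paths.
write_tiny_survey <- function(dir = tempfile("survey")) {
  dir.create(dir)
  df <- data.frame(
    help_any = c("yes", "no", "yes", "yes", "no", "yes"),
    police = c("yes", "no", "no", "no", "no", "yes"),
    own_family = c("no", "no", "yes", "no", "no", "yes"),
    age = c(21, 34, 47, 29, 38, 44),
    education = c("none", "primary", "secondary", "none", "primary", "secondary"),
    age_5yr = c("20-24", "30-34", "45-49", "25-29", "35-39", "40-44"),
    resp_id = 1:6,
    outcome = 0L,
    wt = c(1.2, 0.8, 1.0, 1.1, 0.9, 1.0)
  )
  write.csv(df, file.path(dir, "data.csv"), row.names = FALSE, quote = FALSE)
  meta <- list(
    outcome = "outcome", weight = "wt",
    variables = list(
      list(name = "help_any", kind = "binary"),
      list(name = "police", kind = "binary"),
      list(name = "own_family", kind = "binary"),
      list(name = "age", kind = "continuous", construct_id = "age",
           canonical = TRUE),
      list(name = "education", kind = "categorical",
           categories = c("none", "primary", "secondary")),
      list(name = "age_5yr", kind = "categorical", construct_id = "age",
           categories = c("20-24", "25-29", "30-34", "35-39", "40-44", "45-49")),
      list(name = "resp_id", kind = "continuous", excluded = TRUE,
           exclusion_reason = "respondent ID"),
      list(name = "outcome", kind = "binary"),
      list(name = "wt", kind = "continuous")
    )
  )
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  list(data = file.path(dir, "data.csv"), meta = file.path(dir, "meta.yaml"))
}

# Small-but-real ITA benchmark used by the loop tests (scaled-down version
# of the full generator defaults; strong effects so selection is stable).
small_benchmark <- function(seed = 1, n = 2500, p_noise = 120) {
  spec <- synthetic_spec(n = n, p_noise = p_noise, seed = seed)
  synth_generate(spec)
}
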