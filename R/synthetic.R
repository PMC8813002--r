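#' Specification of a synthetic DHS-like cohort
#'
#' Describes a generative model for respondent-level data shaped like a
#' large household-survey extract: themed blocks of correlated binary signal
#' variables (latent equicorrelated Gaussians thresholded at the marginal
#' rate), bulk independent Bernoulli noise columns, a rare binary outcome
#' drawn from a logistic model whose intercept is calibrated to a target
#' prevalence, and positive log-normal sampling weights.
#'
#' The default benchmark mirrors the scale of a national IPV help-seeking
#' module subsample: n = 19,468 respondents, 970 noise columns plus 6 themes
#' of 5 signal variables (~1,000 encoded columns), log-odds effects drawn
#' uniformly in \[0.5, 1.2\], within-block latent correlation 0.3, outcome
#' prevalence 14.4% (any-source help-seeking); [formal_outcome_spec()]
#' switches to the 1.0% formal-source rate.
#'
#' @param n number of respondents.
#' @param p_noise number of pure-noise binary columns.
#' @param themes list of blocks, each `list(label =, n_vars =, effects =
#'   (length-n_vars log-odds), rho = within-block latent correlation,
#'   marginal = positive rate of each binary)`. `NULL` gives the default
#'   6 x 5 benchmark blocks with effects drawn from `seed`.
#' @param target_prevalence outcome rate in (0, 1).
#' @param weight_sdlog sdlog of the log-normal sampling weights (meanlog 0;
#'   weights are normalized to mean 1 after drawing).
#' @param noise_rate_range range of the per-column noise positive rates,
#'   drawn uniformly from `seed`.
#' @param seed master seed; every random quantity derives from it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n = 19468L, p_noise = 970L, themes = NULL,
                           target_prevalence = 0.144, weight_sdlog = 0.5,
                           noise_rate_range = c(0.05, 0.5), seed = 1L) {
  stopifnot(target_prevalence > 0, target_prevalence < 1, n >= 1,
            p_noise >= 0, weight_sdlog >= 0)
  if (is.null(themes)) {
    labels <- paste0("theme_", LETTERS[1:6])
    betas <- with_local_seed(derive_seed(seed, 11L),
                             runif(30, min = 0.5, max = 1.2))
    themes <- lapply(seq_along(labels), function(b) {
      list(label = labels[b], n_vars = 5L,
           effects = betas[(b - 1) * 5 + 1:5], rho = 0.3, marginal = 0.3)
    })
  }
  for (th in themes) {
    stopifnot(!is.null(th$label), th$n_vars >= 1,
              length(th$effects) == th$n_vars,
              th$rho >= 0, th$rho < 1, th$marginal > 0, th$marginal < 1)
  }
  structure(list(n = as.integer(n), p_noise = as.integer(p_noise),
                 themes = themes, target_prevalence = target_prevalence,
                 weight_sdlog = weight_sdlog,
                 noise_rate_range = noise_rate_range,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("<synthetic_spec> n = %d, %d noise + %d signal columns in %d themes, prevalence %.3f, seed %d\n",
              x$n, x$p_noise, sum(vapply(x$themes, `[[`, 1L, "n_vars")),
              length(x$themes), x$target_prevalence, x$seed))
  invisible(x)
}

# Derived seeds stay below 2^31 for any master seed.
derive_seed <- function(seed, offset) {
  (abs(as.integer(seed)) %% 100000L) * 10000L + as.integer(offset)
}

# Draw the signal design: latent equicorrelated Gaussian per block,
# thresholded so each column has the block's marginal positive rate.
draw_signal <- function(spec, n, seed_offset) {
  blocks <- with_local_seed(derive_seed(spec$seed, seed_offset), {
    lapply(spec$themes, function(th) {
      g <- rnorm(n)  # shared block factor
      z <- sqrt(th$rho) * g +
        sqrt(1 - th$rho) * matrix(rnorm(n * th$n_vars), n, th$n_vars)
      thr <- stats::qnorm(1 - th$marginal)
      m <- matrix(as.numeric(z > thr), n, th$n_vars)
      colnames(m) <- paste0("sig_", sub("theme_", "", th$label),
                            seq_len(th$n_vars))
      m
    })
  })
  do.call(cbind, blocks)
}

signal_names <- function(spec) {
  unlist(lapply(spec$themes, function(th)
    paste0("sig_", sub("theme_", "", th$label), seq_len(th$n_vars))))
}

signal_betas <- function(spec) {
  stats::setNames(unlist(lapply(spec$themes, `[[`, "effects")),
                  signal_names(spec))
}

#' Calibrate the outcome-model intercept to the target prevalence
#'
#' Bisection on the intercept c so that the Monte-Carlo mean of
#' `plogis(c + X beta)` over m = 200,000 fresh signal draws (fixed derived
#' seed) hits `target_prevalence` within 1e-3. With all effects zero the
#' closed form is `qlogis(target_prevalence)`.
#'
#' @param spec a [synthetic_spec()].
#' @param m Monte-Carlo sample size for the calibration draws.
#' @param tol prevalence tolerance.
#' @return The calibrated intercept (scalar).
#' @export
calibrate_intercept <- function(spec, m = 200000L, tol = 1e-3) {
  stopifnot(inherits(spec, "synthetic_spec"))
  beta <- signal_betas(spec)
  if (all(beta == 0)) return(stats::qlogis(spec$target_prevalence))
  cal_spec <- spec; cal_spec$n <- as.integer(m)
  Xs <- draw_signal(cal_spec, m, seed_offset = 77L)
  eta0 <- as.numeric(Xs %*% beta)
  prev <- function(c0) mean(stats::plogis(c0 + eta0))
  lo <- stats::qlogis(spec$target_prevalence) - 10
  hi <- stats::qlogis(spec$target_prevalence) + 10
  for (i in 1:10) {
    if (prev(lo) < spec$target_prevalence) break
    lo <- lo - 10
  }
  for (i in 1:10) {
    if (prev(hi) > spec$target_prevalence) break
    hi <- hi + 10
  }
  if (prev(lo) >= spec$target_prevalence || prev(hi) <= spec$target_prevalence) {
    stop("infeasible calibration: no intercept attains the target prevalence")
  }
  while (TRUE) {
    mid <- (lo + hi) / 2
    p <- prev(mid)
    if (abs(p - spec$target_prevalence) < tol) return(mid)
    if (p < spec$target_prevalence) lo <- mid else hi <- mid
    if (hi - lo < 1e-12) stop("bisection failed to converge")
  }
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws the signal blocks, noise columns, outcome and weights described by
#' the spec. Fully reproducible: the same spec (including its seed) yields a
#' byte-identical dataset.
#'
#' @param spec a [synthetic_spec()].
#' @return `list(data =, truth =)` where `data` is an [encoded_dataset()]
#'   (signal columns first, then noise) and `truth` is a `synthetic_truth`
#'   with `signal_vars`, `theme_map` (variable -> theme label), `beta`
#'   (named true log-odds), `intercept` (calibrated).
#' @export
synth_generate <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n
  intercept <- calibrate_intercept(spec)
  Xs <- draw_signal(spec, n, seed_offset = 1L)
  beta <- signal_betas(spec)

  noise_rates <- with_local_seed(derive_seed(spec$seed, 21L),
    runif(spec$p_noise, spec$noise_rate_range[1], spec$noise_rate_range[2]))
  Xn <- with_local_seed(derive_seed(spec$seed, 22L), {
    m <- matrix(stats::rbinom(n * spec$p_noise, 1, rep(noise_rates, each = n)),
                n, spec$p_noise)
    colnames(m) <- sprintf("noise_%04d", seq_len(spec$p_noise))
    m
  })

  eta <- intercept + as.numeric(Xs %*% beta)
  y <- with_local_seed(derive_seed(spec$seed, 31L),
                       stats::rbinom(n, 1, stats::plogis(eta)))
  w <- with_local_seed(derive_seed(spec$seed, 41L),
                       stats::rlnorm(n, meanlog = 0, sdlog = spec$weight_sdlog))
  w <- w / mean(w)

  X <- if (spec$p_noise > 0) cbind(Xs, Xn) else Xs
  theme_map <- stats::setNames(
    unlist(lapply(spec$themes, function(th)
      rep(th$label, th$n_vars))), signal_names(spec))
  truth <- structure(list(signal_vars = signal_names(spec),
                          theme_map = theme_map, beta = beta,
                          intercept = intercept),
                     class = "synthetic_truth")
  list(data = encoded_dataset(X, y, w), truth = truth)
}

#' Switch a spec to the rare formal-help-seeking outcome
#'
#' Returns the spec with `target_prevalence` set to 0.010 — the
#' formal-institution help-seeking rate — and everything else unchanged.
#' Idempotent.
#'
#' @param spec a [synthetic_spec()].
#' @return The modified spec.
#' @export
formal_outcome_spec <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  spec$target_prevalence <- 0.010
  spec
}

#' Write a synthetic cohort as delimited text + metadata
#'
#' Writes `data.csv` (all covariates plus `outcome` and `weight` columns),
#' `meta.yaml` (typed variable metadata readable by [read_table()]) and
#' `themes_truth.csv` (the ground-truth variable -> theme map, readable by
#' [load_assignment()] / [file_coder()]).
#'
#' @param sim output of [synth_generate()].
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- sim$data
  df <- as.data.frame(ds$X, check.names = FALSE)
  df$outcome <- ds$y
  df$weight <- ds$w
  utils::write.csv(df, file.path(dir, "data.csv"), row.names = FALSE,
                   quote = FALSE)
  vars <- c(
    lapply(colnames(ds$X), function(v)
      list(name = v, kind = "binary", categories = c("0", "1"))),
    list(list(name = "outcome", kind = "binary"),
         list(name = "weight", kind = "continuous"))
  )
  yaml::write_yaml(list(outcome = "outcome", weight = "weight",
                        variables = vars),
                   file.path(dir, "meta.yaml"))
  utils::write.csv(
    data.frame(variable = names(sim$truth$theme_map),
               theme = unname(sim$truth$theme_map)),
    file.path(dir, "themes_truth.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}
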