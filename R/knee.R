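#' Sort fitted coefficients from high to low
#'
#' Stable descending sort of the standardized-scale coefficients of a fit.
#' The default `absolute` mode ranks by magnitude `|theta_j|` (negative,
#' protective-direction correlates are substantively meaningful); `signed`
#' mode ranks by the raw coefficient value. Ties keep the original column
#' order.
#'
#' @param fit a `penalized_fit` with at least 2 coefficients.
#' @param mode `"absolute"` (default) or `"signed"`.
#' @return `list(names =, values =)` where `values` is non-increasing (in
#'   absolute mode these are the magnitudes).
#' @export
sort_coefficients <- function(fit, mode = c("absolute", "signed")) {
  mode <- match.arg(mode)
  stopifnot(inherits(fit, "penalized_fit"), length(fit$theta_std) >= 2)
  v <- if (mode == "absolute") abs(fit$theta_std) else fit$theta_std
  ord <- order(-v)  # radix sort: stable, ties by original position
  list(names = names(fit$theta_std)[ord], values = unname(v[ord]))
}

#' Kneedle knee-point detection on a decreasing curve
#'
#' Locates the point of maximum curvature ("knee") of a non-increasing
#' sequence: x (indices) and y (values) are min-max normalized to \[0, 1\];
#' the difference curve `d_i = (1 - y_i) - x_i` is formed; candidate knees
#' are the local maxima of d; a candidate is accepted once d drops below
#' `d_candidate - S * mean(diff(x_norm))` before a higher local maximum
#' appears. Sensitivity `S` = 1 by default. Normalization makes the result
#' invariant to affine rescaling of the values.
#'
#' @param values non-increasing numeric sequence, length >= 3.
#' @param sensitivity Kneedle S parameter (larger = more conservative).
#' @return 1-based index of the knee point, or `NA_integer_` when the curve
#'   has no knee (e.g. exactly linear descent).
#' @export
kneedle <- function(values, sensitivity = 1) {
  n <- length(values)
  stopifnot(n >= 3)
  if (any(diff(values) > 1e-12 * max(abs(values), 1))) {
    stop("values must be non-increasing")
  }
  rng <- max(values) - min(values)
  if (rng <= 0) return(NA_integer_)  # flat curve: no knee
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (values - min(values)) / rng
  d <- (1 - y) - x

  # local maxima of d (plateaus: first point of the plateau)
  is_lmx <- function(i) {
    left_ok <- i == 1 || d[i] > d[i - 1]
    right_ok <- i == n || d[i] >= d[i + 1]
    left_ok && right_ok && i > 1 && i < n
  }
  spacing <- sensitivity * mean(diff(x))  # = S / (n - 1)
  candidate <- NA_integer_
  threshold <- -Inf
  for (i in 2:(n - 1)) {
    if (is_lmx(i) && (is.na(candidate) || d[i] > d[candidate])) {
      candidate <- i
      threshold <- d[i] - spacing
    } else if (!is.na(candidate) && d[i] < threshold) {
      return(candidate)
    }
  }
  # curve ended; the last candidate counts if d came back down to its end
  if (!is.na(candidate) && d[n] < threshold) return(candidate)
  NA_integer_
}

#' Extract the variables above the knee
#'
#' Returns the prefix of the sorted names strictly before the knee point,
#' i.e. the variables whose coefficient magnitude exceeds the value at the
#' knee. A knee at the first position yields an empty selection (warned).
#'
#' @param sorted `list(names =, values =)` from [sort_coefficients()].
#' @param knee_index 1-based index of the knee point into the sorted
#'   sequence.
#' @return Character vector of selected variable labels.
#' @export
select_above_knee <- function(sorted, knee_index) {
  n <- length(sorted$names)
  stopifnot(knee_index >= 1, knee_index <= n)
  if (knee_index == 1) {
    warning("knee at the first position: empty selection")
    return(character(0))
  }
  sorted$names[seq_len(knee_index - 1)]
}

#' Knee selection of a round's relevant variables
#'
#' Sorts the fit's coefficients, runs [kneedle()], and extracts the
#' above-knee prefix. When no knee exists the selection is empty and the
#' result is flagged degenerate (safer than selecting everything).
#'
#' @param fit a `penalized_fit` (typically the ridge refit of a round).
#' @param sensitivity Kneedle S parameter.
#' @param mode coefficient ranking mode, see [sort_coefficients()].
#' @return An object of class `knee_selection`: `sorted_names`,
#'   `sorted_values`, `knee_index` (1-based, `NA` if none), `threshold`
#'   (magnitude at the knee), `selected`, `sensitivity`, `degenerate`.
#' @export
knee_select <- function(fit, sensitivity = 1, mode = "absolute") {
  sorted <- sort_coefficients(fit, mode)
  ki <- if (length(sorted$values) >= 3) {
    kneedle(sorted$values, sensitivity)
  } else NA_integer_
  degenerate <- is.na(ki)
  selected <- if (degenerate) character(0) else
    suppressWarnings(select_above_knee(sorted, ki))
  structure(list(
    sorted_names = sorted$names, sorted_values = sorted$values,
    knee_index = ki,
    threshold = if (degenerate) NA_real_ else sorted$values[ki],
    selected = selected, sensitivity = sensitivity,
    degenerate = degenerate || length(selected) == 0
  ), class = "knee_selection")
}

#' @export
print.knee_selection <- function(x, ...) {
  if (is.na(x$knee_index)) {
    cat(sprintf("<knee_selection> no knee found over %d coefficients (degenerate)\n",
                length(x$sorted_values)))
  } else {
    cat(sprintf("<knee_selection> knee at %d/%d (threshold %.4g): %d variables selected\n",
                x$knee_index, length(x$sorted_values), x$threshold,
                length(x$selected)))
  }
  invisible(x)
}
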