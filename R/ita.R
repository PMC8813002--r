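#' Configuration of an iterative thematic analysis run
#'
#' Collects the tunable parameters of the pipeline. Defaults follow the
#' study protocol where one is stated (80:20 split, k = 5 cross-validation,
#' Kneedle sensitivity 1) and conventional practice elsewhere.
#'
#' @param seed master seed governing the split, fold assignments and every
#'   other random quantity of the run.
#' @param ratio training fraction of the single initial split.
#' @param stratified stratify the split on the outcome (recommended for
#'   rare outcomes)?
#' @param k cross-validation fold count for lambda selection.
#' @param lam_grid_length,lam_grid_eps shape of the default lambda grid
#'   (log-spaced from lambda_max down to `eps * lambda_max`), re-derived
#'   from the data each round.
#' @param sensitivity Kneedle S parameter.
#' @param mode coefficient ranking mode for knee selection (`"absolute"` or
#'   `"signed"`).
#' @param zero_tol standardized-scale magnitude at or below which a lasso
#'   coefficient counts as zero for the survivor drop.
#' @param max_rounds safety cap on the number of rounds.
#' @param threshold probability cut-off for the reported BER.
#' @param weighted_metrics use sampling weights in the test-set metrics?
#' @return An object of class `ita_config`.
#' @export
ita_config <- function(seed = 1L, ratio = 0.8, stratified = TRUE, k = 5L,
                       lam_grid_length = 50L, lam_grid_eps = 1e-4,
                       sensitivity = 1, mode = "absolute", zero_tol = 1e-8,
                       max_rounds = 10L, threshold = 0.5,
                       weighted_metrics = FALSE) {
  stopifnot(ratio > 0, ratio < 1, k >= 2, zero_tol >= 0, max_rounds >= 1)
  structure(list(seed = as.integer(seed), ratio = ratio,
                 stratified = stratified, k = as.integer(k),
                 lam_grid_length = as.integer(lam_grid_length),
                 lam_grid_eps = lam_grid_eps, sensitivity = sensitivity,
                 mode = mode, zero_tol = zero_tol,
                 max_rounds = as.integer(max_rounds), threshold = threshold,
                 weighted_metrics = weighted_metrics),
            class = "ita_config")
}

ed_keep_cols <- function(ds, cols) {
  encoded_dataset(ds$X[, cols, drop = FALSE], ds$y, ds$w,
                  ds$col_source[cols])
}

#' Run one round of the iterative thematic analysis
#'
#' Executes the round pipeline in order: CV-tuned lasso on the training
#' data; drop of all variables with (standardized) coefficient zero; CV-tuned
#' ridge refit on the survivors; knee-point selection of the sorted ridge
#' coefficients; theme coding of the selection via `coder`; identification
#' of the maximum-coefficient theme (dropped before the next round); AUC and
#' BER of the ridge model on the held-out test set. A round with no lasso
#' survivors or an empty knee selection is recorded as degenerate and stops
#' the loop.
#'
#' @param train,test [encoded_dataset()]s with identical columns.
#' @param config an [ita_config()].
#' @param coder function `(selected_vars, round) -> theme_assignment`; see
#'   [truth_coder()] and [file_coder()].
#' @param round round number (>= 1).
#' @param seen_themes,seen_vars labels already observed in earlier rounds
#'   (for the new-theme / new-variable accounting).
#' @return An object of class `ita_round`: `round`, `input_vars`,
#'   `lasso_fit`, `survivors`, `ridge_fit`, `selection`, `assignment`,
#'   `new_themes`, `new_vars`, `dropped_theme`, `dropped_vars`, `metrics`,
#'   `degenerate`.
#' @export
run_round <- function(train, test, config = ita_config(), coder,
                      round = 1L, seen_themes = character(0),
                      seen_vars = character(0)) {
  stopifnot(inherits(train, "encoded_dataset"),
            inherits(test, "encoded_dataset"),
            identical(colnames(train$X), colnames(test$X)))
  if (sum(train$y) == 0 || sum(train$y) == length(train$y)) {
    stop("training data needs both outcome classes")
  }
  rseed <- derive_seed(config$seed, 100L + round)
  grid <- default_lambda_grid(train, config$lam_grid_length,
                              config$lam_grid_eps)
  lasso <- fit_cv(train, "L1", lam_grid = grid, k = config$k, seed = rseed)
  survivors <- names(lasso$theta_std)[abs(lasso$theta_std) > config$zero_tol]

  rec <- list(round = as.integer(round), input_vars = colnames(train$X),
              lasso_fit = lasso, survivors = survivors,
              ridge_fit = NULL, selection = NULL, assignment = NULL,
              new_themes = character(0), new_vars = character(0),
              dropped_theme = NA_character_, dropped_vars = character(0),
              metrics = NULL, degenerate = FALSE)

  if (length(survivors) == 0) {
    rec$degenerate <- TRUE
    return(structure(rec, class = "ita_round"))
  }
  tr_s <- ed_keep_cols(train, survivors)
  te_s <- ed_keep_cols(test, survivors)
  ridge <- if (length(survivors) >= 2) {
    fit_cv(tr_s, "L2",
           lam_grid = default_lambda_grid(tr_s, config$lam_grid_length,
                                          config$lam_grid_eps),
           k = config$k, seed = derive_seed(config$seed, 500L + round))
  } else {
    fit_penalized(tr_s, "L2", lam = 1e-4)
  }
  rec$ridge_fit <- ridge
  rec$metrics <- classification_metrics(ridge, te_s, config$threshold,
                                        config$weighted_metrics)
  if (length(survivors) < 2) {
    rec$degenerate <- TRUE
    return(structure(rec, class = "ita_round"))
  }
  sel <- knee_select(ridge, config$sensitivity, config$mode)
  rec$selection <- sel
  if (sel$degenerate || length(sel$selected) == 0) {
    rec$degenerate <- TRUE
    return(structure(rec, class = "ita_round"))
  }
  assignment <- coder(sel$selected, round)
  rec$assignment <- assignment
  themes_here <- unique(unname(assignment$mapping))
  themes_here <- themes_here[norm_label(themes_here) != "uncategorized"]
  rec$new_themes <- setdiff(themes_here, seen_themes)
  rec$new_vars <- setdiff(sel$selected, seen_vars)
  rec$dropped_theme <- max_coefficient_theme(assignment, sel)
  rec$dropped_vars <- names(assignment$mapping)[
    norm_label(assignment$mapping) == norm_label(rec$dropped_theme)]
  structure(rec, class = "ita_round")
}

#' @export
print.ita_round <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<ita_round %d> degenerate (%d input vars, %d survivors)\n",
                x$round, length(x$input_vars), length(x$survivors)))
  } else {
    cat(sprintf(
      "<ita_round %d> %d vars -> %d survivors -> %d selected; %d new themes; drop '%s'; AUC %.3f\n",
      x$round, length(x$input_vars), length(x$survivors),
      length(x$selection$selected), length(x$new_themes), x$dropped_theme,
      x$metrics$auc))
  }
  invisible(x)
}

#' Remove a dropped theme's variables from a dataset
#'
#' @param ds an [encoded_dataset()].
#' @param dropped_vars column labels to remove (the dropped theme's coded
#'   variables); must all be present.
#' @return The dataset without those columns; n unchanged.
#' @export
drop_theme <- function(ds, dropped_vars) {
  ed_drop_cols(ds, dropped_vars)
}

#' Evaluate the stopping rules after each round
#'
#' The loop stops when (a) the most recent round contributed zero new
#' variables, (b) the three most recent rounds each contributed zero new
#' themes, (c) the round count reached `max_rounds`, or (d) the most recent
#' round was degenerate (no survivors or empty knee selection).
#'
#' @param rounds list of completed `ita_round` records.
#' @param max_rounds round cap.
#' @return `NULL` to continue, otherwise one of `"no_new_variables"`,
#'   `"no_new_themes_3_rounds"`, `"max_rounds"`, `"degenerate_selection"`.
#' @export
check_stop <- function(rounds, max_rounds = 10L) {
  stopifnot(length(rounds) >= 1)
  last <- rounds[[length(rounds)]]
  if (last$degenerate) return("degenerate_selection")
  if (length(last$new_vars) == 0) return("no_new_variables")
  if (length(rounds) >= 3) {
    recent <- rounds[(length(rounds) - 2):length(rounds)]
    if (all(vapply(recent, function(r) length(r$new_themes), 1L) == 0)) {
      return("no_new_themes_3_rounds")
    }
  }
  if (length(rounds) >= max_rounds) return("max_rounds")
  NULL
}

#' Run the full iterative thematic analysis
#'
#' Splits once (80:20 by default, stratified), then iterates
#' [run_round()] / [drop_theme()] / [check_stop()]: each round's
#' maximum-coefficient theme has its coded variables removed from both the
#' training and the held-out test data before the next round, and every
#' round's metrics are computed on the same held-out rows. The full audit
#' trail is returned; a fixed seed reproduces the run exactly.
#'
#' @param ds an [encoded_dataset()] of the whole cohort.
#' @param config an [ita_config()].
#' @param coder assignment source, see [run_round()].
#' @return An object of class `ita_result`: `rounds` (list of `ita_round`),
#'   `all_themes` (cumulative labels, excluding "uncategorized"),
#'   `all_selected` (union of selections), `stop_reason`, `config`.
#' @export
run_ita <- function(ds, config = ita_config(), coder) {
  stopifnot(inherits(ds, "encoded_dataset"), inherits(config, "ita_config"))
  parts <- split_train_test(ds, config$ratio, config$seed, config$stratified)
  train <- parts$train
  test <- parts$test
  rounds <- list()
  seen_themes <- character(0)
  seen_vars <- character(0)
  stop_reason <- NULL
  repeat {
    r <- length(rounds) + 1L
    rec <- run_round(train, test, config, coder, round = r,
                     seen_themes = seen_themes, seen_vars = seen_vars)
    rounds[[r]] <- rec
    if (!rec$degenerate) {
      seen_themes <- union(seen_themes, rec$new_themes)
      seen_vars <- union(seen_vars, rec$new_vars)
    }
    stop_reason <- check_stop(rounds, config$max_rounds)
    if (!is.null(stop_reason)) break
    train <- drop_theme(train, rec$dropped_vars)
    test <- drop_theme(test, rec$dropped_vars)
  }
  structure(list(rounds = rounds, all_themes = seen_themes,
                 all_selected = seen_vars, stop_reason = stop_reason,
                 config = config),
            class = "ita_result")
}

#' @export
print.ita_result <- function(x, ...) {
  cat(sprintf("<ita_result> %d rounds, %d themes, %d variables selected, stopped: %s\n",
              length(x$rounds), length(x$all_themes),
              length(x$all_selected), x$stop_reason))
  for (r in x$rounds) print(r)
  invisible(x)
}
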