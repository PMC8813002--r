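#' Per-round summary table of an ITA run
#'
#' @param result an `ita_result`.
#' @return data.frame with one row per completed round: counts of input
#'   variables, lasso survivors and knee-selected variables, new themes,
#'   the dropped theme, and the held-out AUC and BER.
#' @export
round_table <- function(result) {
  stopifnot(inherits(result, "ita_result"))
  rows <- lapply(result$rounds, function(r) {
    data.frame(
      round = r$round,
      n_input = length(r$input_vars),
      n_survivors = length(r$survivors),
      n_selected = if (is.null(r$selection)) 0L else length(r$selection$selected),
      n_new_themes = length(r$new_themes),
      new_themes = paste(r$new_themes, collapse = "; "),
      n_new_vars = length(r$new_vars),
      dropped_theme = r$dropped_theme,
      auc = if (is.null(r$metrics)) NA_real_ else r$metrics$auc,
      ber = if (is.null(r$metrics)) NA_real_ else r$metrics$ber,
      ber_prevalence = if (is.null(r$metrics)) NA_real_ else r$metrics$ber_prevalence,
      degenerate = r$degenerate,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Cumulative theme-to-variables table
#'
#' @param result an `ita_result`.
#' @return data.frame with columns `theme`, `variable`, `round` (round of
#'   first selection), ordered by round then coefficient rank.
#' @export
theme_table <- function(result) {
  stopifnot(inherits(result, "ita_result"))
  rows <- list()
  seen <- character(0)
  for (r in result$rounds) {
    if (is.null(r$assignment)) next
    sel <- r$selection$selected
    new <- setdiff(sel, seen)
    seen <- union(seen, sel)
    if (length(new) == 0) next
    rows[[length(rows) + 1]] <- data.frame(
      theme = unname(r$assignment$mapping[new]), variable = new,
      round = r$round, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(theme = character(0), variable = character(0),
                      round = integer(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$round, out$theme), , drop = FALSE]
}

ita_result_as_list <- function(result) {
  list(
    stop_reason = result$stop_reason,
    all_themes = as.list(result$all_themes),
    all_selected = as.list(result$all_selected),
    config = unclass(result$config),
    rounds = lapply(result$rounds, function(r) list(
      round = r$round,
      n_input = length(r$input_vars),
      survivors = as.list(r$survivors),
      lasso_lam = r$lasso_fit$lam,
      ridge_lam = if (is.null(r$ridge_fit)) NULL else r$ridge_fit$lam,
      selection = if (is.null(r$selection)) NULL else list(
        knee_index = r$selection$knee_index,
        threshold = r$selection$threshold,
        selected = as.list(r$selection$selected),
        sorted_names = as.list(r$selection$sorted_names),
        sorted_values = as.list(r$selection$sorted_values)
      ),
      assignment = if (is.null(r$assignment)) NULL else as.list(r$assignment$mapping),
      new_themes = as.list(r$new_themes),
      new_vars = as.list(r$new_vars),
      dropped_theme = r$dropped_theme,
      dropped_vars = as.list(r$dropped_vars),
      metrics = if (is.null(r$metrics)) NULL else list(
        auc = r$metrics$auc, ber = r$metrics$ber,
        ber_prevalence = r$metrics$ber_prevalence,
        threshold = r$metrics$threshold, n = r$metrics$n
      ),
      degenerate = r$degenerate
    ))
  )
}

#' Render an ITA run report
#'
#' `"json"` gives a lossless machine-readable document (numbers serialized
#' at full precision, so re-rendering a parsed report is idempotent);
#' `"csv"` gives the round table; `"markdown"` a human-readable summary with
#' the theme-variable listing. Degenerate rounds are flagged in every
#' format.
#'
#' @param result an `ita_result`.
#' @param format `"json"`, `"csv"` or `"markdown"`.
#' @return A character scalar (the document).
#' @export
render_report <- function(result, format = c("json", "csv", "markdown")) {
  format <- match.arg(format)
  if (format == "json") {
    # 17 significant digits: the shortest precision at which every double
    # round-trips bit-exactly through decimal
    return(as.character(jsonlite::toJSON(ita_result_as_list(result),
                                         auto_unbox = TRUE, digits = I(17),
                                         null = "null")))
  }
  if (format == "csv") {
    tc <- textConnection("out", "w", local = TRUE)
    utils::write.csv(round_table(result), tc, row.names = FALSE)
    close(tc)
    return(paste(out, collapse = "\n"))
  }
  rt <- round_table(result)
  tt <- theme_table(result)
  lines <- c(
    "# Iterative thematic analysis report", "",
    sprintf("Rounds completed: %d. Stop reason: %s.",
            nrow(rt), result$stop_reason),
    if (any(rt$degenerate)) "NOTE: the run ended in a degenerate round (no usable selection)." else NULL,
    "",
    "## Rounds", "",
    "| round | input | survivors | selected | new themes | dropped theme | AUC | BER |",
    "|---|---|---|---|---|---|---|---|",
    sprintf("| %d | %d | %d | %d | %d | %s | %.3f | %.3f |",
            rt$round, rt$n_input, rt$n_survivors, rt$n_selected,
            rt$n_new_themes, ifelse(is.na(rt$dropped_theme), "-", rt$dropped_theme),
            rt$auc, rt$ber),
    "", "## Themes and their variables", ""
  )
  if (nrow(tt) == 0) {
    lines <- c(lines, "(no themes identified)")
  } else {
    for (th in unique(tt$theme)) {
      vars <- tt$variable[tt$theme == th]
      lines <- c(lines, sprintf("- **%s**: %s", th, paste(vars, collapse = ", ")))
    }
  }
  paste(lines, collapse = "\n")
}

#' Write the standard report files for a run
#'
#' Writes `report.json`, `rounds.csv` and `themes.md` to a directory, plus
#' `metrics.png` (AUC/BER per round) when `plot = TRUE` and ggplot2 is
#' available.
#'
#' @param result an `ita_result`.
#' @param dir output directory (created if needed).
#' @param plot also write the metric curve figure?
#' @return The directory path, invisibly.
#' @export
write_report <- function(result, dir, plot = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(render_report(result, "json"), file.path(dir, "report.json"))
  utils::write.csv(round_table(result), file.path(dir, "rounds.csv"),
                   row.names = FALSE)
  writeLines(render_report(result, "markdown"), file.path(dir, "themes.md"))
  if (plot && requireNamespace("ggplot2", quietly = TRUE)) {
    rt <- round_table(result)
    df <- rbind(
      data.frame(round = rt$round, metric = "AUC", value = rt$auc),
      data.frame(round = rt$round, metric = "BER (prevalence threshold)",
                 value = rt$ber_prevalence)
    )
    gg <- ggplot2::ggplot(df, ggplot2::aes(x = round, y = value,
                                           colour = metric)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::scale_x_continuous(breaks = rt$round) +
      ggplot2::ylim(0, 1) +
      ggplot2::labs(x = "ITA round", y = NULL, colour = NULL) +
      ggplot2::theme_minimal()
    ggplot2::ggsave(file.path(dir, "metrics.png"), gg, width = 6, height = 4,
                    dpi = 150)
  }
  invisible(dir)
}
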