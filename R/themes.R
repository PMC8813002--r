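#' Theme assignment of a round's selected variables
#'
#' A theme is a group of variables related by topical similarity (e.g.
#' "Injury from violence"). Coding is a human judgment; in automated runs a
#' ground-truth map or a file stands in for the coder. The reserved label
#' `"uncategorized"` marks variables that could not be placed in any theme.
#'
#' @param mapping named character vector: variable name -> theme label.
#' @param round round number (>= 1).
#' @param coder_id identifier of the coder (person, file, or generator).
#' @return An object of class `theme_assignment`.
#' @export
theme_assignment <- function(mapping, round = 1L, coder_id = "coder") {
  if (is.null(names(mapping)) || any(names(mapping) == "")) {
    stop("mapping must be a named vector (variable -> theme)")
  }
  if (anyDuplicated(names(mapping))) {
    stop("duplicate variables in mapping: ",
         paste(unique(names(mapping)[duplicated(names(mapping))]), collapse = ", "))
  }
  mapping <- vapply(mapping, as.character, "")
  if (any(trimws(mapping) == "")) stop("theme labels must be non-empty")
  structure(list(round = as.integer(round), coder_id = coder_id,
                 mapping = mapping),
            class = "theme_assignment")
}

#' Load a theme assignment from a two-column file
#'
#' Reads a delimited file with columns `variable` and `theme` and checks
#' that it covers the expected variables exactly — no more, no fewer, no
#' duplicates.
#'
#' @param path path to the two-column delimited file (header required).
#' @param expected_vars the round's selected variable names.
#' @param round,coder_id passed to [theme_assignment()].
#' @param delim field delimiter.
#' @return A `theme_assignment`.
#' @export
load_assignment <- function(path, expected_vars, round = 1L,
                            coder_id = basename(path), delim = ",") {
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "\"", comment.char = "")
  if (!all(c("variable", "theme") %in% names(df))) {
    stop("assignment file must have 'variable' and 'theme' columns")
  }
  if (anyDuplicated(df$variable)) {
    stop("duplicate variable rows: ",
         paste(unique(df$variable[duplicated(df$variable)]), collapse = ", "))
  }
  missing <- setdiff(expected_vars, df$variable)
  extra <- setdiff(df$variable, expected_vars)
  if (length(missing) > 0 || length(extra) > 0) {
    stop("assignment does not cover the selection exactly;",
         if (length(missing)) paste0(" missing: ", paste(missing, collapse = ", ")),
         if (length(extra)) paste0(" extra: ", paste(extra, collapse = ", ")))
  }
  theme_assignment(stats::setNames(df$theme, df$variable), round, coder_id)
}

norm_label <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

#' Inter-coder agreement percentage
#'
#' The percentage of variables coded into the same theme by two coders,
#' after whitespace and case normalization of the labels. Symmetric; equals
#' 100 iff the normalized mappings are identical.
#'
#' @param a,b `theme_assignment`s over the same variable set.
#' @return Agreement percentage in \[0, 100\].
#' @export
coder_agreement <- function(a, b) {
  stopifnot(inherits(a, "theme_assignment"), inherits(b, "theme_assignment"))
  va <- sort(names(a$mapping)); vb <- sort(names(b$mapping))
  if (!identical(va, vb)) stop("coders assigned different variable sets")
  same <- norm_label(a$mapping[va]) == norm_label(b$mapping[va])
  100 * mean(same)
}

#' Theme of the maximum-coefficient variable
#'
#' Identifies the theme to be dropped before the next round: the theme
#' containing the top-ranked selected variable ("maximum variance" in the
#' sense of the variable with the highest coefficient value). Magnitude ties
#' are broken by sort stability; among tied leaders an `"uncategorized"`
#' variable never wins over a categorized one.
#'
#' @param assignment a `theme_assignment` covering the selection.
#' @param selection a `knee_selection` with a non-empty `selected` set.
#' @return The theme label.
#' @export
max_coefficient_theme <- function(assignment, selection) {
  stopifnot(inherits(assignment, "theme_assignment"),
            inherits(selection, "knee_selection"))
  sel <- selection$selected
  if (length(sel) == 0) stop("empty selection: no theme to identify")
  uncov <- setdiff(sel, names(assignment$mapping))
  if (length(uncov) > 0) {
    stop("assignment does not cover: ", paste(uncov, collapse = ", "))
  }
  vals <- selection$sorted_values[match(sel, selection$sorted_names)]
  top_val <- vals[1]  # selected is a prefix of the sorted order
  leaders <- sel[vals == top_val]
  themes <- assignment$mapping[leaders]
  categorized <- themes[norm_label(themes) != "uncategorized"]
  if (length(categorized) > 0) unname(categorized[1]) else unname(themes[1])
}

#' Coder that applies a ground-truth theme map
#'
#' For fully automated runs (tests, synthetic benchmarks) the generator's
#' ground-truth theme map serves as the coder: selected variables present in
#' the map get their true theme, all others get `"uncategorized"`. Encoded
#' column labels (`variable=level`) are matched through their source
#' variable when a `col_source` map is given.
#'
#' @param theme_map named character vector: variable name -> theme label
#'   (e.g. `truth$theme_map` from [synth_generate()]).
#' @param col_source optional named map from encoded column label to source
#'   variable name.
#' @return A coder function `(selected_vars, round) -> theme_assignment`.
#' @export
truth_coder <- function(theme_map, col_source = NULL) {
  force(theme_map); force(col_source)
  function(selected_vars, round = 1L) {
    src <- if (is.null(col_source)) selected_vars else {
      ifelse(selected_vars %in% names(col_source),
             col_source[selected_vars], selected_vars)
    }
    labels <- ifelse(src %in% names(theme_map), theme_map[src], "uncategorized")
    theme_assignment(stats::setNames(unname(labels), selected_vars),
                     round = round, coder_id = "ground-truth")
  }
}

#' Coder that reads per-round assignment files
#'
#' For real analyses: round r is coded from
#' `file.path(dir, sprintf(pattern, r))`, validated against the selection by
#' [load_assignment()].
#'
#' @param dir directory containing the assignment files.
#' @param pattern `sprintf` pattern with one integer slot for the round.
#' @param delim field delimiter.
#' @return A coder function `(selected_vars, round) -> theme_assignment`.
#' @export
file_coder <- function(dir, pattern = "round%d_themes.csv", delim = ",") {
  force(dir); force(pattern); force(delim)
  function(selected_vars, round = 1L) {
    load_assignment(file.path(dir, sprintf(pattern, round)), selected_vars,
                    round = round, delim = delim)
  }
}
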