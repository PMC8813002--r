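#' Encoded model-ready dataset
#'
#' Container for a numeric design matrix together with the binary outcome and
#' sampling weights, as produced by [one_hot_encode()] or
#' [synth_generate()]. Column labels use the `variable=level` convention so
#' every encoded column maps back to exactly one source variable.
#'
#' @param X numeric matrix, n x p, with unique column names.
#' @param y binary outcome vector (0/1), length n.
#' @param w strictly positive sampling weights, length n. They are stored as
#'   given; model-fitting code normalizes them to mean 1 so the effective
#'   sample size matches n.
#' @param col_source named character vector mapping each column label of `X`
#'   to its source variable name. Defaults to the column names themselves.
#'
#' @return An object of class `encoded_dataset` with fields `X`, `y`, `w`,
#'   `col_source`.
#' @export
encoded_dataset <- function(X, y, w, col_source = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) {
    stop("X must have column names")
  }
  if (anyDuplicated(colnames(X))) {
    stop("duplicate column labels: ",
         paste(unique(colnames(X)[duplicated(colnames(X))]), collapse = ", "))
  }
  y <- as.integer(y)
  w <- as.numeric(w)
  n <- nrow(X)
  if (length(y) != n || length(w) != n) {
    stop("y and w must have length nrow(X)")
  }
  if (anyNA(X) || anyNA(y) || anyNA(w)) {
    stop("missing values are not allowed in an encoded dataset")
  }
  if (!all(y %in% c(0L, 1L))) stop("outcome must be binary 0/1")
  if (any(w <= 0)) stop("weights must be strictly positive")
  if (is.null(col_source)) {
    col_source <- stats::setNames(colnames(X), colnames(X))
  }
  if (!all(colnames(X) %in% names(col_source))) {
    stop("col_source must cover every column of X")
  }
  structure(
    list(X = X, y = y, w = w, col_source = col_source[colnames(X)]),
    class = "encoded_dataset"
  )
}

#' @export
print.encoded_dataset <- function(x, ...) {
  cat(sprintf(
    "<encoded_dataset> %d respondents x %d columns, prevalence %.3f, weight range [%.3g, %.3g]\n",
    nrow(x$X), ncol(x$X), mean(x$y), min(x$w), max(x$w)
  ))
  invisible(x)
}

#' @export
dim.encoded_dataset <- function(x) dim(x$X)

# Row subset; used by the splitter and CV folds.
ed_rows <- function(ds, idx) {
  encoded_dataset(ds$X[idx, , drop = FALSE], ds$y[idx], ds$w[idx],
                  ds$col_source)
}

# Column drop by label; errors on unknown labels. n is unchanged.
ed_drop_cols <- function(ds, cols) {
  if (length(cols) == 0) return(ds)
  unknown <- setdiff(cols, colnames(ds$X))
  if (length(unknown) > 0) {
    stop("unknown columns: ", paste(unknown, collapse = ", "))
  }
  keep <- setdiff(colnames(ds$X), cols)
  if (length(keep) == 0) stop("empty design: dropping all columns")
  encoded_dataset(ds$X[, keep, drop = FALSE], ds$y, ds$w,
                  ds$col_source[keep])
}

# ---------------------------------------------------------------------------
# Raw (pre-encoding) survey tables with typed metadata
# ---------------------------------------------------------------------------

#' Read a respondent-level survey table with typed metadata
#'
#' Reads a delimited text file (header row required) together with a YAML
#' metadata file that types every column and identifies the outcome and
#' weight columns. The metadata file has top-level keys `outcome`, `weight`
#' and `variables`; each entry of `variables` carries `name`, `kind` (one of
#' `continuous`, `categorical`, `binary`), and optionally `categories`
#' (ordered level labels), `construct_id` (grouping variables that measure
#' the same underlying construct), `canonical` (flag: the group member kept
#' by [screen_variables()]), `excluded` and `exclusion_reason`.
#'
#' @param path path to the delimited data file.
#' @param meta_path path to the YAML metadata file.
#' @param delim field delimiter, `","` by default.
#' @return An object of class `raw_dataset`: fields `data` (data.frame),
#'   `outcome`, `weight` (column names) and `meta` (metadata data.frame with
#'   list-column `categories`).
#' @export
read_table <- function(path, meta_path, delim = ",") {
  meta <- read_variable_meta(meta_path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""), quote = "\"",
                          comment.char = "")
  extra <- setdiff(names(df), meta$meta$name)
  if (length(extra) > 0) {
    stop("columns absent from metadata: ", paste(extra, collapse = ", "))
  }
  missing_cols <- setdiff(meta$meta$name, names(df))
  if (length(missing_cols) > 0) {
    stop("metadata lists columns missing from the table: ",
         paste(missing_cols, collapse = ", "))
  }
  for (v in meta$meta$name[meta$meta$kind == "continuous"]) {
    vals <- df[[v]]
    if (!is.numeric(vals)) {
      coerced <- suppressWarnings(as.numeric(vals))
      if (any(is.na(coerced) & !is.na(vals))) {
        stop("column '", v, "' is declared continuous but has non-numeric values")
      }
      df[[v]] <- coerced
    }
  }
  raw_dataset(df, outcome = meta$outcome, weight = meta$weight,
              meta = meta$meta)
}

read_variable_meta <- function(meta_path) {
  m <- yaml::read_yaml(meta_path)
  if (is.null(m$outcome) || is.null(m$weight)) {
    stop("metadata must name the outcome and weight columns")
  }
  vars <- m$variables
  if (is.null(vars) || length(vars) == 0) stop("metadata lists no variables")
  meta <- data.frame(
    name = vapply(vars, function(v) as.character(v$name), ""),
    kind = vapply(vars, function(v) as.character(v$kind), ""),
    construct_id = vapply(vars, function(v)
      if (is.null(v$construct_id)) NA_character_ else as.character(v$construct_id), ""),
    canonical = vapply(vars, function(v) isTRUE(v$canonical), TRUE),
    excluded = vapply(vars, function(v) isTRUE(v$excluded), TRUE),
    exclusion_reason = vapply(vars, function(v)
      if (is.null(v$exclusion_reason)) NA_character_ else as.character(v$exclusion_reason), ""),
    stringsAsFactors = FALSE
  )
  meta$categories <- lapply(vars, function(v)
    if (is.null(v$categories)) NULL else as.character(v$categories))
  list(outcome = as.character(m$outcome), weight = as.character(m$weight),
       meta = meta)
}

#' Raw survey dataset constructor
#'
#' @param data data.frame of respondent records.
#' @param outcome,weight names of the outcome and weight columns.
#' @param meta metadata data.frame as built by [read_table()]; one row per
#'   column of `data` with fields `name`, `kind`, `construct_id`,
#'   `canonical`, `excluded`, `exclusion_reason`, `categories`.
#' @return An object of class `raw_dataset`.
#' @export
raw_dataset <- function(data, outcome, weight, meta) {
  if (!outcome %in% names(data)) stop("outcome column '", outcome, "' not found")
  if (!weight %in% names(data)) stop("weight column '", weight, "' not found")
  if (anyDuplicated(meta$name)) {
    stop("duplicate variable names in metadata: ",
         paste(unique(meta$name[duplicated(meta$name)]), collapse = ", "))
  }
  bad_kind <- setdiff(meta$kind, c("continuous", "categorical", "binary"))
  if (length(bad_kind) > 0) stop("unknown variable kind: ", paste(bad_kind, collapse = ", "))
  for (i in which(meta$kind == "categorical")) {
    if (length(meta$categories[[i]]) < 2 && !is.null(meta$categories[[i]])) {
      # tolerated but flagged later by the encoder; degenerate after screening
    }
  }
  wvals <- data[[weight]]
  if (any(!is.na(wvals) & wvals <= 0)) stop("weight column must be strictly positive")
  structure(list(data = data, outcome = outcome, weight = weight, meta = meta),
            class = "raw_dataset")
}

#' @export
print.raw_dataset <- function(x, ...) {
  cat(sprintf("<raw_dataset> %d respondents x %d columns (outcome '%s', weight '%s')\n",
              nrow(x$data), ncol(x$data), x$outcome, x$weight))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Outcome construction
# ---------------------------------------------------------------------------

#' Help-seeking outcome rules
#'
#' `outcome_rule_any(item)` defines the any-source outcome from a single
#' yes/no gate item ("have you ever tried to seek help"). `
#' outcome_rule_formal(gate, sources)` defines the formal-source outcome as a
#' disjunction over the listed source indicators (e.g. police, lawyer,
#' doctor, social service organization), gated on the any-source item:
#' respondents answering no to the gate are 0 regardless of source fields.
#'
#' @param item,gate name of the yes/no gate column.
#' @param sources character vector of yes/no source-indicator columns.
#' @return An outcome rule object for [construct_outcome()].
#' @export
outcome_rule_any <- function(item) {
  structure(list(type = "any", item = item), class = "outcome_rule")
}

#' @rdname outcome_rule_any
#' @export
outcome_rule_formal <- function(gate, sources) {
  stopifnot(length(sources) >= 1)
  structure(list(type = "formal", gate = gate, sources = sources),
            class = "outcome_rule")
}

as_yes <- function(x) {
  if (is.numeric(x)) return(!is.na(x) & x != 0)
  x <- tolower(trimws(as.character(x)))
  !is.na(x) & x %in% c("yes", "y", "1", "true")
}

#' Construct the binary outcome column from a help-seeking rule
#'
#' Overwrites the dataset's outcome column with 0/1 per the rule. For the
#' formal rule the gate question is applied first: a "no" to the gate yields
#' outcome 0 even if source indicators are missing (survey skip pattern).
#'
#' @param raw a [raw_dataset()].
#' @param rule an outcome rule from [outcome_rule_any()] or
#'   [outcome_rule_formal()].
#' @return The dataset with the outcome column set to 0/1.
#' @export
construct_outcome <- function(raw, rule) {
  stopifnot(inherits(raw, "raw_dataset"), inherits(rule, "outcome_rule"))
  df <- raw$data
  if (rule$type == "any") {
    if (!rule$item %in% names(df)) {
      stop("outcome rule references missing column '", rule$item, "'")
    }
    out <- as.integer(as_yes(df[[rule$item]]))
  } else {
    absent <- setdiff(c(rule$gate, rule$sources), names(df))
    if (length(absent) > 0) {
      stop("outcome rule references missing columns: ",
           paste(absent, collapse = ", "))
    }
    gate <- as_yes(df[[rule$gate]])
    any_formal <- Reduce(`|`, lapply(rule$sources, function(s) as_yes(df[[s]])))
    out <- as.integer(gate & any_formal)
  }
  df[[raw$outcome]] <- out
  raw$data <- df
  raw
}

# ---------------------------------------------------------------------------
# Screening: exclusions and construct de-duplication
# ---------------------------------------------------------------------------

#' Screen variables: drop exclusions and de-duplicate constructs
#'
#' Removes variables flagged `excluded` in the metadata (survey design and
#' structure fields, respondent identifiers, interview dates, ...) and, for
#' every group of variables sharing a `construct_id` (the same underlying
#' construct measured several ways, e.g. age captured by multiple recodes),
#' keeps only the member flagged `canonical`. The outcome and weight columns
#' are never dropped. A multi-member construct group with no canonical member
#' is a fatal error; a singleton group is kept as implicitly canonical.
#'
#' @param raw a [raw_dataset()].
#' @return The screened dataset; row count unchanged.
#' @export
screen_variables <- function(raw) {
  stopifnot(inherits(raw, "raw_dataset"))
  meta <- raw$meta
  protected <- c(raw$outcome, raw$weight)
  drop <- meta$excluded & !(meta$name %in% protected)

  grp <- meta$construct_id
  for (g in unique(grp[!is.na(grp)])) {
    members <- which(!is.na(grp) & grp == g & !drop)
    if (length(members) <= 1) next
    canon <- members[meta$canonical[members]]
    if (length(canon) == 0) {
      stop("construct group '", g, "' has no canonical member")
    }
    drop[setdiff(members, canon[1])] <- TRUE
  }
  keep <- meta$name[!drop]
  raw$data <- raw$data[, keep, drop = FALSE]
  raw$meta <- meta[!drop, , drop = FALSE]
  raw
}

# ---------------------------------------------------------------------------
# Discretization of continuous variables
# ---------------------------------------------------------------------------

interval_labels <- function(cuts) {
  if (length(cuts) == 0) return("(-Inf,Inf)")
  k <- length(cuts)
  c(paste0("(-Inf,", cuts[1], ")"),
    if (k > 1) paste0("[", cuts[-k], ",", cuts[-1], ")") else character(0),
    paste0("[", cuts[k], ",Inf)"))
}

#' Bin continuous variables into ordered categoricals
#'
#' Each continuous variable listed in `bins` is replaced by an ordered
#' categorical with `length(cuts) + 1` levels covering the whole real line:
#' `(-Inf, c1)`, `[c1, c2)`, ..., `[ck, Inf)`. Missing values stay missing
#' and are handled by the encoder's missing-level mechanism. An empty cut
#' list yields a degenerate single-level variable (warned).
#'
#' @param raw a [raw_dataset()].
#' @param bins named list: variable name -> strictly increasing numeric cut
#'   points.
#' @return The dataset with those variables re-typed as categorical.
#' @export
discretize_continuous <- function(raw, bins) {
  stopifnot(inherits(raw, "raw_dataset"))
  for (v in names(bins)) {
    i <- match(v, raw$meta$name)
    if (is.na(i)) stop("unknown variable '", v, "'")
    if (raw$meta$kind[i] != "continuous") {
      stop("variable '", v, "' is not continuous")
    }
    cuts <- as.numeric(bins[[v]])
    if (length(cuts) >= 2 && any(diff(cuts) <= 0)) {
      stop("non-increasing cuts for '", v, "'")
    }
    if (length(cuts) == 0) {
      warning("empty cut list for '", v, "': degenerate single-level variable")
    }
    labs <- interval_labels(cuts)
    x <- raw$data[[v]]
    lev <- findInterval(x, cuts) + 1L  # 1 .. length(cuts)+1, NA stays NA
    raw$data[[v]] <- labs[lev]
    raw$meta$kind[i] <- "categorical"
    raw$meta$categories[[i]] <- labs
  }
  raw
}

# ---------------------------------------------------------------------------
# One-hot encoding
# ---------------------------------------------------------------------------

#' One-hot encode a screened survey table
#'
#' Turns every (categorical or binary) variable into indicator columns named
#' `variable=level`. A k-level variable contributes k-1 columns with the
#' first level as the dropped reference (full k-column coding available via
#' `reference_drop = FALSE` for sensitivity checks). Missing values become an
#' all-zero block, plus an explicit `variable=<missing>` indicator column
#' when `missing_level = TRUE` (the default: survey skip patterns make
#' listwise deletion destructive, and the indicator preserves n). Variables
#' left with a single observed level are dropped with a warning.
#'
#' @param raw a [raw_dataset()] whose variables are all categorical or
#'   binary (run [discretize_continuous()] first).
#' @param reference_drop drop the first level of each variable (k-1 coding)?
#' @param missing_level add an explicit missing-value indicator column for
#'   variables with missing values?
#' @return An [encoded_dataset()].
#' @export
one_hot_encode <- function(raw, reference_drop = TRUE, missing_level = TRUE) {
  stopifnot(inherits(raw, "raw_dataset"))
  meta <- raw$meta
  covars <- setdiff(meta$name, c(raw$outcome, raw$weight))
  n <- nrow(raw$data)
  blocks <- list()
  col_source <- character(0)
  for (v in covars) {
    i <- match(v, meta$name)
    if (meta$kind[i] == "continuous") {
      stop("variable '", v, "' is still continuous; discretize it first")
    }
    x <- as.character(raw$data[[v]])
    levs <- meta$categories[[i]]
    if (is.null(levs)) levs <- sort(unique(x[!is.na(x)]))
    levs <- levs[levs %in% x | levs %in% unique(x)]  # keep declared order
    if (length(levs) < 2) {
      warning("variable '", v, "' has a single level after screening; dropped")
      next
    }
    use <- if (reference_drop) levs[-1] else levs
    m <- vapply(use, function(l) as.numeric(!is.na(x) & x == l), numeric(n))
    m <- matrix(m, nrow = n)
    cols <- paste0(v, "=", use)
    if (anyNA(x) && missing_level) {
      m <- cbind(m, as.numeric(is.na(x)))
      cols <- c(cols, paste0(v, "=<missing>"))
    }
    colnames(m) <- cols
    blocks[[v]] <- m
    col_source <- c(col_source, stats::setNames(rep(v, length(cols)), cols))
  }
  if (length(blocks) == 0) stop("no encodable variables")
  X <- do.call(cbind, blocks)
  y <- raw$data[[raw$outcome]]
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    stop("outcome must be complete and binary 0/1; run construct_outcome() first")
  }
  w <- raw$data[[raw$weight]]
  if (anyNA(w)) stop("weights must be complete")
  encoded_dataset(X, y, w, col_source)
}

#' Map an encoded column label back to its source variable
#'
#' @param ds an [encoded_dataset()].
#' @param cols column labels (`variable=level`).
#' @return Character vector of source variable names.
#' @export
decode_colnames <- function(ds, cols = colnames(ds$X)) {
  unknown <- setdiff(cols, names(ds$col_source))
  if (length(unknown) > 0) stop("unknown columns: ", paste(unknown, collapse = ", "))
  unname(ds$col_source[cols])
}

# ---------------------------------------------------------------------------
# Train/test splitting
# ---------------------------------------------------------------------------

#' Split an encoded dataset into train and test parts
#'
#' Disjoint, exhaustive partition with `round(ratio * n)` training rows.
#' With `stratified = TRUE` (default) the positive-class proportion is
#' preserved within one respondent per class, which matters for outcomes at
#' ~1% prevalence; plain random splitting is available to mirror a simple
#' random 80:20 protocol. Identical seeds give identical splits.
#'
#' @param ds an [encoded_dataset()].
#' @param ratio training fraction in (0, 1); 0.8 by default.
#' @param seed integer seed governing the permutation.
#' @param stratified stratify on the outcome?
#' @return `list(train =, test =)` of encoded datasets.
#' @export
split_train_test <- function(ds, ratio = 0.8, seed = 1L, stratified = TRUE) {
  stopifnot(inherits(ds, "encoded_dataset"), ratio > 0, ratio < 1)
  n <- nrow(ds$X)
  if (n < 10) stop("need at least 10 rows to split")
  idx_train <- with_local_seed(seed, {
    if (stratified) {
      unlist(lapply(c(0L, 1L), function(cl) {
        rows <- which(ds$y == cl)
        n_tr <- round(ratio * length(rows))
        sample(rows)[seq_len(n_tr)]
      }), use.names = FALSE)
    } else {
      sample.int(n)[seq_len(round(ratio * n))]
    }
  })
  idx_train <- sort(idx_train)
  idx_test <- setdiff(seq_len(n), idx_train)
  train <- ed_rows(ds, idx_train)
  test <- ed_rows(ds, idx_test)
  if (sum(train$y) == 0 || sum(test$y) == 0) {
    stop("split leaves a part with zero positive cases; enable stratification")
  }
  list(train = train, test = test)
}

# Run code under a temporary RNG state; the caller's stream is untouched.
with_local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}
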