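test_that("read_table round-trips a typed survey file and rejects mismatches", {
  paths <- write_tiny_survey()
  raw <- read_table(paths$data, paths$meta)
  expect_s3_class(raw, "raw_dataset")
  expect_equal(nrow(raw$data), 6)
  expect_equal(raw$outcome, "outcome")
  expect_equal(raw$weight, "wt")
  expect_true(is.numeric(raw$data$age))

  # extra column absent from metadata is fatal and named
  df <- read.csv(paths$data, check.names = FALSE)
  df$extra <- 1
  bad <- file.path(dirname(paths$data), "bad.csv")
  write.csv(df, bad, row.names = FALSE)
  expect_error(read_table(bad, paths$meta), "extra")

  # declared-continuous column with non-numeric values is fatal and named
  df2 <- read.csv(paths$data, check.names = FALSE)
  df2$age <- c("x", "y", "z", "x", "y", "z")
  bad2 <- file.path(dirname(paths$data), "bad2.csv")
  write.csv(df2, bad2, row.names = FALSE)
  expect_error(read_table(bad2, paths$meta), "age")
})

test_that("outcome rules implement any-source and gated formal help-seeking", {
  paths <- write_tiny_survey()
  raw <- read_table(paths$data, paths$meta)

  any_out <- construct_outcome(raw, outcome_rule_any("help_any"))
  # respondents 1,3,4,6 said yes to the gate question
  expect_equal(any_out$data$outcome, c(1L, 0L, 1L, 1L, 0L, 1L))

  formal <- construct_outcome(
    raw, outcome_rule_formal("help_any", sources = "police"))
  # gate=yes & police=yes only for respondents 1 and 6; respondent 3 sought
  # help only from own family -> any = 1 but formal = 0
  expect_equal(formal$data$outcome, c(1L, 0L, 0L, 0L, 0L, 1L))
  expect_equal(any_out$data$outcome[3], 1L)
  expect_equal(formal$data$outcome[3], 0L)

  expect_error(construct_outcome(raw, outcome_rule_formal("help_any", "lawyer")),
               "lawyer")
})

test_that("screening drops exclusions and de-duplicates construct groups", {
  paths <- write_tiny_survey()
  raw <- construct_outcome(read_table(paths$data, paths$meta),
                           outcome_rule_any("help_any"))
  scr <- screen_variables(raw)
  expect_false("resp_id" %in% names(scr$data))       # excluded: respondent ID
  expect_true("age" %in% names(scr$data))            # canonical age measure
  expect_false("age_5yr" %in% names(scr$data))       # same construct, dropped
  expect_equal(nrow(scr$data), nrow(raw$data))       # rows untouched

  # a multi-member construct group with no canonical member is fatal
  raw2 <- raw
  raw2$meta$canonical[raw2$meta$name == "age"] <- FALSE
  expect_error(screen_variables(raw2), "no canonical")

  # no exclusions at all -> identity
  raw3 <- raw
  raw3$meta$excluded[] <- FALSE
  raw3$meta$construct_id[] <- NA
  expect_identical(names(screen_variables(raw3)$data), names(raw$data))
})

test_that("discretization bins cover the line and preserve rows", {
  paths <- write_tiny_survey()
  raw <- screen_variables(construct_outcome(
    read_table(paths$data, paths$meta), outcome_rule_any("help_any")))
  cut <- discretize_continuous(raw, list(age = c(25, 35, 45)))
  expect_equal(cut$data$age[1], "(-Inf,25)")   # age 21
  expect_equal(cut$data$age[2], "[25,35)")     # age 34
  expect_equal(cut$data$age[3], "[45,Inf)")    # age 47
  expect_equal(cut$meta$kind[cut$meta$name == "age"], "categorical")
  expect_equal(nrow(cut$data), nrow(raw$data))

  expect_error(discretize_continuous(raw, list(age = c(35, 25))),
               "non-increasing")
  expect_warning(discretize_continuous(raw, list(age = numeric(0))),
                 "degenerate")
})

test_that("one-hot encoding uses k-1 reference coding with recoverable labels", {
  paths <- write_tiny_survey()
  raw <- discretize_continuous(
    screen_variables(construct_outcome(
      read_table(paths$data, paths$meta), outcome_rule_any("help_any"))),
    list(age = c(25, 35, 45)))
  ds <- one_hot_encode(raw)
  expect_s3_class(ds, "encoded_dataset")
  expect_equal(nrow(ds$X), 6)
  # 3-level education with reference "none" -> 2 columns
  edu_cols <- grep("^education=", colnames(ds$X), value = TRUE)
  expect_setequal(edu_cols, c("education=primary", "education=secondary"))
  # binary yes/no -> single column
  expect_length(grep("^police=", colnames(ds$X)), 1)
  # every label decodes to exactly one source variable
  expect_equal(decode_colnames(ds, "education=primary"), "education")
  expect_true(all(decode_colnames(ds) %in% raw$meta$name))

  # full coding keeps all k columns
  ds_full <- one_hot_encode(raw, reference_drop = FALSE)
  expect_length(grep("^education=", colnames(ds_full$X)), 3)
})

test_that("encoded column count follows the sum of (k-1) formula", {
  # 10 categorical variables of 4 levels -> 30 columns
  set.seed(7)
  n <- 40
  df <- as.data.frame(lapply(1:10, function(i)
    sample(paste0("l", 1:4), n, replace = TRUE)))
  names(df) <- paste0("q", 1:10)
  df$outcome <- rbinom(n, 1, 0.5)
  df$wt <- 1
  meta <- data.frame(name = names(df),
                     kind = c(rep("categorical", 10), "binary", "continuous"),
                     construct_id = NA, canonical = FALSE, excluded = FALSE,
                     exclusion_reason = NA, stringsAsFactors = FALSE)
  meta$categories <- c(rep(list(paste0("l", 1:4)), 10), list(NULL), list(NULL))
  raw <- raw_dataset(df, "outcome", "wt", meta)
  expect_equal(ncol(one_hot_encode(raw)$X), 10 * (4 - 1))
})

test_that("missing values become an indicator level and never drop rows", {
  df <- data.frame(q = c("a", "b", NA, "a", NA, "b", "a", "b", "a", "b"),
                   outcome = c(0, 1, 0, 1, 0, 1, 0, 1, 0, 1), wt = 1)
  meta <- data.frame(name = c("q", "outcome", "wt"),
                     kind = c("categorical", "binary", "continuous"),
                     construct_id = NA, canonical = FALSE, excluded = FALSE,
                     exclusion_reason = NA, stringsAsFactors = FALSE)
  meta$categories <- list(c("a", "b"), NULL, NULL)
  raw <- raw_dataset(df, "outcome", "wt", meta)
  ds <- one_hot_encode(raw)
  expect_equal(nrow(ds$X), 10)
  expect_true("q=<missing>" %in% colnames(ds$X))
  expect_equal(sum(ds$X[, "q=<missing>"]), 2)
  expect_false(anyNA(ds$X))
})

test_that("splitting is a seeded partition with stratified allocation", {
  ds <- make_planted(n = 100, seed = 3)
  sp <- split_train_test(ds, ratio = 0.8, seed = 9)
  expect_equal(nrow(sp$train$X), 80)
  expect_equal(nrow(sp$test$X), 20)

  sp2 <- split_train_test(ds, ratio = 0.8, seed = 9)
  expect_identical(sp$train$X, sp2$train$X)   # same seed, same split

  # partition property over several seeds: disjoint and exhaustive
  key <- function(ds) apply(ds$X, 1, paste, collapse = "")
  for (s in 1:5) {
    spk <- split_train_test(ds, 0.8, s)
    expect_equal(nrow(spk$train$X) + nrow(spk$test$X), 100)
    expect_equal(sum(spk$train$y) + sum(spk$test$y), sum(ds$y))
  }

  # exact stratified allocation at 1% prevalence: test gets 2 of 10 positives
  set.seed(11)
  Xr <- matrix(rbinom(1000 * 3, 1, 0.5), 1000, 3,
               dimnames = list(NULL, c("a", "b", "c")))
  yr <- rep(0L, 1000); yr[sample(1000, 10)] <- 1L
  rare <- encoded_dataset(Xr, yr, rep(1, 1000))
  spr <- split_train_test(rare, 0.8, seed = 2, stratified = TRUE)
  expect_equal(sum(spr$test$y), 2)
  expect_equal(sum(spr$train$y), 8)
})

test_that("row count is invariant through the whole encoding pipeline", {
  paths <- write_tiny_survey()
  raw <- read_table(paths$data, paths$meta)
  n0 <- nrow(raw$data)
  raw <- construct_outcome(raw, outcome_rule_any("help_any"))
  raw <- screen_variables(raw)
  raw <- discretize_continuous(raw, list(age = c(30, 40)))
  ds <- one_hot_encode(raw)
  expect_equal(nrow(ds$X), n0)
})
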