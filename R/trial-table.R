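#' Build a trial table
#'
#' The long-format container feeding every agreement and reliability
#' statistic: one row per measurement, identified by sample, rater, method
#' and trial index. Values are hematocrit percentages.
#'
#' @param data A data frame with columns `sample_id`, `rater`, `method`,
#'   `trial`, `hct_pct` (extra columns are kept).
#' @return A tibble of class `trial_table`.
#' @export
trial_table <- function(data) {
  needed <- c("sample_id", "rater", "method", "trial", "hct_pct")
  if (!is.data.frame(data) || !all(needed %in% names(data))) {
    stop_microhct(paste("A trial table needs columns",
                        paste(needed, collapse = ", ")),
                  "microhct_invalid_table")
  }
  out <- tibble::as_tibble(data)
  if (any(!is.finite(out$hct_pct)) || any(out$hct_pct < 0 | out$hct_pct > 100)) {
    stop_microhct("`hct_pct` must be finite and within [0, 100].",
                  "microhct_invalid_table")
  }
  key <- paste(out$sample_id, out$rater, out$method, out$trial)
  if (anyDuplicated(key)) {
    stop_microhct("(sample_id, rater, method, trial) must be unique.",
                  "microhct_invalid_table")
  }
  class(out) <- unique(c("trial_table", class(out)))
  out
}

#' Simulate a trial table with known variance components
#'
#' Generates triplicate-style reliability data from the additive model
#' `hct = mean + subject + rater_shift + error`, with subject effects
#' `N(0, subject_sd^2)`, optional rater shifts, and i.i.d. trial error
#' `N(0, error_sd^2)`. Under this model the expected two-way agreement ICC
#' is `subject_sd^2 / (subject_sd^2 + rater_var + error_sd^2)`, which is
#' what the parameter-recovery tests check.
#'
#' @param n_samples Number of blood samples (subjects).
#' @param trials Trials per rater.
#' @param mean Grand mean hematocrit (default 45, a typical adult value).
#' @param subject_sd Between-sample SD (default 2.5, spanning the normal
#'   adult range).
#' @param error_sd Within-rater trial-to-trial SD (default 0.5, on the
#'   order of one reader division).
#' @param raters Character vector of rater labels.
#' @param rater_sd SD of rater main effects (0 = no rater bias).
#' @param method Method label stored in the table.
#' @param seed Integer seed.
#' @return A [trial_table()].
#' @export
simulate_trial_table <- function(n_samples = 12, trials = 3, mean = 45,
                                 subject_sd = 2.5, error_sd = 0.5,
                                 raters = "rater1", rater_sd = 0,
                                 method = "app", seed = 1L) {
  withr::local_seed(as.integer(seed))
  subj <- rnorm(n_samples, 0, subject_sd)
  rat <- rnorm(length(raters), 0, rater_sd)
  grid <- tidyr::expand_grid(
    sample_id = sprintf("S%02d", seq_len(n_samples)),
    rater = raters,
    trial = seq_len(trials)
  )
  grid$hct_pct <- mean + subj[as.integer(factor(grid$sample_id))] +
    rat[match(grid$rater, raters)] +
    rnorm(nrow(grid), 0, error_sd)
  grid$hct_pct <- pmin(pmax(grid$hct_pct, 0), 100)
  grid$method <- method
  trial_table(grid[, c("sample_id", "rater", "method", "trial", "hct_pct")])
}

# Wide subjects x measurements matrix from a trial table; errors if the
# design is unbalanced.
trial_matrix <- function(data, measurement_col, value_col = "hct_pct") {
  wide <- tidyr::pivot_wider(
    data[, c("sample_id", measurement_col, value_col)],
    names_from = dplyr::all_of(measurement_col),
    values_from = dplyr::all_of(value_col)
  )
  m <- as.matrix(wide[, -1])
  if (anyNA(m)) {
    stop_microhct("Unbalanced design: every sample needs every measurement.",
                  "microhct_design_error")
  }
  rownames(m) <- wide$sample_id
  storage.mode(m) <- "double"
  m
}
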