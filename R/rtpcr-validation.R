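#' Fold change of a relative isoform amount
#'
#' Densitometry of a semiquantitative RT-PCR lane yields, per timepoint, the
#' percentage each product contributes to the lane total. The fold change
#' of the alternative product's relative amount between two timepoints is
#' the simple ratio of those percentages (in the direction reported for the
#' experiment, day7/day0 or day0/day7).
#'
#' @param pct_ref Reference-timepoint percentage (> 0; vectorized).
#' @param pct_cmp Comparison-timepoint percentage (>= 0).
#' @return `pct_cmp / pct_ref`.
#' @export
relative_fold <- function(pct_ref, pct_cmp) {
  if (any(pct_ref <= 0)) {
    stop("fold undefined: reference percentage is zero or negative")
  }
  if (any(pct_cmp < 0)) stop("negative comparison percentage")
  pct_cmp / pct_ref
}

#' Classify an RT-PCR validation experiment
#'
#' Three-way call on the day-7 fold change of the alternative product's
#' relative amount: `"minus"` (no validated change) when the fold is below
#' 2 or when a supplied day-10 fold exceeds the day-7 fold; `"plusplus"`
#' (strong change) when the day-7 fold exceeds 10; `"plus"` otherwise.
#' Folds of exactly 2 or exactly 10 are `"plus"`.
#'
#' @param fold_d7 Day-7 fold change(s).
#' @param fold_d10 Optional day-10 fold change(s); `NA` when not measured.
#' @return Character vector in `c("minus", "plus", "plusplus")`.
#' @examples
#' classify_validation(7.44)    # "plus"
#' classify_validation(111.60)  # "plusplus"
#' classify_validation(1.17)    # "minus"
#' @export
classify_validation <- function(fold_d7, fold_d10 = NA_real_) {
  if (any(is.na(fold_d7))) stop("fold_d7 must be defined")
  fold_d10 <- rep_len(fold_d10, length(fold_d7))
  minus <- fold_d7 < 2 | (!is.na(fold_d10) & fold_d10 > fold_d7)
  out <- ifelse(minus, "minus", ifelse(fold_d7 > 10, "plusplus", "plus"))
  out
}

#' Overall validation rate
#'
#' Percentage of calls that are `"plus"` or `"plusplus"` (i.e. validated as
#' changed at least 2-fold at day 7), rounded half-up to an integer.
#'
#' @param calls Character vector of calls from [classify_validation()].
#' @return Integer percentage.
#' @export
validation_rate <- function(calls) {
  if (length(calls) == 0L) stop("validation_rate needs at least one call")
  if (!all(calls %in% c("minus", "plus", "plusplus"))) {
    stop("calls must be 'minus', 'plus' or 'plusplus'")
  }
  floor(100 * mean(calls != "minus") + 0.5)
}

#' Published RT-PCR densitometry folds of the reference screen
#'
#' The 30 day-7 fold changes of alternative-product relative amounts
#' measured by semiquantitative RT-PCR in the published P19
#' neuronal-differentiation screen, transcribed from its validation table
#' (gene symbol, probeset id, reported day-7 splicing index, fold change of
#' the alternative product with its reported direction, and the published
#' three-way call).
#'
#' @return Data frame with columns `gene`, `probeset_id`, `si_d7`,
#'   `fold_d7`, `direction`, `reported_call`.
#' @export
rtpcr_reference_folds <- function() {
  path <- system.file("extdata", "table2_folds.tsv",
                      package = "spliceCascade", mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "numeric",
                                         "numeric", "character", "character"))
  df
}
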