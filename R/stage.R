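# Stage-level subject data: a tibble with one row per recruited subject.

#' Validate stage data
#'
#' Stage data are tibbles with a `quantile` column (biomarker quantile in
#' `[0, 1]`) and a binary `response` column; a `stage` column is carried
#' along when present. Used internally by every fitting routine.
#'
#' @param data A data frame of recruited subjects.
#' @return The data, invisibly, as a tibble.
#' @keywords internal
validate_stage_data <- function(data) {
  if (!is.data.frame(data) || !all(c("quantile", "response") %in% names(data))) {
    stop("Stage data must contain `quantile` and `response` columns.",
         call. = FALSE)
  }
  check_quantile(data$quantile, "quantile")
  if (!all(data$response %in% c(0, 1))) {
    stop("`response` must be 0/1.", call. = FALSE)
  }
  invisible(tibble::as_tibble(data))
}

#' Simulate one recruitment stage
#'
#' Draws `n` subjects screened into the trial at recruitment threshold `t`:
#' biomarker quantiles uniform on `[t, 1]` (screening truncates the
#' uniform population distribution) and Bernoulli responses at the point
#' response rate `pi(B)` of the true curve.
#'
#' @param n Number of subjects to recruit.
#' @param t Recruitment threshold (quantile in `[0, 1)`).
#' @param curve True [logistic_curve()] generating responses.
#' @param stage Stage label stored with the data (1 or 2).
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with columns `quantile`, `response`, `stage`.
#' @examples
#' generate_stage(5, 0.5, logistic_curve(-3, 6), seed = 1)
#' @export
generate_stage <- function(n, t, curve, stage = 1L, seed = NULL) {
  stopifnot(n >= 1, t >= 0, t < 1, inherits(curve, "cbatt_curve"))
  if (!is.null(seed)) set.seed(seed)
  b <- stats::runif(n, min = t, max = 1)
  x <- stats::rbinom(n, 1L, pi_point(curve$delta0, curve$delta1, b))
  tibble::new_tibble(list(quantile = b, response = x,
                          stage = rep(as.integer(stage), n)), nrow = n)
}
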