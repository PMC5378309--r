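# Applying the design to subject-level data: ingestion, quantile
# transformation against a reference sample, sequential "recruitment" in
# the order subjects present, and the full two-stage analysis.

#' Read subject records from CSV
#'
#' Expects a comma-separated file with a header row
#' `subject_id,biomarker,response`: an opaque subject label, the raw
#' biomarker measurement (assay units) and a 0/1 response. Records with a
#' missing response (not yet evaluable) are dropped with a message.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `subject_id`, `biomarker`, `response`.
#' @export
read_subject_records <- function(path) {
  records <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    biomarker = readr::col_double(),
    response = readr::col_integer()
  ))
  validate_subject_records(records)
}

validate_subject_records <- function(records) {
  records <- tibble::as_tibble(records)
  if (!all(c("subject_id", "biomarker", "response") %in% names(records))) {
    stop("Subject records need columns `subject_id`, `biomarker`, `response`.",
         call. = FALSE)
  }
  if (any(!is.finite(records$biomarker))) {
    stop("All biomarker measurements must be finite.", call. = FALSE)
  }
  n_missing <- sum(is.na(records$response))
  if (n_missing > 0) {
    message(sprintf("Dropping %d record(s) with missing response.", n_missing))
    records <- records[!is.na(records$response), ]
  }
  if (!all(records$response %in% c(0L, 1L))) {
    stop("`response` must be 0/1 (or missing).", call. = FALSE)
  }
  records
}

#' Simulate synthetic subject records
#'
#' Generates a synthetic subject table on a raw assay scale for testing
#' the application workflow end to end: raw biomarker values are drawn
#' log-normally (mimicking a skewed assay such as a receptor count),
#' transformed to quantiles against their own empirical distribution, and
#' responses drawn from the point response rate of the supplied curve.
#'
#' @param n Number of subjects.
#' @param curve True [logistic_curve()] on the quantile scale.
#' @param seed Optional integer seed.
#' @param meanlog,sdlog Log-normal parameters of the raw biomarker scale.
#' @return A tibble with `subject_id`, `biomarker`, `response`.
#' @export
simulate_subject_records <- function(n, curve, seed = NULL,
                                     meanlog = 2, sdlog = 1) {
  stopifnot(n >= 1, inherits(curve, "cbatt_curve"))
  if (!is.null(seed)) set.seed(seed)
  raw <- stats::rlnorm(n, meanlog, sdlog)
  b <- quantile_transform(raw, raw)
  tibble::tibble(
    subject_id = sprintf("S%04d", seq_len(n)),
    biomarker = raw,
    response = stats::rbinom(n, 1L, pi_point(curve$delta0, curve$delta1, b))
  )
}

#' Sequentially recruit eligible subjects
#'
#' Walks the record table in the given order (mimicking subjects
#' presenting over time) and recruits the first `n` whose biomarker
#' quantile — computed against the reference sample — is at least
#' `threshold`. Subjects named in `exclude` (already recruited in an
#' earlier stage) are skipped.
#'
#' @param records Subject records
#'   (`subject_id`, `biomarker`, `response`), in presentation order.
#' @param threshold Recruitment threshold on the quantile scale.
#' @param n Number of subjects to recruit.
#' @param reference Raw-scale reference biomarker sample for the quantile
#'   transform.
#' @param exclude Character vector of subject ids to skip.
#' @return A tibble of the `n` recruited records, in original order, with
#'   a `quantile` column appended.
#' @export
recruit_sequentially <- function(records, threshold, n, reference,
                                 exclude = character(0)) {
  records <- validate_subject_records(records)
  check_quantile(threshold, "threshold")
  q <- quantile_transform(records$biomarker, reference)
  eligible <- q >= threshold & !(records$subject_id %in% exclude)
  idx <- which(eligible)
  if (length(idx) < n) {
    stop(sprintf("Recruitment shortfall: %d eligible subject(s) at threshold %g, %d required.",
                 length(idx), threshold, n), call. = FALSE)
  }
  take <- idx[seq_len(n)]
  dplyr::mutate(records[take, ], quantile = q[take])
}

#' Run the full two-stage analysis on subject-level data
#'
#' The retrospective application workflow: recruit stage 1 sequentially
#' above `t1`, run the interim analysis, recruit stage 2 above the chosen
#' threshold (excluding stage-1 subjects), carry out the binomial exact
#' test on all recruited subjects, and estimate the biomarker threshold on
#' both the quantile and the raw assay scale (via the reference sample).
#'
#' @param records Subject records in presentation order.
#' @param design A [cbatt_design()].
#' @param reference Raw-scale reference biomarker sample; defaults to the
#'   biomarker values of `records` themselves (a documented fallback for
#'   when no larger population sample is available).
#' @param seed Integer seed for the interim resampling.
#' @param coverage Coverage of the threshold interval (default 0.75).
#' @return An object of class `cbatt_application` with the interim, the
#'   final test and the threshold estimate; [glance()] summarises it.
#' @export
run_application <- function(records, design, reference = NULL, seed = NULL,
                            coverage = 0.75) {
  stopifnot(inherits(design, "cbatt_design"))
  records <- validate_subject_records(records)
  if (is.null(reference)) reference <- records$biomarker
  seed <- resolve_seed(seed)

  stage1_rec <- recruit_sequentially(records, design$t1, design$s1, reference)
  stage1 <- dplyr::mutate(
    dplyr::select(stage1_rec, "quantile", "response"), stage = 1L)
  interim <- interim_analysis(stage1, design, seed = child_seed(seed, 2L))

  stopped <- interim$decision$action == "stop"
  t2 <- if (stopped) NA_real_
        else if (is_adaptive(design)) interim$decision$chosen_t2
        else design$t1
  pooled <- stage1
  p_value <- NA_real_
  significant <- FALSE
  if (!stopped) {
    stage2_rec <- recruit_sequentially(records, t2, design$s2, reference,
                                       exclude = stage1_rec$subject_id)
    stage2 <- dplyr::mutate(
      dplyr::select(stage2_rec, "quantile", "response"), stage = 2L)
    pooled <- dplyr::bind_rows(stage1, stage2)
    p_value <- exact_test(sum(pooled$response), design$s1 + design$s2,
                          design$rho)
    significant <- p_value <= design$alpha
  }

  fit <- if (stopped) interim$fit else fit_stage_model(pooled)
  threshold <- threshold_from_fit(fit, design$rho, n_draw = design$n_draw,
                                  coverage = coverage,
                                  seed = child_seed(seed, 4L))
  raw_scale <- if (!threshold$degenerate) {
    c(estimate = raw_threshold(threshold$point, reference),
      lower = raw_threshold(threshold$lower, reference),
      upper = raw_threshold(threshold$upper, reference))
  } else {
    c(estimate = NA_real_, lower = NA_real_, upper = NA_real_)
  }

  structure(
    list(design = design, seed = seed, interim = interim,
         stopped_at_interim = stopped, chosen_t2 = t2, data = pooled,
         x_ob = sum(pooled$response), p_value = p_value,
         significant = significant, threshold_estimate = threshold,
         threshold_raw = raw_scale, reference = reference),
    class = "cbatt_application"
  )
}

#' @export
print.cbatt_application <- function(x, ...) {
  cat(sprintf("<cbatt_application> %s design\n", x$design$variant))
  print(x$interim$decision)
  if (!x$stopped_at_interim) {
    cat(sprintf("  final: X_obs = %d/%d, p = %.4f (%ssignificant)\n",
                x$x_ob, x$design$s1 + x$design$s2, x$p_value,
                if (x$significant) "" else "not "))
  }
  print(x$threshold_estimate)
  if (!is.na(x$threshold_raw["estimate"])) {
    cat(sprintf("  raw-scale threshold: %.3g (%.0f%% CI %.3g, %.3g)\n",
                x$threshold_raw["estimate"],
                100 * x$threshold_estimate$coverage,
                x$threshold_raw["lower"], x$threshold_raw["upper"]))
  }
  invisible(x)
}

#' @rdname run_application
#' @param x A `cbatt_application`.
#' @param ... Unused.
#' @export
glance.cbatt_application <- function(x, ...) {
  tibble::tibble(
    variant = x$design$variant,
    stopped_at_interim = x$stopped_at_interim,
    chosen_t2 = x$chosen_t2,
    x_ob = x$x_ob,
    p_value = x$p_value,
    significant = x$significant,
    t_hat = x$threshold_estimate$point,
    t_hat_lower = x$threshold_estimate$lower,
    t_hat_upper = x$threshold_estimate$upper,
    t_hat_raw = unname(x$threshold_raw["estimate"])
  )
}

#' Serialise an application report to JSON
#'
#' @param x A [run_application()] result.
#' @param path File path to write to.
#' @return `path`, invisibly.
#' @export
write_application_report <- function(x, path) {
  stopifnot(inherits(x, "cbatt_application"))
  report <- c(as.list(glance(x)),
              list(coverage = x$threshold_estimate$coverage,
                   t_hat_raw_lower = unname(x$threshold_raw["lower"]),
                   t_hat_raw_upper = unname(x$threshold_raw["upper"]),
                   seed = x$seed))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
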