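#' Ratio-to-baseline cortical excitability metrics
#'
#' For a MEP amplitude `x` and a baseline set of single-pulse amplitudes
#' T_1..T_m from the same session, the two metrics are
#'
#' \deqn{\varrho = \frac{x\,m}{\sum_i T_i}, \qquad
#'       \delta = \frac{x}{m} \sum_i \frac{1}{T_i}}
#'
#' i.e. the amplitude divided by the arithmetic (rho) or harmonic (delta)
#' mean of the baseline. Both are dimensionless; by the AM-HM inequality
#' `delta >= rho`, with equality exactly when the baseline is constant. For
#' paired pulses they quantify the intracortical facilitation (>1) or
#' inhibition (<1) induced by the conditioning stimulus.
#'
#' @param x MEP amplitude(s), strictly positive (vectorised).
#' @param baseline Numeric vector of m >= 1 strictly positive baseline
#'   amplitudes.
#' @return Numeric vector the length of `x`.
#' @examples
#' compute_rho(2, c(1, 2, 4))   # 6/7
#' compute_delta(2, c(1, 2, 4)) # 7/6
#' @export
compute_rho <- function(x, baseline) {
  check_metric_inputs(x, baseline)
  x / mean(baseline)
}

#' @rdname compute_rho
#' @export
compute_delta <- function(x, baseline) {
  check_metric_inputs(x, baseline)
  x * mean(1 / baseline)
}

check_metric_inputs <- function(x, baseline) {
  if (length(baseline) < 1L || !is.numeric(baseline)) {
    stop_param("`baseline` must contain at least one amplitude")
  }
  if (anyNA(baseline) || any(baseline <= 0)) {
    stop_param("baseline amplitudes must be strictly positive")
  }
  if (!is.numeric(x) || anyNA(x) || any(x <= 0)) {
    stop_param("`x` must be strictly positive")
  }
  invisible(TRUE)
}

#' Annotate a stimulation table with delta and rho
#'
#' Computes `delta` and `rho` for every row against the single pulses
#' (`isi_ms == 0`) of the same session. Single pulses are members of their
#' own baseline by default, so within each session the mean of `rho` over
#' the singles is exactly 1 and the mean of `1/delta` over the singles is
#' exactly 1. With `leave_one_out = TRUE` each single pulse is instead
#' referenced to the other m - 1 singles of its session (requires m >= 2).
#'
#' @param table Stimulation table (see [generate_cohort()] for the schema).
#' @param leave_one_out Exclude each single pulse from its own baseline.
#' @return The table with `delta` and `rho` columns appended.
#' @export
annotate_metrics <- function(table, leave_one_out = FALSE) {
  check_stim_table(table)
  if (nrow(table) == 0L) stop_param("empty stimulation table")
  if (anyNA(table$amplitude_uv) || any(table$amplitude_uv <= 0)) {
    stop_param("amplitudes must be strictly positive")
  }
  table$delta <- NA_real_
  table$rho <- NA_real_
  for (ses in unique(table$session_id)) {
    rows <- which(table$session_id == ses)
    singles <- table$amplitude_uv[rows][table$isi_ms[rows] == 0L]
    m <- length(singles)
    if (m == 0L) {
      stop_param("session '", ses, "' has no single pulses to form a baseline")
    }
    x <- table$amplitude_uv[rows]
    if (!leave_one_out) {
      table$rho[rows] <- compute_rho(x, singles)
      table$delta[rows] <- compute_delta(x, singles)
    } else {
      if (m < 2L) {
        stop_param("session '", ses, "' needs >= 2 singles for leave-one-out")
      }
      sum_t <- sum(singles)
      sum_inv <- sum(1 / singles)
      is_single <- table$isi_ms[rows] == 0L
      rho <- compute_rho(x, singles)
      delta <- compute_delta(x, singles)
      xs <- x[is_single]
      rho[is_single] <- xs * (m - 1) / (sum_t - xs)
      delta[is_single] <- xs * (sum_inv - 1 / xs) / (m - 1)
      table$rho[rows] <- rho
      table$delta[rows] <- delta
    }
  }
  table
}
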