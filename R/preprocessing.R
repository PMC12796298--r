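#' IQR outlier filter
#'
#' Keep-mask under the Tukey fence rule: values outside
#' `[Q1 - k * IQR, Q3 + k * IQR]` are flagged for removal. Quartiles use
#' linear interpolation (R's default type-7 convention), which the removed
#' row counts depend on; the convention is part of the contract.
#'
#' @param amplitudes Numeric vector, at least 4 values.
#' @param k Fence multiplier (> 0), conventionally 1.5.
#' @return Logical keep-mask the length of `amplitudes`.
#' @examples
#' iqr_filter(c(1, 2, 3, 4, 100)) # TRUE TRUE TRUE TRUE FALSE
#' @export
iqr_filter <- function(amplitudes, k = 1.5) {
  if (!is.numeric(amplitudes) || length(amplitudes) < 4L || anyNA(amplitudes)) {
    stop_param("`amplitudes` must be >= 4 non-missing values")
  }
  k <- check_positive_scalar(k, "k")
  q <- quantile(amplitudes, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  amplitudes >= q[1] - k * iqr & amplitudes <= q[2] + k * iqr
}

#' Build the model-ready feature table
#'
#' Applies the IQR filter to MEP amplitudes, then annotates the surviving
#' rows with `delta` and `rho` against each session's surviving single
#' pulses (cleaning precedes metric computation, so outliers never
#' contaminate a baseline). The fences are computed globally over all
#' amplitudes by default; `scope` restricts them per subject or per ISI for
#' sensitivity analyses.
#'
#' @param raw Stimulation table.
#' @param k IQR fence multiplier passed to [iqr_filter()].
#' @param scope `"global"`, `"subject"` or `"isi"`: the grouping within
#'   which fences are computed.
#' @param leave_one_out Passed to [annotate_metrics()].
#' @return A list with `features` (the cleaned, annotated table) and
#'   `report` (rows in / removed / out plus the removed row indices of the
#'   input table).
#' @export
build_feature_table <- function(raw, k = 1.5,
                                scope = c("global", "subject", "isi"),
                                leave_one_out = FALSE) {
  check_stim_table(raw)
  scope <- match.arg(scope)
  keep <- switch(scope,
    global = iqr_filter(raw$amplitude_uv, k),
    subject = stats::ave(
      raw$amplitude_uv, raw$subject_id,
      FUN = function(v) as.numeric(iqr_filter(v, k))
    ) > 0.5,
    isi = stats::ave(
      raw$amplitude_uv, raw$isi_ms,
      FUN = function(v) as.numeric(iqr_filter(v, k))
    ) > 0.5
  )
  cleaned <- raw[keep, , drop = FALSE]
  rownames(cleaned) <- NULL
  features <- annotate_metrics(cleaned, leave_one_out = leave_one_out)
  report <- list(
    rows_in = nrow(raw),
    rows_removed = sum(!keep),
    rows_out = nrow(features),
    removed_indices = which(!keep),
    k = k,
    scope = scope
  )
  list(features = features, report = report)
}
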