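#' A timestamped stress-measurement series
#'
#' Holds repeated perceived-stress ratings (1--7 visual analogue scale) or
#' salivary cortisol concentrations for one participant, with times in
#' minutes relative to the start of the stress induction.
#'
#' @param participant_id Identifier.
#' @param series_type \code{"perceived_stress"} or \code{"cortisol"}.
#' @param times Strictly increasing sample times in minutes.
#' @param values Measurements; may contain \code{NA} for missing samples.
#' @return An object of class \code{stress_series}.
#' @export
stress_series <- function(participant_id,
                          series_type = c("perceived_stress", "cortisol"),
                          times, values) {
  series_type <- match.arg(series_type)
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (series_type == "perceived_stress" &&
      any(values < 1 | values > 7, na.rm = TRUE))
    stop("perceived-stress ratings must lie in [1, 7]")
  structure(
    list(participant_id = participant_id, series_type = series_type,
         times = as.numeric(times), values = as.numeric(values),
         missing_mask = is.na(values)),
    class = "stress_series"
  )
}

#' @export
print.stress_series <- function(x, ...) {
  cat("Stress series (", x$series_type, ") for ", x$participant_id, ": ",
      length(x$times), " samples over [", min(x$times), ", ", max(x$times),
      "] min", if (any(x$missing_mask))
        paste0(", ", sum(x$missing_mask), " missing"), "\n", sep = "")
  invisible(x)
}

#' Area under the curve with respect to ground
#'
#' Trapezoidal area between the piecewise-linear measurement curve and
#' zero, over the observed time span:
#' \eqn{\sum_i (m_i + m_{i+1})/2 \cdot (t_{i+1} - t_i)}. This is the
#' standard total-output summary for repeated cortisol or stress-rating
#' measurements. Missing samples must be interpolated first (see
#' [interpolate_missing()]).
#'
#' @param series A [stress_series()], or a list with \code{times} and
#'   \code{values}.
#' @return AUC in value x minutes.
#' @examples
#' s <- stress_series("p1", "cortisol", c(0, 10, 20), c(2, 2, 2))
#' auc_ground(s) # 40
#' @export
auc_ground <- function(series) {
  t <- series$times; v <- series$values
  if (length(t) < 2L) stop("need at least 2 timepoints to compute AUC")
  if (any(is.na(v)))
    stop("series contains missing values; interpolate_missing() first")
  sum((v[-length(v)] + v[-1]) / 2 * diff(t))
}

#' Interpolate missing samples linearly in time
#'
#' Each missing sample is replaced by the time-weighted linear
#' interpolation between its nearest non-missing neighbours; non-missing
#' values are untouched. Missing first or last samples are an error (there
#' is no principled edge rule for extrapolation).
#'
#' @param series A [stress_series()] with \code{NA}s for missing values.
#' @param method \code{"time"} (linear in clock time, the default) or
#'   \code{"index"} (midpoint-in-index averaging, for sensitivity checks).
#' @return The series with missing values filled and the missing mask
#'   preserved.
#' @export
interpolate_missing <- function(series, method = c("time", "index")) {
  method <- match.arg(method)
  v <- series$values
  if (!any(is.na(v))) return(series)
  if (is.na(v[1]) || is.na(v[length(v)]))
    stop("missing value at the first or last timepoint cannot be ",
         "interpolated")
  x <- if (method == "time") series$times else seq_along(v)
  filled <- stats::approx(x[!is.na(v)], v[!is.na(v)], xout = x,
                          method = "linear")$y
  out <- series
  out$values <- ifelse(is.na(v), filled, v)
  out
}

#' Standardise participant-level summaries across a sample
#'
#' Z-scores a vector of per-participant summaries (e.g. perceived-stress
#' AUC) to mean 0, sample SD 1 (n - 1 denominator).
#'
#' @param values Numeric vector, one summary per participant.
#' @return Standardised scores.
#' @export
zscore_population <- function(values) {
  if (length(values) < 2L) stop("need at least 2 participants to z-score")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0)
    stop("zero variance across participants; z-scores undefined")
  (values - mean(values)) / s
}

#' Summarise a long stress table as AUC-with-respect-to-ground
#'
#' Takes the long format written by [simulate_population()] /
#' [write_stress_csv()] (participant_id, series_type, time_min, value),
#' interpolates interior missing samples, computes [auc_ground()] per
#' participant x series, and z-scores each series type across participants.
#'
#' @param stress_long Long-format data.frame.
#' @return Data.frame: participant_id, series_type, auc_ground, z_auc.
#' @export
summarise_stress <- function(stress_long) {
  keys <- unique(stress_long[, c("participant_id", "series_type")])
  auc <- mapply(function(pid, st) {
    rows <- stress_long$participant_id == pid &
      stress_long$series_type == st
    sub <- stress_long[rows, ]
    sub <- sub[order(sub$time_min), ]
    s <- stress_series(pid, st, sub$time_min, sub$value)
    auc_ground(interpolate_missing(s))
  }, keys$participant_id, keys$series_type)
  out <- data.frame(keys, auc_ground = as.numeric(auc),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$z_auc <- NA_real_
  for (st in unique(out$series_type)) {
    idx <- out$series_type == st
    if (sum(idx) >= 2L && stats::sd(out$auc_ground[idx]) > 0)
      out$z_auc[idx] <- zscore_population(out$auc_ground[idx])
  }
  out
}

#' Write or read a long-format stress table as CSV
#'
#' @param stress_long Data.frame (participant_id, series_type, time_min,
#'   value).
#' @param path File path.
#' @export
write_stress_csv <- function(stress_long, path) {
  utils::write.csv(stress_long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stress_csv
#' @export
read_stress_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
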