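# Gravimetric flow analysis: balance trace -> volumetric flow -> occlusion
# call. The occlusion definition is flow strictly below 0.001 mL/min
# maintained for at least 3 minutes; channels never meeting it are censored
# at 40 min.

#' Tare a balance trace
#'
#' Subtracts the first recorded value (the initial weight of the tubing and
#' vessel) from every mass reading, so the trace starts at 0 g.
#'
#' @param trace a [BalanceTrace-class].
#' @return A tared [BalanceTrace-class]. Taring is idempotent.
#' @examples
#' tare(balanceTrace(c(0, 5, 10), c(2.00, 2.05, 2.11)))
#' @export
tare <- function(trace) {
  if (!is(trace, "BalanceTrace")) stop("'trace' must be a BalanceTrace")
  if (length(trace@mass_g) < 1L) stop("empty trace")
  balanceTrace(trace@time_s, trace@mass_g - trace@mass_g[1])
}

#' Convert mass to blood volume
#'
#' Applies the whole-blood density conversion 1 g = 1/1.06 mL. Negative
#' inputs are allowed (tared noisy readings can dip below zero).
#'
#' @param mass_g mass in grams (vectorised).
#' @return Volume in mL.
#' @examples
#' massToVolume(1.06)   # 1 mL
#' @export
massToVolume <- function(mass_g) {
  mass_g / BLOOD_DENSITY_G_PER_ML
}

# centered moving average with symmetric shrinking windows at the edges
.movingAverage <- function(x, halfwidth) {
  if (halfwidth == 0L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  out <- numeric(n)
  for (i in seq_len(n)) {
    h <- min(halfwidth, i - 1L, n - i)
    out[i] <- (cs[i + h + 1L] - cs[i - h]) / (2L * h + 1L)
  }
  out
}

#' Estimate volumetric flow from a balance trace
#'
#' Converts the (tared) cumulative mass to volume (1 g = 1/1.06 mL), smooths
#' the volume series with a centered moving average, and differentiates by
#' central differences (one-sided at the two edges). The result is the
#' volumetric flow in mL/min at the original sample times.
#'
#' The smoothing window is rounded to an odd number of samples; a window no
#' wider than one sampling interval disables smoothing. Differentiation
#' amplifies balance noise, hence the default 30 s (7 samples at 5 s
#' spacing).
#'
#' @param trace a [BalanceTrace-class]; the trace is used as given, so call
#'   [tare()] first (differentiation is unaffected by the offset either way).
#' @param smoothingWindow_s moving-average window, s (default 30).
#' @return A [FlowSeries-class].
#' @examples
#' tr <- balanceTrace(seq(0, 60, by = 5), seq(0, 0.00106 * 12, by = 0.00106))
#' estimateFlow(tr, smoothingWindow_s = 5)   # 0.012 mL/min throughout
#' @export
estimateFlow <- function(trace, smoothingWindow_s = 30) {
  if (!is(trace, "BalanceTrace")) stop("'trace' must be a BalanceTrace")
  t <- trace@time_s
  n <- length(t)
  if (n < 3L) stop("need at least 3 samples to differentiate")
  if (smoothingWindow_s < 0) stop("smoothing window must be non-negative")
  dt <- stats::median(diff(t))
  w <- max(1L, as.integer(round(smoothingWindow_s / dt)))
  if (w %% 2L == 0L) w <- w + 1L
  if (w > n)
    stop("configuration error: smoothing window longer than the trace")
  v <- massToVolume(trace@mass_g)
  vs <- .movingAverage(v, (w - 1L) %/% 2L)
  f <- numeric(n)
  f[1] <- (vs[2] - vs[1]) / (t[2] - t[1])
  f[n] <- (vs[n] - vs[n - 1]) / (t[n] - t[n - 1])
  i <- 2:(n - 1)
  f[i] <- (vs[i + 1] - vs[i - 1]) / (t[i + 1] - t[i - 1])
  flowSeries(t, f * 60, smoothingWindow_s = smoothingWindow_s)
}

#' Detect occlusion in a flow series
#'
#' Scans for maximal runs of consecutive samples with flow strictly below
#' the threshold. A run qualifies if it spans at least the dwell (last
#' minus first timestamp of the run). The channel is called occluded at the
#' start of the earliest qualifying run: "time to occlude" denotes when flow
#' ceases; the dwell is a confirmation criterion. A below-threshold run cut
#' off by the end of the trace qualifies only if it already spans the dwell.
#' Negative flow estimates count as below threshold (no forward flow).
#'
#' @param flow a [FlowSeries-class].
#' @param threshold_mLmin occlusion flow threshold, mL/min (default 0.001).
#'   The comparison is strict: flow exactly at the threshold does not count.
#' @param dwell_s minimum dwell, s (default 180).
#' @param censor_min censoring value for non-occluding channels, min
#'   (default 40); must be at least the trace duration.
#' @return An [OcclusionCall-class].
#' @examples
#' t <- seq(0, 1800, by = 5)
#' f <- ifelse(t < 600, 0.02, 0)
#' detectOcclusion(flowSeries(t, f))   # occluded at 10 min
#' @export
detectOcclusion <- function(flow, threshold_mLmin = 0.001, dwell_s = 180,
                            censor_min = 40) {
  if (!is(flow, "FlowSeries")) stop("'flow' must be a FlowSeries")
  if (length(flow@time_s) == 0L) stop("empty flow series")
  if (threshold_mLmin <= 0 || dwell_s <= 0)
    stop("configuration error: threshold and dwell must be positive")
  t <- flow@time_s
  duration_min <- max(t) / 60
  if (censor_min < duration_min)
    stop("censor value must be at least the trace duration")
  below <- flow@flow_mLmin < threshold_mLmin
  occTime <- NA_real_
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    if (t[ends[k]] - t[starts[k]] >= dwell_s) {
      occTime <- t[starts[k]] / 60
      break
    }
  }
  new("OcclusionCall", occluded = !is.na(occTime),
      occlusionTime_min = occTime, threshold_mLmin = threshold_mLmin,
      dwell_s = dwell_s, censorValue_min = censor_min,
      traceDuration_min = duration_min)
}

#' Censored occlusion time
#'
#' Returns the occlusion time in minutes, or the fixed censoring value for
#' channels that never occluded. This fixed-value substitution (not a
#' survival model) is what the rank-based group comparison expects.
#'
#' @param call an [OcclusionCall-class].
#' @param censor_min censoring value, min; defaults to the value stored in
#'   the call.
#' @return Time in minutes.
#' @export
censoredTime <- function(call, censor_min = NULL) {
  if (!is(call, "OcclusionCall")) stop("'call' must be an OcclusionCall")
  if (is.null(censor_min)) censor_min <- call@censorValue_min
  if (call@occluded) call@occlusionTime_min else censor_min
}

# --- delimited-text I/O ----------------------------------------------------

#' Read a balance log
#'
#' Reads a delimited text file with a header and columns `time_s` and
#' `mass_g` into a [BalanceTrace-class].
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return A [BalanceTrace-class].
#' @export
readBalanceLog <- function(path, sep = "\t") {
  if (!file.exists(path)) stop(sprintf("balance log not found: %s", path))
  d <- utils::read.table(path, header = TRUE, sep = sep)
  if (!all(c("time_s", "mass_g") %in% names(d)))
    stop("balance log needs columns 'time_s' and 'mass_g'")
  balanceTrace(d$time_s, d$mass_g)
}

#' Write a balance log
#' @param trace a [BalanceTrace-class].
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
writeBalanceLog <- function(trace, path, sep = "\t") {
  utils::write.table(
    data.frame(time_s = trace@time_s, mass_g = trace@mass_g),
    path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a flow series as delimited text
#' @param flow a [FlowSeries-class].
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
writeFlowSeries <- function(flow, path, sep = "\t") {
  utils::write.table(
    data.frame(time_s = flow@time_s, flow_mL_min = flow@flow_mLmin),
    path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an occlusion call as a structured-text summary
#'
#' Writes the detector verdict and the parameters used as a small YAML
#' document, so results are self-describing.
#'
#' @param call an [OcclusionCall-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeOcclusionSummary <- function(call, path) {
  yaml::write_yaml(list(
    occluded = call@occluded,
    occlusion_time_min = if (call@occluded) call@occlusionTime_min else NULL,
    censored_time_min = censoredTime(call),
    parameters = list(
      threshold_mL_min = call@threshold_mLmin,
      dwell_s = call@dwell_s,
      censor_min = call@censorValue_min,
      occlusion_time_convention = "start of first qualifying run"
    ),
    trace_duration_min = call@traceDuration_min
  ), path)
  invisible(path)
}
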