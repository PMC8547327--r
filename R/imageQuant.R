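# Confocal stack quantification: maximum-intensity projection and
# integrated density (raw pixel sum, matching the Fiji "measure" usage:
# no background subtraction, no mean-times-area). Channels are processed
# independently. Sums are accumulated in double precision so 16-bit input
# cannot overflow.

#' Maximum-intensity projection
#'
#' Collapses a z-stack into a 2-D image by taking each pixel's maximum
#' across slices.
#'
#' @param stack numeric 3-D array `[slices x rows x cols]` (a single slice
#'   may be given as `[1 x rows x cols]`).
#' @return A rows x cols matrix.
#' @examples
#' st <- array(0, c(2, 3, 3)); st[1, 1, 1] <- 5; st[2, 3, 3] <- 7
#' maxIntensityProjection(st)
#' @export
maxIntensityProjection <- function(stack) {
  if (!is.array(stack) || length(dim(stack)) != 3L)
    stop("'stack' must be a 3-D array [slices x rows x cols]")
  d <- dim(stack)
  if (d[1] < 1L || prod(d) == 0L) stop("empty stack")
  out <- matrix(stack[1, , ], d[2], d[3])
  if (d[1] > 1L)
    for (s in 2:d[1]) out <- pmax(out, matrix(stack[s, , ], d[2], d[3]))
  out
}

#' Integrated density of an image
#'
#' Sum of all pixel values of a 2-D image (the "integrated density" of a
#' projection). Computed in double precision.
#'
#' @param image numeric matrix.
#' @return The summed intensity (a scalar).
#' @examples
#' integratedDensity(matrix(1, 2, 2))   # 4
#' @export
integratedDensity <- function(image) {
  if (!is.matrix(image) || length(image) == 0L)
    stop("'image' must be a non-empty matrix")
  sum(as.numeric(image))
}

#' Accumulation curves of a stack series
#'
#' For each fluorescence channel, computes the integrated density of the
#' maximum-intensity projection of every stack, in time order. These curves
#' are the assay's measure of platelet and fibrin accumulation.
#'
#' @param series a [StackSeries-class].
#' @return A named list of [AccumulationCurve-class] objects, one per
#'   channel.
#' @export
accumulationCurves <- function(series) {
  if (!is(series, "StackSeries")) stop("'series' must be a StackSeries")
  validObject(series)
  chans <- channelNames(series)
  out <- lapply(chans, function(ch) {
    frs <- Filter(function(f) f$channel == ch, series@frames)
    tp <- vapply(frs, `[[`, 0, "time_min")
    o <- order(tp)
    dens <- vapply(frs[o], function(f)
      integratedDensity(maxIntensityProjection(f$data)), 0)
    new("AccumulationCurve", timepoints_min = tp[o],
        integratedDensity = dens, channel = ch)
  })
  names(out) <- chans
  out
}

#' Endpoint value of an accumulation curve
#'
#' Returns the integrated density at the latest timepoint at or before `t`
#' (the 30-minute endpoint by default). A curve whose last stack completed
#' just short of `t` therefore contributes its final value.
#'
#' @param curve an [AccumulationCurve-class].
#' @param t_min endpoint time, min (default 30).
#' @return The integrated density at the selected timepoint.
#' @export
endpointValue <- function(curve, t_min = 30) {
  if (!is(curve, "AccumulationCurve")) stop("'curve' must be an AccumulationCurve")
  if (length(curve@timepoints_min) == 0L) stop("empty curve")
  idx <- which(curve@timepoints_min <= t_min)
  if (length(idx) == 0L)
    stop("curve has no timepoint at or before the requested endpoint")
  curve@integratedDensity[max(idx)]
}
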