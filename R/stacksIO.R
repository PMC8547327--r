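# TIFF I/O for stack series. One multi-page 16-bit TIFF per (timepoint,
# channel); acquisition metadata (slice spacing, interval, pixel size)
# travels in a YAML sidecar because plain TIFF tags cannot carry it
# portably.

.stackFileName <- function(prefix, time_min, channel) {
  sprintf("%s_t%06.2fmin_%s.tif", prefix, time_min, channel)
}

#' Write a stack series as multi-page TIFFs
#'
#' Writes each frame as a 16-bit multi-page TIFF (one page per z slice)
#' named `<prefix>_t<time>min_<channel>.tif`, plus a `<prefix>_meta.yaml`
#' sidecar with the acquisition metadata. Intensities must lie in
#' `[0, 65535]`.
#'
#' @param series a [StackSeries-class].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default "stack").
#' @return Character vector of the written TIFF paths, invisibly.
#' @export
writeStackSeries <- function(series, dir, prefix = "stack") {
  if (!is(series, "StackSeries")) stop("'series' must be a StackSeries")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (fr in series@frames) {
    d <- fr$data
    if (max(d) > 65535) stop("intensities exceed the 16-bit range")
    pages <- lapply(seq_len(dim(d)[1]),
                    function(z) matrix(d[z, , ], dim(d)[2], dim(d)[3]) / 65535)
    p <- file.path(dir, .stackFileName(prefix, fr$time_min, fr$channel))
    tiff::writeTIFF(pages, p, bits.per.sample = 16L)
    paths <- c(paths, p)
  }
  yaml::write_yaml(list(
    slice_spacing_um = series@sliceSpacing_um,
    frame_interval_min = series@frameInterval_min,
    pixel_size_um = series@pixelSize_um,
    channels = channelNames(series)
  ), file.path(dir, paste0(prefix, "_meta.yaml")))
  invisible(paths)
}

#' Read a stack series written by [writeStackSeries()]
#'
#' @param dir directory containing the TIFFs and the metadata sidecar.
#' @param prefix file-name prefix used when writing (default "stack").
#' @return A [StackSeries-class] with integer intensities in `[0, 65535]`.
#' @export
readStackSeries <- function(dir, prefix = "stack") {
  metaPath <- file.path(dir, paste0(prefix, "_meta.yaml"))
  if (!file.exists(metaPath))
    stop(sprintf("stack metadata not found: %s", metaPath))
  meta <- yaml::read_yaml(metaPath)
  files <- list.files(dir, pattern = paste0("^", prefix,
                                            "_t[0-9.]+min_.*\\.tif$"),
                      full.names = TRUE)
  if (length(files) == 0L) stop("no stack TIFFs found")
  frames <- lapply(files, function(p) {
    base <- sub("\\.tif$", "", basename(p))
    bits <- strsplit(base, "_")[[1]]
    tt <- as.numeric(sub("min$", "", sub("^t", "", bits[length(bits) - 1L])))
    ch <- bits[length(bits)]
    pages <- tiff::readTIFF(p, all = TRUE)
    stk <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
    for (z in seq_along(pages)) stk[z, , ] <- round(pages[[z]] * 65535)
    list(time_min = tt, channel = ch, data = stk)
  })
  ord <- order(vapply(frames, `[[`, 0, "time_min"),
               vapply(frames, `[[`, "", "channel"))
  stackSeries(frames[ord],
              sliceSpacing_um = meta$slice_spacing_um,
              frameInterval_min = meta$frame_interval_min,
              pixelSize_um = meta$pixel_size_um)
}

#' Write accumulation curves as delimited text
#'
#' One table with columns `channel`, `timepoint_min`, `integrated_density`.
#'
#' @param curves named list of [AccumulationCurve-class] objects (as
#'   returned by [accumulationCurves()]).
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
writeAccumulationCurves <- function(curves, path, sep = "\t") {
  tab <- do.call(rbind, lapply(curves, function(cv)
    data.frame(channel = cv@channel, timepoint_min = cv@timepoints_min,
               integrated_density = cv@integratedDensity)))
  utils::write.table(tab, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
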