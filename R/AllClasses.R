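#' @import methods
NULL

# ---------------------------------------------------------------------------
# Device geometry and perfusion design
# ---------------------------------------------------------------------------

#' Rectangular channel geometry
#'
#' Describes one rectangular (slot-like) microfluidic channel: its height
#' (depth) and width in mm, its length in mm (used only by the hydraulic
#' resistance model of the simulator), and how many identical arms run in
#' parallel from the inlet. The wall-shear design formula assumes a wide
#' slot, so the height must not exceed the width.
#'
#' @slot height_mm channel height (depth), mm; default 0.070 (70 um).
#' @slot width_mm channel width, mm.
#' @slot length_mm channel length, mm; only the resistance model uses it.
#' @slot nParallelArms number of identical parallel arms (1 for a single
#'   channel, 2 for a pressure-relief bifurcation).
#'
#' @seealso [channelGeometry()], [wallShearRate()], [pumpFlowForShear()]
#' @export
setClass("ChannelGeometry",
  representation(
    height_mm = "numeric",
    width_mm = "numeric",
    length_mm = "numeric",
    nParallelArms = "integer"
  ),
  prototype(height_mm = 0.070, width_mm = 0.5, length_mm = 10,
            nParallelArms = 1L)
)

setValidity("ChannelGeometry", function(object) {
  msg <- character()
  for (s in c("height_mm", "width_mm", "length_mm")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("'%s' must be a single positive number", s))
  }
  if (length(object@nParallelArms) != 1L || object@nParallelArms < 1L)
    msg <- c(msg, "'nParallelArms' must be a positive integer")
  if (length(msg) == 0L && object@height_mm > object@width_mm)
    msg <- c(msg, "height_mm must not exceed width_mm (wide-slot assumption)")
  if (length(msg)) msg else TRUE
})

#' Construct a ChannelGeometry
#'
#' Defaults describe the reference device: a 70 um deep, 500 um wide
#' channel. (Device fabrication targets 65-70 um; the flow design value of
#' 0.0245 mL/min corresponds to 70 um, which is the default here. A 65 um
#' geometry is equally valid input.)
#'
#' @param height_mm,width_mm,length_mm channel dimensions in mm.
#' @param nParallelArms number of identical parallel arms.
#' @return A [ChannelGeometry-class] object.
#' @examples
#' channelGeometry()                       # reference single channel
#' channelGeometry(nParallelArms = 2)      # pressure-relief bifurcation
#' @export
channelGeometry <- function(height_mm = 0.070, width_mm = 0.5,
                            length_mm = 10, nParallelArms = 1L) {
  new("ChannelGeometry", height_mm = height_mm, width_mm = width_mm,
      length_mm = length_mm, nParallelArms = as.integer(nParallelArms))
}

#' Perfusion design for a target wall shear rate
#'
#' Bundles the flow rates that realise a target wall shear rate in a given
#' device: the syringe-pump blood flow (doubled for two parallel arms), the
#' coagulation-buffer co-flow (1:9 buffer:blood), and the downstream quench
#' (e.g. EDTA) flow that keeps shear uniform where the chamber widens.
#'
#' @slot targetShear_sInv target wall shear rate, 1/s.
#' @slot pumpFlow_mLmin programmed pump flow, mL/min (all arms).
#' @slot coagBufferFlow_mLmin coagulation-buffer co-flow, mL/min.
#' @slot quenchFlow_mLmin quench-buffer flow, mL/min (0 if no quench stage).
#' @export
setClass("PerfusionPlan",
  representation(
    targetShear_sInv = "numeric",
    pumpFlow_mLmin = "numeric",
    coagBufferFlow_mLmin = "numeric",
    quenchFlow_mLmin = "numeric"
  )
)

setValidity("PerfusionPlan", function(object) {
  v <- c(object@targetShear_sInv, object@pumpFlow_mLmin,
         object@coagBufferFlow_mLmin, object@quenchFlow_mLmin)
  if (any(!is.finite(v)) || any(v < 0))
    return("all shear and flow values must be finite and non-negative")
  TRUE
})

# ---------------------------------------------------------------------------
# Gravimetric flow traces
# ---------------------------------------------------------------------------

#' Raw balance trace
#'
#' Cumulative mass readings from a balance under the waste-collection
#' vessel, nominally one reading every 5 s. Time zero is the first reading
#' (recording starts when blood first enters the device).
#'
#' @slot time_s strictly increasing sample times, s.
#' @slot mass_g cumulative mass readings, g (tubing weight included until
#'   tared).
#' @seealso [balanceTrace()], [tare()], [estimateFlow()]
#' @export
setClass("BalanceTrace",
  representation(time_s = "numeric", mass_g = "numeric")
)

setValidity("BalanceTrace", function(object) {
  if (length(object@time_s) < 1L) return("trace must contain at least one sample")
  if (length(object@time_s) != length(object@mass_g))
    return("time_s and mass_g must have the same length")
  if (any(!is.finite(object@time_s)) || any(!is.finite(object@mass_g)))
    return("times and masses must be finite")
  if (length(object@time_s) > 1L && any(diff(object@time_s) <= 0))
    return("time_s must be strictly increasing")
  TRUE
})

#' Construct a BalanceTrace
#'
#' @param time_s sample times in seconds (strictly increasing).
#' @param mass_g cumulative masses in grams.
#' @return A [BalanceTrace-class] object.
#' @export
balanceTrace <- function(time_s, mass_g) {
  new("BalanceTrace", time_s = as.numeric(time_s), mass_g = as.numeric(mass_g))
}

#' Estimated volumetric flow series
#'
#' Volumetric flow (mL/min) derived from a balance trace by converting mass
#' to volume (1 g = 1/1.06 mL), smoothing, and differentiating. Flow values
#' may be negative: balance noise is not clipped, and negative estimates
#' indicate absence of forward flow.
#'
#' @slot time_s sample times, s.
#' @slot flow_mLmin estimated flow, mL/min.
#' @slot smoothingWindow_s width of the centered moving-average smoother
#'   that was applied to the volume series (0 or the sampling interval
#'   means no smoothing).
#' @export
setClass("FlowSeries",
  representation(time_s = "numeric", flow_mLmin = "numeric",
                 smoothingWindow_s = "numeric")
)

setValidity("FlowSeries", function(object) {
  if (length(object@time_s) != length(object@flow_mLmin))
    return("time_s and flow_mLmin must have the same length")
  if (length(object@time_s) > 1L && any(diff(object@time_s) <= 0))
    return("time_s must be strictly increasing")
  if (length(object@smoothingWindow_s) != 1L || object@smoothingWindow_s < 0)
    return("smoothingWindow_s must be a single non-negative number")
  TRUE
})

#' Construct a FlowSeries
#' @param time_s sample times, s.
#' @param flow_mLmin flow estimates, mL/min.
#' @param smoothingWindow_s smoothing window used, s (0 for none).
#' @return A [FlowSeries-class] object.
#' @export
flowSeries <- function(time_s, flow_mLmin, smoothingWindow_s = 0) {
  new("FlowSeries", time_s = as.numeric(time_s),
      flow_mLmin = as.numeric(flow_mLmin),
      smoothingWindow_s = smoothingWindow_s)
}

#' Occlusion detector output
#'
#' Result of applying the occlusion definition (flow below a threshold,
#' sustained for a minimum dwell) to a flow series. Channels that never meet
#' the criterion are censored at a fixed value (default 40 min).
#'
#' @slot occluded did any below-threshold run span at least the dwell?
#' @slot occlusionTime_min start time (min) of the earliest qualifying run;
#'   NA when not occluded.
#' @slot threshold_mLmin flow threshold used, mL/min.
#' @slot dwell_s minimum dwell used, s.
#' @slot censorValue_min value assigned to non-occluding channels, min.
#' @slot traceDuration_min duration of the analysed flow series, min.
#' @seealso [detectOcclusion()], [censoredTime()]
#' @export
setClass("OcclusionCall",
  representation(
    occluded = "logical",
    occlusionTime_min = "numeric",
    threshold_mLmin = "numeric",
    dwell_s = "numeric",
    censorValue_min = "numeric",
    traceDuration_min = "numeric"
  )
)

setValidity("OcclusionCall", function(object) {
  if (object@occluded != !is.na(object@occlusionTime_min))
    return("occluded flag must agree with presence of occlusionTime_min")
  if (object@occluded && object@occlusionTime_min > object@traceDuration_min)
    return("occlusionTime_min cannot exceed the trace duration")
  if (object@censorValue_min < object@traceDuration_min)
    return("censorValue_min must be at least the trace duration")
  if (object@threshold_mLmin <= 0 || object@dwell_s <= 0)
    return("threshold and dwell must be positive")
  TRUE
})

# ---------------------------------------------------------------------------
# Confocal stack series
# ---------------------------------------------------------------------------

#' Two-channel confocal z-stack time series
#'
#' An ordered collection of 3-D fluorescence stacks. Each frame is one
#' (timepoint, channel) acquisition stored as a numeric array
#' [slices x rows x cols] of non-negative intensities. The reference
#' acquisition is 19 slices at 5 um spacing (covering a 70 um deep channel),
#' one stack per channel every 2 min.
#'
#' @slot frames list of frames; each frame is a list with elements
#'   `time_min`, `channel`, and `data` (3-D array).
#' @slot sliceSpacing_um z spacing between slices, um.
#' @slot frameInterval_min nominal interval between stacks, min.
#' @slot pixelSize_um lateral pixel size, um.
#' @slot metadata free-form list (the simulator stores analytic ground
#'   truth here).
#' @seealso [stackSeries()], [accumulationCurves()]
#' @export
setClass("StackSeries",
  representation(
    frames = "list",
    sliceSpacing_um = "numeric",
    frameInterval_min = "numeric",
    pixelSize_um = "numeric",
    metadata = "list"
  ),
  prototype(sliceSpacing_um = 5, frameInterval_min = 2, pixelSize_um = 20,
            metadata = list())
)

setValidity("StackSeries", function(object) {
  if (length(object@frames) == 0L) return(TRUE)
  dims <- NULL
  for (fr in object@frames) {
    if (!is.list(fr) || !all(c("time_min", "channel", "data") %in% names(fr)))
      return("each frame needs elements time_min, channel, data")
    d <- fr$data
    if (!is.array(d) || length(dim(d)) != 3L)
      return("frame data must be a 3-D array [slices x rows x cols]")
    if (dim(d)[1] < 1L) return("stacks need at least one slice")
    if (is.null(dims)) dims <- dim(d)
    else if (!identical(dims, dim(d))) return("all frames must share one shape")
    if (any(d < 0)) return("intensities must be non-negative")
  }
  for (ch in unique(vapply(object@frames, `[[`, "", "channel"))) {
    tp <- vapply(Filter(function(f) f$channel == ch, object@frames),
                 `[[`, 0, "time_min")
    if (any(diff(tp) <= 0))
      return(sprintf("timepoints for channel '%s' must be strictly increasing", ch))
  }
  TRUE
})

#' Construct a StackSeries
#' @param frames list of frames (each: `time_min`, `channel`, `data`).
#' @param sliceSpacing_um z spacing, um.
#' @param frameInterval_min interval between stacks, min.
#' @param pixelSize_um lateral pixel size, um.
#' @param metadata optional list of extra information.
#' @return A [StackSeries-class] object.
#' @export
stackSeries <- function(frames, sliceSpacing_um = 5, frameInterval_min = 2,
                        pixelSize_um = 20, metadata = list()) {
  new("StackSeries", frames = frames, sliceSpacing_um = sliceSpacing_um,
      frameInterval_min = frameInterval_min, pixelSize_um = pixelSize_um,
      metadata = metadata)
}

#' Integrated-density accumulation curve
#'
#' Per-channel time course of the integrated density (summed pixel value) of
#' the maximum-intensity projection of each stack; the assay's measure of
#' platelet or fibrin accumulation.
#'
#' @slot timepoints_min stack timepoints, min.
#' @slot integratedDensity summed projected intensity per timepoint
#'   (arbitrary fluorescence units, non-negative).
#' @slot channel fluorescence channel label (e.g. "platelet", "fibrin").
#' @export
setClass("AccumulationCurve",
  representation(timepoints_min = "numeric", integratedDensity = "numeric",
                 channel = "character")
)

setValidity("AccumulationCurve", function(object) {
  if (length(object@timepoints_min) != length(object@integratedDensity))
    return("timepoints and densities must have the same length")
  if (any(object@integratedDensity < 0))
    return("integrated density must be non-negative")
  TRUE
})

# ---------------------------------------------------------------------------
# Statistics result container
# ---------------------------------------------------------------------------

#' Group-comparison test result
#'
#' Holds the omnibus statistics of a group comparison (one row per effect)
#' and the associated pairwise post hoc comparisons.
#'
#' @slot method descriptive name of the test performed.
#' @slot statistics data.frame with columns `effect`, `statistic`, `df1`,
#'   `df2` (NA where not applicable) and `p_value`.
#' @slot pairwise data.frame of post hoc comparisons with columns
#'   `comparison`, `estimate` (or `z`), `p_raw`, `p_adj`, `adjust`.
#' @export
setClass("TestResult",
  representation(method = "character", statistics = "data.frame",
                 pairwise = "data.frame")
)

setValidity("TestResult", function(object) {
  p <- object@statistics$p_value
  if (!is.null(p) && any(!is.na(p) & (p < 0 | p > 1)))
    return("p-values must lie in [0, 1]")
  if (nrow(object@pairwise) &&
      all(c("p_raw", "p_adj") %in% names(object@pairwise))) {
    bad <- !is.na(object@pairwise$p_raw) & !is.na(object@pairwise$p_adj) &
      object@pairwise$p_adj < object@pairwise$p_raw - 1e-12
    if (any(bad)) return("adjusted p-values cannot be below raw p-values")
  }
  TRUE
})

# ---------------------------------------------------------------------------
# Simulation configuration and output
# ---------------------------------------------------------------------------

#' Simulation scenario configuration
#'
#' All parameters of one synthetic experiment. Scenarios: \code{"single_channel"}
#' (one arm, constant inlet flow, emboli dislodge the growing clot),
#' \code{"pressure_relief_unquenched"} (bifurcated device; off-site downstream
#' coagulation active) and \code{"pressure_relief_quenched"} (bifurcated device
#' with downstream EDTA quench; off-site coagulation suppressed).
#'
#' Rates are per minute; the growth model is logistic in the patch occlusion
#' fraction f and (unquenched) in the off-site fraction g, with the drug
#' effect acting as a fractional inhibition of the platelet-driven patch
#' growth rate. See the package vignette for the full model and the
#' rationale behind each default.
#'
#' @slot scenario one of the three scenario names above.
#' @slot drugEffect fractional inhibition of patch growth in [0, 1].
#' @slot growthRatePerMin logistic rate of patch thrombus growth, 1/min.
#' @slot offsiteRatePerMin logistic rate of off-site coagulation, 1/min.
#' @slot feedForwardGain gain of the flow-drop feed-forward acceleration of
#'   off-site growth (dimensionless).
#' @slot f0,g0 initial occlusion fractions (seeds of the logistic growth).
#' @slot fibrinLagPerMin first-order lag rate of the fibrin signal, 1/min.
#' @slot patchLengthFraction fraction of the arm length covered by the patch.
#' @slot resistanceCapFactor cap on the relative resistance rise of an
#'   occluding segment (keeps the network finite as f -> 1).
#' @slot embolismThreshold_kPa excess patch pressure drop that dislodges the
#'   clot in the single-channel scenario, kPa.
#' @slot embolismJitterSd,growthJitterSd lognormal sd of the per-run jitter
#'   applied to the embolism threshold and to the growth rates (the latter
#'   plays the role of donor-to-donor variability).
#' @slot balanceNoiseSigma_g sd of iid Gaussian noise on each balance
#'   reading, g.
#' @slot tubingMass_g initial (tare) weight on the balance, g.
#' @slot viscosity_Pas blood viscosity used by the resistance model, Pa s.
#' @slot tubingResistanceFactor downstream tubing resistance as a multiple
#'   of the baseline arm resistance.
#' @slot compliance_mL_per_kPa lumped syringe/tubing compliance (single-
#'   channel scenario only), mL/kPa.
#' @slot sampleInterval_s balance sampling interval, s.
#' @slot stackInterval_min interval between image stacks, min.
#' @slot duration_min experiment duration, min.
#' @slot dt_s integration step of the fixed-step explicit update, s.
#' @slot targetShear_sInv design wall shear rate, 1/s.
#' @slot geometry per-arm [ChannelGeometry-class] (arm count set by scenario).
#' @slot imageRows,imageCols stack frame size in pixels.
#' @slot imageNoiseSd sd of Gaussian read noise per voxel, intensity counts.
#' @slot intensityScale voxel intensity corresponding to unit channel signal.
#' @slot seed RNG seed making the run reproducible.
#' @seealso [simConfig()], [simulateRun()]
#' @export
setClass("SimConfig",
  representation(
    scenario = "character",
    drugEffect = "numeric",
    growthRatePerMin = "numeric",
    offsiteRatePerMin = "numeric",
    feedForwardGain = "numeric",
    f0 = "numeric",
    g0 = "numeric",
    fibrinLagPerMin = "numeric",
    patchLengthFraction = "numeric",
    resistanceCapFactor = "numeric",
    embolismThreshold_kPa = "numeric",
    embolismJitterSd = "numeric",
    growthJitterSd = "numeric",
    balanceNoiseSigma_g = "numeric",
    tubingMass_g = "numeric",
    viscosity_Pas = "numeric",
    tubingResistanceFactor = "numeric",
    compliance_mL_per_kPa = "numeric",
    sampleInterval_s = "numeric",
    stackInterval_min = "numeric",
    duration_min = "numeric",
    dt_s = "numeric",
    targetShear_sInv = "numeric",
    geometry = "ChannelGeometry",
    imageRows = "integer",
    imageCols = "integer",
    imageNoiseSd = "numeric",
    intensityScale = "numeric",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (!object@scenario %in% c("single_channel", "pressure_relief_unquenched",
                              "pressure_relief_quenched"))
    msg <- c(msg, "unknown scenario")
  if (object@drugEffect < 0 || object@drugEffect > 1)
    msg <- c(msg, "drugEffect must lie in [0, 1]")
  nonneg <- c("growthRatePerMin", "offsiteRatePerMin", "feedForwardGain",
              "balanceNoiseSigma_g", "imageNoiseSd", "embolismJitterSd",
              "growthJitterSd")
  for (s in nonneg) if (slot(object, s) < 0)
    msg <- c(msg, sprintf("'%s' must be non-negative", s))
  pos <- c("duration_min", "dt_s", "sampleInterval_s", "stackInterval_min",
           "resistanceCapFactor", "viscosity_Pas", "intensityScale")
  for (s in pos) if (slot(object, s) <= 0)
    msg <- c(msg, sprintf("'%s' must be positive", s))
  if (object@f0 <= 0 || object@f0 >= 1 || object@g0 <= 0 || object@g0 >= 1)
    msg <- c(msg, "f0 and g0 must lie strictly in (0, 1)")
  if (object@patchLengthFraction <= 0 || object@patchLengthFraction > 1)
    msg <- c(msg, "patchLengthFraction must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a SimConfig
#'
#' Defaults are calibrated so the control pressure-relief scenario occludes
#' in roughly 10-20 minutes at the reference geometry and 1000 1/s design
#' shear; see the vignette for every choice. The per-arm geometry is derived
#' from the scenario (1 arm for \code{single_channel}, 2 otherwise) unless a
#' geometry is supplied.
#'
#' @param scenario scenario name (see [SimConfig-class]).
#' @param drugEffect fractional inhibition of patch growth in [0, 1].
#' @param seed integer RNG seed.
#' @param geometry optional per-arm [ChannelGeometry-class].
#' @param ... overrides for any other [SimConfig-class] slot.
#' @return A [SimConfig-class] object.
#' @examples
#' cfg <- simConfig("pressure_relief_quenched", drugEffect = 0, seed = 1)
#' @export
simConfig <- function(scenario = "pressure_relief_quenched", drugEffect = 0,
                      seed = 1L, geometry = NULL, ...) {
  nArms <- if (identical(scenario, "single_channel")) 1L else 2L
  if (is.null(geometry))
    geometry <- channelGeometry(nParallelArms = nArms)
  defaults <- list(
    scenario = scenario, drugEffect = drugEffect,
    growthRatePerMin = 0.5, offsiteRatePerMin = 0.35, feedForwardGain = 2,
    f0 = 0.01, g0 = 0.01, fibrinLagPerMin = 0.3,
    patchLengthFraction = 0.2, resistanceCapFactor = 1e6,
    embolismThreshold_kPa = 5, embolismJitterSd = 0.1, growthJitterSd = 0.1,
    balanceNoiseSigma_g = 0.0002, tubingMass_g = 2.5,
    viscosity_Pas = 0.0035, tubingResistanceFactor = 1,
    compliance_mL_per_kPa = 0.005,
    sampleInterval_s = 5, stackInterval_min = 2, duration_min = 30,
    dt_s = 0.5, targetShear_sInv = 1000, geometry = geometry,
    imageRows = 36L, imageCols = 46L, imageNoiseSd = 20,
    intensityScale = 3000, seed = as.integer(seed)
  )
  args <- utils::modifyList(defaults, list(...))
  args$imageRows <- as.integer(args$imageRows)
  args$imageCols <- as.integer(args$imageCols)
  args$seed <- as.integer(args$seed)
  do.call(new, c(list("SimConfig"), args))
}

#' Simulated experiment with ground truth
#'
#' Output of [simulateRun()]: the noisy balance trace as a real experiment
#' would record it, the noise-free monitored-outlet flow, the (optional)
#' synthetic stack series, the true occlusion time obtained by applying the
#' occlusion detector to the noise-free flow, the cause of occlusion
#' ("patch", "offsite" or "none"), and an event log (embolism times).
#'
#' @slot config the [SimConfig-class] that generated the run.
#' @slot balanceTrace noisy [BalanceTrace-class].
#' @slot trueFlow noise-free [FlowSeries-class] at the balance sampling grid.
#' @slot stackSeries [StackSeries-class] or NULL when images were skipped.
#' @slot trueOcclusionTime_min true occlusion time, min (NA if none).
#' @slot occlusionCause "patch", "offsite" or "none".
#' @slot events data.frame of logged events (columns `time_min`, `event`).
#' @export
setClass("SimRun",
  representation(
    config = "SimConfig",
    balanceTrace = "BalanceTrace",
    trueFlow = "FlowSeries",
    stackSeries = "ANY",
    trueOcclusionTime_min = "numeric",
    occlusionCause = "character",
    events = "data.frame"
  )
)

#' Pipeline run manifest
#'
#' Records everything needed to reproduce a pipeline run byte-identically:
#' the configuration snapshot, the seed, detector parameters, the package
#' version, output paths and their md5 digests.
#'
#' @slot config configuration list (as read from the run configuration file).
#' @slot seed integer seed used for all randomness.
#' @slot detector list of occlusion-detector parameters.
#' @slot packageVersion version string of thromboFlow.
#' @slot outputs character vector of output file paths.
#' @slot digests md5 digests of the outputs, named by path.
#' @export
setClass("RunManifest",
  representation(
    config = "list",
    seed = "integer",
    detector = "list",
    packageVersion = "character",
    outputs = "character",
    digests = "character"
  )
)
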