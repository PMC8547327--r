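# Accessor generics and show methods. Slots are never accessed with @ by
# user code; these accessors are the supported surface.

#' @name accessors
#' @title Accessors for thromboFlow classes
#' @description Small read-only accessors for the package's S4 containers.
#' @param object an object of the documented class.
#' @return The slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("timeS", function(object) standardGeneric("timeS"))
#' @rdname accessors
#' @export
setMethod("timeS", "BalanceTrace", function(object) object@time_s)
#' @rdname accessors
#' @export
setMethod("timeS", "FlowSeries", function(object) object@time_s)

#' @rdname accessors
#' @export
setGeneric("massG", function(object) standardGeneric("massG"))
#' @rdname accessors
#' @export
setMethod("massG", "BalanceTrace", function(object) object@mass_g)

#' @rdname accessors
#' @export
setGeneric("flowRate", function(object) standardGeneric("flowRate"))
#' @rdname accessors
#' @export
setMethod("flowRate", "FlowSeries", function(object) object@flow_mLmin)

#' @rdname accessors
#' @export
setGeneric("smoothingWindow", function(object) standardGeneric("smoothingWindow"))
#' @rdname accessors
#' @export
setMethod("smoothingWindow", "FlowSeries", function(object) object@smoothingWindow_s)

#' @rdname accessors
#' @export
setGeneric("occluded", function(object) standardGeneric("occluded"))
#' @rdname accessors
#' @export
setMethod("occluded", "OcclusionCall", function(object) object@occluded)

#' @rdname accessors
#' @export
setGeneric("occlusionTime", function(object) standardGeneric("occlusionTime"))
#' @rdname accessors
#' @export
setMethod("occlusionTime", "OcclusionCall", function(object) object@occlusionTime_min)
#' @rdname accessors
#' @export
setMethod("occlusionTime", "SimRun", function(object) object@trueOcclusionTime_min)

#' @rdname accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))
#' @rdname accessors
#' @export
setMethod("frames", "StackSeries", function(object) object@frames)

#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setMethod("channelNames", "StackSeries", function(object)
  unique(vapply(object@frames, `[[`, "", "channel")))

#' @rdname accessors
#' @export
setGeneric("timepoints", function(object) standardGeneric("timepoints"))
#' @rdname accessors
#' @export
setMethod("timepoints", "AccumulationCurve", function(object) object@timepoints_min)

#' @rdname accessors
#' @export
setGeneric("integratedDensities", function(object) standardGeneric("integratedDensities"))
#' @rdname accessors
#' @export
setMethod("integratedDensities", "AccumulationCurve", function(object)
  object@integratedDensity)

#' @rdname accessors
#' @export
setGeneric("channelName", function(object) standardGeneric("channelName"))
#' @rdname accessors
#' @export
setMethod("channelName", "AccumulationCurve", function(object) object@channel)

#' @rdname accessors
#' @export
setGeneric("statistics", function(object) standardGeneric("statistics"))
#' @rdname accessors
#' @export
setMethod("statistics", "TestResult", function(object) object@statistics)

#' @rdname accessors
#' @export
setGeneric("pairwise", function(object) standardGeneric("pairwise"))
#' @rdname accessors
#' @export
setMethod("pairwise", "TestResult", function(object) object@pairwise)

#' @rdname accessors
#' @export
setGeneric("simulationConfig", function(object) standardGeneric("simulationConfig"))
#' @rdname accessors
#' @export
setMethod("simulationConfig", "SimRun", function(object) object@config)

#' @rdname accessors
#' @export
setGeneric("balanceData", function(object) standardGeneric("balanceData"))
#' @rdname accessors
#' @export
setMethod("balanceData", "SimRun", function(object) object@balanceTrace)

#' @rdname accessors
#' @export
setGeneric("trueFlow", function(object) standardGeneric("trueFlow"))
#' @rdname accessors
#' @export
setMethod("trueFlow", "SimRun", function(object) object@trueFlow)

#' @rdname accessors
#' @export
setGeneric("stackData", function(object) standardGeneric("stackData"))
#' @rdname accessors
#' @export
setMethod("stackData", "SimRun", function(object) object@stackSeries)

#' @rdname accessors
#' @export
setGeneric("occlusionCause", function(object) standardGeneric("occlusionCause"))
#' @rdname accessors
#' @export
setMethod("occlusionCause", "SimRun", function(object) object@occlusionCause)

#' @rdname accessors
#' @export
setGeneric("eventLog", function(object) standardGeneric("eventLog"))
#' @rdname accessors
#' @export
setMethod("eventLog", "SimRun", function(object) object@events)

# --- show methods ----------------------------------------------------------

setMethod("show", "ChannelGeometry", function(object) {
  cat(sprintf(
    "ChannelGeometry: %.0f um x %.0f um (H x W), length %.1f mm, %d arm(s)\n",
    object@height_mm * 1000, object@width_mm * 1000, object@length_mm,
    object@nParallelArms))
})

setMethod("show", "PerfusionPlan", function(object) {
  cat("PerfusionPlan\n")
  cat(sprintf("  target wall shear : %g 1/s\n", object@targetShear_sInv))
  cat(sprintf("  pump flow         : %g mL/min\n", object@pumpFlow_mLmin))
  cat(sprintf("  coag buffer flow  : %g mL/min (1:9 buffer:blood)\n",
              object@coagBufferFlow_mLmin))
  cat(sprintf("  quench flow       : %g mL/min\n", object@quenchFlow_mLmin))
})

setMethod("show", "BalanceTrace", function(object) {
  n <- length(object@time_s)
  cat(sprintf("BalanceTrace: %d samples over %.1f min, mass %.4f-%.4f g\n",
              n, max(object@time_s) / 60, min(object@mass_g),
              max(object@mass_g)))
})

setMethod("show", "FlowSeries", function(object) {
  cat(sprintf(
    "FlowSeries: %d samples over %.1f min (smoothing window %g s)\n",
    length(object@time_s), max(object@time_s) / 60,
    object@smoothingWindow_s))
})

setMethod("show", "OcclusionCall", function(object) {
  if (object@occluded)
    cat(sprintf("OcclusionCall: occluded at %.2f min", object@occlusionTime_min))
  else
    cat(sprintf("OcclusionCall: not occluded (censored at %g min)",
                object@censorValue_min))
  cat(sprintf(" [threshold %g mL/min, dwell %g s]\n",
              object@threshold_mLmin, object@dwell_s))
})

setMethod("show", "StackSeries", function(object) {
  d <- if (length(object@frames)) dim(object@frames[[1]]$data) else c(0, 0, 0)
  cat(sprintf(
    "StackSeries: %d frames (%s), %d slices x %d x %d, dz %g um, every %g min\n",
    length(object@frames), paste(channelNames(object), collapse = "/"),
    d[1], d[2], d[3], object@sliceSpacing_um, object@frameInterval_min))
})

setMethod("show", "AccumulationCurve", function(object) {
  cat(sprintf("AccumulationCurve [%s]: %d timepoints, final density %.4g\n",
              object@channel, length(object@timepoints_min),
              utils::tail(object@integratedDensity, 1)))
})

setMethod("show", "TestResult", function(object) {
  cat(object@method, "\n")
  print(object@statistics, row.names = FALSE)
  if (nrow(object@pairwise)) {
    cat("Pairwise comparisons:\n")
    print(object@pairwise, row.names = FALSE)
  }
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %s, drug effect %.2f, seed %d, %g min\n",
              object@scenario, object@drugEffect, object@seed,
              object@duration_min))
})

setMethod("show", "SimRun", function(object) {
  show(object@config)
  if (is.na(object@trueOcclusionTime_min))
    cat("  true outcome: no occlusion\n")
  else
    cat(sprintf("  true outcome: occluded at %.2f min (cause: %s)\n",
                object@trueOcclusionTime_min, object@occlusionCause))
  if (nrow(object@events))
    cat(sprintf("  events: %d (%s)\n", nrow(object@events),
                paste(unique(object@events$event), collapse = ", ")))
})

setMethod("show", "RunManifest", function(object) {
  cat(sprintf("RunManifest: seed %d, thromboFlow %s, %d outputs\n",
              object@seed, object@packageVersion, length(object@outputs)))
})
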