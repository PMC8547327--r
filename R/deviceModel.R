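# Shear/flow design arithmetic for rectangular (wide-slot) channels.
# Everything is in mm and mL/min; the formula gamma = 100 Q / (H^2 W) is the
# parallel-plate wall shear after unit conversion (100 = 6 * 1000/60).

.checkGeometry <- function(geom) {
  if (!is(geom, "ChannelGeometry"))
    stop("'geom' must be a ChannelGeometry object")
  validObject(geom)
  invisible(geom)
}

#' Wall shear rate in a rectangular channel
#'
#' Computes the wall shear rate produced by a volumetric flow through one
#' arm of a rectangular channel, using the wide-slot design formula
#' \deqn{\dot\gamma = 100\,Q / (H^2 W)}
#' with \eqn{Q} in mL/min and \eqn{H}, \eqn{W} in mm. No aspect-ratio
#' correction is applied (the design assumption is \eqn{H \le W}).
#'
#' @param geom a [ChannelGeometry-class].
#' @param q_mLmin volumetric flow through one arm, mL/min (non-negative).
#' @return Wall shear rate, 1/s.
#' @examples
#' # the reference device: 70 um x 500 um at 0.0245 mL/min gives 1000 1/s
#' wallShearRate(channelGeometry(), 0.0245)
#' @export
wallShearRate <- function(geom, q_mLmin) {
  .checkGeometry(geom)
  if (any(q_mLmin < 0)) stop("flow must be non-negative")
  .SHEAR_CONSTANT * q_mLmin / (geom@height_mm^2 * geom@width_mm)
}

#' Pump flow needed for a target wall shear
#'
#' Inverts [wallShearRate()] and multiplies by the number of parallel arms:
#' with two identical arms the pump must supply twice the per-arm flow.
#'
#' @param geom a [ChannelGeometry-class] (its `nParallelArms` scales the
#'   result).
#' @param targetShear_sInv target wall shear rate, 1/s (non-negative).
#' @return Programmed pump flow, mL/min.
#' @examples
#' pumpFlowForShear(channelGeometry(), 1000)                     # 0.0245
#' pumpFlowForShear(channelGeometry(nParallelArms = 2), 1000)    # 0.049
#' @export
pumpFlowForShear <- function(geom, targetShear_sInv) {
  .checkGeometry(geom)
  if (any(targetShear_sInv < 0)) stop("target shear must be non-negative")
  geom@nParallelArms * targetShear_sInv * geom@height_mm^2 * geom@width_mm /
    .SHEAR_CONSTANT
}

#' Quench flow matching shear across a widening junction
#'
#' Where the chamber width increases at the quench-buffer inlet (it doubles
#' in the reference design), an added quench flow keeps the wall shear rate
#' identical upstream and downstream. This returns that added flow:
#' \eqn{q_\mathrm{add} = \dot\gamma H^2 W_\mathrm{down}/100 - q_\mathrm{blood}},
#' where \eqn{\dot\gamma} is the shear produced by the per-arm blood flow
#' upstream.
#'
#' @param geomUp upstream [ChannelGeometry-class] (before the junction).
#' @param geomDown downstream [ChannelGeometry-class]; same height, width at
#'   least the upstream width.
#' @param qBloodArm_mLmin blood flow through the arm, mL/min.
#' @return Quench-buffer flow, mL/min. With the width exactly doubled this
#'   equals the blood flow itself.
#' @examples
#' up <- channelGeometry(width_mm = 0.5)
#' down <- channelGeometry(width_mm = 1.0)
#' quenchFlowForUniformShear(up, down, 0.0245)   # 0.0245
#' @export
quenchFlowForUniformShear <- function(geomUp, geomDown, qBloodArm_mLmin) {
  .checkGeometry(geomUp)
  .checkGeometry(geomDown)
  if (qBloodArm_mLmin < 0) stop("blood flow must be non-negative")
  if (abs(geomUp@height_mm - geomDown@height_mm) > 1e-12)
    stop("upstream and downstream heights must match")
  if (geomDown@width_mm < geomUp@width_mm)
    stop("downstream width must be at least the upstream width")
  shear <- wallShearRate(geomUp, qBloodArm_mLmin)
  qAdd <- shear * geomDown@height_mm^2 * geomDown@width_mm / .SHEAR_CONSTANT -
    qBloodArm_mLmin
  if (qAdd < -1e-12)
    stop("inconsistent geometries: matching flow would be negative")
  max(qAdd, 0)
}

#' Coagulation-buffer co-flow
#'
#' The recalcification buffer joins the bloodstream at a fixed 1:9
#' buffer:blood ratio just before chamber entry.
#'
#' @param qBloodTotal_mLmin total blood flow, mL/min (non-negative).
#' @return Buffer flow, mL/min (one ninth of the blood flow).
#' @examples
#' coagBufferFlow(0.049)
#' @export
coagBufferFlow <- function(qBloodTotal_mLmin) {
  if (any(qBloodTotal_mLmin < 0)) stop("blood flow must be non-negative")
  qBloodTotal_mLmin / 9
}

#' Design a full perfusion plan
#'
#' Convenience wrapper assembling a [PerfusionPlan-class]: pump flow for the
#' target shear, 1:9 coagulation-buffer co-flow, and (when a downstream
#' geometry is given) the quench flow that keeps shear uniform past the
#' widening junction.
#'
#' @param geom per-device [ChannelGeometry-class] (arm count included).
#' @param targetShear_sInv target wall shear rate, 1/s.
#' @param geomDown optional downstream geometry at the quench junction.
#' @return A [PerfusionPlan-class].
#' @examples
#' designPerfusion(channelGeometry(nParallelArms = 2), 1000,
#'                 geomDown = channelGeometry(width_mm = 1.0))
#' @export
designPerfusion <- function(geom, targetShear_sInv = 1000, geomDown = NULL) {
  pump <- pumpFlowForShear(geom, targetShear_sInv)
  perArm <- pump / geom@nParallelArms
  quench <- if (is.null(geomDown)) 0 else {
    up <- channelGeometry(geom@height_mm, geom@width_mm, geom@length_mm, 1L)
    quenchFlowForUniformShear(up, geomDown, perArm)
  }
  new("PerfusionPlan", targetShear_sInv = targetShear_sInv,
      pumpFlow_mLmin = pump, coagBufferFlow_mLmin = coagBufferFlow(pump),
      quenchFlow_mLmin = quench)
}
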