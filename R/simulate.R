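# Lumped-parameter hydraulic simulator. The device is a two-node network:
# a constant-flow inlet (syringe pump) feeding one or two parallel paths,
# each path an arm (with the thrombogenic patch in arm 1) in series with its
# waste tubing. Thrombus growth raises the patch segment's resistance by a
# cubic slot law; occlusion fractions follow logistic growth. All of this is
# artifact plumbing: the real assay publishes no hydraulic equations, so the
# model is the minimal one consistent with the described mechanics, with
# every rate exposed in SimConfig.

# Poiseuille resistance of a rectangular slot, kPa*min/mL, mm/Pa.s units.
# R = 12 mu L / (w h^3 (1 - 0.63 h/w)) with the unit conversion folded into
# the leading 0.2 factor.
.slotResistance <- function(geom, viscosity_Pas) {
  h <- geom@height_mm; w <- geom@width_mm
  0.2 * viscosity_Pas * geom@length_mm / (w * h^3 * (1 - 0.63 * h / w))
}

#' Hydraulic resistance of a patch-bearing arm
#'
#' Baseline resistance follows the rectangular-slot Poiseuille law
#' \eqn{R \propto L / (W H^3 (1 - 0.63 H/W))}. A thrombus occluding a
#' fraction `f` of the patch segment's height multiplies that segment's
#' resistance by \eqn{(1-f)^{-3}} (the cubic gap law), capped at
#' `capFactor` times baseline so the network stays finite as f approaches 1.
#' The aspect-ratio correction stays at its baseline value; only the cubic
#' gap term scales.
#'
#' @param geom a [ChannelGeometry-class] describing one arm.
#' @param f patch occlusion fraction in `[0, 1)`.
#' @param patchLengthFraction fraction of the arm length occupied by the
#'   patch segment (default 0.2; 1 means the whole arm).
#' @param capFactor cap on the relative resistance rise of the patch
#'   segment (default 1e6).
#' @param viscosity_Pas blood viscosity, Pa s (default 0.0035).
#' @return Arm resistance in kPa min/mL; strictly increasing in `f`.
#' @examples
#' g <- channelGeometry()
#' armResistance(g, 0.5, patchLengthFraction = 1) / armResistance(g, 0)  # 8
#' @export
armResistance <- function(geom, f, patchLengthFraction = 0.2,
                          capFactor = 1e6, viscosity_Pas = 0.0035) {
  if (any(f < 0 | f >= 1)) stop("domain error: f must lie in [0, 1)")
  if (patchLengthFraction <= 0 || patchLengthFraction > 1)
    stop("patchLengthFraction must lie in (0, 1]")
  R0 <- .slotResistance(geom, viscosity_Pas)
  lam <- patchLengthFraction
  rise <- pmin((1 - f)^-3, capFactor)
  R0 * ((1 - lam) + lam * rise)
}

#' Conductance-weighted flow split across parallel paths
#'
#' A constant inlet flow divides across parallel resistive paths sharing
#' inlet and outlet pressure nodes in proportion to their conductances:
#' \eqn{Q_i = Q_{in} (1/R_i) / \sum_j (1/R_j)}. The split conserves flow
#' exactly by construction.
#'
#' @param qIn_mLmin inlet flow, mL/min.
#' @param resistances positive per-path resistances (same units each).
#' @return Per-path flows, mL/min, summing to `qIn_mLmin`.
#' @examples
#' flowSplit(0.049, c(1, 1))   # equal split
#' flowSplit(0.049, c(3, 1))   # 1/4 vs 3/4
#' @export
flowSplit <- function(qIn_mLmin, resistances) {
  if (length(resistances) < 1L || any(resistances <= 0))
    stop("resistances must be positive")
  g <- 1 / resistances
  qIn_mLmin * g / sum(g)
}

# one explicit growth update; pars carries jittered rates
.growthStep <- function(f, g, fib, qLocal, qRef, pars, dt_min) {
  if (qLocal > 0)
    f <- f + pars$rPatch * f * (1 - f) * dt_min
  if (pars$offsiteActive) {
    accel <- 1 + pars$kappa * max(0, 1 - qLocal / qRef)
    g <- g + pars$rOff * accel * g * (1 - g) * dt_min
  }
  target <- min(1, f + if (pars$offsiteActive) g else 0)
  fib <- fib + pars$kFib * (target - fib) * dt_min
  c(f = min(f, 1 - 1e-12), g = min(g, 1 - 1e-12), fib = max(fib, 0))
}

#' One growth step of the thrombus model
#'
#' Advances the growth state by one explicit time step. Patch growth is
#' logistic, \eqn{df = r (1 - \mathrm{drug}) f (1-f)\,dt}, applied only
#' while local flow is positive. Off-site (downstream) growth is logistic
#' with a feed-forward acceleration as local flow falls,
#' \eqn{dg = r_{off} (1 + \kappa (1 - Q/Q_0)) g (1-g)\,dt}; it is active
#' only in the unquenched pressure-relief scenario (the EDTA quench
#' suppresses it; the single-channel regime is dominated by embolism).
#' The platelet signal tracks `f`; the fibrin signal relaxes towards
#' min(1, f + g) with a first-order lag.
#'
#' @param state list with elements `f`, `g`, `platelet`, `fibrin`.
#' @param localFlow_mLmin current flow through the patch arm, mL/min.
#' @param config a [SimConfig-class] (rates are taken as-is, without the
#'   per-run jitter that [simulateRun()] applies).
#' @param dt_min time step, min.
#' @return Updated state list.
#' @export
stepGrowth <- function(state, localFlow_mLmin, config, dt_min) {
  qRef <- pumpFlowForShear(config@geometry, config@targetShear_sInv) /
    config@geometry@nParallelArms
  pars <- list(
    rPatch = config@growthRatePerMin * (1 - config@drugEffect),
    rOff = config@offsiteRatePerMin,
    kappa = config@feedForwardGain,
    kFib = config@fibrinLagPerMin,
    offsiteActive = identical(config@scenario, "pressure_relief_unquenched"))
  s <- .growthStep(state$f, state$g, state$fibrin, localFlow_mLmin, qRef,
                   pars, dt_min)
  list(f = unname(s["f"]), g = unname(s["g"]), platelet = unname(s["f"]),
       fibrin = unname(s["fib"]))
}

#' Embolism check for the single-channel scenario
#'
#' In a single channel the growing clot faces the full pressure drop; once
#' the excess drop across the patch, \eqn{Q\,(R(f) - R(0))}, exceeds the
#' threshold, the clot detaches: `f` resets to its seed value and the event
#' is logged. The operation is inert in pressure-relief scenarios.
#'
#' @param state growth state list (see [stepGrowth()]).
#' @param pressureDrop_kPa current excess pressure drop across the patch, kPa.
#' @param config a [SimConfig-class].
#' @param threshold_kPa embolism threshold (default: the config value;
#'   [simulateRun()] applies a seeded per-run jitter to it).
#' @return list with the (possibly reset) `state` and logical `embolized`.
#' @export
embolismCheck <- function(state, pressureDrop_kPa, config,
                          threshold_kPa = config@embolismThreshold_kPa) {
  if (!identical(config@scenario, "single_channel"))
    return(list(state = state, embolized = FALSE))
  if (is.finite(threshold_kPa) && pressureDrop_kPa > threshold_kPa) {
    state$f <- config@f0
    state$platelet <- config@f0
    list(state = state, embolized = TRUE)
  } else list(state = state, embolized = FALSE)
}

#' Simulate one complete synthetic experiment
#'
#' Integrates thrombus growth and the hydraulic network on a fine fixed
#' grid (explicit update, default dt = 0.5 s), producing everything a real
#' run would: a noisy balance trace sampled every 5 s (cumulative monitored-
#' outlet volume times the blood density 1.06 g/mL, plus the tubing tare
#' weight and iid Gaussian reading noise), the noise-free monitored flow,
#' two-channel synthetic image stacks every 2 min, the true occlusion time
#' (the occlusion detector applied to the noise-free flow), the occlusion
#' cause, and an event log.
#'
#' The monitored outlet is the one downstream from the patch. In the
#' unquenched pressure-relief scenario its tubing resistance grows with the
#' off-site coagulation fraction, so the monitored arm can occlude
#' independently of patch thrombosis. Identical configurations (same seed)
#' give bit-identical runs.
#'
#' @param config a [SimConfig-class].
#' @param images generate the synthetic stack series? Disable for large
#'   flow-only simulation campaigns.
#' @return A [SimRun-class].
#' @examples
#' run <- simulateRun(simConfig("pressure_relief_quenched", seed = 7),
#'                    images = FALSE)
#' occlusionTime(run)
#' @export
simulateRun <- function(config, images = TRUE) {
  if (!is(config, "SimConfig")) stop("configuration error: need a SimConfig")
  validObject(config)
  geom <- config@geometry
  scen <- config@scenario
  set.seed(config@seed)
  jit <- exp(stats::rnorm(1, 0, config@growthJitterSd))
  thr <- config@embolismThreshold_kPa *
    exp(stats::rnorm(1, 0, config@embolismJitterSd))
  nSamp <- floor(config@duration_min * 60 / config@sampleInterval_s) + 1L
  balanceNoise <- stats::rnorm(nSamp, 0, config@balanceNoiseSigma_g)

  dt_min <- config@dt_s / 60
  nStep <- ceiling(config@duration_min / dt_min)
  qIn <- pumpFlowForShear(geom, config@targetShear_sInv)
  nArms <- geom@nParallelArms
  armGeom <- channelGeometry(geom@height_mm, geom@width_mm, geom@length_mm, 1L)
  R0 <- .slotResistance(armGeom, config@viscosity_Pas)
  Rt <- config@tubingResistanceFactor * R0
  lam <- config@patchLengthFraction
  cap <- config@resistanceCapFactor
  qRef <- qIn / nArms

  pars <- list(
    rPatch = config@growthRatePerMin * jit * (1 - config@drugEffect),
    rOff = config@offsiteRatePerMin * jit,
    kappa = config@feedForwardGain,
    kFib = config@fibrinLagPerMin,
    offsiteActive = identical(scen, "pressure_relief_unquenched"))

  f <- config@f0; g <- config@g0; fib <- 0
  P <- qIn * (R0 + Rt)  # single-channel: start at steady pressure
  qMon <- numeric(nStep + 1L)
  fTrace <- numeric(nStep + 1L)
  gTrace <- numeric(nStep + 1L)
  fibTrace <- numeric(nStep + 1L)
  events <- list()

  for (k in 0:nStep) {
    rise <- min((1 - f)^-3, cap)
    R1 <- R0 * ((1 - lam) + lam * rise)
    if (scen == "single_channel") {
      Rtot <- R1 + Rt
      q1 <- P / Rtot
      excess <- q1 * (R1 - R0)
      if (is.finite(thr) && excess > thr) {
        f <- config@f0
        events[[length(events) + 1L]] <-
          data.frame(time_min = k * dt_min, event = "embolism")
        rise <- min((1 - f)^-3, cap)
        R1 <- R0 * ((1 - lam) + lam * rise)
        Rtot <- R1 + Rt
        q1 <- P / Rtot
      }
      P <- P + dt_min * (qIn - q1) / config@compliance_mL_per_kPa
    } else {
      gRise <- if (pars$offsiteActive) min((1 - g)^-3, cap) else 1
      path1 <- R1 + Rt * gRise
      path2 <- R0 + Rt
      q1 <- flowSplit(qIn, c(path1, path2))[1]
    }
    qMon[k + 1L] <- q1
    fTrace[k + 1L] <- f
    gTrace[k + 1L] <- g
    fibTrace[k + 1L] <- fib
    s <- .growthStep(f, g, fib, q1, qRef, pars, dt_min)
    f <- unname(s["f"]); g <- unname(s["g"]); fib <- unname(s["fib"])
  }

  tFine <- (0:nStep) * dt_min                     # min
  volFine <- c(0, cumsum((qMon[-1] + qMon[-(nStep + 1L)]) / 2 * dt_min))
  stride <- as.integer(round(config@sampleInterval_s / config@dt_s))
  idx <- seq(1L, nStep + 1L, by = stride)[seq_len(nSamp)]
  tSamp_s <- tFine[idx] * 60
  mass <- config@tubingMass_g + BLOOD_DENSITY_G_PER_ML * volFine[idx] +
    balanceNoise
  trace <- balanceTrace(tSamp_s, mass)
  true <- flowSeries(tSamp_s, qMon[idx], smoothingWindow_s = 0)
  call <- detectOcclusion(true)

  cause <- "none"
  if (occluded(call)) {
    kOcc <- idx[which.min(abs(tSamp_s - call@occlusionTime_min * 60))]
    patchRise <- lam * (min((1 - fTrace[kOcc])^-3, cap) - 1)
    offRise <- if (pars$offsiteActive)
      (Rt / R0) * (min((1 - gTrace[kOcc])^-3, cap) - 1) else 0
    cause <- if (patchRise >= offRise) "patch" else "offsite"
  }

  stacks <- NULL
  truth <- NULL
  if (images) {
    tStack <- seq(config@stackInterval_min, config@duration_min,
                  by = config@stackInterval_min)
    sIdx <- vapply(tStack, function(tt) which.min(abs(tFine - tt)), 0L)
    stacks <- generateStackSeries(tStack, fTrace[sIdx], fibTrace[sIdx],
                                  config, seed = NULL)
  }

  ev <- if (length(events)) do.call(rbind, events)
  else data.frame(time_min = numeric(), event = character())
  new("SimRun", config = config, balanceTrace = trace, trueFlow = true,
      stackSeries = stacks,
      trueOcclusionTime_min = call@occlusionTime_min,
      occlusionCause = cause, events = ev)
}

#' Generate a synthetic two-channel stack series
#'
#' Builds one 19-slice stack per timepoint and channel. The thrombus is an
#' ellipsoidal cap sitting on the channel floor whose volume scales with
#' the channel's signal (footprint semi-axes scale as the cube root of the
#' signal); voxels inside it carry a constant intensity,
#' `round(intensityScale * signal)`. The analytic integrated density of the
#' maximum-intensity projection is therefore that voxel intensity times the
#' number of footprint pixels. That ground truth is recorded in the
#' series metadata (`metadata(series)$groundTruth`). Gaussian read noise is
#' added per voxel, rounded and clipped to the 16-bit range.
#'
#' @param timepoints_min stack acquisition times, min.
#' @param plateletSignal platelet (patch occlusion fraction) signal in
#'   `[0, 1]`, one value per timepoint.
#' @param fibrinSignal fibrin signal in `[0, 1]`, one value per timepoint.
#' @param config a [SimConfig-class] (image geometry, intensity scale,
#'   read-noise sd).
#' @param seed optional seed; `NULL` continues the current RNG stream
#'   (as [simulateRun()] does).
#' @return A [StackSeries-class] with frames for channels "platelet" and
#'   "fibrin" and a `groundTruth` data.frame in its metadata.
#' @export
generateStackSeries <- function(timepoints_min, plateletSignal, fibrinSignal,
                                config, seed = NULL) {
  if (length(plateletSignal) != length(timepoints_min) ||
      length(fibrinSignal) != length(timepoints_min))
    stop("signals and timepoints must have equal length")
  if (any(plateletSignal < 0) || any(fibrinSignal < 0))
    stop("signals must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  nSlices <- 19L
  dz <- 5
  rows <- config@imageRows; cols <- config@imageCols
  noiseSd <- config@imageNoiseSd
  height_um <- (nSlices - 1) * dz
  cx <- (cols + 1) / 2; cy <- (rows + 1) / 2
  aMax <- 0.45 * cols; bMax <- 0.45 * rows
  xs <- matrix(rep(seq_len(cols), each = rows), rows, cols)
  ys <- matrix(rep(seq_len(rows), times = cols), rows, cols)
  signals <- list(platelet = plateletSignal, fibrin = fibrinSignal)
  frames <- list()
  truth <- list()
  for (i in seq_along(timepoints_min)) {
    for (ch in names(signals)) {
      sig <- signals[[ch]][i]
      I <- round(config@intensityScale * sig)
      sc <- sig^(1 / 3)
      stk <- array(0, c(nSlices, rows, cols))
      nFoot <- 0L
      if (I > 0 && sc > 0) {
        r2xy <- ((xs - cx) / (aMax * sc))^2 + ((ys - cy) / (bMax * sc))^2
        for (z in seq_len(nSlices)) {
          zr <- ((z - 1) * dz / (height_um * sc))^2
          mask <- r2xy <= 1 - zr
          if (any(mask)) stk[z, , ][mask] <- I
        }
        nFoot <- sum(r2xy <= 1)
      }
      if (noiseSd > 0) {
        stk <- stk + array(stats::rnorm(length(stk), 0, noiseSd), dim(stk))
        stk <- pmin(pmax(round(stk), 0), 65535)
      }
      frames[[length(frames) + 1L]] <-
        list(time_min = timepoints_min[i], channel = ch, data = stk)
      truth[[length(truth) + 1L]] <- data.frame(
        time_min = timepoints_min[i], channel = ch,
        integrated_density_truth = I * nFoot)
    }
  }
  stackSeries(frames, sliceSpacing_um = dz,
              frameInterval_min = if (length(timepoints_min) > 1)
                diff(timepoints_min)[1] else config@stackInterval_min,
              pixelSize_um = 20,
              metadata = list(groundTruth = do.call(rbind, truth)))
}
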