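# Hydraulic network, growth model, and simulated experiments

test_that("arm resistance follows the capped cubic gap law", {
  g <- channelGeometry()
  R0 <- armResistance(g, 0)
  # full-length patch at half occlusion: exactly the cube law, 8x baseline
  expect_equal(armResistance(g, 0.5, patchLengthFraction = 1), 8 * R0)
  # partial-length patch: only the patch segment scales
  lam <- 0.2
  expect_equal(armResistance(g, 0.5, patchLengthFraction = lam),
               R0 * ((1 - lam) + lam * 8))
  # strictly increasing over an f grid
  grid <- seq(0, 0.99, by = 0.01)
  expect_true(all(diff(armResistance(g, grid)) > 0))
  # cap keeps the value finite close to full occlusion
  expect_lt(armResistance(g, 1 - 1e-12, patchLengthFraction = 1),
            R0 * 1e6 * 1.001)
  expect_error(armResistance(g, 1), "domain")
  expect_error(armResistance(g, -0.1), "domain")
})

test_that("flow split is conductance-weighted and conserves inlet flow", {
  expect_equal(flowSplit(0.049, c(2, 2)), c(0.0245, 0.0245))
  # R1 = 3 R2: arm 1 takes a quarter of the flow
  expect_equal(flowSplit(0.08, c(3, 1)), c(0.02, 0.06))
  expect_equal(flowSplit(0.0245, 5), 0.0245)  # single arm takes it all
  set.seed(51)
  for (i in 1:100) {
    qin <- runif(1, 0.001, 1)
    r <- runif(sample(1:4, 1), 1e-3, 1e6)
    q <- flowSplit(qin, r)
    expect_lt(abs(sum(q) - qin), 1e-12 * max(1, qin))
    expect_true(all(q >= 0))
  }
  expect_error(flowSplit(0.049, c(1, 0)), "positive")
})

test_that("patch growth follows the logistic closed form as dt shrinks", {
  cfg <- simConfig("pressure_relief_quenched", drugEffect = 0, seed = 1,
                   growthRatePerMin = 0.5)
  tEnd <- 20
  integrate <- function(dt_min) {
    st <- list(f = cfg@f0, g = cfg@g0, platelet = cfg@f0, fibrin = 0)
    for (i in seq_len(round(tEnd / dt_min)))
      st <- stepGrowth(st, 0.0245, cfg, dt_min)
    st$f
  }
  truth <- logisticClosedForm(tEnd, 0.5, cfg@f0)
  dts <- 0.5 / 60 / c(1, 2, 4)
  errs <- abs(vapply(dts, integrate, 0) - truth)
  # first-order convergence: halving dt halves the error
  expect_true(all(diff(errs) < 0))
  expect_equal(errs[1] / errs[2], 2, tolerance = 0.2)
  # Richardson extrapolation of the step-halving pair hits the closed form
  fs <- vapply(dts, integrate, 0)
  expect_equal(2 * fs[3] - fs[2], truth, tolerance = 1e-6)
})

test_that("full drug effect freezes patch growth; quench silences off-site growth", {
  cfg <- simConfig("pressure_relief_quenched", drugEffect = 1, seed = 1)
  st <- list(f = cfg@f0, g = cfg@g0, platelet = cfg@f0, fibrin = 0)
  for (i in 1:200) st <- stepGrowth(st, 0.0245, cfg, 1 / 120)
  expect_equal(st$f, cfg@f0)      # rate is exactly zero
  run <- simulateRun(cfg, images = FALSE)
  expect_false(occluded(detectOcclusion(trueFlow(run))))
  # quenched scenarios never grow the off-site fraction
  runC <- simulateRun(simConfig("pressure_relief_quenched", seed = 2),
                      images = FALSE)
  cfgU <- simConfig("pressure_relief_unquenched", seed = 2)
  stU <- list(f = cfgU@f0, g = cfgU@g0, platelet = cfgU@f0, fibrin = 0)
  stQ <- stU
  cfgQ <- simConfig("pressure_relief_quenched", seed = 2)
  for (i in 1:100) {
    stU <- stepGrowth(stU, 0.01, cfgU, 1 / 120)
    stQ <- stepGrowth(stQ, 0.01, cfgQ, 1 / 120)
  }
  expect_gt(stU$g, cfgU@g0)
  expect_equal(stQ$g, cfgQ@g0)
})

test_that("embolism resets the clot only in the single-channel scenario", {
  cfgS <- simConfig("single_channel", seed = 3)
  st <- list(f = 0.5, g = 0.01, platelet = 0.5, fibrin = 0.2)
  # below threshold: nothing happens
  r1 <- embolismCheck(st, 1, cfgS, threshold_kPa = 5)
  expect_false(r1$embolized)
  # above threshold: f resets to the seed value
  r2 <- embolismCheck(st, 10, cfgS, threshold_kPa = 5)
  expect_true(r2$embolized)
  expect_equal(r2$state$f, cfgS@f0)
  # infinite threshold: never
  expect_false(embolismCheck(st, 1e9, cfgS, threshold_kPa = Inf)$embolized)
  # inert for pressure-relief configurations
  cfgP <- simConfig("pressure_relief_quenched", seed = 3)
  expect_false(embolismCheck(st, 1e9, cfgP)$embolized)
})

test_that("single-channel runs embolize and flow never ceases", {
  nEmb <- 0
  for (s in 1:5) {
    run <- simulateRun(simConfig("single_channel", seed = s), images = FALSE)
    expect_false(occluded(detectOcclusion(trueFlow(run))))
    nEmb <- nEmb + sum(eventLog(run)$event == "embolism")
  }
  expect_gt(nEmb, 0)  # emboli occur within 30 min at the default threshold
})

test_that("simulation is bit-identical for identical configurations", {
  cfg <- quickConfig(seed = 52)
  a <- simulateRun(cfg)
  b <- simulateRun(cfg)
  expect_identical(massG(balanceData(a)), massG(balanceData(b)))
  expect_identical(flowRate(trueFlow(a)), flowRate(trueFlow(b)))
  expect_identical(occlusionTime(a), occlusionTime(b))
  fa <- frames(stackData(a)); fb <- frames(stackData(b))
  for (i in seq_along(fa)) expect_identical(fa[[i]]$data, fb[[i]]$data)
  # a different seed gives a different balance trace
  c2 <- simulateRun(quickConfig(seed = 53), images = FALSE)
  expect_false(identical(massG(balanceData(a)), massG(balanceData(c2))))
})

test_that("noise-free balance mass equals density times integrated outflow", {
  for (s in 1:5) {
    cfg <- simConfig("pressure_relief_quenched", seed = s,
                     balanceNoiseSigma_g = 0)
    run <- simulateRun(cfg, images = FALSE)
    tared <- massG(tare(balanceData(run)))
    t_min <- timeS(trueFlow(run)) / 60
    vol <- pracma::cumtrapz(t_min, flowRate(trueFlow(run)))[, 1]
    expect_equal(tared, 1.06 * vol, tolerance = 1e-3)
  }
})

test_that("scenario regimes reproduce the device behaviours", {
  # quenched control: patch-driven occlusion within the 10-20 min regime
  ctl <- simulateRun(simConfig("pressure_relief_quenched", seed = 54),
                     images = FALSE)
  expect_equal(occlusionCause(ctl), "patch")
  expect_gt(occlusionTime(ctl), 5)
  expect_lt(occlusionTime(ctl), 25)
  # quenched + full drug: no occlusion at all
  qd <- simulateRun(simConfig("pressure_relief_quenched", drugEffect = 1,
                              seed = 54), images = FALSE)
  expect_true(is.na(occlusionTime(qd)))
  expect_equal(occlusionCause(qd), "none")
  # unquenched + full drug: occlusion happens anyway, driven off-site
  ud <- simulateRun(simConfig("pressure_relief_unquenched", drugEffect = 1,
                              seed = 54), images = FALSE)
  expect_false(is.na(occlusionTime(ud)))
  expect_equal(occlusionCause(ud), "offsite")
})

test_that("synthetic stacks have the acquisition geometry and exact truth", {
  cfg <- quickConfig(seed = 55, imageNoiseSd = 0)
  ss <- generateStackSeries(c(2, 4), plateletSignal = c(0.3, 0.6),
                            fibrinSignal = c(0.1, 0.2), cfg, seed = 56)
  expect_equal(length(frames(ss)), 4)
  d <- dim(frames(ss)[[1]]$data)
  expect_equal(d, c(19, 12, 16))
  expect_equal(ss@sliceSpacing_um, 5)
  gt <- ss@metadata$groundTruth
  cv <- accumulationCurves(ss)
  for (ch in c("platelet", "fibrin"))
    expect_equal(integratedDensities(cv[[ch]]),
                 gt$integrated_density_truth[gt$channel == ch])
  # zero signal, zero noise: all-zero stacks and zero ground truth
  z <- generateStackSeries(2, 0, 0, cfg, seed = 57)
  expect_true(all(vapply(frames(z), function(f) all(f$data == 0), TRUE)))
  expect_true(all(z@metadata$groundTruth$integrated_density_truth == 0))
})

test_that("censored occlusion time is non-decreasing in drug effect", {
  for (s in 1:4) {
    tms <- vapply(c(0, 0.3, 0.6, 1.0), function(dd) {
      r <- simulateRun(simConfig("pressure_relief_quenched", drugEffect = dd,
                                 seed = s), images = FALSE)
      fl <- estimateFlow(tare(balanceData(r)), 30)
      censoredTime(detectOcclusion(fl))
    }, 0)
    expect_false(is.unsorted(tms))
  }
})
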