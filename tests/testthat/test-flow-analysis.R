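# Balance trace -> flow -> occlusion call

test_that("taring subtracts the first reading and is idempotent", {
  tr <- balanceTrace(c(0, 5, 10), c(2.00, 2.05, 2.11))
  expect_equal(massG(tare(tr)), c(0, 0.05, 0.11))
  expect_equal(massG(tare(balanceTrace(c(0, 5), c(3.3, 3.3)))), c(0, 0))
  set.seed(21)
  tr2 <- balanceTrace(seq(0, 100, by = 5), cumsum(runif(21)))
  expect_equal(massG(tare(tr2)), massG(tr2) - massG(tr2)[1])
  expect_identical(tare(tare(tr2)), tare(tr2))
})

test_that("mass converts to volume at 1.06 g/mL", {
  expect_equal(massToVolume(1.06), 1)
  expect_equal(massToVolume(0), 0)
  expect_equal(massToVolume(5.3), 5)
  expect_equal(massToVolume(-0.0106), -0.01)  # tared noise may be negative
})

test_that("flow estimation recovers a constant rate and the raw-difference oracle", {
  t <- seq(0, 300, by = 5)
  # 0.00106 g per 5 s  ->  0.001 mL per 5 s  ->  0.012 mL/min
  tr <- balanceTrace(t, 0.00106 * seq_along(t))
  for (w in c(5, 30, 65)) {
    fl <- estimateFlow(tr, smoothingWindow_s = w)
    inner <- flowRate(fl)[8:(length(t) - 7)]
    expect_equal(inner, rep(0.012, length(inner)), tolerance = 1e-12)
  }
  # constant mass -> zero flow everywhere
  fl0 <- estimateFlow(balanceTrace(t, rep(2, length(t))), 30)
  expect_equal(flowRate(fl0), rep(0, length(t)))
  # window of one sample: equals the brute-force central difference
  set.seed(22)
  tr2 <- tare(balanceTrace(t, cumsum(abs(rnorm(length(t), 0.002, 0.001)))))
  fl2 <- estimateFlow(tr2, smoothingWindow_s = 5)
  expect_equal(flowRate(fl2),
               oracleCentralDifference(t, massToVolume(massG(tr2))),
               tolerance = 1e-12)
  expect_error(estimateFlow(tr2, smoothingWindow_s = 1e5), "window")
})

test_that("occlusion detection follows the threshold-dwell definition", {
  t <- seq(0, 1800, by = 5)
  # flow stops at 600 s: occluded, time 10 min (start of the run)
  call <- detectOcclusion(flowSeries(t, ifelse(t < 600, 0.02, 0)))
  expect_true(occluded(call))
  expect_equal(occlusionTime(call), 10)
  # never below threshold
  expect_false(occluded(detectOcclusion(flowSeries(t, rep(0.02, length(t))))))
  # a 160-s dip does not satisfy the 180-s dwell
  dip <- ifelse(t >= 600 & t <= 760, 0, 0.02)
  expect_false(occluded(detectOcclusion(flowSeries(t, dip))))
  # the comparison is strict: flow exactly at the threshold never qualifies
  expect_false(occluded(detectOcclusion(flowSeries(t, rep(0.001, length(t))))))
  # negative estimates count as below threshold
  neg <- ifelse(t < 900, 0.02, -0.002)
  expect_equal(occlusionTime(detectOcclusion(flowSeries(t, neg))), 15)
  # a run truncated by the trace end qualifies only once it spans the dwell
  shortEnd <- flowSeries(seq(0, 700, by = 5),
                         ifelse(seq(0, 700, by = 5) < 600, 0.02, 0))
  expect_false(occluded(detectOcclusion(shortEnd)))
  expect_error(detectOcclusion(flowSeries(t, rep(0, length(t))),
                               threshold_mLmin = 0), "configuration")
  expect_error(detectOcclusion(flowSeries(t, rep(0, length(t))),
                               dwell_s = -1), "configuration")
})

test_that("detection matches the brute-force run-length oracle on random series", {
  set.seed(23)
  t <- seq(0, 1500, by = 5)
  for (i in 1:100) {
    f <- rnorm(length(t), 0.0012, 0.0015)  # hovers around the threshold
    call <- detectOcclusion(flowSeries(t, f))
    expect_equal(censoredTime(call, censor_min = 40),
                 ifelse(is.na(oracleOcclusionScan(t, f)), 40,
                        oracleOcclusionScan(t, f)))
  }
})

test_that("censoring substitutes 40 min for channels that never occlude", {
  t <- seq(0, 1800, by = 5)
  occ <- detectOcclusion(flowSeries(t, ifelse(t < 720, 0.02, 0)))
  non <- detectOcclusion(flowSeries(t, rep(0.02, length(t))))
  expect_equal(censoredTime(occ), 12)
  expect_equal(censoredTime(non), 40)
  expect_equal(censoredTime(non, censor_min = 45), 45)
})

test_that("the unsmoothed flow integral reproduces the tared volume", {
  set.seed(24)
  t <- seq(0, 1800, by = 5)
  for (i in 1:5) {
    tr <- tare(balanceTrace(t, cumsum(abs(rnorm(length(t), 0.002, 5e-4)))))
    fl <- estimateFlow(tr, smoothingWindow_s = 5)
    vol <- pracma::trapz(t / 60, flowRate(fl))
    total <- massToVolume(massG(tr)[length(t)])
    expect_equal(vol, total, tolerance = 0.01)
  }
})

test_that("balance logs round-trip through delimited text", {
  tr <- balanceTrace(seq(0, 50, by = 5), seq(2.5, 2.6, by = 0.01))
  p <- withr::local_tempfile(fileext = ".tsv")
  writeBalanceLog(tr, p)
  tr2 <- readBalanceLog(p)
  expect_equal(timeS(tr2), timeS(tr))
  expect_equal(massG(tr2), massG(tr))
  expect_error(readBalanceLog(file.path(tempdir(), "no-such-log.tsv")),
               "not found")
})

test_that("occlusion summaries are written as readable structured text", {
  t <- seq(0, 1800, by = 5)
  call <- detectOcclusion(flowSeries(t, ifelse(t < 600, 0.02, 0)))
  p <- withr::local_tempfile(fileext = ".yaml")
  writeOcclusionSummary(call, p)
  y <- yaml::read_yaml(p)
  expect_true(y$occluded)
  expect_equal(y$occlusion_time_min, 10)
  expect_equal(y$parameters$threshold_mL_min, 0.001)
})
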