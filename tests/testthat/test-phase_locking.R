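test_that("a pure 20 Hz tone yields one peak per cycle at 50 ms spacing", {
  pk <- detectBetaPeaks(tone(20, 1))
  expect_equal(length(pk), 20)
  expect_true(all(abs(diff(pk) - 0.05) <= 0.001))
  expect_length(detectBetaPeaks(continuousSignal(numeric(1000), fs = FS)), 0)
})

test_that("peaks concentrate inside ground-truth bursts", {
  cfg <- syntheticConfig(durationS = 120, nStims = 11, seed = 51)
  e <- genEcog(cfg)
  pk <- detectBetaPeaks(bandpassFilter(e$signal))
  lg <- e$burstLog
  pad <- 0.05
  inBurst <- vapply(pk, function(p)
    any(p >= lg$start - pad & p <= lg$end + pad), logical(1))
  expect_gt(mean(inBurst), 0.95)
})

test_that("spike phases follow the peak-interpolation definition", {
  peaks <- c(1.00, 1.05, 1.10)
  ph <- spikePhases(spikeTrain(c(1.00, 1.025, 1.075)), peaks)
  expect_equal(ph$phase, c(0, 180, 180))
  # spikes outside [first, last) peak are discarded
  ph2 <- spikePhases(spikeTrain(c(0.5, 1.02, 1.2)), peaks)
  expect_equal(nrow(ph2), 1)
  # cycles outside the beta period band are discarded
  ph3 <- spikePhases(spikeTrain(1.5), c(1, 2, 2.05))
  expect_equal(nrow(ph3), 0)
  expect_error(spikePhases(spikeTrain(1), 1), "two beta peaks")
})

test_that("phase histogram uses 36 ten-degree bins that sum to n", {
  set.seed(52)
  ph <- runif(500, 0, 360)
  h <- phaseHistogram(ph)
  expect_equal(nrow(h), 36)
  expect_equal(sum(h$count), 500)
  expect_equal(sum(h$fraction), 1)
})

test_that("circular mean and vector length match closed forms", {
  expect_equal(circMeanR(c(0, 0)), list(meanAngle = 0, R = 1))
  cm <- circMeanR(c(0, 180))
  expect_equal(cm$R, 0)
  expect_true(is.nan(cm$meanAngle))
  cm2 <- circMeanR(c(10, 50))
  expect_equal(cm2$meanAngle, 30, tolerance = 1e-12)
  expect_equal(cm2$R, cos(20 * pi / 180), tolerance = 1e-12)
  expect_error(circMeanR(numeric(0)), "empty")
})

test_that("resultant agrees with the brute-force vector-sum oracle", {
  set.seed(53)
  for (i in 1:20) {
    ph <- runif(sample(2:200, 1), 0, 360)
    got <- circMeanR(ph)
    want <- resultantOracle(ph)
    expect_lt(abs(got$R - want$R), 1e-12)
    if (got$R > 1e-6)
      expect_lt(min(abs(got$meanAngle - want$angle),
                    360 - abs(got$meanAngle - want$angle)), 1e-9)
  }
})

test_that("Rayleigh statistics behave at the uniform and degenerate limits", {
  exact <- rayleighTest(seq(5, 355, by = 10))  # 36 bin centres
  expect_lt(exact@R, 1e-10)
  expect_gt(exact@p, 0.999)
  ident <- rayleighTest(rep(77, 10))
  expect_equal(ident@Z, 10)
  # frozen from the small-sample correction formula:
  # exp(sqrt(1 + 40 + 0) - 21) = exp(sqrt(41) - 21)
  expect_equal(ident@p, exp(sqrt(41) - 21), tolerance = 1e-12)
  expect_lt(ident@p, 1e-3)
})

test_that("circular statistics are rotationally equivariant", {
  set.seed(54)
  ph <- rvonmises(300, 120, 2)
  base <- rayleighTest(ph)
  for (delta in c(33, 90, 251)) {
    rot <- rayleighTest((ph + delta) %% 360)
    expect_equal(rot@R, base@R, tolerance = 1e-12)
    expect_equal(rot@Z, base@Z, tolerance = 1e-9)
    expect_equal(rot@p, base@p, tolerance = 1e-9)
    expect_equal(rot@meanAngle %% 360, (base@meanAngle + delta) %% 360,
                 tolerance = 1e-6)
  }
})

test_that("Rayleigh type-I error is near nominal for uniform phases", {
  set.seed(55)
  rej <- mean(replicate(400, rayleighTest(runif(100, 0, 360))@p < 0.05))
  expect_lt(abs(rej - 0.05), 1.96 * sqrt(0.05 * 0.95 / 400) + 1e-9)
})

test_that("von Mises parameter recovery matches its sampling theory", {
  set.seed(56)
  # asymptotic SD of the mean direction is 1/sqrt(n kappa A1(kappa));
  # at n = 500 that is 3.8 deg for kappa = 1 (so +/-5 deg is a ~1.3 SD
  # band, ~81% coverage) and < 2.2 deg for kappa >= 2 (> 97% coverage)
  for (kappa in c(2, 5)) {
    hits <- replicate(20, {
      cm <- circMeanR(rvonmises(500, 90, kappa))
      expRl <- besselI(kappa, 1) / besselI(kappa, 0)
      abs(cm$meanAngle - 90) <= 5 && abs(cm$R - expRl) <= 0.05
    })
    expect_gte(mean(hits), 0.95)
  }
  sdDeg <- 180 / pi / sqrt(500 * 1 * besselI(1, 1) / besselI(1, 0))
  want <- 2 * pnorm(5 / sdDeg) - 1
  hits1 <- mean(replicate(200,
    abs(circMeanR(rvonmises(500, 90, 1))$meanAngle - 90) <= 5))
  expect_lt(abs(hits1 - want), 3 * sqrt(want * (1 - want) / 200))
})

test_that("Watson-Williams separates distinct mean directions only", {
  set.seed(57)
  g <- rvonmises(100, 90, 3)
  self <- watsonWilliams(list(g, g))
  expect_lt(self$F, 1e-6)
  expect_gt(self$p, 0.999)
  # power: 0 vs 90 degrees at kappa = 3, n = 100: essentially always rejected
  pvals <- replicate(10,
    watsonWilliams(list(rvonmises(100, 0, 3), rvonmises(100, 90, 3)))$p)
  expect_true(all(pvals < 0.01))
  # null: same distribution, rejection rate near alpha
  nullRej <- mean(replicate(60,
    watsonWilliams(list(rvonmises(100, 90, 3), rvonmises(100, 90, 3)))$p
    < 0.05))
  expect_lt(nullRej, 0.18)
  expect_error(watsonWilliams(list(numeric(0), g)), "empty")
  expect_error(watsonWilliams(list(g)), "two groups")
})

test_that("phase lags convert to the reported conduction delays", {
  expect_equal(round(phaseToDelay(57, 20), 1), 7.9)
  expect_equal(round(phaseToDelay(42, 20), 1), 5.8)
  expect_equal(round(phaseToDelay(45, 20)), 6)
  expect_equal(phaseToDelay(360, 20), 50)
  expect_error(phaseToDelay(90, -1), "positive")
})

test_that("generator preferred phase is recovered through peak detection", {
  # strong continuous beta so peaks are detected throughout
  cfg <- syntheticConfig(durationS = 120, nStims = 11, burstRatePerS = 2,
                         kappa = 2, muDeg = 90, baseRateHz = 20, seed = 58)
  ses <- genSession(cfg)
  betaSig <- bandpassFilter(ses@signals[[1]])
  pk <- detectBetaPeaks(betaSig)
  ph <- spikePhases(ses@spikeTrains[[1]], pk)
  expect_gt(nrow(ph), 500)
  cm <- circMeanR(ph$phase)
  expect_lt(min(abs(cm$meanAngle - 90), 360 - abs(cm$meanAngle - 90)), 15)
})
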