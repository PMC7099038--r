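test_that("PSTH counts match the per-event loop oracle exactly", {
  set.seed(61)
  spikes <- spikeTrain(sort(runif(400, 0, 100)))
  ev <- stimEvents(seq(10, 90, by = 10), 2)
  ps <- buildPsth(spikes, ev)
  expect_equal(length(ps@counts), 120)
  want <- psthOracle(spikeTimes(spikes), ev@onset, ps@edges)
  expect_identical(ps@counts, want)
  # count conservation: total equals spikes falling in any event window
  inWin <- sum(vapply(spikeTimes(spikes), function(s)
    any(s - ev@onset >= -2 & s - ev@onset < 4), logical(1)))
  expect_equal(sum(ps@counts), inWin)
  expect_error(buildPsth(spikes, new("StimEvents")), "no events")
})

test_that("rate conversion divides counts by events times bin width", {
  spikes <- spikeTrain(sort(runif(200, 0, 50)))
  ev <- stimEvents(c(10, 20, 30), 2)
  ps <- suppressMessages(buildPsth(spikes, ev))
  expect_equal(ps@rate, ps@counts / (3 * 0.05))
})

test_that("response classification follows the 2 SD / 3 consecutive bin rule", {
  mk <- function(post) {
    counts <- c(rep(10, 40), post, rep(10, 80 - length(post)))
    new("PSTHResult", edges = seq(-2, 4, by = 0.05), counts = counts,
        rate = counts / 0.5, baselineMean = 10, baselineSd = 1,
        nEvents = 10L, label = "unclassified")
  }
  expect_equal(classifyResponse(mk(rep(0, 8)))@label, "inhibited")
  expect_equal(classifyResponse(mk(rep(20, 8)))@label, "excited")
  # exactly two consecutive deviating bins fail the rule
  expect_equal(classifyResponse(mk(c(20, 20, 10, 10, 10, 10, 10, 10)))@label,
               "not_modulated")
  # three consecutive just beyond threshold succeed
  expect_equal(classifyResponse(mk(c(13, 13, 13, rep(10, 5))))@label,
               "excited")
  # both patterns present: earliest onset wins
  expect_equal(classifyResponse(
    mk(c(20, 20, 20, 0, 0, 0, 10, 10)))@label, "excited")
  expect_equal(classifyResponse(
    mk(c(0, 0, 0, 20, 20, 20, 10, 10)))@label, "inhibited")
  # flat PSTH with zero baseline SD is not modulated
  flat <- new("PSTHResult", edges = seq(-2, 4, by = 0.05),
              counts = rep(5, 120), rate = rep(100, 120), baselineMean = 5,
              baselineSd = 0, nEvents = 10L, label = "unclassified")
  expect_equal(classifyResponse(flat)@label, "not_modulated")
})

test_that("silencing during the pulse empties the ON bins", {
  set.seed(62)
  times <- sort(runif(2000, 0, 100))
  ev <- stimEvents(seq(10, 90, by = 10), 2)
  keep <- !vapply(times, function(s)
    any(s - ev@onset >= 0 & s - ev@onset < 2), logical(1))
  ps <- classifyResponse(buildPsth(spikeTrain(times[keep]), ev))
  onBins <- which(ps@edges[-121] >= 0 & ps@edges[-121] < 2)
  expect_equal(sum(ps@counts[onBins]), 0)
  expect_equal(ps@label, "inhibited")
})

test_that("epoch rates pool counts over total class duration", {
  ep <- buildEpochs(stimEvents(10, 2), c(0, 20))
  spikes <- spikeTrain(c(seq(8.05, 9.95, length.out = 20),
                         seq(10.025, 11.975, length.out = 40)))
  r <- ratesByEpoch(spikes, ep)
  expect_equal(r$fOff, 10)
  expect_equal(r$fOn, 20)
  r0 <- ratesByEpoch(spikeTrain(numeric(0)), ep)
  expect_equal(c(r0$fOff, r0$fOn), c(0, 0))
})

test_that("modulation index matches its definition and is antisymmetric", {
  expect_equal(modulationIndex(10, 10), 0)
  expect_equal(modulationIndex(10, 30), 0.5)
  expect_equal(modulationIndex(5, 0), -1)
  expect_true(is.nan(suppressMessages(modulationIndex(0, 0))))
  set.seed(63)
  for (i in 1:10) {
    a <- runif(1, 0, 50); b <- runif(1, 0, 50)
    expect_equal(modulationIndex(a, b), -modulationIndex(b, a))
    expect_lte(abs(modulationIndex(a, b)), 1)
  }
})

test_that("rate scaling during ON is recovered from a generated session", {
  cfg <- syntheticConfig(durationS = 310, nStims = 30, onRateFactor = 3,
                         seed = 64)
  ses <- genSession(cfg)
  ep <- buildEpochs(ses@events, c(0, 310))
  r <- ratesByEpoch(ses@spikeTrains[[1]], ep)
  expect_lt(abs(r$fOn / r$fOff - 3), 0.3)
})

test_that("random spike removal retains an exact unbiased subsample", {
  set.seed(65)
  st <- spikeTrain(sort(runif(1000, 0, 100)))
  expect_identical(spikeTimes(randomSpikeRemoval(st, 0, seed = 1)),
                   spikeTimes(st))
  half <- randomSpikeRemoval(st, 0.5, seed = 2)
  expect_length(spikeTimes(half), 500)
  expect_false(is.unsorted(spikeTimes(half), strictly = TRUE))
  expect_identical(spikeTimes(randomSpikeRemoval(st, 0.5, seed = 2)),
                   spikeTimes(half))
  expect_true(all(spikeTimes(half) %in% spikeTimes(st)))
  expect_error(randomSpikeRemoval(st, 1), "fraction")
})

test_that("thinning lowers coherence but preserves the preferred phase", {
  set.seed(66)
  t <- seq_len(120 * FS) / FS
  field <- continuousSignal(sin(2 * pi * 20 * t) + rnorm(length(t)), fs = FS)
  ph <- phaseRamp(20, 120)
  st <- genSpikeTrain(syntheticConfig(kappa = 3, baseRateHz = 15, muDeg = 90,
                                      seed = 5), ph)
  band <- function(co) max(co@coherence[co@freq >= 12 & co@freq <= 30])
  full <- band(suppressMessages(spikeFieldCoherence(st, field)))
  drops <- vapply(1:5, function(s) {
    thin <- randomSpikeRemoval(st, 0.5, seed = s)
    band(suppressMessages(spikeFieldCoherence(thin, field))) < full
  }, logical(1))
  expect_gte(mean(drops), 0.8)
  idx <- function(x) floor(spikeTimes(x) * FS) + 1
  muFull <- circMeanR(ph@samples[idx(st)])$meanAngle
  muThin <- circMeanR(ph@samples[idx(randomSpikeRemoval(st, 0.5,
                                                        seed = 3))])$meanAngle
  expect_lt(min(abs(muFull - muThin), 360 - abs(muFull - muThin)), 5)
})
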