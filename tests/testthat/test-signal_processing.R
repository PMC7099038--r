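test_that("preprocessing removes DC and resamples to 500 Hz", {
  dc <- continuousSignal(rep(3.7, 8000), fs = 2000)
  out <- preprocessEcog(dc)
  expect_equal(samplingRate(out), 500)
  expect_lt(max(abs(samples(out))), 1e-6)
  expect_error(preprocessEcog(continuousSignal(rnorm(100), fs = 250)),
               "cannot resample")
})

test_that("preprocessing preserves the passband and rejects above Nyquist", {
  t <- seq_len(20 * 2000) / 2000
  inBand <- continuousSignal(sin(2 * pi * 20 * t), fs = 2000)
  out <- preprocessEcog(inBand)
  core <- samples(out)[500:9500]  # skip filter edges
  expect_lt(abs((max(core) - min(core)) / 2 - 1), 0.02)
  high <- continuousSignal(sin(2 * pi * 400 * t), fs = 2000)
  outH <- samples(preprocessEcog(high))[500:9500]
  expect_lt(sqrt(mean(outH^2)) / sqrt(0.5), 0.01)
})

test_that("band-pass is amplitude-faithful in band and rejects out of band", {
  s20 <- bandpassFilter(tone(20, 10))
  core <- samples(s20)[1000:4000]
  expect_lt(abs((max(core) - min(core)) / 2 - 1), 0.02)
  s5 <- bandpassFilter(tone(5, 10))
  expect_lt(sqrt(mean(samples(s5)[1000:4000]^2)) / sqrt(0.5), 0.1)
  z <- bandpassFilter(continuousSignal(numeric(5000), fs = FS))
  expect_equal(max(abs(samples(z))), 0)
  expect_error(bandpassFilter(tone(20, 2), 30, 12), "invalid band")
})

test_that("filtering is zero-phase", {
  x <- tone(20, 10)
  y <- bandpassFilter(x)
  cc <- ccf(samples(x)[500:4500], samples(y)[500:4500], lag.max = 10,
            plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("envelope recovers constant and slowly varying amplitudes", {
  env <- samples(signalEnvelope(tone(20, 10, amp = 2.5)))[500:4500]
  expect_lt(max(abs(env - 2.5)), 0.03)
  z <- signalEnvelope(continuousSignal(numeric(1000), fs = FS))
  expect_equal(max(abs(samples(z))), 0)
  # AM tone: envelope tracks A(t) within 5%
  t <- seq_len(10 * FS) / FS
  A <- 1 + 0.5 * sin(2 * pi * 0.5 * t)
  am <- continuousSignal(A * sin(2 * pi * 20 * t), fs = FS)
  got <- samples(signalEnvelope(am))[500:4500]
  expect_lt(max(abs(got - A[500:4500]) / A[500:4500]), 0.05)
})

test_that("power spectrum localises tones and respects Parseval", {
  ps <- powerSpectrum(tone(20, 60))
  expect_equal(ps@resolution, 500 / 512)
  expect_lt(abs(ps@freq[which.max(ps@power)] - 20), ps@resolution)
  # two tones, amplitudes 1 and 2: peak power ratio ~ 1:4 (direct-DFT oracle)
  t <- seq_len(60 * FS) / FS
  x <- sin(2 * pi * 15 * t) + 2 * sin(2 * pi * 25 * t)
  ps2 <- powerSpectrum(continuousSignal(x, fs = FS))
  p15 <- max(ps2@power[abs(ps2@freq - 15) < 1])
  p25 <- max(ps2@power[abs(ps2@freq - 25) < 1])
  expect_lt(abs(p25 / p15 - 4), 0.4)
  # Parseval: band-integrated power tracks variance for stationary noise
  set.seed(11)
  wn <- continuousSignal(rnorm(60 * FS), fs = FS)
  psn <- powerSpectrum(wn)
  expect_lt(abs(sum(psn@power) / var(samples(wn)) - 1), 0.05)
  expect_error(powerSpectrum(tone(20, 0.5)), "shorter")
})

test_that("spike-field coherence is bounded, near floor for independent spikes
           and elevated for locked spikes", {
  set.seed(12)
  t <- seq_len(120 * FS) / FS
  field <- continuousSignal(sin(2 * pi * 20 * t) + rnorm(length(t)), fs = FS)
  ph <- phaseRamp(20, 120)
  locked <- genSpikeTrain(syntheticConfig(kappa = 5, baseRateHz = 10,
                                          seed = 3), ph)
  indep <- genSpikeTrain(syntheticConfig(kappa = 0, baseRateHz = 10,
                                         seed = 3), ph)
  cl <- suppressMessages(spikeFieldCoherence(locked, field))
  ci <- suppressMessages(spikeFieldCoherence(indep, field))
  expect_true(all(cl@coherence >= 0 & cl@coherence <= 1))
  band <- cl@freq >= 12 & cl@freq <= 30
  expect_gt(max(cl@coherence[band]), 10 * max(ci@coherence[band]))
  expect_lt(max(ci@coherence[band]), 20 / cl@nSegments)
  expect_error(spikeFieldCoherence(spikeTrain(numeric(0)), field), "empty")
})

test_that("field-field coherence is one at all bins", {
  set.seed(13)
  x <- rnorm(30 * FS)
  w <- BetaOpto:::welchSpectra(x, x, fs = FS, nfft = 512)
  expect_equal(max(abs(w$coherence - 1)), 0, tolerance = 1e-9)
})

test_that("peri-event spectrogram tracks a gated 20 Hz tone", {
  set.seed(14)
  t <- seq_len(100 * FS) / FS
  gate <- ((t %% 10) >= 6) & ((t %% 10) < 8)   # ON during [6, 8) each 10 s
  x <- continuousSignal(0.2 * rnorm(length(t)) +
                        3 * gate * sin(2 * pi * 20 * t), fs = FS)
  ev <- stimEvents(seq(16, 86, by = 10), 2)
  sg <- periEventSpectrogram(x, ev, window = c(-2, 4), fRange = c(15, 25),
                             fStep = 1)
  p20 <- sg@power[, sg@freq == 20]
  onBins <- sg@times >= 0.5 & sg@times < 1.5
  offBins <- sg@times >= -2 & sg@times < -0.5
  expect_gt(mean(p20[onBins]), 10 * mean(p20[offBins]))
  # events outside the recording are dropped with a message
  expect_message(periEventSpectrogram(x, stimEvents(c(1, 50), 2),
                                      window = c(-2, 4)), "dropped")
})
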