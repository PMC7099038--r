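#' SyntheticConfig: parameters of the synthetic recording generator
#'
#' Phenomenological stand-in for an ECoG + unit recording under an
#' optogenetic protocol: 1/f^alpha background carrying transient beta bursts
#' (Gaussian-windowed sinusoids), plus inhomogeneous Poisson spike trains
#' whose rate is von Mises-modulated by the instantaneous beta phase and
#' scaled multiplicatively during laser-ON epochs.
#'
#' @slot durationS recording duration (s).
#' @slot fsHz sampling rate (Hz); must be at least twice the upper analysis
#'   frequency (default 500).
#' @slot betaFreqHz burst carrier frequency (Hz, default 20).
#' @slot burstRatePerS Poisson rate of burst onsets (bursts/s).
#' @slot burstDurMeanS,burstDurSdS burst duration distribution (s).
#' @slot burstAmp burst peak amplitude (microvolts).
#' @slot noiseExponent background spectral slope alpha in 1/f^alpha.
#' @slot noiseAmp background SD (microvolts).
#' @slot baseRateHz baseline firing rate per unit (spikes/s).
#' @slot kappa von Mises concentration of phase locking (>= 0).
#' @slot muDeg preferred firing phase in degrees `[0, 360)` (beta peak = 0).
#' @slot onRateFactor multiplicative rate change during ON epochs (> 0).
#' @slot onBetaFactor multiplicative beta-amplitude change during ON (>= 0).
#' @slot protocol `"pulse_2s_every_10s"` or `"sinusoid_20s"`.
#' @slot nStims number of stimulations.
#' @slot nUnits number of spike trains to generate.
#' @slot seed RNG seed; identical config + seed gives bit-identical output.
#' @export
setClass("SyntheticConfig",
  representation(durationS = "numeric", fsHz = "numeric",
                 betaFreqHz = "numeric", burstRatePerS = "numeric",
                 burstDurMeanS = "numeric", burstDurSdS = "numeric",
                 burstAmp = "numeric", noiseExponent = "numeric",
                 noiseAmp = "numeric", baseRateHz = "numeric",
                 kappa = "numeric", muDeg = "numeric",
                 onRateFactor = "numeric", onBetaFactor = "numeric",
                 protocol = "character", nStims = "numeric",
                 nUnits = "numeric", seed = "numeric"))

setValidity("SyntheticConfig", function(object) {
  msg <- NULL
  if (object@durationS <= 0) msg <- c(msg, "durationS must be positive")
  if (object@fsHz <= 0) msg <- c(msg, "fsHz must be positive")
  if (object@fsHz < 100)
    msg <- c(msg, "fsHz must be >= 100 Hz for a 12-30 Hz analysis band")
  if (object@kappa < 0) msg <- c(msg, "kappa must be >= 0")
  if (object@onRateFactor <= 0) msg <- c(msg, "onRateFactor must be > 0")
  if (object@onBetaFactor < 0) msg <- c(msg, "onBetaFactor must be >= 0")
  if (!object@protocol %in% c("pulse_2s_every_10s", "sinusoid_20s"))
    msg <- c(msg, "unknown protocol")
  if (object@nStims < 1) msg <- c(msg, "nStims must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' Construct a SyntheticConfig
#'
#' Defaults emulate an anaesthetised parkinsonian recording during a
#' prominent-beta epoch: a 300 s session with 30 pulse stimulations (2 s ON
#' every 10 s, hence 60 s total ON and 60 s total OFF), 50 microvolt 1/f
#' background, intermittent 20 Hz bursts (1 burst/s of 300 +/- 100 ms,
#' i.e. roughly a quarter of the time in bursts, 250 microvolt peak = 5x background),
#' and 10 Hz units locked at 90 degrees with concentration kappa = 2.
#'
#' @param durationS,fsHz,betaFreqHz,burstRatePerS,burstDurMeanS,burstDurSdS
#'   see [SyntheticConfig-class].
#' @param burstAmp,noiseExponent,noiseAmp,baseRateHz,kappa,muDeg see
#'   [SyntheticConfig-class].
#' @param onRateFactor,onBetaFactor,protocol,nStims,nUnits,seed see
#'   [SyntheticConfig-class].
#' @return A validated [SyntheticConfig-class].
#' @examples
#' cfg <- syntheticConfig(durationS = 60, nStims = 5, seed = 1)
#' @export
syntheticConfig <- function(durationS = 300, fsHz = 500, betaFreqHz = 20,
                            burstRatePerS = 1.0, burstDurMeanS = 0.3,
                            burstDurSdS = 0.1, burstAmp = 250,
                            noiseExponent = 2, noiseAmp = 50,
                            baseRateHz = 10, kappa = 2, muDeg = 90,
                            onRateFactor = 1, onBetaFactor = 1,
                            protocol = "pulse_2s_every_10s", nStims = 30,
                            nUnits = 1, seed = 1) {
  new("SyntheticConfig", durationS = durationS, fsHz = fsHz,
      betaFreqHz = betaFreqHz, burstRatePerS = burstRatePerS,
      burstDurMeanS = burstDurMeanS, burstDurSdS = burstDurSdS,
      burstAmp = burstAmp, noiseExponent = noiseExponent,
      noiseAmp = noiseAmp, baseRateHz = baseRateHz, kappa = kappa,
      muDeg = muDeg %% 360, onRateFactor = onRateFactor,
      onBetaFactor = onBetaFactor, protocol = protocol, nStims = nStims,
      nUnits = nUnits, seed = seed)
}

# Laser event times implied by a protocol. Pulse: 2 s ON every 10 s with the
# first onset at 6 s (so the Pre window [onset-4, onset-2) starts at 2 s).
# Sinusoid: 20 s ON blocks, each preceded by a 20 s OFF block.
protocolEvents <- function(config) {
  if (config@protocol == "pulse_2s_every_10s") {
    onsets <- 6 + 10 * (0:(config@nStims - 1))
    dur <- 2
    kind <- "pulse"
  } else {
    onsets <- 20 + 40 * (0:(config@nStims - 1))
    dur <- 20
    kind <- "sinusoid"
  }
  if (utils::tail(onsets, 1) + dur > config@durationS)
    stop("protocol does not fit ", config@nStims,
         " stimulation(s) within durationS = ", config@durationS, " s")
  stimEvents(onsets, dur, kind)
}

# Merge overlapping [start, end) burst intervals (log sorted by start).
mergeBurstIntervals <- function(log) {
  if (nrow(log) < 2) return(log)
  log <- log[order(log$start), , drop = FALSE]
  out <- log[1, , drop = FALSE]
  for (i in 2:nrow(log)) {
    j <- nrow(out)
    if (log$start[i] <= out$end[j]) {
      out$end[j] <- max(out$end[j], log$end[i])
      out$amp[j] <- max(out$amp[j], log$amp[i])
    } else out <- rbind(out, log[i, ])
  }
  out$duration <- out$end - out$start
  rownames(out) <- NULL
  out
}

# logical ON mask over the sample grid
onMask <- function(events, n, fs, t0 = 0) {
  m <- logical(n)
  for (i in seq_along(events@onset)) {
    a <- floor((events@onset[i] - t0) * fs) + 1L
    b <- ceiling((events@onset[i] + events@duration[i] - t0) * fs)
    m[max(1L, a):min(n, b)] <- TRUE
  }
  m
}

# 1/f^alpha noise by spectral shaping of white noise, unit variance.
colouredNoise <- function(n, alpha) {
  X <- stats::fft(stats::rnorm(n))
  k <- 0:(n - 1)
  m <- pmax(1, pmin(k, n - k))       # symmetric shaping over +/- frequencies
  X <- X * m^(-alpha / 2)
  X[1] <- 0                          # drop DC

  x <- Re(stats::fft(X, inverse = TRUE) / n)
  x / stats::sd(x)
}

#' Generate a synthetic ECoG trace
#'
#' 1/f^alpha background plus Gaussian-windowed beta bursts whose onsets
#' follow a Poisson process; during laser-ON epochs the beta component is
#' multiplied by `onBetaFactor`. Burst times are returned as ground truth.
#'
#' @param config a [SyntheticConfig-class].
#' @return A list with elements `signal` (a [ContinuousSignal-class]),
#'   `burstLog` (data.frame `start`, `end`, `duration`, `amp`),
#'   `beta` (the emitted noise-free beta component, with any ON scaling
#'   applied, microvolts) and `events`
#'   (the protocol [StimEvents-class]).
#' @details The burst envelope is a Gaussian window with SD = duration / 4,
#'   truncated at +/- 2 SD so the logged duration brackets the waveform
#'   support; each burst carries an independent uniform carrier phase.
#' @export
genEcog <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  fs <- config@fsHz
  n <- round(config@durationS * fs)
  events <- protocolEvents(config)
  withSeed(config@seed, {
    noise <- config@noiseAmp * colouredNoise(n, config@noiseExponent)
    tAx <- (seq_len(n) - 1) / fs
    beta <- numeric(n)
    nB <- stats::rpois(1, config@burstRatePerS * config@durationS)
    log <- data.frame(start = numeric(0), end = numeric(0),
                      duration = numeric(0), amp = numeric(0))
    if (nB > 0) {
      starts <- sort(stats::runif(nB, 0, config@durationS))
      durs <- pmax(0.04, stats::rnorm(nB, config@burstDurMeanS,
                                      config@burstDurSdS))
      phis <- stats::runif(nB, 0, 2 * pi)
      for (i in seq_len(nB)) {
        ctr <- starts[i] + durs[i] / 2
        sdT <- durs[i] / 4
        a <- max(1L, floor((ctr - 2 * sdT) * fs) + 1L)
        b <- min(n, ceiling((ctr + 2 * sdT) * fs))
        if (a > n || b < 1) next
        tt <- tAx[a:b]
        beta[a:b] <- beta[a:b] + config@burstAmp *
          exp(-((tt - ctr)^2) / (2 * sdT^2)) *
          cos(2 * pi * config@betaFreqHz * (tt - ctr) + phis[i])
        log <- rbind(log, data.frame(start = starts[i],
                                     end = starts[i] + durs[i],
                                     duration = durs[i],
                                     amp = config@burstAmp))
      }
      # overlapping bursts superpose into a single envelope excursion in
      # the emitted signal; log them as one so the ground truth stays
      # consistent with what is observable
      log <- mergeBurstIntervals(log)
    }
    scaled <- beta
    if (config@onBetaFactor != 1) {
      m <- onMask(events, n, fs)
      scaled[m] <- scaled[m] * config@onBetaFactor
    }
    list(signal = continuousSignal(noise + scaled, fs = fs, label = "ecog"),
         burstLog = log, beta = scaled, events = events)
  })
}

#' Generate a phase-locked inhomogeneous Poisson spike train
#'
#' Spikes are drawn by thinning a homogeneous Poisson process at the rate
#' ceiling: candidates at `lambda_max` are accepted with probability
#' `lambda(t) / lambda_max`, where
#' `lambda(t) = baseRateHz * exp(kappa * cos(phase(t) - mu)) / I0(kappa)`,
#' scaled by `onRateFactor` inside ON windows. The von Mises factor is
#' normalised, so the expected mean rate equals `baseRateHz` when phases are
#' uniformly distributed over time and `onRateFactor = 1`.
#'
#' @param config a [SyntheticConfig-class].
#' @param betaPhase a [ContinuousSignal-class] whose samples are phases in
#'   degrees `[0, 360)` (e.g. from [signalPhase()]).
#' @param onWindows optional two-column matrix of `[start, end)` ON windows
#'   in seconds inside which the rate is multiplied by `onRateFactor`.
#' @param weight optional per-sample locking weight in `[0, 1]` (aligned
#'   with `betaPhase`): the effective concentration is `kappa * weight`,
#'   each sample normalised by its own Bessel factor so the expected rate
#'   stays `baseRateHz`. Used to gate entrainment by the instantaneous
#'   beta amplitude -- a unit cannot be locked to an oscillation that is
#'   absent. Default 1 everywhere (constant concentration).
#' @param seed RNG seed; defaults to `config@seed`.
#' @param unitId,region,cellClass labels for the output train.
#' @return A [SpikeTrain-class].
#' @export
genSpikeTrain <- function(config, betaPhase, onWindows = NULL, weight = NULL,
                          seed = config@seed, unitId = "u1", region = "STN",
                          cellClass = "STN") {
  stopifnot(is(config, "SyntheticConfig"), is(betaPhase, "ContinuousSignal"))
  validObject(config)
  if (config@kappa < 0) stop("kappa must be >= 0")
  if (config@baseRateHz <= 0) stop("baseRateHz must be positive")
  kap <- config@kappa
  tDur <- signalDuration(betaPhase)
  t0 <- betaPhase@t0
  lamMax <- config@baseRateHz * exp(kap) /
    (besselI(kap, 0, expon.scaled = TRUE) * exp(kap)) *
    max(1, config@onRateFactor)
  withSeed(seed, {
    nCand <- stats::rpois(1, lamMax * tDur)
    cand <- sort(stats::runif(nCand, t0, t0 + tDur))
    idx <- pmin(length(betaPhase@samples),
                floor((cand - t0) * betaPhase@fs) + 1L)
    kapT <- if (is.null(weight)) rep(kap, length(idx)) else {
      w <- if (is(weight, "ContinuousSignal")) weight@samples else weight
      kap * pmin(1, pmax(0, w[idx]))
    }
    i0T <- besselI(kapT, 0, expon.scaled = TRUE) * exp(kapT)
    lam <- config@baseRateHz *
      exp(kapT * cos(degToRad(betaPhase@samples[idx] - config@muDeg))) / i0T
    if (!is.null(onWindows) && nrow(onWindows) > 0) {
      inOn <- vapply(cand, function(tt)
        any(tt >= onWindows[, 1] & tt < onWindows[, 2]), logical(1))
      lam[inOn] <- lam[inOn] * config@onRateFactor
    }
    keep <- stats::runif(nCand) < lam / lamMax
    times <- cand[keep]
    times <- times[!duplicated(times)]
    spikeTrain(times, unitId = unitId, region = region, cellClass = cellClass)
  })
}

#' Assemble a full synthetic recording session
#'
#' Generates the ECoG (with protocol-dependent laser events), one or more
#' phase-locked spike trains, and stores the generator ground truth (burst
#' log, true preferred phase and concentration, ON factors) in the session
#' metadata. For the sinusoidal protocol the stored drive waveform keeps
#' only the positive half-cycles of the sinusoid, as delivered to the laser.
#'
#' @param config a [SyntheticConfig-class].
#' @return A [RecordingSession-class].
#' @export
genSession <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  eco <- genEcog(config)
  events <- eco$events
  fs <- config@fsHz
  anaBeta <- analyticSignal(eco$beta)
  phase <- continuousSignal(radToDeg(Arg(anaBeta)), fs = fs,
                            label = "beta_phase")
  # entrainment gated by the emitted beta amplitude: full concentration at
  # the nominal burst peak, none in the burst-free background
  lockWeight <- pmin(1, Mod(anaBeta) / config@burstAmp)
  onW <- cbind(events@onset, events@onset + events@duration)
  trains <- lapply(seq_len(max(1, round(config@nUnits))), function(j) {
    genSpikeTrain(config, phase, onWindows = onW, weight = lockWeight,
                  seed = config@seed + 1000 + j,
                  unitId = sprintf("u%d", j))
  })
  meta <- list(condition = "synthetic",
               groundTruth = list(burstLog = eco$burstLog,
                                  muDeg = config@muDeg,
                                  kappa = config@kappa,
                                  onRateFactor = config@onRateFactor,
                                  onBetaFactor = config@onBetaFactor,
                                  config = config))
  if (config@protocol == "sinusoid_20s") {
    tOn <- seq(0, events@duration[1], by = 1 / fs)
    meta$driveWaveform <- pmax(0, sin(2 * pi * config@betaFreqHz * tOn))
  }
  new("RecordingSession", signals = list(ecog = eco$signal),
      spikeTrains = trains, events = events, metadata = meta)
}
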