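#' Preprocess a raw ECoG/LFP channel for field analysis
#'
#' High-pass filters at 0.5 Hz (DC removal), anti-alias low-pass filters and
#' decimates the trace to 500 Hz. Signals already at 500 Hz (or any rate
#' below 1000 Hz but at least 500 Hz) are passed through with only the
#' high-pass applied, with a message.
#'
#' @param sig a [ContinuousSignal-class]; `samplingRate(sig)` must be a
#'   multiple of the target rate when decimation is needed.
#' @param targetFs output sampling rate in Hz (default 500).
#' @return A [ContinuousSignal-class] at `targetFs`, zero-mean.
#' @details Decimation uses the `signal` package's polyphase decimator in
#'   stages of at most factor 10 (forward-backward IIR anti-alias filtering),
#'   giving > 40 dB attenuation above the output Nyquist frequency. The
#'   0.5 Hz high-pass is a 3rd-order Butterworth applied forward-backward.
#' @examples
#' raw <- continuousSignal(rnorm(20000), fs = 2000)
#' out <- preprocessEcog(raw)
#' samplingRate(out)
#' @export
preprocessEcog <- function(sig, targetFs = 500) {
  stopifnot(is(sig, "ContinuousSignal"))
  fs <- sig@fs
  if (fs < targetFs)
    stop("cannot resample ", fs, " Hz signal up to ", targetFs, " Hz")
  x <- sig@samples
  x <- x - mean(x)  # DC removal first: also limits filter edge transients
  if (fs >= 2 * targetFs) {
    q <- fs / targetFs
    if (abs(q - round(q)) > 1e-9)
      stop("sampling rate must be an integer multiple of ", targetFs, " Hz")
    q <- round(q)
    while (q > 1) {
      step <- if (q > 10) {
        divs <- (10:2)[q %% (10:2) == 0]
        if (length(divs) == 0) q else divs[1]
      } else q
      x <- signal::decimate(x, step, ftype = "iir")
      q <- q / step
    }
    fs <- targetFs
  } else if (fs > targetFs) {
    message("sampling rate ", fs,
            " Hz below 2x target; passing through without decimation")
  } else {
    message("signal already at ", targetFs, " Hz; high-pass only")
  }
  hp <- signal::butter(3, 0.5 / (fs / 2), type = "high")
  x <- signal::filtfilt(hp, x)
  continuousSignal(x, fs = fs, t0 = sig@t0, label = sig@label)
}

#' Zero-phase band-pass filter
#'
#' 3rd-order Butterworth applied forward-backward (`filtfilt`), so the
#' effective magnitude response is squared and the group delay is zero --
#' required because burst timings and spike phases are read off the output.
#'
#' @param sig a [ContinuousSignal-class].
#' @param lo,hi band edges in Hz; defaults give the 12-30 Hz beta band.
#' @return A filtered [ContinuousSignal-class] at the same rate.
#' @export
bandpassFilter <- function(sig, lo = 12, hi = 30) {
  stopifnot(is(sig, "ContinuousSignal"))
  ny <- sig@fs / 2
  if (!(lo > 0 && lo < hi && hi < ny))
    stop("invalid band [", lo, ", ", hi, "] for fs ", sig@fs)
  bf <- signal::butter(3, c(lo, hi) / ny, type = "pass")
  continuousSignal(signal::filtfilt(bf, sig@samples), fs = sig@fs,
                   t0 = sig@t0, label = paste0(sig@label, "_bp"))
}

#' Instantaneous amplitude envelope
#'
#' Magnitude of the analytic signal (frequency-domain Hilbert transform).
#' Intended for band-limited input, i.e. the output of [bandpassFilter()].
#'
#' @param sig a [ContinuousSignal-class].
#' @return A non-negative [ContinuousSignal-class] (the envelope).
#' @export
signalEnvelope <- function(sig) {
  stopifnot(is(sig, "ContinuousSignal"))
  continuousSignal(Mod(analyticSignal(sig@samples)), fs = sig@fs,
                   t0 = sig@t0, label = paste0(sig@label, "_env"))
}

#' Instantaneous phase in degrees
#'
#' Argument of the analytic signal mapped to `[0, 360)`, with 0 degrees at
#' the oscillation peak (cosine convention).
#'
#' @param sig a band-limited [ContinuousSignal-class].
#' @return A [ContinuousSignal-class] whose samples are phases in degrees.
#' @export
signalPhase <- function(sig) {
  stopifnot(is(sig, "ContinuousSignal"))
  continuousSignal(radToDeg(Arg(analyticSignal(sig@samples))), fs = sig@fs,
                   t0 = sig@t0, label = paste0(sig@label, "_phase"))
}

# nfft giving approximately the requested resolution (power of two >= fs/res)
nfftFor <- function(fs, resolution) 2^ceiling(log2(fs / resolution) - 1e-9)

#' RMS power spectrum by averaged modified periodograms
#'
#' Hann-windowed segments with 50% overlap; at 500 Hz with ~1 Hz resolution
#' this uses 512-point segments, so the bin spacing is 500/512 = 0.977 Hz.
#' Per-bin powers are scaled so their sum tracks the signal variance.
#'
#' @param sig a [ContinuousSignal-class].
#' @param resolution requested frequency resolution in Hz (default 1).
#' @return A [PowerSpectrum-class].
#' @export
powerSpectrum <- function(sig, resolution = 1) {
  stopifnot(is(sig, "ContinuousSignal"))
  nfft <- nfftFor(sig@fs, resolution)
  if (length(sig@samples) < nfft)
    stop("signal shorter than one spectral segment (", nfft, " samples)")
  w <- welchSpectra(sig@samples, fs = sig@fs, nfft = nfft)
  new("PowerSpectrum", freq = w$freq, power = w$pxx,
      resolution = sig@fs / nfft)
}

#' Peri-event Morlet spectrogram
#'
#' 7-cycle complex Morlet wavelet power, computed on the whole trace by FFT
#' convolution and averaged across event-aligned windows sampled every 50 ms.
#'
#' @param sig a [ContinuousSignal-class].
#' @param events a [StimEvents-class]; windows are aligned to `onset`.
#' @param window two numbers, window around onset in seconds
#'   (default `c(-4, 6)`).
#' @param fRange frequency range in Hz (default `c(5, 45)`).
#' @param fStep frequency step in Hz (default 0.5).
#' @param tStep time step in seconds (default 0.05).
#' @param nCycles wavelet width in cycles (default 7).
#' @return A [Spectrogram-class]; events whose window falls outside the
#'   recording are dropped with a message.
#' @export
periEventSpectrogram <- function(sig, events, window = c(-4, 6),
                                 fRange = c(5, 45), fStep = 0.5,
                                 tStep = 0.05, nCycles = 7) {
  stopifnot(is(sig, "ContinuousSignal"), is(events, "StimEvents"))
  fs <- sig@fs
  x <- sig@samples
  n <- length(x)
  tEnd <- sig@t0 + n / fs
  ok <- events@onset + window[1] >= sig@t0 & events@onset + window[2] <= tEnd
  if (any(!ok))
    message(sum(!ok), " event(s) outside the recording were dropped")
  onsets <- events@onset[ok]
  if (length(onsets) == 0) stop("no events with a full window in range")
  freqs <- seq(fRange[1], fRange[2], by = fStep)
  relT <- seq(window[1], window[2], by = tStep)
  # sample indices at which wavelet power is read out, one row per event
  idx <- outer(round((onsets - sig@t0) / (1 / fs)),
               round(relT * fs), "+") + 1L
  X <- stats::fft(x)
  fftFreq <- (0:(n - 1)) / n * fs
  pow <- matrix(0, nrow = length(relT), ncol = length(freqs))
  for (j in seq_along(freqs)) {
    f0 <- freqs[j]
    sdF <- f0 / nCycles            # spectral SD of the Morlet at f0
    # Gaussian frequency-domain Morlet (analytic: positive frequencies only)
    H <- exp(-((fftFreq - f0)^2) / (2 * sdF^2))
    H[fftFreq > fs / 2] <- 0
    conv <- stats::fft(X * H, inverse = TRUE) / n
    p <- Mod(conv)^2
    pow[, j] <- colMeans(matrix(p[idx], nrow = length(onsets)))
  }
  new("Spectrogram", times = relT, freq = freqs, power = pow)
}

# Binarize a spike train onto the sampling grid of a field signal.
# Multiple spikes in one 1/fs bin are clipped to one, with a message.
binarizeSpikes <- function(spikes, field) {
  n <- length(field@samples)
  idx <- floor((spikes@times - field@t0) * field@fs) + 1L
  idx <- idx[idx >= 1L & idx <= n]
  nClip <- length(idx) - length(unique(idx))
  if (nClip > 0)
    message(nClip, " spike(s) clipped (multiple spikes in one sample bin)")
  b <- numeric(n)
  b[unique(idx)] <- 1
  b
}

#' Spike-field magnitude-squared coherence
#'
#' Coherence between the binarized spike train (delta train at the field
#' sampling rate) and the field, by Welch-averaged cross spectra at ~1 Hz
#' resolution. Values are bounded in `[0, 1]`; with `K` averaged segments
#' the expected bias floor for independent signals is approximately `1/K`.
#'
#' @param spikes a [SpikeTrain-class] (must contain at least one spike).
#' @param field a [ContinuousSignal-class].
#' @param resolution frequency resolution in Hz (default 1).
#' @return A [CoherenceSpectrum-class].
#' @export
spikeFieldCoherence <- function(spikes, field, resolution = 1) {
  stopifnot(is(spikes, "SpikeTrain"), is(field, "ContinuousSignal"))
  if (length(spikes@times) == 0) stop("empty spike train")
  if (signalDuration(field) < 60)
    message("field support below 60 s; coherence estimates will be noisy")
  b <- binarizeSpikes(spikes, field)
  nfft <- nfftFor(field@fs, resolution)
  w <- welchSpectra(b, field@samples, fs = field@fs, nfft = nfft)
  new("CoherenceSpectrum", freq = w$freq, coherence = pmin(w$coherence, 1),
      nSegments = as.integer(w$nSegments))
}
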