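#' Construct a ContinuousSignal
#'
#' @param samples numeric vector of samples (microvolts).
#' @param fs sampling rate (Hz).
#' @param t0 time of first sample (s).
#' @param label channel label.
#' @return A [ContinuousSignal-class] object.
#' @examples
#' s <- continuousSignal(sin(2 * pi * 20 * seq(0, 1, by = 1 / 500)), fs = 500)
#' samplingRate(s)
#' @export
continuousSignal <- function(samples, fs, t0 = 0, label = "ecog") {
  new("ContinuousSignal", samples = as.numeric(samples), fs = fs, t0 = t0,
      label = label)
}

#' Construct a SpikeTrain
#'
#' @param times strictly increasing spike times (s).
#' @param unitId unit identifier.
#' @param region recording structure.
#' @param cellClass cell class label.
#' @return A [SpikeTrain-class] object.
#' @export
spikeTrain <- function(times, unitId = "u1", region = "other",
                       cellClass = "unknown") {
  new("SpikeTrain", times = as.numeric(times), unitId = unitId,
      region = region, cellClass = cellClass)
}

#' Construct StimEvents
#'
#' @param onset event onset times (s).
#' @param duration event durations (s); recycled to the number of onsets.
#' @param kind `"pulse"` or `"sinusoid"`.
#' @return A [StimEvents-class] object.
#' @export
stimEvents <- function(onset, duration, kind = "pulse") {
  new("StimEvents", onset = as.numeric(onset),
      duration = rep_len(as.numeric(duration), length(onset)), kind = kind)
}

#' @rdname continuousSignal
#' @param x a `ContinuousSignal`.
#' @export
samples <- function(x) x@samples

#' @rdname continuousSignal
#' @export
samplingRate <- function(x) x@fs

#' @rdname continuousSignal
#' @export
startTime <- function(x) x@t0

#' Time axis of a ContinuousSignal
#' @param x a `ContinuousSignal`.
#' @return numeric vector of sample times in seconds.
#' @export
timePoints <- function(x) x@t0 + (seq_along(x@samples) - 1) / x@fs

#' Duration of a ContinuousSignal in seconds
#' @param x a `ContinuousSignal`.
#' @export
signalDuration <- function(x) length(x@samples) / x@fs

#' Spike times of a SpikeTrain
#' @param x a `SpikeTrain`.
#' @export
spikeTimes <- function(x) x@times

#' Epoch table of an EpochSet
#' @param x an `EpochSet`.
#' @return data.frame with columns event, class, start, end.
#' @export
epochTable <- function(x) x@table

setMethod("show", "ContinuousSignal", function(object) {
  cat(sprintf("ContinuousSignal '%s': %d samples @ %g Hz (%.1f s from t0=%g)\n",
              object@label, length(object@samples), object@fs,
              signalDuration(object), object@t0))
})

setMethod("show", "SpikeTrain", function(object) {
  cat(sprintf("SpikeTrain '%s' [%s/%s]: %d spikes", object@unitId,
              object@region, object@cellClass, length(object@times)))
  if (length(object@times))
    cat(sprintf(" over %.1f s (mean rate %.2f Hz)",
                diff(range(object@times)),
                length(object@times) / max(diff(range(object@times)), 1e-12)))
  cat("\n")
})

setMethod("show", "StimEvents", function(object) {
  cat(sprintf("StimEvents: %d %s event(s)", length(object@onset),
              paste(unique(object@kind), collapse = "/")))
  if (length(object@onset))
    cat(sprintf(", onsets %.1f-%.1f s, total ON %.1f s",
                min(object@onset), max(object@onset), sum(object@duration)))
  cat("\n")
})

setMethod("show", "EpochSet", function(object) {
  tb <- object@table
  cat(sprintf("EpochSet (%s protocol): %d event(s), %d window(s)",
              object@protocol, length(unique(tb$event)), nrow(tb)))
  if (object@nDropped > 0L)
    cat(sprintf(" [%d event(s) dropped at boundary]", object@nDropped))
  cat("\n")
  for (cl in intersect(c("pre", "off", "on"), tb$class))
    cat(sprintf("  %-3s: total %.1f s\n", cl,
                sum(tb$end[tb$class == cl] - tb$start[tb$class == cl])))
})

setMethod("show", "PowerSpectrum", function(object) {
  cat(sprintf("PowerSpectrum: %d bins, %.3f-%.1f Hz, resolution %.3f Hz\n",
              length(object@freq), min(object@freq), max(object@freq),
              object@resolution))
})

setMethod("show", "CoherenceSpectrum", function(object) {
  cat(sprintf("CoherenceSpectrum: %d bins (%d segments averaged), max %.3f\n",
              length(object@freq), object@nSegments, max(object@coherence)))
})

setMethod("show", "Spectrogram", function(object) {
  cat(sprintf("Spectrogram: %d time bins x %d frequencies (%.1f-%.1f Hz)\n",
              length(object@times), length(object@freq),
              min(object@freq), max(object@freq)))
})

setMethod("show", "CircResult", function(object) {
  cat(sprintf(
    "CircResult: n=%d, mean angle=%.1f deg, R=%.3f, Rayleigh Z=%.2f, p=%.3g\n",
    object@n, object@meanAngle, object@R, object@Z, object@p))
})

setMethod("show", "PSTHResult", function(object) {
  cat(sprintf(
    "PSTHResult: %d bins x %d events, baseline %.2f +/- %.2f counts, label: %s\n",
    length(object@counts), object@nEvents, object@baselineMean,
    object@baselineSd, object@label))
})

setMethod("show", "RecordingSession", function(object) {
  cat(sprintf("RecordingSession: %d signal(s), %d spike train(s), %d event(s)\n",
              length(object@signals), length(object@spikeTrains),
              length(object@events@onset)))
})
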