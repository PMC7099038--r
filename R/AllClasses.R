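#' @import methods
#' @importFrom stats quantile sd fft rnorm runif rpois pf approx ks.test
#' @importFrom utils head tail read.csv write.csv
#' @importFrom graphics hist
NULL

#' ContinuousSignal: a uniformly sampled voltage trace
#'
#' Container for one continuous channel (ECoG or LFP). Sample `i`
#' (1-based) occurs at time `t0 + (i - 1) / fs` seconds.
#'
#' @slot samples numeric vector of samples (microvolts).
#' @slot fs sampling rate in Hz.
#' @slot t0 time of the first sample in seconds.
#' @slot label free-text channel label.
#' @export
setClass("ContinuousSignal",
  representation(samples = "numeric", fs = "numeric", t0 = "numeric",
                 label = "character"),
  prototype(samples = numeric(0), fs = 500, t0 = 0, label = "ecog"))

setValidity("ContinuousSignal", function(object) {
  msg <- NULL
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(object@samples) < 1L)
    msg <- c(msg, "signal must contain at least one sample")
  if (length(object@t0) != 1L || !is.finite(object@t0))
    msg <- c(msg, "t0 must be a single finite number")
  if (is.null(msg)) TRUE else msg
})

#' SpikeTrain: sorted spike times of one unit
#'
#' @slot times strictly increasing spike times in seconds.
#' @slot unitId unit identifier.
#' @slot region recording structure: one of `"mCx"`, `"STN"`, `"GP"`, `"other"`.
#' @slot cellClass putative cell class label (input metadata, not inferred).
#' @export
setClass("SpikeTrain",
  representation(times = "numeric", unitId = "character",
                 region = "character", cellClass = "character"),
  prototype(times = numeric(0), unitId = "u1", region = "other",
            cellClass = "unknown"))

setValidity("SpikeTrain", function(object) {
  msg <- NULL
  if (is.unsorted(object@times, strictly = TRUE))
    msg <- c(msg, "spike times must be strictly increasing")
  if (!object@region %in% c("mCx", "STN", "GP", "other"))
    msg <- c(msg, "region must be one of mCx, STN, GP, other")
  if (!object@cellClass %in%
      c("pyramidal", "STN", "prototypic", "arkypallidal", "unknown"))
    msg <- c(msg, "unknown cellClass")
  if (is.null(msg)) TRUE else msg
})

#' StimEvents: laser stimulation events
#'
#' Sorted, non-overlapping light-delivery events. `kind` distinguishes the
#' 2 s continuous pulse protocol from the 20 s sinusoidally patterned one.
#'
#' @slot onset onset times in seconds.
#' @slot duration durations in seconds.
#' @slot kind `"pulse"` or `"sinusoid"` (one value recycled over events).
#' @export
setClass("StimEvents",
  representation(onset = "numeric", duration = "numeric", kind = "character"),
  prototype(onset = numeric(0), duration = numeric(0), kind = "pulse"))

setValidity("StimEvents", function(object) {
  msg <- NULL
  n <- length(object@onset)
  if (length(object@duration) != n)
    msg <- c(msg, "onset and duration lengths differ")
  if (any(object@duration <= 0))
    msg <- c(msg, "durations must be positive")
  if (n > 1L) {
    if (is.unsorted(object@onset, strictly = TRUE))
      msg <- c(msg, "events must be sorted by onset")
    else if (any(object@onset[-1L] < (object@onset + object@duration)[-n]))
      msg <- c(msg, "events must not overlap")
  }
  if (!all(object@kind %in% c("pulse", "sinusoid")))
    msg <- c(msg, "kind must be 'pulse' or 'sinusoid'")
  if (is.null(msg)) TRUE else msg
})

#' EpochSet: Pre/OFF/ON analysis windows derived from laser events
#'
#' Windows are half-open `[start, end)` seconds. For the pulse protocol each
#' event contributes pre `[onset-4, onset-2)`, off `[onset-2, onset)` and
#' on `[onset, onset+duration)`. For the sinusoid protocol the baseline OFF
#' window is the full stimulus duration preceding onset and Pre is undefined.
#'
#' @slot table data.frame with columns `event`, `class` ("pre"/"off"/"on"),
#'   `start`, `end`.
#' @slot protocol `"pulse"` or `"sinusoid"`.
#' @slot nDropped number of events dropped at the recording boundary.
#' @export
setClass("EpochSet",
  representation(table = "data.frame", protocol = "character",
                 nDropped = "integer"),
  prototype(table = data.frame(event = integer(0), class = character(0),
                               start = numeric(0), end = numeric(0)),
            protocol = "pulse", nDropped = 0L))

setValidity("EpochSet", function(object) {
  msg <- NULL
  tb <- object@table
  if (!all(c("event", "class", "start", "end") %in% names(tb)))
    msg <- c(msg, "epoch table must have event/class/start/end columns")
  else {
    if (!all(tb$class %in% c("pre", "off", "on")))
      msg <- c(msg, "epoch class must be pre/off/on")
    if (any(tb$end <= tb$start))
      msg <- c(msg, "epoch end must exceed start")
  }
  if (!object@protocol %in% c("pulse", "sinusoid"))
    msg <- c(msg, "protocol must be 'pulse' or 'sinusoid'")
  if (is.null(msg)) TRUE else msg
})

#' PowerSpectrum: averaged-periodogram RMS power spectrum
#'
#' One-sided spectrum in per-bin power units (microvolts squared), scaled so
#' that the sum over bins approximates the signal variance.
#'
#' @slot freq ascending frequency grid in Hz.
#' @slot power per-bin power, same length as `freq`.
#' @slot resolution bin spacing in Hz.
#' @export
setClass("PowerSpectrum",
  representation(freq = "numeric", power = "numeric", resolution = "numeric"))

setValidity("PowerSpectrum", function(object) {
  msg <- NULL
  if (length(object@freq) != length(object@power))
    msg <- c(msg, "freq and power lengths differ")
  if (is.unsorted(object@freq))
    msg <- c(msg, "freq must ascend")
  if (any(object@power < 0))
    msg <- c(msg, "power must be non-negative")
  if (is.null(msg)) TRUE else msg
})

#' Spectrogram: peri-event time-frequency power
#'
#' @slot times time axis in seconds (relative to event onset).
#' @slot freq frequency axis in Hz.
#' @slot power time-by-frequency matrix of wavelet power.
#' @export
setClass("Spectrogram",
  representation(times = "numeric", freq = "numeric", power = "matrix"))

setValidity("Spectrogram", function(object) {
  msg <- NULL
  if (!identical(dim(object@power),
                 c(length(object@times), length(object@freq))))
    msg <- c(msg, "power must be times x freq")
  if (any(object@power < 0))
    msg <- c(msg, "power must be non-negative")
  if (is.null(msg)) TRUE else msg
})

#' CoherenceSpectrum: spike-field magnitude-squared coherence
#'
#' @slot freq frequency grid in Hz.
#' @slot coherence values in `[0, 1]`.
#' @slot nSegments number of averaged segments (determines the bias floor).
#' @export
setClass("CoherenceSpectrum",
  representation(freq = "numeric", coherence = "numeric",
                 nSegments = "integer"))

setValidity("CoherenceSpectrum", function(object) {
  msg <- NULL
  if (length(object@freq) != length(object@coherence))
    msg <- c(msg, "freq and coherence lengths differ")
  if (any(object@coherence < -1e-9 | object@coherence > 1 + 1e-9))
    msg <- c(msg, "coherence must lie in [0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' CircResult: circular-statistics summary of a spike-phase sample
#'
#' @slot meanAngle circular mean direction in degrees `[0, 360)`; `NaN` when
#'   the resultant has zero length.
#' @slot R mean resultant (vector) length in `[0, 1]`.
#' @slot n sample size.
#' @slot Z Rayleigh statistic, `n * R^2`.
#' @slot p Rayleigh p-value (small-sample corrected approximation).
#' @export
setClass("CircResult",
  representation(meanAngle = "numeric", R = "numeric", n = "integer",
                 Z = "numeric", p = "numeric"))

setValidity("CircResult", function(object) {
  msg <- NULL
  if (object@R < -1e-12 || object@R > 1 + 1e-12)
    msg <- c(msg, "R must lie in [0, 1]")
  if (object@p > 1 + 1e-12 || object@p <= 0)
    msg <- c(msg, "p must lie in (0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' PSTHResult: peri-stimulus time histogram with baseline statistics
#'
#' Histogram over `[-2, +4)` s around laser onset at 50 ms bins (120 bins).
#' Baseline mean/SD are computed on counts over the 40 OFF bins `[-2, 0)`.
#'
#' @slot edges bin edges in seconds relative to onset (length 121).
#' @slot counts spike counts per bin, summed over events.
#' @slot rate per-bin firing rate in Hz, `counts / (nEvents * binWidth)`.
#' @slot baselineMean mean baseline bin count.
#' @slot baselineSd SD of baseline bin counts.
#' @slot nEvents number of events entering the histogram.
#' @slot label response class: `"inhibited"`, `"excited"`, `"not_modulated"`,
#'   or `"unclassified"` before [classifyResponse()] is applied.
#' @export
setClass("PSTHResult",
  representation(edges = "numeric", counts = "numeric", rate = "numeric",
                 baselineMean = "numeric", baselineSd = "numeric",
                 nEvents = "integer", label = "character"))

setValidity("PSTHResult", function(object) {
  msg <- NULL
  if (length(object@edges) != length(object@counts) + 1L)
    msg <- c(msg, "edges must be one longer than counts")
  if (any(object@counts < 0))
    msg <- c(msg, "counts must be non-negative")
  if (!object@label %in% c("inhibited", "excited", "not_modulated",
                           "unclassified"))
    msg <- c(msg, "unknown response label")
  if (is.null(msg)) TRUE else msg
})

#' RecordingSession: one experiment
#'
#' Bundles the continuous channel(s), sorted spike trains, laser events and
#' free-form metadata (for synthetic sessions, the ground-truth block).
#'
#' @slot signals named list of [ContinuousSignal-class] objects.
#' @slot spikeTrains list of [SpikeTrain-class] objects.
#' @slot events a [StimEvents-class] object.
#' @slot metadata free-form list (animal id, condition, ground truth, ...).
#' @export
setClass("RecordingSession",
  representation(signals = "list", spikeTrains = "list",
                 events = "StimEvents", metadata = "list"),
  prototype(signals = list(), spikeTrains = list(),
            events = new("StimEvents"), metadata = list()))

setValidity("RecordingSession", function(object) {
  msg <- NULL
  if (!all(vapply(object@signals, is, logical(1), "ContinuousSignal")))
    msg <- c(msg, "signals must all be ContinuousSignal")
  if (!all(vapply(object@spikeTrains, is, logical(1), "SpikeTrain")))
    msg <- c(msg, "spikeTrains must all be SpikeTrain")
  if (length(object@signals) > 0L && length(object@events@onset) > 0L) {
    sig <- object@signals[[1L]]
    tEnd <- sig@t0 + length(sig@samples) / sig@fs
    if (any(object@events@onset < sig@t0) ||
        any(object@events@onset + object@events@duration > tEnd + 1e-9))
      msg <- c(msg, "events must lie within the signal support")
  }
  if (is.null(msg)) TRUE else msg
})
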