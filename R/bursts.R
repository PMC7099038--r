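#' Detect beta bursts from the band-limited envelope
#'
#' A burst is a maximal run of samples whose envelope strictly exceeds the
#' given percentile of the envelope computed over the entire recording, and
#' whose duration is strictly longer than `minDurS`. Duration is measured
#' from the first to the last supra-threshold sample inclusive, i.e.
#' `(n_samples) / fs`. Edge samples (first/last `edgeS` seconds) are
#' excluded from both thresholding and detection to avoid analytic-signal
#' edge artifacts.
#'
#' @param env a [ContinuousSignal-class] holding the beta-band envelope
#'   (output of [signalEnvelope()] on [bandpassFilter()] output).
#' @param percentile envelope percentile defining the threshold (default 75).
#' @param minDurS minimum burst duration in seconds (default 0.05).
#' @param edgeS edge exclusion in seconds (default 0.5; set 0 to disable).
#' @return data.frame with columns `start`, `end`, `duration` (seconds) and
#'   `peakAmp` (microvolts); zero rows when nothing crosses threshold.
#'   Multiplying the envelope by any positive constant leaves the result
#'   unchanged, since the threshold scales with the signal.
#' @examples
#' fs <- 500; t <- seq(0, 10, by = 1 / fs)
#' x <- continuousSignal(sin(2 * pi * 20 * t) *
#'   exp(-(t - 5)^2 / 0.02), fs = fs)
#' detectBursts(signalEnvelope(bandpassFilter(x)), edgeS = 0)
#' @export
detectBursts <- function(env, percentile = 75, minDurS = 0.05, edgeS = 0.5) {
  stopifnot(is(env, "ContinuousSignal"))
  x <- env@samples
  n <- length(x)
  if (n == 0) stop("empty envelope signal")
  fs <- env@fs
  nEdge <- min(floor(edgeS * fs), (n - 1) %/% 2)
  keep <- if (nEdge > 0) (nEdge + 1L):(n - nEdge) else seq_len(n)
  thr <- stats::quantile(x[keep], percentile / 100, names = FALSE)
  mask <- logical(n)
  mask[keep] <- x[keep] > thr
  runs <- trueRuns(mask)
  if (nrow(runs) == 0)
    return(data.frame(start = numeric(0), end = numeric(0),
                      duration = numeric(0), peakAmp = numeric(0)))
  len <- runs[, "end"] - runs[, "start"] + 1L
  ok <- len / fs > minDurS
  runs <- runs[ok, , drop = FALSE]
  if (nrow(runs) == 0)
    return(data.frame(start = numeric(0), end = numeric(0),
                      duration = numeric(0), peakAmp = numeric(0)))
  data.frame(
    start = env@t0 + (runs[, "start"] - 1) / fs,
    end = env@t0 + runs[, "end"] / fs,
    duration = (runs[, "end"] - runs[, "start"] + 1L) / fs,
    peakAmp = apply(runs, 1, function(r) max(x[r[1]:r[2]])))
}

#' Summarise burst dynamics per laser epoch class
#'
#' Each burst is assigned to the epoch containing its start time (bursts
#' straddling a boundary count where they start; bursts outside all epochs
#' are ignored). Returns, per class, the mean burst duration and the mean
#' number of bursts per epoch window.
#'
#' @param bursts data.frame from [detectBursts()].
#' @param epochs an [EpochSet-class].
#' @return data.frame with one row per epoch class present in `epochs`:
#'   `class`, `nEpochs`, `nBursts`, `meanCountPerEpoch`, `meanDuration`
#'   (`NA` when no bursts fall in that class).
#' @export
burstStatsByEpoch <- function(bursts, epochs) {
  stopifnot(is(epochs, "EpochSet"))
  tb <- epochs@table
  classes <- intersect(c("pre", "off", "on"), unique(tb$class))
  out <- lapply(classes, function(cl) {
    wins <- tb[tb$class == cl, , drop = FALSE]
    inCl <- if (nrow(bursts)) vapply(bursts$start, function(s)
      any(s >= wins$start & s < wins$end), logical(1)) else logical(0)
    nb <- sum(inCl)
    data.frame(class = cl, nEpochs = nrow(wins), nBursts = nb,
               meanCountPerEpoch = nb / max(1L, nrow(wins)),
               meanDuration = if (nb > 0) mean(bursts$duration[inCl]) else NA_real_)
  })
  do.call(rbind, out)
}
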