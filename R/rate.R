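#' Peri-stimulus time histogram
#'
#' Spike counts binned over `[-offset, width - offset)` seconds around each
#' laser onset (defaults: 6 s width, 2 s offset, 50 ms bins, i.e. 120 bins
#' over `[-2, +4)`), summed over events. Baseline mean and SD are computed
#' on the per-bin counts of the 40 OFF bins in `[-2, 0)`. Classification of
#' the response (at least ten stimulations expected; fewer allowed with a
#' message) is applied by [classifyResponse()].
#'
#' @param spikes a [SpikeTrain-class].
#' @param events a [StimEvents-class] (at least one event).
#' @param widthS histogram width in seconds (default 6).
#' @param offsetS pre-onset offset in seconds (default 2).
#' @param binS bin size in seconds (default 0.05).
#' @return A [PSTHResult-class] with label `"unclassified"`.
#' @export
buildPsth <- function(spikes, events, widthS = 6, offsetS = 2, binS = 0.05) {
  stopifnot(is(spikes, "SpikeTrain"), is(events, "StimEvents"))
  nEv <- length(events@onset)
  if (nEv == 0) stop("no events")
  if (nEv < 10)
    message("only ", nEv, " stimulation(s): response classification is ",
            "usually based on at least ten")
  edges <- seq(-offsetS, widthS - offsetS, by = binS)
  nBins <- length(edges) - 1L
  counts <- numeric(nBins)
  for (on in events@onset) {
    rel <- spikes@times - on
    rel <- rel[rel >= edges[1] & rel < edges[nBins + 1L]]
    if (length(rel))
      counts <- counts + hist(rel, breaks = edges, plot = FALSE,
                              right = FALSE)$counts
  }
  baseBins <- which(edges[-length(edges)] >= -offsetS &
                    edges[-1] <= 0 + 1e-9)
  new("PSTHResult", edges = edges, counts = counts,
      rate = counts / (nEv * binS),
      baselineMean = mean(counts[baseBins]),
      baselineSd = stats::sd(counts[baseBins]),
      nEvents = as.integer(nEv), label = "unclassified")
}

# indices of runs of >= k consecutive TRUE; returns first index or NA
firstRunStart <- function(mask, k) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= k)
  if (length(hit)) starts[hit[1]] else NA_integer_
}

#' Classify an opto-response from a PSTH
#'
#' A unit is `"inhibited"` when at least three consecutive of the bins
#' within the first 400 ms after light onset (8 bins at 50 ms) fall below
#' baseline mean minus 2 SD, `"excited"` when at least three consecutive
#' bins exceed baseline mean plus 2 SD, and `"not_modulated"` otherwise.
#' When both patterns occur in the same window, the earlier-onset pattern
#' wins (tie: inhibited). SD is measured on the OFF-epoch baseline bins. A
#' zero baseline SD with deviating bins is classified with a message about
#' the degenerate baseline.
#'
#' @param psth a [PSTHResult-class].
#' @param responseWindowS post-onset window examined (default 0.4 s).
#' @param nConsecutive consecutive-bin rule (default 3).
#' @param sdMult threshold in baseline SD units (default 2).
#' @return The input [PSTHResult-class] with its `label` slot set.
#' @export
classifyResponse <- function(psth, responseWindowS = 0.4, nConsecutive = 3,
                             sdMult = 2) {
  stopifnot(is(psth, "PSTHResult"))
  binS <- psth@edges[2] - psth@edges[1]
  lo <- psth@edges[-length(psth@edges)]
  win <- which(lo >= 0 & lo < responseWindowS - 1e-9)
  cnt <- psth@counts[win]
  m <- psth@baselineMean
  s <- psth@baselineSd
  if (is.na(s) || s == 0) {
    if (all(abs(cnt - m) < 1e-12)) {
      psth@label <- "not_modulated"
      return(psth)
    }
    message("degenerate baseline (SD = 0); classifying against the mean only")
    s <- 0
  }
  inhStart <- firstRunStart(cnt < m - sdMult * s, nConsecutive)
  excStart <- firstRunStart(cnt > m + sdMult * s, nConsecutive)
  psth@label <- if (is.na(inhStart) && is.na(excStart)) "not_modulated"
  else if (is.na(excStart)) "inhibited"
  else if (is.na(inhStart)) "excited"
  else if (inhStart <= excStart) "inhibited" else "excited"
  psth
}

#' Pooled firing rates over OFF and ON epochs
#'
#' Counts spikes falling in all OFF (resp. ON) windows and divides by the
#' total OFF (resp. ON) duration. Windows are half-open, so a spike at an
#' exact boundary belongs to the later epoch.
#'
#' @param spikes a [SpikeTrain-class].
#' @param epochs an [EpochSet-class] with positive total OFF and ON time.
#' @return A list with `fOff` and `fOn` in Hz.
#' @export
ratesByEpoch <- function(spikes, epochs) {
  stopifnot(is(spikes, "SpikeTrain"), is(epochs, "EpochSet"))
  tb <- epochs@table
  one <- function(cl) {
    wins <- tb[tb$class == cl, , drop = FALSE]
    tot <- sum(wins$end - wins$start)
    if (tot <= 0) stop("zero total ", cl, " duration")
    nSp <- sum(vapply(spikes@times, function(s)
      any(s >= wins$start & s < wins$end), logical(1)))
    nSp / tot
  }
  list(fOff = one("off"), fOn = one("on"))
}

#' Firing-rate modulation index
#'
#' `MI = (fOn - fOff) / (fOn + fOff)`, bounded in `[-1, 1]`; -1 is complete
#' silencing during ON, +1 firing only during ON. Undefined (returned as
#' `NaN` with a message) when both rates are zero.
#'
#' @param fOff,fOn firing rates in Hz (non-negative).
#' @return The modulation index; antisymmetric under exchanging its
#'   arguments.
#' @examples
#' modulationIndex(10, 30)  # 0.5
#' @export
modulationIndex <- function(fOff, fOn) {
  if (fOff < 0 || fOn < 0) stop("rates must be non-negative")
  if (fOff + fOn <= 0) {
    message("modulation index undefined: both rates are zero")
    return(NaN)
  }
  (fOn - fOff) / (fOn + fOff)
}

#' Randomly thin a spike train
#'
#' Retains `floor((1 - fraction) * n)` spikes sampled uniformly without
#' replacement (deterministic for a given seed), emulating a firing-rate
#' decrease while leaving the phase distribution of retained spikes an
#' unbiased subsample of the original. Used as the rate-bias control for
#' spike-field coherence.
#'
#' @param spikes a [SpikeTrain-class].
#' @param fraction fraction of spikes to remove, in `[0, 1)`.
#' @param seed RNG seed.
#' @return A [SpikeTrain-class] with the retained (sorted) spikes.
#' @export
randomSpikeRemoval <- function(spikes, fraction, seed = 1) {
  stopifnot(is(spikes, "SpikeTrain"))
  if (fraction < 0 || fraction >= 1) stop("fraction must lie in [0, 1)")
  n <- length(spikes@times)
  nKeep <- floor((1 - fraction) * n)
  keep <- withSeed(seed, sort(sample.int(n, nKeep)))
  spikeTrain(spikes@times[keep], unitId = spikes@unitId,
             region = spikes@region, cellClass = spikes@cellClass)
}
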