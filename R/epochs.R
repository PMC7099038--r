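#' Build Pre/OFF/ON analysis windows from laser events
#'
#' For the pulse protocol each event yields three half-open windows:
#' pre `[onset-4, onset-2)`, off `[onset-2, onset)` (the 2 s baseline
#' directly preceding the light pulse) and on `[onset, onset+duration)`.
#' For the sinusoidal protocol the OFF baseline is the full stimulus
#' duration preceding onset and no Pre window is defined (the beta-AUC
#' cumulative-distribution analysis is pulse-mode only). Events whose
#' earliest window precedes the recording start (or whose ON window runs
#' past its end) are dropped with a message.
#'
#' @param events a [StimEvents-class].
#' @param recordingBounds numeric length-2, `c(start, end)` of the recording
#'   in seconds.
#' @return An [EpochSet-class].
#' @examples
#' buildEpochs(stimEvents(10, 2), c(0, 20))
#' @export
buildEpochs <- function(events, recordingBounds) {
  stopifnot(is(events, "StimEvents"), length(recordingBounds) == 2)
  validObject(events)
  protocol <- if (all(events@kind == "sinusoid")) "sinusoid" else "pulse"
  rows <- list()
  dropped <- 0L
  for (i in seq_along(events@onset)) {
    on <- events@onset[i]
    dur <- events@duration[i]
    win <- if (protocol == "pulse") {
      data.frame(event = i, class = c("pre", "off", "on"),
                 start = c(on - 4, on - 2, on), end = c(on - 2, on, on + dur))
    } else {
      data.frame(event = i, class = c("off", "on"),
                 start = c(on - dur, on), end = c(on, on + dur))
    }
    if (min(win$start) < recordingBounds[1] - 1e-9 ||
        max(win$end) > recordingBounds[2] + 1e-9) {
      dropped <- dropped + 1L
      next
    }
    rows[[length(rows) + 1L]] <- win
  }
  if (dropped > 0L)
    message(dropped, " event(s) dropped: windows outside the recording")
  tb <- if (length(rows)) do.call(rbind, rows) else
    data.frame(event = integer(0), class = character(0),
               start = numeric(0), end = numeric(0))
  new("EpochSet", table = tb, protocol = protocol, nDropped = dropped)
}

#' Session inclusion rule for beta-synchronisation analyses
#'
#' Pulse mode requires at least 30 laser stimulations and at least 60 s of
#' total OFF and ON time; sinusoid mode requires at least 3 stimulation
#' blocks (60 s of ON).
#'
#' @param epochs an [EpochSet-class].
#' @param mode `"pulse"` or `"sinusoid"`; defaults to the epoch protocol.
#' @return A list with `include` (logical) and `reasons` (named list with
#'   `nStims`, `totalOffS`, `totalOnS` and any failed rules).
#' @export
checkSessionInclusion <- function(epochs, mode = epochs@protocol) {
  stopifnot(is(epochs, "EpochSet"), mode %in% c("pulse", "sinusoid"))
  tb <- epochs@table
  nStims <- length(unique(tb$event))
  offS <- sum(tb$end[tb$class == "off"] - tb$start[tb$class == "off"])
  onS <- sum(tb$end[tb$class == "on"] - tb$start[tb$class == "on"])
  failed <- character(0)
  if (mode == "pulse") {
    if (nStims < 30) failed <- c(failed, "n_stims < 30")
    if (offS < 60) failed <- c(failed, "total OFF < 60 s")
    if (onS < 60) failed <- c(failed, "total ON < 60 s")
  } else {
    if (nStims < 3) failed <- c(failed, "n_blocks < 3")
  }
  list(include = length(failed) == 0L,
       reasons = list(nStims = nStims, totalOffS = offS, totalOnS = onS,
                      failed = failed))
}

#' Opto-mapping inclusion rule
#'
#' An animal's optogenetic control is accepted when at least ten cells were
#' opto-tested and strictly more than 60% of them were significantly
#' laser-modulated (labelled `"inhibited"` or `"excited"`).
#'
#' @param cellLabels character vector of response labels from
#'   [classifyResponse()].
#' @return A list with `include`, `n`, `fractionModulated`.
#' @examples
#' checkOptomappingInclusion(c(rep("inhibited", 7), rep("not_modulated", 3)))
#' @export
checkOptomappingInclusion <- function(cellLabels) {
  n <- length(cellLabels)
  frac <- if (n > 0) mean(cellLabels %in% c("inhibited", "excited")) else 0
  list(include = n >= 10 && frac > 0.60, n = n, fractionModulated = frac)
}
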