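#' Beta-band area-under-curve statistic
#'
#' Draws the straight chord between the (linearly interpolated) spectrum
#' values at the band edges and returns the signed area between spectrum and
#' chord over the band: (area above the chord) minus (area below it),
#' integrated by the trapezoid rule over the spectrum bins augmented with
#' the interpolated edge points. A spectrum that is exactly linear across
#' the band gives 0; adding any linear-in-frequency component leaves the
#' statistic unchanged because the chord absorbs it.
#'
#' @param spec a [PowerSpectrum-class].
#' @param band numeric length-2 band edges in Hz (default `c(12, 30)`).
#' @return The beta-AUC in microvolt^2 * Hz.
#' @examples
#' ps <- new("PowerSpectrum", freq = 0:50, power = rep(1, 51), resolution = 1)
#' betaAUC(ps)  # flat spectrum equals its chord -> 0
#' @export
betaAUC <- function(spec, band = c(12, 30)) {
  stopifnot(is(spec, "PowerSpectrum"), length(band) == 2, band[1] < band[2])
  fr <- spec@freq
  if (band[1] < min(fr) || band[2] > max(fr))
    stop("band [", band[1], ", ", band[2], "] outside spectrum range")
  inside <- fr > band[1] & fr < band[2]
  fGrid <- c(band[1], fr[inside], band[2])
  pGrid <- c(interpAt(fr, spec@power, band[1]), spec@power[inside],
             interpAt(fr, spec@power, band[2]))
  chord <- pGrid[1] + (pGrid[length(pGrid)] - pGrid[1]) *
    (fGrid - band[1]) / (band[2] - band[1])
  trapz(fGrid, pGrid - chord)
}

# Welch spectrum of one epoch window of a 500 Hz signal (512-point segments,
# Hann, 50% overlap: a 2 s / 1000-sample epoch yields two averaged segments).
epochSpectrum <- function(sig, start, end, resolution = 1) {
  fs <- sig@fs
  a <- floor((start - sig@t0) * fs) + 1L
  b <- min(length(sig@samples), ceiling((end - sig@t0) * fs))
  seg <- sig@samples[a:b]
  nfft <- nfftFor(fs, resolution)
  if (length(seg) < nfft)
    stop("epoch window shorter than one spectral segment")
  w <- welchSpectra(seg, fs = fs, nfft = nfft)
  new("PowerSpectrum", freq = w$freq, power = w$pxx, resolution = fs / nfft)
}

#' Per-stimulation beta-AUC differences
#'
#' For every pulse event, computes one spectrum per 2 s Pre, OFF and ON
#' window, its beta-AUC, and the two differences d_pre_off = AUC(Pre) -
#' AUC(OFF) and d_off_on = AUC(OFF) - AUC(ON). The empirical cumulative
#' distributions of the two difference samples are the per-epoch laser
#' effect statistic: under no laser effect they coincide.
#'
#' @param sig the preprocessed [ContinuousSignal-class] (500 Hz).
#' @param epochs a pulse-protocol [EpochSet-class].
#' @param band beta band in Hz (default `c(12, 30)`).
#' @return data.frame with columns `event`, `aucPre`, `aucOff`, `aucOn`,
#'   `dPreOff`, `dOffOn`.
#' @export
epochAucDifferences <- function(sig, epochs, band = c(12, 30)) {
  stopifnot(is(sig, "ContinuousSignal"), is(epochs, "EpochSet"))
  if (epochs@protocol != "pulse")
    stop("per-epoch AUC differences are defined for the pulse protocol only")
  tb <- epochs@table
  evs <- unique(tb$event)
  if (length(evs) < 1) stop("no events in epoch set")
  rows <- lapply(evs, function(ev) {
    sub <- tb[tb$event == ev, ]
    auc <- vapply(c("pre", "off", "on"), function(cl) {
      w <- sub[sub$class == cl, ]
      betaAUC(epochSpectrum(sig, w$start, w$end), band = band)
    }, numeric(1))
    data.frame(event = ev, aucPre = auc[["pre"]], aucOff = auc[["off"]],
               aucOn = auc[["on"]], dPreOff = auc[["pre"]] - auc[["off"]],
               dOffOn = auc[["off"]] - auc[["on"]])
  })
  do.call(rbind, rows)
}

#' Select the best beta-oscillation recording
#'
#' Returns the index of the recording whose full-recording power spectrum
#' maximises the beta-AUC; ties are broken by the lowest index (reported
#' with a message).
#'
#' @param recordings list of [ContinuousSignal-class] objects.
#' @param band beta band in Hz (default `c(12, 30)`).
#' @return Integer index into `recordings`.
#' @export
selectBestBeta <- function(recordings, band = c(12, 30)) {
  if (length(recordings) < 1) stop("no recordings supplied")
  aucs <- vapply(recordings, function(r) betaAUC(powerSpectrum(r), band),
                 numeric(1))
  best <- which(aucs == max(aucs))
  if (length(best) > 1)
    message("beta-AUC tie between recordings ",
            paste(best, collapse = ", "), "; taking the first")
  best[1]
}
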