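#' Detect beta-oscillation peaks in the band-pass filtered ECoG
#'
#' Returns the times of local maxima of the 12-30 Hz filtered trace whose
#' amplitude exceeds `threshSd` standard deviations of the whole filtered
#' trace, with successive peaks constrained to be at least one minimal beta
#' period (1/30 s) apart.
#'
#' @param betaSig the beta-band filtered [ContinuousSignal-class].
#' @param threshSd detection threshold in SD units of the trace (default 1).
#' @return Numeric vector of peak times in seconds (possibly empty).
#' @export
detectBetaPeaks <- function(betaSig, threshSd = 1.0) {
  stopifnot(is(betaSig, "ContinuousSignal"))
  x <- betaSig@samples
  n <- length(x)
  if (n < 3) return(numeric(0))
  thr <- threshSd * stats::sd(x)
  if (!is.finite(thr) || thr == 0) return(numeric(0))
  core <- 2:(n - 1)
  isPeak <- x[core] > x[core - 1] & x[core] >= x[core + 1] & x[core] > thr
  idx <- core[isPeak]
  if (length(idx) == 0) return(numeric(0))
  minGap <- betaSig@fs / 30
  kept <- idx[1]
  for (i in idx[-1]) if (i - kept[length(kept)] >= minGap) kept <- c(kept, i)
  betaSig@t0 + (kept - 1) / betaSig@fs
}

#' Assign beta-cycle phases to spikes
#'
#' Phase is defined cycle-by-cycle from consecutive detected beta peaks:
#' `phase = 360 * (t_spike - t_prev_peak) / (t_next_peak - t_prev_peak)`,
#' so the ECoG beta peak sits at 0/360 degrees. Only spikes between the
#' first and last peak are used, and cycles whose period falls outside the
#' beta band (shorter than 1/30 s or longer than 1/12 s) are discarded as
#' non-beta.
#'
#' @param spikes a [SpikeTrain-class].
#' @param peaks numeric vector of peak times from [detectBetaPeaks()]
#'   (at least two).
#' @param cycleRange admissible cycle period range in seconds
#'   (default `c(1/30, 1/12)`).
#' @return data.frame with columns `time` (spike time) and `phase`
#'   (degrees in `[0, 360)`).
#' @export
spikePhases <- function(spikes, peaks, cycleRange = c(1 / 30, 1 / 12)) {
  stopifnot(is(spikes, "SpikeTrain"))
  if (length(peaks) < 2) stop("need at least two beta peaks")
  peaks <- sort(peaks)
  st <- spikes@times
  st <- st[st >= peaks[1] & st < peaks[length(peaks)]]
  if (length(st) == 0)
    return(data.frame(time = numeric(0), phase = numeric(0)))
  cyc <- findInterval(st, peaks)
  period <- peaks[cyc + 1] - peaks[cyc]
  ok <- period >= cycleRange[1] & period <= cycleRange[2]
  ph <- 360 * (st - peaks[cyc]) / period
  data.frame(time = st[ok], phase = ph[ok] %% 360)
}

#' Linear phase histogram (10-degree bins)
#'
#' @param phases numeric vector of phases in degrees `[0, 360)`.
#' @param binDeg bin width in degrees (default 10, i.e. 36 bins).
#' @return data.frame with `binStart`, `binEnd`, `count`, `fraction`
#'   (fractions sum to 1 when any spikes are present).
#' @export
phaseHistogram <- function(phases, binDeg = 10) {
  edges <- seq(0, 360, by = binDeg)
  cnt <- hist(phases %% 360, breaks = edges, plot = FALSE,
              right = FALSE)$counts
  data.frame(binStart = edges[-length(edges)], binEnd = edges[-1],
             count = cnt,
             fraction = if (sum(cnt) > 0) cnt / sum(cnt) else cnt * 0)
}

#' Circular mean direction and vector length
#'
#' Resultant of unit phase vectors: `R` is the mean resultant length in
#' `[0, 1]` and the mean angle is its direction in degrees `[0, 360)`.
#' When the resultant is (numerically) zero the angle is undefined and
#' returned as `NaN` with `R = 0`.
#'
#' @param phases numeric vector of phases in degrees (at least one).
#' @return A list with `meanAngle` (degrees) and `R`.
#' @examples
#' circMeanR(c(10, 50))  # mean 30 degrees, R = cos(20 deg)
#' @export
circMeanR <- function(phases) {
  n <- length(phases)
  if (n == 0) stop("empty phase sample")
  th <- degToRad(phases)
  C <- mean(cos(th)); S <- mean(sin(th))
  R <- sqrt(C^2 + S^2)
  if (R < 1e-12)
    list(meanAngle = NaN, R = 0)
  else
    list(meanAngle = radToDeg(atan2(S, C)), R = min(R, 1))
}

#' Rayleigh test of circular uniformity
#'
#' `Z = n * R^2`; the p-value uses the standard small-sample corrected
#' approximation `p = exp(sqrt(1 + 4n + 4(n^2 - Rn^2)) - (1 + 2n))` with
#' `Rn = n * R` (accurate for n >= 4; a message is emitted below that). A
#' unit is declared entrained when `p < 0.05`.
#'
#' @param phases numeric vector of phases in degrees (at least one).
#' @return A [CircResult-class].
#' @export
rayleighTest <- function(phases) {
  n <- length(phases)
  if (n == 0) stop("empty phase sample")
  if (n < 4) message("Rayleigh p approximation is unreliable for n < 4")
  cm <- circMeanR(phases)
  Rn <- n * cm$R
  Z <- n * cm$R^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - Rn^2)) - (1 + 2 * n))
  new("CircResult", meanAngle = cm$meanAngle, R = cm$R, n = as.integer(n),
      Z = Z, p = min(max(p, .Machine$double.xmin), 1))
}

# Best-practice inverse of A1(kappa) = I1(kappa)/I0(kappa).
a1inv <- function(r) {
  if (r < 0.53) 2 * r + r^3 + 5 * r^5 / 6
  else if (r < 0.85) -0.4 + 1.39 * r + 0.43 / (1 - r)
  else 1 / (r^3 - 4 * r^2 + 3 * r)
}

#' Watson-Williams F test for equal mean directions
#'
#' Classical multi-sample test of a common mean direction under a shared
#' von Mises concentration, with the standard kappa correction factor
#' `K = 1 + 3 / (8 kappa_hat)`. Validity assumes reasonably concentrated
#' samples; a message is emitted when the pooled within-group resultant
#' falls below 0.45.
#'
#' @param groups list of numeric vectors of phases in degrees, each
#'   non-empty; at least two groups.
#' @return A list with `F`, `p`, `df1`, `df2`, `kappa`.
#' @export
watsonWilliams <- function(groups) {
  if (length(groups) < 2) stop("need at least two groups")
  if (any(vapply(groups, length, integer(1)) == 0)) stop("empty group")
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 5))
    message("Watson-Williams approximation is unreliable for group n < 5")
  N <- sum(ns)
  r <- length(groups)
  Ri <- vapply(groups, function(g) length(g) * circMeanR(g)$R, numeric(1))
  allPh <- unlist(groups)
  Rtot <- N * circMeanR(allPh)$R
  rw <- sum(Ri) / N
  if (rw < 0.45)
    message("pooled resultant ", round(rw, 3),
            " < 0.45: Watson-Williams assumptions questionable")
  kap <- a1inv(rw)
  K <- 1 + 3 / (8 * kap)
  num <- (N - r) * (sum(Ri) - Rtot)
  den <- (r - 1) * (N - sum(Ri))
  Fstat <- if (den < 1e-12) {
    if (num < 1e-9) 0 else Inf   # fully concentrated groups
  } else K * num / den
  Fstat <- max(Fstat, 0)
  p <- stats::pf(Fstat, r - 1, N - r, lower.tail = FALSE)
  list(F = Fstat, p = p, df1 = r - 1, df2 = N - r, kappa = kap)
}

#' Convert a phase lag to a time delay
#'
#' `delay_ms = (lag_deg / 360) * (1000 / freq_hz)`: a full cycle at the
#' oscillation frequency corresponds to one period. At 20 Hz, lags of 57 and
#' 42 degrees correspond to delays of 7.9 and 5.8 ms.
#'
#' @param lagDeg phase lag in degrees.
#' @param freqHz oscillation frequency in Hz (positive).
#' @return Delay in milliseconds.
#' @examples
#' phaseToDelay(57, 20)  # 7.9 ms
#' @export
phaseToDelay <- function(lagDeg, freqHz) {
  if (any(freqHz <= 0)) stop("frequency must be positive")
  (lagDeg / 360) * (1000 / freqHz)
}
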