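# Internal numerics shared across modules.

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
# the caller's RNG state afterwards so generators are pure in (config, seed).
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Analytic signal via the frequency-domain Hilbert construction.
analyticSignal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Hann window (periodic form, as used for averaged modified periodograms).
hannWindow <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)

# Averaged modified periodogram (Hann, 50% overlap) of one or two signals.
# Returns one-sided per-bin power scaled so sum(power) tracks the variance;
# for two inputs additionally the averaged cross-spectrum. Segment means are
# removed before windowing.
welchSpectra <- function(x, y = NULL, fs, nfft) {
  n <- length(x)
  if (n < nfft) stop("signal shorter than one ", nfft, "-point segment")
  step <- nfft %/% 2
  starts <- seq(1L, n - nfft + 1L, by = step)
  w <- hannWindow(nfft)
  U <- sum(w^2)
  nb <- nfft %/% 2 + 1L
  pxx <- numeric(nb)
  pyy <- if (!is.null(y)) numeric(nb)
  pxy <- if (!is.null(y)) complex(nb)
  for (s in starts) {
    seg <- x[s:(s + nfft - 1L)]
    X <- stats::fft(w * (seg - mean(seg)))[1:nb]
    pxx <- pxx + Mod(X)^2
    if (!is.null(y)) {
      segy <- y[s:(s + nfft - 1L)]
      Y <- stats::fft(w * (segy - mean(segy)))[1:nb]
      pyy <- pyy + Mod(Y)^2
      pxy <- pxy + X * Conj(Y)
    }
  }
  k <- length(starts)
  # one-sided doubling except DC and Nyquist; per-bin power P = 2|X|^2/(N U)
  # (rectangular window: U = N, so a full-scale cosine gives A^2/2 and the
  # sum over bins equals the mean square -- Parseval bookkeeping).
  dbl <- c(1, rep(2, nb - 2L), if (nfft %% 2 == 0) 1 else 2)[1:nb]
  out <- list(freq = (0:(nb - 1L)) * fs / nfft,
              pxx = pxx * dbl / (k * nfft * U),
              nSegments = k)
  if (!is.null(y)) {
    out$pyy <- pyy * dbl / (k * nfft * U)
    # magnitude-squared coherence from the raw segment sums (scalings cancel)
    out$coherence <- Mod(pxy)^2 /
      pmax(pxx * pyy, .Machine$double.xmin)
  }
  out
}

# Run-length encode a logical vector into (start, end) index pairs of TRUE runs.
trueRuns <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

# Linear interpolation of a tabulated function at x0 (assumes x ascending).
interpAt <- function(x, yv, x0) stats::approx(x, yv, xout = x0, rule = 2)$y

# Trapezoid-rule integral of y over x.
trapz <- function(x, yv) sum(diff(x) * (head(yv, -1) + tail(yv, -1)) / 2)

degToRad <- function(d) d * pi / 180
radToDeg <- function(r) {
  d <- r * 180 / pi
  d %% 360
}
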