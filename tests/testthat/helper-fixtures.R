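# Shared fixtures built in code.

FS <- 500

# a sampled tone (open interval start so the length is exactly dur*fs)
tone <- function(freqHz, durS, fs = FS, amp = 1, phase = 0) {
  t <- seq_len(durS * fs) / fs
  continuousSignal(amp * sin(2 * pi * freqHz * t + phase), fs = fs)
}

# phase ramp of a perfect oscillation at freqHz, degrees in [0, 360)
phaseRamp <- function(freqHz, durS, fs = FS) {
  t <- (seq_len(durS * fs) - 1) / fs
  continuousSignal((360 * freqHz * t) %% 360, fs = fs)
}

# von Mises sampler (rejection from uniform), degrees
rvonmises <- function(n, muDeg, kappa) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::runif(2 * n, 0, 360)
    u <- stats::runif(2 * n)
    out <- c(out, x[u < exp(kappa * (cos((x - muDeg) * pi / 180) - 1))])
  }
  out[seq_len(n)]
}

# independent per-event loop oracle for PSTH counts
psthOracle <- function(times, onsets, edges) {
  counts <- numeric(length(edges) - 1)
  for (on in onsets)
    for (s in times) {
      rel <- s - on
      for (b in seq_len(length(edges) - 1))
        if (rel >= edges[b] && rel < edges[b + 1])
          counts[b] <- counts[b] + 1
    }
  counts
}

# independent brute-force resultant-vector oracle
resultantOracle <- function(phasesDeg) {
  sx <- 0; sy <- 0
  for (p in phasesDeg) {
    sx <- sx + cos(p * pi / 180)
    sy <- sy + sin(p * pi / 180)
  }
  list(R = sqrt(sx^2 + sy^2) / length(phasesDeg),
       angle = (atan2(sy, sx) * 180 / pi) %% 360)
}
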