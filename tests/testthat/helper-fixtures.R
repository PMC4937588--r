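# shared fixtures: built in code, no files

default_params <- function(...) waveform_params(...)

# triangular pulse: baseline 0, linear rise from `onset`, shallower linear decay
triangular_curve <- function(n = 100, cycle = 1000, onset = 100,
                             rise_end = 250, decay_end = 600, slope = 2) {
  t <- (0:(n - 1)) * cycle / n
  f <- numeric(n)
  ris <- t >= onset & t < rise_end
  f[ris] <- (t[ris] - onset) * slope
  peak <- (rise_end - onset) * slope
  dec <- t >= rise_end & t < decay_end
  f[dec] <- peak * (1 - (t[dec] - rise_end) / (decay_end - rise_end))
  flow_curve(t, f, cycle)
}

# circularly shift a flow curve right by `k` samples
shift_curve <- function(curve, k) {
  n <- nrow(curve)
  k <- k %% n
  idx <- c((n - k + 1):n, seq_len(n - k))
  if (k == 0) idx <- seq_len(n)
  flow_curve(curve$time_ms, curve$flow_ml_s[idx], cycle_ms(curve))
}

# single-harmonic amplitude of a uniform curve (two-sided -> physical amplitude)
harmonic_amplitude <- function(curve, k) {
  s <- stats::fft(curve$flow_ml_s) / nrow(curve)
  2 * Mod(s[k + 1])
}
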