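# shared fixtures built in code

# raised-cosine (Hann) angular-velocity pulse, peak deg/s, support dur_s
hann_pulse <- function(dur_s, peak, fs) {
  k <- round(dur_s * fs)
  tt <- (seq_len(k) - 0.5) / k
  peak * 0.5 * (1 - cos(2 * pi * tt))
}

# zero trace with one planted pulse starting at frame `at`
planted_trace <- function(n, at, dur_s, peak, fs = 60) {
  x <- numeric(n)
  p <- hann_pulse(dur_s, peak, fs)
  x[at:(at + length(p) - 1)] <- p
  x
}

# circular distance between two angles, degrees
ang_dist <- function(a, b, period = 360) {
  abs(((a - b + period / 2) %% period) - period / 2)
}

# sampled circular-arc path of radius R at constant speed v (mm/s)
circle_path <- function(R, v, fs, n) {
  omega <- v / R
  tt <- (seq_len(n) - 1) / fs
  list(x = R * cos(omega * tt), y = R * sin(omega * tt))
}

# trapezoidal integral reference
.trapz_ref <- function(y) sum((y[-1] + y[-length(y)]) / 2)
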