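# independent oracles and small fixture builders shared across test files

# direct time-domain Morlet transform: literal truncated convolution sum,
# no FFT anywhere; mirrors only the mathematical definition
slow_cwt <- function(x, fs, cfg) {
  dt <- 1 / fs
  n <- length(x)
  ff <- 4 * pi / (cfg$omega0 + sqrt(2 + cfg$omega0^2))
  spo <- cfg$scales_per_octave
  j_max <- floor(spo * log2(cfg$period_max_s / cfg$period_min_s))
  scales <- (cfg$period_min_s / ff) * 2^((0:j_max) / spo)
  xd <- x - mean(x)
  w <- matrix(0i, nrow = n, ncol = length(scales))
  for (j in seq_along(scales)) {
    s <- scales[j]
    k_half <- min(ceiling(6 * s / dt), n - 1L)
    offs <- -k_half:k_half
    eta <- offs * dt / s
    h <- sqrt(dt / s) * Conj(pi^(-0.25) * exp(1i * cfg$omega0 * eta) *
                               exp(-eta^2 / 2))
    for (t in seq_len(n)) {
      src <- t + offs
      ok <- src >= 1L & src <= n
      w[t, j] <- sum(xd[src[ok]] * h[ok])
    }
  }
  list(coefficients = w, scales = scales, periods = scales * ff)
}

# literal Benjamini-Hochberg step-up loop
slow_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# hand paired t on subject-wise mode differences
slow_paired_t <- function(d) {
  n <- length(d)
  tt <- mean(d) / (sd(d) / sqrt(n))
  list(t = tt, p = 2 * pt(-abs(tt), n - 1))
}

# small white-noise norm series
noise_series <- function(n, fs, id = "s", offset = 10) {
  norm_series(rnorm(n) + offset, fs, subject_id = id)
}

# compact wtc config for fast unit tests
small_cfg <- function(period_max_s = 8) {
  wtc_config(period_max_s = period_max_s)
}
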