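# internal helpers shared across modules

.cs_cache <- new.env(parent = emptyenv())

.next_pow2 <- function(n) as.integer(2^ceiling(log2(max(n, 1))))

.check_finite <- function(x, what = "values") {
  bad <- which(!is.finite(x))
  if (length(bad) > 0L) {
    stop(sprintf("non-finite %s (first offending index: %d)", what, bad[1L]),
         call. = FALSE)
  }
  invisible(TRUE)
}

# population standard deviation (divide by n)
.pop_sd <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

.softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  ifelse(x > 30, x, log1p(exp(x)))
}

# exact discretisation of an Ornstein-Uhlenbeck process:
# correlation time tau_s, stationary sd sigma, mean mu; initialised from the
# stationary distribution so paths are strictly stationary
.ou_path <- function(n, dt, tau_s, sigma, mu = 0) {
  a <- exp(-dt / tau_s)
  innov_sd <- sigma * sqrt(1 - a^2)
  z <- numeric(n)
  z[1L] <- mu + sigma * stats::rnorm(1L)
  eps <- stats::rnorm(n - 1L, sd = innov_sd)
  for (k in 2:n) z[k] <- mu + a * (z[k - 1L] - mu) + eps[k - 1L]
  z
}

# FFT-based circular cross-correlation machinery: y(t) = sum_k x(t+k) h(k).
# Builds the spectrum of the flipped kernel so a single complex multiply per
# column implements the correlation.
.kernel_spectrum <- function(h, offsets, pad_n) {
  idx <- ((-offsets) %% pad_n) + 1L
  if (length(h) <= pad_n && !anyDuplicated(idx)) {
    g <- complex(length.out = pad_n)
    g[idx] <- h
  } else {
    # kernel longer than the pad: fold it onto the circle (alias-add);
    # pads are chosen so the folded tail reaching valid outputs is below
    # the kernel's own truncation level
    acc <- rowsum(cbind(Re(h), Im(h)), idx)
    g <- complex(length.out = pad_n)
    g[as.integer(rownames(acc))] <- complex(real = acc[, 1L],
                                            imaginary = acc[, 2L])
  }
  stats::fft(g)
}

.ifft <- function(x) stats::fft(x, inverse = TRUE) / length(x)

.analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  .ifft(X * h)
}
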