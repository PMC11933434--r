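test_that("period/scale conversion and spectral peak localisation", {
  expect_equal(round(morlet_fourier_factor(6), 4), 1.0330)

  fs <- 25; n <- 40 * fs
  t <- (0:(n - 1)) / fs
  cfg <- small_cfg()
  spec <- cwt_morlet(norm_series(sin(2 * pi * t / 2), fs), cfg)
  pw <- colMeans(Mod(spec$coefficients)^2)
  pk <- spec$periods[which.max(pw)]
  expect_equal(pk, spec$periods[which.min(abs(spec$periods - 2))])

  zero <- cwt_morlet(norm_series(numeric(n), fs), cfg)
  expect_equal(max(Mod(zero$coefficients)), 0)

  expect_error(cwt_morlet(norm_series(numeric(0), fs), cfg), "empty")
  expect_warning(cwt_morlet(norm_series(rnorm(100), fs), small_cfg(32)),
                 "truncated")
})

test_that("CWT coefficients equal the direct time-domain convolution oracle", {
  set.seed(21)
  fs <- 50
  x <- rnorm(512)
  cfg <- wtc_config(period_min_s = 0.5, period_max_s = 5)
  got <- cwt_morlet(norm_series(x, fs), cfg)
  want <- slow_cwt(x, fs, cfg)
  expect_equal(got$periods, want$periods, tolerance = 1e-12)
  for (j in seq_along(got$periods)) {
    ref <- max(Mod(want$coefficients[, j]))
    expect_lt(max(Mod(got$coefficients[, j] - want$coefficients[, j])) / ref,
              1e-8)
  }
})

test_that("self-coherence is 1 at powered points and wtc is symmetric", {
  set.seed(22)
  fs <- 25; n <- 50 * fs
  cfg <- small_cfg()
  x <- noise_series(n, fs, "x")
  y <- noise_series(n, fs, "y")
  wx <- cwt_morlet(x, cfg); wy <- cwt_morlet(y, cfg)

  self <- wtc(wx, wx, cfg)
  adm <- outer(self$coi, self$periods, ">")
  expect_lt(max(abs(self$r2[adm] - 1)), 1e-6)

  m1 <- wtc(wx, wy, cfg); m2 <- wtc(wy, wx, cfg)
  expect_lt(max(abs(m1$r2 - m2$r2)), 1e-12)

  # amplitude invariance and [0,1] bounds
  x3 <- x; x3$values <- 7.3 * x3$values
  m3 <- wtc(cwt_morlet(x3, cfg), wy, cfg)
  expect_lt(max(abs(m3$r2 - m1$r2)), 1e-9)
  expect_true(all(m1$r2 >= 0 & m1$r2 <= 1))
  expect_lt(m1$max_excursion, 1e-6)
})

test_that("coherence tolerates sub-period lags and detects shared bands", {
  set.seed(23)
  fs <- 25; n <- 120 * fs
  cfg <- wtc_config(period_max_s = 16)
  base <- morlet_bandpass(rnorm(n), fs, c(7, 9))
  x <- norm_series(base + 10, fs, subject_id = "x")
  lag <- round(0.1 * fs)
  y <- norm_series(c(rep(base[1], lag), base[1:(n - lag)]) + 10, fs,
                   subject_id = "y")
  m <- wtc(cwt_morlet(x, cfg), cwt_morlet(y, cfg), cfg)
  j8 <- which.min(abs(m$periods - 8))
  adm <- m$coi > m$periods[j8]
  expect_gt(mean(m$r2[adm, j8]), 0.9)
})

test_that("grand-mean coherence of independent noise sits in the surrogate band", {
  set.seed(24)
  fs <- 25; n <- 60 * fs
  cfg <- small_cfg()
  grand_mean <- function(seed_a, seed_b) {
    set.seed(seed_a); a <- noise_series(n, fs, "a")
    set.seed(seed_b); b <- noise_series(n, fs, "b")
    m <- wtc(cwt_morlet(a, cfg), cwt_morlet(b, cfg), cfg)
    adm <- outer(m$coi, m$periods, ">")
    mean(m$r2[adm])
  }
  surro <- vapply(1:100, function(k) grand_mean(1000 + k, 2000 + k),
                  numeric(1))
  test_val <- grand_mean(5001, 5002)
  expect_gt(test_val, quantile(surro, 0.025))
  expect_lt(test_val, quantile(surro, 0.975))
})

test_that("profiles match a scalar-loop oracle and honour the COI policy", {
  set.seed(25)
  n <- 400
  periods <- c(1, 2, 4)
  coi <- c(seq(0, 5, length.out = n / 2), seq(5, 0, length.out = n / 2))
  r2 <- matrix(runif(n * 3), n, 3)
  map <- structure(list(r2 = r2, periods = periods, coi = coi, fs = 10),
                   class = "cs_coherence_map")
  prof <- coherence_profile(map, wtc_config(coi_policy = "exclude"))
  for (j in seq_along(periods)) {
    idx <- which(coi > periods[j])
    expect_equal(prof$mean_r2[j], mean(r2[idx, j]), tolerance = 1e-12)
    expect_equal(prof$sd_r2[j], sqrt(mean((r2[idx, j] - mean(r2[idx, j]))^2)),
                 tolerance = 1e-12)
    expect_equal(prof$n_times_used[j], length(idx))
  }

  const <- map; const$r2 <- matrix(0.37, n, 3)
  pc <- coherence_profile(const, wtc_config(coi_policy = "include"))
  expect_equal(pc$mean_r2, rep(0.37, 3))
  expect_equal(pc$sd_r2, rep(0, 3))

  alt <- map; alt$r2 <- matrix(rep(c(0, 1), length.out = n), n, 3)
  pa <- coherence_profile(alt, wtc_config(coi_policy = "include"))
  expect_equal(pa$mean_r2, rep(0.5, 3))
  expect_equal(pa$sd_r2, rep(0.5, 3))

  hi <- map; hi$periods <- c(1, 2, 10)  # 10 s never inside this coi
  expect_warning(ph <- coherence_profile(hi, wtc_config()), "dropped")
  expect_equal(nrow(ph), 2)
})

test_that("P-A aggregation averages pair profiles across performers", {
  set.seed(26)
  fs <- 20; n <- 40 * fs
  cfg <- small_cfg()
  p1 <- noise_series(n, fs, "P01"); p2 <- noise_series(n, fs, "P02")
  a1 <- noise_series(n, fs, "A01")
  got <- pa_profiles(list(p1, p2), list(a1), cfg)[["A01"]]
  pr1 <- coherence_profile(wtc(cwt_morlet(p1, cfg), cwt_morlet(a1, cfg), cfg), cfg)
  pr2 <- coherence_profile(wtc(cwt_morlet(p2, cfg), cwt_morlet(a1, cfg), cfg), cfg)
  expect_equal(got$mean_r2, (pr1$mean_r2 + pr2$mean_r2) / 2, tolerance = 1e-12)
  expect_equal(got$sd_r2, (pr1$sd_r2 + pr2$sd_r2) / 2, tolerance = 1e-12)

  # single performer: identity passthrough
  solo <- pa_profiles(list(p1), list(a1), cfg)[["A01"]]
  expect_equal(solo$mean_r2, pr1$mean_r2, tolerance = 1e-12)

  # identical performers: equals the single-pair profile
  same <- pa_profiles(list(p1, p1, p1), list(a1), cfg)[["A01"]]
  expect_equal(same$mean_r2, pr1$mean_r2, tolerance = 1e-12)
})

test_that("A-A aggregation equals the brute-force all-pairs average", {
  set.seed(27)
  fs <- 20; n <- 40 * fs
  cfg <- small_cfg()
  ss <- lapply(1:3, function(i) noise_series(n, fs, sprintf("A%02d", i)))
  got <- aa_profiles(ss, cfg)
  pair_prof <- function(i, j) {
    coherence_profile(wtc(cwt_morlet(ss[[i]], cfg), cwt_morlet(ss[[j]], cfg),
                          cfg), cfg)
  }
  p12 <- pair_prof(1, 2); p13 <- pair_prof(1, 3); p23 <- pair_prof(2, 3)
  expect_lt(max(abs(got[["A01"]]$mean_r2 - (p12$mean_r2 + p13$mean_r2) / 2)),
            1e-12)
  expect_lt(max(abs(got[["A02"]]$mean_r2 - (p12$mean_r2 + p23$mean_r2) / 2)),
            1e-12)
  expect_lt(max(abs(got[["A03"]]$mean_r2 - (p13$mean_r2 + p23$mean_r2) / 2)),
            1e-12)
  expect_error(aa_profiles(ss[1], cfg), ">= 2")

  # two members: both get the single-pair profile
  two <- aa_profiles(ss[1:2], cfg)
  expect_equal(two[["A01"]]$mean_r2, two[["A02"]]$mean_r2)

  # identical members: coherence 1 at powered scales
  same <- aa_profiles(list(ss[[1]], ss[[1]], ss[[1]]), cfg)
  expect_lt(max(abs(same[["A01"]]$mean_r2 - 1)), 1e-6)
})
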