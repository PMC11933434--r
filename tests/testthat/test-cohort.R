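small_config <- function(seed = 1, n_aud = 3) {
  cohort_config(n_aud, 1, pieces = "Mozart", duration_s = 70, fs = 25,
                seed = seed)
}

test_that("identical seeds give byte-identical cohorts on disk", {
  truth <- synthetic_truth()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  c1 <- suppressWarnings(gen_cohort(small_config(5), truth))
  c2 <- suppressWarnings(gen_cohort(small_config(5), truth))
  write_cohort(c1, d1)
  write_cohort(c2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  c3 <- suppressWarnings(gen_cohort(small_config(6), truth))
  expect_false(identical(c1$recordings[[1]]$ax, c3$recordings[[1]]$ax))
})

test_that("cohort directory round-trips through the CSV dialect", {
  truth <- synthetic_truth()
  coh <- suppressWarnings(gen_cohort(small_config(2, n_aud = 2), truth))
  dir <- withr::local_tempdir()
  sv <- gen_sync_var(coh$design, truth, seed = 2)
  rt <- gen_ratings(coh$design, truth, sv, missing_rate = 0.1, seed = 2)
  write_cohort(coh, dir, ratings = rt)
  back <- read_cohort(dir)
  expect_equal(nrow(back$design), nrow(coh$design))
  k <- names(coh$recordings)[1]
  expect_lt(max(abs(back$recordings[[k]]$az - coh$recordings[[k]]$az)), 1e-5)
  rt_back <- read.csv(file.path(dir, "ratings.csv"))
  expect_equal(sum(is.na(rt_back[, rating_items()])),
               sum(is.na(rt[, rating_items()])))
})

test_that("doubling the white-noise SD doubles the noise residual", {
  mk <- function(nsd) {
    suppressWarnings(gen_cohort(small_config(3),
                                synthetic_truth(noise_sd = nsd)))
  }
  c1 <- mk(1); c2 <- mk(2); c4 <- mk(4)
  key <- grep("^A01", names(c1$recordings), value = TRUE)[1]
  d12 <- c2$recordings[[key]]$ax - c1$recordings[[key]]$ax
  d24 <- c4$recordings[[key]]$ax - c2$recordings[[key]]$ax
  # same seed -> identical noise stream, so the increments scale exactly
  expect_equal(sd(d24) / sd(d12), 2, tolerance = 1e-9)
})

test_that("design satisfies the performance-order and invariant structure", {
  cfg <- cohort_config(5, 4, seed = 1)
  des <- performance_design(cfg)
  expect_equal(nrow(des), 9 * 4)
  aud <- des[des$role == "audience", ]
  expect_true(all(table(aud$subject_id) == 4))
  ord <- unique(des[, c("piece", "mode", "order")])
  ord <- ord[order(ord$order), ]
  expect_equal(ord$mode, c("Strict", "Let-go", "Let-go", "Strict"))

  expect_error(cohort_config(0, 4), "n_audience")
  expect_error(synthetic_truth(alpha_beat = -1), "alpha_beat")
  expect_error(synthetic_truth(noise_sd = NaN), "non-finite")
  expect_error(synthetic_truth(breath_period_s = 6), "breath_period")
  short_cfg <- cohort_config(2, 1, pieces = "Mozart", duration_s = 50,
                             fs = 25, seed = 1)
  w <- capture_warnings(gen_cohort(short_cfg, synthetic_truth()))
  expect_true(any(grepl("4x the longest gesture period", w)))
})

test_that("strong breathing concentration drives pairwise PLV towards 1", {
  cfg <- cohort_config(5, 1, pieces = "Mozart", duration_s = 110, fs = 50,
                       seed = 9)
  coh <- gen_cohort(cfg, synthetic_truth(breath_kappa = 1000))
  recs <- coh$recordings[vapply(coh$recordings, function(r) {
    r$role == "audience" && r$mode == "Strict"
  }, logical(1))]
  breaths <- lapply(recs, reconstruct_breathing)
  expect_gt(mean(mean_pairwise_plv(breaths)), 0.95)
})

test_that("ratings generator plants monotone loadings and associations", {
  truth <- synthetic_truth()
  design <- performance_design(cohort_config(20, 2, seed = 3))
  sv <- gen_sync_var(design, truth, seed = 3)

  # unit latent mode shift with no noise: every subject rates higher in Let-go
  rt <- gen_ratings(design, synthetic_truth(rating_gamma = 0), sv,
                    mode_mu = c(Strict = 0, "Let-go" = 1), subject_sd = 0.3,
                    noise_sd = 0, item_noise_sd = 0, seed = 4)
  sm <- tapply(rt$improvisatory, list(rt$subject_id, rt$mode), mean)
  expect_true(all(sm[, "Let-go"] > sm[, "Strict"]))

  # gamma = 0, equal means, zero noise: items constant within subject
  rt0 <- gen_ratings(design, synthetic_truth(rating_gamma = 0), sv,
                     mode_mu = c(Strict = 0, "Let-go" = 0), subject_sd = 0.5,
                     noise_sd = 0, item_noise_sd = 0, seed = 5)
  wvar <- tapply(rt0$improvisatory, rt0$subject_id, var)
  expect_equal(max(wvar), 0)

  # perfectly linear latent without discretisation: rm-correlation is 1
  rt1 <- gen_ratings(design, truth, sv,
                     mode_mu = c(Strict = 0, "Let-go" = 0), subject_sd = 1,
                     noise_sd = 0, item_noise_sd = 0, discretize = FALSE,
                     seed = 6)
  aud <- design$role == "audience"
  rc <- rm_corr(rt1$improvisatory, sv[aud], rt1$subject_id)
  expect_equal(rc$r, 1, tolerance = 1e-9)

  expect_error(gen_ratings(design, truth, sv, missing_rate = 0.5),
               "missingness")
  expect_error(gen_ratings(design, truth, sv[-1]), "length")
})

test_that("an uncoupled cohort is indistinguishable from independent pairs", {
  # alpha_beat = alpha_slow = 0 and kappa = 0: within-cohort performer-audience
  # pairs must match cross-cohort surrogate pairs scale by scale
  truth <- synthetic_truth(alpha_beat = 0, alpha_slow = 0, breath_kappa = 0)
  cfg <- wtc_config(period_max_s = 8)
  fs <- 20
  pair_profile <- function(seed, cross_seed = NULL) {
    c1 <- gen_cohort(cohort_config(1, 1, pieces = "M", duration_s = 60,
                                   fs = fs, seed = seed), truth)
    perf <- c1$recordings[[grep("^P01__M__Strict", names(c1$recordings))]]
    aud_src <- if (is.null(cross_seed)) c1 else {
      gen_cohort(cohort_config(1, 1, pieces = "M", duration_s = 60,
                               fs = fs, seed = cross_seed), truth)
    }
    aud <- aud_src$recordings[[grep("^A01__M__Strict",
                                    names(aud_src$recordings))]]
    to_s <- function(r) accel_norm(r)
    m <- wtc(cwt_morlet(to_s(perf), cfg), cwt_morlet(to_s(aud), cfg), cfg)
    coherence_profile(m, cfg)$mean_r2
  }
  surro <- suppressWarnings(
    sapply(1:52, function(k) pair_profile(3000 + k, 4000 + k)))
  within <- suppressWarnings(sapply(1:20, function(k) pair_profile(5000 + k)))
  lo <- apply(surro, 1, quantile, 0.025)
  hi <- apply(surro, 1, quantile, 0.975)
  outside <- mean(within < lo | within > hi)
  # nominal 5% of (pair, scale) combinations fall outside the band
  expect_lt(outside, 0.12)
})
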