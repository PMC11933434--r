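make_ratings <- function(n = 24, seed = 51) {
  set.seed(seed)
  items <- matrix(sample(0:5, n * 7, replace = TRUE), n, 7,
                  dimnames = list(NULL, rating_items()))
  cbind(data.frame(subject_id = sprintf("A%02d", rep(1:(n / 4), each = 4)),
                   piece = rep(c("Mozart", "Mozart", "Haydn", "Haydn"), n / 4),
                   mode = rep(c("Strict", "Let-go"), n / 2)),
        as.data.frame(items))
}

test_that("imputation is an identity on complete tables and is seeded", {
  rt <- make_ratings()
  out <- impute_ratings(rt, seed = 1)
  expect_equal(out[, rating_items()], rt[, rating_items()])

  rt2 <- rt
  rt2$engaging[c(3, 11)] <- NA
  a <- impute_ratings(rt2, seed = 7)
  b <- impute_ratings(rt2, seed = 7)
  expect_identical(a, b)
  expect_true(all(a$engaging %in% 0:5))
  expect_equal(sum(attr(a, "imputed_mask")), 2)

  rt3 <- rt
  rt3$sleepy[] <- NA
  expect_error(impute_ratings(rt3), "entirely missing")
})

test_that("a duplicated column pins the imputed value", {
  set.seed(52)
  n <- 40
  base <- sample(0:5, n, replace = TRUE, prob = c(1, 2, 3, 3, 2, 1))
  rt <- make_ratings(n)
  rt$improvisatory <- base
  rt$innovative <- base  # exact duplicate
  miss_row <- which(base == 2)[1]
  rt$improvisatory[miss_row] <- NA
  out <- impute_ratings(rt, seed = 3)
  expect_equal(out$improvisatory[miss_row], 2)
})

test_that("ratings PCA matches the two-block closed form", {
  # two groups of perfectly correlated items: standardised covariance is a
  # rank-2 block matrix whose leading eigenvalue is (7 + sqrt(1 + 48 r^2))/2
  x1 <- c(0, 1, 2, 3, 4, 5, 1, 3)
  x2 <- c(0, 2, 1, 3, 5, 4, 2, 3)
  r <- cor(scale(x1), scale(x2))[1]
  rt <- make_ratings(8)
  for (it in c("improvisatory", "innovative", "risktaking", "engaging")) {
    rt[[it]] <- x1
  }
  for (it in c("convincing", "familiar", "sleepy")) rt[[it]] <- x2
  pc <- pca_ratings(rt)
  lambda1 <- (7 + sqrt(1 + 48 * r^2)) / 2
  expect_equal(pc$explained_variance[1], lambda1 / 7, tolerance = 1e-9)
  expect_equal(sum(pc$explained_variance), 1, tolerance = 1e-9)
  expect_gt(pc$loadings["improvisatory", 1], 0)

  # reconstruction: scores %*% t(loadings) returns the standardised data
  zs <- scale(as.matrix(rt[, rating_items()]))
  recon <- pc$scores %*% t(pc$loadings)
  expect_lt(max(abs(recon - zs)), 1e-9)

  rt$familiar <- 3
  expect_error(pca_ratings(rt), "familiar")
})

test_that("mode model recovers a noise-free planted difference exactly", {
  design <- performance_design(cohort_config(10, 1, seed = 1))
  aud <- design[design$role == "audience", ]
  dv <- 10 + 1 * ifelse(aud$mode == "Let-go", 0.5, -0.5)
  fit <- suppressWarnings(fit_mode_model(dv, aud))
  mode_row <- fit$effects[fit$effects$term == "M", ]
  expect_equal(mode_row$estimate, 1, tolerance = 1e-9)
  expect_lt(mode_row$p, 1e-6)

  flat <- suppressWarnings(fit_mode_model(rep(3, nrow(aud)), aud))
  expect_lt(max(abs(flat$effects$estimate)), 1e-9)
})

test_that("mode model matches the subject-mean contrast and reports R2", {
  set.seed(53)
  design <- performance_design(cohort_config(16, 1, seed = 1))
  aud <- design[design$role == "audience", ]
  b <- rnorm(16, sd = 0.6)
  names(b) <- unique(aud$subject_id)
  dv <- 2 + b[aud$subject_id] + 0.4 * ifelse(aud$mode == "Let-go", 0.5, -0.5) +
    rnorm(nrow(aud), sd = 0.3)
  fit <- suppressWarnings(fit_mode_model(dv, aud))
  mode_row <- fit$effects[fit$effects$term == "M", ]
  sm <- tapply(dv, list(aud$subject_id, aud$mode), mean)
  expect_equal(mode_row$estimate, mean(sm[, "Let-go"] - sm[, "Strict"]),
               tolerance = 1e-6)
  if (fit$engine != "lm") {
    expect_gte(fit$r2_conditional, fit$r2_marginal)
  }
})

test_that("the absorption covariate model recovers planted slopes", {
  set.seed(55)
  design <- performance_design(cohort_config(20, 1, seed = 1))
  aud <- design[design$role == "audience", ]
  absorption <- setNames(rnorm(20, 3, 1), unique(aud$subject_id))
  dv <- 1 + 0.8 * scale(absorption[aud$subject_id])[, 1] +
    0.5 * ifelse(aud$mode == "Let-go", 0.5, -0.5) +
    rnorm(nrow(aud), 0, 0.3)
  fit <- suppressWarnings(
    fit_mode_model(dv, aud, covariate = absorption[aud$subject_id]))
  eff <- fit$effects
  expect_equal(eff$estimate[eff$term == "A"], 0.8, tolerance = 0.25)
  expect_equal(eff$estimate[eff$term == "M"], 0.5, tolerance = 0.2)
  expect_lt(eff$p[eff$term == "A"], 0.001)
  expect_lt(eff$p[eff$term == "M"], 0.001)
})

test_that("planted mode shifts on ratings are recovered with high power", {
  design <- performance_design(cohort_config(40, 1, seed = 1))
  truth <- synthetic_truth(rating_gamma = 0)
  signs <- vapply(1:50, function(s) {
    rt <- gen_ratings(design, truth, rep(0, nrow(design)),
                      mode_mu = c(Strict = 0, "Let-go" = 0.8),
                      noise_sd = 1, seed = s)
    sm <- tapply(rt$improvisatory, list(rt$subject_id, rt$mode), mean)
    sign(mean(sm[, "Let-go"] - sm[, "Strict"]))
  }, numeric(1))
  expect_gte(mean(signs > 0), 0.95)
})

test_that("repeated-measures correlation matches the hand oracle", {
  rating <- c(1, 2, 3, 4,  11, 12, 13, 14,  5, 6, 8, 7)
  sync <- c(0.1, 0.2, 0.3, 0.4,  0.5, 0.6, 0.7, 0.8,  0.1, 0.3, 0.2, 0.4)
  ids <- rep(c("a", "b", "c"), each = 4)
  got <- rm_corr(rating, sync, ids)
  rc <- rating - ave(rating, ids)
  sc <- sync - ave(sync, ids)
  r <- cor(rc, sc)
  expect_equal(got$r, r, tolerance = 1e-12)
  expect_equal(got$df, 12 - 3 - 1)
  expect_equal(got$t, r * sqrt(got$df / (1 - r^2)), tolerance = 1e-12)

  # invariance to per-subject offsets
  shift <- rating + rep(c(100, -50, 3), each = 4)
  expect_equal(rm_corr(shift, sync, ids)$r, got$r, tolerance = 1e-12)

  # subject-specific offsets only: r = 1 when within-subject identical
  expect_equal(rm_corr(sync + rep(c(5, 9, -2), each = 4), sync, ids)$r, 1,
               tolerance = 1e-12)

  expect_error(rm_corr(rep(1, 12), sync, ids), "zero within-subject")
})

test_that("rm-corr type-I error is nominal under within-subject permutation", {
  set.seed(54)
  k <- 20; per <- 4
  ids <- rep(sprintf("s%02d", 1:k), each = per)
  sync <- rnorm(k * per)
  rating <- rnorm(k * per)
  rej <- vapply(1:1000, function(i) {
    perm <- unlist(lapply(split(seq_along(ids), ids), sample))
    rm_corr(rating[perm], sync, ids)$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})
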