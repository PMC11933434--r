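#' Configuration for Morlet wavelet-coherence analysis
#'
#' Holds the parameters of the continuous wavelet transform and of the
#' wavelet-transform-coherence smoothing operator. The defaults follow the
#' standard Morlet analysis of movement data: centre frequency
#' \code{omega0 = 6} (near-equal scale and Fourier period), a dyadic scale
#' grid with 12 voices per octave, and Fourier periods from 0.5 s to 32 s.
#'
#' @param omega0 Morlet centre frequency (dimensionless).
#' @param scales_per_octave number of voices per octave of the dyadic grid.
#' @param period_min_s,period_max_s bounds of the Fourier-period grid, in
#'   seconds. Periods below 0.5 s are conventionally excluded as having no
#'   musically meaningful counterpart.
#' @param time_smooth_sd_scales SD of the Gaussian time-smoothing kernel, in
#'   units of the wavelet scale (default 1: SD equals the scale in seconds).
#' @param scale_smooth_octaves width of the boxcar scale-smoothing window in
#'   octaves (default 0.6, the Morlet decorrelation length).
#' @param coi_policy \code{"exclude"} (default) drops time samples inside the
#'   cone of influence from time-averaged summaries; \code{"include"} keeps
#'   them.
#' @return An object of class \code{cs_wtc_config}.
#' @export
wtc_config <- function(omega0 = 6, scales_per_octave = 12,
                       period_min_s = 0.5, period_max_s = 32,
                       time_smooth_sd_scales = 1, scale_smooth_octaves = 0.6,
                       coi_policy = c("exclude", "include")) {
  coi_policy <- match.arg(coi_policy)
  stopifnot(period_min_s > 0, period_min_s < period_max_s,
            scales_per_octave >= 1, omega0 > 0,
            time_smooth_sd_scales > 0, scale_smooth_octaves > 0)
  structure(list(omega0 = omega0, scales_per_octave = scales_per_octave,
                 period_min_s = period_min_s, period_max_s = period_max_s,
                 time_smooth_sd_scales = time_smooth_sd_scales,
                 scale_smooth_octaves = scale_smooth_octaves,
                 coi_policy = coi_policy),
            class = "cs_wtc_config")
}

#' Fourier period per unit Morlet scale
#'
#' @param omega0 Morlet centre frequency.
#' @return The factor converting scale to Fourier period,
#'   \code{4*pi / (omega0 + sqrt(2 + omega0^2))} (about 1.0330 for
#'   \code{omega0 = 6}).
#' @export
morlet_fourier_factor <- function(omega0 = 6) {
  4 * pi / (omega0 + sqrt(2 + omega0^2))
}

# dyadic scale grid for a given config and record length; truncates the upper
# period bound (with a warning) when the record is shorter than twice the
# largest requested period
.wtc_scales <- function(n, dt, cfg) {
  ff <- morlet_fourier_factor(cfg$omega0)
  pmax_eff <- cfg$period_max_s
  if (n * dt < 2 * cfg$period_max_s) {
    pmax_eff <- n * dt / 2
    warning(sprintf(
      "record too short for period_max_s = %g; period grid truncated at %g s",
      cfg$period_max_s, pmax_eff), call. = FALSE)
    if (pmax_eff <= cfg$period_min_s) {
      stop("record too short for the requested minimum period", call. = FALSE)
    }
  }
  spo <- cfg$scales_per_octave
  j_max <- floor(spo * log2(pmax_eff / cfg$period_min_s))
  scales <- (cfg$period_min_s / ff) * 2^((0:j_max) / spo)
  list(scales = scales, periods = scales * ff, fourier_factor = ff)
}

# FFT spectra of the sampled, 6-sigma-truncated Morlet daughter wavelets,
# cached per (n, dt, grid) so batch analyses pay the construction cost once
.morlet_kernels <- function(n, dt, scales, omega0) {
  k_half <- pmin(ceiling(6 * scales / dt), n - 1L)
  # per-scale pad: large enough that any circularly folded kernel tail
  # reaching a valid output sits >= 6 sigma out (the truncation level);
  # scales sharing a pad length are batched into one FFT group
  pad_by_scale <- vapply(seq_along(scales), function(j) {
    .next_pow2(min(n + 2L * k_half[j] + 1L, n + ceiling(6 * scales[j] / dt)))
  }, integer(1))
  key <- paste("morlet", n, signif(dt, 12), signif(omega0, 12),
               length(scales), signif(scales[1L], 12),
               signif(scales[length(scales)], 12), sep = "|")
  hit <- .cs_cache[[key]]
  if (!is.null(hit)) return(hit)
  groups <- lapply(unique(pad_by_scale), function(p) {
    cols <- which(pad_by_scale == p)
    spec <- matrix(0i, nrow = p, ncol = length(cols))
    for (ci in seq_along(cols)) {
      j <- cols[ci]
      s <- scales[j]
      offs <- seq.int(-k_half[j], k_half[j])
      eta <- offs * dt / s
      psi <- pi^(-0.25) * exp(1i * omega0 * eta) * exp(-eta^2 / 2)
      spec[, ci] <- .kernel_spectrum(sqrt(dt / s) * Conj(psi), offs, p)
    }
    list(cols = cols, pad_n = p, spectra = spec)
  })
  out <- list(groups = groups, k_half = k_half)
  .cs_cache[[key]] <- out
  out
}

#' Continuous Morlet wavelet transform
#'
#' Computes complex wavelet coefficients of an acceleration-norm series on a
#' dyadic scale grid, together with the Fourier periods and the cone of
#' influence. The series mean is removed before the transform. The transform
#' is the discrete correlation of the signal with the sampled Morlet daughter
#' wavelet \eqn{\psi_0(\eta) = \pi^{-1/4} e^{i\omega_0\eta} e^{-\eta^2/2}},
#' truncated at \eqn{|\eta| > 6} and evaluated by zero-padded FFT convolution
#' (exactly equal to the direct time-domain sum).
#'
#' @param series a \code{\link{norm_series}} (or any list with numeric
#'   \code{values} and \code{fs}).
#' @param cfg a \code{\link{wtc_config}}.
#' @return An object of class \code{cs_wavelet_spectrum}: complex coefficient
#'   matrix (time x scale), \code{scales}, \code{periods} (s), \code{coi}
#'   (maximum valid period per time sample, s), \code{fs}, and provenance
#'   labels carried over from the input.
#' @export
cwt_morlet <- function(series, cfg = wtc_config()) {
  x <- as.numeric(series$values)
  fs <- series$fs
  if (length(x) == 0L) stop("empty series", call. = FALSE)
  .check_finite(x, "series values")
  dt <- 1 / fs
  n <- length(x)
  g <- .wtc_scales(n, dt, cfg)
  ker <- .morlet_kernels(n, dt, g$scales, cfg$omega0)
  xd <- x - mean(x)
  w <- matrix(0i, nrow = n, ncol = length(g$scales))
  for (grp in ker$groups) {
    xpad <- complex(length.out = grp$pad_n)
    xpad[1:n] <- xd
    xf <- stats::fft(xpad)
    wg <- stats::mvfft(xf * grp$spectra, inverse = TRUE) / grp$pad_n
    w[, grp$cols] <- wg[1:n, , drop = FALSE]
  }
  dist <- dt * pmin(seq_len(n) - 1L, n - seq_len(n))
  coi <- g$fourier_factor / sqrt(2) * dist
  structure(list(coefficients = w, scales = g$scales, periods = g$periods,
                 coi = coi, fs = fs, omega0 = cfg$omega0,
                 subject_id = series$subject_id, piece = series$piece,
                 mode = series$mode),
            class = "cs_wavelet_spectrum")
}

#' @export
print.cs_wavelet_spectrum <- function(x, ...) {
  cat(sprintf("Morlet wavelet spectrum: %d samples at %g Hz, %d scales (%.3g-%.3g s)\n",
              nrow(x$coefficients), x$fs, length(x$periods),
              min(x$periods), max(x$periods)))
  invisible(x)
}

# Gaussian time smoothing (SD proportional to scale), applied columnwise by
# cached FFT correlation; works for real or complex fields
.time_smooth <- function(m, dt, scales, sd_scales) {
  n <- nrow(m)
  sd_samp <- sd_scales * scales / dt
  k_half <- pmin(pmax(ceiling(4 * sd_samp), 1L), n - 1L)
  pad_by_scale <- vapply(seq_along(scales), function(j) {
    .next_pow2(min(n + 2L * k_half[j] + 1L, n + ceiling(4 * sd_samp[j])))
  }, integer(1))
  key <- paste("tsm", n, signif(dt, 12), signif(sd_scales, 12),
               length(scales), signif(scales[1L], 12),
               signif(scales[length(scales)], 12), sep = "|")
  ker <- .cs_cache[[key]]
  if (is.null(ker)) {
    ker <- lapply(unique(pad_by_scale), function(p) {
      cols <- which(pad_by_scale == p)
      spec <- matrix(0i, nrow = p, ncol = length(cols))
      for (ci in seq_along(cols)) {
        j <- cols[ci]
        offs <- seq.int(-k_half[j], k_half[j])
        h <- exp(-0.5 * (offs / sd_samp[j])^2)
        spec[, ci] <- .kernel_spectrum(h / sum(h), offs, p)
      }
      list(cols = cols, pad_n = p, spectra = spec)
    })
    .cs_cache[[key]] <- ker
  }
  out <- matrix(0i, nrow = n, ncol = ncol(m))
  for (grp in ker) {
    mpad <- matrix(0i, nrow = grp$pad_n, ncol = length(grp$cols))
    mpad[1:n, ] <- m[, grp$cols, drop = FALSE]
    og <- stats::mvfft(stats::mvfft(mpad) * grp$spectra,
                       inverse = TRUE) / grp$pad_n
    out[, grp$cols] <- og[1:n, , drop = FALSE]
  }
  out
}

# boxcar smoothing across scales spanning `octaves` octaves, with fractional
# end weights and edge renormalisation
.scale_smooth <- function(m, scales_per_octave, octaves) {
  ns <- ncol(m)
  key <- paste("ssm", ns, signif(scales_per_octave, 12),
               signif(octaves, 12), sep = "|")
  w_mat <- .cs_cache[[key]]
  if (is.null(w_mat)) {
    halfwidth <- octaves * scales_per_octave / 2
    k <- floor(halfwidth + 0.5)
    offs <- seq.int(-k, k)
    w <- pmin(pmax(halfwidth - (abs(offs) - 0.5), 0), 1)
    w[offs == 0L] <- 1
    w_mat <- matrix(0, ns, ns)
    for (i in seq_along(offs)) {
      src <- seq_len(ns) + offs[i]
      ok <- src >= 1L & src <= ns
      w_mat[cbind(src[ok], seq_len(ns)[ok])] <- w[i]
    }
    w_mat <- sweep(w_mat, 2L, colSums(w_mat), "/")
    .cs_cache[[key]] <- w_mat
  }
  m %*% w_mat
}

.smooth_field <- function(m, spec, cfg) {
  sm <- .time_smooth(m, 1 / spec$fs, spec$scales, cfg$time_smooth_sd_scales)
  .scale_smooth(sm, cfg$scales_per_octave, cfg$scale_smooth_octaves)
}

# smoothed scale-normalised auto-spectrum S(|W|^2 / s); cached computation
# entry point used by wtc() and the profile aggregators
.smoothed_auto <- function(spec, cfg) {
  a <- sweep(Mod(spec$coefficients)^2, 2L, spec$scales, "/")
  Re(.smooth_field(a, spec, cfg))
}

.pair_r2 <- function(spec_x, spec_y, auto_x, auto_y, cfg) {
  cross <- sweep(spec_x$coefficients * Conj(spec_y$coefficients),
                 2L, spec_x$scales, "/")
  num <- Mod(.smooth_field(cross, spec_x, cfg))^2
  den <- auto_x * auto_y
  powered <- den > 1e-12 * max(den, .Machine$double.xmin)
  r2 <- matrix(0, nrow = nrow(num), ncol = ncol(num))
  r2[powered] <- num[powered] / den[powered]
  excursion <- max(0, max(r2) - 1)
  r2[r2 > 1] <- 1
  r2[r2 < 0] <- 0
  list(r2 = r2, powered = powered, excursion = excursion)
}

.check_same_grid <- function(x, y) {
  if (nrow(x$coefficients) != nrow(y$coefficients) ||
      length(x$scales) != length(y$scales) ||
      x$fs != y$fs ||
      max(abs(x$scales - y$scales)) > 1e-12 * max(x$scales)) {
    stop("wavelet spectra are not on identical time and scale grids",
         call. = FALSE)
  }
}

#' Wavelet transform coherence of two series
#'
#' Squared wavelet coherence
#' \deqn{R^2(t,s) = \frac{|S(s^{-1} W^X W^{Y*})|^2}
#'                      {S(s^{-1}|W^X|^2)\, S(s^{-1}|W^Y|^2)}}
#' where \eqn{S} smooths in time (Gaussian with SD equal to the scale) and
#' across scales (boxcar spanning 0.6 octaves). Values are clipped to
#' \eqn{[0,1]}; points with (numerically) zero smoothed power are set to 0 and
#' counted in \code{n_zero_power}.
#'
#' @param x,y \code{cs_wavelet_spectrum} objects on identical grids.
#' @param cfg the \code{\link{wtc_config}} used for the transforms.
#' @return An object of class \code{cs_coherence_map} with fields \code{r2}
#'   (time x scale), \code{periods}, \code{coi}, \code{fs}, pair labels and
#'   \code{n_zero_power}.
#' @export
wtc <- function(x, y, cfg = wtc_config()) {
  .check_same_grid(x, y)
  ax <- .smoothed_auto(x, cfg)
  ay <- .smoothed_auto(y, cfg)
  res <- .pair_r2(x, y, ax, ay, cfg)
  structure(list(r2 = res$r2, periods = x$periods, coi = x$coi, fs = x$fs,
                 x_id = x$subject_id, y_id = y$subject_id,
                 n_zero_power = sum(!res$powered),
                 max_excursion = res$excursion),
            class = "cs_coherence_map")
}

#' @export
print.cs_coherence_map <- function(x, ...) {
  cat(sprintf("wavelet coherence map: %d x %d (time x scale), mean R2 = %.3f\n",
              nrow(x$r2), ncol(x$r2), mean(x$r2)))
  invisible(x)
}

#' Per-scale synchrony profile of a coherence map
#'
#' Time-averages the squared coherence at each scale and records its temporal
#' variability (population SD). Under \code{coi_policy = "exclude"} only time
#' samples whose period lies inside the cone of influence are admitted; scales
#' with no admitted samples are dropped with a warning.
#'
#' @param map a \code{cs_coherence_map}.
#' @param cfg the \code{\link{wtc_config}}.
#' @return A data frame with columns \code{period_s}, \code{mean_r2},
#'   \code{sd_r2} and \code{n_times_used} (class \code{cs_scale_profile}).
#' @export
coherence_profile <- function(map, cfg = wtc_config()) {
  ns <- length(map$periods)
  out <- data.frame(period_s = map$periods,
                    mean_r2 = NA_real_, sd_r2 = NA_real_,
                    n_times_used = 0L)
  for (j in seq_len(ns)) {
    idx <- if (cfg$coi_policy == "exclude") {
      which(map$coi > map$periods[j])
    } else {
      seq_len(nrow(map$r2))
    }
    if (length(idx) > 0L) {
      v <- map$r2[idx, j]
      out$mean_r2[j] <- mean(v)
      out$sd_r2[j] <- .pop_sd(v)
      out$n_times_used[j] <- length(idx)
    }
  }
  dropped <- which(out$n_times_used == 0L)
  if (length(dropped) > 0L) {
    warning(sprintf("%d scale(s) with no admitted time samples dropped (periods %s s)",
                    length(dropped),
                    paste(signif(out$period_s[dropped], 3), collapse = ", ")),
            call. = FALSE)
    out <- out[-dropped, , drop = FALSE]
  }
  class(out) <- c("cs_scale_profile", "data.frame")
  out
}

# internal: profiles straight from a precomputed r2 field
.profile_from_r2 <- function(r2, periods, coi, coi_policy) {
  admitted <- lapply(seq_along(periods), function(j) {
    if (coi_policy == "exclude") which(coi > periods[j]) else seq_len(nrow(r2))
  })
  mean_r2 <- vapply(seq_along(periods), function(j) {
    if (length(admitted[[j]]) > 0L) mean(r2[admitted[[j]], j]) else NA_real_
  }, numeric(1))
  sd_r2 <- vapply(seq_along(periods), function(j) {
    if (length(admitted[[j]]) > 0L) .pop_sd(r2[admitted[[j]], j]) else NA_real_
  }, numeric(1))
  n_used <- vapply(admitted, length, integer(1))
  data.frame(period_s = periods, mean_r2 = mean_r2, sd_r2 = sd_r2,
             n_times_used = n_used)
}

.truncate_common <- function(series_list) {
  lens <- vapply(series_list, function(s) length(s$values), integer(1))
  if (length(unique(lens)) > 1L) {
    warning("mixed durations; truncating all series to the shortest",
            call. = FALSE)
    nmin <- min(lens)
    series_list <- lapply(series_list, function(s) {
      s$values <- s$values[seq_len(nmin)]
      s
    })
  }
  series_list
}

# shared engine for the P-A and A-A aggregations: computes each CWT and each
# smoothed auto-spectrum once, then only the cross term per pair
.pairwise_profiles <- function(series_x, series_y, pairs, cfg) {
  all_series <- c(series_x, series_y)
  specs <- lapply(all_series, cwt_morlet, cfg = cfg)
  autos <- lapply(specs, .smoothed_auto, cfg = cfg)
  lapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    res <- .pair_r2(specs[[i]], specs[[j]], autos[[i]], autos[[j]], cfg)
    .profile_from_r2(res$r2, specs[[i]]$periods, specs[[i]]$coi,
                     cfg$coi_policy)
  })
}

.average_profiles <- function(profile_list) {
  base <- profile_list[[1L]]
  m <- rowMeans(sapply(profile_list, function(p) p$mean_r2))
  s <- rowMeans(sapply(profile_list, function(p) p$sd_r2))
  out <- data.frame(period_s = base$period_s, mean_r2 = m, sd_r2 = s,
                    n_times_used = base$n_times_used)
  class(out) <- c("cs_scale_profile", "data.frame")
  out
}

.drop_unpowered_scales <- function(profiles) {
  keep <- profiles[[1L]]$n_times_used > 0L
  if (!all(keep)) {
    warning(sprintf("%d scale(s) with no admitted time samples dropped",
                    sum(!keep)), call. = FALSE)
  }
  lapply(profiles, function(p) {
    out <- p[keep, , drop = FALSE]
    class(out) <- c("cs_scale_profile", "data.frame")
    out
  })
}

#' Performer-audience synchrony profiles
#'
#' For each audience member, computes the wavelet-coherence profile against
#' every performer and averages the per-scale mean and SD across performers.
#'
#' @param performers,audience lists of \code{\link{norm_series}} of common
#'   duration (mixed durations are truncated to the shortest, with a warning).
#' @param cfg a \code{\link{wtc_config}}.
#' @return A named list (one per audience member) of per-scale profiles.
#' @export
pa_profiles <- function(performers, audience, cfg = wtc_config()) {
  stopifnot(length(performers) >= 1L, length(audience) >= 1L)
  all_series <- .truncate_common(c(performers, audience))
  np <- length(performers)
  performers <- all_series[seq_len(np)]
  audience <- all_series[-seq_len(np)]
  pairs <- as.matrix(expand.grid(p = seq_len(np),
                                 a = np + seq_along(audience)))
  prof <- .pairwise_profiles(performers, audience, pairs, cfg)
  out <- lapply(seq_along(audience), function(ai) {
    .average_profiles(prof[pairs[, 2L] == np + ai])
  })
  names(out) <- vapply(audience, function(s) s$subject_id %||% "", character(1))
  .drop_unpowered_scales(out)
}

#' Audience-audience synchrony profiles
#'
#' For each audience member, averages the wavelet-coherence profiles over all
#' pairs with the other audience members; each unordered pair is computed
#' once.
#'
#' @param audience list of at least two \code{\link{norm_series}}.
#' @param cfg a \code{\link{wtc_config}}.
#' @return A named list (one per audience member) of per-scale profiles.
#' @export
aa_profiles <- function(audience, cfg = wtc_config()) {
  na <- length(audience)
  if (na < 2L) stop("audience-audience profiles need >= 2 members", call. = FALSE)
  audience <- .truncate_common(audience)
  pairs <- t(utils::combn(na, 2L))
  prof <- .pairwise_profiles(audience, list(), pairs, cfg)
  out <- lapply(seq_len(na), function(ai) {
    .average_profiles(prof[pairs[, 1L] == ai | pairs[, 2L] == ai])
  })
  names(out) <- vapply(audience, function(s) s$subject_id %||% "", character(1))
  .drop_unpowered_scales(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
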