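#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up BH adjustment with monotonicity enforcement (via
#' \code{\link[stats]{p.adjust}}) and a rejection mask at rate \code{q}.
#'
#' @param pvals numeric p-values in \eqn{[0,1]} (NAs passed through).
#' @param q target false-discovery rate.
#' @return List with \code{adjusted} p-values and logical \code{reject} mask
#'   (\code{adjusted < q}).
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (length(pvals) == 0L) {
    return(list(adjusted = numeric(0), reject = logical(0)))
  }
  ok <- !is.na(pvals)
  stopifnot(all(pvals[ok] >= 0 & pvals[ok] <= 1))
  adjusted <- stats::p.adjust(pvals, method = "BH")
  list(adjusted = adjusted, reject = !is.na(adjusted) & adjusted < q)
}

# deviation coding: second level of `levels` maps to +0.5, first to -0.5,
# so the coefficient equals the marginal (second - first) difference
.dev_code <- function(x, levels) {
  stopifnot(all(x %in% levels))
  ifelse(x == levels[2L], 0.5, -0.5)
}

# paired contrast on subject means: d_i = mean(DV | mode2) - mean(DV | mode1)
.paired_contrast <- function(d) {
  n <- length(d)
  est <- mean(d)
  sdd <- stats::sd(d)
  if (n < 2L || !is.finite(sdd)) {
    return(list(est = est, t = NA_real_, df = n - 1, p = NA_real_))
  }
  if (sdd < 1e-12 * max(abs(est), 1e-300)) {
    tt <- if (abs(est) > 0) sign(est) * Inf else 0
    return(list(est = est, t = tt, df = n - 1,
                p = if (abs(est) > 0) 0 else 1))
  }
  tt <- est / (sdd / sqrt(n))
  list(est = est, t = tt, df = n - 1,
       p = 2 * stats::pt(-abs(tt), df = n - 1))
}

# one mixed-model fit of DV ~ B*C*M + (1|S) + (1|C:S) + (1|M:S); returns the
# Mode row (estimate on the raw DV scale, Satterthwaite t/df/p) or NULL when
# the fit fails, does not converge, or is singular
.lmm_mode_fit <- function(df) {
  fit <- tryCatch(
    suppressWarnings(suppressMessages(
      lmerTest::lmer(dv ~ B * C * M + (1 | subject) + (1 | comp_subj) +
                       (1 | mode_subj), data = df, REML = TRUE)
    )),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  if (lme4::isSingular(fit, tol = 1e-5)) return(NULL)
  conv <- fit@optinfo$conv$lme4
  if (!is.null(conv$code) && conv$code != 0) return(NULL)
  ct <- tryCatch(stats::coef(summary(fit)), error = function(e) NULL)
  if (is.null(ct) || !("M" %in% rownames(ct))) return(NULL)
  row <- ct["M", ]
  if (!all(is.finite(row[c("Estimate", "t value", "Pr(>|t|)")]))) return(NULL)
  # degenerate fits (zero residual variance) yield vanishing Satterthwaite df
  if (!is.finite(row["df"]) || row["df"] < 1) return(NULL)
  list(est = unname(row["Estimate"]), t = unname(row["t value"]),
       df = unname(row["df"]), p = unname(row["Pr(>|t|)"]))
}

#' Scale-wise performance-mode contrast
#'
#' For every timescale, contrasts the chosen synchrony summary (time-mean or
#' temporal SD of coherence) between the two performance modes with the
#' three-way mixed model
#' \code{DV ~ Blindfold*Composition*Mode + (1|Subject) +
#' (1|Composition:Subject) + (1|Mode:Subject)}, all fixed factors
#' deviation-coded to \eqn{\pm 0.5} so the Mode coefficient equals the
#' marginal mode-2-minus-mode-1 difference. The reported coefficient is
#' standardised (DV and predictor scaled to unit SD); t and p are unaffected
#' by that scaling. When the mixed fit fails, does not converge, or is
#' singular, a paired contrast on subject means (averaged over pieces) is
#' used instead; the two engines always agree in sign. Benjamini-Hochberg
#' adjustment is applied across scales.
#'
#' @param profiles long-format profile table with columns \code{subject_id},
#'   \code{piece}, \code{mode}, \code{period_s} and the DV columns
#'   \code{mean_r2}, \code{sd_r2} (see \code{\link{profiles_table}}).
#' @param design performance design table (provides \code{blindfold} per
#'   subject).
#' @param dv \code{"mean"} (time-averaged coherence) or \code{"sd"}
#'   (temporal variability).
#' @param q false-discovery rate for the significance flags.
#' @param method \code{"auto"} (mixed model with paired fallback),
#'   \code{"lmm"}, or \code{"paired"}.
#' @param mode_levels the two mode labels; the contrast is
#'   \code{mode_levels[2] - mode_levels[1]}.
#' @return Data frame (class \code{cs_scale_stats}) with one row per scale:
#'   \code{period_s, beta, t, df, p, p_adj, sig, sign, method, n_subjects}.
#' @export
per_scale_contrast <- function(profiles, design, dv = c("mean", "sd"),
                               q = 0.05, method = c("auto", "lmm", "paired"),
                               mode_levels = c("Strict", "Let-go")) {
  dv <- match.arg(dv)
  method <- match.arg(method)
  dvcol <- if (dv == "mean") "mean_r2" else "sd_r2"
  bf <- design[!duplicated(design$subject_id),
               c("subject_id", "blindfold"), drop = FALSE]
  periods <- sort(unique(profiles$period_s))
  pieces <- sort(unique(profiles$piece))
  res <- lapply(periods, function(per) {
    d <- profiles[abs(profiles$period_s - per) < 1e-9 * per, , drop = FALSE]
    d <- d[is.finite(d[[dvcol]]), , drop = FALSE]
    cnt <- table(d$subject_id)
    complete <- names(cnt)[cnt == 2L * length(pieces)]
    if (length(complete) < length(cnt)) {
      warning(sprintf("period %.3g s: %d subject(s) with missing cells dropped",
                      per, length(cnt) - length(complete)), call. = FALSE)
    }
    d <- d[d$subject_id %in% complete, , drop = FALSE]
    ns <- length(complete)
    if (ns < 3L) {
      return(data.frame(period_s = per, beta = NA_real_, t = NA_real_,
                        df = NA_real_, p = NA_real_, method = NA_character_,
                        n_subjects = ns))
    }
    d <- merge(d, bf, by = "subject_id")
    d$dv <- d[[dvcol]]
    d$M <- .dev_code(d$mode, mode_levels)
    d$C <- if (length(pieces) == 2L) .dev_code(d$piece, pieces) else 0
    d$B <- ifelse(as.logical(d$blindfold), 0.5, -0.5)
    d$subject <- factor(d$subject_id)
    d$comp_subj <- interaction(d$piece, d$subject, drop = TRUE)
    d$mode_subj <- interaction(d$mode, d$subject, drop = TRUE)
    fit <- NULL
    used <- "paired"
    if (method %in% c("auto", "lmm")) {
      fit <- .lmm_mode_fit(d)
      if (!is.null(fit)) used <- "lmm"
      if (is.null(fit) && method == "lmm") {
        warning(sprintf("period %.3g s: mixed model degenerate; paired fallback used",
                        per), call. = FALSE)
      }
    }
    if (is.null(fit)) {
      sm <- tapply(d$dv, list(d$subject_id, d$mode), mean)
      fit <- .paired_contrast(sm[, mode_levels[2L]] - sm[, mode_levels[1L]])
    }
    sd_dv <- stats::sd(d$dv)
    beta <- if (sd_dv > 0) fit$est * stats::sd(d$M) / sd_dv else 0
    data.frame(period_s = per, beta = beta, t = fit$t, df = fit$df,
               p = fit$p, method = used, n_subjects = ns)
  })
  out <- do.call(rbind, res)
  adj <- bh_fdr(out$p, q = q)
  out$p_adj <- adj$adjusted
  out$sig <- adj$reject
  raw_sign <- sign(out$beta)
  raw_sign[!is.finite(raw_sign)] <- 0
  raw_sign[abs(out$beta) < 1e-12] <- 0
  out$sign <- as.integer(raw_sign)
  out <- out[, c("period_s", "beta", "t", "df", "p", "p_adj", "sig", "sign",
                 "method", "n_subjects")]
  class(out) <- c("cs_scale_stats", "data.frame")
  out
}

#' Extract synchrony bands from scale-wise statistics
#'
#' Beat-sync scales are those with a significant negative mode contrast on
#' the time-averaged coherence (higher synchrony in the first mode, short
#' rhythmic timescales); music-sync scales have a significant positive
#' contrast (higher in the second mode, long gesture timescales); the
#' variability band collects significant positive contrasts on the temporal
#' SD. The sets need not be contiguous.
#'
#' @param stats_mean \code{cs_scale_stats} for the time-mean DV.
#' @param stats_sd \code{cs_scale_stats} for the temporal-SD DV.
#' @param q false-discovery rate used for the significance flags.
#' @param channel label (\code{"P-A"} or \code{"A-A"}), carried through.
#' @return An object of class \code{cs_band_definition}: period sets
#'   \code{beat_scales}, \code{music_scales}, \code{var_scales}.
#' @export
extract_bands <- function(stats_mean, stats_sd, q = 0.05, channel = "P-A") {
  sig_m <- !is.na(stats_mean$p_adj) & stats_mean$p_adj < q
  sig_s <- !is.na(stats_sd$p_adj) & stats_sd$p_adj < q
  structure(list(
    beat_scales = stats_mean$period_s[sig_m & stats_mean$sign == -1L],
    music_scales = stats_mean$period_s[sig_m & stats_mean$sign == 1L],
    var_scales = stats_sd$period_s[sig_s & stats_sd$sign == 1L],
    channel = channel, q = q),
    class = "cs_band_definition")
}

#' @export
print.cs_band_definition <- function(x, ...) {
  fmt <- function(p) if (length(p) == 0L) "(empty)" else
    paste(signif(p, 3), collapse = ", ")
  cat(sprintf("synchrony bands (%s, q = %g):\n  beat-sync periods:  %s\n  music-sync periods: %s\n  variability periods: %s\n",
              x$channel, x$q, fmt(x$beat_scales), fmt(x$music_scales),
              fmt(x$var_scales)))
  invisible(x)
}

#' Band-averaged synchrony measures per subject and performance
#'
#' Averages the per-scale time-mean coherence over the beat-sync and
#' music-sync period sets, and the per-scale temporal SD over the
#' variability band. An empty band yields a missing value (not zero), with a
#' warning.
#'
#' @param profiles long-format profile table (see
#'   \code{\link{profiles_table}}).
#' @param bands a \code{\link{extract_bands}} result.
#' @return Data frame with one row per subject x performance:
#'   \code{subject_id, piece, mode, beat_sync, music_sync, music_sync_var}.
#' @export
band_measures <- function(profiles, bands) {
  in_set <- function(p, set) {
    if (length(set) == 0L) return(rep(FALSE, length(p)))
    vapply(p, function(pp) any(abs(set - pp) < 1e-9 * pp), logical(1))
  }
  for (nm in c("beat_scales", "music_scales", "var_scales")) {
    if (length(bands[[nm]]) == 0L) {
      warning(sprintf("empty %s band: measure reported as missing", nm),
              call. = FALSE)
    }
  }
  key <- interaction(profiles$subject_id, profiles$piece, profiles$mode,
                     drop = TRUE)
  rows <- lapply(split(profiles, key), function(d) {
    data.frame(
      subject_id = d$subject_id[1L], piece = d$piece[1L], mode = d$mode[1L],
      beat_sync = if (length(bands$beat_scales) > 0L)
        mean(d$mean_r2[in_set(d$period_s, bands$beat_scales)]) else NA_real_,
      music_sync = if (length(bands$music_scales) > 0L)
        mean(d$mean_r2[in_set(d$period_s, bands$music_scales)]) else NA_real_,
      music_sync_var = if (length(bands$var_scales) > 0L)
        mean(d$sd_r2[in_set(d$period_s, bands$var_scales)]) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
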