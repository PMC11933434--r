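.rating_items <- c("improvisatory", "innovative", "risktaking", "engaging",
                   "convincing", "familiar", "sleepy")

#' Questionnaire item names
#'
#' The seven audience-rating items, each on a 0-5 Likert scale.
#' @return Character vector of column names.
#' @export
rating_items <- function() .rating_items

.check_rating_table <- function(table) {
  stopifnot(all(c("subject_id", "piece", "mode") %in% names(table)),
            all(.rating_items %in% names(table)))
  m <- as.matrix(table[, .rating_items])
  ok <- is.na(m) | (m >= 0 & m <= 5 & m == round(m))
  if (!all(ok)) stop("rating values must be integers 0-5 or missing",
                     call. = FALSE)
  if (any(rowSums(is.na(m)) > 1L)) {
    stop("more than one missing item in a subject x performance row",
         call. = FALSE)
  }
  invisible(m)
}

#' Iterative tree-ensemble imputation of Likert ratings
#'
#' Fills missing questionnaire cells by iterated random-forest regression of
#' each incomplete item on the remaining six, in the spirit of forest-based
#' multiple imputation: missing cells start at the item median and are
#' re-predicted until the imputations stabilise or \code{max_iter} rounds.
#' Imputed values are rounded and clamped to 0-5. Fully seeded: the same
#' seed yields identical imputations.
#'
#' @param table rating table with columns \code{subject_id, piece, mode} and
#'   the seven items (integers 0-5 or \code{NA}; at most one missing item per
#'   row).
#' @param seed integer seed.
#' @param max_iter maximum refinement rounds.
#' @param ntree trees per forest.
#' @return The completed table, with attribute \code{imputed_mask} marking
#'   the filled cells.
#' @export
impute_ratings <- function(table, seed = 1, max_iter = 10, ntree = 300) {
  m <- .check_rating_table(table)
  mask <- is.na(m)
  if (!any(mask)) {
    attr(table, "imputed_mask") <- mask
    return(table)
  }
  if (any(colSums(!mask) == 0L)) {
    stop(sprintf("item '%s' is entirely missing",
                 .rating_items[which(colSums(!mask) == 0L)[1L]]),
         call. = FALSE)
  }
  withr::with_seed(seed, {
    filled <- apply(m, 2L, function(col) {
      col[is.na(col)] <- round(stats::median(col, na.rm = TRUE))
      col
    })
    cols <- order(colSums(mask))  # least missing first
    for (iter in seq_len(max_iter)) {
      prev <- filled
      for (j in cols) {
        if (!any(mask[, j])) next
        rf <- randomForest::randomForest(
          x = filled[!mask[, j], -j, drop = FALSE],
          y = filled[!mask[, j], j],
          ntree = ntree)
        filled[mask[, j], j] <- stats::predict(
          rf, filled[mask[, j], -j, drop = FALSE])
      }
      if (sum((filled[mask] - prev[mask])^2) < 1e-8) break
    }
    filled <- pmin(pmax(round(filled), 0), 5)
    out <- table
    out[, .rating_items] <- filled
    attr(out, "imputed_mask") <- mask
    out
  })
}

#' Principal component analysis of the rating items
#'
#' Items are z-scored across all rows; components come from the covariance of
#' the standardised items. The sign of PC1 is fixed so that the
#' \code{improvisatory} loading is positive (component signs are arbitrary;
#' this orients PC1 along perceived improvisatory/innovative quality).
#'
#' @param table complete rating table.
#' @return List of class \code{cs_pca_result}: \code{loadings} (item x
#'   component), \code{scores} (row x component), \code{explained_variance}
#'   ratios.
#' @export
pca_ratings <- function(table) {
  m <- .check_rating_table(table)
  if (any(is.na(m))) stop("PCA requires a complete table; impute first",
                          call. = FALSE)
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("zero-variance item: '%s'", .rating_items[which(sds == 0)[1L]]),
         call. = FALSE)
  }
  z <- scale(m)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  flip <- if (pc$rotation["improvisatory", 1L] < 0) -1 else 1
  pc$rotation[, 1L] <- flip * pc$rotation[, 1L]
  pc$x[, 1L] <- flip * pc$x[, 1L]
  structure(list(loadings = pc$rotation, scores = pc$x,
                 explained_variance = pc$sdev^2 / sum(pc$sdev^2)),
            class = "cs_pca_result")
}

#' @export
print.cs_pca_result <- function(x, ...) {
  cat(sprintf("ratings PCA: PC1 explains %.1f%% of variance\n",
              100 * x$explained_variance[1L]))
  invisible(x)
}

# Nakagawa marginal / conditional R2 from an lme4 fit
.nakagawa_r2 <- function(fit) {
  var_f <- stats::var(stats::predict(fit, re.form = NA))
  vc <- lme4::VarCorr(fit)
  var_re <- sum(vapply(vc, function(v) v[1L, 1L], numeric(1)))
  var_e <- attr(vc, "sc")^2
  tot <- var_f + var_re + var_e
  c(marginal = var_f / tot, conditional = (var_f + var_re) / tot)
}

.fixef_table <- function(fit, data) {
  ct <- stats::coef(summary(fit))
  ct <- ct[rownames(ct) != "(Intercept)", , drop = FALSE]
  sd_dv <- stats::sd(data$dv)
  beta <- vapply(rownames(ct), function(term) {
    cols <- strsplit(term, ":", fixed = TRUE)[[1L]]
    xs <- apply(do.call(cbind, lapply(cols, function(cc) data[[cc]])), 1L, prod)
    if (sd_dv > 0 && stats::sd(xs) > 0)
      ct[term, "Estimate"] * stats::sd(xs) / sd_dv else 0
  }, numeric(1))
  data.frame(term = rownames(ct), beta = beta,
             estimate = ct[, "Estimate"], t = ct[, "t value"],
             df = ct[, "df"], p = ct[, "Pr(>|t|)"], row.names = NULL)
}

# exact fixed-effects fit used when every mixed parameterisation degenerates
# (e.g. noise-free planted data); balanced designs give identical estimates
.lm_fallback <- function(formula, data) {
  fit <- stats::lm(formula, data = data)
  sm <- summary(fit)
  ct <- sm$coefficients
  keep <- rownames(ct) != "(Intercept)"
  res_sd <- stats::sd(stats::residuals(fit))
  dv_sd <- stats::sd(data$dv)
  out <- data.frame(term = rownames(ct)[keep],
                    estimate = ct[keep, "Estimate"],
                    t = ct[keep, "t value"],
                    df = fit$df.residual,
                    p = ct[keep, "Pr(>|t|)"], row.names = NULL)
  if (is.finite(dv_sd) && dv_sd > 0 && res_sd < 1e-10 * dv_sd) {
    nz <- abs(out$estimate) > 1e-10 * dv_sd
    out$t[nz] <- sign(out$estimate[nz]) * Inf
    out$p[nz] <- 0
    out$t[!nz] <- 0
    out$p[!nz] <- 1
  }
  out
}

#' Mixed model for mode effects on a per-performance outcome
#'
#' Fits \code{DV ~ Blindfold*Composition*Mode + (1|Subject) +
#' (1|Composition:Subject) + (1|Mode:Subject)} with all fixed factors
#' deviation-coded to \eqn{\pm 0.5} and zero-centred, reporting standardised
#' coefficients, Satterthwaite t/df/p, and Nakagawa marginal/conditional R2.
#' With \code{covariate} given, fits the absorption variant
#' \code{DV ~ covariate*Mode + (1|Subject)} instead. Singular or
#' non-converging fits fall back to a reduced random structure
#' (\code{(1|Subject)} only), then to an exact fixed-effects fit, with a
#' note in the result.
#'
#' @param dv numeric outcome, one value per design row.
#' @param design performance design table (columns \code{subject_id, piece,
#'   mode, blindfold}) aligned with \code{dv}.
#' @param covariate optional numeric per-row covariate (e.g. trait
#'   absorption).
#' @param mode_levels the two mode labels (contrast: second minus first).
#' @return List of class \code{cs_model_result}: \code{effects} data frame
#'   (term, beta, estimate, t, df, p), \code{r2_marginal},
#'   \code{r2_conditional}, \code{engine}.
#' @export
fit_mode_model <- function(dv, design, covariate = NULL,
                           mode_levels = c("Strict", "Let-go")) {
  stopifnot(length(dv) == nrow(design))
  d <- data.frame(dv = dv, subject_id = design$subject_id,
                  piece = design$piece, mode = design$mode,
                  blindfold = design$blindfold)
  cnt <- table(d$subject_id[is.finite(d$dv)])
  n_perf <- length(unique(interaction(d$piece, d$mode)))
  complete <- names(cnt)[cnt == n_perf]
  if (length(complete) < length(cnt)) {
    warning(sprintf("%d subject(s) with missing performances dropped",
                    length(cnt) - length(complete)), call. = FALSE)
  }
  d <- d[d$subject_id %in% complete & is.finite(d$dv), , drop = FALSE]
  pieces <- sort(unique(d$piece))
  d$M <- .dev_code(d$mode, mode_levels)
  d$C <- if (length(pieces) == 2L) .dev_code(d$piece, pieces) else 0
  d$B <- ifelse(as.logical(d$blindfold), 0.5, -0.5)
  d$subject <- factor(d$subject_id)
  d$comp_subj <- interaction(d$piece, d$subject, drop = TRUE)
  d$mode_subj <- interaction(d$mode, d$subject, drop = TRUE)
  if (!is.null(covariate)) {
    d$A <- scale(covariate[design$subject_id %in% complete &
                             is.finite(dv)])[, 1L]
    forms <- list(full = dv ~ A * M + (1 | subject),
                  reduced = dv ~ A * M + (1 | subject))
    lm_form <- dv ~ A * M
  } else {
    forms <- list(full = dv ~ B * C * M + (1 | subject) + (1 | comp_subj) +
                    (1 | mode_subj),
                  reduced = dv ~ B * C * M + (1 | subject))
    lm_form <- dv ~ B * C * M
  }
  try_fit <- function(f) {
    fit <- tryCatch(
      suppressWarnings(suppressMessages(
        lmerTest::lmer(f, data = d, REML = TRUE))),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    if (lme4::isSingular(fit, tol = 1e-5)) return(NULL)
    ct <- tryCatch(stats::coef(summary(fit)), error = function(e) NULL)
    if (is.null(ct) || !all(is.finite(ct[, "Pr(>|t|)"]))) return(NULL)
    # zero-residual degenerate fits produce vanishing Satterthwaite df
    if (any(!is.finite(ct[, "df"])) || any(ct[, "df"] < 1)) return(NULL)
    fit
  }
  fit <- try_fit(forms$full)
  engine <- "lmm"
  if (is.null(fit) && !identical(forms$full, forms$reduced)) {
    fit <- try_fit(forms$reduced)
    if (!is.null(fit)) engine <- "lmm-reduced"
  }
  if (!is.null(fit)) {
    eff <- .fixef_table(fit, d)
    r2 <- .nakagawa_r2(fit)
  } else {
    engine <- "lm"
    eff <- .lm_fallback(lm_form, d)
    sd_dv <- stats::sd(d$dv)
    eff$beta <- vapply(seq_len(nrow(eff)), function(i) {
      cols <- strsplit(eff$term[i], ":", fixed = TRUE)[[1L]]
      xs <- apply(do.call(cbind, lapply(cols, function(cc) d[[cc]])), 1L, prod)
      if (sd_dv > 0 && stats::sd(xs) > 0)
        eff$estimate[i] * stats::sd(xs) / sd_dv else 0
    }, numeric(1))
    eff <- eff[, c("term", "beta", "estimate", "t", "df", "p")]
    r2 <- c(marginal = NA_real_, conditional = NA_real_)
  }
  structure(list(effects = eff, r2_marginal = unname(r2["marginal"]),
                 r2_conditional = unname(r2["conditional"]),
                 engine = engine, n_subjects = length(complete)),
            class = "cs_model_result")
}

#' @export
print.cs_model_result <- function(x, ...) {
  cat(sprintf("mixed-model result (%s, %d subjects):\n", x$engine,
              x$n_subjects))
  print(x$effects, digits = 3)
  invisible(x)
}

#' Repeated-measures correlation
#'
#' Within-subject association of two per-performance variables: both are
#' centred within subject, then correlated; the test statistic is
#' \eqn{t = r\sqrt{df/(1-r^2)}} with \eqn{df = N - k - 1} (N observations, k
#' subjects), equivalent to the random-intercept model
#' \code{rating ~ sync + (1|Subject)} after centring within cluster.
#'
#' @param rating,sync numeric vectors, one value per observation.
#' @param subject_ids subject label per observation.
#' @return List of class \code{cs_rmcorr_result}: \code{r, t, df, p, n, k}.
#' @export
rm_corr <- function(rating, sync, subject_ids) {
  ok <- is.finite(rating) & is.finite(sync)
  rating <- rating[ok]; sync <- sync[ok]
  subject_ids <- as.character(subject_ids)[ok]
  cnt <- table(subject_ids)
  keep <- subject_ids %in% names(cnt)[cnt >= 2L]
  rating <- rating[keep]; sync <- sync[keep]; subject_ids <- subject_ids[keep]
  k <- length(unique(subject_ids))
  if (k < 2L) stop("need at least 2 subjects with >= 2 observations",
                   call. = FALSE)
  ctr <- function(v) v - stats::ave(v, subject_ids)
  rc <- ctr(rating); sc <- ctr(sync)
  if (stats::sd(rc) == 0 || stats::sd(sc) == 0) {
    stop("zero within-subject variance", call. = FALSE)
  }
  r <- stats::cor(rc, sc)
  n <- length(rc)
  df <- n - k - 1
  t <- if (abs(r) < 1) r * sqrt(df / (1 - r^2)) else sign(r) * Inf
  p <- if (is.finite(t)) 2 * stats::pt(-abs(t), df) else 0
  structure(list(r = r, t = t, df = df, p = p, n = n, k = k),
            class = "cs_rmcorr_result")
}

#' @export
print.cs_rmcorr_result <- function(x, ...) {
  cat(sprintf("repeated-measures correlation: r = %.3f, t(%d) = %.2f, p = %.3g\n",
              x$r, x$df, x$t, x$p))
  invisible(x)
}

#' Repeated-measures correlations between ratings and band measures
#'
#' Convenience wrapper producing the full item-by-measure correlation table
#' for one synchrony channel.
#'
#' @param ratings complete rating table (optionally with a \code{pc1}
#'   column; otherwise PC1 is computed here).
#' @param measures band-measure table from \code{\link{band_measures}}.
#' @return Data frame with one row per (item, measure):
#'   \code{item, measure, r, t, df, p}.
#' @export
rating_sync_correlations <- function(ratings, measures) {
  d <- merge(ratings, measures, by = c("subject_id", "piece", "mode"))
  if (!("pc1" %in% names(d))) {
    pc <- pca_ratings(d[, c("subject_id", "piece", "mode", .rating_items)])
    d$pc1 <- pc$scores[, 1L]
  }
  items <- c("pc1", .rating_items)
  meas <- c("beat_sync", "music_sync", "music_sync_var")
  rows <- list()
  for (it in items) {
    for (ms in meas) {
      if (all(is.na(d[[ms]]))) next
      res <- tryCatch(rm_corr(d[[it]], d[[ms]], d$subject_id),
                      error = function(e) NULL)
      if (is.null(res)) next
      rows[[length(rows) + 1L]] <- data.frame(
        item = it, measure = ms, r = res$r, t = res$t, df = res$df, p = res$p)
    }
  }
  do.call(rbind, rows)
}
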