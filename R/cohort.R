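#' Synthetic concert-cohort configuration
#'
#' Describes the shape of a simulated concert: a string-quartet-sized group
#' of performers and an audience, each piece performed once in each of two
#' performance modes, with recordings of 120-140 s at the accelerometer rate.
#'
#' @param n_audience number of audience members.
#' @param n_performers number of performers (default 4).
#' @param pieces piece labels.
#' @param modes the two performance-mode labels; the contrast convention
#'   throughout the package is \code{modes[2] - modes[1]}.
#' @param duration_s recording duration per performance in seconds; a scalar,
#'   a vector (one per performance), or \code{NULL} to draw each duration
#'   uniformly from \eqn{[120, 140]} s.
#' @param fs sampling frequency (Hz, default 100).
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#' @return An object of class \code{cs_cohort_config}.
#' @export
cohort_config <- function(n_audience, n_performers = 4,
                          pieces = c("Mozart", "Haydn"),
                          modes = c("Strict", "Let-go"),
                          duration_s = NULL, fs = 100, seed = 1) {
  stopifnot(n_audience >= 1, n_performers >= 1, fs > 0,
            length(modes) == 2L, length(pieces) >= 1L)
  if (!is.null(duration_s)) {
    .check_finite(duration_s, "duration_s")
    stopifnot(all(duration_s > 0))
  }
  stopifnot(is.finite(fs), is.finite(seed))
  structure(list(n_audience = as.integer(n_audience),
                 n_performers = as.integer(n_performers),
                 pieces = pieces, modes = modes, duration_s = duration_s,
                 fs = fs, seed = as.integer(seed)),
            class = "cs_cohort_config")
}

#' Ground-truth parameters of the synthetic cohort
#'
#' The generator couples every audience member to two shared drivers: a beat
#' oscillator whose instantaneous period follows a bounded Gaussian random
#' walk, and a slow "gesture" driver band-limited to the stated period range.
#' Mode-dependent parameters may be given as a named vector (one value per
#' mode) or a scalar applied to both modes.
#'
#' @param beat_period_s mean beat period (s); 0.74 s corresponds to a
#'   crotchet at the tempo of the faster repertoire piece.
#' @param tempo_jitter_sd SD of the per-beat period random walk (s/beat).
#' @param alpha_beat beat-coupling gain.
#' @param alpha_slow gesture-coupling gain.
#' @param gate_sd SD of the slow nonnegative coupling gate.
#' @param gesture_band_s period range of the gesture driver (s).
#' @param breath_period_s breathing period (s), within \eqn{[3, 5]}.
#' @param breath_kappa phase concentration of each subject's breathing
#'   around the common driver (von Mises-equivalent; 0 = independent).
#' @param noise_sd white accelerometer/idle-motion noise SD (m/s^2).
#' @param slow_noise_sd SD of each subject's independent slow movement
#'   component, band-limited to \code{slow_noise_band_s} (m/s^2). Audience
#'   accelerometry is strongly coloured at low frequency; a purely white
#'   noise floor would leave essentially no in-band noise power at gesture
#'   periods. Set to 0 for the white-only assumption.
#' @param slow_noise_band_s period band of the slow noise component (s).
#' @param breath_amp breathing amplitude on the z-axis (m/s^2).
#' @param performer_drive scaling of the beat + gesture drivers in the
#'   performers' own movement (default 1; 0 simulates performers at rest,
#'   the fully structureless null world).
#' @param rating_gamma loading of latent engagement on the planted
#'   long-scale sync variability (per SD of the planted values).
#' @return An object of class \code{cs_synthetic_truth}.
#' @export
synthetic_truth <- function(beat_period_s = 0.74,
                            tempo_jitter_sd = c(Strict = 0.005, "Let-go" = 0.02),
                            alpha_beat = c(Strict = 1.0, "Let-go" = 0.5),
                            alpha_slow = c(Strict = 0.3, "Let-go" = 1.0),
                            gate_sd = c(Strict = 0.1, "Let-go" = 1.8),
                            gesture_band_s = c(8, 16),
                            breath_period_s = 3.8,
                            breath_kappa = c(Strict = 8, "Let-go" = 2),
                            noise_sd = 2,
                            slow_noise_sd = 1,
                            slow_noise_band_s = c(6, 32),
                            breath_amp = 0.8,
                            performer_drive = 1,
                            rating_gamma = 0.8) {
  vals <- c(beat_period_s, tempo_jitter_sd, alpha_beat, alpha_slow, gate_sd,
            gesture_band_s, breath_period_s, breath_kappa, noise_sd,
            slow_noise_sd, slow_noise_band_s, breath_amp, performer_drive,
            rating_gamma)
  .check_finite(vals, "truth parameters")
  stopifnot(all(alpha_beat >= 0), all(alpha_slow >= 0), all(gate_sd >= 0),
            all(breath_kappa >= 0), all(noise_sd >= 0),
            all(slow_noise_sd >= 0), all(performer_drive >= 0),
            breath_period_s >= 3, breath_period_s <= 5,
            gesture_band_s[1L] < gesture_band_s[2L])
  structure(list(beat_period_s = beat_period_s,
                 tempo_jitter_sd = tempo_jitter_sd,
                 alpha_beat = alpha_beat, alpha_slow = alpha_slow,
                 gate_sd = gate_sd, gesture_band_s = gesture_band_s,
                 breath_period_s = breath_period_s,
                 breath_kappa = breath_kappa, noise_sd = noise_sd,
                 slow_noise_sd = slow_noise_sd,
                 slow_noise_band_s = slow_noise_band_s,
                 breath_amp = breath_amp, performer_drive = performer_drive,
                 rating_gamma = rating_gamma),
            class = "cs_synthetic_truth")
}

# mode-dependent parameter lookup: named vector -> value for this mode,
# scalar -> shared value
.mode_par <- function(par, mode) {
  if (length(par) == 1L && is.null(names(par))) return(unname(par))
  if (!is.null(names(par)) && mode %in% names(par)) return(unname(par[[mode]]))
  if (length(par) == 1L) return(unname(par))
  stop(sprintf("parameter has no value for mode '%s'", mode), call. = FALSE)
}

#' Performance design table
#'
#' One row per subject and performance. Each piece is performed twice, once
#' in each mode, with the mode order alternating across pieces; half the
#' audience is blindfolded (a between-subject factor).
#'
#' @param config a \code{\link{cohort_config}}.
#' @return Data frame \code{subject_id, role, piece, mode, order, blindfold}.
#' @export
performance_design <- function(config) {
  perf <- list()
  o <- 0L
  for (pi in seq_along(config$pieces)) {
    mode_order <- if (pi %% 2L == 1L) config$modes else rev(config$modes)
    for (m in mode_order) {
      o <- o + 1L
      perf[[o]] <- data.frame(piece = config$pieces[pi], mode = m, order = o)
    }
  }
  perf <- do.call(rbind, perf)
  performers <- sprintf("P%02d", seq_len(config$n_performers))
  audience <- sprintf("A%02d", seq_len(config$n_audience))
  subj <- data.frame(
    subject_id = c(performers, audience),
    role = c(rep("performer", config$n_performers),
             rep("audience", config$n_audience)),
    blindfold = c(rep(FALSE, config$n_performers),
                  rep(c(FALSE, TRUE), length.out = config$n_audience)))
  out <- merge(subj, perf, by = NULL)
  out <- out[order(out$order, out$subject_id),
             c("subject_id", "role", "piece", "mode", "order", "blindfold")]
  rownames(out) <- NULL
  out
}

# quaternion -> rotation matrix; used for the per-subject axis projection
.quat_rotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3L, byrow = TRUE)
}

# beat oscillator: instantaneous period is a bounded Gaussian random walk;
# returns a unit-SD waveform with a weak second harmonic
.beat_driver <- function(t, period0, jitter_sd) {
  dur <- t[length(t)]
  onsets <- numeric(ceiling(dur / (0.5 * period0)) + 2L)
  p <- period0
  k <- 1L
  onsets[1L] <- 0
  while (onsets[k] <= dur) {
    p <- min(max(p + stats::rnorm(1L, 0, jitter_sd), 0.5 * period0),
             1.5 * period0)
    onsets[k + 1L] <- onsets[k] + p
    k <- k + 1L
  }
  onsets <- onsets[1:k]
  phase <- 2 * pi * stats::approx(onsets, seq_along(onsets) - 1L,
                                  xout = t, rule = 2)$y
  v <- sin(phase) + 0.4 * sin(2 * phase + 0.7)
  v / .pop_sd(v)
}

# slow wandering phase of the shared breathing driver
.breath_driver_phase <- function(n, dt, period0) {
  p <- .ou_path(n, dt, tau_s = 30, sigma = 0.15, mu = period0)
  p <- pmax(p, 0.5 * period0)
  cumsum(2 * pi * dt / p)
}

# per-subject breathing phase offset around the driver: wrapped OU with
# stationary circular concentration kappa; kappa = 0 means a free-running
# independent phase walk
# kappa > 0: wrapped-OU offset around the common driver with stationary
# circular concentration kappa; kappa = 0: no coupling at all -- the subject
# breathes on an independent wandering clock
.breath_phase <- function(n, dt, kappa, driver_phase, period0) {
  if (kappa > 0) {
    driver_phase + .ou_path(n, dt, tau_s = 20, sigma = 1 / sqrt(kappa), mu = 0)
  } else {
    stats::runif(1L, 0, 2 * pi) + .breath_driver_phase(n, dt, period0)
  }
}

.delay_signal <- function(x, t, tau) {
  stats::approx(t, x, xout = t - tau, rule = 2)$y
}

# nonnegative slowly varying coupling gate with mean ~1 and SD ~gate_sd:
# softplus of an OU path with 20 s correlation time
.gate_path <- function(n, dt, gate_sd) {
  mz <- log(exp(1) - 1)             # softplus(mz) = 1
  slope <- 1 / (1 + exp(-mz))       # local softplus slope at mz
  .softplus(.ou_path(n, dt, tau_s = 20, sigma = gate_sd / slope, mu = mz))
}

#' Generate a synthetic concert cohort
#'
#' Simulates triaxial accelerometer recordings for performers and audience
#' over every performance of the design. Performer movement contains the
#' beat and gesture drivers directly; audience member \eqn{i} receives
#' \deqn{\alpha_{beat}\,\mathrm{beat}(t-\tau_i) +
#'       \alpha_{slow}\, g_i(t)\,\mathrm{gesture}(t-\tau_i) + \mathrm{noise}}
#' with a sub-beat coupling delay \eqn{\tau_i \sim U[0, 0.2]} s and a
#' nonnegative slowly varying gate \eqn{g_i(t)}. The movement signal rides on
#' a gravity-scale constant along a per-subject random direction (random
#' unit quaternion), so the Euclidean norm is approximately affine in the
#' movement; breathing is added on the z-axis after rotation.
#'
#' @param config a \code{\link{cohort_config}}.
#' @param truth a \code{\link{synthetic_truth}}.
#' @return List of class \code{cs_cohort}: \code{recordings} (named list of
#'   \code{\link{accel_recording}}), \code{design}, and \code{truth_record}
#'   (data frame of per-subject-performance planted gains, delays, realized
#'   gate SDs and \code{planted_sync_var}, plus the full gate trajectories
#'   in attribute-free list form under \code{$gates}).
#' @export
gen_cohort <- function(config, truth) {
  stopifnot(inherits(config, "cs_cohort_config"),
            inherits(truth, "cs_synthetic_truth"))
  design <- performance_design(config)
  perf <- unique(design[, c("piece", "mode", "order")])
  perf <- perf[order(perf$order), ]
  withr::with_seed(config$seed, {
    durations <- if (is.null(config$duration_s)) {
      stats::runif(nrow(perf), 120, 140)
    } else {
      rep(config$duration_s, length.out = nrow(perf))
    }
    if (any(durations < 4 * truth$gesture_band_s[2L])) {
      warning("duration shorter than 4x the longest gesture period; long-scale estimates unreliable",
              call. = FALSE)
    }
    fs <- config$fs
    dt <- 1 / fs
    g0 <- 9.81
    subj <- design[!duplicated(design$subject_id),
                   c("subject_id", "role", "blindfold")]
    # fixed per-subject axis orientation across performances
    dirs <- lapply(seq_len(nrow(subj)), function(i) {
      as.numeric(.quat_rotation(stats::rnorm(4L)) %*% c(1, 0, 0))
    })
    names(dirs) <- subj$subject_id
    recordings <- list()
    truth_rows <- list()
    gates <- list()
    for (k in seq_len(nrow(perf))) {
      piece <- perf$piece[k]; mode <- perf$mode[k]
      n <- round(durations[k] * fs)
      t <- (seq_len(n) - 1L) * dt
      beat <- .beat_driver(t, truth$beat_period_s,
                           .mode_par(truth$tempo_jitter_sd, mode))
      gesture <- morlet_bandpass(stats::rnorm(n), fs, truth$gesture_band_s)
      gesture <- gesture / .pop_sd(gesture)
      breath_phase <- .breath_driver_phase(n, dt, truth$breath_period_s)
      ab <- .mode_par(truth$alpha_beat, mode)
      as_ <- .mode_par(truth$alpha_slow, mode)
      gsd <- .mode_par(truth$gate_sd, mode)
      kap <- .mode_par(truth$breath_kappa, mode)
      gates_k <- list()
      for (i in seq_len(nrow(subj))) {
        sid <- subj$subject_id[i]
        role <- subj$role[i]
        breathing <- truth$breath_amp *
          sin(.breath_phase(n, dt, kap, breath_phase, truth$breath_period_s))
        if (role == "performer") {
          m <- truth$performer_drive * (beat + gesture) +
            stats::rnorm(n, 0, 0.3)
          tau <- 0
          gate <- rep(1, n)
        } else {
          tau <- stats::runif(1L, 0, 0.2)
          gate <- .gate_path(n, dt, gsd)
          slow <- if (truth$slow_noise_sd > 0) {
            sn <- morlet_bandpass(stats::rnorm(n), fs, truth$slow_noise_band_s)
            truth$slow_noise_sd * sn / .pop_sd(sn)
          } else 0
          m <- ab * .delay_signal(beat, t, tau) +
            as_ * gate * .delay_signal(gesture, t, tau) +
            slow + stats::rnorm(n, 0, truth$noise_sd)
        }
        d <- dirs[[sid]]
        base <- g0 + m
        az <- base * d[3L] + breathing
        key <- paste(sid, piece, mode, sep = "__")
        recordings[[key]] <- accel_recording(
          sid, role, ax = base * d[1L], ay = base * d[2L], az = az, fs = fs,
          piece = piece, mode = mode, blindfold = subj$blindfold[i])
        if (role == "audience") {
          gates_k[[sid]] <- gate
          truth_rows[[length(truth_rows) + 1L]] <- data.frame(
            subject_id = sid, piece = piece, mode = mode,
            alpha_beat = ab, alpha_slow = as_, gate_sd_param = gsd,
            gate_sd_realized = .pop_sd(gate),
            planted_sync_var = as_ * .pop_sd(gate),
            tau_s = tau, breath_kappa = kap)
        }
      }
      gates[[paste(piece, mode, sep = "__")]] <- gates_k
    }
    truth_record <- do.call(rbind, truth_rows)
    structure(list(recordings = recordings, design = design,
                   truth_record = truth_record, gates = gates,
                   config = config, truth = truth),
              class = "cs_cohort")
  })
}

#' @export
print.cs_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d performers + %d audience, %d performances, fs = %g Hz\n",
              x$config$n_performers, x$config$n_audience,
              length(unique(x$design$order)), x$config$fs))
  invisible(x)
}

#' Planted long-scale sync variability without full signal synthesis
#'
#' Simulates only the slow coupling gates of the generator and returns each
#' audience member's planted music-sync variability
#' (\code{alpha_slow * sd(gate)}), aligned with the design rows. Useful for
#' ratings-association studies at design scale where synthesising full
#' accelerometer cohorts would be wasteful; \code{\link{gen_cohort}} records
#' the same quantity from its own gates.
#'
#' @param design a \code{\link{performance_design}} table.
#' @param truth a \code{\link{synthetic_truth}}.
#' @param duration_s gate duration (s).
#' @param fs gate simulation rate (Hz); the gate has a 20 s correlation
#'   time, so a few Hz suffices.
#' @param seed integer seed.
#' @return Numeric vector aligned with \code{design} rows (NA for
#'   performers).
#' @export
gen_sync_var <- function(design, truth, duration_s = 130, fs = 5, seed = 1) {
  n <- round(duration_s * fs)
  withr::with_seed(seed, {
    out <- rep(NA_real_, nrow(design))
    for (r in seq_len(nrow(design))) {
      if (design$role[r] != "audience") next
      mode <- design$mode[r]
      gate <- .gate_path(n, 1 / fs, .mode_par(truth$gate_sd, mode))
      out[r] <- .mode_par(truth$alpha_slow, mode) * .pop_sd(gate)
    }
    out
  })
}

#' Generate audience ratings from planted latent engagement
#'
#' Latent engagement per audience row is
#' \code{mode_mu[mode] + rating_gamma * centred(planted_sync_var) +
#' subject intercept + noise}; the Improvisatory, Innovative, Risk-taking and
#' Engaging items load positively on it, Convincing weakly, and Familiar and
#' Sleepy are independent. Items are mapped affinely onto the 0-5 Likert
#' range and discretised by clamped rounding (optionally left continuous for
#' closed-form checks).
#'
#' @param design a \code{\link{performance_design}} table.
#' @param truth a \code{\link{synthetic_truth}} (supplies
#'   \code{rating_gamma}).
#' @param planted_sync_var numeric vector aligned with \code{design} rows
#'   (values on audience rows; e.g. from \code{\link{gen_sync_var}} or a
#'   cohort's \code{truth_record}).
#' @param mode_mu named latent mode means.
#' @param subject_sd SD of the latent subject intercepts.
#' @param noise_sd SD of the latent row noise.
#' @param item_noise_sd SD of per-item noise.
#' @param missing_rate probability that a row has one missing item (at most
#'   one per row; rates above 0.2 are refused as incompatible with the
#'   imputation assumptions).
#' @param discretize clamp-round items to integers 0-5 (default TRUE).
#' @param seed integer seed.
#' @return Rating table: \code{subject_id, piece, mode} plus the seven item
#'   columns.
#' @export
gen_ratings <- function(design, truth, planted_sync_var,
                        mode_mu = c(Strict = 0, "Let-go" = 0.8),
                        subject_sd = 0.5, noise_sd = 0.3,
                        item_noise_sd = 0.3, missing_rate = 0,
                        discretize = TRUE, seed = 1) {
  stopifnot(length(planted_sync_var) == nrow(design))
  if (missing_rate > 0.2) {
    stop("missingness rate > 0.2 violates the imputation assumptions",
         call. = FALSE)
  }
  d <- design[design$role == "audience", , drop = FALSE]
  sv <- planted_sync_var[design$role == "audience"]
  .check_finite(sv, "planted_sync_var (audience rows)")
  svc <- if (stats::sd(sv) > 0) (sv - mean(sv)) / stats::sd(sv) else sv * 0
  withr::with_seed(seed, {
    subjects <- unique(d$subject_id)
    b <- stats::rnorm(length(subjects), 0, subject_sd)
    names(b) <- subjects
    mu <- vapply(d$mode, function(m) .mode_par(mode_mu, m), numeric(1))
    e <- mu + truth$rating_gamma * svc + b[d$subject_id] +
      stats::rnorm(nrow(d), 0, noise_sd)
    loadings <- c(improvisatory = 1, innovative = 0.9, risktaking = 0.85,
                  engaging = 0.7, convincing = 0.25)
    items <- matrix(NA_real_, nrow(d), length(.rating_items),
                    dimnames = list(NULL, .rating_items))
    for (nm in names(loadings)) {
      items[, nm] <- 2.5 + loadings[[nm]] * e +
        stats::rnorm(nrow(d), 0, item_noise_sd)
    }
    for (nm in c("familiar", "sleepy")) {
      items[, nm] <- 2.5 + stats::rnorm(nrow(d), 0, 0.9)
    }
    if (discretize) items <- pmin(pmax(round(items), 0), 5)
    if (missing_rate > 0) {
      miss_row <- stats::runif(nrow(d)) < missing_rate
      for (r in which(miss_row)) {
        items[r, sample.int(length(.rating_items), 1L)] <- NA
      }
    }
    out <- data.frame(subject_id = d$subject_id, piece = d$piece,
                      mode = d$mode)
    out[, .rating_items] <- items
    rownames(out) <- NULL
    out
  })
}

#' Write a synthetic cohort to disk
#'
#' One \code{t,ax,ay,az} CSV per subject and performance, the design table,
#' the ground-truth record as JSON, and optionally the ratings table (empty
#' cells for missing values).
#'
#' @param cohort a \code{\link{gen_cohort}} result.
#' @param dir output directory (created if needed).
#' @param ratings optional rating table to write alongside.
#' @param gate_trajectories include the full gate trajectories in the
#'   ground-truth JSON (large; default FALSE keeps the per-performance
#'   summaries only).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir, ratings = NULL,
                         gate_trajectories = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (key in names(cohort$recordings)) {
    rec <- cohort$recordings[[key]]
    t <- (seq_along(rec$ax) - 1L) / rec$fs
    lines <- c("t,ax,ay,az",
               sprintf("%.5f,%.6f,%.6f,%.6f", t, rec$ax, rec$ay, rec$az))
    writeLines(lines, file.path(dir, paste0(key, ".csv")))
  }
  utils::write.csv(cohort$design, file.path(dir, "design.csv"),
                   row.names = FALSE)
  gt <- list(truth = unclass(cohort$truth), record = cohort$truth_record)
  if (gate_trajectories) gt$gates <- cohort$gates
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = FALSE)
  if (!is.null(ratings)) {
    utils::write.csv(ratings, file.path(dir, "ratings.csv"),
                     row.names = FALSE, na = "")
  }
  invisible(dir)
}

#' Read a cohort directory written by \code{\link{write_cohort}}
#'
#' @param dir directory containing \code{design.csv} and the per-subject
#'   recording CSVs.
#' @return List with \code{recordings} and \code{design}.
#' @export
read_cohort <- function(dir) {
  design <- utils::read.csv(file.path(dir, "design.csv"))
  recordings <- list()
  for (r in seq_len(nrow(design))) {
    key <- paste(design$subject_id[r], design$piece[r], design$mode[r],
                 sep = "__")
    path <- file.path(dir, paste0(key, ".csv"))
    if (!file.exists(path)) next
    recordings[[key]] <- read_recording_csv(
      path, subject_id = design$subject_id[r], role = design$role[r],
      piece = design$piece[r], mode = design$mode[r],
      blindfold = design$blindfold[r])
  }
  list(recordings = recordings, design = design)
}
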