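#' Triaxial acceleration recording
#'
#' Container for one subject's raw accelerometer signal during one
#' performance.
#'
#' @param subject_id subject label.
#' @param role \code{"performer"} or \code{"audience"}.
#' @param ax,ay,az numeric acceleration samples (m/s^2), equal length.
#' @param fs sampling frequency (Hz).
#' @param piece,mode performance labels.
#' @param blindfold logical flag.
#' @return An object of class \code{cs_accel_recording}.
#' @export
accel_recording <- function(subject_id, role = c("audience", "performer"),
                            ax, ay, az, fs, piece = NA_character_,
                            mode = NA_character_, blindfold = FALSE) {
  role <- match.arg(role)
  if (length(ax) != length(ay) || length(ax) != length(az)) {
    stop("axes must have equal length", call. = FALSE)
  }
  stopifnot(fs > 0)
  structure(list(subject_id = subject_id, role = role,
                 ax = as.numeric(ax), ay = as.numeric(ay), az = as.numeric(az),
                 fs = fs, piece = piece, mode = mode, blindfold = blindfold),
            class = "cs_accel_recording")
}

#' @export
print.cs_accel_recording <- function(x, ...) {
  cat(sprintf("acceleration recording: %s (%s), %s/%s, %d samples at %g Hz\n",
              x$subject_id, x$role, x$piece, x$mode, length(x$ax), x$fs))
  invisible(x)
}

#' One-dimensional acceleration-norm series
#'
#' @param values nonnegative acceleration magnitudes (m/s^2).
#' @param fs sampling frequency (Hz).
#' @param subject_id,piece,mode,role provenance labels.
#' @return An object of class \code{cs_norm_series}.
#' @export
norm_series <- function(values, fs, subject_id = NA_character_,
                        piece = NA_character_, mode = NA_character_,
                        role = NA_character_) {
  stopifnot(fs > 0)
  structure(list(values = as.numeric(values), fs = fs,
                 subject_id = subject_id, piece = piece, mode = mode,
                 role = role),
            class = "cs_norm_series")
}

#' @export
print.cs_norm_series <- function(x, ...) {
  cat(sprintf("acceleration-norm series: %s, %d samples at %g Hz\n",
              x$subject_id, length(x$values), x$fs))
  invisible(x)
}

#' Euclidean norm of a triaxial acceleration recording
#'
#' Converts the three axes to the one-dimensional series
#' \eqn{a(t) = \sqrt{a_x^2(t) + a_y^2(t) + a_z^2(t)}}. The constant (gravity)
#' component is deliberately not removed: it is irrelevant to wavelet
#' coherence at the analysis periods because the Morlet wavelet has zero mean.
#'
#' @param rec a \code{\link{accel_recording}}.
#' @return A \code{\link{norm_series}} of the same length and rate.
#' @export
accel_norm <- function(rec) {
  .check_finite(rec$ax, "ax samples")
  .check_finite(rec$ay, "ay samples")
  .check_finite(rec$az, "az samples")
  norm_series(sqrt(rec$ax^2 + rec$ay^2 + rec$az^2), rec$fs,
              subject_id = rec$subject_id, piece = rec$piece,
              mode = rec$mode, role = rec$role)
}

# anti-alias filtered resampling of a plain numeric vector; used by both the
# norm-series resampler and the breathing-band decimator
.resample_values <- function(x, fs, target_fs, antialias = TRUE) {
  if (target_fs > fs) stop("upsampling unsupported", call. = FALSE)
  if (target_fs == fs) return(x)
  if (antialias) {
    wc <- 2 * (0.4 * target_fs) / fs  # zero-phase low-pass at 0.4 * target
    bf <- signal::butter(8, wc)
    dc <- mean(x)
    x <- signal::filtfilt(bf, x - dc) + dc
  }
  ratio <- fs / target_fs
  if (abs(ratio - round(ratio)) < 1e-9) {
    x[seq(1L, length(x), by = round(ratio))]
  } else {
    # rational (non-integer) factor: sample the filtered signal on the new
    # grid by linear interpolation
    t_old <- (seq_along(x) - 1) / fs
    t_new <- seq(0, t_old[length(t_old)], by = 1 / target_fs)
    stats::approx(t_old, x, xout = t_new)$y
  }
}

#' Resample an acceleration-norm series to the analysis rate
#'
#' Applies a zero-phase low-pass filter (8th-order Butterworth at 0.4 times
#' the target rate, forward-backward) before decimation, so no lag bias is
#' introduced into subsequent coherence estimates. Filtering is configurable
#' because the upstream acquisition convention (filtered or plain decimation)
#' can differ between labs.
#'
#' @param series a \code{\link{norm_series}}.
#' @param target_fs target rate (Hz); must not exceed \code{series$fs} and the
#'   ratio must be rational.
#' @param antialias apply the anti-alias filter (default \code{TRUE}).
#' @return A \code{\link{norm_series}} at \code{target_fs}.
#' @export
resample_to <- function(series, target_fs, antialias = TRUE) {
  v <- .resample_values(series$values, series$fs, target_fs, antialias)
  norm_series(pmax(v, 0), target_fs, subject_id = series$subject_id,
              piece = series$piece, mode = series$mode, role = series$role)
}

#' Read a triaxial recording from CSV
#'
#' Reads the \code{t,ax,ay,az} dialect written by the synthetic-cohort
#' generator; the rate is inferred from the time column unless given.
#'
#' @param path CSV file path.
#' @param subject_id,role,piece,mode,blindfold provenance labels.
#' @param fs sampling rate; inferred from \code{t} when \code{NULL}.
#' @return A \code{\link{accel_recording}}.
#' @export
read_recording_csv <- function(path, subject_id = NA_character_,
                               role = "audience", piece = NA_character_,
                               mode = NA_character_, blindfold = FALSE,
                               fs = NULL) {
  d <- utils::read.csv(path)
  stopifnot(all(c("t", "ax", "ay", "az") %in% names(d)))
  if (is.null(fs)) fs <- 1 / stats::median(diff(d$t))
  accel_recording(subject_id, role, d$ax, d$ay, d$az, fs = round(fs),
                  piece = piece, mode = mode, blindfold = blindfold)
}

#' Write an acceleration-norm series as \code{t,a} CSV
#'
#' @param series a \code{\link{norm_series}}.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_norm_csv <- function(series, path) {
  t <- (seq_along(series$values) - 1) / series$fs
  lines <- c("t,a", sprintf("%.5f,%.6f", t, series$values))
  writeLines(lines, path)
  invisible(path)
}
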