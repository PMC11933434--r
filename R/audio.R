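#' Windowed loudness curve of a mono audio signal
#'
#' Sliding-window mean-square power per frame expressed in dB relative to
#' full scale, with the frame hop set so the output rate is
#' \code{frame_rate} frames per second. This is a LUFS-like curve: true ITU
#' gating and frequency weighting are not applied, because the downstream
#' pattern metrics depend only on the curve's shape. Stereo input is averaged
#' to mono first. All-zero windows are marked as silence and excluded from
#' summary statistics.
#'
#' @param audio numeric vector (mono) or two-column matrix (stereo) of PCM
#'   samples in \eqn{[-1, 1]}.
#' @param fs sample rate (Hz); must be a multiple of \code{frame_rate}.
#' @param window window length in samples (default 480).
#' @param frame_rate output frames per second (default 200).
#' @return List of class \code{cs_loudness_curve}: \code{values_db} (NA on
#'   silent frames), \code{silent} mask, \code{frame_rate}, \code{window}.
#' @export
loudness_curve <- function(audio, fs, window = 480, frame_rate = 200) {
  stopifnot(fs > 0)
  if (is.matrix(audio)) audio <- rowMeans(audio)
  hop <- fs / frame_rate
  if (abs(hop - round(hop)) > 1e-9) {
    stop("fs must be an integer multiple of frame_rate", call. = FALSE)
  }
  hop <- round(hop)
  n <- length(audio)
  if (n < window) stop("audio shorter than one window", call. = FALSE)
  cs <- c(0, cumsum(audio^2))
  starts <- seq(1L, n - window + 1L, by = hop)
  ms <- (cs[starts + window] - cs[starts]) / window
  silent <- ms <= 0
  db <- rep(NA_real_, length(ms))
  db[!silent] <- 10 * log10(ms[!silent])
  structure(list(values_db = db, silent = silent, frame_rate = frame_rate,
                 window = window),
            class = "cs_loudness_curve")
}

#' @export
print.cs_loudness_curve <- function(x, ...) {
  cat(sprintf("loudness curve: %d frames at %g fps (%d silent), mean %.2f dBFS\n",
              length(x$values_db), x$frame_rate, sum(x$silent),
              mean(x$values_db, na.rm = TRUE)))
  invisible(x)
}

#' Lempel-Ziv (LZ76) pattern complexity of a loudness curve
#'
#' Binarises the curve against its median (values >= median map to 1) and
#' counts the number of distinct phrases in the exhaustive LZ76 parsing.
#' Because binarisation depends only on rank relative to the median, the
#' result is invariant under strictly monotone transforms of the curve.
#'
#' @param curve a \code{\link{loudness_curve}} or numeric vector.
#' @return Integer complexity (>= 1).
#' @export
lz_complexity <- function(curve) {
  v <- if (inherits(curve, "cs_loudness_curve")) {
    curve$values_db[!curve$silent]
  } else {
    as.numeric(curve)
  }
  if (length(v) < 2L) stop("need at least 2 non-silent frames", call. = FALSE)
  if (.pop_sd(v) == 0) {
    warning("constant curve: complexity of a uniform string", call. = FALSE)
  }
  s <- as.integer(v >= stats::median(v))
  n <- length(s)
  # Kaspar-Schuster exhaustive-history phrase counting
  c_cnt <- 1L; l <- 1L; i <- 0L; k <- 1L; k_max <- 1L
  repeat {
    if (s[i + k] != s[l + k]) {
      if (k > k_max) k_max <- k
      i <- i + 1L
      if (i == l) {
        c_cnt <- c_cnt + 1L
        l <- l + k_max
        if (l + 1L > n) break
        i <- 0L; k <- 1L; k_max <- 1L
      } else {
        k <- 1L
      }
    } else {
      k <- k + 1L
      if (l + k > n) {
        c_cnt <- c_cnt + 1L
        break
      }
    }
  }
  c_cnt
}

#' Spectral entropy of a signal
#'
#' Shannon entropy (base 2) of the normalised one-sided power spectrum,
#' estimated as the average of periodograms over non-overlapping segments of
#' length \code{min(8192, 2^floor(log2 n))}. The entropy is reported in bits
#' without normalising by the bin count, so longer windows give larger
#' maxima (\code{log2} of the number of bins). Scaling the input leaves the
#' result unchanged.
#'
#' @param x numeric signal, length >= 64.
#' @return Spectral entropy in bits, with the number of spectral bins as an
#'   attribute.
#' @export
spectral_entropy <- function(x) {
  n <- length(x)
  if (n < 64L) stop("need at least 64 samples", call. = FALSE)
  if (all(x == 0)) stop("zero signal", call. = FALSE)
  nseg_len <- min(8192L, 2L^floor(log2(n)))
  nseg <- n %/% nseg_len
  nb <- nseg_len %/% 2L
  pow <- numeric(nb)
  for (k in seq_len(nseg)) {
    seg <- x[((k - 1L) * nseg_len + 1L):(k * nseg_len)]
    seg <- seg - mean(seg)
    sp <- Mod(stats::fft(seg))^2
    pow <- pow + sp[2L:(nb + 1L)]
  }
  if (sum(pow) <= 0) stop("zero spectral power", call. = FALSE)
  p <- pow / sum(pow)
  p <- p[p > 0]
  structure(-sum(p * log2(p)), n_bins = nb)
}

#' Per-section tempo variability from bar-onset annotations
#'
#' Bar durations are successive onset differences within each section; the
#' mean and population SD are reported per section plus an overall row
#' pooling all bar durations.
#'
#' @param ann data frame with column \code{onset_s} (strictly increasing)
#'   and optional \code{section} labels.
#' @return Data frame \code{section, n_bars, mean_s, sd_s}; the last row is
#'   the pooled \code{"overall"} summary.
#' @export
tempo_variability <- function(ann) {
  stopifnot("onset_s" %in% names(ann))
  on <- ann$onset_s
  if (any(diff(on) <= 0)) stop("onsets must be strictly increasing",
                               call. = FALSE)
  section <- if ("section" %in% names(ann)) as.character(ann$section) else
    rep("all", length(on))
  durs <- list()
  for (sec in unique(section)) {
    o <- on[section == sec]
    if (length(o) < 2L) stop(sprintf("section '%s' has fewer than 2 onsets", sec),
                             call. = FALSE)
    durs[[sec]] <- diff(o)
  }
  rows <- lapply(names(durs), function(sec) {
    d <- durs[[sec]]
    data.frame(section = sec, n_bars = length(d), mean_s = mean(d),
               sd_s = .pop_sd(d))
  })
  all_d <- unlist(durs, use.names = FALSE)
  out <- rbind(do.call(rbind, rows),
               data.frame(section = "overall", n_bars = length(all_d),
                          mean_s = mean(all_d), sd_s = .pop_sd(all_d)))
  rownames(out) <- NULL
  out
}

#' Summary audio metrics for one performance
#'
#' @param audio mono or stereo PCM samples.
#' @param fs sample rate (Hz).
#' @param annotations optional bar-onset data frame for
#'   \code{\link{tempo_variability}}.
#' @return List of class \code{cs_audio_metrics}: mean/SD loudness (dB),
#'   loudness pattern complexity, spectral entropy of the loudness curve and
#'   of the raw audio, and the tempo table when annotations are given.
#' @export
audio_metrics <- function(audio, fs, annotations = NULL) {
  lc <- loudness_curve(audio, fs)
  v <- lc$values_db[!lc$silent]
  mono <- if (is.matrix(audio)) rowMeans(audio) else audio
  structure(list(
    mean_loudness_db = mean(v),
    sd_loudness_db = .pop_sd(v),
    loudness_complexity = lz_complexity(lc),
    spectral_entropy_loudness = as.numeric(spectral_entropy(v)),
    spectral_entropy_audio = as.numeric(spectral_entropy(mono)),
    tempo = if (!is.null(annotations)) tempo_variability(annotations) else NULL
  ), class = "cs_audio_metrics")
}

#' @export
print.cs_audio_metrics <- function(x, ...) {
  cat(sprintf(
    "audio metrics: loudness %.2f dB (SD %.2f), LZ complexity %d, spectral entropy %.2f bits\n",
    x$mean_loudness_db, x$sd_loudness_db, x$loudness_complexity,
    x$spectral_entropy_audio))
  invisible(x)
}
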