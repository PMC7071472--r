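#' Downsample a recording with anti-alias filtering
#'
#' Integer-factor decimation (e.g. the canonical 2048 -> 256 Hz, factor 8):
#' a zero-phase FIR low-pass (Hamming-window design, cutoff at 80% of the
#' target Nyquist) applied forward-backward, then every M-th sample kept.
#' Non-integer ratios fall back to polyphase rational resampling.
#' Upsampling is out of scope and raises an error.
#'
#' @param rec an [eeg_recording()].
#' @param target_rate target sampling rate in Hz (must not exceed `rec$rate`).
#' @return the resampled [eeg_recording()]; duration preserved within one
#'   sample period; annotations carried over unchanged (they are in seconds).
#' @export
resample_recording <- function(rec, target_rate) {
  stopifnot(inherits(rec, "eeg_recording"))
  assert_scalar_pos(target_rate, "target_rate")
  if (target_rate > rec$rate) {
    stop("upsampling (", rec$rate, " -> ", target_rate,
         " Hz) is not supported", call. = FALSE)
  }
  if (target_rate == rec$rate) return(rec)
  ratio <- rec$rate / target_rate
  if (abs(ratio - round(ratio)) < 1e-9) {
    m <- round(ratio)
    taps <- as.numeric(signal::fir1(20 * m, 0.8 / m))   # linear phase, odd length
    gd <- (length(taps) - 1) / 2                        # integer group delay
    n <- nrow(rec$data)
    data <- apply(rec$data, 2, function(x) {
      # FFT convolution, then shift out the known delay: exact zero phase
      y <- signal::fftfilt(taps, c(x, numeric(2 * gd)))[(gd + 1):(gd + n)]
      y[seq(1, n, by = m)]
    })
  } else {
    p_q <- as.integer(c(target_rate, rec$rate) /
                        gcd_int(round(target_rate), round(rec$rate)))
    data <- apply(rec$data, 2, function(x) signal::resample(x, p_q[1], p_q[2]))
  }
  eeg_recording(data, rate = target_rate, channels = rec$channels,
                roles = rec$roles, annotations = rec$annotations)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) order-4 Butterworth band-pass; applied
#' forward and backward so no group delay shifts segment boundaries, and the
#' effective magnitude response is the squared one-pass response.
#'
#' @param rec an [eeg_recording()].
#' @param lo,hi band edges in Hz; must satisfy `0 < lo < hi < rate/2`.
#' @param order one-pass Butterworth order.
#' @return the filtered [eeg_recording()].
#' @export
bandpass_recording <- function(rec, lo = 0.5, hi = 30, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(lo > 0 && hi > lo && hi < rec$rate / 2)) {
    stop("invalid band edges: need 0 < lo < hi < rate/2 (got ", lo, "-", hi,
         " Hz at rate ", rec$rate, ")", call. = FALSE)
  }
  bf <- signal::butter(order, c(lo, hi) / (rec$rate / 2), type = "pass")
  data <- apply(rec$data, 2, function(x) signal::filtfilt(bf, x))
  eeg_recording(data, rate = rec$rate, channels = rec$channels,
                roles = rec$roles, annotations = rec$annotations)
}

#' Segment a recording into sliding windows
#'
#' Half-open windows `[start, start + window_s)` advancing by
#' `window_s * (1 - overlap_frac)`; a trailing partial window is discarded.
#' All segments start valid; [reject_segments()] marks artifact-contaminated
#' ones invalid.
#'
#' @param rec an [eeg_recording()].
#' @param window_s window length, seconds (default 1).
#' @param overlap_frac overlap fraction in `[0, 1)` (default 0.5).
#' @return An object of class `segment_series`: list with `data`
#'   (segments x samples x channels array), `starts` (seconds), `window_s`,
#'   `overlap_frac`, `rate`, `channels`, `roles`, `valid` (logical mask).
#' @examples
#' rec <- eeg_recording(matrix(rnorm(512), ncol = 2,
#'                             dimnames = list(NULL, c("Fp1", "Fp2"))), 256)
#' segment_recording(rec)$starts  # one 1-s window
#' @export
segment_recording <- function(rec, window_s = 1, overlap_frac = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  dur <- duration(rec)
  if (dur < window_s) {
    stop("recording (", dur, " s) shorter than the window (", window_s, " s)",
         call. = FALSE)
  }
  if (overlap_frac < 0 || overlap_frac >= 1) {
    stop("overlap_frac must be in [0, 1)", call. = FALSE)
  }
  step <- window_s * (1 - overlap_frac)
  n_seg <- floor((dur - window_s) / step + 1e-9) + 1
  starts <- (seq_len(n_seg) - 1) * step
  spw <- round(window_s * rec$rate)
  data <- array(NA_real_, dim = c(n_seg, spw, length(rec$channels)),
                dimnames = list(NULL, NULL, rec$channels))
  for (s in seq_len(n_seg)) {
    i0 <- round(starts[s] * rec$rate)
    data[s, , ] <- rec$data[(i0 + 1):(i0 + spw), , drop = FALSE]
  }
  structure(
    list(data = data, starts = starts, window_s = window_s,
         overlap_frac = overlap_frac, rate = rec$rate,
         channels = rec$channels, roles = rec$roles,
         valid = rep(TRUE, n_seg)),
    class = "segment_series"
  )
}

#' @export
print.segment_series <- function(x, ...) {
  cat(sprintf("<segment_series> %d windows of %g s (%.0f%% overlap), %d/%d valid\n",
              length(x$starts), x$window_s, 100 * x$overlap_frac,
              sum(x$valid), length(x$valid)))
  invisible(x)
}

#' Detect eye-blink intervals on the prefrontal channels
#'
#' Multiwindow derivative-sum detector: on the mean of the prefrontal EEG
#' channels, the signed first differences are summed over several window
#' lengths (50/100/200 ms by default) -- the windowed sum of derivatives
#' telescopes to the net amplitude change `x(t) - x(t - w)`, which is large
#' for a blink's slow high-amplitude swing but small for ongoing band-limited
#' activity. Each scale's absolute value is robust-standardized (median/MAD)
#' and the maximum across scales is thresholded at `k`. Flagged samples
#' closer than `merge_gap_s` are merged into one interval and each interval
#' is padded by `pad_s` on both sides.
#'
#' @param rec an [eeg_recording()] with at least one prefrontal EEG channel
#'   (Fp1/Fp2).
#' @param windows_ms window lengths for the derivative sums, milliseconds.
#' @param k robust z-score threshold (median + k * MAD).
#' @param merge_gap_s intervals closer than this are merged (seconds).
#' @param pad_s padding added to each side of an interval (seconds).
#' @return data frame with columns `start_s`, `end_s`: sorted,
#'   non-overlapping half-open intervals (zero rows on clean input).
#' @export
detect_blinks <- function(rec, windows_ms = c(50, 100, 200), k = 8,
                          merge_gap_s = 0.1, pad_s = 0.05) {
  stopifnot(inherits(rec, "eeg_recording"))
  pf <- intersect(c("Fp1", "Fp2"), channels_with_role(rec, "EEG"))
  if (length(pf) == 0) {
    stop("recording has no prefrontal EEG channel (Fp1/Fp2)", call. = FALSE)
  }
  x <- rowMeans(rec$data[, pf, drop = FALSE])
  n <- length(x)
  z <- rep(-Inf, n)
  for (w_ms in windows_ms) {
    w <- max(round(w_ms / 1000 * rec$rate), 2)
    # windowed sum of signed derivatives == net change over the window
    s <- abs(c(rep(0, w), x[(w + 1):n] - x[1:(n - w)]))
    med <- stats::median(s)
    scale <- stats::mad(s)
    if (scale < 1e-12) scale <- stats::sd(s) + 1e-12
    z <- pmax(z, (s - med) / scale)
  }
  flagged <- which(z > k)
  if (length(flagged) == 0) {
    return(data.frame(start_s = numeric(), end_s = numeric()))
  }
  t_flag <- (flagged - 1) / rec$rate
  gaps <- which(diff(t_flag) > merge_gap_s)
  starts <- t_flag[c(1, gaps + 1)]
  ends <- t_flag[c(gaps, length(t_flag))] + 1 / rec$rate
  starts <- pmax(starts - pad_s, 0)
  ends <- pmin(ends + pad_s, duration(rec))
  # padding may re-introduce overlaps; merge again
  keep_s <- starts[1]
  out_s <- numeric()
  out_e <- numeric()
  cur_e <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= cur_e) {
      cur_e <- max(cur_e, ends[i])
    } else {
      out_s <- c(out_s, keep_s); out_e <- c(out_e, cur_e)
      keep_s <- starts[i]; cur_e <- ends[i]
    }
  }
  out_s <- c(out_s, keep_s); out_e <- c(out_e, cur_e)
  data.frame(start_s = out_s, end_s = out_e)
}

#' Invalidate segments overlapping artifact intervals
#'
#' A segment whose half-open window `[start, start + window_s)` intersects any
#' half-open interval is marked invalid; the segment list itself is unchanged.
#' Idempotent: re-applying the same (or empty) intervals never revalidates.
#'
#' @param series a [segment_recording()] result.
#' @param intervals data frame with `start_s`, `end_s` columns (e.g. from
#'   [detect_blinks()]).
#' @return the `segment_series` with an updated validity mask.
#' @export
reject_segments <- function(series, intervals) {
  stopifnot(inherits(series, "segment_series"))
  if (is.null(intervals) || nrow(intervals) == 0) return(series)
  for (i in seq_len(nrow(intervals))) {
    a <- intervals$start_s[i]
    b <- intervals$end_s[i]
    hit <- series$starts < b & a < series$starts + series$window_s
    series$valid[hit] <- FALSE
  }
  series
}

#' Remove ocular artifacts by LMS adaptive filtering on EOG references
#'
#' Normalized least-mean-squares (NLMS) adaptive linear prediction: each EEG
#' channel is predicted from tapped-delay-line copies of the EOG reference
#' channels and replaced by the prediction residual. The step size anneals
#' hyperbolically with time constant `anneal_s`: narrowband EOG references
#' make successive NLMS updates strongly correlated, inflating steady-state
#' weight noise (and hence distortion of the retained EEG) at a fixed step,
#' so for offline runs the step decays once the weights have converged.
#' Output length and rate are unchanged. With all-zero references the
#' prediction is identically zero and the recording passes through untouched.
#'
#' @param rec an [eeg_recording()].
#' @param eog_channels labels of the reference channels (default: all channels
#'   with role EOG).
#' @param step initial normalized step size (default 0.005).
#' @param order taps per reference channel (default 3; steady-state weight
#'   noise grows with the total tap count, so a lean delay line distorts the
#'   retained EEG less while still covering the near-instantaneous
#'   EOG-to-forehead mixing).
#' @param anneal_s step-annealing time constant in seconds
#'   (`Inf` = classical fixed-step NLMS).
#' @return the cleaned [eeg_recording()] (EOG channels retained unmodified).
#' @export
lms_remove_eog <- function(rec, eog_channels = channels_with_role(rec, "EOG"),
                           step = 0.005, order = 3, anneal_s = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  missing_ch <- setdiff(eog_channels, rec$channels)
  if (length(eog_channels) == 0 || length(missing_ch) > 0) {
    stop("EOG channel(s) ", paste(missing_ch, collapse = ", "),
         " not found; available channels: ",
         paste(rec$channels, collapse = ", "), call. = FALSE)
  }
  n <- nrow(rec$data)
  refs <- rec$data[, eog_channels, drop = FALSE]
  # tapped delay lines: n x (order * n_ref)
  u <- do.call(cbind, lapply(seq_len(ncol(refs)), function(j) {
    vapply(0:(order - 1), function(d) c(rep(0, d), refs[1:(n - d), j]),
           numeric(n))
  }))
  data <- rec$data
  eeg_idx <- which(rec$roles == "EEG")
  tau <- anneal_s * rec$rate
  for (ch in eeg_idx) {
    data[, ch] <- nlms_residual(rec$data[, ch], u, step, tau)
  }
  eeg_recording(data, rate = rec$rate, channels = rec$channels,
                roles = rec$roles, annotations = rec$annotations)
}

# annealed-step NLMS residual of predicting d from rows of u
nlms_residual <- function(d, u, step, tau = Inf, eps = 1e-8) {
  n <- length(d)
  p <- ncol(u)
  w <- numeric(p)
  e <- numeric(n)
  for (t in seq_len(n)) {
    ut <- u[t, ]
    mu <- step / (1 + (t - 1) / tau)
    e[t] <- d[t] - sum(w * ut)
    w <- w + (mu / (eps + sum(ut * ut))) * e[t] * ut
  }
  e
}

#' Preprocess one recording into an artifact-handled segment series
#'
#' Fixed stage order: downsample to `target_rate`, then (for session types in
#' `lms_sessions`, when EOG references are present) LMS ocular-artifact
#' removal, then zero-phase 0.5-30 Hz band-pass, then 1-s / 50%-overlap
#' segmentation on the downsampled signal, then -- for the non-LMS session
#' types -- blink detection and segment rejection. Mirrors the two artifact
#' treatments of the study design: derivative-sum blink rejection for
#' resting/valence/relaxation, EOG-referenced LMS for attention.
#'
#' @param rec an [eeg_recording()].
#' @param session_type one of `"resting"`, `"valence"`, `"relaxation"`,
#'   `"attention"`.
#' @param target_rate working rate, Hz.
#' @param band band-pass edges, Hz.
#' @param window_s,overlap_frac segmentation parameters.
#' @param lms_sessions session types receiving LMS instead of blink rejection.
#' @param detector_k robust threshold for [detect_blinks()].
#' @return a `segment_series`; detected blink intervals (if any) are attached
#'   as attribute `"blink_intervals"`.
#' @export
preprocess_recording <- function(rec, session_type = "resting",
                                 target_rate = 256, band = c(0.5, 30),
                                 window_s = 1, overlap_frac = 0.5,
                                 lms_sessions = "attention",
                                 detector_k = 8) {
  stopifnot(inherits(rec, "eeg_recording"))
  session_type <- match.arg(session_type,
                            c("resting", "valence", "relaxation", "attention"))
  rec <- resample_recording(rec, target_rate)
  use_lms <- session_type %in% lms_sessions &&
    length(channels_with_role(rec, "EOG")) > 0
  if (use_lms) {
    rec <- lms_remove_eog(rec)
  }
  rec <- bandpass_recording(rec, band[1], band[2])
  series <- segment_recording(rec, window_s, overlap_frac)
  intervals <- data.frame(start_s = numeric(), end_s = numeric())
  if (!use_lms) {
    intervals <- detect_blinks(rec, k = detector_k)
    series <- reject_segments(series, intervals)
  }
  attr(series, "blink_intervals") <- intervals
  series
}
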