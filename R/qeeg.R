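#' Absolute band power of a signal segment
#'
#' Periodogram estimate with a rectangular window, one-sided scaling, and
#' band integration over the half-open interval `[lo, hi)`. For a 1-s segment
#' the frequency resolution is 1 Hz, so the seven canonical bands partition
#' the 2-18 Hz total band without double counting shared edges; Parseval's
#' identity holds (the sum over all bins equals the mean square of the
#' signal), so a bin-centered sinusoid of amplitude A contributes A^2/2.
#'
#' @param x numeric vector, one single-channel segment (typically 1 s).
#' @param band a band: row of [canonical_bands()], a band name, or `c(lo, hi)`
#'   in Hz.
#' @param rate sampling rate, Hz.
#' @return band power in signal-units squared (microvolts^2); non-negative.
#' @examples
#' t <- seq(0, 1, length.out = 257)[-257]
#' band_power(2 * sin(2 * pi * 10 * t), "alpha2", 256)  # ~ 2 = A^2/2
#' @export
band_power <- function(x, band, rate) {
  band <- resolve_band(band)
  if (band$hi > rate / 2) {
    stop("band upper edge (", band$hi, " Hz) exceeds the Nyquist frequency (",
         rate / 2, " Hz)", call. = FALSE)
  }
  psd <- periodogram_psd(matrix(x, ncol = 1), rate)
  sum(psd$psd[psd$freq >= band$lo & psd$freq < band$hi, 1]) * psd$df
}

resolve_band <- function(band) {
  if (is.character(band)) {
    return(canonical_bands(band))
  }
  if (is.numeric(band) && length(band) == 2) {
    return(data.frame(name = "custom", label = "custom",
                      lo = band[1], hi = band[2]))
  }
  stopifnot(is.data.frame(band), all(c("lo", "hi") %in% names(band)))
  band
}

# one-sided rectangular-window periodogram of each column; returns PSD in
# units^2/Hz such that sum(psd) * df == column mean square (Parseval)
periodogram_psd <- function(xm, rate) {
  n <- nrow(xm)
  xf <- stats::mvfft(xm)
  nyq <- floor(n / 2)
  keep <- 1:(nyq + 1)
  p <- Mod(xf[keep, , drop = FALSE])^2 / (n * rate)
  scale <- rep(2, length(keep))
  scale[1] <- 1
  if (n %% 2 == 0) scale[length(keep)] <- 1
  p <- p * scale
  list(psd = p, freq = (keep - 1) * rate / n, df = rate / n)
}

#' Relative band power
#'
#' Absolute band power divided by the total-band (2-18 Hz) power of the same
#' segment. In `(0, 1]` for any band inside the total band.
#'
#' @inheritParams band_power
#' @return unitless ratio.
#' @export
relative_power <- function(x, band, rate) {
  tot <- band_power(x, "total", rate)
  if (tot <= 0) {
    stop("degenerate segment: total-band (2-18 Hz) power is zero",
         call. = FALSE)
  }
  band_power(x, band, rate) / tot
}

#' Interhemispheric asymmetry index
#'
#' `ln(p_fp1 / p_fp2)`, in nats. Antisymmetric under channel swap.
#'
#' @param p_fp1,p_fp2 band powers (> 0) at Fp1 and Fp2.
#' @return asymmetry in nats.
#' @export
asymmetry <- function(p_fp1, p_fp2) {
  if (any(p_fp1 <= 0) || any(p_fp2 <= 0)) {
    stop("asymmetry requires strictly positive band powers", call. = FALSE)
  }
  log(p_fp1 / p_fp2)
}

#' Frontal alpha asymmetry of one segment pair
#'
#' `ln(alpha power at Fp1 / alpha power at Fp2)` with alpha = 10-12 Hz
#' (the alpha2 band): the valence-related feature. Exactly the composition
#' [asymmetry()] of [band_power()] in the alpha2 band.
#'
#' @param segment_fp1,segment_fp2 single-channel segments (same length).
#' @param rate sampling rate, Hz.
#' @return FAA in nats.
#' @export
faa <- function(segment_fp1, segment_fp2, rate) {
  asymmetry(band_power(segment_fp1, "alpha2", rate),
            band_power(segment_fp2, "alpha2", rate))
}

# band powers of all valid segments: n_valid x n_band matrix per channel
segment_band_powers <- function(series, bands = canonical_bands(),
                                channels = c("Fp1", "Fp2")) {
  stopifnot(inherits(series, "segment_series"))
  missing_ch <- setdiff(channels, series$channels)
  if (length(missing_ch) > 0) {
    stop("channels not in series: ", paste(missing_ch, collapse = ", "),
         call. = FALSE)
  }
  idx <- which(series$valid)
  if (length(idx) == 0) stop("no valid segments", call. = FALSE)
  spw <- dim(series$data)[2]
  out <- lapply(channels, function(ch) {
    xm <- t(matrix(series$data[idx, , ch, drop = FALSE], nrow = length(idx)))
    psd <- periodogram_psd(xm, series$rate)
    bp <- vapply(seq_len(nrow(bands)), function(b) {
      sel <- psd$freq >= bands$lo[b] & psd$freq < bands$hi[b]
      colSums(psd$psd[sel, , drop = FALSE]) * psd$df
    }, numeric(length(idx)))
    bp <- matrix(bp, nrow = length(idx))
    colnames(bp) <- bands$label
    bp
  })
  names(out) <- channels
  attr(out, "starts") <- series$starts[idx]
  out
}

#' Per-segment feature series for one target feature
#'
#' Computes the chosen feature on every valid segment of a preprocessed
#' series. FAA is the alpha2 (10-12 Hz) log power ratio of Fp1 over Fp2;
#' rFTP and rFLBP are the theta (4-8 Hz) and low-beta (12-15 Hz) powers
#' averaged across the two channels, divided by the likewise channel-averaged
#' total (2-18 Hz) power.
#'
#' @param series a `segment_series` from [preprocess_recording()].
#' @param feature `"FAA"`, `"rFTP"` or `"rFLBP"`.
#' @return data frame with columns `feature`, `segment_start_s`, `value`
#'   (one row per valid segment; all values finite).
#' @export
feature_series <- function(series, feature = c("FAA", "rFTP", "rFLBP")) {
  feature <- match.arg(feature)
  band <- switch(feature, FAA = "Alpha-10-12", rFTP = "Theta-4-8",
                 rFLBP = "Beta-12-15")
  bands <- canonical_bands()
  bp <- segment_band_powers(series, bands)
  b <- match(band, bands$label)
  tot <- match("total", bands$label)
  value <- if (feature == "FAA") {
    asymmetry(bp$Fp1[, b], bp$Fp2[, b])
  } else {
    ((bp$Fp1[, b] + bp$Fp2[, b]) / 2) / ((bp$Fp1[, tot] + bp$Fp2[, tot]) / 2)
  }
  if (any(!is.finite(value))) {
    stop("non-finite feature values (degenerate segments?)", call. = FALSE)
  }
  data.frame(feature = feature, segment_start_s = attr(bp, "starts"),
             value = value, stringsAsFactors = FALSE)
}
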