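#' The fixed ordered vocabulary of the 112 resting-state predictors
#'
#' 8 frequency bands (the seven canonical bands plus the full 2-18 Hz band)
#' x 7 quantities (absolute power at Fp1, Fp2 and their mean "Fp12"; relative
#' power at Fp1, Fp2, Fp12; interhemispheric asymmetry of the absolute
#' powers) x 2 statistics (Mean, IQR) = 112 named predictors. Names follow
#' the `[Mean|IQR]-[Abs|Rel|Asym]-[channel]-[band]` dialect, e.g.
#' `"IQR-Asym-Alpha-8-12"` (asymmetry has no channel slot) and
#' `"IQR-Rel-Fp12-Beta-12-15"`.
#'
#' @return data frame with columns `name`, `stat`, `kind`, `channel`
#'   (`NA` for Asym), `band_label`; exactly 112 rows in canonical order.
#' @export
predictor_vocabulary <- function() {
  cached <- get0("vocab", envir = .restdyn_cache)
  if (!is.null(cached)) return(cached)
  bands <- canonical_bands()$label
  rows <- list()
  for (stat in c("Mean", "IQR")) {
    for (kind in c("Abs", "Rel", "Asym")) {
      chans <- if (kind == "Asym") NA_character_ else c("Fp1", "Fp2", "Fp12")
      for (ch in chans) {
        for (band in bands) {
          rows[[length(rows) + 1]] <- data.frame(
            name = predictor_name(stat, kind, ch, band),
            stat = stat, kind = kind, channel = ch, band_label = band,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  vocab <- do.call(rbind, rows)
  assign("vocab", vocab, envir = .restdyn_cache)
  vocab
}

.restdyn_cache <- new.env(parent = emptyenv())

#' Canonical predictor name
#'
#' @param stat `"Mean"` or `"IQR"`.
#' @param kind `"Abs"`, `"Rel"` or `"Asym"`.
#' @param channel `"Fp1"`, `"Fp2"`, `"Fp12"`, or `NA`/`NULL`; must be absent
#'   exactly when `kind` is `"Asym"`.
#' @param band a band label (`"Alpha-8-12"`, `"total"`, ...) or band name
#'   (`"alpha3"`, ...).
#' @return the canonical name string, e.g. `"IQR-Asym-Alpha-8-12"`.
#' @examples
#' predictor_name("IQR", "Asym", NULL, "alpha3")   # "IQR-Asym-Alpha-8-12"
#' predictor_name("IQR", "Rel", "Fp1", "theta")    # "IQR-Rel-Fp1-Theta-4-8"
#' @export
predictor_name <- function(stat, kind, channel, band) {
  stat <- match.arg(stat, c("Mean", "IQR"))
  kind <- match.arg(kind, c("Abs", "Rel", "Asym"))
  no_channel <- is.null(channel) || is.na(channel)
  if (kind == "Asym" && !no_channel) {
    stop("asymmetry predictors take no channel (got '", channel, "')",
         call. = FALSE)
  }
  if (kind != "Asym" && no_channel) {
    stop(kind, " predictors require a channel (Fp1/Fp2/Fp12)", call. = FALSE)
  }
  cb <- canonical_bands()
  label <- if (band %in% cb$label) band
           else if (band %in% cb$name) cb$label[cb$name == band]
           else stop("unknown band '", band, "'", call. = FALSE)
  if (kind == "Asym") {
    paste(stat, kind, label, sep = "-")
  } else {
    match.arg(channel, c("Fp1", "Fp2", "Fp12"))
    paste(stat, kind, channel, label, sep = "-")
  }
}

# shared assembly: per-epoch 8-band absolute power matrices (columns labeled
# as canonical_bands()$label) for the two channels -> named 112-vector
assemble_predictors <- function(p_fp1, p_fp2) {
  vocab <- predictor_vocabulary()
  tot1 <- p_fp1[, "total"]
  tot2 <- p_fp2[, "total"]
  series_for <- function(kind, channel, band) {
    switch(kind,
      Abs = switch(channel,
                   Fp1 = p_fp1[, band],
                   Fp2 = p_fp2[, band],
                   Fp12 = (p_fp1[, band] + p_fp2[, band]) / 2),
      Rel = switch(channel,
                   Fp1 = p_fp1[, band] / tot1,
                   Fp2 = p_fp2[, band] / tot2,
                   Fp12 = ((p_fp1[, band] + p_fp2[, band]) / 2) /
                          ((tot1 + tot2) / 2)),
      Asym = log(p_fp1[, band] / p_fp2[, band])
    )
  }
  out <- vapply(seq_len(nrow(vocab)), function(i) {
    v <- series_for(vocab$kind[i], vocab$channel[i], vocab$band_label[i])
    if (vocab$stat[i] == "Mean") mean(v) else iqr(v)
  }, numeric(1))
  names(out) <- vocab$name
  out
}

#' Extract the 112 candidate resting-state predictors
#'
#' For each of the eight bands, the per-segment absolute powers at Fp1 and
#' Fp2 (periodogram, valid segments only) are combined into the seven qEEG
#' quantities (Abs/Rel at Fp1, Fp2, and the two-channel power mean "Fp12";
#' interhemispheric asymmetry of the absolute powers), and each per-segment
#' series is summarized by its mean and IQR. The two full-band relative
#' predictors are degenerate by construction (`Mean-Rel-*-total` is
#' identically 1, `IQR-Rel-*-total` identically 0) and are retained so the
#' vector always has exactly 112 entries.
#'
#' @param resting a `segment_series` of the resting recording with at least
#'   4 valid segments.
#' @return named numeric vector over [predictor_vocabulary()], length 112.
#' @export
extract_candidate_predictors <- function(resting) {
  stopifnot(inherits(resting, "segment_series"))
  if (sum(resting$valid) < 4) {
    stop("need at least 4 valid resting segments to compute predictor IQRs (",
         sum(resting$valid), " available)", call. = FALSE)
  }
  bp <- segment_band_powers(resting, canonical_bands())
  assemble_predictors(bp$Fp1, bp$Fp2)
}

#' Write / read a participant-by-predictor matrix as a delimited table
#'
#' One row per participant, 112 named predictor columns. The reader
#' validates the complete canonical vocabulary and restores canonical column
#' order, so serialization round-trips losslessly.
#'
#' @param x matrix or data frame of predictor values with participant row
#'   names (or a `participant` column).
#' @param path file path (tab-separated).
#' @return `write_predictors`: `path` invisibly; `read_predictors`: a numeric
#'   matrix with participants as row names.
#' @export
write_predictors <- function(x, path) {
  x <- as.data.frame(x, check.names = FALSE)
  if (!"participant" %in% names(x)) {
    x <- cbind(participant = rownames(x), x)
  }
  stopifnot(all(predictor_vocabulary()$name %in% names(x)))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_predictors
#' @export
read_predictors <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  vocab <- predictor_vocabulary()$name
  missing_cols <- setdiff(vocab, names(tab))
  if (length(missing_cols) > 0) {
    stop("predictor table is missing ", length(missing_cols),
         " canonical columns (first: ", missing_cols[1], ")", call. = FALSE)
  }
  m <- as.matrix(tab[vocab])
  rownames(m) <- tab$participant
  m
}
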