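#' Interquartile range under the linear-interpolation quantile convention
#'
#' `Q3 - Q1` with quantiles computed by linear interpolation between order
#' statistics (R's default type 7), declared explicitly so every dynamic
#' range in the package is reproducible bit for bit. Translation invariant;
#' scales with `|c|` under `x -> c * x`.
#'
#' @param values numeric vector of at least 4 finite values.
#' @return nonnegative scalar.
#' @examples
#' iqr(c(1, 2, 3, 4))  # 1.5
#' @export
iqr <- function(values) {
  if (length(values) < 4) {
    stop("IQR requires at least 4 values (got ", length(values), ")",
         call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("IQR requires finite values", call. = FALSE)
  }
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  q[2] - q[1]
}

#' Dynamic ranges (feature IQRs) per participant and feature
#'
#' Concatenates each feature's per-segment values across its sessions and
#' takes the IQR: the measure of how much usable variability a participant's
#' feature exhibits. By default the resting-state segments are included for
#' the relative-power features but not for the asymmetry feature; the band
#' features' sessions are whatever the input table contains.
#' (participant, feature) groups with fewer than `min_segments` values are
#' omitted with a message, mirroring recordings lost to technical problems.
#'
#' @param features data frame with columns `participant`, `session`,
#'   `feature`, `value` (stacked [feature_series()] outputs).
#' @param include_resting named logical vector per feature: include
#'   `session == "resting"` rows in that feature's pool.
#' @param min_segments minimum per-group segment count (default 4, the
#'   smallest n for which an interpolated IQR is meaningful).
#' @return data frame with columns `participant`, `feature`, `iqr`,
#'   `n_segments`; row order is by sorted participant then feature,
#'   independent of input order.
#' @export
dynamic_ranges <- function(features,
                           include_resting = c(FAA = FALSE, rFTP = TRUE,
                                               rFLBP = TRUE),
                           min_segments = 4) {
  stopifnot(all(c("participant", "session", "feature", "value") %in%
                  names(features)))
  drop_rest <- names(include_resting)[!include_resting]
  features <- features[!(features$session == "resting" &
                           features$feature %in% drop_rest), , drop = FALSE]
  groups <- split(features, features[c("participant", "feature")], drop = TRUE)
  out <- lapply(groups, function(df) {
    if (nrow(df) < min_segments) {
      message("omitting participant ", df$participant[1], " feature ",
              df$feature[1], ": only ", nrow(df), " segments")
      return(NULL)
    }
    data.frame(participant = df$participant[1], feature = df$feature[1],
               iqr = iqr(df$value), n_segments = nrow(df),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(data.frame(participant = character(), feature = character(),
                      iqr = numeric(), n_segments = integer()))
  }
  out <- out[order(out$participant, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}
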