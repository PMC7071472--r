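#' Canonical frequency band definitions
#'
#' The seven analysis bands plus the full band used throughout the package:
#' delta (2-4 Hz), theta (4-8 Hz), alpha1 (8-9 Hz), alpha2 (10-12 Hz),
#' alpha3 (8-12 Hz), low beta (12-15 Hz), beta (15-18 Hz) and total (2-18 Hz).
#' Band intervals are half-open, `[lo, hi)`: a 1-Hz periodogram bin at a shared
#' edge frequency (4, 8, 12, 15 Hz) belongs to the upper band only, so the
#' disjoint bands partition 2-18 Hz without double counting. Note the gap at
#' 9-10 Hz between alpha1 and alpha2, and that alpha3 spans both: these bands
#' overlap by design and are not part of the disjoint partition.
#'
#' @param name optional band name; if given, return that single band definition.
#' @return A data frame with columns `name`, `label` (the predictor-name
#'   dialect, e.g. `"Alpha-10-12"`), `lo`, `hi` (Hz); or one row if `name`
#'   is supplied.
#' @examples
#' canonical_bands()
#' canonical_bands("alpha2")
#' @export
canonical_bands <- function(name = NULL) {
  bands <- data.frame(
    name  = c("delta", "theta", "alpha1", "alpha2", "alpha3",
              "lowbeta", "beta", "total"),
    label = c("Delta-2-4", "Theta-4-8", "Alpha-8-9", "Alpha-10-12",
              "Alpha-8-12", "Beta-12-15", "Beta-15-18", "total"),
    lo    = c(2, 4, 8, 10, 8, 12, 15, 2),
    hi    = c(4, 8, 9, 12, 12, 15, 18, 18),
    stringsAsFactors = FALSE
  )
  if (is.null(name)) {
    return(bands)
  }
  hit <- bands[bands$name == name, , drop = FALSE]
  if (nrow(hit) == 0) {
    stop("unknown band '", name, "'; valid bands: ",
         paste(bands$name, collapse = ", "), call. = FALSE)
  }
  hit
}

#' The five disjoint bands partitioning 2-18 Hz
#'
#' delta, theta, alpha3, low beta and beta tile the total band exactly under
#' the half-open convention. Used by the synthetic generator and by additivity
#' checks.
#'
#' @return data frame as in [canonical_bands()].
#' @export
partition_bands <- function() {
  b <- canonical_bands()
  b[b$name %in% c("delta", "theta", "alpha3", "lowbeta", "beta"), , drop = FALSE]
}
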