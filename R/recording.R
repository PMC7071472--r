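#' Construct an EEG recording object
#'
#' A recording is a set of equal-length channels sampled at a common rate, with
#' channel roles (EEG or EOG) and optional labeled time-interval annotations
#' (e.g. blink events). Units are microvolts and seconds; time intervals are
#' half-open `[start, end)`; sample indexing is 0-based in time
#' (sample `k` sits at `k / rate` seconds).
#'
#' @param data numeric matrix, one column per channel (samples x channels), or
#'   a named list of equal-length numeric vectors.
#' @param rate sampling rate in Hz.
#' @param channels character vector of channel labels (defaults to column
#'   names of `data`).
#' @param roles character vector, one of `"EEG"`/`"EOG"` per channel. Channels
#'   named `Fp1`/`Fp2` default to EEG, `EOG*` to EOG.
#' @param annotations data frame with columns `label`, `start_s`, `end_s`
#'   (half-open seconds), or `NULL`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, rate, channels = NULL, roles = NULL,
                          annotations = NULL) {
  if (is.list(data) && !is.data.frame(data)) {
    channels <- channels %||% names(data)
    data <- do.call(cbind, data)
  }
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  channels <- channels %||% colnames(data)
  if (is.null(channels)) {
    stop("channel labels required (give 'channels' or name the columns)",
         call. = FALSE)
  }
  if (length(channels) != ncol(data)) {
    stop("length(channels) must equal ncol(data)", call. = FALSE)
  }
  assert_scalar_pos(rate, "rate")
  if (is.null(roles)) {
    roles <- ifelse(grepl("^EOG", channels, ignore.case = TRUE), "EOG", "EEG")
  }
  if (!all(roles %in% c("EEG", "EOG"))) {
    stop("roles must be 'EEG' or 'EOG'", call. = FALSE)
  }
  colnames(data) <- channels
  dur <- nrow(data) / rate
  if (!is.null(annotations)) {
    stopifnot(all(c("label", "start_s", "end_s") %in% names(annotations)))
    if (nrow(annotations) > 0 &&
        (any(annotations$start_s < 0) || any(annotations$end_s > dur + 1e-9))) {
      stop("annotation intervals must lie within [0, duration)", call. = FALSE)
    }
  } else {
    annotations <- data.frame(label = character(), start_s = numeric(),
                              end_s = numeric(), stringsAsFactors = FALSE)
  }
  structure(
    list(data = data, rate = rate, channels = channels, roles = roles,
         annotations = annotations),
    class = "eeg_recording"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Recording duration in seconds
#' @param rec an [eeg_recording()].
#' @return duration in seconds.
#' @export
duration <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  nrow(rec$data) / rec$rate
}

#' Labels of channels with a given role
#' @param rec an [eeg_recording()].
#' @param role `"EEG"` or `"EOG"`.
#' @return character vector of channel labels.
#' @export
channels_with_role <- function(rec, role = "EEG") {
  rec$channels[rec$roles == role]
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %.1f s @ %g Hz\n",
              ncol(x$data), duration(x), x$rate))
  cat("  channels:", paste(sprintf("%s[%s]", x$channels, x$roles),
                           collapse = " "), "\n")
  if (nrow(x$annotations) > 0) {
    cat(sprintf("  annotations: %d (%s)\n", nrow(x$annotations),
                paste(unique(x$annotations$label), collapse = ", ")))
  }
  invisible(x)
}

#' Write a recording as a delimited table
#'
#' Plain-text interchange format: one row per sample, first column `time_s`,
#' then one column per channel. Annotations, roles and the rate are stored in
#' `#`-prefixed header lines so the file round-trips losslessly.
#'
#' @param rec an [eeg_recording()].
#' @param path output file path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate_hz: %.10g", rec$rate), con)
  writeLines(sprintf("# roles: %s", paste(rec$roles, collapse = ",")), con)
  if (nrow(rec$annotations) > 0) {
    writeLines(sprintf("# annotation: %s %.9f %.9f", rec$annotations$label,
                       rec$annotations$start_s, rec$annotations$end_s), con)
  }
  n <- nrow(rec$data)
  tab <- data.frame(time_s = (seq_len(n) - 1) / rec$rate, rec$data,
                    check.names = FALSE)
  utils::write.table(format(tab, digits = 10, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path file path.
#' @return an [eeg_recording()].
#' @export
read_recording <- function(path) {
  header <- character()
  con <- file(path, "r")
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || !startsWith(line, "#")) break
    header <- c(header, line)
  }
  close(con)
  rate <- as.numeric(sub("^# rate_hz: *", "", grep("^# rate_hz:", header,
                                                   value = TRUE)))
  roles_line <- grep("^# roles:", header, value = TRUE)
  ann_lines <- grep("^# annotation:", header, value = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", check.names = FALSE)
  chans <- setdiff(names(tab), "time_s")
  roles <- NULL
  if (length(roles_line) == 1) {
    roles <- strsplit(sub("^# roles: *", "", roles_line), ",")[[1]]
  }
  ann <- NULL
  if (length(ann_lines) > 0) {
    parts <- strsplit(sub("^# annotation: *", "", ann_lines), " +")
    ann <- data.frame(
      label = vapply(parts, `[`, "", 1),
      start_s = as.numeric(vapply(parts, `[`, "", 2)),
      end_s = as.numeric(vapply(parts, `[`, "", 3)),
      stringsAsFactors = FALSE
    )
  }
  eeg_recording(as.matrix(tab[chans]), rate = rate, channels = chans,
                roles = roles, annotations = ann)
}
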