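#' Configuration for a synthetic pBCI cohort
#'
#' Defines the study conditions a generated cohort emulates: a 35-participant
#' cohort recorded at 2048 Hz from Fp1/Fp2 (plus two EOG channels), one 60-s
#' resting session and three task sessions (valence / relaxation / attention
#' analogues). Each EEG channel is a sum of five band-limited Gaussian
#' oscillations (delta, theta, alpha 8-12, low beta, beta) over a 1/f
#' background; per-band amplitudes follow a participant-specific epochwise
#' log-amplitude random walk whose depth controls the dynamic range (IQR) of
#' the derived features. A `link_spec` ties each task feature's dynamic range
#' to one designated resting-state predictor, giving downstream regression a
#' known recoverable signal.
#'
#' @param n_participants cohort size (>= 3).
#' @param native_rate sampling rate in Hz of the generated raw recordings.
#' @param resting_duration resting-session length, seconds.
#' @param task_durations named vector of task-session lengths in seconds;
#'   names must be a subset of `c("valence", "relaxation", "attention")`.
#' @param sessions which sessions to synthesize (always includes "resting").
#' @param band_profile data frame with columns `name` (delta, theta, alpha,
#'   lowbeta, beta), `rms_uv` (baseline RMS amplitude, microvolts), `depth_lo`,
#'   `depth_hi` (range of the participant-specific modulation depth, in
#'   log-amplitude IQR units; participant depths drawn uniformly).
#' @param asym_depth length-2 range for the participant-specific depth of the
#'   interhemispheric alpha log-amplitude difference walk. The resting truth
#'   value of the `IQR-Asym-Alpha-8-12` predictor is twice this depth.
#' @param asym_offset constant log-amplitude offset between Fp1 and Fp2 alpha
#'   (Fp1 gets `+offset/2`); nonzero values shift the frontal alpha asymmetry
#'   without affecting its IQR.
#' @param background_rms RMS amplitude (microvolts) of the 1/f background
#'   (power exponent 1.0) per channel.
#' @param link_spec named list, one entry per feature (`FAA`, `rFTP`,
#'   `rFLBP`), each a list with `predictor` (canonical resting predictor
#'   name), `coefficient`, and either `noise_sd` (absolute Gaussian noise SD)
#'   or `noise_frac` (noise SD as a fraction of the cohort SD of
#'   `coefficient * predictor`). `NULL` entries leave a feature unlinked.
#' @param blink_rate eye-blink rate, events per minute.
#' @param eog if `TRUE`, synthesize two EOG channels carrying the blink train.
#' @param seed integer root seed; all randomness flows from it through
#'   counter-based per-participant substreams.
#' @return A validated list of class `cohort_config`.
#' @seealso [generate_participant()], [generate_cohort()]
#' @export
cohort_config <- function(n_participants = 35,
                          native_rate = 2048,
                          resting_duration = 60,
                          task_durations = c(valence = 120, relaxation = 120,
                                             attention = 120),
                          sessions = c("resting", names(task_durations)),
                          band_profile = default_band_profile(),
                          asym_depth = c(0.1, 0.5),
                          asym_offset = 0,
                          background_rms = 10,
                          link_spec = default_link_spec(),
                          blink_rate = 12,
                          eog = TRUE,
                          seed = 1L) {
  if (!is.numeric(n_participants) || n_participants < 3) {
    config_error("n_participants", "must be >= 3")
  }
  assert_scalar_pos(native_rate, "native_rate")
  assert_scalar_pos(resting_duration, "resting_duration")
  if (length(task_durations) > 0) {
    if (is.null(names(task_durations)) ||
        !all(names(task_durations) %in% c("valence", "relaxation", "attention"))) {
      config_error("task_durations",
                   "must be named with valence/relaxation/attention")
    }
    if (any(task_durations <= 0)) config_error("task_durations", "must be > 0")
  }
  sessions <- unique(c("resting", intersect(sessions, names(task_durations))))
  stopifnot(is.data.frame(band_profile),
            all(c("name", "rms_uv", "depth_lo", "depth_hi") %in%
                  names(band_profile)))
  if (!setequal(band_profile$name,
                c("delta", "theta", "alpha", "lowbeta", "beta"))) {
    config_error("band_profile",
                 "must define bands delta, theta, alpha, lowbeta, beta")
  }
  # native rate must comfortably exceed twice the highest synthesized frequency
  if (native_rate <= 2 * 18) {
    config_error("native_rate", "must exceed twice the highest band edge (18 Hz)")
  }
  if (length(asym_depth) != 2 || any(asym_depth < 0)) {
    config_error("asym_depth", "must be a nonnegative length-2 range")
  }
  if (blink_rate < 0) config_error("blink_rate", "must be >= 0")
  if (!is.null(link_spec)) {
    if (!all(names(link_spec) %in% c("FAA", "rFTP", "rFLBP"))) {
      config_error("link_spec", "entries must be named FAA/rFTP/rFLBP")
    }
    vocab <- predictor_vocabulary()$name
    for (feat in names(link_spec)) {
      ls <- link_spec[[feat]]
      if (is.null(ls)) next
      if (is.null(ls$predictor) || !(ls$predictor %in% vocab)) {
        stop("link_spec for ", feat, " names unknown predictor '",
             ls$predictor, "'; valid names are the 112 canonical predictors, ",
             "e.g. ", paste(utils::head(vocab, 3), collapse = ", "),
             ", ... (see predictor_vocabulary())", call. = FALSE)
      }
      if (is.null(ls$coefficient)) config_error("link_spec", "needs coefficient")
      if (is.null(ls$noise_sd) && is.null(ls$noise_frac)) {
        config_error("link_spec", "needs noise_sd or noise_frac")
      }
    }
  }
  seed <- as.integer(seed)
  structure(
    list(n_participants = as.integer(n_participants),
         native_rate = native_rate,
         resting_duration = resting_duration,
         task_durations = task_durations,
         sessions = sessions,
         band_profile = band_profile,
         asym_depth = asym_depth,
         asym_offset = asym_offset,
         background_rms = background_rms,
         link_spec = link_spec,
         blink_rate = blink_rate,
         eog = isTRUE(eog),
         seed = seed),
    class = "cohort_config"
  )
}

#' Default band amplitude/modulation profile for the synthetic cohort
#'
#' Baseline RMS amplitudes are typical prefrontal scalp values (microvolts);
#' modulation-depth ranges produce feature IQRs spanning roughly a factor of
#' five across participants, emulating the large interindividual variability
#' of dynamic ranges the screening problem targets.
#'
#' @return data frame with columns `name`, `rms_uv`, `depth_lo`, `depth_hi`.
#' @export
default_band_profile <- function() {
  data.frame(
    name     = c("delta", "theta", "alpha", "lowbeta", "beta"),
    rms_uv   = c(8, 6, 10, 4, 3),
    depth_lo = c(0.10, 0.10, 0.10, 0.10, 0.10),
    depth_hi = c(0.40, 0.50, 0.50, 0.40, 0.40),
    stringsAsFactors = FALSE
  )
}

#' Default predictor-to-feature link specification
#'
#' Ties each task feature's dynamic range to its feature-matched resting-state
#' predictor with unit coefficient and noise SD equal to 10% of the cohort
#' spread of the linked component.
#' @return named list usable as `link_spec` in [cohort_config()].
#' @export
default_link_spec <- function() {
  list(
    FAA   = list(predictor = "IQR-Asym-Alpha-8-12",     coefficient = 1,
                 noise_frac = 0.1),
    rFTP  = list(predictor = "IQR-Rel-Fp12-Theta-4-8",  coefficient = 1,
                 noise_frac = 0.1),
    rFLBP = list(predictor = "IQR-Rel-Fp12-Beta-12-15", coefficient = 1,
                 noise_frac = 0.1)
  )
}

# session carrying the linked task feature
feature_session <- c(FAA = "valence", rFTP = "relaxation", rFLBP = "attention")

# centered random walk rescaled to interquartile range exactly 1
standardized_walk <- function(n) {
  if (n < 4) return(rep(0, n))
  s <- cumsum(stats::rnorm(n))
  s <- s - mean(s)
  q <- iqr(s)
  if (q < 1e-12) return(rep(0, n))
  s / q
}

# substream counter layout (per participant): params, per-session truth walks,
# per-session waveform noise, per-session blinks, link noise
.k_params <- 0L
.k_truth <- function(j) 10L + j
.k_wave  <- function(j) 30L + j
.k_blink <- function(j) 50L + j
.k_link  <- 70L

session_duration <- function(config, session) {
  if (session == "resting") config$resting_duration
  else unname(config$task_durations[[session]])
}

# participant-specific modulation depths and offsets
participant_params <- function(config, i) {
  with_substream(config$seed, i * 100L + .k_params, {
    bp <- config$band_profile
    depths <- stats::runif(nrow(bp), bp$depth_lo, bp$depth_hi)
    names(depths) <- bp$name
    asym <- stats::runif(1, config$asym_depth[1], config$asym_depth[2])
    list(depths = depths, asym_depth = asym)
  })
}

# Truth band powers (epochs x 5 bands x 2 channels) for one session, plus the
# truth per-epoch feature series derived analytically from those powers.
# `target` optionally pins the session's linked feature IQR by construction.
session_truth <- function(config, i, session, params,
                          target = NULL, target_feature = NULL) {
  n_ep <- floor(session_duration(config, session))
  bp <- config$band_profile
  j <- match(session, c("resting", "valence", "relaxation", "attention"))
  walks <- with_substream(config$seed, i * 100L + .k_truth(j), {
    w <- vapply(seq_len(nrow(bp)), function(b) standardized_walk(n_ep),
                numeric(n_ep))
    d <- standardized_walk(n_ep)   # interhemispheric alpha difference walk
    extra <- standardized_walk(n_ep)  # walk reserved for linked targets
    list(bands = w, d = d, extra = extra)
  })
  logamp <- sweep(walks$bands, 2, params$depths[bp$name], `*`)
  logamp <- sweep(logamp, 2, log(bp$rms_uv), `+`)   # n_ep x 5, shared channels
  colnames(logamp) <- bp$name

  d <- params$asym_depth * walks$d
  if (!is.null(target) && identical(target_feature, "FAA")) {
    # FAA(e) = 2 * d(e) (+ constant offset): pin IQR to the target exactly
    d <- (target / 2) * walks$extra
  }
  half <- (d + config$asym_offset) / 2
  P <- array(NA_real_, dim = c(n_ep, nrow(bp), 2),
             dimnames = list(NULL, bp$name, c("Fp1", "Fp2")))
  for (b in bp$name) {
    la1 <- logamp[, b] + if (b == "alpha") half else 0
    la2 <- logamp[, b] - if (b == "alpha") half else 0
    # floor keeps silent bands (rms 0) from degenerating log-ratio truths
    P[, b, 1] <- pmax(exp(2 * la1), 1e-20)
    P[, b, 2] <- pmax(exp(2 * la2), 1e-20)
  }

  if (!is.null(target) && target_feature %in% c("rFTP", "rFLBP")) {
    band <- if (target_feature == "rFTP") "theta" else "lowbeta"
    r0 <- bp$rms_uv[bp$name == band]^2 / sum(bp$rms_uv^2)
    r <- pmin(pmax(r0 + target * walks$extra, 0.02), 0.95)
    for (ch in 1:2) {
      other <- rowSums(P[, setdiff(bp$name, band), ch, drop = FALSE])
      P[, band, ch] <- r / (1 - r) * other
    }
  }
  list(P = P, features = truth_features(P))
}

# analytic per-epoch feature values from truth band powers
truth_features <- function(P) {
  tot1 <- rowSums(matrix(P[, , 1], ncol = dim(P)[2]))
  tot2 <- rowSums(matrix(P[, , 2], ncol = dim(P)[2]))
  data.frame(
    epoch = rep(seq_len(nrow(P)), 3),
    feature = rep(c("FAA", "rFTP", "rFLBP"), each = nrow(P)),
    value = c(log(P[, "alpha", 1] / P[, "alpha", 2]),
              (P[, "theta", 1] + P[, "theta", 2]) / (tot1 + tot2),
              (P[, "lowbeta", 1] + P[, "lowbeta", 2]) / (tot1 + tot2)),
    stringsAsFactors = FALSE
  )
}

#' Ground-truth resting-state predictor vector from truth band powers
#'
#' Assembles the full 112-entry canonical predictor vector analytically from
#' the generator's per-epoch truth band powers (before waveform synthesis,
#' spectral estimation, or artifacts). Sub-bands of the generator's flat
#' 8-12 Hz alpha process (alpha1 8-9, alpha2 10-12) receive the proportional
#' share of its power (1/4 and 2/4).
#'
#' @param P epochs x 5-band x 2-channel truth power array from the generator.
#' @return named numeric vector over [predictor_vocabulary()].
#' @export
truth_predictor_vector <- function(P) {
  stopifnot(length(dim(P)) == 3, dim(P)[2] == 5)
  share <- c(delta = NA, theta = NA, alpha1 = 1 / 4, alpha2 = 2 / 4,
             alpha3 = 1, lowbeta = NA, beta = NA)
  p8 <- function(ch) {
    tot <- rowSums(matrix(P[, , ch], ncol = dim(P)[2]))
    cbind(`Delta-2-4`   = P[, "delta", ch],
          `Theta-4-8`   = P[, "theta", ch],
          `Alpha-8-9`   = P[, "alpha", ch] * share[["alpha1"]],
          `Alpha-10-12` = P[, "alpha", ch] * share[["alpha2"]],
          `Alpha-8-12`  = P[, "alpha", ch],
          `Beta-12-15`  = P[, "lowbeta", ch],
          `Beta-15-18`  = P[, "beta", ch],
          total         = tot)
  }
  assemble_predictors(p8(1), p8(2))
}

# synthesize one channel's waveform from truth powers (band-limited Gaussian
# noise per band, piecewise-constant per-epoch RMS envelopes, 1/f background)
synth_channel <- function(P_ch, bands_def, rate, n_samp, background_rms) {
  n_ep <- nrow(P_ch)
  x <- numeric(n_samp)
  for (b in seq_len(ncol(P_ch))) {
    def <- bands_def[b, ]
    z <- band_limited_noise(n_samp, rate, def$lo, def$hi)
    env <- rep(sqrt(P_ch[, b]), each = round(rate))[seq_len(n_samp)]
    if (length(env) < n_samp) env <- c(env, rep(env[length(env)],
                                                n_samp - length(env)))
    x <- x + z * env
  }
  x + pink_noise(n_samp, rate, background_rms)
}

# unit-RMS Gaussian noise band-limited to [lo, hi) Hz: complex Gaussian
# spectrum drawn on the band bins only (Hermitian), one inverse DFT
band_limited_noise <- function(n, rate, lo, hi) {
  half <- floor(n / 2)
  f <- (0:half) * rate / n
  keep <- which(f >= lo & f < hi)
  if (length(keep) == 0) return(numeric(n))
  z <- complex(real = stats::rnorm(length(keep)),
               imaginary = stats::rnorm(length(keep)))
  spec <- complex(length.out = n)
  spec[keep] <- z
  mirror <- keep[keep > 1 & keep <= (n + 1) %/% 2]
  spec[n + 2 - mirror] <- Conj(spec[mirror])
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s < 1e-15) return(numeric(n))
  x / s
}

# 1/f-power background (amplitude ~ f^-1/2) above 0.5 Hz, scaled to given RMS
pink_noise <- function(n, rate, rms) {
  if (rms <= 0) return(numeric(n))
  half <- floor(n / 2)
  f <- (0:half) * rate / n
  keep <- which(f >= 0.5)
  z <- complex(real = stats::rnorm(length(keep)),
               imaginary = stats::rnorm(length(keep)))
  spec <- complex(length.out = n)
  spec[keep] <- z / sqrt(f[keep])
  mirror <- keep[keep > 1 & keep <= (n + 1) %/% 2]
  spec[n + 2 - mirror] <- Conj(spec[mirror])
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x / stats::sd(x) * rms
}

# clean-waveform synthesis of one session's recording (no blinks yet)
synth_session_recording <- function(config, i, session, P) {
  n_samp <- round(session_duration(config, session) * config$native_rate)
  bands_def <- data.frame(
    lo = c(2, 4, 8, 12, 15), hi = c(4, 8, 12, 15, 18),
    row.names = c("delta", "theta", "alpha", "lowbeta", "beta")
  )
  j <- match(session, c("resting", "valence", "relaxation", "attention"))
  with_substream(config$seed, i * 100L + .k_wave(j), {
    fp1 <- synth_channel(P[, , 1], bands_def, config$native_rate, n_samp,
                         config$background_rms)
    fp2 <- synth_channel(P[, , 2], bands_def, config$native_rate, n_samp,
                         config$background_rms)
    chans <- list(Fp1 = fp1, Fp2 = fp2)
    if (config$eog) {
      # ocular activity is band-limited; 0.5-8 Hz covers blinks + saccades
      chans$EOG1 <- band_limited_noise(n_samp, config$native_rate, 0.5, 8) * 5
      chans$EOG2 <- band_limited_noise(n_samp, config$native_rate, 0.5, 8) * 5
    }
    eeg_recording(chans, rate = config$native_rate)
  })
}

# measure the 112 resting predictors from a clean recording through the
# standard spectral pipeline (downsample, band-pass, segment; no rejection)
measured_resting_predictors <- function(rec) {
  rec <- bandpass_recording(resample_recording(rec, 256), 0.5, 30)
  extract_candidate_predictors(segment_recording(rec, 1, 0.5))
}

# everything about a participant that exists before the task-feature link is
# applied: modulation parameters, resting truth, the clean resting recording,
# and the resting predictors measured from it
participant_core <- function(config, i) {
  params <- participant_params(config, i)
  rest <- session_truth(config, i, "resting", params)
  rec <- synth_session_recording(config, i, "resting", rest$P)
  list(params = params, rest = rest,
       truth_pred = truth_predictor_vector(rest$P),
       resting_rec = rec,
       measured_pred = measured_resting_predictors(rec))
}

# resolve fractional link noise to absolute SDs using the cohort spread of
# the measured resting predictors (synthesizes resting waveforms if cores
# are not supplied)
resolve_link_noise <- function(config, cores = NULL) {
  if (is.null(config$link_spec)) return(config)
  fracs <- vapply(config$link_spec, function(l) !is.null(l$noise_frac), TRUE)
  if (!any(fracs)) return(config)
  if (is.null(cores)) {
    cores <- lapply(seq_len(config$n_participants) - 1L,
                    function(i) participant_core(config, i))
  }
  mp <- vapply(cores, `[[`, numeric(112), "measured_pred")
  for (feat in names(config$link_spec)[fracs]) {
    l <- config$link_spec[[feat]]
    comp <- l$coefficient * mp[l$predictor, ]
    config$link_spec[[feat]]$noise_sd <- l$noise_frac * stats::sd(comp)
    config$link_spec[[feat]]$noise_frac <- NULL
  }
  config
}

# finish a participant from a prepared core: linked task targets, task truth
# and waveforms, blink injection, ground-truth bookkeeping
assemble_participant <- function(config, i, core) {
  targets <- data.frame(feature = character(), target_iqr = numeric(),
                        stringsAsFactors = FALSE)
  if (!is.null(config$link_spec)) {
    noise <- with_substream(config$seed, i * 100L + .k_link,
                            stats::rnorm(3))
    names(noise) <- c("FAA", "rFTP", "rFLBP")
    for (feat in names(config$link_spec)) {
      l <- config$link_spec[[feat]]
      if (is.null(l)) next
      tgt <- l$coefficient * core$measured_pred[[l$predictor]] +
        l$noise_sd * noise[[feat]]
      targets <- rbind(targets, data.frame(feature = feat,
                                           target_iqr = max(tgt, 1e-4)))
    }
  }

  truths <- list(resting = core$rest)
  for (session in setdiff(config$sessions, "resting")) {
    feat <- names(feature_session)[feature_session == session]
    tgt <- targets$target_iqr[targets$feature == feat]
    truths[[session]] <- session_truth(
      config, i, session, core$params,
      target = if (length(tgt) == 1) tgt else NULL,
      target_feature = if (length(tgt) == 1) feat else NULL
    )
  }

  recordings <- list()
  blink_times <- list()
  j_of <- function(s) match(s, c("resting", "valence", "relaxation",
                                 "attention"))
  for (session in config$sessions) {
    rec <- if (session == "resting") {
      core$resting_rec
    } else {
      synth_session_recording(config, i, session, truths[[session]]$P)
    }
    if (config$blink_rate > 0) {
      rec <- inject_blinks(rec, config$blink_rate,
                           seed = substream_seed(
                             config$seed, i * 100L + .k_blink(j_of(session))))
    }
    recordings[[session]] <- rec
    ann <- rec$annotations
    blink_times[[session]] <- ann$start_s[ann$label == "blink"]
  }

  series <- do.call(rbind, lapply(names(truths), function(s) {
    cbind(session = s, truths[[s]]$features, stringsAsFactors = FALSE)
  }))
  iqr_tab <- do.call(rbind, lapply(split(series,
                                         series[c("session", "feature")]),
                                   function(df) {
    data.frame(session = df$session[1], feature = df$feature[1],
               iqr = iqr(df$value), stringsAsFactors = FALSE)
  }))
  rownames(iqr_tab) <- NULL

  structure(
    list(participant = sprintf("P%03d", i + 1),
         recordings = recordings,
         truth = list(series = series, iqr = iqr_tab,
                      predictors = core$truth_pred, targets = targets),
         measured_predictors = core$measured_pred,
         blink_times = blink_times),
    class = "synthetic_participant"
  )
}

#' Generate one synthetic participant
#'
#' Deterministic given `(config$seed, participant_index)`: returns the
#' participant's recordings for the resting session and every configured task
#' session at the native rate, the analytic ground-truth per-epoch feature
#' series and their IQRs (recorded before artifact injection), the analytic
#' truth predictor vector, the 112 resting predictors as measured from the
#' clean resting recording (the quantities the task-feature link operates
#' on), the linked task-feature IQR targets, and injected blink onset times.
#'
#' @param config a [cohort_config()]. Fractional link noise is resolved
#'   internally (deterministically) if needed, which requires synthesizing
#'   the whole cohort's resting recordings; prefer [generate_cohort()] when
#'   generating everyone.
#' @param participant_index 0-based index below `config$n_participants`.
#' @return list of class `synthetic_participant` with elements `participant`,
#'   `recordings`, `truth` (`series`, `iqr`, `predictors`, `targets`),
#'   `measured_predictors`, `blink_times`.
#' @export
generate_participant <- function(config, participant_index) {
  stopifnot(inherits(config, "cohort_config"))
  if (participant_index < 0 || participant_index >= config$n_participants) {
    config_error("participant_index", "must be in [0, n_participants)")
  }
  config <- resolve_link_noise(config)
  i <- as.integer(participant_index)
  assemble_participant(config, i, participant_core(config, i))
}

#' Generate a full synthetic cohort
#'
#' Applies [generate_participant()] across the cohort after resolving any
#' fractional link noise to a cohort-level absolute SD, and assembles the
#' ground-truth tables: per-participant linked task-feature IQR targets,
#' realized truth IQRs, and the full truth predictor matrix.
#'
#' @param config a [cohort_config()].
#' @return list of class `synthetic_cohort` with `participants` (list),
#'   `truth_iqr` (data frame: participant, session, feature, true_iqr,
#'   target_iqr), `truth_predictors` and `measured_predictors`
#'   (participants x 112 matrices: analytic truth values and the values
#'   measured from the clean resting recordings), and the resolved `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  ids <- seq_len(config$n_participants) - 1L
  cores <- lapply(ids, function(i) participant_core(config, i))
  config <- resolve_link_noise(config, cores)
  parts <- lapply(seq_along(ids),
                  function(k) assemble_participant(config, ids[k], cores[[k]]))
  truth_iqr <- do.call(rbind, lapply(parts, function(p) {
    tab <- p$truth$iqr
    tab$participant <- p$participant
    tab$target_iqr <- p$truth$targets$target_iqr[
      match(tab$feature, p$truth$targets$feature)]
    tab[c("participant", "session", "feature", "iqr", "target_iqr")]
  }))
  names(truth_iqr)[names(truth_iqr) == "iqr"] <- "true_iqr"
  tp <- t(vapply(parts, function(p) p$truth$predictors, numeric(112)))
  mp <- t(vapply(parts, function(p) p$measured_predictors, numeric(112)))
  rownames(tp) <- rownames(mp) <- vapply(parts, `[[`, "", "participant")
  structure(
    list(participants = parts, truth_iqr = truth_iqr, truth_predictors = tp,
         measured_predictors = mp, config = config),
    class = "synthetic_cohort"
  )
}

# raised-cosine biphasic blink pulse, peak amplitude 1, duration dur_s
blink_template <- function(rate, dur_s) {
  n <- max(round(dur_s * rate), 8)
  t <- seq(0, 1, length.out = n)
  pos <- ifelse(t <= 0.65, 0.5 * (1 - cos(2 * pi * t / 0.65)), 0)
  neg <- ifelse(t >= 0.55, -0.35 * 0.5 * (1 - cos(2 * pi * (t - 0.55) / 0.45)), 0)
  pos + neg
}

#' Inject stereotyped eye-blink transients into a recording
#'
#' Adds raised-cosine biphasic pulses (duration 200-400 ms) at
#' Poisson-distributed onsets. On prefrontal EEG channels the peak amplitude
#' is eight times the channel's pre-injection RMS (well above the 5x floor a
#' blink detector targets); EOG channels receive a stronger copy of the same
#' pulse train, emulating their proximity to the eyes. Blink intervals are
#' recorded as `"blink"` annotations.
#'
#' @param rec an [eeg_recording()] with at least one prefrontal EEG channel.
#' @param rate blink rate in events per minute (>= 0).
#' @param seed integer seed for onset/duration/gain draws.
#' @return the recording with blinks added and annotated.
#' @export
inject_blinks <- function(rec, rate, seed = 1L) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rate < 0) stop("blink rate must be >= 0", call. = FALSE)
  pf <- intersect(c("Fp1", "Fp2"), channels_with_role(rec, "EEG"))
  if (length(pf) == 0) {
    stop("recording has no prefrontal EEG channel (Fp1/Fp2)", call. = FALSE)
  }
  if (rate == 0) return(rec)
  dur <- duration(rec)
  with_substream(as.integer(seed), 0L, {
    k <- stats::rpois(1, rate * dur / 60)
    if (k == 0) return(rec)
    durs <- stats::runif(k, 0.2, 0.4)
    onsets <- sort(stats::runif(k, 0, pmax(dur - max(durs), 0)))
    data <- rec$data
    rms <- apply(data, 2, function(x) sqrt(mean(x^2)))
    for (idx in seq_len(k)) {
      tpl <- blink_template(rec$rate, durs[idx])
      s0 <- round(onsets[idx] * rec$rate) + 1
      span <- s0:min(s0 + length(tpl) - 1, nrow(data))
      tpl <- tpl[seq_along(span)]
      for (ch in seq_along(rec$channels)) {
        gain <- if (rec$roles[ch] == "EOG") {
          12 * max(rms[ch], 1)
        } else if (rec$channels[ch] %in% pf) {
          8 * rms[ch] * stats::runif(1, 0.9, 1.1)
        } else {
          2 * rms[ch]
        }
        data[span, ch] <- data[span, ch] + gain * tpl
      }
    }
    ann <- rbind(rec$annotations,
                 data.frame(label = "blink", start_s = onsets,
                            end_s = onsets + durs, stringsAsFactors = FALSE))
    eeg_recording(data, rate = rec$rate, channels = rec$channels,
                  roles = rec$roles, annotations = ann)
  })
}

#' Write a synthetic cohort to disk as delimited tables
#'
#' One tab-separated file per session per participant
#' (`<participant>_<session>.tsv`, columns `time_s`, `Fp1`, `Fp2`, and EOG
#' channels if present), plus `ground_truth_iqr.tsv` and
#' `truth_predictors.tsv`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in cohort$participants) {
    for (session in names(p$recordings)) {
      write_recording(p$recordings[[session]],
                      file.path(dir, paste0(p$participant, "_", session,
                                            ".tsv")))
    }
  }
  utils::write.table(cohort$truth_iqr,
                     file.path(dir, "ground_truth_iqr.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tp <- data.frame(participant = rownames(cohort$truth_predictors),
                   cohort$truth_predictors, check.names = FALSE)
  utils::write.table(tp, file.path(dir, "truth_predictors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  mp <- data.frame(participant = rownames(cohort$measured_predictors),
                   cohort$measured_predictors, check.names = FALSE)
  utils::write.table(mp, file.path(dir, "measured_predictors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
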