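# deterministic fixtures shared across the suite; everything is generated in
# code at test time

# two-channel recording from explicit sample vectors
make_rec <- function(x1, x2 = x1, rate = 256, eog = NULL) {
  chans <- list(Fp1 = x1, Fp2 = x2)
  if (!is.null(eog)) chans <- c(chans, eog)
  eeg_recording(chans, rate = rate)
}

# pure sinusoid sampled over whole seconds (bin-centered for 1-s windows)
sinusoid <- function(freq, amp = 1, rate = 256, dur = 1, phase = 0) {
  t <- seq(0, dur, length.out = rate * dur + 1)[-(rate * dur + 1)]
  amp * sin(2 * pi * freq * t + phase)
}

# small resting-only cohort configuration used by unit tests
tiny_config <- function(seed = 1, n = 3, dur = 20, ...) {
  cohort_config(n_participants = n, resting_duration = dur,
                task_durations = NULL, sessions = "resting",
                eog = FALSE, link_spec = NULL, seed = seed, ...)
}

# sort-based type-7 quantile oracle, independent of stats::quantile
iqr_oracle <- function(x) {
  q7 <- function(p) {
    xs <- sort(x)
    h <- (length(xs) - 1) * p + 1
    lo <- floor(h)
    xs[lo] + (h - lo) * (xs[min(lo + 1, length(xs))] - xs[lo])
  }
  q7(0.75) - q7(0.25)
}
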