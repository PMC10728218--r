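#' Specification of a synthetic two-group EEG cohort
#'
#' Describes a seeded cohort of resting-state EEG recordings split into a
#' seizure-free-like (SF) and a non-seizure-free-like (NSF) group. Both groups
#' share a 1/f^alpha background; the group difference is planted as transient
#' Gaussian-windowed oscillatory bursts whose carrier frequency lies in a
#' configurable narrow band, at group-specific rates and amplitudes. Bursts
#' produce heavy-tailed band-limited amplitude distributions, so their
#' footprint shows up in kurtosis and maximum-value features after
#' band-passing.
#'
#' Defaults mirror a 46-patient cohort (22 SF / 24 NSF) of 21-channel
#' recordings sampled at 250 Hz and long enough to contain the 20-320 s
#' resting epoch.
#'
#' @param n_sf,n_nsf Number of subjects per group (each >= 2).
#' @param fs Sampling rate in Hz.
#' @param duration_s Recording length in seconds (>= 320).
#' @param channels Ordered list of exactly 21 unique channel names.
#' @param effect_band Length-2 numeric `(low_hz, high_hz)` of the planted
#'   difference; must satisfy `0 < low < high < fs/2`.
#' @param event_rate_sf,event_rate_nsf Expected bursts per minute per group.
#' @param event_amp_sf,event_amp_nsf Burst amplitude in microvolts per group.
#' @param event_duration_s Burst envelope duration (s).
#' @param background_exponent Spectral slope alpha of the 1/f^alpha background.
#' @param background_sd Per-channel background standard deviation (microvolts).
#' @param seed Integer seed; identical specs (including seed) generate
#'   bit-identical cohorts.
#'
#' @return A list of class `synthetic_cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
synthetic_cohort_spec <- function(n_sf = 22, n_nsf = 24, fs = 250,
                                  duration_s = 330,
                                  channels = montage_1020(),
                                  effect_band = c(39, 41),
                                  event_rate_sf = 2, event_rate_nsf = 8,
                                  event_amp_sf = 40, event_amp_nsf = 80,
                                  event_duration_s = 0.2,
                                  background_exponent = 1,
                                  background_sd = 15,
                                  seed = 1L) {
  spec <- list(
    n_sf = n_sf, n_nsf = n_nsf, fs = fs, duration_s = duration_s,
    channels = channels, effect_band = effect_band,
    event_rate_sf = event_rate_sf, event_rate_nsf = event_rate_nsf,
    event_amp_sf = event_amp_sf, event_amp_nsf = event_amp_nsf,
    event_duration_s = event_duration_s,
    background_exponent = background_exponent,
    background_sd = background_sd, seed = as.integer(seed)
  )
  class(spec) <- "synthetic_cohort_spec"
  validate_cohort_spec(spec)
}

validate_cohort_spec <- function(spec) {
  bad <- function(field, why) {
    abort(sprintf("invalid `%s`: %s", field, why))
  }
  if (!is.numeric(spec$n_sf) || spec$n_sf < 2) bad("n_sf", "need >= 2 subjects")
  if (!is.numeric(spec$n_nsf) || spec$n_nsf < 2) bad("n_nsf", "need >= 2 subjects")
  if (spec$fs <= 0) bad("fs", "sampling rate must be positive")
  if (spec$duration_s < 320) {
    bad("duration_s", "must be >= 320 s so the 20-320 s resting epoch exists")
  }
  if (length(spec$channels) != 21 || anyDuplicated(spec$channels)) {
    bad("channels", "need exactly 21 unique channel names")
  }
  eb <- spec$effect_band
  if (length(eb) != 2 || !(0 < eb[1] && eb[1] < eb[2] && eb[2] < spec$fs / 2)) {
    bad("effect_band", "need 0 < low < high < fs/2")
  }
  for (f in c("event_rate_sf", "event_rate_nsf")) {
    if (spec[[f]] < 0) bad(f, "rate must be non-negative")
  }
  for (f in c("event_amp_sf", "event_amp_nsf", "event_duration_s",
              "background_sd")) {
    if (spec[[f]] <= 0) bad(f, "must be positive")
  }
  invisible(spec)
}

# 1/f^alpha noise via FFT shaping of white Gaussian noise. A real, symmetric
# spectral envelope preserves conjugate symmetry, so the output is real.
# Content below `hp_hz` is removed, mimicking a hardware high-pass.
# Returns an n x ncol matrix of independent unit-variance traces.
pink_noise <- function(n, fs, alpha, ncol = 1, hp_hz = 0.1) {
  w <- matrix(rnorm(n * ncol), n, ncol)
  f <- seq(0, n - 1) * fs / n
  f <- pmin(f, fs - f)                      # fold to physical frequency
  h <- ifelse(f < hp_hz, 0, f^(-alpha / 2))
  x <- Re(stats::mvfft(stats::mvfft(w) * h, inverse = TRUE)) / n
  sweep(x, 2, apply(x, 2, sd), "/")
}

# Gaussian-windowed sinusoidal bursts added to a channels x n matrix.
# The loop runs inside one function so the matrix is updated in place
# (a single copy) rather than once per event.
add_bursts <- function(mat, fs, times, freqs, phases, gains, amp, dur) {
  n <- ncol(mat)
  half <- dur / 2                           # envelope support: +/- 3 sd
  sd_env <- dur / 6
  for (e in seq_along(times)) {
    t0 <- times[e]
    i0 <- max(1L, floor((t0 - half) * fs) + 1L)
    i1 <- min(n, ceiling((t0 + half) * fs) + 1L)
    if (i0 > i1) next
    tt <- (seq(i0, i1) - 1) / fs
    burst <- amp * exp(-(tt - t0)^2 / (2 * sd_env^2)) *
      cos(2 * pi * freqs[e] * (tt - t0) + phases[e])
    mat[, i0:i1] <- mat[, i0:i1] + outer(gains[, e], burst)
  }
  mat
}

#' Generate a seeded synthetic EEG cohort
#'
#' Draws `n_sf + n_nsf` recordings according to a [synthetic_cohort_spec()].
#' Each subject's background combines a shared low-rank 1/f^alpha component
#' (a per-subject 21 x 4 mixing matrix applied to 4 common sources, giving
#' non-degenerate cross-channel correlation and phase locking) with
#' independent per-channel 1/f^alpha noise. Poisson-placed oscillatory bursts
#' with carrier frequency uniform in `effect_band` are then added at each
#' group's rate and amplitude, with per-channel gains.
#'
#' @param spec A [synthetic_cohort_spec()].
#' @return A list of class `labeled_cohort` with elements `recordings` (list
#'   of [eeg_recording()]), `labels` (factor with levels `SF`, `NSF`) and
#'   `subject_ids`.
#' @export
#' @examples
#' cohort <- generate_cohort(synthetic_cohort_spec(
#'   n_sf = 2, n_nsf = 2, fs = 100, duration_s = 320,
#'   effect_band = c(10, 12), seed = 7))
#' table(cohort$labels)
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  n_total <- spec$n_sf + spec$n_nsf
  labels <- factor(rep(c("SF", "NSF"), c(spec$n_sf, spec$n_nsf)),
                   levels = c("SF", "NSF"))
  subject_ids <- sprintf("S%02d_%s", seq_len(n_total), labels)
  n <- round(spec$fs * spec$duration_s)
  n_ch <- length(spec$channels)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  recs <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    grp <- as.character(labels[i])
    rate <- if (grp == "SF") spec$event_rate_sf else spec$event_rate_nsf
    amp <- if (grp == "SF") spec$event_amp_sf else spec$event_amp_nsf
    # shared low-rank background + independent channel noise
    traces <- pink_noise(n, spec$fs, spec$background_exponent, ncol = 4 + n_ch)
    sources <- t(traces[, 1:4, drop = FALSE])
    mixing <- matrix(rnorm(n_ch * 4, sd = 0.5), n_ch, 4)
    noise <- t(traces[, 4 + seq_len(n_ch), drop = FALSE])
    x <- mixing %*% sources + noise
    x <- x / apply(x, 1, sd) * spec$background_sd
    # transient oscillatory bursts in the effect band
    n_events <- rpois(1, rate * spec$duration_s / 60)
    if (n_events > 0) {
      times <- runif(n_events, 0, spec$duration_s)
      freqs <- runif(n_events, spec$effect_band[1], spec$effect_band[2])
      phases <- runif(n_events, 0, 2 * pi)
      gains <- matrix(runif(n_ch * n_events, 0.5, 1.5), n_ch, n_events)
      x <- add_bursts(x, spec$fs, times, freqs, phases, gains, amp,
                      spec$event_duration_s)
    }
    recs[[i]] <- eeg_recording(x, fs = spec$fs,
                               channel_names = spec$channels,
                               subject_id = subject_ids[i])
  }
  structure(
    list(recordings = recs, labels = labels, subject_ids = subject_ids,
         spec = spec),
    class = "labeled_cohort"
  )
}

#' @export
print.labeled_cohort <- function(x, ...) {
  cat(sprintf("<labeled_cohort: %d subjects (%d SF, %d NSF)>\n",
              length(x$recordings), sum(x$labels == "SF"),
              sum(x$labels == "NSF")))
  invisible(x)
}

# save/restore global RNG state so generation is seed-local
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
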