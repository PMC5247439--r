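#' Generate a seeded oddball stimulus sequence
#'
#' Produces a uniformly random permutation of `floor(target_fraction *
#' n_trials)` target trials among standards, mirroring the classic rare /
#' frequent visual oddball design (30% targets: 40 targets out of 135
#' trials).
#'
#' @param n_trials total number of trials (>= 1).
#' @param target_fraction proportion of target trials in `[0, 1]`.
#' @param seed integer seed; the same seed reproduces the same ordering.
#' @return an object of class `stimulus_sequence`: list with
#'   `trial_labels` (character vector of `"target"`/`"standard"`),
#'   `n_trials`, `target_fraction`, `seed`.
#' @examples
#' s <- generate_oddball_sequence(135, 0.30, seed = 1)
#' sum(s$trial_labels == "target")  # 40
#' @export
generate_oddball_sequence <- function(n_trials, target_fraction, seed) {
  n_trials <- stopifnot_scalar_count(n_trials, "n_trials", min = 1L)
  target_fraction <- stopifnot_fraction(target_fraction, "target_fraction")
  n_target <- floor(target_fraction * n_trials)
  labels <- c(rep("target", n_target), rep("standard", n_trials - n_target))
  labels <- with_seed(seed, sample(labels))
  structure(list(trial_labels = labels, n_trials = n_trials,
                 target_fraction = target_fraction, seed = seed),
            class = "stimulus_sequence")
}

#' Generate a synthetic RAPM score table
#'
#' Draws integer Raven's Advanced Progressive Matrices scores (0--36 scale)
#' from group-specific normal distributions, rounded and clipped to the
#' scale, emulating the structure of a published two-group score table.
#'
#' @param n_ha,n_la subjects per group (non-negative).
#' @param mean_ha,mean_la group score means, each in `[0, 36]`.
#' @param sd common score standard deviation (> 0).
#' @param content stimulus content label, `"2D"` or `"3D"`.
#' @param seed integer seed.
#' @return data frame (class `rapm_table`) with columns `subject_id`,
#'   `score`, `content` and the generating `group`.
#' @export
generate_rapm_table <- function(n_ha, n_la, mean_ha, mean_la, sd,
                                content = c("2D", "3D"), seed = 1) {
  n_ha <- stopifnot_scalar_count(n_ha, "n_ha")
  n_la <- stopifnot_scalar_count(n_la, "n_la")
  content <- match.arg(content)
  if (mean_ha < 0 || mean_ha > 36 || mean_la < 0 || mean_la > 36)
    stop("group means must lie in [0, 36]", call. = FALSE)
  if (sd <= 0) stop("`sd` must be positive", call. = FALSE)
  scores <- with_seed(seed, {
    c(rnorm(n_ha, mean_ha, sd), rnorm(n_la, mean_la, sd))
  })
  scores <- pmin(36L, pmax(0L, as.integer(round(scores))))
  out <- data.frame(subject_id = seq_len(n_ha + n_la),
                    score = scores,
                    content = content,
                    group = rep(c("HA", "LA"), c(n_ha, n_la)))
  class(out) <- c("rapm_table", "data.frame")
  out
}

#' Simulation parameters for the synthetic oddball-EEG cohort
#'
#' Bundles and validates every knob of the generator. The group contrast
#' is a slow evoked deflection (half-sine spanning roughly 0--350 ms
#' post-stimulus, spectral content < 3 Hz) added to target trials, whose
#' mean amplitude differs between the LA and HA groups; the contrast is
#' therefore confined to the delta band the downstream wavelet bands
#' A4/D4 cover. Background activity has two parts: stationary 1/f^alpha
#' noise, and bursty band-limited beta (15--30 Hz) and gamma-range
#' (30--80 Hz) rhythms whose amplitudes are redrawn log-normally on every
#' trial. The bursts emulate the waxing and waning of ongoing
#' high-frequency rhythms in real EEG; without them every band's
#' relative energy would inherit the evoked total-energy shift (relative
#' energies are compositional), and no band would be specifically
#' discriminative.
#'
#' @param n_subjects_per_group subjects per group.
#' @param trials_per_subject oddball trials per subject.
#' @param target_fraction proportion of target trials.
#' @param fs sampling rate, Hz.
#' @param epoch_pre_ms,epoch_post_ms epoch window bounds, ms.
#' @param evoked_amp_la,evoked_amp_ha mean evoked amplitude (uV) of the
#'   slow post-stimulus component for the LA and HA groups.
#' @param amp_jitter_sd per-trial amplitude jitter SD, uV.
#' @param latency_jitter_ms per-trial onset latency jitter SD, ms.
#' @param evoked_duration_ms duration of the half-sine deflection, ms.
#' @param noise_sd stationary background noise SD per channel, uV.
#' @param noise_alpha exponent of the 1/f^alpha background spectrum
#'   (0 = white, 1 = pink).
#' @param burst_sd base SD (uV) of each bursty high-frequency rhythm
#'   component; 0 disables the bursts.
#' @param burst_jitter log-normal sigma of the per-trial burst
#'   amplitudes (shared across channels within a trial).
#' @param channel_gains length-3 evoked gain for Fz, Pz, Cz.
#' @param artifact_rate fraction of epochs given an injected excursion
#'   exceeding 90 uV (emulating blinks), in `[0, 1]`.
#' @param content content label attached to every epoch.
#' @param seed integer master seed.
#' @return a validated list of class `sim_params`.
#' @export
sim_params <- function(n_subjects_per_group = 17, trials_per_subject = 135,
                       target_fraction = 0.30, fs = 250,
                       epoch_pre_ms = 100, epoch_post_ms = 500,
                       evoked_amp_la = 4, evoked_amp_ha = 12,
                       amp_jitter_sd = 1, latency_jitter_ms = 20,
                       evoked_duration_ms = 350,
                       noise_sd = 3, noise_alpha = 1,
                       burst_sd = 3, burst_jitter = 0.8,
                       channel_gains = c(Fz = 0.9, Pz = 1.0, Cz = 0.8),
                       artifact_rate = 0.05,
                       content = c("2D", "3D"), seed = 1) {
  p <- list(n_subjects_per_group = stopifnot_scalar_count(n_subjects_per_group,
                                                          "n_subjects_per_group", 1L),
            trials_per_subject = stopifnot_scalar_count(trials_per_subject,
                                                        "trials_per_subject", 1L),
            target_fraction = stopifnot_fraction(target_fraction, "target_fraction"),
            fs = fs, epoch_pre_ms = epoch_pre_ms, epoch_post_ms = epoch_post_ms,
            evoked_amp_la = evoked_amp_la, evoked_amp_ha = evoked_amp_ha,
            amp_jitter_sd = amp_jitter_sd, latency_jitter_ms = latency_jitter_ms,
            evoked_duration_ms = evoked_duration_ms,
            noise_sd = noise_sd, noise_alpha = noise_alpha,
            burst_sd = burst_sd, burst_jitter = burst_jitter,
            channel_gains = unname(channel_gains),
            artifact_rate = stopifnot_fraction(artifact_rate, "artifact_rate"),
            content = match.arg(content), seed = seed)
  amps <- c(p$evoked_amp_la, p$evoked_amp_ha, p$amp_jitter_sd, p$noise_sd,
            p$latency_jitter_ms, p$evoked_duration_ms, p$burst_sd,
            p$burst_jitter)
  if (any(amps < 0)) stop("amplitudes, jitters and durations must be non-negative",
                          call. = FALSE)
  if (length(p$channel_gains) != 3L)
    stop("`channel_gains` must have length 3 (Fz, Pz, Cz)", call. = FALSE)
  if (p$fs <= 0) stop("`fs` must be positive", call. = FALSE)
  class(p) <- "sim_params"
  p
}

## 1/f^alpha Gaussian noise, unit sd, via spectral shaping.
pink_noise <- function(n, alpha) {
  w <- rnorm(n)
  if (alpha == 0) return(w)
  X <- fft(w)
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k) / n           # two-sided frequency index
  scale <- ifelse(f > 0, f^(-alpha / 2), 0)
  x <- Re(fft(X * scale, inverse = TRUE)) / n
  s <- sd(x)
  if (s > 0) x / s else x
}

## Band-limited Gaussian noise, unit sd, via spectral masking.
band_noise <- function(n, fs, lo, hi) {
  w <- rnorm(n)
  X <- fft(w)
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k) / n * fs
  X[f < lo | f > hi] <- 0
  x <- Re(fft(X, inverse = TRUE)) / n
  s <- sd(x)
  if (s > 0) x / s else x
}

## Burst bands (Hz): beta and gamma-range ongoing rhythms.
BURST_BANDS <- list(c(15, 30), c(30, 80))

## One trial's 3-channel background: stationary 1/f^alpha noise plus
## bursty high-band rhythms whose per-trial amplitudes are shared across
## channels (the rhythm waxes and wanes coherently over the scalp).
background_trial <- function(n, p) {
  g <- if (p$burst_sd > 0) exp(rnorm(length(BURST_BANDS), 0, p$burst_jitter))
  else numeric(length(BURST_BANDS))
  bg <- matrix(0, 3, n)
  for (ch in 1:3) {
    x <- p$noise_sd * pink_noise(n, p$noise_alpha)
    if (p$burst_sd > 0) {
      for (b in seq_along(BURST_BANDS)) {
        x <- x + p$burst_sd * g[b] *
          band_noise(n, p$fs, BURST_BANDS[[b]][1], BURST_BANDS[[b]][2])
      }
    }
    bg[ch, ] <- x
  }
  bg
}

## Half-sine evoked deflection sampled on the epoch grid (uV).
## Onset at stimulus + latency_ms; spectral energy is concentrated well
## below 3 Hz for the default 350 ms duration.
evoked_waveform <- function(n_samples, fs, pre_ms, amp, duration_ms,
                            latency_ms = 0) {
  t_ms <- (seq_len(n_samples) - 1) / fs * 1000 - pre_ms  # 0 = stimulus onset
  u <- (t_ms - latency_ms) / duration_ms
  ifelse(u >= 0 & u <= 1, amp * sin(pi * u), 0)
}

#' Simulate a synthetic two-group oddball-EEG cohort
#'
#' Generates single-trial epochs directly: every trial is independent
#' 1/f^alpha background noise on each channel; target trials additionally
#' carry the slow evoked deflection with group-specific mean amplitude,
#' per-trial amplitude/latency jitter, and per-channel gain. A seeded
#' fraction `artifact_rate` of epochs receives an injected excursion
#' exceeding 90 uV, logged in the `artifact_injected` column of the
#' epoch metadata so rejection can be verified against ground truth.
#'
#' @param params a [sim_params()] object.
#' @return an [epoch_set()] covering both groups; `info` carries
#'   `subject_id`, `group`, `content`, `trial_id`, `stimulus` and the
#'   ground-truth `artifact_injected` flag.
#' @examples
#' ep <- simulate_epochs(sim_params(n_subjects_per_group = 2,
#'                                  trials_per_subject = 10, seed = 7))
#' table(ep$info$group, ep$info$stimulus)
#' @export
simulate_epochs <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  n_s <- round(p$fs * (p$epoch_pre_ms + p$epoch_post_ms) / 1000)
  sets <- list()
  si <- 0L
  for (grp in c("LA", "HA")) {
    amp_mean <- if (grp == "LA") p$evoked_amp_la else p$evoked_amp_ha
    for (subj in seq_len(p$n_subjects_per_group)) {
      si <- si + 1L
      subject_id <- sprintf("%s%02d", grp, subj)
      seq_seed <- derive_seed(p$seed, si)
      sequence <- generate_oddball_sequence(p$trials_per_subject,
                                            p$target_fraction, seq_seed)
      dat <- array(0, c(3, n_s, p$trials_per_subject))
      with_seed(derive_seed(p$seed, 10000L + si), {
        for (tr in seq_len(p$trials_per_subject)) {
          is_target <- sequence$trial_labels[tr] == "target"
          amp <- if (is_target) max(0, rnorm(1, amp_mean, p$amp_jitter_sd)) else 0
          lat <- if (is_target) rnorm(1, 0, p$latency_jitter_ms) else 0
          ev <- if (is_target)
            evoked_waveform(n_s, p$fs, p$epoch_pre_ms, amp,
                            p$evoked_duration_ms, lat)
          else numeric(n_s)
          bg <- background_trial(n_s, p)
          for (ch in 1:3) {
            dat[ch, , tr] <- p$channel_gains[ch] * ev + bg[ch, ]
          }
        }
      })
      info <- data.frame(subject_id = subject_id, group = grp,
                         content = p$content,
                         trial_id = seq_len(p$trials_per_subject),
                         stimulus = sequence$trial_labels)
      sets[[si]] <- epoch_set(dat, info, fs = p$fs,
                              pre_ms = p$epoch_pre_ms, post_ms = p$epoch_post_ms)
    }
  }
  epochs <- combine_epoch_sets(sets)
  ## seeded artifact injection with ground-truth log
  n_e <- n_epochs(epochs)
  inject <- with_seed(derive_seed(p$seed, 999983L),
                      rbinom(n_e, 1L, p$artifact_rate) == 1L)
  if (any(inject)) {
    spec <- with_seed(derive_seed(p$seed, 999984L), {
      data.frame(ch = sample(1:3, sum(inject), replace = TRUE),
                 at = sample(seq_len(dim(epochs$data)[2] - 6L), sum(inject),
                             replace = TRUE),
                 sign = sample(c(-1, 1), sum(inject), replace = TRUE))
    })
    w <- which(inject)
    for (j in seq_along(w)) {
      idx <- spec$at[j]:(spec$at[j] + 5L)
      epochs$data[spec$ch[j], idx, w[j]] <-
        epochs$data[spec$ch[j], idx, w[j]] + spec$sign[j] * 200
    }
  }
  epochs$info$artifact_injected <- inject
  epochs
}

#' Simulate a continuous three-channel recording for one subject
#'
#' Builds a continuous Fz/Pz/Cz recording realizing a stimulus sequence
#' with a 1500 ms stimulus-onset asynchrony (500 ms stimulus + 1000 ms
#' blank), so that [segment_epochs()] can be exercised end to end. Target
#' onsets carry the same slow evoked deflection as [simulate_epochs()].
#'
#' @param sequence a [generate_oddball_sequence()] result.
#' @param params a [sim_params()] object (cohort-size fields ignored).
#' @param subject_id,group,content metadata attached to the recording.
#' @return an object of class `recording`: list with `channels` (3 x N
#'   matrix, rows Fz, Pz, Cz, uV), `fs`, `events` (data frame
#'   `sample_index`, `stimulus`, 1-based onset samples) and the metadata.
#' @export
simulate_recording <- function(sequence, params, subject_id = "S01",
                               group = "unknown", content = params$content) {
  stopifnot(inherits(sequence, "stimulus_sequence"),
            inherits(params, "sim_params"))
  p <- params
  soa <- round(1.5 * p$fs)               # 1500 ms stimulus-onset asynchrony
  pad <- round(1.0 * p$fs)
  n_total <- pad + sequence$n_trials * soa + pad
  onsets <- pad + (seq_len(sequence$n_trials) - 1L) * soa + 1L
  amp_mean <- if (group == "HA") p$evoked_amp_ha else p$evoked_amp_la
  channels <- with_seed(derive_seed(p$seed, 424243L), {
    ch <- matrix(0, 3, n_total, dimnames = list(CHANNELS, NULL))
    for (k in 1:3) {
      x <- p$noise_sd * pink_noise(n_total, p$noise_alpha)
      if (p$burst_sd > 0) {
        # continuous record: rhythms kept stationary (no per-trial redraw)
        for (b in seq_along(BURST_BANDS))
          x <- x + p$burst_sd *
            band_noise(n_total, p$fs, BURST_BANDS[[b]][1], BURST_BANDS[[b]][2])
      }
      ch[k, ] <- x
    }
    for (tr in seq_len(sequence$n_trials)) {
      if (sequence$trial_labels[tr] != "target") next
      amp <- max(0, rnorm(1, amp_mean, p$amp_jitter_sd))
      lat <- rnorm(1, 0, p$latency_jitter_ms)
      n_ev <- round(p$evoked_duration_ms / 1000 * p$fs)
      start <- onsets[tr] + round(lat / 1000 * p$fs)
      idx <- start:(start + n_ev - 1L)
      keep <- idx >= 1 & idx <= n_total
      pulse <- amp * sin(pi * (seq_len(n_ev) - 0.5) / n_ev)
      for (k in 1:3)
        ch[k, idx[keep]] <- ch[k, idx[keep]] + p$channel_gains[k] * pulse[keep]
    }
    ch
  })
  structure(list(channels = channels, fs = p$fs,
                 events = data.frame(sample_index = onsets,
                                     stimulus = sequence$trial_labels),
                 subject_id = subject_id, group = group, content = content),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> 3 channels x %d samples (fs = %g Hz), %d events\n",
              ncol(x$channels), x$fs, nrow(x$events)))
  invisible(x)
}
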