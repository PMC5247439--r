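make_recording <- function(channels, fs = 250, events = NULL) {
  structure(list(channels = channels, fs = fs,
                 events = events %||%
                   data.frame(sample_index = integer(), stimulus = character()),
                 subject_id = "S1", group = "unknown", content = "2D"),
            class = "recording")
}

test_that("band-pass filter rejects DC, is linear, and matches the analytic response", {
  fs <- 250
  n <- fs * 40
  t <- (seq_len(n) - 1) / fs

  dc <- make_recording(matrix(10, 3, n), fs)
  out <- bandpass_filter(dc)
  mid <- (10 * fs):(n - 10 * fs)   # a 0.3 Hz edge needs seconds to settle
  expect_lt(max(abs(out$channels[1, mid])), 0.1)

  x <- matrix(rnorm(3 * n), 3, n)
  f1 <- bandpass_filter(make_recording(x, fs))$channels
  f2 <- bandpass_filter(make_recording(2 * x, fs))$channels
  expect_equal(f2, 2 * f1, tolerance = 1e-10)

  amp_of <- function(freq) {
    r <- make_recording(matrix(sin(2 * pi * freq * t), 3, n, byrow = TRUE), fs)
    seg <- bandpass_filter(r)$channels[1, mid]
    sqrt(2 * mean(seg^2))
  }
  measured <- amp_of(10) / amp_of(50)
  # zero-phase = two passes, so the amplitude ratio is the squared gain ratio
  analytic <- (butter_bp_gain(10, 0.3, 30, fs) / butter_bp_gain(50, 0.3, 30, fs))^2
  expect_lt(abs(measured / analytic - 1), 0.05)

  # double filtering leaves passband energy nearly unchanged
  r10 <- make_recording(matrix(sin(2 * pi * 10 * t), 3, n, byrow = TRUE), fs)
  once <- bandpass_filter(r10)
  twice <- bandpass_filter(once)
  e1 <- mean(once$channels[1, mid]^2)
  e2 <- mean(twice$channels[1, mid]^2)
  expect_lt(abs(e2 / e1 - 1), 0.02)

  expect_error(bandpass_filter(dc, low = 0, high = 30), "band edges")
  expect_error(bandpass_filter(dc, low = 1, high = 200), "band edges")
})

test_that("segmentation cuts the stated window and skips edge events", {
  fs <- 250
  sig <- matrix(rep(seq_len(2000), each = 3), 3, 2000)
  rec <- make_recording(sig, fs,
                        data.frame(sample_index = c(1000, 10),
                                   stimulus = c("target", "target")))
  expect_warning(ep <- segment_epochs(rec), "skipped")
  expect_equal(n_epochs(ep), 1)
  expect_equal(dim(ep$data)[2], 150)
  # 0-based half-open [975, 1125) = 1-based samples 976..1125,
  # the event sample (1-based 1000 here given as index) starting post-stim side
  expect_equal(ep$data[1, , 1], seq(1000 - 25, 1000 + 125 - 1))

  sq <- generate_oddball_sequence(135, 0.30, seed = 3)
  rec2 <- simulate_recording(sq, tiny_params(seed = 6))
  ep2 <- segment_epochs(rec2)
  expect_equal(n_epochs(ep2), 40)
  ep_all <- segment_epochs(rec2, stimulus_filter = NULL)
  expect_equal(n_epochs(ep_all), 135)
})

test_that("artifact rejection applies the +/-90 uV rule and is monotone", {
  dat <- array(0, c(3, 150, 3))
  dat[3, 70, 1] <- 95           # Cz excursion
  dat[1, 10, 3] <- -60
  ep <- epoch_set(dat, data.frame(subject_id = "S1", group = "LA",
                                  content = "2D", trial_id = 1:3))
  res <- reject_artifacts(ep)
  expect_equal(n_epochs(res$kept), 2)
  expect_equal(res$log$trial_id, 1)
  expect_equal(res$log$channel, "Cz")
  expect_equal(res$log$peak, 95)

  # exactly at the threshold is rejected
  expect_equal(n_epochs(reject_artifacts(ep, amp_threshold = 95)$kept), 2)
  # raising the threshold never rejects a previously kept epoch
  kept60 <- reject_artifacts(ep, 60)$kept$info$trial_id
  kept96 <- reject_artifacts(ep, 96)$kept$info$trial_id
  expect_true(all(kept60 %in% kept96))

  empty <- reject_artifacts(ep[integer(0)])
  expect_equal(n_epochs(empty$kept), 0)
})

test_that("rejection partition equals the simulator's injection log", {
  # calm background (no bursts) so every excursion is an injected one
  p <- sim_params(n_subjects_per_group = 3, trials_per_subject = 50,
                  burst_sd = 0, artifact_rate = 0.1, seed = 13)
  ep <- simulate_epochs(p)
  res <- reject_artifacts(ep)
  kept_key <- paste(res$kept$info$subject_id, res$kept$info$trial_id)
  inj_key <- paste(ep$info$subject_id, ep$info$trial_id)[ep$info$artifact_injected]
  expect_length(intersect(kept_key, inj_key), 0)
  expect_equal(n_epochs(res$kept) + length(inj_key), n_epochs(ep))
})

test_that("RAPM summaries reproduce the published means and bounds", {
  tab <- rapm_table1()
  s2 <- rapm_summary(tab$score[tab$content == "2D"])
  s3 <- rapm_summary(tab$score[tab$content == "3D"])
  expect_equal(round(s2$mean, 2), 22.85)
  expect_equal(round(s3$mean, 2), 23.18)
  expect_equal(s2$n, 34)
  expect_equal(s2$lower, s2$mean - 3 * s2$sd)

  flat <- rapm_summary(c(20, 20, 20))
  expect_equal(flat$sd, 0)
  expect_equal(c(flat$lower, flat$upper), c(20, 20))

  expect_error(rapm_summary(5), "at least 2")
})

test_that("group assignment recovers the published splits and screens outliers", {
  tab <- rapm_table1()
  ga <- assign_groups(tab[, c("subject_id", "score", "content")])
  tallies <- table(ga$content, ga$group)
  expect_equal(unname(tallies["2D", c("HA", "LA")]), c(17, 17))
  expect_equal(unname(tallies["3D", c("HA", "LA")]), c(15, 19))
  expect_false("excluded" %in% ga$group)
  # recovered labels match the published ones subject by subject
  merged <- merge(ga, tab, by = c("subject_id", "content"))
  expect_true(all(merged$group.x == merged$group.y))
  # HA minimum always exceeds LA maximum
  expect_gt(min(ga$score[ga$group == "HA"]), max(ga$score[ga$group == "LA"]))

  # a score violating mean - 3 SD is excluded
  out <- assign_groups(data.frame(subject_id = 1:34,
                                  score = c(rep(20, 33), 0), content = "2D"))
  expect_equal(out$group[out$score == 0], "excluded")
  expect_true(all(out$group[out$score == 20] == "LA"))
})
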