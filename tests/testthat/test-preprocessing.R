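make_sine_rec <- function(freq, amp, n_sec = 10, fs = 512, n_ch = 2,
                          offset = 0) {
  t <- (0:(n_sec * fs - 1)) / fs
  x <- amp * sin(2 * pi * freq * t) + offset
  toy_recording(matrix(rep(x, each = n_ch), nrow = n_ch), fs = fs)
}

test_that("band-pass keeps in-band tones, kills out-of-band tones and DC", {
  mid <- 2000:3000
  rec <- make_sine_rec(10, 2)
  out <- bandpass_filter(rec, 0.1, 30)
  expect_equal(sqrt(mean(out$data[1, mid]^2)), 2 / sqrt(2), tolerance = 0.05)

  rec60 <- make_sine_rec(60, 2)
  out60 <- bandpass_filter(rec60, 0.1, 30)
  atten <- sqrt(mean(out60$data[1, mid]^2)) / (2 / sqrt(2))
  expect_lt(20 * log10(atten), -20)

  recdc <- make_sine_rec(10, 1, n_sec = 60, offset = 100)
  outdc <- bandpass_filter(recdc, 0.1, 30)
  expect_lt(abs(mean(outdc$data[1, 10000:20000])), 1)

  expect_error(bandpass_filter(rec, 0.1, 300), "Nyquist")
})

test_that("flatline criterion flags an all-zero recording end to end", {
  rec <- toy_recording(matrix(0, 2, 2048))
  mask <- detect_artifacts(rec)
  expect_equal(mask$intervals[[1]], cbind(start = 0L, end = 2048L),
               ignore_attr = TRUE)
})

test_that("a single voltage step is flagged with the documented padding", {
  fs <- 512
  t <- (0:(4 * fs - 1)) / fs
  x <- 10 * sin(2 * pi * 10 * t)
  k <- 1000L # 0-based step position
  x[(k + 1):length(x)] <- x[(k + 1):length(x)] + 60
  mask <- detect_artifacts(toy_recording(matrix(x, 1, byrow = TRUE)))
  expect_equal(mask$intervals[[1]],
               cbind(start = k - 102L, end = k + 103L), ignore_attr = TRUE)
})

test_that("a clean in-range oscillation produces an empty mask", {
  rec <- make_sine_rec(10, 10, n_sec = 4)
  mask <- detect_artifacts(rec)
  expect_true(all(vapply(mask$intervals, nrow, 1L) == 0L))
})

test_that("detector equals the naive reference on random artifact traces", {
  set.seed(99)
  fs <- 512
  for (i in 1:10) {
    n <- 1500L
    x <- 10 * sin(2 * pi * 9 * (0:(n - 1)) / fs) + rnorm(n, sd = 3)
    k <- sample(300:1100, 1)
    x[k:n] <- x[k:n] + sample(c(-70, 70, 260), 1)
    if (i %% 2 == 0) {
      f <- sample(200:900, 1)
      x[f:(f + 160)] <- mean(x[f:(f + 160)])
    }
    mask <- detect_artifacts(toy_recording(matrix(x, 1)))
    ref <- naive_detect_trace(x, fs)
    expect_equal(mask$intervals[[1]], ref, ignore_attr = TRUE)
  }
})

test_that("interpolation replaces only channels above the rejection fraction", {
  fs <- 512
  n <- 4 * fs
  t <- (0:(n - 1)) / fs
  good <- 10 * sin(2 * pi * 10 * t)
  data <- rbind(rep(0, n), # flat channel -> fully flagged
                matrix(rep(good, 5), nrow = 5, byrow = TRUE))
  rec <- toy_recording(data)
  mask <- detect_artifacts(rec)
  out <- interpolate_bad_channels(rec, mask, k_neighbors = 4)
  expect_equal(nrow(out$report), 1L)
  expect_equal(out$report$channel, rec$montage$label[1])
  expect_equal(out$recording$data[2, ], rec$data[2, ])
  expect_equal(out$recording$data[1, ], good, tolerance = 1e-10,
               ignore_attr = TRUE)

  ## constant neighbours -> constant replacement
  data2 <- rbind(rep(0, n), matrix(5, 4, n))
  rec2 <- toy_recording(data2)
  mask2 <- detect_artifacts(rec2)
  ## constant-5 channels are also "flat"; only test the averaging rule
  out2 <- interpolate_bad_channels(rec2, mask2, reject_fraction = 1.1,
                                   k_neighbors = 2)
  expect_equal(nrow(out2$report), 0L) # nothing above threshold: identity
  expect_identical(out2$recording$data, rec2$data)

  expect_error(interpolate_bad_channels(rec, mask, max_interp = 0), "cap")
})

test_that("average reference zeroes column means and is idempotent", {
  rec <- toy_recording(matrix(c(3, -1), 2, 100))
  out <- rereference_average(rec)
  expect_equal(out$data[, 1], c(2, -2), ignore_attr = TRUE)
  expect_equal(rereference_average(out)$data, out$data)

  set.seed(1)
  rec2 <- toy_recording(matrix(rnorm(16 * 500), 16))
  out2 <- rereference_average(rec2)
  expect_lt(max(abs(colMeans(out2$data))), 1e-9)
})

test_that("interpolation and re-referencing commute only in the clean case", {
  set.seed(12)
  rec <- toy_recording(matrix(5 * rnorm(16 * 1024), 16))
  mask <- detect_artifacts(rec)
  ## nothing replaced: the two orders agree
  a <- rereference_average(interpolate_bad_channels(rec, mask)$recording)
  b <- interpolate_bad_channels(rereference_average(rec), mask)$recording
  expect_equal(a$data, b$data, tolerance = 1e-12)
  ## with a replaced channel they do not: the fixed order is
  ## interpolate-then-rereference
  rec$data[1, ] <- 0 # flat channel, fully flagged
  mask2 <- detect_artifacts(rec)
  a2 <- rereference_average(interpolate_bad_channels(rec, mask2)$recording)
  b2 <- interpolate_bad_channels(rereference_average(rec), mask2)$recording
  expect_gt(max(abs(a2$data - b2$data)), 0.1)
})

test_that("eyes-closed extraction trims the protocol segments correctly", {
  cfg <- quick_cfg(ec_segment_seconds = 120, n_channels = 16, noise_sd = 1,
                   artifact_rates = c(blink = 0, step = 0, flat = 0))
  rec <- generate_resting_eeg(cfg, 1)$recording
  segs <- extract_ec_segments(rec, trim_s = 5)
  expect_length(segs, 2)
  expect_equal(vapply(segs, function(s) ncol(s$data) / s$fs, 1.0),
               c(110, 110))
  segs0 <- extract_ec_segments(rec, trim_s = 0)
  expect_equal(vapply(segs0, function(s) ncol(s$data) / s$fs, 1.0),
               c(120, 120))
})

test_that("a segment shorter than twice the trim is dropped with a warning", {
  rec <- toy_recording(matrix(rnorm(2 * 8 * 512), 2), fs = 512)
  rec$events <- data.frame(sample = 0L, kind = "eyes_closed", payload = "")
  expect_warning(segs <- extract_ec_segments(rec, trim_s = 5), "dropped")
  expect_length(segs, 0)
  rec$events <- data.frame(sample = integer(0), kind = character(0),
                           payload = character(0))
  expect_error(extract_ec_segments(rec), "eyes-closed")
})

test_that("overlapping epoch counts follow the tiling arithmetic", {
  seg <- function(sec) list(data = matrix(0, 2, sec * 512), fs = 512,
                            labels = c("A1", "A2"), offset = 0L)
  expect_equal(dim(epoch_fixed_overlap(list(seg(110)), NULL)$epochs)[3L], 109L)
  expect_equal(dim(epoch_fixed_overlap(list(seg(10)), NULL,
                                       overlap = 0)$epochs)[3L], 5L)
  expect_equal(dim(epoch_fixed_overlap(list(seg(1)), NULL)$epochs)[3L], 0L)
  ## a mask covering the full segment removes every epoch
  full_mask <- structure(list(
    intervals = list(A1 = cbind(start = 0L, end = 110L * 512L)),
    n_samples = 110L * 512L, pad_ms = 0), class = "artifact_mask")
  es <- epoch_fixed_overlap(list(seg(110)), full_mask)
  expect_equal(dim(es$epochs)[3L], 0L)
  expect_equal(attr(es, "n_skipped"), 109L)
})

test_that("event-locked epoching drops out-of-bounds anchors and baselines", {
  fs <- 512
  n <- 600 * 4
  data <- matrix(7, 2, n) # constant channel
  ev <- data.frame(sample = c(0L, 600L, 1200L),
                   kind = "target",
                   payload = c("a", "a", "b"))
  rec <- toy_recording(data, fs = fs, events = ev)
  es <- epoch_events(rec, NULL, "target")
  expect_equal(attr(es, "n_dropped_bounds"), 1L) # anchor at sample 0
  expect_equal(dim(es$epochs)[3L], 2L)
  expect_lt(max(abs(es$epochs)), 1e-12) # constant removed by baseline
  expect_equal(es$conditions, c("a", "b"))
})

test_that("the full 2x2 anchor layout yields 80 epochs per condition", {
  fs <- 512
  conds <- c("no_switch_congruent", "no_switch_incongruent",
             "switch_congruent", "switch_incongruent")
  anchors <- seq(600, by = 600, length.out = 320)
  ev <- data.frame(sample = as.integer(anchors), kind = "target",
                   payload = rep(conds, 80))
  rec <- toy_recording(matrix(rnorm(2 * (max(anchors) + 600)), 2),
                       fs = fs, events = ev)
  es <- epoch_events(rec, NULL, "target")
  expect_equal(dim(es$epochs)[3L], 320L)
  expect_equal(as.integer(table(es$conditions)), rep(80L, 4L))
})

test_that("ocular correction shrinks blink variance and spares clean data", {
  cfg <- quick_cfg(artifact_rates = c(blink = 8, step = 0, flat = 0),
                   seed = 17)
  out <- generate_resting_eeg(cfg, 1)
  rec <- out$recording
  log <- out$ground_truth$artifact_log
  corr <- correct_ocular(rec)
  expect_false(corr$report$passthrough)
  blink_flags <- logical(ncol(rec$data))
  for (i in which(log$kind == "blink")) {
    blink_flags[(log$start[i] + 1L):log$end[i]] <- TRUE
  }
  frontal <- which(rec$montage$frontal)
  v_in_before <- mean(apply(rec$data[frontal, blink_flags, drop = FALSE], 1, var))
  v_in_after <- mean(apply(corr$recording$data[frontal, blink_flags,
                                               drop = FALSE], 1, var))
  expect_lt(v_in_after, 0.5 * v_in_before)
  out_flags <- !blink_flags
  for (ch in frontal) {
    v0 <- var(rec$data[ch, out_flags])
    v1 <- var(corr$recording$data[ch, out_flags])
    expect_lt(abs(v1 - v0) / v0, 0.10)
  }
  ## blink-free recording passes through nearly unchanged
  cfg2 <- quick_cfg(artifact_rates = c(blink = 0, step = 0, flat = 0))
  rec2 <- generate_resting_eeg(cfg2, 1)$recording
  corr2 <- correct_ocular(rec2)
  for (ch in seq_len(nrow(rec2$data))) {
    expect_gt(cor(rec2$data[ch, ], corr2$recording$data[ch, ]), 0.99)
  }
  expect_warning(correct_ocular(rec2, method = "none"), "pass-through")
})

test_that("masked fraction matches the analytic flat-artifact footprint", {
  cfg <- quick_cfg(ec_segment_seconds = 30, n_channels = 16,
                   artifact_rates = c(blink = 0, step = 0, flat = 1.2),
                   seed = 21)
  out <- generate_resting_eeg(cfg, 1)
  mask <- detect_artifacts(out$recording)
  log <- out$ground_truth$artifact_log
  n <- ncol(out$recording$data)
  ## each flat segment is flagged exactly over its own span plus padding
  expected <- vapply(out$recording$montage$label, function(lb) {
    iv <- log[log$channel == lb, , drop = FALSE]
    if (!nrow(iv)) return(0)
    flags <- logical(n)
    for (i in seq_len(nrow(iv))) {
      lo <- max(1L, iv$start[i] + 1L - 102L)
      hi <- min(n, iv$end[i] + 102L)
      flags[lo:hi] <- TRUE
    }
    mean(flags)
  }, 1.0)
  got <- mask_fraction(mask)
  expect_lt(max(abs(got - expected)), 0.02)
})
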