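test_that("the band-pass keeps the passband, kills DC and attenuates 100 Hz", {
  fs <- 1000
  t <- seq(0, 10, by = 1 / fs)
  mid <- 4000:7000                              # away from edge transients
  r <- bandpass(toy_recording(sin(2 * pi * 10 * t), fs))
  expect_equal(max(abs(r$data[1, mid])), 1, tolerance = 0.06)
  r <- bandpass(toy_recording(rep(5, length(t)), fs))
  expect_lt(max(abs(r$data[1, mid])), 0.1)      # >= 20 dB down from 5
  r <- bandpass(toy_recording(sin(2 * pi * 100 * t), fs))
  expect_lt(max(abs(r$data[1, mid])), 0.1)      # >= 20 dB at 100 Hz
  imp <- numeric(2001); imp[1001] <- 1
  r <- bandpass(toy_recording(imp, fs))
  expect_equal(which.max(r$data[1, ]), 1001)    # zero phase: peak unmoved
  expect_error(bandpass(toy_recording(imp, fs), hi = 600), "Nyquist")
})

test_that("decimation keeps every k-th sample and rescales events exactly", {
  x <- sin(2 * pi * 10 * seq(0, 2, by = 1 / 3000))
  rec <- toy_recording(x, 3000)
  rec$events <- data.frame(index = 1L, sample = 3001L, carrier_sample = 3001L,
                           stimulus = "A", role = "deviant", train_id = 1L,
                           position_in_train = 1L)
  dn <- downsample(rec, 300)
  expect_equal(dn$sample_rate, 300)
  expect_equal(dn$data[1, ], x[seq(1, length(x), by = 10)])
  expect_equal(dn$events$sample, 301L)
  # a 10-Hz sine survives decimation within 1% amplitude
  expect_equal(max(abs(dn$data[1, ])), max(abs(x)), tolerance = 0.01)
  expect_error(downsample(toy_recording(x, 3000), 299), "integer multiple")
})

test_that("epoching yields 270 samples at 300 Hz locked to carrier onset", {
  fs <- 300
  x <- numeric(fs * 6)
  x[2 * fs + 1] <- 10                           # impulse at 2 s
  rec <- toy_recording(x, fs)
  rec$events <- data.frame(index = 1:2, sample = c(2 * fs + 1L, 4 * fs + 1L),
                           carrier_sample = c(2 * fs + 1L, 4 * fs + 1L + 45L),
                           stimulus = c("tone", "syll"),
                           role = c("deviant", "deviant"),
                           train_id = 1:2, position_in_train = 1L)
  ep <- epoch(rec)
  expect_equal(dim(ep$data)[3], 270)
  expect_equal(ep$time[1], -100)
  # impulse lands at t = 0 for the tone event
  expect_equal(ep$time[which.max(ep$data[1, 1, ])], 0)
  # the syllable event extracts 150 ms (45 samples) later
  x2 <- numeric(fs * 6); x2[4 * fs + 1 + 45] <- 10
  rec2 <- rec; rec2$data <- matrix(x2, 1)
  ep2 <- epoch(rec2)
  expect_equal(ep2$time[which.max(ep2$data[2, 1, ])], 0)
  # out-of-bounds events are skipped with a warning
  rec$events$carrier_sample[2] <- fs * 6
  expect_warning(epoch(rec), "skipped")
})

test_that("baseline correction zeroes the prestimulus mean and is
           invariant to added constants", {
  cfg <- analytic_config(amplitude = -1)
  rec <- simulate_block(cfg, "p1", "tone", "spectral")
  ep <- baseline_correct(epoch(downsample(rec, 300)))
  pre <- ep$time < 0
  expect_lt(max(abs(apply(ep$data[, , pre, drop = FALSE], c(1, 2), mean))),
            1e-9)
  ep_shift <- epoch(downsample(rec, 300))
  ep_shift$data <- ep_shift$data + 7.5
  expect_equal(baseline_correct(ep_shift)$data, ep$data, tolerance = 1e-12)
  # hand-computed toy: one trial, one channel, baseline mean (1+3)/2 = 2
  toy <- list(data = array(c(1, 3, 5, 7), c(1, 1, 4)), time = c(-60, -30, 0, 30),
              channels = "Cz")
  class(toy) <- "epoch_set"
  expect_equal(drop(baseline_correct(toy, c(-100, 0))$data), c(-1, 1, 3, 5))
})

test_that("rejection removes trials at or above threshold, keeps the rest", {
  base <- array(0, c(3, 2, 10))
  base[2, 1, 4] <- 60
  ep <- structure(list(data = base, time = seq(-100, 800, length.out = 10),
                       channels = c("Fz", "Cz"),
                       meta = data.frame(stimulus = "A", role = "deviant",
                                         train_id = 1:3, event_index = 1:3)),
                  class = "epoch_set")
  out <- reject(ep, 50)
  expect_equal(out$n_retained, 2)
  expect_equal(out$log$event_index, 2)
  expect_equal(out$log$channel, "Fz")
  expect_equal(out$n_extracted, out$n_retained + out$n_rejected)
  # boundary: exactly 50 uV is rejected (retention is strict "under")
  ep$data[2, 1, 4] <- 50
  expect_equal(reject(ep, 50)$n_rejected, 1)
  ep$data[2, 1, 4] <- 49.999
  expect_equal(reject(ep, 50)$n_rejected, 0)
  # averaging refuses when everything was rejected
  ep$data[, , 4] <- 100
  out <- reject(ep, 50)
  expect_error(average_epochs(out$epochs), "rejected")
})

test_that("averaging is the plain arithmetic mean per condition cell", {
  set.seed(1)
  arr <- array(rnorm(5 * 2 * 8), c(5, 2, 8))
  ep <- structure(list(data = arr, time = 1:8, channels = c("Fz", "Cz"),
                       sample_rate = 300,
                       meta = data.frame(
                         stimulus = c("A", "A", "A", "B", "B"),
                         role = c("deviant", "deviant", "standard",
                                  "deviant", "standard"),
                         train_id = 1:5, event_index = 1:5)),
                  class = "epoch_set")
  erps <- average_epochs(ep)
  # brute-force loop oracle
  manual <- (arr[1, , ] + arr[2, , ]) / 2
  expect_equal(erps[["A.deviant"]]$data, manual)
  expect_equal(erps[["A.deviant"]]$n_trials, 2)
  expect_equal(erps[["B.standard"]]$data, arr[5, , ])
  # averaging identical epochs returns the epoch; +1/-1 averages to 0
  ep$data[1, , ] <- 1; ep$data[2, , ] <- -1
  expect_true(all(average_epochs(ep)[["A.deviant"]]$data == 0))
})

test_that("order-1/21-sample Savitzky-Golay equals the moving average
           inside, preserves polynomials, and validates its window", {
  set.seed(2)
  e <- toy_erp(function(t) cumsum(rnorm(length(t))))
  sm <- savgol_smooth(e)
  ma <- stats::filter(e$data[1, ], rep(1 / 21, 21))
  inner <- 11:(length(ma) - 10)
  expect_lt(max(abs(sm$data[1, inner] - ma[inner])), 1e-9)
  # cross-check the interior against the signal package's implementation
  sg <- signal::sgolayfilt(e$data[1, ], p = 1, n = 21)
  expect_lt(max(abs(sm$data[1, inner] - sg[inner])), 1e-9)
  lin <- toy_erp(function(t) 0.3 * t + 2)
  expect_equal(savgol_smooth(lin)$data, lin$data, tolerance = 1e-9)
  const <- toy_erp(function(t) rep(4, length(t)))
  expect_equal(savgol_smooth(const)$data, const$data, tolerance = 1e-12)
  expect_error(savgol_smooth(e, window = 20), "odd")
  short <- list(data = matrix(0, 1, 5), time = 1:5, channels = "Fz")
  expect_error(savgol_smooth(short, window = 21), "longer")
})

test_that("the processing chain is linear up to rejection", {
  cfg <- analytic_config(amplitude = -0.5)
  cfg$filter <- TRUE; cfg$smooth <- TRUE
  rec <- simulate_block(cfg, "p1", "tone", "spectral")
  res1 <- process_block(rec, cfg, channels = "Fz")
  rec3 <- rec; rec3$data <- 3 * rec$data
  res3 <- process_block(rec3, cfg, channels = "Fz")
  expect_equal(res3$mmn$auc_uv_ms, 3 * res1$mmn$auc_uv_ms, tolerance = 1e-6)
})
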