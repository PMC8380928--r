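test_that("inharmonic series is the documented geometric sequence", {
  expect_equal(inharmonic_series(500, 1.15, 1), 500)
  s <- inharmonic_series(500, 1.15, 15)
  expect_equal(s[2], 575)
  expect_equal(s[15], 500 * 1.15^14)    # ~3537.9 Hz
  expect_equal(round(s[15], 1), 3537.9)
  expect_true(all(diff(s) > 0))
  expect_error(inharmonic_series(500, 1.15, 0), "at least 1")
})

test_that("formant weights are resonant, positive, and match a direct
           real-arithmetic evaluation of the resonator magnitude", {
  fs <- formant_set(700, 1500, 2500)
  freqs <- c(300, 700, 1100, 1500, 2500)
  g <- formant_weights(freqs, fs)
  expect_true(all(g > 0))
  # a component at f1 outweighs components > 1 bandwidth from every formant
  expect_gt(g[2], g[1])
  expect_gt(g[2], g[3])
  # flat-filter limit
  g_flat <- formant_weights(freqs, fs, bandwidths = rep(1e9, 3))
  expect_lt(max(g_flat) / min(g_flat), 1.001)
  # independent oracle: |H|^2 = |p|^4 / ((|p|^2 - w^2)^2 + (2 Re(-p) w)^2)
  bw <- c(80, 120, 160)
  oracle <- sapply(freqs, function(f) {
    w <- 2 * pi * f
    out <- 1
    for (k in 1:3) {
      re <- pi * bw[k]; im <- 2 * pi * unlist(fs)[k]
      p2 <- re^2 + im^2
      out <- out * p2 / sqrt((p2 - w^2)^2 + (2 * re * w)^2)
    }
    out
  })
  expect_equal(unname(g), unname(oracle), tolerance = 1e-10)
})

test_that("synthesized complexes honour length, normalization and spectrum", {
  spec <- tone_complex_spec(duration = 220, label = "t")
  s <- synthesize_complex(spec)
  expect_equal(length(s$samples), 9702)      # round(0.220 * 44100)
  expect_equal(max(abs(s$samples)), spec$peak, tolerance = 1e-6)
  expect_equal(s$samples[1], 0)              # ramp starts from silence
  # rolling peak grows through the onset ramp
  ramp_n <- round(0.005 * spec$sample_rate)
  seg <- abs(s$samples[seq_len(ramp_n)])
  expect_true(all(diff(cummax(seg)) >= 0) && cummax(seg)[ramp_n] > 0.5 * max(seg))
  # the 15 dominant spectral peaks sit at the series frequencies (+/- 1 bin);
  # a Hann window suppresses the leakage sidelobes of the strong components
  # that would otherwise mask the heavily formant-attenuated top component
  long <- synthesize_complex(tone_complex_spec(duration = 360, label = "t"))
  n <- length(long$samples)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
  mag <- Mod(stats::fft(long$samples * w))[1:(n %/% 2)]
  loc_max <- which(diff(sign(diff(mag))) == -2) + 1
  ord <- loc_max[order(mag[loc_max], decreasing = TRUE)]
  top <- integer(0)
  for (b in ord) {
    if (all(abs(b - top) > 5)) top <- c(top, b)
    if (length(top) == 15) break
  }
  expected_bins <- inharmonic_series(500, 1.15, 15) / long$sample_rate * n + 1
  expect_true(all(abs(sort(top) - sort(expected_bins)) <= 1))
})

test_that("the component frequencies must respect the sampling theorem", {
  expect_error(tone_complex_spec(base_freq = 4000, sample_rate = 16000),
               "sample_rate")
})

test_that("peak normalization equalizes the four stimuli of one set", {
  set <- make_stimulus_set("tone")
  peaks <- vapply(set, function(s) max(abs(s$samples)), numeric(1))
  expect_equal(unname(peaks), rep(peaks[[1]], 4))
  meta <- attr(set, "meta")
  expect_equal(meta$duration_ms, c(220, 220, 180, 360))
  expect_equal(sum(meta$prominence == "prominent"), 2)
})

test_that("vowel fixtures carry the fricative prefix contract", {
  spec <- tone_complex_spec(harmonic_mode = TRUE, f0 = 220, duration = 220,
                            label = "fe220")
  v <- synthesize_vowel_fixture(spec)
  expect_equal(v$carrier_onset, 150)
  expect_equal(length(v$samples), round(0.150 * 44100) + round(0.220 * 44100))
  bare <- synthesize_vowel_fixture(spec, fricative_prefix = FALSE)
  expect_equal(bare$carrier_onset, 0)
  # degenerate equivalence: no prefix + inharmonic mode == synthesize_complex
  spec2 <- tone_complex_spec(duration = 220, label = "x")
  expect_identical(synthesize_vowel_fixture(spec2, fricative_prefix = FALSE,
                                            seed = 42)$samples,
                   synthesize_complex(spec2, seed = 42)$samples)
})

test_that("WAV round-trips preserve samples, rate and sidecar metadata", {
  spec <- tone_complex_spec(harmonic_mode = TRUE, f0 = 200, duration = 100,
                            label = "fix")
  v <- synthesize_vowel_fixture(spec)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(v, path)
  back <- read_wav(path)
  expect_lt(max(abs(back$samples - v$samples)), 1e-6)  # float32 precision
  expect_equal(back$sample_rate, 44100)
  expect_equal(back$label, "fix")
  expect_equal(back$carrier_onset, 150)
  # 16-bit PCM stays within one quantization step
  path2 <- withr::local_tempfile(fileext = ".wav")
  write_wav(v, path2, format = "pcm16")
  back2 <- read_wav(path2)
  expect_lt(max(abs(back2$samples - v$samples)), 1 / 32767 + 1e-9)
  expect_error(read_wav(withr::local_tempfile(lines = "not a wav")), "RIFF")
})
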