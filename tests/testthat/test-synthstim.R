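test_that("generators honor length, determinism and calibration contracts", {
  n <- gen_ltass_noise(1.0, 48000, seed = 5)
  expect_length(n$samples, 48000)
  expect_identical(n$samples, gen_ltass_noise(1.0, 48000, seed = 5)$samples)
  expect_false(identical(n$samples, gen_ltass_noise(1.0, 48000, seed = 6)$samples))
  ## exact RMS calibration (well within the 0.1 dB contract)
  t1 <- gen_speech_like_target(1.0, 48000, seed = 5, rms_level = 0.02)
  expect_equal(20 * log10(rms(t1$samples) / 0.02), 0, tolerance = 1e-10)
  ## zero modulation depth degenerates to the masker generator bit-for-bit
  t0 <- gen_speech_like_target(1.0, 48000, seed = 5, mod_depth = 0)
  expect_identical(t0$samples, gen_ltass_noise(1.0, 48000, seed = 5)$samples)
  expect_error(gen_ltass_noise(-1, 48000, 1), "duration")
  expect_error(gen_speech_like_target(1, 48000, 1, mod_depth = 1), "mod_depth")
})

test_that("masker octave-band spectrum follows the LTASS shaping table", {
  x <- gen_ltass_noise(30, 48000, seed = 11)
  pw <- welch_psd(x$samples, 48000)
  tab <- ltass_table()
  octs <- c(250, 500, 1000, 2000, 4000, 8000)
  got <- vapply(octs, function(fc)
    welch_band_level(pw, fc / sqrt(2), fc * sqrt(2)), numeric(1))
  ## octave-band target: sum the three third-octave bands of the table
  want <- vapply(octs, function(fc) {
    f3 <- tab$freq_hz[tab$freq_hz >= fc / sqrt(2) & tab$freq_hz < fc * sqrt(2)]
    10 * log10(sum(10^(approx(log(tab$freq_hz), tab$level_db,
                              xout = log(f3))$y / 10)))
  }, numeric(1))
  diffs <- got - want
  expect_lt(max(abs(diffs - mean(diffs))), 2)   # shape match, offset-free
})

test_that("target and masker long-term spectra agree in all 30 model bands", {
  dur <- 20
  tg <- gen_speech_like_target(dur, 48000, seed = 21)
  mk <- gen_ltass_noise(dur, 48000, seed = 22)
  bt <- gammatone_analyze(tg, fb48())
  bm <- gammatone_analyze(mk, fb48())
  d <- 10 * log10(colMeans(bt$bands^2) / colMeans(bm$bands^2))
  expect_lt(max(abs(d)), 1)
})

test_that("target envelope modulation spectrum peaks at the modulation rate", {
  x <- gen_speech_like_target(30, 48000, seed = 31, mod_rate_hz = 4)
  env <- binsrm:::hilbert_envelope(x$samples)
  env <- env - mean(env)
  nfft <- length(env)
  sp <- Mod(fft(env)[1:4000])^2
  fr <- (0:3999) * 48000 / nfft
  sel <- fr >= 1 & fr <= 16
  expect_equal(fr[sel][which.max(sp[sel])], 4, tolerance = 0.25)
})

test_that("anechoic impulse responses carry the designed ITD and ILD cues", {
  h0 <- gen_hrir(0)
  expect_identical(h0$left, h0$right)
  expect_equal(estimate_broadband_delay(h0), 0)

  h90 <- gen_hrir(90)
  d <- estimate_broadband_delay(h90)
  expect_lt(abs(d - 0.70e-3), 1 / 48000)     # cross-correlation peak at the ITD
  ## head-shadow shape: strong ILD above 3 kHz, weak below 500 Hz
  ild <- band_ild(h90)
  cfs <- fb48()$cfs
  expect_true(all(-ild[cfs > 3000] >= 6))
  expect_true(all(-ild[cfs < 500] <= 3))
  expect_error(gen_hrir(45), "azimuth")
})

test_that("reverberant tail decays 60 dB over T60 and respects coherence", {
  room <- room_spec("reverberant", t60_s = 1.25)
  h <- gen_hrir(90, room = room, seed = 9)
  onset <- binsrm:::HRIR_HEAD_MARGIN + round(0.005 * 48000) + 100
  t60 <- schroeder_t60(h$left[onset:length(h$left)], 48000)
  expect_lt(abs(t60 - 1.25) / 1.25, 0.10)
  ## interaural coherence of the tail approximates the requested value
  tl <- h$left[onset:length(h$left)]; tr <- h$right[onset:length(h$right)]
  rho <- sum(tl * tr) / sqrt(sum(tl^2) * sum(tr^2))
  expect_equal(rho, 0.25, tolerance = 0.1)
})
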