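test_that("broadband delay estimation recovers constructed shifts", {
  x <- with_fixed_seed(4, rnorm(4000))
  p <- irpair(x, shift <- binsrm:::shift_int(x, 33), 48000)
  expect_equal(estimate_broadband_delay(p), 33 / 48000)
  expect_equal(estimate_broadband_delay(irpair(x, x, 48000)), 0)
  ## swapping channels negates the delay
  expect_equal(estimate_broadband_delay(irpair(shift, x, 48000)), -33 / 48000)
  expect_error(estimate_broadband_delay(irpair(numeric(10), numeric(10), 48000)),
               "degenerate")
})

test_that("cue-condition manipulations isolate ITD and ILD per band", {
  h0 <- gen_hrir(0); h90 <- gen_hrir(90)
  fb <- fb48()
  cfs <- fb$cfs

  ## A: bit-identical pass-through
  hA <- make_cue_condition_hrir(h0, h90, "A_BOTH")
  expect_identical(hA$left, h90$left)
  expect_identical(hA$right, h90$right)

  ## B: per-band ILD equals that of the frontal response (~0 dB) in every
  ## model band, broadband delay equals the 90-degree delay
  hB <- make_cue_condition_hrir(h0, h90, "B_ITD_ONLY")
  expect_lt(max(abs(band_ild(hB, fb) - band_ild(h0, fb))), 0.5)
  expect_equal(estimate_broadband_delay(hB), estimate_broadband_delay(h90),
               tolerance = 1 / 48000)

  ## C: broadband delay below one sample, per-band delay below one sample up
  ## to 1.5 kHz, per-band ILD preserved from the 90-degree response
  hC <- make_cue_condition_hrir(h0, h90, "C_ILD_ONLY")
  expect_lt(abs(estimate_broadband_delay(hC)) * 48000, 1)
  lo <- which(cfs <= 1500)
  expect_true(all(abs(band_delay_samples(hC, fb, lo)) <= 1))
  expect_lt(max(abs(band_ild(hC, fb) - band_ild(h90, fb))), 0.5)

  expect_error(make_cue_condition_hrir(h0, irpair(h90$left, h90$right, 44100),
                                       "B_ITD_ONLY"), "rates")
})

test_that("reference-ITD injection delays the right channel exactly", {
  x <- binaural_signal(with_fixed_seed(5, rnorm(9600)),
                       with_fixed_seed(6, rnorm(9600)), 48000)
  expect_identical(apply_reference_itd(x, 0), x)
  y <- apply_reference_itd(x, 1.75)
  expect_identical(y$left, x$left)
  expect_identical(y$right[85:9600], x$right[1:9516])   # 84-sample shift
  expect_identical(y$right[1:84], numeric(84))
  ## cross-correlation lag of a correlated pair moves by the injected ITD
  w <- with_fixed_seed(7, rnorm(48000))
  p0 <- binaural_signal(w, binsrm:::shift_int(w, 10), 48000)
  p1 <- apply_reference_itd(p0, 2)
  l0 <- binsrm:::xcorr_peak_lag(p0$left, p0$right, 500)
  l1 <- binsrm:::xcorr_peak_lag(p1$left, p1$right, 500)
  expect_equal(l1 - l0, 96)
  expect_error(apply_reference_itd(x, -1), "ref_itd_ms")
})

test_that("spatialize_and_mix respects level, additivity and shared-delay contracts", {
  tgt <- gen_speech_like_target(0.5, 48000, seed = 41)
  msk <- gen_ltass_noise(0.5, 48000, seed = 42)
  h0 <- gen_hrir(0)
  sc <- spatialize_and_mix(tgt, msk, scene_spec(0, "A_BOTH", 0, snr_db = 0),
                           h0, h0)
  ## equal source levels through the same response: equal ear levels
  expect_lt(abs(rms_db(sc$speech_clean$left, sc$noise_clean$left)), 0.1)
  ## additivity to numerical precision
  expect_lt(max(abs(sc$mixture$left - sc$speech_clean$left - sc$noise_clean$left)),
            1e-9 * rms(sc$mixture$left))
  ## masker at its nominal SPL
  cal <- binsrm_config()$calibration
  expect_equal(20 * log10(rms(msk$samples * 0.05 / rms(msk$samples)) / 0.05),
               0, tolerance = 1e-9)

  ## S0N0 with a reference ITD: speech and noise share the interchannel delay
  sc2 <- spatialize_and_mix(tgt, msk, scene_spec(0, "A_BOTH", 3.5, snr_db = -5),
                            h0, h0)
  ls <- binsrm:::xcorr_peak_lag(sc2$speech_clean$left, sc2$speech_clean$right, 600)
  ln <- binsrm:::xcorr_peak_lag(sc2$noise_clean$left, sc2$noise_clean$right, 600)
  expect_equal(ls, ln)
  expect_equal(ls, round(3.5e-3 * 48000))
})

test_that("reference-ITD injection commutes with rendering", {
  src <- gen_ltass_noise(0.4, 48000, seed = 43)
  h90 <- gen_hrir(90)
  ## delay applied to the rendered signal...
  a <- apply_reference_itd(
    binaural_signal(binsrm:::fft_conv(src$samples, h90$left),
                    binsrm:::fft_conv(src$samples, h90$right), 48000), 1.75)
  ## ...equals rendering through a right-delayed response
  h90d <- irpair(h90$left, c(numeric(84), h90$right[1:(length(h90$right) - 84)]),
                 48000)
  b <- binaural_signal(binsrm:::fft_conv(src$samples, h90d$left),
                       binsrm:::fft_conv(src$samples, h90d$right), 48000)
  expect_lt(max(abs(a$right - b$right)) / rms(b$right), 1e-9)
})
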