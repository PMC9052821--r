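## Synthetic stimuli: speech-shaped stationary masker, modulated speech-like
## target, and parametric binaural impulse responses.  These stand in for
## matrix-test sentence material, its matched masking noise, and a measured
## in-ear HRIR database, with the statistical structure the model relies on:
## a long-term average speech spectrum (LTASS), low-rate envelope modulation
## of the target, and broadband ITD / head-shadow ILD cues at 90 degrees.

## ---- seeded determinism helper ---------------------------------------------

## Evaluate expr under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647))
  expr
}

## Derive a child seed from a parent seed and one or more indices; keeps
## every intermediate value below 2^53 so integer arithmetic stays exact.
mix_seed <- function(seed, ...) {
  for (k in c(...)) seed <- (seed * 69069 + k * 12345 + 1) %% 2147483563
  seed
}

## ---- LTASS ------------------------------------------------------------------

#' Long-term average speech spectrum table
#'
#' One-third-octave band levels (dB SPL for speech at roughly 70 dB overall)
#' of the combined-language LTASS of Byrne et al. (1994), shipped as a CSV in
#' `extdata`.  Only the spectral *shape* is used; generators rescale to a
#' requested RMS.
#'
#' @param table table name (currently `"byrne1994"`) or path to a CSV with
#'   columns `freq_hz`, `level_db`.
#' @return data.frame with columns `freq_hz` and `level_db`.
#' @export
ltass_table <- function(table = "byrne1994") {
  path <- if (file.exists(table)) table
  else system.file("extdata", paste0("ltass_", table, ".csv"), package = "binsrm")
  if (!nzchar(path)) stop("invalid-argument: unknown LTASS table '", table, "'", call. = FALSE)
  read.csv(path)
}

## LTASS power-spectral-density shape in dB (arbitrary offset) at freqs_hz.
## Band levels are interpolated on a log-frequency axis and converted to
## density by removing the one-third-octave bandwidth 0.2316*f.
ltass_density_db <- function(freqs_hz, tab) {
  lf <- log(tab$freq_hz)
  f <- pmax(freqs_hz, 1)
  band <- approx(lf, tab$level_db, xout = log(pmin(pmax(f, min(tab$freq_hz)),
                                                   max(tab$freq_hz))))$y
  dens <- band - 10 * log10(0.2316 * f)
  ## gentle roll-off below half the lowest tabulated frequency
  f0 <- min(tab$freq_hz) / 2
  low <- f < f0
  dens[low] <- dens[low] + 24 * log10(pmax(f[low], 1e-3) / f0)
  dens
}

## ---- generators -------------------------------------------------------------

#' Generate stationary speech-shaped (LTASS) Gaussian noise
#'
#' White Gaussian noise is spectrally shaped in the frequency domain to the
#' LTASS density and rescaled to the requested RMS.  Deterministic given
#' `seed`; the caller's RNG state is left untouched.
#'
#' @param duration_s duration in seconds (> 0).
#' @param rate sampling rate in samples/second.
#' @param seed integer seed.
#' @param rms_level target RMS (full-scale relative); the default 0.05
#'   corresponds to 65 dB SPL under the package calibration.
#' @param table LTASS table, see [ltass_table()].
#' @return [monaural_signal()].
#' @export
gen_ltass_noise <- function(duration_s, rate, seed, rms_level = 0.05,
                            table = "byrne1994") {
  check_duration(duration_s, rate)
  n <- round(duration_s * rate)
  tab <- ltass_table(table)
  x <- with_seed(seed, shaped_noise(n, rate, tab))
  monaural_signal(x * (rms_level / rms(x)), rate)
}

shaped_noise <- function(n, rate, tab) {
  w <- rnorm(n)
  nfft <- good_nfft(n)
  fr <- seq(0, nfft %/% 2) * rate / nfft
  amp <- db_to_amp(ltass_density_db(fr, tab))
  amp[1] <- 0
  irfft(rfft(w, nfft) * amp, nfft, n)
}

#' Generate a speech-like modulated target
#'
#' LTASS-shaped noise with an imposed sinusoidal low-rate envelope
#' `1 + mod_depth*sin(2*pi*mod_rate_hz*t + phi)` (random phase), standing in
#' for running speech: same long-term spectrum as the masker from
#' [gen_ltass_noise()], plus the slow envelope modulation that the blind
#' modulation-analysis selectors exploit.  No harmonic fine structure is
#' modeled.  With `mod_depth = 0` the output is bit-identical to
#' [gen_ltass_noise()] with the same seed.
#'
#' @inheritParams gen_ltass_noise
#' @param mod_rate_hz envelope modulation rate (default 4 Hz, the dominant
#'   syllable rate of running speech).
#' @param mod_depth modulation depth in `[0, 1)`.
#' @return [monaural_signal()].
#' @export
gen_speech_like_target <- function(duration_s, rate, seed, mod_rate_hz = 4,
                                   mod_depth = 0.7, rms_level = 0.05,
                                   table = "byrne1994") {
  check_duration(duration_s, rate)
  if (mod_depth < 0 || mod_depth >= 1)
    stop("invalid-argument: mod_depth must be in [0, 1)", call. = FALSE)
  n <- round(duration_s * rate)
  tab <- ltass_table(table)
  res <- with_seed(seed, {
    x <- shaped_noise(n, rate, tab)
    phi <- runif(1, 0, 2 * pi)
    list(x = x, phi = phi)
  })
  env <- 1 + mod_depth * sin(2 * pi * mod_rate_hz * seq_len(n) / rate + res$phi)
  y <- res$x * env
  monaural_signal(y * (rms_level / rms(y)), rate)
}

check_duration <- function(duration_s, rate) {
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("invalid-argument: duration must be positive", call. = FALSE)
  if (!is.numeric(rate) || rate <= 0)
    stop("invalid-argument: rate must be positive", call. = FALSE)
}

## ---- head / room parameter types -------------------------------------------

#' Parametric head model
#'
#' @param itd_90_ms broadband interaural time difference of a 90-degree
#'   source in milliseconds (default 0.70 ms).
#' @param ild_shelf_db high-frequency head-shadow attenuation of the far ear
#'   in dB (default 12 dB, smoothly onset above `shelf_corner_hz`).
#' @param shelf_corner_hz shelf corner frequency (default 1500 Hz).
#' @param rate sampling rate in samples/second.
#' @export
head_model_params <- function(itd_90_ms = 0.70, ild_shelf_db = 12,
                              shelf_corner_hz = 1500, rate = 48000) {
  if (itd_90_ms < 0 || ild_shelf_db < 0)
    stop("invalid-argument: itd_90_ms and ild_shelf_db must be >= 0", call. = FALSE)
  structure(list(itd_90_ms = itd_90_ms, ild_shelf_db = ild_shelf_db,
                 shelf_corner_hz = shelf_corner_hz, rate = rate),
            class = "head_model_params")
}

#' Room specification for the impulse-response generator
#'
#' @param environment `"anechoic"` or `"reverberant"`.
#' @param t60_s reverberation time in seconds (default 1.25 s).
#' @param direct_to_reverberant_db level of the direct sound relative to the
#'   integrated diffuse tail, in dB (default 0).
#' @param tail_coherence interaural coherence of the diffuse tail in `[0, 1]`.
#' @param tail_onset_ms gap between direct sound and tail onset.
#' @export
room_spec <- function(environment = c("anechoic", "reverberant"), t60_s = 1.25,
                      direct_to_reverberant_db = 0, tail_coherence = 0.25,
                      tail_onset_ms = 5) {
  environment <- match.arg(environment)
  if (environment == "reverberant" && t60_s <= 0)
    stop("invalid-argument: t60_s must be positive", call. = FALSE)
  if (tail_coherence < 0 || tail_coherence > 1)
    stop("invalid-argument: tail_coherence must be in [0, 1]", call. = FALSE)
  structure(list(environment = environment, t60_s = t60_s,
                 direct_to_reverberant_db = direct_to_reverberant_db,
                 tail_coherence = tail_coherence, tail_onset_ms = tail_onset_ms),
            class = "room_spec")
}

## ---- impulse-response generator --------------------------------------------

## Head margin before the direct pulse, in samples; leaves room for the
## ILD-only cue manipulation, which advances the far-ear channel.
HRIR_HEAD_MARGIN <- 256L

#' Generate a synthetic binaural impulse-response pair
#'
#' At 0 degrees azimuth the two ears receive identical unit pulses.  At 90
#' degrees the source sits on the left: the left (near) ear keeps the unit
#' pulse while the right (far) ear is delayed by `head$itd_90_ms` and
#' attenuated by a smooth high-frequency head-shadow shelf
#' (`ild_shelf_db / (1 + (shelf_corner_hz/f)^2)` dB, i.e. about 1 dB at
#' 500 Hz and 10 dB at 3 kHz for the defaults).  A reverberant room adds an
#' exponentially decaying, partially interaurally coherent Gaussian tail
#' whose energy decays by 60 dB over `t60_s`.
#'
#' @param azimuth_deg source azimuth; 0 or 90.
#' @param head [head_model_params()].
#' @param room [room_spec()].
#' @param seed integer seed (used for the reverberant tail).
#' @return [irpair()].
#' @export
gen_hrir <- function(azimuth_deg, head = head_model_params(),
                     room = room_spec(), seed = 1) {
  if (!azimuth_deg %in% c(0, 90))
    stop("invalid-argument: azimuth must be 0 or 90 degrees", call. = FALSE)
  rate <- head$rate
  off <- HRIR_HEAD_MARGIN
  n_anech <- 1024L
  left <- numeric(n_anech); left[off + 1L] <- 1
  if (azimuth_deg == 0) {
    right <- left
  } else {
    itd_samp <- head$itd_90_ms * 1e-3 * rate
    right <- fractional_delay(left, itd_samp)
    right <- apply_shelf(right, rate, head$ild_shelf_db, head$shelf_corner_hz)
  }
  label <- sprintf("az%d/%s", azimuth_deg, room$environment)
  if (room$environment == "anechoic")
    return(irpair(left, right, rate, label))

  ## diffuse tail, common to both ears up to the requested coherence
  onset <- off + round(room$tail_onset_ms * 1e-3 * rate)
  nt <- ceiling(room$t60_s * rate)
  tail <- with_seed(mix_seed(seed, azimuth_deg), {
    list(a = rnorm(nt), b = rnorm(nt))
  })
  decay <- exp(-6.9078 * seq_len(nt) / (room$t60_s * rate))
  rho <- room$tail_coherence
  tl <- decay * tail$a
  tr <- decay * (rho * tail$a + sqrt(1 - rho^2) * tail$b)
  e_direct <- sum(left^2)
  g <- sqrt(e_direct * 10^(-room$direct_to_reverberant_db / 10) / sum(tl^2))
  n_tot <- onset + nt
  pad <- function(x) c(x, numeric(n_tot - length(x)))
  left  <- pad(left);  left[(onset + 1L):n_tot]  <- left[(onset + 1L):n_tot]  + g * tl
  right <- pad(right); right[(onset + 1L):n_tot] <- right[(onset + 1L):n_tot] + g * tr
  irpair(left, right, rate, label)
}

## zero-phase high-shelf attenuation filter applied via frequency sampling
apply_shelf <- function(x, rate, shelf_db, corner_hz, ntaps = 257L) {
  half <- (ntaps - 1L) %/% 2L
  nfft <- good_nfft(length(x) + ntaps)
  fr <- seq(0, nfft %/% 2) * rate / nfft
  att_db <- shelf_db / (1 + (corner_hz / pmax(fr, 1))^2)
  h_full <- irfft(db_to_amp(-att_db) + 0i, nfft, nfft)
  kern <- c(h_full[(nfft - half + 1L):nfft], h_full[1:(half + 1L)])
  fft_conv(x, kern)[(half + 1L):(half + length(x))]
}
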