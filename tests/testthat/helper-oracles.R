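## Independent oracles and shared fixtures for the test suite.  Expensive
## simulation results are computed once per session and memoized so several
## test files can assert against the same sweep.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, fn) {
  hit <- .fixture_cache[[name]]
  if (!is.null(hit)) return(hit)
  val <- fn()
  .fixture_cache[[name]] <- val
  val
}

fb48 <- function() cached("fb48", function() gammatone_filterbank(48000))

db_to_amp_test <- function(db) 10^(db / 20)

## all permutations of 1..k (permutation-null oracle support)
combinat_perms <- function(k) {
  if (k == 1) return(list(1))
  out <- list()
  for (p in combinat_perms(k - 1)) for (pos in 0:(k - 1))
    out[[length(out) + 1]] <- append(p, k, after = pos)
  out
}

## low-frequency band pair fixture: band 6 of a noise probe
ec_band_pair <- function(delay_samples = 0, gain_db = 0) {
  b <- cached("ec_band6", function() {
    x <- monaural_signal(with_fixed_seed(12, rnorm(48000)), 48000)
    gammatone_analyze(x, fb48())$bands[, 6]
  })
  list(left = b,
       right = fractional_delay(b, delay_samples) * db_to_amp_test(gain_db))
}

## ---- spectral oracles -------------------------------------------------------

## Welch power spectral density (Hann window, 50% overlap); returns
## data.frame(freq, psd) -- used as an independent check of the generators'
## spectral shaping.
welch_psd <- function(x, rate, nseg = 8192) {
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  hop <- nseg %/% 2
  starts <- seq(1, length(x) - nseg + 1, by = hop)
  acc <- numeric(nseg %/% 2 + 1)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nseg - 1)] * win
    X <- fft(seg)[1:(nseg %/% 2 + 1)]
    acc <- acc + Mod(X)^2
  }
  psd <- 2 * acc / (length(starts) * sum(win^2) * rate)
  data.frame(freq = seq(0, nseg %/% 2) * rate / nseg, psd = psd)
}

## band level (dB) by PSD integration between f1 and f2
welch_band_level <- function(pw, f1, f2) {
  sel <- pw$freq >= f1 & pw$freq < f2
  10 * log10(sum(pw$psd[sel]) * diff(pw$freq[1:2]))
}

## Schroeder backward-integrated decay time to -60 dB, from the fitted
## 0 .. -30 dB slope of the backward integral of the squared tail.
schroeder_t60 <- function(tail, rate) {
  e <- rev(cumsum(rev(tail^2)))
  db <- 10 * log10(e / e[1])
  t <- (seq_along(db) - 1) / rate
  sel <- db > -30 & db < -5
  fit <- lm(db[sel] ~ t[sel])
  -60 / coef(fit)[2]
}

## ---- cue-measurement oracles ------------------------------------------------

## per-gammatone-band ILD (right minus left, dB) of an impulse-response pair
band_ild <- function(pair, fb = fb48()) {
  bl <- gammatone_analyze(monaural_signal(pair$left, pair$rate), fb)
  br <- gammatone_analyze(monaural_signal(pair$right, pair$rate), fb)
  10 * log10(colSums(br$bands^2) / colSums(bl$bands^2))
}

## per-gammatone-band interchannel delay (samples) of a pair, measured on a
## fixed noise probe rendered through it
band_delay_samples <- function(pair, fb = fb48(), bands = seq_along(fb$cfs)) {
  probe <- with_fixed_seed(42, rnorm(0.5 * pair$rate))
  l <- binsrm:::fft_conv(probe, pair$left)
  r <- binsrm:::fft_conv(probe, pair$right)
  bl <- gammatone_analyze(monaural_signal(l, pair$rate), fb)
  br <- gammatone_analyze(monaural_signal(r, pair$rate), fb)
  vapply(bands, function(k)
    binsrm:::xcorr_peak_lag(bl$bands[, k], br$bands[, k], 600), numeric(1))
}

with_fixed_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

## true (shadow-path) SNR in dB of a mixture path built as g_t*target + g_n*noise
true_snr_db <- function(target, noise, g_t, g_n) {
  20 * log10(g_t * rms(target) / (g_n * rms(noise)))
}

## ---- SII oracle -------------------------------------------------------------

## Independent, deliberately literal (scalar loop) coding of the
## critical-band SII procedure, kept free of any package internals.
sii_oracle <- function(E, N, tab, thresh = 0) {
  nb <- nrow(tab)
  Z <- numeric(nb)
  B <- numeric(nb); C <- numeric(nb)
  for (i in 1:nb) {
    V <- E[i] - 24
    B[i] <- if (N[i] > V) N[i] else V
    C[i] <- -80 + 0.6 * (B[i] + 10 * log10(tab$f_hi_hz[i] - tab$f_lo_hz[i]))
  }
  for (i in 1:nb) {
    if (i == 1) { Z[1] <- B[1]; next }
    s <- 10^(0.1 * N[i])
    for (k in 1:(i - 1))
      s <- s + 10^(0.1 * (B[k] + 3.32 * C[k] *
                            log10(tab$f_center_hz[i] / tab$f_hi_hz[k])))
    Z[i] <- 10 * log10(s)
  }
  total <- 0
  for (i in 1:nb) {
    D <- max(Z[i], tab$internal_noise_db[i] + thresh)
    K <- (E[i] - D + 15) / 30
    K <- min(1, max(0, K))
    L <- 1 - (E[i] - tab$standard_speech_db[i] - 10) / 160
    L <- min(1, max(0, L))
    total <- total + tab$importance[i] * K * L
  }
  total
}

## ---- experiment sweep fixtures ----------------------------------------------

## SRM at the six reported-model-prediction cells: condition x {0, 10} ms,
## anechoic, 21-point grid, 5 sentences x 5 Monte-Carlo runs.
target_srm_sweep <- function() cached("target_srm", function() {
  cfg <- binsrm_config()
  run <- function(az, cond, itd)
    simulate_condition(scene_spec(az, cond, itd), cfg,
                       n_sentences = 5, n_mc = 5, seed = 1)
  c00 <- run(0, "A_BOTH", 0)
  ref <- calibrate_reference_sii(c00, cfg$pipeline$calibration_srt_db)
  srt0 <- c(`0` = srt_from_curve(c00, ref)$srt_db,
            `10` = srt_from_curve(run(0, "A_BOTH", 10), ref)$srt_db)
  out <- list(ref_sii = ref, srt0 = srt0, curve_cal = c00)
  for (cond in cue_conditions)
    for (itd in c(0, 10))
      out[[sprintf("srm_%s_%g", cond, itd)]] <-
        srt0[[as.character(itd)]] -
        srt_from_curve(run(90, cond, itd), ref)$srt_db
  out
})

## Reduced-repetition reference-ITD sweep (11-point 2-dB grid, 4 sentences x
## 4 Monte-Carlo runs) for the monotonicity / spread properties.
itd_property_sweep <- function() cached("itd_sweep", function() {
  cfg <- binsrm_config()
  grid <- seq(-20, 0, by = 2)
  itds <- c(0, 1.75, 3.5, 5.25, 7, 10)
  run <- function(az, cond, itd)
    simulate_condition(scene_spec(az, cond, itd), cfg,
                       n_sentences = 4, n_mc = 4, grid = grid, seed = 1)
  c0 <- lapply(itds, function(it) run(0, "A_BOTH", it))
  ref <- calibrate_reference_sii(c0[[1]], cfg$pipeline$calibration_srt_db)
  s0 <- vapply(c0, function(cv) srt_from_curve(cv, ref)$srt_db, numeric(1))
  srm <- sapply(cue_conditions, function(cond)
    s0 - vapply(itds, function(it)
      srt_from_curve(run(90, cond, it), ref)$srt_db, numeric(1)))
  list(itds = itds, s0n0_srt = s0, srm = srm, ref_sii = ref)
})

## Reduced reverberant cells for the directional reverberation checks.
reverb_sweep <- function() cached("reverb_sweep", function() {
  grid <- seq(-20, 0, by = 2)
  run <- function(az, cond, itd, env) {
    cfg <- binsrm_config(room = list(environment = env))
    room <- do.call(room_spec, cfg$room[c("environment", "t60_s",
                                          "direct_to_reverberant_db",
                                          "tail_coherence", "tail_onset_ms")])
    simulate_condition(scene_spec(az, cond, itd, room = room), cfg,
                       n_sentences = 3, n_mc = 3, grid = grid, seed = 1)
  }
  cal <- run(0, "A_BOTH", 0, "anechoic")
  ref <- calibrate_reference_sii(cal, -7)
  srt <- function(cv) srt_from_curve(cv, ref)$srt_db
  out <- list()
  for (env in c("anechoic", "reverberant")) {
    s0_0 <- srt(if (env == "anechoic") cal else run(0, "A_BOTH", 0, env))
    s0_10 <- srt(run(0, "A_BOTH", 10, env))
    out[[paste0("srm_B0_", env)]] <- s0_0 - srt(run(90, "B_ITD_ONLY", 0, env))
    out[[paste0("srm_A0_", env)]] <- s0_0 - srt(run(90, "A_BOTH", 0, env))
    out[[paste0("srm_A10_", env)]] <- s0_10 - srt(run(90, "A_BOTH", 10, env))
  }
  out
})
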