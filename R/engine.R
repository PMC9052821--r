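## Vectorized frequency-domain experiment engine.
##
## The full model is linear up to the (scalar) blind decisions, and within a
## psychometric-curve cell only the target gain and the EC jitter change
## between evaluations.  The engine therefore caches, per rendered sentence:
## the one-sided spectra of the clean speech and noise ear signals, the
## low-band spectra (analysis transfer functions applied), their interchannel
## cross-spectra and band energies, and the combined high-band
## (better-ear-region) transfer once.  Per SNR it recombines the cached
## cross-spectra to estimate the EC parameters from the mixture and makes the
## better-ear decision; per Monte-Carlo run it applies the jittered EC in the
## frequency domain (exact phase-ramp delays), selects the EC path from the
## mixture's modulation profile, and evaluates the SII from the accumulated
## output spectra.  The filter definitions are shared with the public
## operations, so the engine and the reference composition implement the same
## processing chain.

## smallest 4*2^a*3^b >= n (divisibility by 12 keeps the reduced spectral
## grids M/12, M/6, M/4 integer)
good_nfft12 <- function(n) {
  best <- Inf
  p2 <- 4
  repeat {
    p3 <- p2
    while (p3 < n) p3 <- p3 * 3
    if (p3 < best) best <- p3
    if (p2 >= n) break
    p2 <- p2 * 2
  }
  best
}

## per-(rate, filterbank, nfft) cache of transfer functions
.engine_cache <- new.env(parent = emptyenv())

engine_filters <- function(fb, cfg, nfft) {
  key <- sprintf("%g_%d_%g_%g_%d", fb$rate, length(fb$cfs), min(fb$cfs),
                 max(fb$cfs), nfft)
  hit <- .engine_cache[[key]]
  if (!is.null(hit)) return(hit)
  lo <- low_band_idx(fb, cfg$fbank$ec_fmax)
  hi <- high_band_idx(fb, cfg$fbank$ec_fmax)
  m_low <- nfft %/% 12L      # spectral support to rate/24 (covers EC bands)
  m_high <- nfft %/% 4L      # support to rate/8 (covers the full band range)
  fr_low <- (seq_len(m_low) - 1) * fb$rate / nfft
  fr_high <- (seq_len(m_high) - 1) * fb$rate / nfft
  G_low <- band_response(fb, fr_low)[, lo, drop = FALSE]
  C_low <- synth_comp(fb, fr_low)[, lo, drop = FALSE]
  Gh <- band_response(fb, fr_high)[, hi, drop = FALSE]
  Ch <- synth_comp(fb, fr_high)[, hi, drop = FALSE]
  out <- list(nfft = nfft, lo = lo, hi = hi, m_low = m_low, m_high = m_high,
              G_low = G_low, C_low = C_low,
              F_high = rowSums(Gh * Ch),
              w_low = 2 * pi * (seq_len(m_low) - 1) / nfft,
              E_fine = exp(1i * 2 * pi / nfft *
                             outer(seq_len(m_low) - 1, -6:6)))
  .engine_cache[[key]] <- out
  out
}

## one-sided inner product <a, b> of two real signals given their truncated
## spectra (factor for levels/energies; DC bin counted once)
spec_ip <- function(A, B, nfft)
  (2 * sum(Re(Conj(A) * B)) - Re(Conj(A[1]) * B[1])) / nfft

## Prepare one rendered sentence for repeated evaluation.  `sc` must be
## rendered at snr_db = 0; the target gain g = 10^(snr/20) is applied
## spectrally later.
ev_prepare <- function(sc, fb, cfg) {
  rate <- sc$mixture$rate
  n <- length(sc$mixture$left)
  nfft <- good_nfft12(n + analysis_pad(fb))
  ef <- engine_filters(fb, cfg, nfft)
  sp <- function(x) rfft(x, nfft)
  SL <- sp(sc$speech_clean$left);  SR <- sp(sc$speech_clean$right)
  NL <- sp(sc$noise_clean$left);   NR <- sp(sc$noise_clean$right)
  idx <- seq_len(ef$m_low)
  bl <- function(X) X[idx] * ef$G_low            # m_low x nb_low matrices
  pb <- list(SL = bl(SL), SR = bl(SR), NL = bl(NL), NR = bl(NR))
  ih <- seq_len(ef$m_high)
  prep <- list(
    rate = rate, n = n, nfft = nfft, ef = ef, cfg = cfg, fb = fb,
    bands = pb,
    cross = list(ss = Conj(pb$SL) * pb$SR, sn = Conj(pb$SL) * pb$NR,
                 ns = Conj(pb$NL) * pb$SR, nn = Conj(pb$NL) * pb$NR),
    energy = list(
      ss_l = colSums(2 * Mod(pb$SL)^2) / nfft,
      ss_r = colSums(2 * Mod(pb$SR)^2) / nfft,
      nn_l = colSums(2 * Mod(pb$NL)^2) / nfft,
      nn_r = colSums(2 * Mod(pb$NR)^2) / nfft,
      sn_l = colSums(2 * Re(Conj(pb$SL) * pb$NL)) / nfft,
      sn_r = colSums(2 * Re(Conj(pb$SR) * pb$NR)) / nfft),
    high = list(SL = SL[ih] * ef$F_high, SR = SR[ih] * ef$F_high,
                NL = NL[ih] * ef$F_high, NR = NR[ih] * ef$F_high))
  prep
}

## analytic envelope from a truncated one-sided spectrum; returns the
## envelope and its sampling rate
spec_envelope <- function(X, nfft, rate) {
  m <- length(X)
  X2 <- 2 * X
  X2[1] <- X[1]
  env <- Mod(fft(X2, inverse = TRUE)) / nfft
  list(env = env, rate = rate * m / nfft)
}

## EC parameter estimation and better-ear decision for one target gain g
ev_estimate <- function(prep, g) {
  ef <- prep$ef
  cst <- do.call(ec_constants, prep$cfg$ec[
    c("sigma_delta0", "tau0", "sigma_eps0", "alpha0", "p")])
  max_lag <- round(prep$cfg$ec$window_ms * 1e-3 * prep$rate)
  m_cc <- prep$nfft %/% 6L
  step <- prep$nfft %/% m_cc                 # coarse lag step (6 samples)
  jmax <- max_lag %/% step
  nb <- ncol(prep$bands$SL)
  params <- vector("list", nb)
  for (k in seq_len(nb)) {
    cs <- g^2 * prep$cross$ss[, k] + g * (prep$cross$sn[, k] + prep$cross$ns[, k]) +
      prep$cross$nn[, k]
    el <- g^2 * prep$energy$ss_l[k] + 2 * g * prep$energy$sn_l[k] + prep$energy$nn_l[k]
    er <- g^2 * prep$energy$ss_r[k] + 2 * g * prep$energy$sn_r[k] + prep$energy$nn_r[k]
    if (min(el, er) < 1e-300) {
      params[[k]] <- c(ec_error_sigmas(0, 0, cst), list(degenerate = TRUE))
      next
    }
    cc <- Re(fft(c(cs, complex(length.out = m_cc - length(cs))), inverse = TRUE))
    lags_c <- c(0:jmax, -(jmax:1)) * step
    vals_c <- cc[c(1:(jmax + 1L), (m_cc - jmax + 1L):m_cc)]
    t0 <- lags_c[which.max(vals_c)]
    ph <- exp(1i * 2 * pi / prep$nfft * (seq_along(cs) - 1) * t0)
    fine <- Re(crossprod(cs * ph, ef$E_fine))[1, ]
    tf <- t0 + (-6:6)
    keep <- abs(tf) <= max_lag
    tf <- tf[keep]; fine <- fine[keep]
    o <- order(abs(tf), tf)
    tau <- tf[o][which.max(fine[o])] / prep$rate
    params[[k]] <- c(ec_error_sigmas(tau, 10 * log10(er / el), cst),
                     list(degenerate = FALSE))
  }
  ## better-ear decision from the high-band mixture envelopes
  sel <- prep$cfg$selector
  srmr_of <- function(X) {
    e <- spec_envelope(X, prep$nfft, prep$rate)
    envelope_profile(e$env, e$rate, sel)$srmr
  }
  s_l <- srmr_of(g * prep$high$SL + prep$high$NL)
  s_r <- srmr_of(g * prep$high$SR + prep$high$NR)
  list(params = params, better_ear = if (s_l >= s_r) "left" else "right", g = g)
}

## One Monte-Carlo evaluation: jittered EC application, blind path
## selection, SII.
ev_evaluate_mc <- function(prep, est, g, jitter = NULL) {
  ef <- prep$ef
  if (is.null(jitter)) jitter <- draw_jitter(est$params)
  nb <- length(est$params)
  m <- ef$m_low
  smin <- smax <- nmin <- nmax <- complex(length.out = m)
  for (k in seq_len(nb)) {
    p <- est$params[[k]]
    d <- (p$tau_hat + jitter$delta[k]) * prep$rate
    pl <- exp(-0.5i * ef$w_low * d)
    gl <- db_to_amp(+p$alpha_hat / 2) * (1 + jitter$eps_left[k])
    gr <- db_to_amp(-p$alpha_hat / 2) * (1 + jitter$eps_right[k])
    ck <- ef$C_low[, k]
    sl <- (gl / 2) * pl * prep$bands$SL[, k]; sr <- (gr / 2) * Conj(pl) * prep$bands$SR[, k]
    nl <- (gl / 2) * pl * prep$bands$NL[, k]; nr <- (gr / 2) * Conj(pl) * prep$bands$NR[, k]
    smin <- smin + ck * (sl - sr); smax <- smax + ck * (sl + sr)
    nmin <- nmin + ck * (nl - nr); nmax <- nmax + ck * (nl + nr)
  }
  sel <- prep$cfg$selector
  srmr_of <- function(X) {
    e <- spec_envelope(X, prep$nfft, prep$rate)
    envelope_profile(e$env, e$rate, sel)$srmr
  }
  s_min <- srmr_of(g * smin + nmin)
  s_max <- srmr_of(g * smax + nmax)
  path <- if (s_min >= s_max) "minimize" else "maximize"
  sp_low <- if (path == "minimize") smin else smax
  no_low <- if (path == "minimize") nmin else nmax
  ear <- est$better_ear
  sp_hi <- if (ear == "left") prep$high$SL else prep$high$SR
  no_hi <- if (ear == "left") prep$high$NL else prep$high$NR
  sp_spec <- g * sp_hi; sp_spec[seq_len(m)] <- sp_spec[seq_len(m)] + g * sp_low
  no_spec <- no_hi;     no_spec[seq_len(m)] <- no_spec[seq_len(m)] + no_low
  tab <- sii_band_table_cached()
  cal <- prep$cfg$calibration
  slev <- levels_from_spectrum(sp_spec, prep$nfft, prep$n, prep$rate, tab, cal)
  nlev <- levels_from_spectrum(no_spec, prep$nfft, prep$n, prep$rate, tab, cal)
  res <- compute_sii(slev, nlev, tab)
  structure(list(sii = res$sii, ec_path = path, better_ear = ear,
                 params = est$params, jitter = jitter,
                 speech_levels = slev, noise_levels = nlev),
            class = "ec_evaluation")
}

sii_band_table_cached <- function() {
  hit <- .engine_cache[["sii_tab"]]
  if (is.null(hit)) {
    hit <- sii_band_table()
    .engine_cache[["sii_tab"]] <- hit
  }
  hit
}
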