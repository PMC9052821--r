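## Blind decision stages.
##
## Both decisions -- level-minimization versus level-maximization of the EC
## output, and left versus right ear for the high-frequency bands -- are made
## from the *mixture* alone via a modulation analysis: the Hilbert envelope
## is lowpassed, passed through a bank of second-order modulation-rate
## bandpass filters, and the speech-to-reverberation modulation energy ratio
## (SRMR) is the energy in the low-rate (speech-like) modulation bands over
## the energy in the high-rate bands.  Higher SNR leaves more of the
## target's slow envelope modulation intact, so the larger SRMR marks the
## better-SNR signal.

#' Modulation-rate filterbank centre frequencies
#' @param n number of bands (default 8).
#' @param f_lo,f_hi first and last centre frequency in Hz (defaults 4, 128).
#' @return log-spaced centre frequencies.
#' @export
modulation_band_centers <- function(n = 8L, f_lo = 4, f_hi = 128)
  exp(seq(log(f_lo), log(f_hi), length.out = n))

#' Modulation profile and SRMR of a signal
#'
#' Envelope extraction (magnitude of the analytic signal, lowpassed at
#' `env_lp_hz` and decimated), modulation filtering (second-order bandpass
#' filters, Q = `mod_q`), and the SRMR as the ratio of the energy summed over
#' the lower half of the modulation bands to the upper half.
#'
#' @param x [monaural_signal()], at least 0.5 s long.
#' @param sel selector block of [binsrm_config()].
#' @return list of class `modulation_profile`: `energies` (per modulation
#'   band), `centers_hz`, `srmr`.
#' @export
modulation_ratio <- function(x, sel = binsrm_config()$selector) {
  if (length(x$samples) / x$rate < 0.5)
    stop("invalid-argument: signal shorter than 0.5 s", call. = FALSE)
  env <- hilbert_envelope(x$samples)
  ep <- envelope_profile(env, x$rate, sel)
  structure(ep, class = "modulation_profile")
}

#' @export
print.modulation_profile <- function(x, ...) {
  cat(sprintf("<modulation_profile: srmr %.3f>\n", x$srmr))
  invisible(x)
}

hilbert_envelope <- function(x) {
  n <- length(x)
  nfft <- good_nfft(n)
  X <- rfft(x, nfft)
  nh <- length(X)
  X[2:(nh - 1L)] <- 2 * X[2:(nh - 1L)]     # analytic-signal spectrum
  z <- fft(c(X, complex(length.out = nfft - nh)), inverse = TRUE) / nfft
  Mod(z[seq_len(n)])
}

## SRMR machinery shared with the experiment engine: the envelope may arrive
## at any rate (e.g. already band-limited and decimated).
envelope_profile <- function(env, rate_env, sel) {
  ## lowpass and decimate to ~sel$env_rate_hz
  lp <- signal::butter(4, min(sel$env_lp_hz / (rate_env / 2), 0.95))
  env <- signal::filter(lp, env)
  dec <- max(1L, floor(rate_env / sel$env_rate_hz))
  env <- env[seq(1L, length(env), by = dec)]
  re <- rate_env / dec
  env <- env - mean(env)
  ctr <- modulation_band_centers(sel$n_mod_bands, sel$mod_f_lo, sel$mod_f_hi)
  en <- vapply(ctr, function(f0) {
    bp <- biquad_bandpass(f0, re, sel$mod_q)
    y <- signal::filter(bp$b, bp$a, env)
    sum(y^2)
  }, numeric(1))
  half <- length(ctr) %/% 2
  lo <- sum(en[seq_len(half)]); hi <- sum(en[(half + 1L):length(ctr)])
  list(energies = en, centers_hz = ctr,
       srmr = if (hi <= 0) Inf else lo / hi)
}

## RBJ-style constant-0dB-peak bandpass biquad
biquad_bandpass <- function(f0, rate, Q) {
  w0 <- 2 * pi * f0 / rate
  al <- sin(w0) / (2 * Q)
  b <- c(al, 0, -al) / (1 + al)
  a <- c(1, -2 * cos(w0) / (1 + al), (1 - al) / (1 + al))
  list(b = b, a = a)
}

#' Choose between the EC level-minimization and level-maximization paths
#'
#' Returns the path whose (mixture) signal has the larger SRMR; ties fall to
#' `"minimize"`.
#'
#' @param min_out,max_out [monaural_signal()]s: the resynthesized low-band EC
#'   mixture outputs of the two paths.
#' @param sel selector configuration block.
#' @return `"minimize"` or `"maximize"`.
#' @export
select_ec_path <- function(min_out, max_out, sel = binsrm_config()$selector) {
  s_min <- modulation_ratio(min_out, sel)$srmr
  s_max <- modulation_ratio(max_out, sel)$srmr
  if (s_min >= s_max) "minimize" else "maximize"
}

#' Choose the better ear for the high-frequency bands
#'
#' Returns the ear whose resynthesized high-band mixture has the larger
#' SRMR (one decision for the entire high-frequency region); ties fall to
#' `"left"`.
#'
#' @param high_left,high_right [monaural_signal()]s: per-ear resynthesized
#'   high-band mixtures.
#' @param sel selector configuration block.
#' @return `"left"` or `"right"`.
#' @export
better_ear_select <- function(high_left, high_right,
                              sel = binsrm_config()$selector) {
  s_l <- modulation_ratio(high_left, sel)$srmr
  s_r <- modulation_ratio(high_right, sel)$srmr
  if (s_l >= s_r) "left" else "right"
}
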