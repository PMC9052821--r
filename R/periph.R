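## Linear gammatone analysis/synthesis filterbank.
##
## Fourth-order complex all-pole gammatone filters on an ERB-number grid.
## Filtering is carried out by frequency-domain multiplication with the
## filters' exact transfer functions (the signal is zero-padded well past the
## impulse-response decay, so this equals time-domain recursion to numerical
## precision); the same transfer functions drive both the public time-domain
## operations and the vectorized experiment engine, so the two paths share a
## single filter definition.  Resynthesis applies per-band delay, phase and
## gain compensation and sums the bands, yielding an approximately flat
## passband with a common group delay.

#' ERB scale helpers
#'
#' `erb_bandwidth` is the Glasberg--Moore equivalent rectangular bandwidth at
#' centre frequency `f`; `erb_number`/`erb_number_inv` convert between
#' frequency in Hz and ERB number.
#'
#' @param f frequency in Hz.
#' @export
erb_bandwidth <- function(f) 24.7 * (0.00437 * f + 1)

#' @rdname erb_bandwidth
#' @export
erb_number <- function(f) 21.4 * log10(0.00437 * f + 1)

#' @rdname erb_bandwidth
#' @param e ERB number.
#' @export
erb_number_inv <- function(e) (10^(e / 21.4) - 1) / 0.00437

#' ERB-spaced centre frequencies
#'
#' `n` frequencies uniformly spaced on the ERB-number scale with endpoints
#' `f_lo` and `f_hi` (defaults: 30 bands, 150--8500 Hz).
#'
#' @param n number of bands (>= 2).
#' @param f_lo,f_hi endpoint frequencies in Hz.
#' @return increasing numeric vector of length `n`.
#' @export
erb_center_frequencies <- function(n = 30, f_lo = 150, f_hi = 8500) {
  if (n < 2 || f_lo <= 0 || f_hi <= f_lo)
    stop("invalid-argument: need n >= 2 and 0 < f_lo < f_hi", call. = FALSE)
  erb_number_inv(seq(erb_number(f_lo), erb_number(f_hi), length.out = n))
}

#' Gammatone analysis/synthesis filterbank
#'
#' Precomputes the per-band pole parameters and the synthesis compensation
#' (delay alignment to the envelope peak of the lowest band, fine-structure
#' phase alignment at each centre frequency, and iteratively flattened band
#' gains).
#'
#' @param rate sampling rate in samples/second (must be at least twice the
#'   highest centre frequency).
#' @param n,f_lo,f_hi see [erb_center_frequencies()].
#' @param order filter order (fixed at 4).
#' @return object of class `gt_fbank`.
#' @export
gammatone_filterbank <- function(rate, n = 30, f_lo = 150, f_hi = 8500,
                                 order = 4L) {
  cfs <- erb_center_frequencies(n, f_lo, f_hi)
  if (rate < 2 * f_hi)
    stop("invalid-argument: rate must be >= 2 * f_hi", call. = FALSE)
  b <- 1.019 * erb_bandwidth(cfs)           # gammatone bandwidth parameter
  theta <- 2 * pi * cfs / rate
  r <- exp(-2 * pi * b / rate)
  fb <- structure(list(rate = rate, cfs = cfs, order = order,
                       b = b, r = r, theta = theta),
                  class = "gt_fbank")
  ## synthesis compensation: align envelope peaks (t_pk = 3/(2 pi b) for a
  ## 4th-order gammatone) to the slowest band, then phase-align the carrier
  tpk <- (order - 1) / (2 * pi * b)
  fb$sync_delay <- max(tpk)
  fb$comp_delay <- fb$sync_delay - tpk
  g0 <- band_response(fb, cfs)              # n x n matrix: G_k evaluated at cfs
  fb$comp_phase <- -Arg(diag(g0)) + theta * rate * fb$comp_delay -
    theta * rate * fb$sync_delay
  fb$gain <- rep(1, n)
  for (it in 1:4) {
    tf <- synth_response(fb, cfs)
    fb$gain <- fb$gain / Mod(tf)
  }
  fb
}

## Real-filter frequency response G_k(f) of every band at frequencies f:
## complex all-pole response plus its negative-frequency image, peak
## normalized at the band centre.  Returns length(f) x n complex matrix.
band_response <- function(fb, f) {
  w <- 2 * pi * f / fb$rate
  n <- length(fb$cfs)
  G <- matrix(0i, length(f), n)
  for (k in seq_len(n)) {
    a <- fb$r[k] * exp(1i * fb$theta[k])
    hp <- (1 - abs(a))^fb$order / (1 - a * exp(-1i * w))^fb$order
    hm <- (1 - abs(a))^fb$order / (1 - a * exp(+1i * w))^fb$order
    g  <- hp + Conj(hm)
    pk <- (1 - abs(a))^fb$order / (1 - a * exp(-1i * fb$theta[k]))^fb$order +
      Conj((1 - abs(a))^fb$order / (1 - a * exp(+1i * fb$theta[k]))^fb$order)
    G[, k] <- g / Mod(pk)
  }
  G
}

## Synthesis compensation factors C_k(f): gain, delay and phase per band.
synth_comp <- function(fb, f) {
  w <- 2 * pi * f / fb$rate
  n <- length(fb$cfs)
  C <- matrix(0i, length(f), n)
  for (k in seq_len(n))
    C[, k] <- fb$gain[k] *
      exp(-1i * w * fb$comp_delay[k] * fb$rate + 1i * fb$comp_phase[k])
  C
}

## Overall analysis+synthesis transfer function at frequencies f, with the
## common synchronization delay removed.
synth_response <- function(fb, f) {
  G <- band_response(fb, f)
  C <- synth_comp(fb, f)
  rowSums(G * C) * exp(2i * pi * f * fb$sync_delay)
}

#' Gammatone analysis
#'
#' Splits a signal into the filterbank's band signals (linear,
#' time-invariant; real-valued band waveforms).
#'
#' @param x [monaural_signal()] with `x$rate == fb$rate`.
#' @param fb [gammatone_filterbank()].
#' @return object of class `band_signals`: list with `bands` (samples x n
#'   matrix), `cfs`, `rate`.
#' @export
gammatone_analyze <- function(x, fb) {
  if (x$rate != fb$rate)
    stop("invalid-argument: signal and filterbank rates differ", call. = FALSE)
  n <- length(x$samples)
  nfft <- good_nfft(n + analysis_pad(fb))
  X <- rfft(x$samples, nfft)
  fr <- seq(0, nfft %/% 2) * fb$rate / nfft
  G <- band_response(fb, fr)
  bands <- matrix(0, n, length(fb$cfs))
  for (k in seq_along(fb$cfs)) bands[, k] <- irfft(X * G[, k], nfft, n)
  structure(list(bands = bands, cfs = fb$cfs, rate = fb$rate, fb = fb),
            class = "band_signals")
}

## padding to cover filter ringing and the synthesis alignment delay
analysis_pad <- function(fb) ceiling((fb$sync_delay + 0.05) * fb$rate)

#' Gammatone synthesis
#'
#' Recombines band signals into a broadband waveform, applying the per-band
#' delay/phase/gain compensation of the filterbank.  The output retains the
#' common synchronization delay of the filterbank
#' (`fb$sync_delay` seconds, identical for every band).
#'
#' @param bs `band_signals` from [gammatone_analyze()] (or a compatible
#'   subset of bands).
#' @param fb filterbank; defaults to the one stored in `bs`.
#' @param bands_idx indices of the bands in `bs` within the filterbank's
#'   band set (defaults to matching by centre frequency).
#' @return [monaural_signal()].
#' @export
gammatone_synthesize <- function(bs, fb = bs$fb, bands_idx = NULL) {
  if (is.null(bands_idx))
    bands_idx <- match(round(bs$cfs, 6), round(fb$cfs, 6))
  if (anyNA(bands_idx))
    stop("invalid-argument: band centre frequencies not in filterbank", call. = FALSE)
  if (is.null(dim(bs$bands)) || nrow(bs$bands) == 0)
    stop("invalid-argument: empty band signals", call. = FALSE)
  n <- nrow(bs$bands)
  nfft <- good_nfft(n + analysis_pad(fb))
  fr <- seq(0, nfft %/% 2) * fb$rate / nfft
  C <- synth_comp(fb, fr)
  acc <- complex(length.out = nfft %/% 2 + 1L)
  for (j in seq_along(bands_idx))
    acc <- acc + rfft(bs$bands[, j], nfft) * C[, bands_idx[j]]
  monaural_signal(irfft(acc, nfft, n), fb$rate)
}

#' @export
print.gt_fbank <- function(x, ...) {
  cat(sprintf("<gammatone filterbank: %d bands, %.0f-%.0f Hz @ %g Hz, order %d>\n",
              length(x$cfs), min(x$cfs), max(x$cfs), x$rate, x$order))
  invisible(x)
}

## indices of EC (low) and better-ear (high) bands
low_band_idx <- function(fb, ec_fmax = 1500) which(fb$cfs <= ec_fmax)
high_band_idx <- function(fb, ec_fmax = 1500) which(fb$cfs > ec_fmax)
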