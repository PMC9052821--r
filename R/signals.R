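## Core audio carriers and low-level signal utilities.
##
## All audio is carried as plain numeric vectors wrapped in light S3 objects:
## `monaural_signal` (samples + rate), `binaural_signal` (left/right + rate)
## and `irpair` (a per-ear impulse-response pair).  Amplitudes are linear and
## full-scale relative; the SPL calibration convention lives in `binsrm_config()`.

#' Monaural audio signal
#'
#' @param samples numeric vector of linear, full-scale-relative amplitudes.
#' @param rate sampling rate in samples/second.
#' @return object of class `monaural_signal` with fields `samples` and `rate`.
#' @export
monaural_signal <- function(samples, rate) {
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("invalid-argument: rate must be a positive scalar", call. = FALSE)
  samples <- as.numeric(samples)
  if (any(!is.finite(samples)))
    stop("invalid-argument: samples must be finite", call. = FALSE)
  structure(list(samples = samples, rate = rate), class = "monaural_signal")
}

#' Binaural (two-channel) audio signal
#'
#' @param left,right numeric vectors, equal length.
#' @param rate sampling rate in samples/second.
#' @export
binaural_signal <- function(left, right, rate) {
  if (length(left) != length(right))
    stop("invalid-argument: channel lengths differ", call. = FALSE)
  if (rate <= 0) stop("invalid-argument: rate must be positive", call. = FALSE)
  structure(list(left = as.numeric(left), right = as.numeric(right), rate = rate),
            class = "binaural_signal")
}

#' Impulse-response pair for one source position/environment
#'
#' @param left,right per-ear impulse responses (equal length).
#' @param rate sampling rate in samples/second.
#' @param label free-form tag, e.g. `"az90/anechoic"`.
#' @export
irpair <- function(left, right, rate, label = "") {
  if (length(left) != length(right))
    stop("invalid-argument: left/right responses must have equal length", call. = FALSE)
  if (rate <= 0) stop("invalid-argument: rate must be positive", call. = FALSE)
  structure(list(left = as.numeric(left), right = as.numeric(right),
                 rate = rate, label = label), class = "irpair")
}

#' @export
print.monaural_signal <- function(x, ...) {
  cat(sprintf("<monaural_signal: %d samples @ %g Hz (%.3f s), rms %.4g>\n",
              length(x$samples), x$rate, length(x$samples) / x$rate, rms(x$samples)))
  invisible(x)
}

#' @export
print.binaural_signal <- function(x, ...) {
  cat(sprintf("<binaural_signal: %d samples @ %g Hz, rms L %.4g / R %.4g>\n",
              length(x$left), x$rate, rms(x$left), rms(x$right)))
  invisible(x)
}

#' @export
print.irpair <- function(x, ...) {
  cat(sprintf("<irpair '%s': %d taps @ %g Hz>\n", x$label, length(x$left), x$rate))
  invisible(x)
}

## ---- scalar level helpers ---------------------------------------------------

#' Root-mean-square of a numeric vector
#' @param x numeric vector.
#' @export
rms <- function(x) sqrt(mean(x^2))

#' Ratio of two RMS amplitudes in dB
#' @param a,b numeric vectors; returns `20*log10(rms(a)/rms(b))`.
#' @export
rms_db <- function(a, b) 20 * log10(rms(a) / rms(b))

db_to_amp <- function(db) 10^(db / 20)

## ---- FFT helpers ------------------------------------------------------------

## One-sided FFT of a real signal zero-padded to length nfft.
rfft <- function(x, nfft) {
  if (length(x) < nfft) x <- c(x, numeric(nfft - length(x)))
  fft(x)[seq_len(nfft %/% 2 + 1L)]
}

## Inverse of rfft: reconstruct the Hermitian spectrum and return a real
## signal of length n (<= nfft).
irfft <- function(X, nfft, n = nfft) {
  full <- c(X, Conj(X[seq(nfft %/% 2, 2L)]))
  Re(fft(full, inverse = TRUE))[seq_len(n)] / nfft
}

## Good FFT length (2^a * 3^b) at least n.
good_nfft <- function(n) {
  best <- Inf
  p2 <- 1
  while (p2 < 2 * n) {
    p3 <- p2
    while (p3 < n) p3 <- p3 * 3
    if (p3 < best) best <- p3
    p2 <- p2 * 2
  }
  min(best, p2)
}

## Linear (acyclic) convolution via FFT.
fft_conv <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nfft <- good_nfft(n)
  irfft(rfft(x, nfft) * rfft(h, nfft), nfft, n)
}

## ---- delays -----------------------------------------------------------------

#' Delay a signal by a possibly fractional number of samples
#'
#' Positive `d_samples` delays (shifts the waveform later), negative values
#' advance it.  The output keeps the input length: samples shifted beyond the
#' ends are dropped and the vacated head (or tail) is zero-padded.  Fractional
#' parts are realized by a Kaiser-windowed sinc interpolator of order 64
#' (`method = "sinc"`) or by an FFT phase ramp (`method = "fft"`, exact for
#' band-limited periodic extension).
#'
#' @param x numeric vector.
#' @param d_samples delay in samples (any real number).
#' @param method `"sinc"` (default) or `"fft"`.
#' @param order sinc interpolator order (even; default 64).
#' @return numeric vector, same length as `x`.
#' @export
fractional_delay <- function(x, d_samples, method = c("sinc", "fft"), order = 64L) {
  method <- match.arg(method)
  n <- length(x)
  if (d_samples == 0) return(x)
  if (abs(d_samples) >= n)
    stop("invalid-argument: delay exceeds signal length", call. = FALSE)
  m <- floor(d_samples)
  f <- d_samples - m            # fractional part in [0, 1)
  if (method == "fft") {
    nfft <- good_nfft(n + ceiling(abs(d_samples)) + 1L)
    w <- 2 * pi * seq(0L, nfft %/% 2) / nfft
    y <- irfft(rfft(x, nfft) * exp(-1i * w * d_samples), nfft, nfft)
    return(y[seq_len(n)])
  }
  if (f > 1e-12) {
    half <- order %/% 2
    k <- seq(-half, half)
    h <- sinc_kernel(k - f, order)
    y <- fft_conv(x, h)[(half + 1L):(half + n)]
  } else {
    y <- x
  }
  shift_int(y, m)
}

## windowed-sinc interpolation kernel (Kaiser window, beta = 8)
sinc_kernel <- function(t, order) {
  s <- ifelse(abs(t) < 1e-12, 1, sin(pi * t) / (pi * t))
  arg <- 1 - (2 * t / (order + 2))^2
  arg[arg < 0] <- 0
  w <- besselI(8 * sqrt(arg), 0) / besselI(8, 0)
  s * w
}

## integer shift, zero-padding, length preserving
shift_int <- function(x, m) {
  n <- length(x)
  if (m == 0) return(x)
  if (m > 0) c(numeric(m), x[seq_len(n - m)]) else c(x[(1 - m):n], numeric(-m))
}

## ---- WAV I/O ----------------------------------------------------------------

#' Write a RIFF WAV file (IEEE float32)
#'
#' Writes one or two channels.  Two-channel input may be a `binaural_signal`,
#' an `irpair`, or a matrix with one column per channel.
#'
#' @param x `monaural_signal`, `binaural_signal`, `irpair`, numeric vector or
#'   matrix (columns = channels).
#' @param path output file path.
#' @param rate sampling rate; taken from `x` when it carries one.
#' @export
write_wav <- function(x, path, rate = NULL) {
  if (inherits(x, "monaural_signal")) { dat <- cbind(x$samples); rate <- x$rate }
  else if (inherits(x, c("binaural_signal", "irpair"))) { dat <- cbind(x$left, x$right); rate <- x$rate }
  else if (is.matrix(x)) dat <- x
  else dat <- cbind(as.numeric(x))
  if (is.null(rate)) stop("invalid-argument: rate required", call. = FALSE)
  nch <- ncol(dat); nsamp <- nrow(dat)
  interleaved <- as.numeric(t(dat))
  data_bytes <- 4L * nch * nsamp
  con <- file(path, "wb"); on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")           # IEEE float
  writeBin(nch, con, size = 2, endian = "little")
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * nch * 4L), con, size = 4, endian = "little")
  writeBin(as.integer(nch * 4L), con, size = 2, endian = "little")
  writeBin(32L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(interleaved, con, size = 4, endian = "little")
  invisible(path)
}

#' Read a RIFF WAV file (PCM16/24/32 or float32/64)
#'
#' @param path file path.
#' @return for one channel a `monaural_signal`; for two a `binaural_signal`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- readChar(con, 4)
  if (!identical(hdr, "RIFF")) stop("invalid-argument: not a RIFF file", call. = FALSE)
  readBin(con, integer(), size = 4, endian = "little")
  if (!identical(readChar(con, 4), "WAVE"))
    stop("invalid-argument: not a WAVE file", call. = FALSE)
  fmt <- NULL; dat <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        code = readBin(con, integer(), size = 2, endian = "little"),
        nch  = readBin(con, integer(), size = 2, endian = "little"),
        rate = readBin(con, integer(), size = 4, endian = "little"))
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      fmt$bits <- readBin(con, integer(), size = 2, endian = "little")
      if (sz > 16) readBin(con, raw(), n = sz - 16L)
    } else if (id == "data") {
      nb <- fmt$bits %/% 8L
      nval <- sz %/% nb
      dat <- if (fmt$code == 3L) {
        readBin(con, numeric(), n = nval, size = nb, endian = "little")
      } else if (nb == 3L) {
        raw3 <- readBin(con, raw(), n = sz)
        b <- matrix(as.integer(raw3), nrow = 3)
        v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
        ifelse(v >= 2^23, v - 2^24, v) / 2^23
      } else {
        readBin(con, integer(), n = nval, size = nb, endian = "little") /
          2^(fmt$bits - 1)
      }
      break
    } else {
      readBin(con, raw(), n = sz + sz %% 2L)
    }
  }
  if (is.null(fmt) || is.null(dat)) stop("invalid-argument: malformed WAV", call. = FALSE)
  if (fmt$nch == 1L) monaural_signal(dat, fmt$rate)
  else {
    m <- matrix(dat, nrow = fmt$nch)
    binaural_signal(m[1, ], m[2, ], fmt$rate)
  }
}
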