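## Speech Intelligibility Index back end (critical-band procedure).
##
## The 21-band critical-band SII: equivalent speech and noise spectrum
## levels per band, self-speech masking, upward spread of masking into an
## equivalent masking spectrum, comparison against the listener's internal
## noise (normal-hearing reference), band audibility ((SNR + 15)/30 clipped
## to [0, 1]), a level distortion factor for overly loud speech, and the
## band-importance-weighted sum.  The band table (edges, importance function
## for generic speech material, reference internal noise, standard speech
## spectrum at normal vocal effort) ships as a documented CSV in `extdata`.

#' Critical-band SII table
#'
#' Columns: `band`, `f_center_hz`, `f_lo_hz`, `f_hi_hz`, `importance`
#' (band-importance function, sums to 1), `internal_noise_db` (reference
#' internal noise spectrum level of a normal-hearing listener) and
#' `standard_speech_db` (equivalent speech spectrum level at normal vocal
#' effort, used by the level distortion factor).
#'
#' @param path optional path to an alternative CSV with the same columns.
#' @return data.frame with 21 rows.
#' @export
sii_band_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "sii_critical_band_tables.csv",
                        package = "binsrm")
  read.csv(path)
}

#' Band spectrum levels of a signal on the SII critical-band grid
#'
#' Integrates the periodogram over each critical band and converts to a
#' spectrum level (band SPL minus 10*log10(bandwidth)) under the package SPL
#' calibration.  Near-silent bands are floored at -200 dB and flagged.
#'
#' @param x [monaural_signal()] (calibrated: full-scale-relative amplitudes).
#' @param tab [sii_band_table()].
#' @param cal calibration block of [binsrm_config()].
#' @return numeric vector of 21 spectrum levels (dB), with attribute
#'   `"silent"` marking floored bands.
#' @export
band_spectrum_levels <- function(x, tab = sii_band_table(),
                                 cal = binsrm_config()$calibration) {
  n <- length(x$samples)
  nfft <- good_nfft(n)
  X <- rfft(x$samples, nfft)
  levels_from_spectrum(X, nfft, n, x$rate, tab, cal)
}

## Shared with the engine: band spectrum levels from a one-sided spectrum of
## a length-n signal zero-padded to nfft.  Bin powers 2|X|^2/(nfft*n) sum to
## the mean square of the signal.
levels_from_spectrum <- function(X, nfft, n, rate, tab, cal) {
  p <- 2 * Mod(X)^2 / (nfft * n)
  fr_idx_lo <- pmax(2L, 1L + ceiling(tab$f_lo_hz * nfft / rate))
  fr_idx_hi <- pmin(length(X), 1L + floor((tab$f_hi_hz * nfft / rate) - 1e-9))
  bp <- vapply(seq_len(nrow(tab)), function(i)
    sum(p[fr_idx_lo[i]:fr_idx_hi[i]]), numeric(1))
  db_off <- cal$spl_ref_db - 20 * log10(cal$spl_ref_rms)
  lev <- 10 * log10(pmax(bp, 1e-30)) + db_off -
    10 * log10(tab$f_hi_hz - tab$f_lo_hz)
  silent <- bp <= 1e-30 | lev < -200
  lev[lev < -200] <- -200
  attr(lev, "silent") <- silent
  lev
}

#' Compute the critical-band Speech Intelligibility Index
#'
#' @param speech_levels,noise_levels equivalent speech and noise spectrum
#'   levels (dB) on the grid of `tab`, as from [band_spectrum_levels()].
#' @param tab [sii_band_table()].
#' @param threshold_adjust_db per-band hearing-threshold elevation (0 for the
#'   normal-hearing reference).
#' @return list of class `sii_result`: `sii` in `[0, 1]`, `band_snr_db`,
#'   `band_audibility`, `band_importance`, `masking_db`.
#' @export
compute_sii <- function(speech_levels, noise_levels, tab = sii_band_table(),
                        threshold_adjust_db = 0) {
  nb <- nrow(tab)
  if (length(speech_levels) != nb || length(noise_levels) != nb)
    stop("invalid-argument: levels must match the SII band grid", call. = FALSE)
  E <- as.numeric(speech_levels)
  N <- as.numeric(noise_levels)
  V <- E - 24                                    # self-speech masking
  B <- pmax(N, V)
  C <- -80 + 0.6 * (B + 10 * log10(tab$f_hi_hz - tab$f_lo_hz))
  Z <- numeric(nb)
  Z[1] <- B[1]
  for (i in 2:nb) {
    k <- seq_len(i - 1L)
    spread <- B[k] + 3.32 * C[k] * log10(tab$f_center_hz[i] / tab$f_hi_hz[k])
    Z[i] <- 10 * log10(10^(0.1 * N[i]) + sum(10^(0.1 * spread)))
  }
  X <- tab$internal_noise_db + threshold_adjust_db
  D <- pmax(Z, X)                                # disturbance spectrum
  K <- pmin(1, pmax(0, (E - D + 15) / 30))       # band audibility
  L <- pmin(1, pmax(0, 1 - (E - tab$standard_speech_db - 10) / 160))
  structure(list(sii = sum(tab$importance * K * L),
                 band_snr_db = E - D,
                 band_audibility = K,
                 band_importance = tab$importance,
                 masking_db = Z),
            class = "sii_result")
}

#' @export
print.sii_result <- function(x, ...) {
  cat(sprintf("<sii_result: SII = %.4f>\n", x$sii))
  invisible(x)
}
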