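## Equalization-cancellation stage.
##
## For every band up to 1500 Hz the interaural equalization delay and level
## are estimated *blindly* from the two-ear mixture; the equalization is then
## applied -- corrupted by Gaussian delay and amplitude jitter whose standard
## deviations grow with the magnitude of the equalized delay and level
## difference -- and the equalized ear signals are either subtracted
## (level-minimization) or added (level-maximization).  The identical
## jittered transformation is applied to the clean speech and clean noise
## shadow paths, keeping the operator linear so that
## EC(speech) + EC(noise) = EC(mixture) for fixed parameters.

#' EC error-model constants
#'
#' Processing-error constants of the EC stage: the delay jitter has standard
#' deviation `sigma_delta0 * (1 + |tau|/tau0)` and the amplitude jitter
#' `sigma_eps0 * (1 + (|alpha|/alpha0)^p)`, so equalizing a large interaural
#' delay (e.g. a large reference ITD) is increasingly imprecise while the
#' level equalization error depends only on the level difference.
#'
#' @param sigma_delta0 base delay-jitter SD in seconds (default 65e-6).
#' @param tau0 delay scale in seconds (default 1.6e-3).
#' @param sigma_eps0 base relative amplitude-jitter SD (default 0.25).
#' @param alpha0 level scale in dB (default 13).
#' @param p level-error exponent (default 1.6).
#' @return list of class `ec_constants`.
#' @export
ec_constants <- function(sigma_delta0 = 65e-6, tau0 = 1.6e-3,
                         sigma_eps0 = 0.25, alpha0 = 13, p = 1.6) {
  vals <- c(sigma_delta0, tau0, sigma_eps0, alpha0, p)
  if (any(vals < 0))
    stop("invalid-argument: EC constants must be non-negative", call. = FALSE)
  structure(list(sigma_delta0 = sigma_delta0, tau0 = tau0,
                 sigma_eps0 = sigma_eps0, alpha0 = alpha0, p = p),
            class = "ec_constants")
}

#' Estimate per-band equalization parameters from a band pair
#'
#' The equalization delay `tau_hat` is the lag of the maximum of the
#' normalized interchannel cross-correlation within `+/- window_ms`
#' (positive: right lags left; ties broken toward the smallest absolute
#' lag), and `alpha_hat` is the RMS level difference right minus left in dB.
#' Jitter standard deviations follow the error model of [ec_constants()].
#'
#' @param band_left,band_right equal-length numeric vectors (one band's two
#'   ear signals -- for blind operation, of the *mixture*).
#' @param rate sampling rate in samples/second.
#' @param constants [ec_constants()].
#' @param window_ms half-width of the delay search window (default 11 ms).
#' @return list of class `ec_params`: `tau_hat` (s), `alpha_hat` (dB),
#'   `sigma_delta` (s), `sigma_eps`, `degenerate` flag.
#' @export
estimate_eq_params <- function(band_left, band_right, rate,
                               constants = ec_constants(), window_ms = 11) {
  if (length(band_left) != length(band_right))
    stop("invalid-argument: band signals must have equal length", call. = FALSE)
  el <- sum(band_left^2); er <- sum(band_right^2)
  ref <- max(el, er)
  if (ref < 1e-300 || min(el, er) < 1e-12 * ref) {
    p <- list(tau_hat = 0, alpha_hat = 0,
              sigma_delta = constants$sigma_delta0,
              sigma_eps = constants$sigma_eps0, degenerate = TRUE)
    class(p) <- "ec_params"
    return(p)
  }
  max_lag <- min(round(window_ms * 1e-3 * rate), length(band_left) - 1L)
  tau <- xcorr_peak_lag(band_left, band_right, max_lag) / rate
  alpha <- 10 * log10(er / el)
  p <- ec_error_sigmas(tau, alpha, constants)
  p$degenerate <- FALSE
  class(p) <- "ec_params"
  p
}

ec_error_sigmas <- function(tau, alpha, constants) {
  list(tau_hat = tau, alpha_hat = alpha,
       sigma_delta = constants$sigma_delta0 * (1 + abs(tau) / constants$tau0),
       sigma_eps = constants$sigma_eps0 *
         (1 + (abs(alpha) / constants$alpha0)^constants$p))
}

#' Draw EC jitter for a set of bands
#'
#' One independent zero-mean Gaussian draw per band for the delay jitter and
#' one per ear and band for the amplitude jitter, constant over the signal
#' duration (run-level jitter: one draw per Monte-Carlo run).
#'
#' @param params list of `ec_params`, one per band.
#' @return list with `delta` (seconds, per band), `eps_left`, `eps_right`
#'   (relative, per band).
#' @export
draw_jitter <- function(params) {
  sd_d <- vapply(params, `[[`, numeric(1), "sigma_delta")
  sd_e <- vapply(params, `[[`, numeric(1), "sigma_eps")
  nb <- length(params)
  list(delta = rnorm(nb, 0, sd_d),
       eps_left = rnorm(nb, 0, sd_e),
       eps_right = rnorm(nb, 0, sd_e))
}

zero_jitter <- function(nb) list(delta = numeric(nb), eps_left = numeric(nb),
                                 eps_right = numeric(nb))

#' Apply the (jittered) EC transformation to one band
#'
#' Each ear is compensated by half the jittered equalization delay
#' (`(tau_hat + delta)/2`, the left ear delayed and the right ear advanced
#' when the right lags) and by half the level equalization (`+/-
#' alpha_hat/2` dB), the amplitude jitter scales each ear by `(1 + eps)`,
#' and the equalized channels are subtracted (`mode = "minimize"`) or added
#' (`mode = "maximize"`) and halved.
#'
#' @param band_left,band_right one band's two ear signals.
#' @param params `ec_params` for this band.
#' @param jitter list with scalar `delta`, `eps_left`, `eps_right` (as one
#'   band's slice of [draw_jitter()]).
#' @param mode `"minimize"` or `"maximize"`.
#' @param rate sampling rate in samples/second.
#' @return numeric vector: the monaural EC output for this band.
#' @export
ec_apply <- function(band_left, band_right, params, jitter,
                     mode = c("minimize", "maximize"), rate) {
  mode <- match.arg(mode)
  d <- (params$tau_hat + jitter$delta) * rate    # samples
  if (abs(d) / 2 >= length(band_left))
    stop("invalid-argument: equalization delay exceeds signal length", call. = FALSE)
  gl <- db_to_amp(+params$alpha_hat / 2) * (1 + jitter$eps_left)
  gr <- db_to_amp(-params$alpha_hat / 2) * (1 + jitter$eps_right)
  l <- fractional_delay(band_left, +d / 2) * gl
  r <- fractional_delay(band_right, -d / 2) * gr
  if (mode == "minimize") (l - r) / 2 else (l + r) / 2
}

#' Blind EC processing of the low-frequency bands
#'
#' Estimates the equalization parameters of every band at or below the EC
#' cutoff from the *mixture* band signals only, draws one jitter realization,
#' and applies the identical transformation to mixture, clean speech and
#' clean noise (shadow filtering) for both the level-minimization and
#' level-maximization paths.
#'
#' @param mixture,speech,noise lists with elements `left`, `right`, each a
#'   `band_signals` object restricted to (or containing) the low bands.
#' @param constants [ec_constants()].
#' @param window_ms EC delay search half-window in ms.
#' @param jitter optional jitter list as from [draw_jitter()]; when `NULL`
#'   one realization is drawn from the current RNG stream.
#' @return list with `params` (per band), `jitter`, and `min`/`max` paths,
#'   each containing `mixture`, `speech`, `noise` band matrices.
#' @export
process_low_bands <- function(mixture, speech, noise,
                              constants = ec_constants(), window_ms = 11,
                              jitter = NULL) {
  rate <- mixture$left$rate
  nb <- ncol(mixture$left$bands)
  params <- lapply(seq_len(nb), function(k)
    estimate_eq_params(mixture$left$bands[, k], mixture$right$bands[, k],
                       rate, constants, window_ms))
  if (is.null(jitter)) jitter <- draw_jitter(params)
  out <- list(params = params, jitter = jitter)
  for (mode in c("minimize", "maximize")) {
    res <- lapply(list(mixture = mixture, speech = speech, noise = noise),
                  function(sig) {
                    m <- matrix(0, nrow(sig$left$bands), nb)
                    for (k in seq_len(nb))
                      m[, k] <- ec_apply(sig$left$bands[, k], sig$right$bands[, k],
                                         params[[k]],
                                         list(delta = jitter$delta[k],
                                              eps_left = jitter$eps_left[k],
                                              eps_right = jitter$eps_right[k]),
                                         mode, rate)
                    m
                  })
    out[[if (mode == "minimize") "min" else "max"]] <- res
  }
  out
}
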