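## One full model evaluation: rendered scene in, SII out.
##
## `evaluate_scene()` composes the public stage operations directly
## (`method = "reference"`), or defers to the vectorized frequency-domain
## engine (`method = "fast"`, the default; see engine.R) which evaluates the
## identical processing chain from cached band spectra.  Both paths: blind
## EC on the low bands with one jitter realization, blind min/max path
## selection, blind better-ear selection for the high bands, resynthesis,
## and the SII on the shadow-filtered clean speech and noise.

#' Evaluate the blind EC model on one rendered scene
#'
#' @param sc `spatial_scene` from [spatialize_and_mix()].
#' @param fb [gammatone_filterbank()] at the scene's rate.
#' @param cfg configuration from [binsrm_config()].
#' @param jitter optional jitter realization (as [draw_jitter()]); `NULL`
#'   draws one from the current RNG stream.
#' @param method `"fast"` (vectorized engine) or `"reference"` (direct
#'   composition of the stage operations; identical processing, much slower).
#' @return list of class `ec_evaluation`: `sii`, `ec_path`
#'   (`"minimize"`/`"maximize"`), `better_ear`, `params` (per low band),
#'   `speech_levels`, `noise_levels`.
#' @export
evaluate_scene <- function(sc, fb = NULL, cfg = binsrm_config(), jitter = NULL,
                           method = c("fast", "reference")) {
  method <- match.arg(method)
  if (is.null(fb))
    fb <- gammatone_filterbank(sc$mixture$rate, cfg$fbank$n_bands,
                               cfg$fbank$f_lo, cfg$fbank$f_hi)
  if (method == "fast") {
    prep <- ev_prepare(sc, fb, cfg)
    est <- ev_estimate(prep, 1)
    return(ev_evaluate_mc(prep, est, 1, jitter = jitter))
  }
  evaluate_scene_reference(sc, fb, cfg, jitter)
}

evaluate_scene_reference <- function(sc, fb, cfg, jitter = NULL) {
  rate <- sc$mixture$rate
  analyze2 <- function(bn) list(left = gammatone_analyze(monaural_signal(bn$left, rate), fb),
                                right = gammatone_analyze(monaural_signal(bn$right, rate), fb))
  mixb <- analyze2(sc$mixture)
  spb  <- analyze2(sc$speech_clean)
  nob  <- analyze2(sc$noise_clean)
  lo <- low_band_idx(fb, cfg$fbank$ec_fmax)
  hi <- high_band_idx(fb, cfg$fbank$ec_fmax)
  sub <- function(pair, idx) list(left = band_subset(pair$left, idx),
                                  right = band_subset(pair$right, idx))
  ec <- process_low_bands(sub(mixb, lo), sub(spb, lo), sub(nob, lo),
                          constants = do.call(ec_constants, cfg$ec[
                            c("sigma_delta0", "tau0", "sigma_eps0", "alpha0", "p")]),
                          window_ms = cfg$ec$window_ms, jitter = jitter)
  synth_lo <- function(m) gammatone_synthesize(band_signals_raw(m, fb$cfs[lo], rate, fb),
                                               fb, bands_idx = lo)
  path <- select_ec_path(synth_lo(ec$min$mixture), synth_lo(ec$max$mixture),
                         cfg$selector)
  ecsel <- if (path == "minimize") ec$min else ec$max
  synth_hi <- function(bs) gammatone_synthesize(band_subset(bs, hi), fb, bands_idx = hi)
  ear <- better_ear_select(synth_hi(mixb$left), synth_hi(mixb$right),
                           cfg$selector)
  sp_path <- add_sig(synth_lo(ecsel$speech), synth_hi(spb[[ear]]))
  no_path <- add_sig(synth_lo(ecsel$noise),  synth_hi(nob[[ear]]))
  tab <- sii_band_table()
  slev <- band_spectrum_levels(sp_path, tab, cfg$calibration)
  nlev <- band_spectrum_levels(no_path, tab, cfg$calibration)
  res <- compute_sii(slev, nlev, tab)
  structure(list(sii = res$sii, ec_path = path, better_ear = ear,
                 params = ec$params, jitter = ec$jitter,
                 speech_levels = slev, noise_levels = nlev),
            class = "ec_evaluation")
}

band_subset <- function(bs, idx) {
  structure(list(bands = bs$bands[, idx, drop = FALSE], cfs = bs$cfs[idx],
                 rate = bs$rate, fb = bs$fb), class = "band_signals")
}

band_signals_raw <- function(m, cfs, rate, fb) {
  structure(list(bands = m, cfs = cfs, rate = rate, fb = fb),
            class = "band_signals")
}

add_sig <- function(a, b) monaural_signal(a$samples + b$samples, a$rate)

#' @export
print.ec_evaluation <- function(x, ...) {
  cat(sprintf("<ec_evaluation: SII %.4f, EC path %s, better ear %s>\n",
              x$sii, x$ec_path, x$better_ear))
  invisible(x)
}
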