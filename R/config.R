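## Central configuration: every tunable constant of the model and of the
## synthetic-stimulus generators in one nested list, overridable from YAML or
## JSON.  The defaults are the study conditions of the simulated experiment.

#' Default configuration for the binsrm model and experiment
#'
#' Returns the full nested list of constants used across the package.  Any
#' subset can be overridden via `...` (named sublists are merged recursively)
#' or from a file with [load_config()].
#'
#' Main blocks:
#' \describe{
#'   \item{rate}{sampling rate, 48000 Hz.  At this rate every reference ITD of
#'     the experiment (multiples of 1.75 ms, plus 10 ms) is an integer number
#'     of samples.}
#'   \item{duration_s}{stimulus duration per model evaluation (2 s, the scale
#'     of one matrix-test sentence).}
#'   \item{calibration}{SPL convention: digital RMS `spl_ref_rms` (0.05)
#'     corresponds to `spl_ref_db` (65 dB SPL).}
#'   \item{head}{parametric head model: broadband ITD at 90 degrees (0.70 ms)
#'     and high-frequency head-shadow shelf (12 dB above about 1.5 kHz).}
#'   \item{room}{reverberant stand-in: T60 (1.25 s), direct-to-reverberant
#'     ratio and interaural coherence of the diffuse tail.}
#'   \item{fbank}{gammatone filterbank: 30 ERB-spaced bands, 150--8500 Hz;
#'     bands with centre frequency at or below `ec_fmax` (1500 Hz) are
#'     EC-processed, the rest take the better-ear path.}
#'   \item{ec}{EC error-model constants `sigma_delta0` (65 us), `tau0`
#'     (1.6 ms), `sigma_eps0` (0.25), `alpha0` (13 dB), `p` (1.6), and the
#'     equalization delay search window (+/- 11 ms).}
#'   \item{selector}{modulation analysis: envelope lowpass 150 Hz, 8
#'     log-spaced modulation bands with centres 4--128 Hz, Q = 1; the SRMR is
#'     the energy ratio of the lower four to the upper four bands.}
#'   \item{pipeline}{SNR grid 0 to -20 dB in 1-dB steps, 10 sentences, 10
#'     Monte-Carlo runs per sentence, calibration SRT -7 dB SNR.}
#' }
#'
#' @param ... named overrides, e.g. `binsrm_config(ec = list(sigma_eps0 = 0.2))`.
#' @return nested configuration list of class `binsrm_config`.
#' @export
binsrm_config <- function(...) {
  cfg <- list(
    rate = 48000,
    duration_s = 2.0,
    calibration = list(spl_ref_rms = 0.05, spl_ref_db = 65),
    ltass = list(table = "byrne1994"),
    head = list(itd_90_ms = 0.70, ild_shelf_db = 12, shelf_corner_hz = 1500),
    room = list(environment = "anechoic", t60_s = 1.25,
                direct_to_reverberant_db = 0, tail_coherence = 0.25,
                tail_onset_ms = 5),
    fbank = list(n_bands = 30, f_lo = 150, f_hi = 8500, ec_fmax = 1500),
    ec = list(sigma_delta0 = 65e-6, tau0 = 1.6e-3, sigma_eps0 = 0.25,
              alpha0 = 13, p = 1.6, window_ms = 11),
    selector = list(env_lp_hz = 150, n_mod_bands = 8L,
                    mod_f_lo = 4, mod_f_hi = 128, mod_q = 1,
                    env_rate_hz = 480),
    target = list(mod_rate_hz = 4, mod_depth = 0.7),
    pipeline = list(snr_max_db = 0, snr_min_db = -20, snr_step_db = 1,
                    n_sentences = 10L, n_mc = 10L,
                    calibration_srt_db = -7.0,
                    ref_itds_ms = c(0, 1.75, 3.5, 5.25, 7, 10))
  )
  ov <- list(...)
  if (length(ov)) cfg <- merge_config(cfg, ov)
  class(cfg) <- c("binsrm_config", "list")
  cfg
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load a configuration from YAML or JSON
#'
#' The file may specify any subset of the blocks of [binsrm_config()]; missing
#' entries keep their defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return configuration list as from [binsrm_config()].
#' @export
load_config <- function(path) {
  ov <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  do.call(binsrm_config, ov)
}

## dB SPL of a digital RMS amplitude under the package calibration
spl_of_rms <- function(r, cal) 20 * log10(r / cal$spl_ref_rms) + cal$spl_ref_db
rms_of_spl <- function(db, cal) cal$spl_ref_rms * 10^((db - cal$spl_ref_db) / 20)
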