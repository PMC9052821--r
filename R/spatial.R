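## Spatialization and interaural cue manipulation: render target and masker
## through impulse-response pairs, isolate ITD or ILD cues in the separated
## masker's response, inject a reference ITD on the right-ear channel, and
## mix at a source-level SNR while keeping clean speech and noise shadow
## paths alongside the mixture.

#' Cue conditions
#'
#' `A_BOTH` leaves the 90-degree response untouched (ITDs and ILDs),
#' `B_ITD_ONLY` delays the right channel of the 0-degree response by the
#' broadband delay of the 90-degree response (ITDs without ILDs), and
#' `C_ILD_ONLY` advances the right channel of the 90-degree response by that
#' delay (ILDs without the broadband ITD).
#'
#' @format character constants `"A_BOTH"`, `"B_ITD_ONLY"`, `"C_ILD_ONLY"`.
#' @export
cue_conditions <- c("A_BOTH", "B_ITD_ONLY", "C_ILD_ONLY")

#' Scene specification
#'
#' Describes one simulated listening configuration: target fixed at 0 degrees,
#' masker collocated (0) or separated (90 degrees), a cue condition, a
#' reference ITD injected on the right-ear channel, the source-level SNR, and
#' the masker presentation level.
#'
#' @param masker_azimuth_deg 0 or 90.
#' @param condition one of [cue_conditions].
#' @param ref_itd_ms reference ITD in milliseconds (>= 0), applied by delaying
#'   the right-ear channel of every rendered path.
#' @param snr_db target-to-masker ratio at the source (pre-spatialization)
#'   reference point, in dB.
#' @param masker_level_db_spl masker source level (default 65 dB SPL).
#' @param room [room_spec()].
#' @export
scene_spec <- function(masker_azimuth_deg = 90, condition = "A_BOTH",
                       ref_itd_ms = 0, snr_db = 0, masker_level_db_spl = 65,
                       room = room_spec()) {
  if (!masker_azimuth_deg %in% c(0, 90))
    stop("invalid-argument: masker azimuth must be 0 or 90", call. = FALSE)
  condition <- match.arg(condition, cue_conditions)
  if (ref_itd_ms < 0)
    stop("invalid-argument: ref_itd_ms must be >= 0", call. = FALSE)
  structure(list(target_azimuth_deg = 0, masker_azimuth_deg = masker_azimuth_deg,
                 condition = condition, ref_itd_ms = ref_itd_ms, snr_db = snr_db,
                 masker_level_db_spl = masker_level_db_spl, room = room),
            class = "scene_spec")
}

#' Broadband interchannel delay of an impulse-response pair
#'
#' Lag of the maximum of the normalized interchannel cross-correlation,
#' positive when the right channel lags the left.  Ties are broken in favor
#' of the smallest absolute lag.
#'
#' @param pair [irpair()].
#' @param max_lag_ms search window (default 20 ms).
#' @return delay in seconds.
#' @export
estimate_broadband_delay <- function(pair, max_lag_ms = 20) {
  el <- sum(pair$left^2); er <- sum(pair$right^2)
  if (el < 1e-300 || er < 1e-300)
    stop("degenerate-input: all-zero impulse response", call. = FALSE)
  lag <- xcorr_peak_lag(pair$left, pair$right,
                        max_lag = min(round(max_lag_ms * 1e-3 * pair$rate),
                                      length(pair$left) - 1L))
  lag / pair$rate
}

## Lag (samples) of the maximum of cross-correlation sum x[t]*y[t+lag],
## restricted to |lag| <= max_lag; smallest |lag| wins ties.
xcorr_peak_lag <- function(x, y, max_lag) {
  n <- length(x)
  nfft <- good_nfft(n + max_lag + 1L)
  cc <- fft(Conj(fft(c(x, numeric(nfft - n)))) * fft(c(y, numeric(nfft - n))),
            inverse = TRUE)
  cc <- Re(cc) / nfft
  lags <- c(0:max_lag, -(max_lag:1))
  vals <- cc[c(1:(max_lag + 1L), (nfft - max_lag + 1L):nfft)]
  o <- order(abs(lags), lags)          # visit small |lag| first
  lags <- lags[o]; vals <- vals[o]
  lags[which.max(vals)]
}

#' Build the cue-condition impulse response for the separated masker
#'
#' @param h0 impulse-response pair at 0 degrees.
#' @param h90 impulse-response pair at 90 degrees.
#' @param condition one of [cue_conditions].
#' @return [irpair()]: condition A returns `h90` unchanged; B returns `h0`
#'   with the right channel delayed by the broadband delay of `h90` (pure
#'   ITDs); C returns `h90` with the right channel advanced by that delay
#'   (pure ILDs, broadband delay approximately zero).
#' @export
make_cue_condition_hrir <- function(h0, h90, condition) {
  condition <- match.arg(condition, cue_conditions)
  if (h0$rate != h90$rate)
    stop("invalid-argument: impulse-response rates differ", call. = FALSE)
  if (condition == "A_BOTH") return(h90)
  d <- estimate_broadband_delay(h90) * h90$rate      # samples, > 0: right lags
  if (condition == "B_ITD_ONLY")
    irpair(h0$left, fractional_delay(h0$right, d), h0$rate,
           label = paste0(h90$label, "/B_ITD_ONLY"))
  else
    irpair(h90$left, fractional_delay(h90$right, -d), h90$rate,
           label = paste0(h90$label, "/C_ILD_ONLY"))
}

#' Inject a reference ITD
#'
#' Delays the right-ear channel by `ref_itd_ms`; the left channel is
#' untouched.  The length is preserved: the right channel's head is
#' zero-padded and samples shifted beyond the end are dropped.
#'
#' @param x [binaural_signal()].
#' @param ref_itd_ms reference ITD in milliseconds (>= 0).
#' @export
apply_reference_itd <- function(x, ref_itd_ms) {
  if (ref_itd_ms < 0)
    stop("invalid-argument: ref_itd_ms must be >= 0", call. = FALSE)
  if (ref_itd_ms == 0) return(x)
  binaural_signal(x$left,
                  fractional_delay(x$right, ref_itd_ms * 1e-3 * x$rate),
                  x$rate)
}

#' Spatialize target and masker and mix at a source-level SNR
#'
#' The masker source is scaled to `masker_level_db_spl` and the target source
#' to `masker_level_db_spl + snr_db` (SNR defined at the source, before
#' spatialization), each is convolved with its impulse-response pair, the
#' reference ITD is applied identically to both rendered paths, and the
#' mixture is their sample-wise sum.  Clean speech and noise paths are
#' returned alongside the mixture for the shadow-filtering back end.
#'
#' @param target,masker [monaural_signal()]s with a common rate.
#' @param scene [scene_spec()].
#' @param h_target,h_masker [irpair()]s used for rendering (the caller
#'   applies [make_cue_condition_hrir()] beforehand for the masker).
#' @param cal calibration block of [binsrm_config()].
#' @return `spatial_scene`: list with `mixture`, `speech_clean`,
#'   `noise_clean` ([binaural_signal()]s of equal length) and the `scene`.
#' @export
spatialize_and_mix <- function(target, masker, scene, h_target, h_masker,
                               cal = binsrm_config()$calibration) {
  if (target$rate != masker$rate || target$rate != h_target$rate ||
      h_target$rate != h_masker$rate)
    stop("invalid-argument: sampling rates differ", call. = FALSE)
  ns <- min(length(target$samples), length(masker$samples))
  t_src <- target$samples[seq_len(ns)]
  m_src <- masker$samples[seq_len(ns)]
  m_src <- m_src * (rms_of_spl(scene$masker_level_db_spl, cal) / rms(m_src))
  t_src <- t_src * (rms_of_spl(scene$masker_level_db_spl + scene$snr_db, cal) /
                      rms(t_src))
  nh <- max(length(h_target$left), length(h_masker$left))
  n_out <- ns + nh - 1L
  render <- function(src, h) {
    binaural_signal(c(fft_conv(src, h$left), numeric(n_out - ns - length(h$left) + 1L)),
                    c(fft_conv(src, h$right), numeric(n_out - ns - length(h$right) + 1L)),
                    target$rate)
  }
  sp <- apply_reference_itd(render(t_src, h_target), scene$ref_itd_ms)
  no <- apply_reference_itd(render(m_src, h_masker), scene$ref_itd_ms)
  mix <- binaural_signal(sp$left + no$left, sp$right + no$right, target$rate)
  structure(list(mixture = mix, speech_clean = sp, noise_clean = no,
                 scene = scene), class = "spatial_scene")
}
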