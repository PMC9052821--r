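## Experiment driver: SNR grids, Monte-Carlo repetitions, reference-SII
## calibration, SRT extraction, SRM computation, and the full factorial
## condition sweep (cue condition x reference ITD x masker azimuth x
## environment).
##
## Seeding: every random quantity derives from one master seed through
## documented substreams -- sentence/masker realizations from
## (master, sentence index), reverberant-tail realizations from (master, 7),
## and EC jitter from (master, azimuth, condition, reference ITD,
## environment, sentence, SNR index, Monte-Carlo index) -- so a full run is
## bit-reproducible while all substreams stay statistically independent.

#' Default SNR grid
#'
#' 21 SNRs from 0 down to -20 dB in 1-dB steps.
#'
#' @param cfg configuration from [binsrm_config()].
#' @return increasing numeric vector, -20 to 0 dB.
#' @export
default_snr_grid <- function(cfg = binsrm_config()) {
  seq(cfg$pipeline$snr_min_db, cfg$pipeline$snr_max_db,
      by = cfg$pipeline$snr_step_db)
}

## HRIR set for a scene: target response (0 deg) and masker response
## (0 deg, or the cue-conditioned 90-deg response)
scene_hrirs <- function(scene, cfg, seed) {
  head <- do.call(head_model_params, c(cfg$head, list(rate = cfg$rate)))
  room <- do.call(room_spec, scene$room[c("environment", "t60_s",
                                          "direct_to_reverberant_db",
                                          "tail_coherence", "tail_onset_ms")])
  h0 <- gen_hrir(0, head, room, seed = mix_seed(seed, 7))
  if (scene$masker_azimuth_deg == 0)
    return(list(h_target = h0, h_masker = h0))
  h90 <- gen_hrir(90, head, room, seed = mix_seed(seed, 7))
  list(h_target = h0,
       h_masker = make_cue_condition_hrir(h0, h90, scene$condition))
}

#' Simulate one psychometric curve (mean SII versus SNR)
#'
#' For each SNR of the grid, `n_sentences` target realizations are rendered
#' into the scene and the full model is evaluated `n_mc` times per sentence
#' with fresh EC jitter; the SII is averaged over all evaluations.  With the
#' full defaults (21 SNRs, 10 sentences, 10 Monte-Carlo runs) this is 2100
#' model evaluations per condition cell.
#'
#' @param scene [scene_spec()]; its `snr_db` field is ignored (the grid is
#'   swept).
#' @param cfg configuration from [binsrm_config()].
#' @param n_sentences,n_mc repetitions (defaults from `cfg$pipeline`).
#' @param grid SNR grid in dB (default [default_snr_grid()]).
#' @param seed master seed.
#' @param engine `"fast"` or `"reference"` (see [evaluate_scene()]).
#' @param hrirs optional list `(h_target, h_masker)` of [irpair()]s to use
#'   instead of the synthetic generator (e.g. measured responses read with
#'   [read_wav()]).
#' @param verbose print per-SNR progress.
#' @return object of class `psychometric_curve`: `snr_grid_db`, `mean_sii`,
#'   `sd_sii`, `n_sentences`, `n_mc`, `n_evals`, `scene`.
#' @export
simulate_condition <- function(scene, cfg = binsrm_config(),
                               n_sentences = cfg$pipeline$n_sentences,
                               n_mc = cfg$pipeline$n_mc,
                               grid = default_snr_grid(cfg), seed = 1,
                               engine = c("fast", "reference"),
                               hrirs = NULL, verbose = FALSE) {
  engine <- match.arg(engine)
  stopifnot(all(diff(grid) > 0))
  fb <- gammatone_filterbank(cfg$rate, cfg$fbank$n_bands, cfg$fbank$f_lo,
                             cfg$fbank$f_hi)
  if (is.null(hrirs)) hrirs <- scene_hrirs(scene, cfg, seed)
  cell <- c(scene$masker_azimuth_deg, match(scene$condition, cue_conditions),
            round(scene$ref_itd_ms * 100),
            if (scene$room$environment == "reverberant") 1L else 0L)
  acc <- matrix(0, length(grid), n_sentences * n_mc)
  for (s in seq_len(n_sentences)) {
    target <- gen_speech_like_target(cfg$duration_s, cfg$rate,
                                     seed = mix_seed(seed, 1000, s),
                                     mod_rate_hz = cfg$target$mod_rate_hz,
                                     mod_depth = cfg$target$mod_depth)
    masker <- gen_ltass_noise(cfg$duration_s, cfg$rate,
                              seed = mix_seed(seed, 2000, s))
    sc0 <- spatialize_and_mix(target, masker, scene_at_snr(scene, 0),
                              hrirs$h_target, hrirs$h_masker, cfg$calibration)
    if (engine == "fast") {
      prep <- ev_prepare(sc0, fb, cfg)
      for (gi in seq_along(grid)) {
        g <- db_to_amp(grid[gi])
        est <- ev_estimate(prep, g)
        for (mc in seq_len(n_mc)) {
          ev <- with_seed(mix_seed(seed, cell, s, gi, mc),
                          ev_evaluate_mc(prep, est, g))
          acc[gi, (s - 1L) * n_mc + mc] <- ev$sii
        }
      }
    } else {
      for (gi in seq_along(grid)) {
        sc <- scale_scene_snr(sc0, grid[gi])
        for (mc in seq_len(n_mc)) {
          ev <- with_seed(mix_seed(seed, cell, s, gi, mc),
                          evaluate_scene(sc, fb, cfg, method = "reference"))
          acc[gi, (s - 1L) * n_mc + mc] <- ev$sii
        }
      }
    }
    if (verbose)
      message(sprintf("  sentence %d/%d done", s, n_sentences))
  }
  structure(list(snr_grid_db = grid, mean_sii = rowMeans(acc),
                 sd_sii = apply(acc, 1, sd), n_sentences = n_sentences,
                 n_mc = n_mc, n_evals = length(acc), scene = scene),
            class = "psychometric_curve")
}

scene_at_snr <- function(scene, snr_db) { scene$snr_db <- snr_db; scene }

## rescale the clean speech path of a rendered scene to a new source SNR
## (the scene must have been rendered at 0 dB)
scale_scene_snr <- function(sc0, snr_db) {
  g <- db_to_amp(snr_db)
  sp <- binaural_signal(g * sc0$speech_clean$left, g * sc0$speech_clean$right,
                        sc0$speech_clean$rate)
  structure(list(mixture = binaural_signal(sp$left + sc0$noise_clean$left,
                                           sp$right + sc0$noise_clean$right, sp$rate),
                 speech_clean = sp, noise_clean = sc0$noise_clean,
                 scene = scene_at_snr(sc0$scene, snr_db)),
            class = "spatial_scene")
}

#' @export
print.psychometric_curve <- function(x, ...) {
  cat(sprintf("<psychometric_curve: %d SNRs in [%g, %g] dB, %d evals, SII %.3f..%.3f>\n",
              length(x$snr_grid_db), min(x$snr_grid_db), max(x$snr_grid_db),
              x$n_evals, min(x$mean_sii), max(x$mean_sii)))
  invisible(x)
}

#' Reference SII from a calibration curve
#'
#' Linearly interpolates the mean SII of the collocated, zero-reference-ITD,
#' both-cues calibration curve at the calibration SRT; this SII is then used
#' as the criterion for SRT extraction in every other condition.
#'
#' @param curve `psychometric_curve` of the calibration condition.
#' @param calibration_srt_db calibration SRT in dB SNR (within the grid).
#' @return scalar reference SII.
#' @export
calibrate_reference_sii <- function(curve, calibration_srt_db) {
  g <- curve$snr_grid_db
  if (calibration_srt_db < min(g) || calibration_srt_db > max(g))
    stop("out-of-range: calibration SRT outside the SNR grid", call. = FALSE)
  approx(g, curve$mean_sii, xout = calibration_srt_db)$y
}

#' Speech reception threshold from a psychometric curve
#'
#' The SRT is the SNR at which the mean SII crosses the reference SII,
#' found by linear interpolation scanning from the lowest SNR upward.  With
#' a non-monotone curve the lowest-SNR crossing is returned with a warning.
#'
#' @param curve `psychometric_curve`.
#' @param reference_sii criterion SII from [calibrate_reference_sii()].
#' @return list of class `srt_result`: `srt_db` and the `scene`.
#' @export
srt_from_curve <- function(curve, reference_sii) {
  s <- curve$mean_sii - reference_sii
  g <- curve$snr_grid_db
  hits <- which(s[-length(s)] * s[-1] <= 0 &
                  (s[-length(s)] != 0 | s[-1] != 0))
  exact <- which(s == 0)
  if (!length(hits) && !length(exact))
    stop(sprintf(
      "no-threshold: mean SII (%.3f..%.3f) never crosses reference %.3f",
      min(curve$mean_sii), max(curve$mean_sii), reference_sii), call. = FALSE)
  cand <- sort(c(g[exact], vapply(hits, function(i)
    g[i] + (g[i + 1] - g[i]) * (0 - s[i]) / (s[i + 1] - s[i]), numeric(1))))
  cand <- cand[!duplicated(round(cand, 9))]
  if (length(cand) > 1)
    warning("non-monotone psychometric curve: using the lowest-SNR crossing")
  structure(list(srt_db = cand[1], scene = curve$scene), class = "srt_result")
}

#' Spatial release from masking
#'
#' `SRM = SRT(collocated) - SRT(separated)`.  Accepts `srt_result`s (their
#' scene descriptors must agree in condition, reference ITD and environment)
#' or bare numbers.
#'
#' @param srt_colocated,srt_separated `srt_result` or numeric SRTs in dB.
#' @return SRM in dB.
#' @export
compute_srm <- function(srt_colocated, srt_separated) {
  if (inherits(srt_colocated, "srt_result") &&
      inherits(srt_separated, "srt_result")) {
    a <- srt_colocated$scene; b <- srt_separated$scene
    if (!isTRUE(all.equal(c(a$ref_itd_ms, a$room$environment),
                          c(b$ref_itd_ms, b$room$environment))))
      stop("invalid-argument: SRT descriptors do not match", call. = FALSE)
  }
  srt_db <- function(x) if (inherits(x, "srt_result")) x$srt_db else x
  srt_db(srt_colocated) - srt_db(srt_separated)
}

#' Run the full reference-ITD experiment sweep
#'
#' Sweeps cue conditions x reference ITDs x masker azimuths (0 and 90
#' degrees) x environments, extracts the SRT of every cell against the
#' anechoic calibration reference SII, and attaches the SRM to every
#' separated cell.  Collocated cells are independent of the cue condition
#' (the masker then uses the unmanipulated frontal response) and are computed
#' once per (reference ITD, environment) and replicated across conditions.
#'
#' @param cfg configuration from [binsrm_config()].
#' @param seed master seed.
#' @param conditions subset of [cue_conditions].
#' @param ref_itds_ms reference ITDs in ms (default
#'   `cfg$pipeline$ref_itds_ms`, i.e. 0, 1.75, 3.5, 5.25, 7 and 10 ms).
#' @param environments `"anechoic"`, `"reverberant"`, or both.
#' @param n_sentences,n_mc,grid repetitions and SNR grid per cell.
#' @param engine `"fast"` or `"reference"`.
#' @param out_dir optional directory: tidy CSV (`srt_table.csv`) and a JSON
#'   summary are written there, and partial results are persisted as cells
#'   complete.
#' @param verbose print per-cell progress.
#' @return data.frame of class `experiment_result` with columns `condition`,
#'   `ref_itd_ms`, `masker_azimuth`, `environment`, `srt_db`, `srm_db` (NA
#'   for collocated rows), and attribute `reference_sii`.
#' @export
run_experiment <- function(cfg = binsrm_config(), seed = 1,
                           conditions = cue_conditions,
                           ref_itds_ms = cfg$pipeline$ref_itds_ms,
                           environments = "anechoic",
                           n_sentences = cfg$pipeline$n_sentences,
                           n_mc = cfg$pipeline$n_mc,
                           grid = default_snr_grid(cfg),
                           engine = "fast", out_dir = NULL, verbose = TRUE) {
  room_of <- function(env) {
    r <- cfg$room; r$environment <- env; r
  }
  curve_of <- function(az, cond, itd, env) {
    scene <- scene_spec(masker_azimuth_deg = az, condition = cond,
                        ref_itd_ms = itd, room = room_of(env))
    simulate_condition(scene, cfg, n_sentences, n_mc, grid, seed, engine)
  }
  ## calibration: collocated, 0 ms reference ITD, anechoic, both cues
  if (verbose) message("calibrating reference SII (S0N0, 0 ms, anechoic)")
  cal_key <- "0|A_BOTH|0|anechoic"
  s0_cache <- list()
  s0_cache[[cal_key]] <- curve_of(0, "A_BOTH", 0, "anechoic")
  ref_sii <- calibrate_reference_sii(s0_cache[[cal_key]],
                                     cfg$pipeline$calibration_srt_db)
  rows <- list()
  persist <- function() {
    if (is.null(out_dir)) return(invisible())
    df <- do.call(rbind, rows)
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(df, file.path(out_dir, "srt_table.csv"), row.names = FALSE)
  }
  for (env in environments) for (itd in ref_itds_ms) {
    k0 <- sprintf("0|A_BOTH|%g|%s", itd, env)
    if (is.null(s0_cache[[k0]])) s0_cache[[k0]] <- curve_of(0, "A_BOTH", itd, env)
    srt0 <- srt_from_curve(s0_cache[[k0]], ref_sii)$srt_db
    for (cond in conditions) {
      if (verbose) message(sprintf("cell: %s, %g ms, %s", cond, itd, env))
      srt90 <- srt_from_curve(curve_of(90, cond, itd, env), ref_sii)$srt_db
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, ref_itd_ms = itd, masker_azimuth = 0,
        environment = env, srt_db = srt0, srm_db = NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, ref_itd_ms = itd, masker_azimuth = 90,
        environment = env, srt_db = srt90, srm_db = srt0 - srt90)
      persist()
    }
  }
  res <- do.call(rbind, rows)
  attr(res, "reference_sii") <- ref_sii
  class(res) <- c("experiment_result", "data.frame")
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(reference_sii = ref_sii,
           srm = res[res$masker_azimuth == 90,
                     c("condition", "ref_itd_ms", "environment", "srm_db")]),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  res
}

#' Plot modeled SRM against reference ITD
#'
#' One line per cue condition (and line type per environment), mirroring the
#' experiment's summary figure.
#'
#' @param res `experiment_result` from [run_experiment()].
#' @param ... passed to [graphics::matplot()].
#' @export
plot_srm <- function(res, ...) {
  d <- res[res$masker_azimuth == 90, ]
  envs <- unique(d$environment)
  conds <- unique(d$condition)
  itds <- sort(unique(d$ref_itd_ms))
  cols <- c(A_BOTH = "black", B_ITD_ONLY = "dodgerblue3", C_ILD_ONLY = "firebrick3")
  plot(range(itds), range(d$srm_db, 0), type = "n",
       xlab = "reference ITD [ms]", ylab = "modeled SRM [dB]", ...)
  for (env in envs) for (cond in conds) {
    dd <- d[d$environment == env & d$condition == cond, ]
    dd <- dd[order(dd$ref_itd_ms), ]
    lines(dd$ref_itd_ms, dd$srm_db, col = cols[[cond]],
          lty = if (env == "anechoic") 1 else 2, type = "b", pch = 16)
  }
  legend("topright", bty = "n",
         legend = c(paste(conds), paste(envs)),
         col = c(cols[conds], rep("grey40", length(envs))),
         lty = c(rep(1, length(conds)), seq_along(envs)))
  invisible(d)
}
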