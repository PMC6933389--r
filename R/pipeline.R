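#' Default run configuration
#'
#' Returns the fully populated configuration list that [runPipeline()]
#' consumes, optionally overridden field-by-field.  The configuration is
#' plain-YAML-serializable; a run re-executed from its saved config and
#' seed is bit-identical through the deterministic stages.
#'
#' @param ... named overrides of top-level sections or fields, e.g.
#'   `seed = 7`, `acquisition = list(frame_h = 64)` (section overrides are
#'   merged, not replaced wholesale).
#' @return a list of class `"RunConfig"`.
#' @export
defaultRunConfig <- function(...) {
  cfg <- list(
    seed = 1L,
    panel = c("3CHO", "4CHO", "5CHO", "6CHO", "7CHO"),
    trials_per_stimulus = 4L,
    acquisition = list(frame_rate_hz = 125, n_frames = 1625L,
                       frame_h = 128L, frame_w = 128L,
                       pixel_size_um = 1750 / 128,
                       bleach_tau_s = 5, bleach_fraction = 0.2,
                       noise_sd = 5, baseline_level = 1000),
    breath = list(rate_hz = 2, duty_inhale = 0.35, jitter_sd_s = 0.02,
                  amplitude = 1, noise_sd = 0.05),
    stimulus = list(requested_onset_s = 5, duration_s = 2,
                    min_prestimulus_s = 4, concentration_pct = 0.2),
    map_layout = list(n_glomeruli = 8L, ap_offset_px = 12L,
                      radius_px = 4, peak_amplitude = 0.08,
                      margin_px = 16, min_sep_px = 12),
    bleach_correct = list(enabled = TRUE, block_size = 4L,
                          head_frames = 480L, tail_frames = 5L,
                          exclude_threshold = 2),
    map_windows = list(response_s = 1.6, baseline_from_s = 1.4,
                       baseline_to_s = 0.4),
    compare = list(max_shift_px = 20L, gate_px = 5, roi_radius_px = 3,
                   sigma_px = 1, threshold_k = 3),
    stages = list(simulate = TRUE, map = TRUE, compare = TRUE),
    write_movies = TRUE
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = "RunConfig")
}

#' Validate a run configuration
#'
#' Checks cross-field consistency (window arithmetic, block divisibility,
#' fitting-window fit) before any stage runs.
#'
#' @param cfg a `"RunConfig"` list.
#' @return the config, invisibly; errors describe the offending field.
#' @export
validateRunConfig <- function(cfg) {
  a <- cfg$acquisition; b <- cfg$bleach_correct; w <- cfg$map_windows
  if (a$n_frames < 2L) stop("config: n_frames must be >= 2")
  if (b$head_frames + b$tail_frames >= a$n_frames)
    stop("config: head_frames + tail_frames (",
         b$head_frames + b$tail_frames,
         ") must be smaller than n_frames (", a$n_frames, ")")
  if (a$frame_h %% b$block_size != 0L || a$frame_w %% b$block_size != 0L)
    stop("config: frame dimensions must be divisible by block_size")
  fs <- a$frame_rate_hz
  need <- framesIn(cfg$stimulus$min_prestimulus_s, fs)
  if (framesIn(w$baseline_from_s, fs) > need)
    stop("config: baseline window reaches before the minimum prestimulus ",
         "period")
  if (length(cfg$panel) < 1L) stop("config: empty odorant panel")
  if (cfg$trials_per_stimulus < 1L)
    stop("config: trials_per_stimulus must be >= 1")
  invisible(cfg)
}

#' Save / load a run configuration as YAML
#'
#' `loadRunConfig(saveRunConfig(cfg, f))` reproduces `cfg` exactly.
#'
#' @param cfg a `"RunConfig"` list.
#' @param path YAML file path.
#' @return `saveRunConfig` returns `path` invisibly; `loadRunConfig`
#'   returns the validated `"RunConfig"`.
#' @export
saveRunConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15L)
  invisible(path)
}

#' @rdname saveRunConfig
#' @export
loadRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg <- do.call(defaultRunConfig, cfg)
  validateRunConfig(cfg)
  cfg
}

pipelineAcq <- function(cfg, seed = NULL) {
  a <- cfg$acquisition
  AcquisitionSpec(frameRateHz = a$frame_rate_hz, nFrames = a$n_frames,
                  frameDim = c(a$frame_h, a$frame_w),
                  pixelSizeUm = a$pixel_size_um,
                  bleachTauS = a$bleach_tau_s,
                  bleachFraction = a$bleach_fraction,
                  noiseSd = a$noise_sd, baselineLevel = a$baseline_level,
                  seed = seed)
}

#' Run the full pipeline: simulate, correct, align, map, compare
#'
#' Executes the configured stages in order on synthetic data and writes
#' all stage outputs plus a manifest into `outDir`:
#' `trials/<view>/<odorant>/trial_<k>.tif|_breath.csv|_truth.json`,
#' `maps/<view>_<odorant>.tif|.png`, `compare/registration.json`,
#' `compare/pairs.csv`, `compare/chemotopy.csv` and `manifest.json`.  The
#' manifest records package version, seed, config, per-trial block-noise
#' exclusion decisions and an MD5 checksum of every emitted file.
#' Excluded trials stay on disk, flagged in the manifest, never deleted.
#'
#' @param cfg a `"RunConfig"` (see [defaultRunConfig()]) or a YAML path.
#' @param outDir run directory, created if needed.
#' @return the manifest list, invisibly.
#' @export
runPipeline <- function(cfg, outDir) {
  if (is.character(cfg)) cfg <- loadRunConfig(cfg)
  validateRunConfig(cfg)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  manifest <- list(
    package = "glomap",
    version = as.character(utils::packageVersion("glomap")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed, config = unclass(cfg))

  withStage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("[stage ", stage, "] ", conditionMessage(e), call. = FALSE))
  }

  # --- simulate ------------------------------------------------------
  set.seed(cfg$seed)
  ml <- cfg$map_layout
  pair <- withStage("simulate",
    generateMapPair(ml$n_glomeruli, cfg$panel,
                    apOffsetPx = ml$ap_offset_px,
                    frameDim = c(cfg$acquisition$frame_h,
                                 cfg$acquisition$frame_w),
                    radiusPx = ml$radius_px,
                    peakAmplitude = ml$peak_amplitude,
                    marginPx = ml$margin_px, minSepPx = ml$min_sep_px))
  acq <- pipelineAcq(cfg)
  bs <- do.call(BreathSpec, cfg$breath[c("rate_hz", "duty_inhale",
                                         "jitter_sd_s", "amplitude",
                                         "noise_sd")] |>
                  stats::setNames(c("rateHz", "dutyInhale", "jitterSdS",
                                    "amplitude", "noiseSd")))
  views <- list(dorsal = pair$dorsal, medial = pair$medial)
  trialInfo <- list()
  trialSets <- list()
  for (vw in names(views)) {
    for (od in cfg$panel) {
      stim <- StimulusSpec(od,
        nominalConcentrationPct = cfg$stimulus$concentration_pct,
        requestedOnsetS = cfg$stimulus$requested_onset_s,
        durationS = cfg$stimulus$duration_s,
        minPrestimulusS = cfg$stimulus$min_prestimulus_s)
      set <- withStage("simulate",
        simulateTrialSet(views[[vw]], acq, bs, stim,
                         nTrials = cfg$trials_per_stimulus))
      trialSets[[paste(vw, od, sep = "/")]] <- set
      if (isTRUE(cfg$stages$simulate) && isTRUE(cfg$write_movies)) {
        tdir <- file.path(outDir, "trials", vw, od)
        for (k in seq_along(set))
          files <- c(files, withStage("simulate",
            writeTrial(set[[k]], tdir, paste0("trial_", k))))
      }
    }
  }

  # --- map (bleach-correct + align + average + dF/F0) ----------------
  maps <- list()
  if (isTRUE(cfg$stages$map)) {
    bc <- cfg$bleach_correct
    for (key in names(trialSets)) {
      vw <- strsplit(key, "/")[[1L]][1L]
      res <- withStage("map",
        computeTrialSetMap(trialSets[[key]],
                           correctBleach = isTRUE(bc$enabled),
                           view = vw, blockSize = bc$block_size,
                           headFrames = bc$head_frames,
                           tailFrames = bc$tail_frames,
                           excludeThreshold = bc$exclude_threshold,
                           responseS = cfg$map_windows$response_s,
                           baselineFromS = cfg$map_windows$baseline_from_s,
                           baselineToS = cfg$map_windows$baseline_to_s))
      maps[[key]] <- res$map
      scores <- vapply(res$reports, function(r)
        if (is.null(r)) NA_real_ else r@blockNoiseScore, numeric(1))
      trialInfo[[key]] <- data.frame(
        view = vw, odorant = sub(".*/", "", key),
        trial = seq_along(trialSets[[key]]),
        block_noise_score = scores, excluded = res$excluded)
      mdir <- file.path(outDir, "maps")
      dir.create(mdir, showWarnings = FALSE)
      files <- c(files, withStage("map",
        writeActivityMap(res$map,
                         file.path(mdir, paste0(gsub("/", "_", key),
                                                ".tif")))))
    }
  }

  # --- compare -------------------------------------------------------
  if (isTRUE(cfg$stages$compare) && isTRUE(cfg$stages$map)) {
    cp <- cfg$compare
    cdir <- file.path(outDir, "compare")
    dir.create(cdir, showWarnings = FALSE)
    dorsalMaps <- maps[grep("^dorsal/", names(maps))]
    medialMaps <- lapply(maps[grep("^medial/", names(maps))], flipMedial)
    reg <- withStage("compare",
      registerApOffset(Reduce(pmax, lapply(dorsalMaps, mapValues)),
                       Reduce(pmax, lapply(medialMaps, mapValues)),
                       maxShiftPx = cp$max_shift_px))
    gd <- withStage("compare",
      detectGlomeruli(unname(dorsalMaps), sigmaPx = cp$sigma_px,
                      thresholdK = cp$threshold_k,
                      radiusPx = cp$roi_radius_px, view = "dorsal"))
    gm <- withStage("compare",
      detectGlomeruli(unname(medialMaps), sigmaPx = cp$sigma_px,
                      thresholdK = cp$threshold_k,
                      radiusPx = cp$roi_radius_px,
                      view = "medial_flipped"))
    pairs <- withStage("compare",
      matchEnsembles(gd, gm, reg, gatePx = cp$gate_px))
    fReg <- file.path(cdir, "registration.json")
    jsonlite::write_json(list(flip_axis = reg@flipAxis,
                              ap_shift_px = reg@apShiftPx,
                              score = reg@score),
                         fReg, auto_unbox = TRUE, digits = NA)
    fPairs <- file.path(cdir, "pairs.csv")
    utils::write.csv(pairs, fPairs, row.names = FALSE)
    files <- c(files, fReg, fPairs)
    if (length(cfg$panel) >= 3L) {
      chD <- withStage("compare", chemotopyShift(gd, cfg$panel))
      chM <- withStage("compare", chemotopyShift(gm, cfg$panel))
      chTab <- rbind(cbind(view = "dorsal", chD$table),
                     cbind(view = "medial_flipped", chM$table))
      chTab$monotone <- rep(c(chD$monotone, chM$monotone),
                            each = nrow(chD$table))
      fCh <- file.path(cdir, "chemotopy.csv")
      utils::write.csv(chTab, fCh, row.names = FALSE)
      files <- c(files, fCh)
    }
    manifest$registration <- list(ap_shift_px = reg@apShiftPx,
                                  score = reg@score)
    manifest$n_pairs <- nrow(pairs)
  }

  manifest$trials <- if (length(trialInfo))
    do.call(rbind, unname(trialInfo)) else NULL
  manifest$files <- data.frame(
    path = sub(paste0("^", outDir, "/?"), "", files),
    md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", force = TRUE)
  invisible(manifest)
}
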