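#' Write and read movies as multi-page TIFF
#'
#' Movies are stored as 16-bit multi-page TIFF (one page per frame),
#' intensities in counts (quantized to integers on write; keep intensities
#' below 65,535).  Frame rate and pixel size are not stored in the TIFF
#' and must be supplied on read.
#'
#' @param movie a [Movie].
#' @param path output file path.
#' @return `writeMovieTiff` returns `path` invisibly; `readMovieTiff`
#'   returns a [Movie].
#' @export
writeMovieTiff <- function(movie, path) {
  stopifnot(is(movie, "Movie"))
  a <- movieData(movie)
  if (min(a) < 0 || max(a) > 65534)
    stop("intensities must lie in [0, 65535] for 16-bit TIFF export")
  a <- roundHalfAway(a)  # the TIFF writer truncates; quantize explicitly
  frames <- lapply(seq_len(dim(a)[3L]), function(f) (a[, , f] + 0.5) / 65535)
  tiff::writeTIFF(frames, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname writeMovieTiff
#' @param frameRateHz,pixelSizeUm acquisition metadata for the movie read
#'   back.
#' @export
readMovieTiff <- function(path, frameRateHz = 125,
                          pixelSizeUm = 1750 / 128) {
  frames <- tiff::readTIFF(path, all = TRUE)
  a <- array(0, c(dim(frames[[1L]])[1:2], length(frames)))
  for (f in seq_along(frames)) a[, , f] <- frames[[f]] * 65535
  Movie(a, frameRateHz = frameRateHz, pixelSizeUm = pixelSizeUm)
}

#' Write and read a breath trace as two-column CSV
#'
#' Columns `time_s` and `value`; ground-truth or detected events are not
#' stored in the CSV (use the truth JSON sidecar or re-run detection).
#'
#' @param trace a [BreathTrace].
#' @param path file path.
#' @return `writeBreathCsv` returns `path` invisibly; `readBreathCsv`
#'   returns a [BreathTrace] without events.
#' @export
writeBreathCsv <- function(trace, path) {
  stopifnot(is(trace, "BreathTrace"))
  df <- data.frame(
    time_s = (seq_along(trace@samples) - 1L) / trace@sampleRateHz,
    value = trace@samples)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeBreathCsv
#' @export
readBreathCsv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_s", "value") %in% names(df)), nrow(df) >= 2L)
  fs <- 1 / stats::median(diff(df$time_s))
  BreathTrace(df$value, sampleRateHz = fs)
}

#' Write one synthetic trial to disk
#'
#' Emits `<prefix>.tif` (movie), `<prefix>_breath.csv` (breath trace) and
#' `<prefix>_truth.json` (ground truth + stimulus descriptor).
#'
#' @param trial a [Trial].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix, e.g. `"trial_1"`.
#' @return character vector of the files written, invisibly.
#' @export
writeTrial <- function(trial, dir, prefix) {
  stopifnot(is(trial, "Trial"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fMov <- file.path(dir, paste0(prefix, ".tif"))
  fBre <- file.path(dir, paste0(prefix, "_breath.csv"))
  fTru <- file.path(dir, paste0(prefix, "_truth.json"))
  writeMovieTiff(trial@movie, fMov)
  writeBreathCsv(trial@breath, fBre)
  truth <- trial@truth
  truth$odorant <- trial@odorant
  truth$concentration_pct <- trial@concentrationPct
  truth$stimulus_onset_s <- trial@onsetS
  truth$frame_rate_hz <- frameRate(trial@movie)
  jsonlite::write_json(truth, fTru, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(fMov, fBre, fTru))
}

#' Write an activity map as 32-bit TIFF plus PNG render
#'
#' dF/F0 values are min-max scaled into `[0, 1]` for TIFF storage (the
#' TIFF writer stores only that range); the scale is recorded in a JSON
#' sidecar `<path>.json` together with the map's provenance, so
#' `original = lo + stored * (hi - lo)`.
#'
#' @param map an [ActivityMap].
#' @param path TIFF path; a PNG with a symmetric gray scale is written
#'   alongside when `png = TRUE`.
#' @param png write the PNG render.
#' @return files written, invisibly.
#' @export
writeActivityMap <- function(map, path, png = TRUE) {
  stopifnot(is(map, "ActivityMap"))
  v <- mapValues(map)
  lo <- min(v); hi <- max(v)
  enc <- if (hi > lo) (v - lo) / (hi - lo) else v * 0
  tiff::writeTIFF(enc, path, bits.per.sample = 32L, compression = "none")
  side <- paste0(path, ".json")
  jsonlite::write_json(
    list(lo = lo, hi = hi, odorant = map@odorant,
         concentration_pct = map@concentrationPct, n_trials = map@nTrials,
         view = map@view, flipped = map@flipped,
         anchor_frame = map@anchorFrame,
         response_frames = map@responseFrames,
         baseline_frames = map@baselineFrames),
    side, auto_unbox = TRUE, digits = NA)
  files <- c(path, side)
  if (png) {
    v <- mapValues(map)
    lim <- max(abs(v), 1e-9)
    pngPath <- sub("\\.tiff?$", ".png", path)
    if (pngPath == path) pngPath <- paste0(path, ".png")
    png::writePNG((v / lim + 1) / 2, pngPath)
    files <- c(files, pngPath)
  }
  invisible(files)
}
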