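#' Convert a duration to a frame count
#'
#' Windows in this pipeline are specified in seconds and realized as frame
#' counts via `round(seconds * rate)` (half away from zero).  At the native
#' 125 Hz acquisition rate, a 13 s trial is 1,625 frames, the 1.6 s response
#' window is 200 frames and the 1.0 s baseline window is 125 frames.
#'
#' @param seconds duration in seconds.
#' @param rateHz frame rate in Hz.
#' @return integer number of frames.
#' @examples
#' framesIn(13, 125)   # 1625
#' framesIn(1.6, 125)  # 200
#' @export
framesIn <- function(seconds, rateHz) {
  stopifnot(rateHz > 0)
  as.integer(roundHalfAway(seconds * rateHz))
}

#' Nominal odorant concentration under flow dilution
#'
#' Odorant vapour is produced by bubbling nitrogen through a liquid
#' dilution in mineral oil and then mixing 1 part odorous gas with 4 parts
#' carrier air (1:5 flow dilution).  The nominal concentration is therefore
#' the liquid dilution divided by the flow-dilution factor: a 1% liquid
#' dilution is reported as 0.2%.
#'
#' @param liquidDilutionPct liquid dilution, percent.
#' @param flowDilution flow-dilution factor (default 5).
#' @return nominal concentration, percent of saturated vapour.
#' @examples
#' nominalConcentration(1)   # 0.2
#' nominalConcentration(10)  # 2
#' @export
nominalConcentration <- function(liquidDilutionPct, flowDilution = 5) {
  stopifnot(flowDilution > 0, liquidDilutionPct >= 0)
  liquidDilutionPct / flowDilution
}

#' Prism placement geometry
#'
#' A right-angle prism with a mirror-coated hypotenuse replaces one
#' olfactory bulb and reflects the medial wall of the remaining bulb up
#' into the objective.  The in-prism light path lengthens the optical path,
#' so the focal plane for the medial view sits below the dorsal focal
#' plane; the prism top then protrudes above the dorsal surface by the
#' difference between the in-prism path length and the focal-plane offset
#' (1.5 mm path, 1 mm offset: 0.5 mm protrusion).
#'
#' @param prismPathMm light-path length inside the prism, mm (default 1.5,
#'   the prism edge length).
#' @param focalOffsetMm focal-plane offset between dorsal and medial views,
#'   mm (default 1.0).
#' @return list with `prism_path_mm`, `focal_offset_mm` and
#'   `top_above_surface_mm`.
#' @examples
#' prismGeometry()$top_above_surface_mm  # 0.5
#' @export
prismGeometry <- function(prismPathMm = 1.5, focalOffsetMm = 1.0) {
  stopifnot(prismPathMm > 0, focalOffsetMm >= 0, focalOffsetMm <= prismPathMm)
  list(prism_path_mm = prismPathMm,
       focal_offset_mm = focalOffsetMm,
       top_above_surface_mm = prismPathMm - focalOffsetMm)
}
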