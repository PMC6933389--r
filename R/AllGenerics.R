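#' @rdname Movie-class
#' @param x,object a `Movie`, `BreathTrace` or `ActivityMap`.
#' @export
setGeneric("movieData", function(x) standardGeneric("movieData"))

#' @rdname Movie-class
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @rdname Movie-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname Movie-class
#' @export
setGeneric("frameDim", function(x) standardGeneric("frameDim"))

#' @rdname BreathTrace-class
#' @param x a `BreathTrace`.
#' @export
setGeneric("inhalationOnsets", function(x) standardGeneric("inhalationOnsets"))

#' @rdname BreathTrace-class
#' @export
setGeneric("inhalationEnds", function(x) standardGeneric("inhalationEnds"))

#' @rdname ActivityMap-class
#' @param x an `ActivityMap` or `GlomerulusSet`.
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' @rdname GlomerulusSet-class
#' @export
setGeneric("rois", function(x) standardGeneric("rois"))

#' @rdname GlomerulusSet-class
#' @export
setGeneric("roiAmplitudes", function(x) standardGeneric("roiAmplitudes"))

#' Undo the dorso-ventral inversion of a through-prism map
#'
#' The mirror-coated prism presents the medial olfactory-bulb wall
#' dorso-ventrally inverted; `flipMedial` reverses the rows of a medial
#' activity map so the dorso-ventral axis matches the dorsal view.  The
#' flip is an involution; applying it to an already-flipped map warns
#' (double-flip guard) but still flips, so `flipMedial(flipMedial(m))`
#' recovers the original values.
#'
#' @param map an [ActivityMap] from the medial view.
#' @return the map with rows reversed and the `flipped` flag toggled.
#' @export
setGeneric("flipMedial", function(map) standardGeneric("flipMedial"))
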