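#' @import methods
NULL

.n3l_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "n3lband_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

#' SamplingSpec: sampling parameters of a discretely sampled recording
#'
#' Holds the repetition (sampling) interval and the number of samples of a
#' recording, from which every frequency-domain quantity used by the band
#' decoder is derived: the sampling rate, the DFT bin width, and the
#' detectable frequency limits given by the Nyquist-Shannon theorem.
#'
#' @slot trSeconds sampling interval in seconds (fMRI repetition time TR).
#' @slot nSamples number of samples (volumes/timepoints).
#' @export
setClass("SamplingSpec",
  representation(trSeconds = "numeric", nSamples = "integer"))

setValidity("SamplingSpec", function(object) {
  if (length(object@trSeconds) != 1L || !is.finite(object@trSeconds) ||
      object@trSeconds <= 0)
    return("trSeconds must be a single positive number")
  if (length(object@nSamples) != 1L || is.na(object@nSamples) ||
      object@nSamples < 2L)
    return("nSamples must be a single integer >= 2")
  TRUE
})

#' FrequencyBand: one natural-log-linear oscillator band on a DFT grid
#'
#' A band with integer centre index \eqn{n} on the natural-log frequency axis
#' spans \eqn{(e^{n-0.5}, e^{n+0.5})} Hz in theory; on a finite recording its
#' edges are snapped to DFT bins and possibly clipped to the detectable range.
#'
#' @slot centerIndex integer centre index n (band centre at e^n Hz).
#' @slot name conventional band name ("Slow-4", "Delta", ...).
#' @slot loBin,hiBin DFT bin indices of the snapped (possibly clipped) edges.
#' @slot deltaFHz DFT bin width of the grid the band lives on (Hz).
#' @slot truncatedLow,truncatedHigh whether an edge was clipped to the
#'   usable range (floor bin / Nyquist bin).
#' @export
setClass("FrequencyBand",
  representation(centerIndex = "integer", name = "character",
                 loBin = "integer", hiBin = "integer", deltaFHz = "numeric",
                 truncatedLow = "logical", truncatedHigh = "logical"))

setValidity("FrequencyBand", function(object) {
  if (object@loBin < 0L) return("loBin must be non-negative")
  if (object@loBin >= object@hiBin) return("loBin must be < hiBin")
  if (object@deltaFHz <= 0) return("deltaFHz must be positive")
  TRUE
})

#' BandSet: the ordered, contiguous bands decodable from one recording
#'
#' @slot spec the \linkS4class{SamplingSpec} the bands were derived from.
#' @slot bands list of \linkS4class{FrequencyBand}, ascending centre index.
#' @slot floorBin lowest usable DFT bin (minimum-cycles floor).
#' @export
setClass("BandSet",
  representation(spec = "SamplingSpec", bands = "list", floorBin = "integer"))

setValidity("BandSet", function(object) {
  b <- object@bands
  if (length(b) == 0L) return("empty band list")
  if (!all(vapply(b, is, logical(1), "FrequencyBand")))
    return("bands must all be FrequencyBand objects")
  n <- vapply(b, function(x) x@centerIndex, integer(1))
  if (is.unsorted(n, strictly = TRUE))
    return("bands must be in strictly ascending centre-index order")
  lo <- vapply(b, function(x) x@loBin, integer(1))
  hi <- vapply(b, function(x) x@hiBin, integer(1))
  if (length(b) > 1L && any(hi[-length(hi)] != lo[-1L]))
    return("adjacent bands must share an edge bin (contiguity)")
  nyq <- object@spec@nSamples %/% 2L
  if (lo[1L] != object@floorBin || hi[length(hi)] > nyq)
    return("band bins must span [floorBin, Nyquist bin]")
  TRUE
})

#' TimeSeriesMatrix: a units-by-timepoints data matrix with its sampling spec
#'
#' @slot values numeric matrix, rows = units (voxels/parcels/vertices or a
#'   single scalar trace), columns = timepoints.
#' @slot spec the \linkS4class{SamplingSpec} of the time axis.
#' @slot unitKind one of "voxel", "parcel", "vertex", "scalar-trace".
#' @export
setClass("TimeSeriesMatrix",
  representation(values = "matrix", spec = "SamplingSpec",
                 unitKind = "character"))

setValidity("TimeSeriesMatrix", function(object) {
  if (!is.numeric(object@values)) return("values must be numeric")
  if (ncol(object@values) != object@spec@nSamples)
    return(sprintf("timepoints (%d) must equal spec nSamples (%d)",
                   ncol(object@values), object@spec@nSamples))
  if (!object@unitKind %in% c("voxel", "parcel", "vertex", "scalar-trace"))
    return("unitKind must be voxel, parcel, vertex or scalar-trace")
  TRUE
})

#' DecodedSeries: per-band components of a decomposed time-series matrix
#'
#' Each component is a units-by-timepoints matrix holding the band-limited
#' part of the input; the residual holds everything the bands do not own
#' (the DC bin and sub-floor bins), so components + residual reconstruct
#' the input exactly up to floating-point error.
#'
#' @slot components named list of matrices, one per band.
#' @slot residual matrix of the unowned-bin content.
#' @slot bandSet the \linkS4class{BandSet} used for the decomposition.
#' @slot unitKind unit kind inherited from the input.
#' @export
setClass("DecodedSeries",
  representation(components = "list", residual = "matrix",
                 bandSet = "BandSet", unitKind = "character"))

#' MotionTrace: a six-parameter rigid-body head motion log
#'
#' @slot params numeric matrix, timepoints x 6: three translations (mm)
#'   then three rotations (degrees).
#' @slot spec the \linkS4class{SamplingSpec} of the recording.
#' @slot zeroIndex sample index (1-based) at which the parameters were zeroed.
#' @slot metadata free-form list (flags such as excludedShort).
#' @export
setClass("MotionTrace",
  representation(params = "matrix", spec = "SamplingSpec",
                 zeroIndex = "integer", metadata = "list"))

setValidity("MotionTrace", function(object) {
  if (ncol(object@params) != 6L)
    return("params must have 6 columns (3 translations mm, 3 rotations deg)")
  if (object@zeroIndex < 1L || object@zeroIndex > nrow(object@params))
    return("zeroIndex out of range")
  TRUE
})

#' ReliabilityTable: subject x occasion x parcel measurements for ICC
#'
#' @slot measurements 3-d numeric array, dim = (subjects, occasions, parcels).
#' @slot design "short_term" (two scans within a visit) or "long_term"
#'   (two visits months apart).
#' @export
setClass("ReliabilityTable",
  representation(measurements = "array", design = "character"))

setValidity("ReliabilityTable", function(object) {
  d <- dim(object@measurements)
  if (length(d) != 3L) return("measurements must be a 3-d array")
  if (d[1L] < 2L) return("need at least 2 subjects")
  if (d[2L] < 2L) return("need at least 2 occasions")
  if (!object@design %in% c("short_term", "long_term"))
    return("design must be short_term or long_term")
  TRUE
})
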