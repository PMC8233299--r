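#' Construct a sampling specification
#'
#' A recording is described by its sampling interval (the fMRI repetition
#' time, seconds per sample) and the number of samples. Either the interval
#' (`trSeconds`) or the rate (`fsHz = 1/trSeconds`) may be supplied. The
#' Nyquist-Shannon theorem fixes the detectable frequency range: the highest
#' detectable frequency is \eqn{f_{max} = 1/(2 T_R)} and the lowest, set by
#' the total sampling time \eqn{T = N T_R}, is \eqn{f_{min} = 1/(2 N T_R)}.
#'
#' @param trSeconds sampling interval in seconds (exclusive with `fsHz`).
#' @param nSamples number of samples, an integer >= 2.
#' @param fsHz sampling rate in Hz (exclusive with `trSeconds`).
#' @return a \linkS4class{SamplingSpec}.
#' @examples
#' samplingSpec(trSeconds = 0.72, nSamples = 1200)
#' samplingSpec(fsHz = 9.285, nSamples = 1672)
#' @export
samplingSpec <- function(trSeconds = NULL, nSamples, fsHz = NULL) {
  if (is.null(trSeconds) == is.null(fsHz))
    .n3l_stop("supply exactly one of trSeconds or fsHz",
              "n3lband_invalid_sampling")
  if (!is.null(fsHz)) {
    if (!is.numeric(fsHz) || length(fsHz) != 1L || !is.finite(fsHz) || fsHz <= 0)
      .n3l_stop("fsHz must be a single positive number",
                "n3lband_invalid_sampling")
    trSeconds <- 1 / fsHz
  }
  if (!is.numeric(trSeconds) || length(trSeconds) != 1L ||
      !is.finite(trSeconds) || trSeconds <= 0)
    .n3l_stop("trSeconds must be a single positive number",
              "n3lband_invalid_sampling")
  if (!is.numeric(nSamples) || length(nSamples) != 1L || is.na(nSamples) ||
      nSamples < 2 || nSamples != round(nSamples))
    .n3l_stop("nSamples must be a single integer >= 2",
              "n3lband_invalid_sampling")
  new("SamplingSpec", trSeconds = as.numeric(trSeconds),
      nSamples = as.integer(nSamples))
}

#' @rdname samplingSpec
#' @param x a SamplingSpec.
#' @export
setMethod("trSeconds", "SamplingSpec", function(x) x@trSeconds)
#' @rdname samplingSpec
#' @export
setMethod("nSamples", "SamplingSpec", function(x) x@nSamples)
#' @rdname samplingSpec
#' @export
setMethod("fsHz", "SamplingSpec", function(x) 1 / x@trSeconds)
#' @rdname samplingSpec
#' @export
setMethod("durationSeconds", "SamplingSpec",
          function(x) x@nSamples * x@trSeconds)
#' @rdname samplingSpec
#' @export
setMethod("deltaFHz", "SamplingSpec",
          function(x) 1 / (x@nSamples * x@trSeconds))

#' Detectable frequency range of a recording
#'
#' Returns the lowest and highest frequencies that the sampling parameters
#' can in principle resolve: \eqn{f_{min} = 1/(2 N T_R)} and
#' \eqn{f_{max} = 1/(2 T_R)}.
#'
#' @param spec a \linkS4class{SamplingSpec}.
#' @return named numeric vector `c(fMinHz =, fMaxHz =)`.
#' @examples
#' detectableRange(samplingSpec(trSeconds = 0.72, nSamples = 1200))
#' @export
detectableRange <- function(spec) {
  stopifnot(is(spec, "SamplingSpec"))
  c(fMinHz = 1 / (2 * spec@nSamples * spec@trSeconds),
    fMaxHz = 1 / (2 * spec@trSeconds))
}

## round half away from zero (base round() is half-to-even)
.round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Snap a frequency to the nearest DFT bin
#'
#' The DFT grid of an N-point recording has bins at \eqn{k \Delta f},
#' \eqn{\Delta f = 1/(N T_R)}. A continuous band edge is snapped to the
#' nearest bin index, rounding halves away from zero.
#'
#' @param freqHz frequency in Hz, within `[0, fs/2]`.
#' @param spec a \linkS4class{SamplingSpec}.
#' @return integer bin index.
#' @examples
#' snapEdgeToBin(exp(-4.5), samplingSpec(trSeconds = 0.72, nSamples = 1200))
#' @export
snapEdgeToBin <- function(freqHz, spec) {
  stopifnot(is(spec, "SamplingSpec"))
  if (!is.numeric(freqHz) || any(!is.finite(freqHz)) ||
      any(freqHz < 0) || any(freqHz > 1 / (2 * spec@trSeconds)))
    .n3l_stop("frequency outside [0, fs/2]", "n3lband_domain_error")
  as.integer(.round_half_away(freqHz * spec@nSamples * spec@trSeconds))
}

setMethod("show", "SamplingSpec", function(object) {
  r <- detectableRange(object)
  cat(sprintf(
    "SamplingSpec: TR = %g s (fs = %g Hz), N = %d\n  duration %g s, bin width %.6g Hz, detectable %.6g - %.6g Hz\n",
    object@trSeconds, 1 / object@trSeconds, object@nSamples,
    object@nSamples * object@trSeconds, deltaFHz(object),
    r[["fMinHz"]], r[["fMaxHz"]]))
})
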