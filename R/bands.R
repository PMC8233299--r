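#' Conventional name of the band centred at e^n Hz
#'
#' Bands on the natural-log frequency axis are named by the electrophysiology
#' convention: the band centred at 1 Hz (n = 0) is Slow-1, bands below it are
#' Slow-2, Slow-3, ... (down to Slow-9 at n = -8), n = 1 is Delta and n = 2
#' is Theta. Outside that range the generic label `OSC(n)` is used rather
#' than guessing Greek names.
#'
#' @param centerIndex integer centre index (vectorised).
#' @return character vector of band names.
#' @examples
#' bandName(-3)  # "Slow-4"
#' bandName(1)   # "Delta"
#' @export
bandName <- function(centerIndex) {
  stopifnot(is.numeric(centerIndex), all(centerIndex == round(centerIndex)))
  n <- as.integer(centerIndex)
  out <- sprintf("OSC(%d)", n)
  slow <- n <= 0L & n >= -8L
  out[slow] <- sprintf("Slow-%d", 1L - n[slow])
  out[n == 1L] <- "Delta"
  out[n == 2L] <- "Theta"
  out
}

## bin index of the theoretical upper edge of band n on the grid of `spec`
.edge_bin <- function(n, spec) {
  as.integer(.round_half_away(exp(n + 0.5) * spec@nSamples * spec@trSeconds))
}

#' Enumerate the natural-log bands decodable from a recording
#'
#' Applies the natural-log-linear band law to the DFT grid of a recording:
#' each band has an integer centre index \eqn{n} (centre \eqn{e^n} Hz) and
#' theoretical edges \eqn{e^{n \pm 0.5}} Hz. Edges are snapped to the nearest
#' DFT bin (`round(e^{n+0.5} N T_R)`), and the usable grid is clipped to
#' `[minCycles, floor(N/2)]`: the ceiling is the Nyquist bin, and the floor
#' requires at least `minCycles` full cycles of an oscillation within the
#' record before the band is considered resolvable. Bands that fall entirely
#' outside the usable grid are dropped; partially clipped bands are kept and
#' flagged truncated.
#'
#' @param spec a \linkS4class{SamplingSpec}.
#' @param minCycles usable floor bin, i.e. minimum number of full cycles per
#'   record (default 6).
#' @return a \linkS4class{BandSet}.
#' @examples
#' enumerateBands(samplingSpec(fsHz = 9.285, nSamples = 1672))
#' @export
enumerateBands <- function(spec, minCycles = 6L) {
  stopifnot(is(spec, "SamplingSpec"))
  if (!is.numeric(minCycles) || length(minCycles) != 1L || minCycles < 1)
    .n3l_stop("minCycles must be a positive integer", "n3lband_domain_error")
  floorBin <- as.integer(minCycles)
  ceilBin <- spec@nSamples %/% 2L
  if (floorBin >= ceilBin)
    .n3l_stop(sprintf(
      "no decodable band: floor bin %d >= Nyquist bin %d (recording too short or too slow)",
      floorBin, ceilBin), "n3lband_no_band_error")
  df <- deltaFHz(spec)
  nLo <- floor(log(floorBin * df)) - 1L
  nHi <- ceiling(log(ceilBin * df)) + 1L
  bands <- list()
  for (n in seq(nLo, nHi)) {
    kLo <- .edge_bin(n - 1L, spec)
    kHi <- .edge_bin(n, spec)
    lo <- max(kLo, floorBin)
    hi <- min(kHi, ceilBin)
    if (lo >= hi) next
    bands[[length(bands) + 1L]] <- new("FrequencyBand",
      centerIndex = as.integer(n), name = bandName(n),
      loBin = lo, hiBin = hi, deltaFHz = df,
      truncatedLow = kLo < floorBin, truncatedHigh = kHi > ceilBin)
  }
  if (length(bands) == 0L)
    .n3l_stop("no decodable band for this sampling specification",
              "n3lband_no_band_error")
  new("BandSet", spec = spec, bands = bands, floorBin = floorBin)
}

#' Accessors for FrequencyBand and BandSet objects
#'
#' `loHz`/`hiHz` give the grid-snapped edges (bin index times bin width);
#' `loTheoreticalHz`/`hiTheoreticalHz` the continuous edges
#' \eqn{e^{n \mp 0.5}}; `widthRatio` the snapped width relative to the
#' theoretical width, used to flag heavily clipped bands.
#'
#' @param x a \linkS4class{FrequencyBand} or \linkS4class{BandSet}.
#' @name bandAccessors
NULL

#' @rdname bandAccessors
#' @export
setMethod("loHz", "FrequencyBand", function(x) x@loBin * x@deltaFHz)
#' @rdname bandAccessors
#' @export
setMethod("hiHz", "FrequencyBand", function(x) x@hiBin * x@deltaFHz)
#' @rdname bandAccessors
#' @export
setMethod("centerIndex", "FrequencyBand", function(x) x@centerIndex)

#' @rdname bandAccessors
#' @export
loTheoreticalHz <- function(x) exp(centerIndex(x) - 0.5)
#' @rdname bandAccessors
#' @export
hiTheoreticalHz <- function(x) exp(centerIndex(x) + 0.5)

#' @rdname bandAccessors
#' @export
setMethod("widthRatio", "FrequencyBand", function(x)
  (hiHz(x) - loHz(x)) / (hiTheoreticalHz(x) - loTheoreticalHz(x)))

setMethod("show", "FrequencyBand", function(object) {
  cat(sprintf("%s (n = %d): %.3f - %.3f Hz [bins %d-%d]%s%s\n",
    object@name, object@centerIndex, loHz(object), hiHz(object),
    object@loBin, object@hiBin,
    if (object@truncatedLow) " trunc-lo" else "",
    if (object@truncatedHigh) " trunc-hi" else ""))
})

#' @rdname bandAccessors
#' @export
setMethod("length", "BandSet", function(x) length(x@bands))
#' @rdname bandAccessors
#' @export
setMethod("bandNames", "BandSet",
          function(x) vapply(x@bands, function(b) b@name, character(1)))
#' @rdname bandAccessors
#' @param i band index or name.
#' @export
setMethod("[[", "BandSet", function(x, i) {
  if (is.character(i)) i <- match(i, bandNames(x))
  if (is.na(i) || i < 1L || i > length(x@bands))
    .n3l_stop("no such band", "n3lband_domain_error")
  x@bands[[i]]
})

#' @rdname samplingSpec
#' @export
samplingOf <- function(x) {
  stopifnot(is(x, "BandSet") || is(x, "TimeSeriesMatrix") ||
            is(x, "MotionTrace"))
  x@spec
}

## 0-based DFT bins owned by band i: [loBin, hiBin), and the highest band
## also owns its final (Nyquist-side) bin so the bands partition the grid.
.owned_bins <- function(bandset, i) {
  b <- bandset@bands[[i]]
  if (i == length(bandset@bands)) b@loBin:b@hiBin else b@loBin:(b@hiBin - 1L)
}

setMethod("show", "BandSet", function(object) {
  cat(sprintf("BandSet: %d band(s) on N = %d, TR = %g s (floor bin %d)\n",
              length(object@bands), object@spec@nSamples,
              object@spec@trSeconds, object@floorBin))
  for (b in object@bands) show(b)
})

#' Tabulate a band set
#'
#' One row per band, ascending frequency, with snapped and theoretical
#' edges, bin indices, truncation flags and the width ratio.
#'
#' @param x a \linkS4class{BandSet}.
#' @param ... unused.
#' @return a data.frame.
#' @export
setMethod("bandTable", "BandSet", function(x, ...) {
  b <- x@bands
  data.frame(
    band_name = vapply(b, function(z) z@name, character(1)),
    center_index = vapply(b, function(z) z@centerIndex, integer(1)),
    lo_hz = vapply(b, loHz, numeric(1)),
    hi_hz = vapply(b, hiHz, numeric(1)),
    lo_bin = vapply(b, function(z) z@loBin, integer(1)),
    hi_bin = vapply(b, function(z) z@hiBin, integer(1)),
    truncated_low = vapply(b, function(z) z@truncatedLow, logical(1)),
    truncated_high = vapply(b, function(z) z@truncatedHigh, logical(1)),
    width_ratio = vapply(b, widthRatio, numeric(1)),
    stringsAsFactors = FALSE)
})

#' Write band boundaries to CSV / JSON
#'
#' `writeBoundariesCsv` records the boundary frequencies of each decoded
#' band (full precision); `writeBandsJson` emits the same table plus the
#' sampling parameters as JSON for machine use.
#'
#' @param bandset a nonempty \linkS4class{BandSet}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeBoundariesCsv <- function(bandset, path) {
  stopifnot(is(bandset, "BandSet"))
  if (length(bandset) == 0L)
    .n3l_stop("empty band set", "n3lband_domain_error")
  tab <- bandTable(bandset)
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2L) != 0L)
    .n3l_stop(sprintf("cannot write to '%s'", path), "n3lband_io_error")
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeBoundariesCsv
#' @export
writeBandsJson <- function(bandset, path) {
  stopifnot(is(bandset, "BandSet"))
  obj <- list(
    sampling = list(tr_seconds = trSeconds(bandset@spec),
                    fs_hz = fsHz(bandset@spec),
                    n_samples = nSamples(bandset@spec),
                    delta_f_hz = deltaFHz(bandset@spec),
                    floor_bin = bandset@floorBin),
    bands = bandTable(bandset))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
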