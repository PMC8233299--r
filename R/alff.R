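#' Band-limited amplitude of low-frequency fluctuation per parcel
#'
#' For each unit (parcel), the single-sided amplitude spectrum
#' \eqn{(2/N) |X_k|} is averaged over the DFT bins owned by the requested
#' band. The mean (rather than the sum) makes truncated bands comparable
#' with full-width ones; set `summary = "sum"` for the summed-amplitude
#' convention.
#'
#' @param ts a \linkS4class{TimeSeriesMatrix}.
#' @param bandset the \linkS4class{BandSet} of the recording (bin ownership
#'   depends on the band's position in the set).
#' @param band band name or index within `bandset`.
#' @param summary "mean" (default) or "sum" over the band's bins.
#' @return non-negative numeric vector, one ALFF value per unit.
#' @export
parcelAlff <- function(ts, bandset, band, summary = c("mean", "sum")) {
  summary <- match.arg(summary)
  stopifnot(is(ts, "TimeSeriesMatrix"), is(bandset, "BandSet"))
  if (!.same_spec(ts@spec, bandset@spec))
    .n3l_stop("sampling spec of the series does not match the band set",
              "n3lband_data_error")
  i <- if (is.character(band)) match(band, bandNames(bandset)) else band
  if (is.na(i) || i < 1L || i > length(bandset))
    .n3l_stop("no such band in the band set", "n3lband_domain_error")
  bins <- .owned_bins(bandset, i)
  if (length(bins) == 0L)
    .n3l_stop("band owns no bins", "n3lband_domain_error")
  N <- ncol(ts@values)
  X <- stats::mvfft(t(ts@values))           # N x units
  amp <- (2 / N) * Mod(X[bins + 1L, , drop = FALSE])
  if (summary == "mean") colMeans(amp) else colSums(amp)
}

#' Z-standardise a parcel map
#'
#' Subtracts the mean over parcels and divides by the standard deviation,
#' yielding a map with mean 0 and SD 1 (the subject-level Z-score map).
#'
#' @param map numeric vector over parcels (length >= 2).
#' @return standardised map.
#' @export
standardizeMap <- function(map) {
  if (!is.numeric(map) || length(map) < 2L)
    .n3l_stop("need a numeric map over at least 2 parcels",
              "n3lband_data_error")
  s <- stats::sd(map)
  if (!is.finite(s) || s == 0)
    .n3l_stop("zero or undefined map SD; cannot standardise",
              "n3lband_data_error")
  (map - mean(map)) / s
}

#' Average parcel maps within groups
#'
#' Elementwise means of maps sharing a group label (scans within a session,
#' sessions within a visit, visits within the dataset). Groups missing
#' members relative to `expectedSize` are dropped with a warning (e.g. a
#' subject lacking one scan of a test-retest pair).
#'
#' @param maps list of equal-length numeric vectors.
#' @param groups factor or character vector, one label per map; NULL
#'   averages everything into one map.
#' @param expectedSize required members per group (NULL = no check).
#' @return named list of group-mean maps.
#' @export
averageMaps <- function(maps, groups = NULL, expectedSize = NULL) {
  stopifnot(is.list(maps), length(maps) > 0L)
  len <- unique(vapply(maps, length, integer(1)))
  if (length(len) != 1L)
    .n3l_stop("maps must all have the same length", "n3lband_data_error")
  if (is.null(groups)) groups <- rep("all", length(maps))
  if (length(groups) != length(maps))
    .n3l_stop("one group label per map required", "n3lband_data_error")
  out <- list()
  for (g in unique(as.character(groups))) {
    members <- maps[as.character(groups) == g]
    if (!is.null(expectedSize) && length(members) < expectedSize) {
      warning(sprintf("group '%s' has %d of %d expected maps; dropped",
                      g, length(members), expectedSize))
      next
    }
    out[[g]] <- Reduce(`+`, members) / length(members)
  }
  out
}

#' Ordinal rank map of parcel values
#'
#' Assigns ranks 1..P ascending in value (rank 1 = lowest value); ties are
#' broken by parcel index (lower index first), so the result is always a
#' permutation of 1..P.
#'
#' @param map numeric vector over parcels.
#' @return integer rank map.
#' @export
rankMap <- function(map) {
  stopifnot(is.numeric(map), all(is.finite(map)))
  as.integer(rank(map, ties.method = "first"))
}

## classical one-way ICC(1) from the balanced ANOVA decomposition
.icc_anova_one <- function(y, subject) {
  m <- tapply(y, subject, mean)
  k <- length(y) / length(m)
  grand <- mean(y)
  bms <- k * sum((m - grand)^2) / (length(m) - 1L)
  wms <- sum((y - m[subject])^2) / (length(m) * (k - 1L))
  (bms - wms) / (bms + (k - 1) * wms)
}

.icc_reml_one <- function(y, subject, occasion, model) {
  d <- data.frame(y = y, subject = subject, occasion = occasion)
  fit <- suppressMessages(suppressWarnings(
    if (model == "twoway")
      lme4::lmer(y ~ occasion + (1 | subject), data = d, REML = TRUE)
    else
      lme4::lmer(y ~ 1 + (1 | subject), data = d, REML = TRUE)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  sb2 <- vc$vcov[vc$grp == "subject"]
  se2 <- vc$vcov[vc$grp == "Residual"]
  sb2 / (sb2 + se2)
}

#' Parcel-wise intraclass correlation from a reliability table
#'
#' Per parcel, a subject-random-intercept linear mixed model is fitted by
#' restricted maximum likelihood and the ICC is the between-subject
#' variance over the total: \eqn{\sigma_b^2 / (\sigma_b^2 + \sigma_e^2)}.
#' Variance components are non-negative by the mixed-model
#' parameterisation, so ICC lies in `[0, 1]`. `model = "twoway"` adds a
#' fixed occasion effect (the consistency two-way variant);
#' `method = "anova"` uses the classical one-way ANOVA estimator
#' \eqn{(BMS - WMS)/(BMS + (k-1) WMS)} instead (clamped to `[0, 1]`),
#' useful as a closed-form cross-check.
#'
#' Degenerate parcels with zero total variance yield NA.
#'
#' @param table a \linkS4class{ReliabilityTable}.
#' @param method "reml" (default) or "anova".
#' @param model "oneway" (default) or "twoway" (fixed occasion effect).
#' @return numeric ICC vector over parcels.
#' @export
parcelIcc <- function(table, method = c("reml", "anova"),
                      model = c("oneway", "twoway")) {
  method <- match.arg(method); model <- match.arg(model)
  stopifnot(is(table, "ReliabilityTable"))
  m <- table@measurements
  d <- dim(m)
  subject <- factor(rep(seq_len(d[1L]), d[2L]))
  occasion <- factor(rep(seq_len(d[2L]), each = d[1L]))
  vapply(seq_len(d[3L]), function(p) {
    y <- as.vector(m[, , p])
    ok <- is.finite(y)
    if (sum(ok) < 4L || stats::var(y[ok]) == 0) return(NA_real_)
    icc <- if (method == "anova")
      .icc_anova_one(y[ok], droplevels(subject[ok]))
    else
      .icc_reml_one(y[ok], subject[ok], occasion[ok], model)
    min(max(icc, 0), 1)
  }, numeric(1))
}

#' Construct a reliability table
#'
#' @param measurements numeric array, subjects x occasions x parcels.
#' @param design "short_term" or "long_term".
#' @return a \linkS4class{ReliabilityTable}.
#' @export
reliabilityTable <- function(measurements,
                             design = c("short_term", "long_term")) {
  design <- match.arg(design)
  new("ReliabilityTable", measurements = measurements, design = design)
}

setMethod("show", "ReliabilityTable", function(object) {
  d <- dim(object@measurements)
  cat(sprintf("ReliabilityTable (%s): %d subjects x %d occasions x %d parcels\n",
              object@design, d[1L], d[2L], d[3L]))
})
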