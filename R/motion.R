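#' Construct a six-parameter motion trace
#'
#' @param translations numeric matrix or data.frame, timepoints x 3, mm.
#' @param rotations numeric matrix or data.frame, timepoints x 3, degrees.
#' @param spec a \linkS4class{SamplingSpec}.
#' @param zeroIndex 1-based index of the sample at which the parameters were
#'   zeroed (calibration reset).
#' @return a \linkS4class{MotionTrace}.
#' @export
motionTrace <- function(translations, rotations, spec, zeroIndex = 1L) {
  tm <- as.matrix(translations); rm_ <- as.matrix(rotations)
  if (ncol(tm) != 3L || ncol(rm_) != 3L || nrow(tm) != nrow(rm_))
    .n3l_stop("need 3 translation and 3 rotation series of equal length",
              "n3lband_data_error")
  p <- cbind(tm, rm_)
  storage.mode(p) <- "double"
  colnames(p) <- c("tx_mm", "ty_mm", "tz_mm", "rx_deg", "ry_deg", "rz_deg")
  new("MotionTrace", params = p, spec = spec,
      zeroIndex = as.integer(zeroIndex), metadata = list())
}

setMethod("show", "MotionTrace", function(object) {
  cat(sprintf("MotionTrace: %d samples at %g Hz (zeroed at %d)%s\n",
              nrow(object@params), 1 / object@spec@trSeconds,
              object@zeroIndex,
              if (isTRUE(object@metadata$excludedShort)) " [excluded: short]"
              else ""))
})

#' Framewise displacement from six rigid-body parameters
#'
#' The Power convention: per frame, the sum of the absolute frame-to-frame
#' changes of the three translations (mm) plus the three rotation changes
#' converted from degrees to arc length on a reference sphere
#' (radius x angle in radians). The first sample, having no predecessor, is
#' defined as 0.
#'
#' @param trace a \linkS4class{MotionTrace} with at least 2 samples.
#' @param sphereRadiusMm reference sphere radius in mm (default 50).
#' @return numeric FD series (mm), same length as the trace.
#' @examples
#' spec <- samplingSpec(fsHz = 10, nSamples = 5)
#' tr <- motionTrace(cbind(c(0, 1, 1, 1, 1), 0, 0), matrix(0, 5, 3), spec)
#' fdFromParams(tr)  # 0 1 0 0 0
#' @export
fdFromParams <- function(trace, sphereRadiusMm = 50) {
  stopifnot(is(trace, "MotionTrace"))
  p <- trace@params
  if (nrow(p) < 2L)
    .n3l_stop("need at least 2 samples to form displacements",
              "n3lband_data_error")
  dt <- abs(diff(p[, 1:3, drop = FALSE]))
  dr <- abs(diff(p[, 4:6, drop = FALSE])) * pi / 180
  c(0, rowSums(dt) + sphereRadiusMm * rowSums(dr))
}

#' Remove spikes from a series with a running-median/MAD rule
#'
#' A robust spike suppressor: the trend is the running median over `window`
#' samples; samples whose residual from the trend exceeds `thresholdMads`
#' robust scale units are replaced by the trend value. The scale is
#' estimated as `mad(diff(x)) / sqrt(2)`, which tracks the sample-to-sample
#' noise while staying insensitive both to the slow trend and to the spikes
#' themselves. All other samples are returned unchanged, so the operator is
#' idempotent on spike-free data. Constant (zero-scale) series are returned
#' unchanged.
#'
#' This is a self-contained robust operator in the spirit of interpolation-
#' based despiking tools, with the detection threshold and trend window
#' exposed as parameters.
#'
#' @param x numeric series, longer than `window`.
#' @param thresholdMads detection threshold in robust (MAD) units (default 5).
#' @param window running-median window, odd (default 11).
#' @return despiked series.
#' @export
despikeSeries <- function(x, thresholdMads = 5, window = 11L) {
  stopifnot(is.numeric(x))
  if (length(x) <= window)
    .n3l_stop("series must be longer than the despike window",
              "n3lband_data_error")
  trend <- stats::runmed(x, k = window, endrule = "median")
  resid <- x - trend
  s <- stats::mad(diff(x)) / sqrt(2)
  if (s == 0) return(x)
  spikes <- abs(resid) > thresholdMads * s
  x[spikes] <- trend[spikes]
  x
}

#' Retain a fixed window of samples from the zeroed time point
#'
#' Keeps exactly `nKeep` samples starting at the trace's zero index. Traces
#' with fewer samples available are not truncated to failure: the available
#' window is kept and the trace is flagged `excludedShort` in its metadata
#' so cohort assembly can drop it (recordings shorter than the analysis
#' window).
#'
#' @param trace a \linkS4class{MotionTrace}.
#' @param nKeep samples to keep (default 1672, three minutes at 9.285 Hz).
#' @return a windowed \linkS4class{MotionTrace}.
#' @export
windowFromZero <- function(trace, nKeep = 1672L) {
  stopifnot(is(trace, "MotionTrace"))
  avail <- nrow(trace@params) - trace@zeroIndex + 1L
  short <- avail < nKeep
  take <- trace@zeroIndex + seq_len(min(nKeep, avail)) - 1L
  p <- trace@params[take, , drop = FALSE]
  out <- new("MotionTrace", params = p,
             spec = samplingSpec(trSeconds = trSeconds(trace@spec),
                                 nSamples = nrow(p)),
             zeroIndex = 1L,
             metadata = utils::modifyList(trace@metadata,
                                          list(excludedShort = short)))
  out
}

#' Per-band mean absolute value and standard deviation of a decoded FD trace
#'
#' Band components of the (all-positive) FD series are demeaned by
#' construction, so the band-wise motion magnitude is summarised as the mean
#' of the absolute component and its stability as the component's standard
#' deviation.
#'
#' @param decoded a \linkS4class{DecodedSeries} of a scalar FD trace.
#' @return data.frame with columns band, mean_abs_fd, sd_fd.
#' @export
bandSummaries <- function(decoded) {
  stopifnot(is(decoded, "DecodedSeries"))
  bands <- names(decoded@components)
  data.frame(
    band = bands,
    mean_abs_fd = vapply(decoded@components,
                         function(m) mean(abs(m[1L, ])), numeric(1)),
    sd_fd = vapply(decoded@components,
                   function(m) stats::sd(m[1L, ]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Band names wide enough for analysis
#'
#' Bands clipped to less than `minWidthRatio` of their theoretical width
#' (typically the highest, Nyquist-truncated band) are too narrow relative
#' to their full range to support band-wise statistics.
#'
#' @param bandset a \linkS4class{BandSet}.
#' @param minWidthRatio minimum observed/theoretical width (default 0.1).
#' @return character vector of retained band names.
#' @export
analysisBands <- function(bandset, minWidthRatio = 0.1) {
  tab <- bandTable(bandset)
  tab$band_name[tab$width_ratio >= minWidthRatio]
}

#' Assemble a motion cohort table
#'
#' Runs the per-subject motion pipeline: window from the zeroed time point,
#' convert to framewise displacement, despike, decompose into the shared
#' band set, and summarise each band. Subjects whose recording is shorter
#' than the window are flagged `excluded_short` (their band columns are NA).
#'
#' @param traces named list of \linkS4class{MotionTrace} objects.
#' @param info data.frame with columns id, age (years), sex, one row per
#'   trace (matched by id = names(traces)).
#' @param nKeep analysis window length in samples (default 1672).
#' @param minCycles band-floor parameter passed to
#'   \code{\link{enumerateBands}}.
#' @param despike apply \code{\link{despikeSeries}} to the FD trace.
#' @param sphereRadiusMm FD rotation sphere radius (default 50 mm).
#' @param thresholdMads,window despike parameters.
#' @return a cohort data.frame (one row per subject) with full-band mean FD
#'   (`mean_fd`), per-band columns `meanFD_<band>` / `sdFD_<band>`, and
#'   exclusion flags; the shared \linkS4class{BandSet} is attached as
#'   attribute "bandSet".
#' @export
motionCohortTable <- function(traces, info, nKeep = 1672L, minCycles = 6L,
                              despike = TRUE, sphereRadiusMm = 50,
                              thresholdMads = 5, window = 11L) {
  stopifnot(is.list(traces), all(c("id", "age", "sex") %in% names(info)))
  ids <- names(traces)
  if (is.null(ids) || !all(ids %in% info$id))
    .n3l_stop("traces must be named by subject id, all present in info",
              "n3lband_data_error")
  bandset <- NULL
  rows <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    id <- ids[[j]]
    meta <- info[match(id, info$id), ]
    w <- windowFromZero(traces[[id]], nKeep = nKeep)
    row <- data.frame(id = id, age = meta$age, sex = as.character(meta$sex),
                      excluded_short = isTRUE(w@metadata$excludedShort),
                      excluded_outlier = FALSE, mean_fd = NA_real_,
                      stringsAsFactors = FALSE)
    if (!row$excluded_short) {
      fd <- fdFromParams(w, sphereRadiusMm = sphereRadiusMm)
      if (despike) fd <- despikeSeries(fd, thresholdMads = thresholdMads,
                                       window = window)
      if (is.null(bandset)) bandset <- enumerateBands(w@spec, minCycles)
      dec <- decomposeBands(timeSeriesMatrix(fd, w@spec,
                                             unitKind = "scalar-trace"),
                            bandset, strategy = "whole")
      s <- bandSummaries(dec)
      row$mean_fd <- mean(fd)
      row[paste0("meanFD_", s$band)] <- as.list(s$mean_abs_fd)
      row[paste0("sdFD_", s$band)] <- as.list(s$sd_fd)
    }
    rows[[j]] <- row
  }
  cohort <- do.call(rbind, lapply(rows, function(r) {
    missing <- setdiff(names(rows[[which.max(vapply(rows, ncol, 0L))]]),
                       names(r))
    r[missing] <- NA_real_
    r
  }))
  rownames(cohort) <- NULL
  attr(cohort, "bandSet") <- bandset
  cohort
}

#' Flag high-motion outliers in a cohort
#'
#' One-pass rule: subjects whose full-band mean FD exceeds the group mean
#' plus `kSd` group standard deviations are flagged `excluded_outlier`.
#' The group statistics are computed once over all non-short subjects
#' (no re-computation after removal).
#'
#' @param cohort a cohort data.frame from \code{\link{motionCohortTable}}.
#' @param kSd number of standard deviations (default 3).
#' @return the cohort with the `excluded_outlier` flag updated.
#' @export
excludeOutliers <- function(cohort, kSd = 3) {
  use <- !cohort$excluded_short
  if (sum(use) < 3L)
    .n3l_stop("need at least 3 non-short subjects", "n3lband_data_error")
  m <- mean(cohort$mean_fd[use]); s <- stats::sd(cohort$mean_fd[use])
  cohort$excluded_outlier <- use & cohort$mean_fd > m + kSd * s
  cohort
}

.cohort_subset <- function(cohort, band, sex = NULL, measure = "mean") {
  col <- paste0(if (measure == "mean") "meanFD_" else "sdFD_", band)
  if (!col %in% names(cohort))
    .n3l_stop(sprintf("no band column '%s' in cohort", col),
              "n3lband_data_error")
  d <- cohort[!cohort$excluded_short & !cohort$excluded_outlier, ]
  if (!is.null(sex)) d <- d[d$sex == sex, ]
  data.frame(id = d$id, age = d$age, sex = d$sex, y = d[[col]],
             stringsAsFactors = FALSE)
}

#' Exponential age model of band-wise head motion
#'
#' Fits the growth model \eqn{y = e^{a \cdot age + b}} by ordinary least
#' squares of \eqn{\ln y} on age within one sex stratum, where y is the
#' band's mean absolute FD (or its SD with `measure = "sd"`).
#'
#' @param cohort a cohort data.frame.
#' @param band band name (e.g. "Slow-4").
#' @param sex stratum label as used in the cohort's `sex` column.
#' @param measure "mean" (mean absolute FD) or "sd" (FD stability).
#' @return list with slope `a`, intercept `b`, `r_squared`, `p` (slope
#'   t-test), `df` (residual), and the underlying `lm` fit.
#' @export
logLinearAgeFit <- function(cohort, band, sex, measure = c("mean", "sd")) {
  measure <- match.arg(measure)
  d <- .cohort_subset(cohort, band, sex, measure)
  if (nrow(d) < 3L)
    .n3l_stop("need at least 3 subjects in the stratum", "n3lband_data_error")
  if (any(d$y <= 0))
    .n3l_stop("non-positive FD summary; cannot log-transform",
              "n3lband_data_error")
  fit <- stats::lm(log(y) ~ age, data = d)
  sm <- summary(fit)
  list(a = unname(stats::coef(fit)[["age"]]),
       b = unname(stats::coef(fit)[["(Intercept)"]]),
       r_squared = sm$r.squared,
       p = sm$coefficients["age", "Pr(>|t|)"],
       df = fit$df.residual,
       fit = fit)
}

#' Test equality of the male and female age lines
#'
#' On the log scale, tests (i) slope equality via the age-by-sex interaction
#' F test and (ii), under a common slope, intercept equality via the sex
#' main-effect F test — the classical ANCOVA decomposition.
#'
#' @param cohort a cohort data.frame.
#' @param band band name.
#' @param measure "mean" or "sd".
#' @return list with `F_slope`, `p_slope`, `df_slope`, `F_intercept`,
#'   `p_intercept`, `df_intercept` (dfs are `c(numerator, denominator)`).
#' @export
compareSexLines <- function(cohort, band, measure = c("mean", "sd")) {
  measure <- match.arg(measure)
  d <- .cohort_subset(cohort, band, NULL, measure)
  if (length(unique(d$sex)) != 2L)
    .n3l_stop("need exactly two sex strata", "n3lband_data_error")
  if (any(d$y <= 0))
    .n3l_stop("non-positive FD summary; cannot log-transform",
              "n3lband_data_error")
  d$ly <- log(d$y)
  full <- stats::lm(ly ~ age * sex, data = d)
  if (any(!is.finite(stats::coef(full))))
    .n3l_stop("singular design in sex-line comparison", "n3lband_data_error")
  common <- stats::lm(ly ~ age + sex, data = d)
  ageOnly <- stats::lm(ly ~ age, data = d)
  aSlope <- stats::anova(common, full)
  aInt <- stats::anova(ageOnly, common)
  list(F_slope = aSlope$F[2L], p_slope = aSlope$`Pr(>F)`[2L],
       df_slope = as.integer(c(aSlope$Df[2L], full$df.residual)),
       F_intercept = aInt$F[2L], p_intercept = aInt$`Pr(>F)`[2L],
       df_intercept = as.integer(c(aInt$Df[2L], common$df.residual)))
}

#' Two-way repeated-measures ANOVA of band-wise motion by sex
#'
#' Within each age group, a two-way ANOVA with frequency band as the
#' within-subject (repeated) factor and sex as the between-subject factor,
#' on the band-wise mean absolute FD. Reports the band main effect and the
#' sex-by-band interaction from the within-subject stratum.
#'
#' @param cohort a cohort data.frame.
#' @param bands character vector of band names to use as the repeated factor
#'   (at least 2).
#' @param ageGroups named list of `c(lo, hi)` age ranges (inclusive);
#'   default the three child groups 3-6, 7-9 and 10-16 years.
#' @return data.frame, one row per age group, with F and p for the band
#'   main effect and the sex:band interaction.
#' @export
repeatedMeasuresAnova <- function(cohort, bands,
                                  ageGroups = list(`3-6` = c(3, 6),
                                                   `7-9` = c(7, 9),
                                                   `10-16` = c(10, 16))) {
  if (length(bands) < 2L)
    .n3l_stop("need at least two bands as the repeated factor",
              "n3lband_data_error")
  keep <- !cohort$excluded_short & !cohort$excluded_outlier
  out <- list()
  for (g in names(ageGroups)) {
    rng <- ageGroups[[g]]
    d <- cohort[keep & cohort$age >= rng[1L] & cohort$age <= rng[2L], ]
    if (any(table(d$sex) < 2L) || length(unique(d$sex)) != 2L)
      .n3l_stop(sprintf("age group %s: need >= 2 subjects per sex", g),
                "n3lband_data_error")
    long <- do.call(rbind, lapply(bands, function(b) {
      data.frame(id = d$id, sex = d$sex, band = b,
                 value = d[[paste0("meanFD_", b)]],
                 stringsAsFactors = FALSE)
    }))
    long$id <- factor(long$id); long$sex <- factor(long$sex)
    long$band <- factor(long$band, levels = bands)
    fit <- stats::aov(value ~ sex * band + Error(id / band), data = long)
    s <- summary(fit)
    within <- s[[grep("id:band", names(s))]][[1L]]
    rn <- trimws(rownames(within))
    out[[g]] <- data.frame(
      age_group = g,
      n = nrow(d),
      F_band = within[rn == "band", "F value"],
      p_band = within[rn == "band", "Pr(>F)"],
      F_interaction = within[rn == "sex:band", "F value"],
      p_interaction = within[rn == "sex:band", "Pr(>F)"],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR adjustment of a vector of p-values; inputs are validated to
#' lie in `[0, 1]`.
#'
#' @param pvalues numeric vector of p-values.
#' @return adjusted p-values in the input order.
#' @export
fdrAdjust <- function(pvalues) {
  if (!is.numeric(pvalues) || any(!is.finite(pvalues)) ||
      any(pvalues < 0 | pvalues > 1))
    .n3l_stop("p-values must be numeric in [0, 1]", "n3lband_data_error")
  stats::p.adjust(pvalues, method = "BH")
}
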