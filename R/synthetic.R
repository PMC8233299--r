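#' Generate band-limited oscillatory signals with known ground truth
#'
#' Sums one sinusoid per requested band, placed at the bin nearest the
#' band's centre frequency \eqn{e^n} (clamped into the band's owned bin
#' range, so edge-bin ownership never blurs the ground truth), plus white
#' Gaussian noise. Phases are drawn uniformly per unit and band. Each
#' sinusoid of amplitude A contributes variance \eqn{A^2/2}.
#'
#' @param spec a \linkS4class{SamplingSpec}.
#' @param amplitudes named numeric vector: band name -> sinusoid amplitude.
#'   Names must be bands of the enumerated set; an amplitude keyed to a
#'   dropped/unknown band is an error.
#' @param noiseSd white-noise standard deviation (default 0).
#' @param nUnits number of units (rows) to generate (default 1).
#' @param seed RNG seed (the recipe is fully deterministic given it).
#' @param minCycles passed to \code{\link{enumerateBands}}.
#' @return list with `ts` (a \linkS4class{TimeSeriesMatrix}), `bandset`,
#'   and `truth` (data.frame: band, amplitude, center_bin, freq_hz,
#'   variance).
#' @export
genBandSignal <- function(spec, amplitudes, noiseSd = 0, nUnits = 1L,
                          seed = 1L, minCycles = 6L) {
  stopifnot(is(spec, "SamplingSpec"))
  bandset <- enumerateBands(spec, minCycles)
  if (length(amplitudes) > 0L &&
      (is.null(names(amplitudes)) ||
       !all(names(amplitudes) %in% bandNames(bandset))))
    .n3l_stop("amplitudes must be named by decodable band names",
              "n3lband_domain_error")
  set.seed(seed)
  N <- nSamples(spec)
  tt <- (seq_len(N) - 1L) * trSeconds(spec)
  vals <- matrix(0, nrow = nUnits, ncol = N)
  truth <- list()
  for (nm in names(amplitudes)) {
    A <- amplitudes[[nm]]
    i <- match(nm, bandNames(bandset))
    b <- bandset@bands[[i]]
    owned <- .owned_bins(bandset, i)
    cb <- as.integer(.round_half_away(exp(b@centerIndex) *
                                      N * trSeconds(spec)))
    cb <- min(max(cb, min(owned)), max(owned))
    f <- cb * deltaFHz(spec)
    phases <- stats::runif(nUnits, 0, 2 * pi)
    vals <- vals + A * sin(outer(phases, 2 * pi * f * tt, `+`))
    truth[[nm]] <- data.frame(band = nm, amplitude = A, center_bin = cb,
                              freq_hz = f, variance = A^2 / 2,
                              stringsAsFactors = FALSE)
  }
  if (noiseSd > 0)
    vals <- vals + matrix(stats::rnorm(nUnits * N, 0, noiseSd), nUnits, N)
  list(ts = timeSeriesMatrix(vals, spec, unitKind = "parcel"),
       bandset = bandset,
       truth = if (length(truth) > 0L) do.call(rbind, truth)
               else data.frame(band = character(0), amplitude = numeric(0),
                               center_bin = integer(0), freq_hz = numeric(0),
                               variance = numeric(0)))
}

#' Generate a synthetic motion cohort under the exponential age model
#'
#' Each subject gets an age, a sex, and a six-parameter motion log whose
#' framewise displacement scales as \eqn{e^{a \cdot age + b}} with
#' multiplicative log-normal subject noise (keeping FD positive for the log
#' transform). Parameter increments are white noise, so every band's mean
#' absolute FD is proportional to the subject scale and the log-linear age
#' fit recovers the slope `a` in every band (band intercepts are offset by
#' a fixed band constant). Logs include a pre-zero segment and end buffer
#' so windowing from the zeroed time point is exercised.
#'
#' @param nPerSex subjects per sex (default 42).
#' @param ageRange inclusive integer age range in years (default 3-16).
#' @param a,b exponential model coefficients; scalars apply to both sexes,
#'   or named vectors `c(male =, female =)`.
#' @param sdLog SD of the log-normal subject noise (default 0.05).
#' @param fsHz sampling rate of the logs (default 9.285).
#' @param nKeep analysis window the logs must cover (default 1672).
#' @param zeroIndex sample at which parameters are zeroed (default 101).
#' @param seed RNG seed.
#' @return list with `traces` (named list of \linkS4class{MotionTrace}),
#'   `info` (data.frame id, age, sex, scale) and `truth` (a, b, sdLog).
#' @export
genMotionCohort <- function(nPerSex = 42L, ageRange = c(3L, 16L),
                            a = -0.1, b = 1.0, sdLog = 0.05,
                            fsHz = 9.285, nKeep = 1672L, zeroIndex = 101L,
                            seed = 1L) {
  stopifnot(nPerSex >= 2L)
  getc <- function(x, sex) if (length(x) == 1L) unname(x) else unname(x[[sex]])
  set.seed(seed)
  nRaw <- as.integer(zeroIndex + nKeep + 49L)
  sexes <- rep(c("male", "female"), each = nPerSex)
  ids <- sprintf("sub%03d", seq_along(sexes))
  ages <- sample(seq(ageRange[1L], ageRange[2L]), length(sexes),
                 replace = TRUE)
  spec <- samplingSpec(fsHz = fsHz, nSamples = nRaw)
  ## per-increment scales: translations mm, rotations deg (arc ~ 0.1 mm each)
  wTrans <- c(0.4, 0.3, 0.3)
  wRotDeg <- rep(0.1 * 180 / (50 * pi), 3L)
  traces <- list()
  scales <- numeric(length(ids))
  for (j in seq_along(ids)) {
    s <- exp(getc(a, sexes[j]) * ages[j] + getc(b, sexes[j]) +
             stats::rnorm(1L, 0, sdLog))
    scales[j] <- s
    inc <- cbind(
      sapply(wTrans, function(w) stats::rnorm(nRaw, 0, s * w)),
      sapply(wRotDeg, function(w) stats::rnorm(nRaw, 0, s * w)))
    p <- apply(inc, 2L, cumsum)
    p <- sweep(p, 2L, p[zeroIndex, ])      # exact zero at the reset sample
    traces[[ids[j]]] <- motionTrace(p[, 1:3], p[, 4:6], spec,
                                    zeroIndex = zeroIndex)
  }
  list(traces = traces,
       info = data.frame(id = ids, age = ages, sex = sexes, scale = scales,
                         stringsAsFactors = FALSE),
       truth = list(a = a, b = b, sdLog = sdLog))
}

#' Generate test-retest parcel data with known variance components
#'
#' Per parcel: subject effects ~ N(0, sigmaB2), visit effects ~ N(0,
#' sigmaV2) and scan residuals ~ N(0, sigmaE2). The short-term table holds
#' the two scans of one visit (the visit effect is shared, so the true
#' short-term ICC is \eqn{(\sigma_b^2+\sigma_v^2)/(\sigma_b^2+\sigma_v^2+
#' \sigma_e^2)}); the long-term table holds one draw per visit, so the true
#' long-term ICC is \eqn{\sigma_b^2/(\sigma_b^2+\sigma_v^2+\sigma_e^2)}.
#'
#' @param nSubjects number of subjects (default 42).
#' @param nParcels number of parcels (default 400).
#' @param sigmaB2,sigmaV2,sigmaE2 between-subject, visit-level and residual
#'   variances (defaults 4, 0, 1; not all zero).
#' @param seed RNG seed.
#' @return list with `short` and `long` \linkS4class{ReliabilityTable}s and
#'   `trueIcc = c(short =, long =)`.
#' @export
genTestRetest <- function(nSubjects = 42L, nParcels = 400L,
                          sigmaB2 = 4, sigmaV2 = 0, sigmaE2 = 1, seed = 1L) {
  if (sigmaB2 < 0 || sigmaV2 < 0 || sigmaE2 < 0)
    .n3l_stop("variances must be non-negative", "n3lband_domain_error")
  tot <- sigmaB2 + sigmaV2 + sigmaE2
  if (tot == 0)
    .n3l_stop("all variance components are zero", "n3lband_domain_error")
  set.seed(seed)
  S <- nSubjects; P <- nParcels
  bsub <- matrix(stats::rnorm(S * P, 0, sqrt(sigmaB2)), S, P)
  vis <- array(stats::rnorm(S * 2L * P, 0, sqrt(sigmaV2)), c(S, 2L, P))
  short <- array(NA_real_, c(S, 2L, P))
  for (o in 1:2)                            # two scans within visit 1
    short[, o, ] <- bsub + vis[, 1L, ] +
      matrix(stats::rnorm(S * P, 0, sqrt(sigmaE2)), S, P)
  long <- array(NA_real_, c(S, 2L, P))
  for (o in 1:2)                            # one draw per visit
    long[, o, ] <- bsub + vis[, o, ] +
      matrix(stats::rnorm(S * P, 0, sqrt(sigmaE2)), S, P)
  list(short = reliabilityTable(short, "short_term"),
       long = reliabilityTable(long, "long_term"),
       trueIcc = c(short = (sigmaB2 + sigmaV2) / tot, long = sigmaB2 / tot))
}
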