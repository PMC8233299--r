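spec10 <- function(n) samplingSpec(fsHz = 10, nSamples = n)

test_that("framewise displacement matches its closed forms", {
  n <- 10
  zero <- matrix(0, n, 3)
  # constant parameters -> FD identically zero
  tr0 <- motionTrace(matrix(1.3, n, 3), matrix(-0.4, n, 3), spec10(n))
  expect_identical(fdFromParams(tr0), rep(0, n))
  # single 1 mm x-translation step -> FD 1 mm at that step
  tx <- zero; tx[5:n, 1] <- 1
  tr1 <- motionTrace(tx, zero, spec10(n))
  expect_equal(fdFromParams(tr1), c(rep(0, 4), 1, rep(0, 5)))
  # single 1 degree rotation step -> arc length 50*pi/180 mm
  rx <- zero; rx[5:n, 2] <- 1
  tr2 <- motionTrace(zero, rx, spec10(n))
  expect_equal(max(fdFromParams(tr2)), 50 * pi / 180)
  expect_equal(max(fdFromParams(tr2, sphereRadiusMm = 100)), 100 * pi / 180)
  # first sample has no predecessor
  expect_identical(fdFromParams(tr1)[1], 0)
  expect_error(fdFromParams(motionTrace(zero[1, , drop = FALSE],
                                        zero[1, , drop = FALSE],
                                        samplingSpec(fsHz = 10, nSamples = 2),
                                        zeroIndex = 1)),
               class = "n3lband_data_error")
})

test_that("despiking removes spikes and leaves clean data untouched", {
  x <- sin(2 * pi * 3 * (0:299) / 300)
  expect_lt(max(abs(despikeSeries(x) - x)), 1e-12)       # spike-free
  expect_identical(despikeSeries(rep(2, 100)), rep(2, 100))  # constant

  set.seed(31)
  y <- sin(2 * pi * 3 * (0:299) / 300) + rnorm(300, 0, 0.05)
  spiked <- y; spiked[150] <- y[150] + 20 * sd(y)
  clean <- despikeSeries(spiked)
  trend <- stats::runmed(spiked, 11, endrule = "median")
  s <- stats::mad(spiked - trend)
  expect_lt(abs(clean[150] - trend[150]), 3 * s)
  expect_identical(clean[-150], spiked[-150])
  # idempotent once the spike is gone
  expect_identical(despikeSeries(clean), clean)
  expect_error(despikeSeries(1:5), class = "n3lband_data_error")
})

test_that("windowing retains nKeep samples from the zeroed time point", {
  set.seed(32)
  p <- matrix(rnorm(2000 * 6), 2000, 6)
  tr <- motionTrace(p[, 1:3], p[, 4:6], spec10(2000), zeroIndex = 100L)
  w <- windowFromZero(tr, nKeep = 1672L)
  expect_identical(nrow(w@params), 1672L)
  expect_equal(unname(w@params), p[100:1771, ], tolerance = 1e-15)
  expect_false(isTRUE(w@metadata$excludedShort))

  short <- motionTrace(p[1:1500, 1:3], p[1:1500, 4:6], spec10(1500),
                       zeroIndex = 100L)
  ws <- windowFromZero(short, nKeep = 1672L)
  expect_true(ws@metadata$excludedShort)

  # 1672 samples at 9.285 Hz last just over three minutes
  expect_equal(1672 / 9.285, 180.07, tolerance = 1e-4)
})

test_that("band summaries recover the mean-absolute-sine closed form", {
  spec <- spec_motion()
  bs <- enumerateBands(spec)
  zero <- decomposeBands(timeSeriesMatrix(rep(0, 1672), spec,
                                          unitKind = "scalar-trace"), bs)
  sz <- bandSummaries(zero)
  expect_true(all(sz$mean_abs_fd == 0) && all(sz$sd_fd == 0))

  A <- 0.37
  x <- sinusoid(spec, 46 * deltaFHz(spec), A = A)   # centre of Slow-2
  d <- decomposeBands(timeSeriesMatrix(x, spec, unitKind = "scalar-trace"), bs)
  s1 <- bandSummaries(d)
  expect_equal(s1$mean_abs_fd[s1$band == "Slow-2"], 2 * A / pi,
               tolerance = 1e-3)
  d2 <- decomposeBands(timeSeriesMatrix(2 * x, spec,
                                        unitKind = "scalar-trace"), bs)
  s2 <- bandSummaries(d2)
  expect_equal(s2$mean_abs_fd, 2 * s1$mean_abs_fd, tolerance = 1e-12)
  expect_equal(s2$sd_fd, 2 * s1$sd_fd, tolerance = 1e-12)
})

test_that("the 3-SD outlier rule flags exactly the constructed outlier", {
  coh <- make_stat_cohort(20, seed = 33)
  coh$mean_fd <- rnorm(nrow(coh), 1, 0.1)
  none <- excludeOutliers(coh)
  expect_false(any(none$excluded_outlier))
  m <- mean(coh$mean_fd); s <- sd(coh$mean_fd)
  coh$mean_fd[7] <- m + 5 * s
  one <- excludeOutliers(coh)
  expect_identical(which(one$excluded_outlier), 7L)
  expect_false(any(excludeOutliers(coh, kSd = Inf)$excluded_outlier))
})

test_that("log-linear age fits recover exact and noisy exponential models", {
  # perfectly exponential data -> exact coefficients, R^2 = 1
  coh <- make_stat_cohort(15, a = -0.12, b = c(male = 0.8, female = 0.8),
                          noise_sd = 0, seed = 34)
  f <- suppressWarnings(logLinearAgeFit(coh, "X", "male"))  # perfect fit
  expect_equal(f$a, -0.12, tolerance = 1e-10)
  expect_equal(f$b, 0.8, tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)

  # simulated stratum: slope recovered within +/- 0.02, R^2 > 0.9
  coh2 <- make_stat_cohort(42, a = -0.1, b = c(male = 1, female = 1),
                           noise_sd = 0.05, seed = 35)
  f2 <- logLinearAgeFit(coh2, "X", "female")
  expect_lt(abs(f2$a - (-0.1)), 0.02)
  expect_gt(f2$r_squared, 0.9)
  expect_identical(f2$df, 40L)

  bad <- coh2; bad$meanFD_X[3] <- 0
  expect_error(logLinearAgeFit(bad, "X", "male"),
               class = "n3lband_data_error")
})

test_that("slope p-value agrees with a permutation oracle", {
  coh <- make_stat_cohort(10, a = -0.08, noise_sd = 0.35, seed = 36)
  f <- logLinearAgeFit(coh, "X", "male")
  d <- coh[coh$sex == "male", ]
  ly <- log(d$meanFD_X)
  obs <- abs(cor(d$age, ly))
  set.seed(361)
  perm <- replicate(4000, abs(cor(sample(d$age), ly)))
  p_perm <- (1 + sum(perm >= obs)) / (4000 + 1)
  expect_lt(abs(f$p - p_perm), 0.02)   # within Monte-Carlo error
})

test_that("sex-line comparison matches the interaction GLM and is null on identical strata", {
  # identical strata -> no slope or intercept difference
  coh <- make_stat_cohort(20, a = -0.1, noise_sd = 0.1, seed = 37)
  coh$age <- rep(coh$age[coh$sex == "male"], 2)  # mirror ages across sexes
  coh$meanFD_X <- rep(coh$meanFD_X[coh$sex == "male"], 2)
  cmp0 <- compareSexLines(coh, "X")
  expect_lt(cmp0$F_slope, 1e-8)
  expect_gt(cmp0$p_slope, 0.999)

  # equivalence with the general linear model with sex x age interaction
  coh2 <- make_stat_cohort(25, a = -0.1, b = c(male = 1.1, female = 0.9),
                           noise_sd = 0.1, seed = 38)
  cmp <- compareSexLines(coh2, "X")
  d <- coh2; d$ly <- log(d$meanFD_X)
  full <- lm(ly ~ age * sex, data = d)
  tfull <- summary(full)$coefficients["age:sexmale", "t value"]
  expect_equal(cmp$F_slope, tfull^2, tolerance = 1e-8)
  common <- lm(ly ~ age + sex, data = d)
  tsex <- summary(common)$coefficients["sexmale", "t value"]
  expect_equal(cmp$F_intercept, tsex^2, tolerance = 1e-8)
  # pooled df: n - 4 for the interaction model (84 subjects -> 80)
  coh3 <- make_stat_cohort(42, seed = 39)
  expect_identical(compareSexLines(coh3, "X")$df_slope[2L], 80L)
})

test_that("an intercept shift of 3 residual SDs is detected reliably", {
  hits <- 0L
  for (r in 1:200) {
    coh <- make_stat_cohort(42, a = -0.1,
                            b = c(male = 1 + 3 * 0.05, female = 1),
                            noise_sd = 0.05, seed = 4000 + r)
    if (compareSexLines(coh, "X")$p_intercept < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.95)
})

test_that("repeated-measures ANOVA separates band effects from interactions", {
  set.seed(40)
  n <- 12
  coh <- data.frame(id = sprintf("s%02d", 1:(2 * n)),
                    age = rep(8, 2 * n),
                    sex = rep(c("male", "female"), each = n),
                    excluded_short = FALSE, excluded_outlier = FALSE,
                    mean_fd = 1, stringsAsFactors = FALSE)
  bands <- c("B1", "B2", "B3", "B4")
  for (i in seq_along(bands))      # increasing band means, no sex effect
    coh[[paste0("meanFD_", bands[i])]] <- rnorm(2 * n, mean = i, sd = 0.5)
  res <- repeatedMeasuresAnova(coh, bands, ageGroups = list(all = c(0, 99)))
  expect_lt(res$p_band, 1e-6)
  expect_gt(res$p_interaction, 0.05)

  expect_error(repeatedMeasuresAnova(coh, "B1",
                                     ageGroups = list(all = c(0, 99))),
               class = "n3lband_data_error")
  solo <- coh; solo$sex[2:(2 * n)] <- "female"
  expect_error(repeatedMeasuresAnova(solo, bands,
                                     ageGroups = list(all = c(0, 99))),
               class = "n3lband_data_error")
})

test_that("BH adjustment reproduces the step-up rule and validates input", {
  expect_equal(fdrAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdrAdjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(fdrAdjust(0.73), 0.73)
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205)
  expect_equal(fdrAdjust(p), p.adjust(p, "BH"))
  ord <- order(p)
  expect_false(is.unsorted(fdrAdjust(p)[ord]))   # monotone in input ranks
  expect_error(fdrAdjust(c(0.5, 1.2)), class = "n3lband_data_error")
  expect_error(fdrAdjust(c(0.5, NA)), class = "n3lband_data_error")
})

test_that("the cohort pipeline flags short subjects and scales with the trace", {
  sim <- genMotionCohort(nPerSex = 3, nKeep = 400, zeroIndex = 21,
                         fsHz = 9.285, seed = 41)
  # truncate one subject below the window
  short_id <- names(sim$traces)[2]
  tr <- sim$traces[[short_id]]
  sim$traces[[short_id]] <- motionTrace(tr@params[1:200, 1:3],
                                        tr@params[1:200, 4:6],
                                        samplingSpec(fsHz = 9.285,
                                                     nSamples = 200),
                                        zeroIndex = 21)
  coh <- motionCohortTable(sim$traces, sim$info, nKeep = 400)
  expect_true(coh$excluded_short[coh$id == short_id])
  expect_true(is.na(coh$mean_fd[coh$id == short_id]))
  expect_identical(sum(!coh$excluded_short), 5L)

  # despiking, windowing and decoding commute with scalar scaling
  doubled <- lapply(sim$traces, function(tr)
    motionTrace(2 * tr@params[, 1:3], 2 * tr@params[, 4:6], tr@spec,
                zeroIndex = tr@zeroIndex))
  coh2 <- motionCohortTable(doubled, sim$info, nKeep = 400)
  keep <- !coh$excluded_short
  bcols <- grep("^(meanFD|sdFD)_", names(coh), value = TRUE)
  for (cl in bcols)
    expect_equal(coh2[[cl]][keep], 2 * coh[[cl]][keep], tolerance = 1e-10)
})
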