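test_that("detectable range follows the Nyquist-Shannon limits", {
  r <- detectableRange(spec_hcp())
  expect_equal(r[["fMaxHz"]], 1 / (2 * 0.72))
  expect_equal(r[["fMinHz"]], 1 / (2 * 1200 * 0.72))
  expect_equal(r[["fMinHz"]], 1 / 1728)

  expect_equal(detectableRange(samplingSpec(trSeconds = 1,
                                            nSamples = 64))[["fMaxHz"]], 0.5)
  r1 <- detectableRange(spec_motion())
  expect_equal(r1[["fMaxHz"]], 9.285 / 2)

  expect_error(samplingSpec(trSeconds = -1, nSamples = 100),
               class = "n3lband_invalid_sampling")
  expect_error(samplingSpec(trSeconds = 1, nSamples = 1),
               class = "n3lband_invalid_sampling")
})

test_that("edge snapping rounds to the nearest DFT bin, half away from zero", {
  hcp <- spec_hcp()
  # e^-4.5 * 864 = 9.596 -> bin 10 -> 0.011574 Hz
  expect_identical(snapEdgeToBin(exp(-4.5), hcp), 10L)
  expect_equal(10 * deltaFHz(hcp), 0.0115740741, tolerance = 1e-8)
  expect_identical(snapEdgeToBin(0, hcp), 0L)
  # 0.6065 Hz lands on bin 524 of the 864-second grid
  expect_identical(snapEdgeToBin(0.6065, hcp), 524L)
  expect_error(snapEdgeToBin(1.0, hcp), class = "n3lband_domain_error")
  expect_error(snapEdgeToBin(-0.1, hcp), class = "n3lband_domain_error")
})

test_that("band naming follows the electrophysiology convention", {
  expect_identical(bandName(0), "Slow-1")
  expect_identical(bandName(-3), "Slow-4")
  expect_identical(bandName(1), "Delta")
  expect_identical(bandName(2), "Theta")
  expect_identical(bandName(-8), "Slow-9")
  expect_identical(bandName(-9), "OSC(-9)")
  expect_identical(bandName(3), "OSC(3)")
  expect_identical(bandName(c(-1, 0, 1)), c("Slow-2", "Slow-1", "Delta"))
})

test_that("band enumeration at 9.285 Hz / 1672 points yields the six mock-scanner bands", {
  bs <- enumerateBands(spec_motion())
  tab <- bandTable(bs)
  expect_identical(nrow(tab), 6L)
  expect_identical(tab$band_name,
                   c("Slow-4", "Slow-3", "Slow-2", "Slow-1", "Delta", "Theta"))
  expect_identical(tab$center_index, c(-3L, -2L, -1L, 0L, 1L, 2L))
  expect_identical(tab$lo_bin, c(6L, 15L, 40L, 109L, 297L, 807L))
  expect_identical(tab$hi_bin, c(15L, 40L, 109L, 297L, 807L, 836L))
  expect_true(tab$truncated_low[1L])   # Slow-4 clipped at the 6-cycle floor
  expect_true(tab$truncated_high[6L])  # Theta clipped at Nyquist
  expect_false(any(tab$truncated_low[-1L]), any(tab$truncated_high[-6L]))
  expect_lt(tab$width_ratio[6L], 0.1)  # Theta too narrow for analysis
  expect_identical(analysisBands(bs),
                   c("Slow-4", "Slow-3", "Slow-2", "Slow-1", "Delta"))
})

test_that("band enumeration at TR 0.72 s / 1200 volumes yields the six rfMRI bands", {
  bs <- enumerateBands(spec_hcp())
  tab <- bandTable(bs)
  expect_identical(nrow(tab), 6L)
  expect_identical(tab$band_name,
                   c("Slow-6", "Slow-5", "Slow-4", "Slow-3", "Slow-2", "Slow-1"))
  expect_identical(tab$lo_bin, c(6L, 10L, 26L, 71L, 193L, 524L))
  expect_identical(tab$hi_bin, c(10L, 26L, 71L, 193L, 524L, 600L))
  expect_equal(tab$lo_hz, tab$lo_bin / 864)
  expect_equal(tab$hi_hz, tab$hi_bin / 864)
})

test_that("too short or too slow recordings yield the no-decodable-band error", {
  expect_error(enumerateBands(samplingSpec(trSeconds = 2, nSamples = 10)),
               class = "n3lband_no_band_error")
  expect_error(enumerateBands(samplingSpec(trSeconds = 1, nSamples = 12)),
               class = "n3lband_no_band_error")
})

test_that("band bins partition the usable grid with shared edges", {
  for (cfg in list(spec_motion(), spec_hcp(),
                   samplingSpec(trSeconds = 2, nSamples = 300))) {
    bs <- enumerateBands(cfg)
    tab <- bandTable(bs)
    # contiguity of adjacent edges
    expect_identical(tab$hi_bin[-nrow(tab)], tab$lo_bin[-1L])
    # ownership covers [floor, Nyquist] exactly once
    owned <- unlist(lapply(seq_len(length(bs)),
                           function(i) n3lband:::.owned_bins(bs, i)))
    expect_identical(sort(owned), seq(6L, nSamples(cfg) %/% 2L))
    expect_identical(anyDuplicated(owned), 0L)
  }
})

test_that("theoretical edges of every band keep the ratio e", {
  bs <- enumerateBands(spec_motion())
  for (i in seq_len(length(bs))) {
    b <- bs[[i]]
    expect_equal(hiTheoreticalHz(b) / loTheoreticalHz(b), exp(1),
                 tolerance = 1e-12)
  }
})

test_that("scaling TR by a band spacing shifts the ladder and divides edges exactly", {
  ## multiplying TR by e^k leaves every product e^{n+0.5} N TR invariant
  ## under n -> n - k, so the bands keep their bins (ladder shifted by k)
  ## and every reported edge is divided by e^k
  base <- enumerateBands(spec_hcp())
  for (k in c(-1L, 1L)) {
    c_ <- exp(k)
    bsc <- enumerateBands(samplingSpec(trSeconds = 0.72 * c_,
                                       nSamples = 1200))
    expect_identical(length(bsc), length(base))
    for (i in seq_len(length(base))) {
      b0 <- base[[i]]; b1 <- bsc[[i]]
      expect_identical(centerIndex(b1), centerIndex(b0) - k)
      expect_identical(b1@loBin, b0@loBin)
      expect_identical(b1@hiBin, b0@hiBin)
      expect_equal(loHz(b1), loHz(b0) / c_, tolerance = 1e-9)
      expect_equal(hiHz(b1), hiHz(b0) / c_, tolerance = 1e-9)
    }
  }
})

test_that("lengthening the recording never removes a band and never raises the floor", {
  prev <- NULL
  for (N in c(300, 600, 1200, 2400, 4800)) {
    bs <- enumerateBands(samplingSpec(trSeconds = 0.72, nSamples = N))
    idx <- vapply(bs@bands, centerIndex, integer(1))
    flo <- loHz(bs[[1L]])
    if (!is.null(prev)) {
      expect_true(all(prev$idx %in% idx))
      expect_lte(flo, prev$flo)
    }
    prev <- list(idx = idx, flo = flo)
  }
})

test_that("the boundary CSV round-trips bins exactly and refuses bad input", {
  bs <- enumerateBands(spec_hcp())
  path <- file.path(tempdir(), "bounds.csv")
  writeBoundariesCsv(bs, path)
  back <- read.csv(path)
  expect_identical(nrow(back), 6L)
  expect_identical(back$band_name[1L], "Slow-6")
  tab <- bandTable(bs)
  expect_identical(as.integer(back$lo_bin), tab$lo_bin)
  expect_identical(as.integer(back$hi_bin), tab$hi_bin)
  expect_equal(back$lo_hz, tab$lo_hz, tolerance = 1e-12)

  expect_error(writeBoundariesCsv(bs, "/nonexistent-dir/x.csv"),
               class = "n3lband_io_error")
  expect_false(file.exists("/nonexistent-dir/x.csv"))

  jpath <- file.path(tempdir(), "bounds.json")
  writeBandsJson(bs, jpath)
  j <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  expect_identical(as.integer(j$bands$lo_bin), tab$lo_bin)
  expect_equal(j$sampling$n_samples, 1200)
})
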