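## shared fixtures, all built in code

spec_motion <- function() samplingSpec(fsHz = 9.285, nSamples = 1672)
spec_hcp <- function() samplingSpec(trSeconds = 0.72, nSamples = 1200)

## sinusoid of amplitude A at frequency f on the grid of `spec`
sinusoid <- function(spec, f, A = 1, phase = 0) {
  tt <- (seq_len(nSamples(spec)) - 1L) * trSeconds(spec)
  A * sin(2 * pi * f * tt + phase)
}

## variance of each band component plus the residual, per unit then summed
component_variances <- function(decoded) {
  vapply(decoded@components,
         function(m) sum(apply(m, 1L, stats::var)), numeric(1))
}

## a ready-made cohort data.frame for the statistical operations (log-scale
## model ln(meanFD) = a*age + b_sex + noise), bypassing the signal pipeline
make_stat_cohort <- function(n_per_sex, a = -0.1, b = c(male = 1, female = 1),
                             noise_sd = 0.05, bands = "X", seed = 1) {
  set.seed(seed)
  sex <- rep(c("male", "female"), each = n_per_sex)
  age <- stats::runif(2 * n_per_sex, 3, 16)
  out <- data.frame(id = sprintf("s%03d", seq_along(sex)), age = age,
                    sex = sex, excluded_short = FALSE,
                    excluded_outlier = FALSE, mean_fd = 1,
                    stringsAsFactors = FALSE)
  for (bnd in bands) {
    ly <- a * age + unname(b[sex]) + stats::rnorm(length(sex), 0, noise_sd)
    out[[paste0("meanFD_", bnd)]] <- exp(ly)
    out[[paste0("sdFD_", bnd)]] <- exp(ly)
  }
  out
}

## unique empty directory under the session tempdir
fresh_dir <- function(prefix) {
  d <- tempfile(prefix)
  dir.create(d, recursive = TRUE)
  d
}
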