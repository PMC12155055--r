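# Synthetic-spectra generator: distributional contracts, determinism,
# the Beer-Lambert linearity of the clean model, state ordering, and
# outlier injection provenance.

test_that("protein draws respect the truncated-normal contract", {
  cfg <- synthetic_config(seed = 1)
  p <- draw_protein_values(cfg)
  expect_length(p, 124)
  expect_true(all(p >= 6.46 & p <= 12.44))
  expect_identical(p, draw_protein_values(cfg))

  # sd = 0 collapses to the mean
  p0 <- draw_protein_values(synthetic_config(protein_sd_pct = 0, seed = 3))
  expect_true(all(p0 == 9.64))

  # Monte-Carlo mean against the closed-form truncated-normal moment
  cfg_big <- synthetic_config(n_samples = 1e4, seed = 11)
  pb <- draw_protein_values(cfg_big)
  mu_true <- truncnorm_mean(9.64, 0.90, 6.46, 12.44)
  expect_lt(abs(mean(pb) - mu_true), 3 * 0.90 / sqrt(1e4))
})

test_that("degenerate protein range is rejected", {
  expect_error(synthetic_config(protein_min_pct = 9, protein_max_pct = 9),
               "degenerate")
})

test_that("clean spectra are proportional to protein at a single band", {
  cfg <- clean_cfg(n_samples = 2, background_absorbance = 0,
                   band_centers_nm = 1200, band_widths_nm = 30,
                   band_amplitudes = 0.01, interferent_bands = list())
  # draw_protein_values not used: supply protein directly
  ds <- generate_spectra(cfg, c(1, 2))
  at <- function(i, nm) ds$spectra$absorbance[i, as.character(nm)]
  expect_equal(unname(at(2, 1200)), 2 * unname(at(1, 1200)))
  # affine in protein at every wavelength: rank-1 regression is exact
  cfg3 <- clean_cfg(n_samples = 5, interferent_bands = list())
  prot <- c(7, 8, 9, 10, 11)
  ds3 <- generate_spectra(cfg3, prot)
  j <- which(ds3$spectra$wavelengths_nm == 1200)
  fit <- lm(ds3$spectra$absorbance[, j] ~ prot)
  expect_lt(max(abs(residuals(fit))), 1e-10)
})

test_that("granule spectra peak near 1450 nm relative to the 1350 nm valley", {
  ds <- simulate_nir_dataset(synthetic_config(seed = 5))
  mu <- colMeans(ds$spectra$absorbance)
  expect_gt(mu[["1450"]], mu[["1350"]])
  expect_gt(mu[["1200"]], mu[["1350"]])
})

test_that("same config and seed give bit-identical datasets", {
  cfg <- quick_cfg(seed = 9)
  d1 <- simulate_nir_dataset(cfg)
  d2 <- simulate_nir_dataset(cfg)
  expect_identical(d1$spectra$absorbance, d2$spectra$absorbance)
  expect_identical(d1$samples, d2$samples)
})

test_that("mean spectra order as granules > deshelled > shell", {
  mu <- lapply(c("granules", "deshelled", "shell"), function(st)
    colMeans(simulate_nir_dataset(synthetic_config(seed = 4, state = st))
             $spectra$absorbance))
  expect_true(all(mu[[1]] > mu[[2]]))
  expect_true(all(mu[[2]] > mu[[3]]))
})

test_that("wavelength axis has 651 points under defaults", {
  cfg <- synthetic_config()
  expect_length(cfg$wavelengths_nm, 651)
  expect_equal(cfg$wavelengths_nm[1], 1000)
  expect_equal(cfg$wavelengths_nm[651], 1650)
})

test_that("outlier injection updates spectra, reference values and provenance", {
  ds <- simulate_nir_dataset(quick_cfg(seed = 2))
  expect_identical(inject_outliers(ds), ds)  # empty index sets: no-op
  ds2 <- inject_outliers(ds, spectral_idx = 3, chemical_idx = c(5, 7),
                         chemical_magnitude = 2)
  expect_false(identical(ds2$spectra$absorbance[3, ], ds$spectra$absorbance[3, ]))
  expect_identical(ds2$spectra$absorbance[4, ], ds$spectra$absorbance[4, ])
  shift <- ds2$samples$protein_pct[c(5, 7)] - ds$samples$protein_pct[c(5, 7)]
  expect_equal(abs(shift), c(2, 2))
  expect_setequal(ds2$outliers$index, c(3, 5, 7))
  expect_setequal(ds2$outliers$kind[ds2$outliers$index == 3], "spectral")

  expect_error(inject_outliers(ds, spectral_idx = 99), "out of range")
  expect_error(inject_outliers(ds, spectral_idx = 2, chemical_idx = 2),
               "disjoint")
})

test_that("wide CSV round-trips spectra and reference values", {
  ds <- simulate_nir_dataset(quick_cfg(seed = 6))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(ds$spectra, ds$samples$protein_pct, path)
  back <- read_spectra_csv(path)
  expect_equal(back$spectra$wavelengths_nm, ds$spectra$wavelengths_nm)
  expect_equal(unname(back$spectra$absorbance),
               unname(ds$spectra$absorbance), tolerance = 1e-12)
  expect_equal(back$samples$protein_pct, ds$samples$protein_pct)
})

test_that("generator config reads from YAML/JSON and requires a seed", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_samples: 10", "seed: 42", "noise_sd: 0.001"), path)
  cfg <- read_synthetic_config(path)
  expect_equal(cfg$n_samples, 10L)
  expect_equal(cfg$noise_sd, 0.001)

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("n_samples: 10", bad)
  expect_error(read_synthetic_config(bad), "seed")
})
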