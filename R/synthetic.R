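#' Configuration for the synthetic NIR spectra generator
#'
#' Builds the parameter set for simulating portable NIR diffuse-reflectance
#' spectra of nut kernels in three physical states. The clean spectrum of a
#' sample is Beer-Lambert-style additive mixing: a state-dependent
#' attenuation factor times (constant background + protein concentration
#' times Gaussian protein bands + interferent concentrations times their
#' bands). On top of the clean spectrum each sample receives multiplicative
#' scatter \eqn{(1+b)A + a}, a smooth low-order polynomial baseline drift,
#' and i.i.d. Gaussian noise.
#'
#' Defaults emulate the study conditions: 124 kernels, protein 6.46-12.44%
#' (mean 9.64, sd 0.90), wavelength axis 1000-1650 nm in 1 nm steps
#' (651 points), protein absorption bands at 1200 nm (C-H stretch) and
#' 1450 nm (N-H stretch), and two interferent constituents whose bands
#' overlap the protein bands (oil C-H near 1210 nm, water O-H near 1440 nm)
#' with concentrations uncorrelated with protein, which is what makes
#' multivariate calibration necessary. Attenuation orders the mean spectra
#' as granules > deshelled > in-shell.
#'
#' @param n_samples number of kernels to simulate.
#' @param wavelength_start_nm,wavelength_end_nm,step_nm wavelength axis (nm).
#' @param protein_min_pct,protein_max_pct,protein_mean_pct,protein_sd_pct
#'   truncated-normal parameters of the protein mass fraction (%).
#' @param band_centers_nm,band_widths_nm,band_amplitudes protein band
#'   centers (nm), Gaussian sigmas (nm), and amplitudes (absorbance per %
#'   protein).
#' @param interferent_bands list of interferent constituents; each a list
#'   with \code{center_nm}, \code{width_nm}, \code{amplitude} (absorbance per
#'   concentration unit), \code{conc_mean}, \code{conc_sd}.
#' @param background_absorbance amplitude (AU) of the fixed matrix
#'   absorption profile shared by every sample (bulk oil/water/carbohydrate
#'   continuum: a gentle slope with broad bands under the 1200 and 1450 nm
#'   peaks); 0 disables it.
#' @param state kernel state, one of \code{"shell"}, \code{"deshelled"},
#'   \code{"granules"}.
#' @param signal_attenuation named numeric vector of per-state attenuation
#'   factors in [0, 1]; the state's entry scales the clean spectrum.
#' @param scatter_slope_sd,scatter_offset_sd standard deviations of the
#'   per-sample multiplicative slope \eqn{b} and additive offset \eqn{a}.
#' @param baseline_drift_amplitude sd (AU) of the per-sample linear and
#'   quadratic drift coefficients.
#' @param noise_sd sd (AU) of the i.i.d. measurement noise.
#' @param seed integer seed; every stochastic draw in the generator derives
#'   from it, so identical configs give bit-identical datasets.
#' @return An object of class \code{synthetic_config} (a list).
#' @export
synthetic_config <- function(n_samples = 124,
                             wavelength_start_nm = 1000,
                             wavelength_end_nm = 1650,
                             step_nm = 1,
                             protein_min_pct = 6.46,
                             protein_max_pct = 12.44,
                             protein_mean_pct = 9.64,
                             protein_sd_pct = 0.90,
                             band_centers_nm = c(1200, 1450),
                             band_widths_nm = c(30, 30),
                             band_amplitudes = c(0.012, 0.012),
                             interferent_bands = list(
                               list(center_nm = 1210, width_nm = 40,
                                    amplitude = 0.006,
                                    conc_mean = 50, conc_sd = 3),
                               list(center_nm = 1440, width_nm = 50,
                                    amplitude = 0.020,
                                    conc_mean = 5, conc_sd = 0.5)),
                             background_absorbance = 0.3,
                             state = c("granules", "deshelled", "shell"),
                             signal_attenuation = c(shell = 0.45,
                                                    deshelled = 0.75,
                                                    granules = 1.0),
                             scatter_slope_sd = 0.25,
                             scatter_offset_sd = 0.10,
                             baseline_drift_amplitude = 0.02,
                             noise_sd = 0.002,
                             seed = 1L) {
  state <- match.arg(state)
  if (n_samples < 2) stop("n_samples must be at least 2", call. = FALSE)
  if (protein_min_pct >= protein_max_pct)
    stop("degenerate protein range: min must be < max (zero-variance response)",
         call. = FALSE)
  disp <- c(protein_sd_pct, scatter_slope_sd, scatter_offset_sd,
            baseline_drift_amplitude, noise_sd)
  if (any(disp < 0)) stop("dispersion parameters must be >= 0", call. = FALSE)
  if (!all(c("shell", "deshelled", "granules") %in% names(signal_attenuation)))
    stop("signal_attenuation needs entries shell, deshelled, granules", call. = FALSE)
  if (any(signal_attenuation < 0 | signal_attenuation > 1))
    stop("signal_attenuation factors must lie in [0, 1]", call. = FALSE)
  stopifnot(length(band_centers_nm) == length(band_widths_nm),
            length(band_centers_nm) == length(band_amplitudes))
  wl <- seq(wavelength_start_nm, wavelength_end_nm, by = step_nm)
  cfg <- list(n_samples = as.integer(n_samples),
              wavelength_start_nm = wavelength_start_nm,
              wavelength_end_nm = wavelength_end_nm,
              step_nm = step_nm, wavelengths_nm = wl,
              protein_min_pct = protein_min_pct,
              protein_max_pct = protein_max_pct,
              protein_mean_pct = protein_mean_pct,
              protein_sd_pct = protein_sd_pct,
              band_centers_nm = band_centers_nm,
              band_widths_nm = band_widths_nm,
              band_amplitudes = band_amplitudes,
              interferent_bands = interferent_bands,
              background_absorbance = background_absorbance,
              state = state,
              signal_attenuation = signal_attenuation,
              scatter_slope_sd = scatter_slope_sd,
              scatter_offset_sd = scatter_offset_sd,
              baseline_drift_amplitude = baseline_drift_amplitude,
              noise_sd = noise_sd,
              seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  cfg
}

#' Read a generator configuration from JSON or YAML
#'
#' Field names mirror the arguments of \code{\link{synthetic_config}};
#' \code{seed} is mandatory in the file.
#'
#' @param path path to a \code{.json}, \code{.yaml} or \code{.yml} file.
#' @return A \code{synthetic_config}.
#' @export
read_synthetic_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(vals$seed))
    stop("config file must set an explicit seed", call. = FALSE)
  if (!is.null(vals$signal_attenuation))
    vals$signal_attenuation <- unlist(vals$signal_attenuation)
  if (!is.null(vals$interferent_bands) && is.data.frame(vals$interferent_bands))
    vals$interferent_bands <- lapply(seq_len(nrow(vals$interferent_bands)),
                                     function(i) as.list(vals$interferent_bands[i, ]))
  keep <- intersect(names(vals), names(formals(synthetic_config)))
  do.call(synthetic_config, vals[keep])
}

# Inverse-CDF sampler for the truncated normal (no CRAN provider installed).
rtruncnorm_icdf <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Draw reference protein values
#'
#' Samples protein mass fractions from a normal distribution truncated to
#' the configured range, via the inverse-CDF method. With \code{sd = 0}
#' every value equals the mean. Reproducible under the config seed.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return Numeric vector of length \code{n_samples}, values in
#'   \code{[protein_min_pct, protein_max_pct]}.
#' @export
draw_protein_values <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  rtruncnorm_icdf(config$n_samples, config$protein_mean_pct,
                  config$protein_sd_pct, config$protein_min_pct,
                  config$protein_max_pct)
}

gaussian_band <- function(wl, center, sigma) exp(-(wl - center)^2 / (2 * sigma^2))

#' Generate synthetic NIR spectra for given protein values
#'
#' Builds each clean spectrum as attenuation times (background + protein
#' times the protein-band profile + interferent contributions), then applies
#' per-sample multiplicative scatter \eqn{(1+b)A + a}, a smooth quadratic
#' baseline drift, and i.i.d. Gaussian noise. All randomness derives from
#' \code{config$seed} (offset so the protein draw stream is not reused), so
#' two calls with the same config and protein vector are bit-identical.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @param protein numeric vector of protein values (%), length
#'   \code{n_samples}.
#' @return An object of class \code{synthetic_dataset}: list with
#'   \code{spectra} (a \code{\link{spectra_matrix}}), \code{samples}
#'   (data.frame: sample_id, protein_pct, state), \code{config}, and
#'   \code{outliers} (data.frame of injected outliers, initially empty).
#' @export
generate_spectra <- function(config, protein) {
  stopifnot(inherits(config, "synthetic_config"))
  if (length(protein) != config$n_samples)
    stop("protein has length ", length(protein), " but config expects ",
         config$n_samples, " samples", call. = FALSE)
  if (any(!is.finite(protein)) || any(protein <= 0))
    stop("protein values must be finite and positive", call. = FALSE)
  set.seed(config$seed + 1L)
  wl <- config$wavelengths_nm
  n <- config$n_samples
  m <- length(wl)

  # protein band profile: absorbance per % protein
  prot_profile <- rep(0, m)
  for (k in seq_along(config$band_centers_nm))
    prot_profile <- prot_profile + config$band_amplitudes[k] *
      gaussian_band(wl, config$band_centers_nm[k], config$band_widths_nm[k])

  clean <- outer(protein, prot_profile)
  for (ib in config$interferent_bands) {
    conc <- stats::rnorm(n, ib$conc_mean, ib$conc_sd)
    clean <- clean + outer(conc * ib$amplitude,
                           gaussian_band(wl, ib$center_nm, ib$width_nm))
  }
  # fixed matrix absorption of the kernel bulk (oil/water/carbohydrate
  # continuum): a gentle slope plus broad bands under the 1200/1450 peaks,
  # identical for every sample. Anchors the spectral scale so that
  # row-standardizing transforms (SNV/MSC) stay nearly affine in the
  # constituent concentrations, as for real diffuse-reflectance spectra.
  u0 <- (wl - mean(wl)) / (diff(range(wl)) / 2)
  matrix_bg <- config$background_absorbance *
    (1 + 0.3 * u0 + 0.5 * gaussian_band(wl, 1190, 80) +
       0.7 * gaussian_band(wl, 1450, 90))
  clean <- sweep(clean, 2, matrix_bg, `+`)
  atten <- config$signal_attenuation[[config$state]]
  clean <- atten * clean

  # per-sample affine scatter, smooth drift, measurement noise
  b <- stats::rnorm(n, 0, config$scatter_slope_sd)
  a <- stats::rnorm(n, 0, config$scatter_offset_sd)
  u <- (wl - mean(wl)) / (diff(range(wl)) / 2)  # normalized to [-1, 1]
  c1 <- stats::rnorm(n, 0, config$baseline_drift_amplitude)
  c2 <- stats::rnorm(n, 0, config$baseline_drift_amplitude)
  drift <- outer(c1, u) + outer(c2, u^2)
  noise <- matrix(stats::rnorm(n * m, 0, config$noise_sd), n, m)
  absorb <- (1 + b) * clean + a + drift + noise

  ids <- paste0("S", seq_len(n))
  structure(list(
    spectra = spectra_matrix(absorb, wl, ids),
    samples = data.frame(sample_id = ids, protein_pct = protein,
                         state = config$state),
    config = config,
    outliers = data.frame(index = integer(), kind = character(),
                          magnitude = numeric())),
    class = "synthetic_dataset")
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper: draws protein values then generates spectra.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return A \code{synthetic_dataset}.
#' @export
simulate_nir_dataset <- function(config = synthetic_config()) {
  generate_spectra(config, draw_protein_values(config))
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic NIR dataset (", x$config$state, "): ",
      nrow(x$spectra$absorbance), " samples, ",
      length(x$spectra$wavelengths_nm), " wavelengths",
      if (nrow(x$outliers)) paste0(", ", nrow(x$outliers), " injected outliers"),
      "\n", sep = "")
  invisible(x)
}

#' Inject spectral and chemical outliers into a synthetic dataset
#'
#' Spectral outliers receive a large additive artifact on the spectrum:
#' either a localized Gaussian spike (default; survives scatter-correcting
#' preprocessing, as instrument artifacts do) or a gross flat offset.
#' Chemical outliers have their recorded reference protein value perturbed
#' by the stated magnitude with alternating sign, emulating reference-method
#' blunders well above the 0.4% residual gate. Provenance is recorded in
#' \code{$outliers}.
#'
#' @param dataset a \code{synthetic_dataset}.
#' @param spectral_idx,chemical_idx disjoint integer index sets (may be
#'   empty).
#' @param spectral_magnitude artifact peak height (AU), default 1.0.
#' @param chemical_magnitude absolute protein perturbation (%), default 2.0.
#' @param artifact \code{"spike"} or \code{"offset"}.
#' @param seed seed for spike placement; defaults to \code{config$seed + 2}.
#' @return The modified \code{synthetic_dataset}.
#' @export
inject_outliers <- function(dataset, spectral_idx = integer(),
                            chemical_idx = integer(),
                            spectral_magnitude = 1.0,
                            chemical_magnitude = 2.0,
                            artifact = c("spike", "offset"),
                            seed = NULL) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  artifact <- match.arg(artifact)
  n <- nrow(dataset$spectra$absorbance)
  spectral_idx <- as.integer(spectral_idx)
  chemical_idx <- as.integer(chemical_idx)
  all_idx <- c(spectral_idx, chemical_idx)
  if (length(all_idx) && (min(all_idx) < 1 || max(all_idx) > n))
    stop("outlier index out of range 1..", n, call. = FALSE)
  if (length(intersect(spectral_idx, chemical_idx)))
    stop("spectral and chemical index sets must be disjoint", call. = FALSE)
  if (!length(all_idx)) return(dataset)
  if (is.null(seed)) seed <- dataset$config$seed + 2L
  set.seed(seed)

  wl <- dataset$spectra$wavelengths_nm
  A <- dataset$spectra$absorbance
  for (i in spectral_idx) {
    if (artifact == "spike") {
      center <- stats::runif(1, min(wl) + 50, max(wl) - 50)
      A[i, ] <- A[i, ] + spectral_magnitude * gaussian_band(wl, center, 20)
    } else {
      A[i, ] <- A[i, ] + spectral_magnitude
    }
  }
  dataset$spectra <- spectra_matrix(A, wl, dataset$spectra$sample_ids)
  if (length(chemical_idx)) {
    signs <- rep_len(c(1, -1), length(chemical_idx))
    dataset$samples$protein_pct[chemical_idx] <-
      dataset$samples$protein_pct[chemical_idx] + signs * chemical_magnitude
  }
  dataset$outliers <- rbind(
    dataset$outliers,
    data.frame(index = c(spectral_idx, chemical_idx),
               kind = c(rep("spectral", length(spectral_idx)),
                        rep("chemical", length(chemical_idx))),
               magnitude = c(rep(spectral_magnitude, length(spectral_idx)),
                             rep(chemical_magnitude, length(chemical_idx)))))
  dataset
}
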