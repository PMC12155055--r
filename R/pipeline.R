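# End-to-end pipeline: simulate/load -> two-stage screen -> SPXY split ->
# preprocessing-chain grid -> PLSR (one-SE latent variables) -> metric grid.

#' The default preprocessing-chain grid
#'
#' The eleven chains assessed per kernel state: raw spectra, each single
#' operator, and the three derivative/smoothing + SNV combinations.
#'
#' @return Character vector of chain labels.
#' @export
default_chain_grid <- function() {
  c("Original", "1Der", "2Der", "SG", "Normalize", "Baseline", "SNV",
    "MSC", "1Der+SNV", "2Der+SNV", "SG+SNV")
}

#' Model label in the field's naming scheme
#'
#' \code{"<chain>-PLSR-<state code>"} with \code{+} replaced by \code{-}
#' and state codes S (shell), WS (without shell / deshelled), G (granules):
#' e.g. chain \code{"1Der+SNV"} on granules gives
#' \code{"1Der-SNV-PLSR-G"}.
#'
#' @param chain chain label.
#' @param state kernel state.
#' @return Character label.
#' @export
model_label <- function(chain, state) {
  code <- switch(state, shell = "S", deshelled = "WS", granules = "G",
                 stop("unknown state '", state, "'", call. = FALSE))
  paste0(gsub("+", "-", chain, fixed = TRUE), "-PLSR-", code)
}

#' Fit and evaluate one preprocessing chain on a fixed split
#'
#' Applies the chain to the retained spectra, fits PLSR on the calibration
#' rows (latent variables by the one-SE rule unless \code{ncomp} is given),
#' predicts both sets, and returns the full \code{\link{eval_report}}.
#'
#' @param chain chain label.
#' @param spectra \code{\link{spectra_matrix}} of retained samples.
#' @param y measured protein (%), retained samples.
#' @param split a \code{\link{spxy_split}} on the same samples.
#' @param ncomp fixed latent-variable count, or \code{NULL} for one-SE
#'   selection.
#' @param max_ncomp,folds,seed cross-validation design.
#' @return List with \code{model} (\code{nir_plsr}) and \code{report}
#'   (\code{eval_report}).
#' @export
evaluate_chain <- function(chain, spectra, y, split, ncomp = NULL,
                           max_ncomp = 12, folds = 10, seed = 1) {
  pre <- apply_chain(chain, spectra)
  cal <- split$calibration; prd <- split$prediction
  model <- nir_plsr(pre[cal], y[cal], ncomp = ncomp, max_ncomp = max_ncomp,
                    folds = folds, seed = seed, chain = parse_chain(chain)$label)
  rep <- eval_report(y[cal], predict(model),
                     y[prd], predict(model, pre[prd]),
                     chain = parse_chain(chain)$label, ncomp = model$ncomp)
  list(model = model, report = rep)
}

#' Run configuration for the full pipeline
#'
#' @param synthetic a \code{\link{synthetic_config}}, or \code{NULL} when
#'   \code{input_csv} is given.
#' @param input_csv path to a wide spectra CSV (see
#'   \code{\link{read_spectra_csv}}); used when \code{synthetic} is NULL.
#' @param state kernel state label (taken from \code{synthetic} if given).
#' @param pca_k PCA components for the Mahalanobis screen.
#' @param pca_chain preprocessing before PCA; \code{NULL} = state default.
#' @param residual_threshold chemical outlier gate (%).
#' @param split_ratio calibration fraction.
#' @param chains chain grid to evaluate.
#' @param max_ncomp,cv_folds PLSR selection design.
#' @param seed master seed (mandatory); all stage seeds derive from it.
#' @param output_dir optional directory for report files.
#' @return An object of class \code{run_config}.
#' @export
run_config <- function(synthetic = synthetic_config(), input_csv = NULL,
                       state = NULL, pca_k = 4, pca_chain = NULL,
                       residual_threshold = 0.4, split_ratio = 0.75,
                       chains = default_chain_grid(), max_ncomp = 12,
                       cv_folds = 10, seed = NULL, output_dir = NULL) {
  if (is.null(seed)) {
    if (!is.null(synthetic)) seed <- synthetic$seed
    else stop("seed is mandatory", call. = FALSE)
  }
  if (is.null(state))
    state <- if (!is.null(synthetic)) synthetic$state else "granules"
  structure(list(synthetic = synthetic, input_csv = input_csv,
                 state = state, pca_k = pca_k, pca_chain = pca_chain,
                 residual_threshold = residual_threshold,
                 split_ratio = split_ratio, chains = chains,
                 max_ncomp = max_ncomp, cv_folds = cv_folds,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

#' Run the full calibration pipeline
#'
#' Stages, in order: (1) simulate or load the dataset; (2) two-stage
#' outlier screen (PCA-MD gate, then concentration residuals); (3) SPXY
#' 3:1 split of the retained samples, computed on the state-default
#' preprocessed spectra so the whole chain grid shares one split, as in a
#' per-state study design; (4) for every chain in the grid, PLSR with
#' one-SE latent-variable selection and full evaluation; (5) ranked metric
#' grid. When \code{output_dir} is set, the outlier report, split listing,
#' metric grid and a manifest echoing the resolved configuration are
#' written there, and reruns from the same manifest are byte-identical.
#'
#' @param config a \code{\link{run_config}}.
#' @return An object of class \code{nir_run}: \code{dataset},
#'   \code{screen}, \code{split}, \code{split_summary}, \code{results}
#'   (list of per-chain model/report), \code{grid} (ranked data frame),
#'   \code{best} (label of the top chain), \code{config}.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  # stage 1: data
  if (!is.null(config$synthetic)) {
    dataset <- simulate_nir_dataset(config$synthetic)
  } else {
    io <- read_spectra_csv(config$input_csv)
    dataset <- list(spectra = io$spectra, samples = io$samples,
                    config = list(state = config$state, seed = config$seed))
  }
  spectra <- dataset$spectra
  y <- dataset$samples$protein_pct
  pca_chain <- if (is.null(config$pca_chain))
    state_pca_chain(config$state) else config$pca_chain

  # stage 2: two-stage outlier screen
  screen <- screen_outliers(spectra, y, pca_chain = pca_chain,
                            k = config$pca_k,
                            residual_threshold = config$residual_threshold,
                            max_ncomp = config$max_ncomp,
                            folds = config$cv_folds, seed = config$seed)
  keep <- screen$retained
  spec_r <- spectra[keep]
  y_r <- y[keep]

  # stage 3: SPXY split in the state-default preprocessed space
  split <- spxy_split(apply_chain(pca_chain, spec_r), y_r,
                      ratio = config$split_ratio)
  split_summary <- data.frame(
    set = c("calibration", "prediction"),
    n = c(length(split$calibration), length(split$prediction)),
    min = c(min(y_r[split$calibration]), min(y_r[split$prediction])),
    max = c(max(y_r[split$calibration]), max(y_r[split$prediction])),
    mean = c(mean(y_r[split$calibration]), mean(y_r[split$prediction])),
    sd = c(stats::sd(y_r[split$calibration]),
           stats::sd(y_r[split$prediction])))

  # stage 4: chain grid
  results <- lapply(config$chains, function(ch)
    evaluate_chain(ch, spec_r, y_r, split, max_ncomp = config$max_ncomp,
                   folds = config$cv_folds, seed = config$seed))
  names(results) <- config$chains

  # stage 5: ranked grid
  grid <- grid_report(lapply(results, `[[`, "report"), config$state)

  run <- structure(list(dataset = dataset, screen = screen, split = split,
                        split_summary = split_summary, results = results,
                        grid = grid, best = grid$label[1], config = config),
                   class = "nir_run")
  if (!is.null(config$output_dir)) write_run(run, config$output_dir)
  run
}

#' Ranked metric grid across preprocessing chains
#'
#' Rows sorted by prediction-set determination coefficient (Rp2),
#' descending; each row is labelled with the field's model naming scheme
#' (\code{\link{model_label}}).
#'
#' @param reports list of \code{\link{eval_report}} objects.
#' @param state kernel state for the labels.
#' @return Data frame with columns chain, ncomp, r2_cal, rmsec, r2_pred,
#'   rmsep, rpd, rer, label, ordered best first.
#' @export
grid_report <- function(reports, state) {
  stopifnot(length(reports) >= 1)
  grid <- do.call(rbind, lapply(reports, as.data.frame))
  grid$label <- vapply(grid$chain, model_label, "", state = state)
  grid <- grid[order(-grid$r2_pred), ]
  rownames(grid) <- NULL
  grid
}

#' @export
print.nir_run <- function(x, ...) {
  cat("NIR protein calibration run (state: ", x$config$state, ", seed ",
      x$config$seed, ")\n", sep = "")
  cat("  screened out: ", length(x$screen$md_flagged), " spectral + ",
      length(x$screen$residual_flagged), " chemical of ",
      length(x$screen$md_values), " samples\n", sep = "")
  cat("  split: ", length(x$split$calibration), " calibration / ",
      length(x$split$prediction), " prediction\n", sep = "")
  best <- x$grid[1, ]
  cat(sprintf("  best model %s: Rp2 %.2f, RMSEP %.2f, RPD %.2f, RER %.2f\n",
              best$label, best$r2_pred, best$rmsep, best$rpd, best$rer))
  invisible(x)
}

#' @export
summary.nir_run <- function(object, ...) {
  print(object)
  cat("\nMetric grid (2 dp, ranked by Rp2):\n")
  g <- object$grid
  g[, c("r2_cal", "rmsec", "r2_pred", "rmsep", "rpd", "rer")] <-
    round(g[, c("r2_cal", "rmsec", "r2_pred", "rmsep", "rpd", "rer")], 2)
  print(g, row.names = FALSE)
  invisible(object)
}

# serialize all run artifacts; numeric tables rounded to 2 dp at write time
write_run <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_outlier_report(run$screen, file.path(dir, "outliers.csv"))
  ids <- run$dataset$samples$sample_id[run$screen$retained]
  split_table(run$split, ids, file.path(dir, "split.csv"))
  sm <- run$split_summary
  sm[, c("min", "max", "mean", "sd")] <- round(sm[, c("min", "max", "mean", "sd")], 2)
  utils::write.csv(sm, file.path(dir, "split_summary.csv"), row.names = FALSE)
  g <- run$grid
  g[, c("r2_cal", "rmsec", "r2_pred", "rmsep", "rpd", "rer")] <-
    round(g[, c("r2_cal", "rmsec", "r2_pred", "rmsep", "rpd", "rer")], 2)
  utils::write.csv(g, file.path(dir, "metrics.csv"), row.names = FALSE)
  cfg <- run$config
  cfg$synthetic <- if (!is.null(cfg$synthetic)) unclass(cfg$synthetic)
  jsonlite::write_json(list(config = unclass(cfg),
                            best = run$best,
                            retained = run$screen$retained),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
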