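# Two-stage outlier screening: PCA-score Mahalanobis distance with a robust
# median + 3*MAD gate, then concentration residuals against a 0.4% gate.

#' PCA scores of a spectra matrix
#'
#' Column-mean-centered PCA (via \code{prcomp}); scores are projections on
#' the top-k right singular directions. The sign of each component is fixed
#' so that its largest-magnitude loading element is positive, making score
#' signs reproducible across platforms.
#'
#' @param spectra a \code{\link{spectra_matrix}} or numeric matrix.
#' @param k number of components to keep (default 4, the count used for
#'   the Mahalanobis screen).
#' @param chain optional preprocessing label recorded on the result.
#' @return An object of class \code{pca_scores}: \code{scores} (n x k),
#'   \code{explained_variance_ratio}, \code{loadings}, \code{chain}.
#' @export
pca_scores <- function(spectra, k = 4, chain = NULL) {
  X <- if (inherits(spectra, "spectra_matrix")) spectra$absorbance else as.matrix(spectra)
  n <- nrow(X); m <- ncol(X)
  if (k < 1 || k >= min(n, m))
    stop("k must satisfy 1 <= k < min(n, m) = ", min(n, m), call. = FALSE)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  scores <- pc$x[, 1:k, drop = FALSE]
  load <- pc$rotation[, 1:k, drop = FALSE]
  flip <- vapply(seq_len(k), function(j)
    sign(load[which.max(abs(load[, j])), j]), 0)
  flip[flip == 0] <- 1
  scores <- sweep(scores, 2, flip, `*`)
  load <- sweep(load, 2, flip, `*`)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores,
                 explained_variance_ratio = evr[1:k],
                 loadings = load, chain = chain),
            class = "pca_scores")
}

#' Mahalanobis distance of each sample in PCA score space
#'
#' \eqn{MD_i = \sqrt{(s_i - \bar s)^\top \Sigma^{-1} (s_i - \bar s)}} with
#' \eqn{\bar s} the score centroid and \eqn{\Sigma} the sample covariance
#' of the scores. A near-singular covariance is ridge-regularized by
#' \code{1e-10 * trace / k} on the diagonal (recorded in attribute
#' \code{"regularized"}).
#'
#' @param scores a \code{pca_scores} object or numeric score matrix.
#' @return Numeric vector of distances.
#' @export
mahalanobis_distances <- function(scores) {
  S <- if (inherits(scores, "pca_scores")) scores$scores else as.matrix(scores)
  ctr <- colMeans(S)
  Sig <- stats::cov(S)
  reg <- FALSE
  inv_try <- function(M) tryCatch(solve(M), error = function(e) NULL)
  if (is.null(inv_try(Sig)) || rcond(Sig) < 1e-12) {
    Sig <- Sig + diag(1e-10 * sum(diag(Sig)) / ncol(S), ncol(S))
    reg <- TRUE
    if (is.null(inv_try(Sig)))
      stop("score covariance singular even after regularization", call. = FALSE)
  }
  md <- sqrt(stats::mahalanobis(S, ctr, Sig))
  attr(md, "regularized") <- reg
  md
}

#' Robust Mahalanobis-distance gate
#'
#' Threshold = median(md) + 3 * MAD(md), with the raw (unscaled) median
#' absolute deviation \code{median(|md - median(md)|)}. Samples strictly
#' above the threshold are flagged as spectral outliers. A degenerate
#' all-equal spread (MAD = 0) flags nothing and warns.
#'
#' @param md numeric vector of Mahalanobis distances (length >= 4).
#' @return List with \code{threshold} and \code{flagged} (integer indices).
#' @export
md_gate <- function(md) {
  stopifnot(length(md) >= 4)
  med <- stats::median(md)
  mad0 <- stats::median(abs(md - med))
  if (mad0 == 0) {
    warning("MAD of Mahalanobis distances is zero; no samples flagged",
            call. = FALSE)
    return(list(threshold = Inf, flagged = integer()))
  }
  thr <- med + 3 * mad0
  list(threshold = thr, flagged = which(md > thr))
}

#' Concentration-residual gate for chemical outliers
#'
#' Flags samples whose absolute difference between measured and predicted
#' protein content strictly exceeds the threshold (default 0.4%).
#'
#' @param measured,predicted numeric vectors (%), equal length.
#' @param threshold gate in protein percentage points.
#' @return Integer vector of flagged indices.
#' @export
residual_gate <- function(measured, predicted, threshold = 0.4) {
  stopifnot(length(measured) == length(predicted))
  which(abs(measured - predicted) > threshold)
}

# study defaults: preprocessing applied before PCA, per kernel state
state_pca_chain <- function(state) {
  switch(state, shell = "Normalize", deshelled = "MSC", granules = "SNV",
         stop("unknown state '", state, "'", call. = FALSE))
}

#' Two-stage outlier screen
#'
#' Stage 1 (spectral): the spectra are preprocessed with the state-default
#' chain (Normalize for in-shell, MSC for deshelled, SNV for granules,
#' overridable), PCA scores of the top \code{k} components are computed,
#' and samples failing the median + 3*MAD Mahalanobis gate are removed.
#' Stage 2 (chemical): on the survivors, a preliminary PLSR (latent
#' variables by the one-SE rule) produces 10-fold cross-validated
#' predictions, and samples whose absolute concentration residual exceeds
#' 0.4% are removed. The report keeps the two stages separate.
#'
#' @param spectra a \code{\link{spectra_matrix}}, or a
#'   \code{synthetic_dataset} (in which case \code{y} is taken from it).
#' @param y measured protein values (%), one per sample.
#' @param pca_chain preprocessing chain label for the PCA stage;
#'   \code{NULL} picks the state default (for a synthetic dataset) or
#'   \code{"SNV"}. Use \code{"Original"} to screen raw spectra.
#' @param k PCA components used for the Mahalanobis screen (default 4).
#' @param residual_threshold chemical gate (%), default 0.4.
#' @param max_ncomp,folds,seed preliminary-PLSR cross-validation design.
#' @return An object of class \code{outlier_report}: \code{md_values},
#'   \code{md_threshold}, \code{md_flagged}, \code{residuals} (full-length,
#'   NA at stage-1 removals), \code{residual_threshold},
#'   \code{residual_flagged}, \code{removed} (sorted union),
#'   \code{retained}, \code{pca} (the \code{pca_scores}), \code{sample_ids}.
#' @export
screen_outliers <- function(spectra, y = NULL, pca_chain = NULL, k = 4,
                            residual_threshold = 0.4, max_ncomp = 12,
                            folds = 10, seed = 1) {
  if (inherits(spectra, "synthetic_dataset")) {
    if (is.null(y)) y <- spectra$samples$protein_pct
    if (is.null(pca_chain)) pca_chain <- state_pca_chain(spectra$config$state)
    spectra <- spectra$spectra
  }
  stopifnot(inherits(spectra, "spectra_matrix"), !is.null(y))
  n <- nrow(spectra$absorbance)
  stopifnot(length(y) == n)
  if (is.null(pca_chain)) pca_chain <- "SNV"

  pre <- apply_chain(pca_chain, spectra)
  pca <- pca_scores(pre, k = k, chain = pca_chain)
  md <- mahalanobis_distances(pca)
  gate <- md_gate(md)
  md_flagged <- gate$flagged

  survivors <- setdiff(seq_len(n), md_flagged)
  resid_full <- rep(NA_real_, n)
  cvfit <- plsr_cv(pre$absorbance[survivors, , drop = FALSE], y[survivors],
                   max_ncomp = max_ncomp, folds = folds, seed = seed)
  # out-of-fold predictions at the one-SE component count
  pred <- cvfit$predictions[, cvfit$ncomp_1se]
  resid_full[survivors] <- y[survivors] - pred
  res_flagged <- survivors[residual_gate(y[survivors], pred,
                                         residual_threshold)]

  structure(list(md_values = md, md_threshold = gate$threshold,
                 md_flagged = md_flagged,
                 residuals = resid_full,
                 residual_threshold = residual_threshold,
                 residual_flagged = res_flagged,
                 removed = sort(union(md_flagged, res_flagged)),
                 retained = setdiff(seq_len(n),
                                    sort(union(md_flagged, res_flagged))),
                 pca = pca, pca_chain = pca_chain,
                 sample_ids = spectra$sample_ids),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("Two-stage outlier screen (PCA chain: ", x$pca_chain, ")\n", sep = "")
  cat("  PCA-MD gate (median + 3*MAD = ", round(x$md_threshold, 3), "): ",
      length(x$md_flagged), " flagged",
      if (length(x$md_flagged))
        paste0(" [", paste(x$sample_ids[x$md_flagged], collapse = ", "), "]"),
      "\n", sep = "")
  cat("  residual gate (|residual| > ", x$residual_threshold, "%): ",
      length(x$residual_flagged), " flagged",
      if (length(x$residual_flagged))
        paste0(" [", paste(x$sample_ids[x$residual_flagged], collapse = ", "), "]"),
      "\n", sep = "")
  cat("  retained: ", length(x$retained), " of ", length(x$md_values),
      "\n", sep = "")
  invisible(x)
}

#' Serialize an outlier report
#'
#' \code{as.data.frame} gives the two-column (stage, sample_id) layout;
#' \code{write_outlier_report} writes it as CSV or JSON by extension.
#'
#' @param x an \code{outlier_report}.
#' @param ... ignored.
#' @export
as.data.frame.outlier_report <- function(x, ...) {
  data.frame(stage = c(rep("PCA-MD", length(x$md_flagged)),
                       rep("Concentration residual",
                           length(x$residual_flagged))),
             sample_id = c(x$sample_ids[x$md_flagged],
                           x$sample_ids[x$residual_flagged]))
}

#' @rdname as.data.frame.outlier_report
#' @param report an \code{outlier_report}.
#' @param path output file, \code{.csv} or \code{.json}.
#' @export
write_outlier_report <- function(report, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(
      md_threshold = report$md_threshold,
      md_flagged = report$sample_ids[report$md_flagged],
      residual_threshold = report$residual_threshold,
      residual_flagged = report$sample_ids[report$residual_flagged],
      removed = report$sample_ids[report$removed]),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  }
  invisible(path)
}
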