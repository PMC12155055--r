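# SPXY calibration/prediction partitioning: Kennard-Stone selection on the
# normalized joint spectral + response distance.

#' Calibration-set size under the 3:1 rounding rule
#'
#' Nearest integer with halves rounding up: \code{floor(ratio * n + 0.5)}.
#' With the study's counts, 113 retained samples at ratio 0.75 give 85
#' calibration / 28 prediction samples and 112 give 84 / 28.
#'
#' @param n_retained number of samples after outlier screening.
#' @param ratio calibration fraction (default 0.75, i.e. 3:1).
#' @return Named integer vector \code{c(calibration =, prediction =)}.
#' @export
split_sizes <- function(n_retained, ratio = 0.75) {
  n_cal <- as.integer(floor(ratio * n_retained + 0.5))
  c(calibration = n_cal, prediction = as.integer(n_retained) - n_cal)
}

#' SPXY partitioning into calibration and prediction sets
#'
#' Joint distance \eqn{d(i,j) = d_x(i,j)/\max d_x + d_y(i,j)/\max d_y}
#' with Euclidean \eqn{d_x} on the spectra and \eqn{|y_i - y_j|} on the
#' response. Selection is Kennard-Stone on \eqn{d}: seed with the pair at
#' maximal joint distance, then repeatedly add the sample whose minimum
#' distance to the already-selected set is largest, until the calibration
#' size is reached. Ties break to the lowest index, so the split is fully
#' deterministic.
#'
#' @param spectra a \code{\link{spectra_matrix}} or numeric matrix
#'   (typically the preprocessed spectra used for modeling).
#' @param y numeric response vector (%), nonconstant.
#' @param ratio calibration fraction (default 0.75).
#' @return An object of class \code{spxy_split}: \code{calibration},
#'   \code{prediction} (integer index vectors), \code{ratio}.
#' @export
spxy_split <- function(spectra, y, ratio = 0.75) {
  X <- if (inherits(spectra, "spectra_matrix")) spectra$absorbance else as.matrix(spectra)
  y <- as.numeric(y)
  n <- nrow(X)
  stopifnot(length(y) == n)
  if (n < 4) stop("need at least 4 samples to split", call. = FALSE)
  dx <- as.matrix(stats::dist(X))
  dy <- abs(outer(y, y, `-`))
  if (max(dx) == 0) stop("degenerate spectra: all pairwise distances zero",
                         call. = FALSE)
  if (max(dy) == 0) stop("degenerate response: y is constant", call. = FALSE)
  d <- dx / max(dx) + dy / max(dy)

  n_cal <- split_sizes(n, ratio)[["calibration"]]
  # seed: pair at maximal joint distance, lowest indices on ties
  hit <- which(d == max(d), arr.ind = TRUE)
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
  sel <- sort(as.integer(hit[1, ]))
  min_d <- pmin(d[, sel[1]], d[, sel[2]])
  while (length(sel) < n_cal) {
    min_d[sel] <- -Inf
    nxt <- as.integer(which.max(min_d))  # first (lowest index) wins ties
    sel <- c(sel, nxt)
    min_d <- pmin(min_d, d[, nxt])
  }
  structure(list(calibration = as.integer(sort(sel)),
                 prediction = setdiff(seq_len(n), sel),
                 ratio = ratio),
            class = "spxy_split")
}

#' @export
print.spxy_split <- function(x, ...) {
  cat("SPXY split: ", length(x$calibration), " calibration / ",
      length(x$prediction), " prediction (ratio ", x$ratio, ")\n", sep = "")
  invisible(x)
}

#' Serialize a split as a (sample_id, set) table
#'
#' @param split a \code{spxy_split}.
#' @param sample_ids identifiers for all retained samples, in index order.
#' @param path optional CSV path; when given the table is also written.
#' @return Data frame with columns \code{sample_id}, \code{set}.
#' @export
split_table <- function(split, sample_ids, path = NULL) {
  n <- length(split$calibration) + length(split$prediction)
  stopifnot(length(sample_ids) == n)
  set <- rep("prediction", n)
  set[split$calibration] <- "calibration"
  df <- data.frame(sample_id = sample_ids, set = set)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
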