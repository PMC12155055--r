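# NIPALS partial least squares regression for a univariate response,
# with cross-validated latent-variable selection by the one-SE rule.

# Core NIPALS factorization on centered X, y. Returns weights W, x-loadings
# P, y-loadings q, scores T for up to ncomp components; stops early (with a
# warning) if a weight vector's norm vanishes.
nipals_pls <- function(Xc, yc, ncomp, tol = 1e-10, max_iter = 500) {
  n <- nrow(Xc); m <- ncol(Xc)
  W <- P <- matrix(0, m, ncomp)
  Tm <- matrix(0, n, ncomp)
  q <- numeric(ncomp)
  X <- Xc; y <- yc
  A <- 0
  for (a in seq_len(ncomp)) {
    u <- y
    w_old <- rep(0, m)
    for (it in seq_len(max_iter)) {
      w <- as.vector(crossprod(X, u))
      nw <- sqrt(sum(w^2))
      if (nw < tol) break
      w <- w / nw
      tt <- as.vector(X %*% w)
      qq <- sum(y * tt) / sum(tt * tt)
      u_new <- y * qq
      if (sqrt(sum((w - w_old)^2)) < tol) { u <- u_new; break }
      w_old <- w; u <- u_new
    }
    if (nw < tol || sum(tt^2) < tol) {
      warning("component ", a, " has vanishing weight norm; returning ",
              a - 1, " components", call. = FALSE)
      break
    }
    p <- as.vector(crossprod(X, tt)) / sum(tt * tt)
    W[, a] <- w; P[, a] <- p; Tm[, a] <- tt; q[a] <- qq
    X <- X - tcrossprod(tt, p)
    y <- y - qq * tt
    A <- a
  }
  if (A == 0) stop("no PLS component could be extracted", call. = FALSE)
  list(W = W[, 1:A, drop = FALSE], P = P[, 1:A, drop = FALSE],
       scores = Tm[, 1:A, drop = FALSE], q = q[1:A], ncomp = A)
}

# Collapsed regression coefficients for centered data:
# B = W (P'W)^{-1} q, so yhat = y_mean + (X - x_mean) B.
pls_coefficients <- function(fac, ncomp = fac$ncomp) {
  W <- fac$W[, 1:ncomp, drop = FALSE]
  P <- fac$P[, 1:ncomp, drop = FALSE]
  as.vector(W %*% solve(crossprod(P, W), fac$q[1:ncomp]))
}

#' Select the latent-variable count by the one-standard-error rule
#'
#' Given the cross-validated RMSE curve and its per-size standard errors,
#' returns the smallest component count whose RMSECV is within one standard
#' error of the minimum: \eqn{\min \{A : RMSECV(A) \le RMSECV(A^*) +
#' SE(A^*)\}} with \eqn{A^*} the argmin.
#'
#' @param rmsecv numeric vector of cross-validated RMSE, index = component
#'   count.
#' @param se numeric vector of standard errors, same length.
#' @return Integer component count.
#' @export
choose_ncomp_1se <- function(rmsecv, se) {
  stopifnot(length(rmsecv) == length(se), length(rmsecv) >= 1)
  a_star <- which.min(rmsecv)
  as.integer(min(which(rmsecv <= rmsecv[a_star] + se[a_star])))
}

#' Cross-validate a PLSR fit over component counts
#'
#' Venetian-blind fold assignment over a seeded random ordering of the
#' samples: after shuffling, sample i goes to fold \code{(i mod folds) + 1},
#' so folds are balanced and the design is deterministic under the seed.
#' RMSECV per component count is pooled over out-of-fold residuals; the
#' standard error is the sd of per-fold RMSEs divided by \code{sqrt(folds)}.
#'
#' @param X numeric matrix (or \code{spectra_matrix}) of predictors.
#' @param y numeric response vector (%).
#' @param max_ncomp largest component count to assess; capped (with a
#'   warning) at the largest count trainable in every fold.
#' @param folds number of folds (default 10).
#' @param seed integer seed for the fold shuffle.
#' @return List of class \code{plsr_cv}: \code{rmsecv}, \code{se} (vectors
#'   over 1..max_ncomp), \code{ncomp_1se}, \code{ncomp_min}, \code{folds},
#'   \code{assignments}.
#' @export
plsr_cv <- function(X, y, max_ncomp = 12, folds = 10, seed = 1) {
  if (inherits(X, "spectra_matrix")) X <- X$absorbance
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  stopifnot(length(y) == n, folds >= 2)
  if (n < folds) stop("need at least as many samples as folds", call. = FALSE)
  min_train <- n - ceiling(n / folds)
  cap <- min(min_train - 1, ncol(X))
  if (max_ncomp > cap) {
    warning("max_ncomp capped at ", cap, " by fold size", call. = FALSE)
    max_ncomp <- cap
  }
  set.seed(seed)
  ord <- sample.int(n)
  fold_id <- integer(n)
  fold_id[ord] <- rep_len(seq_len(folds), n)

  pred <- matrix(NA_real_, n, max_ncomp)
  for (f in seq_len(folds)) {
    tr <- which(fold_id != f); te <- which(fold_id == f)
    xm <- colMeans(X[tr, , drop = FALSE]); ym <- mean(y[tr])
    Xc <- sweep(X[tr, , drop = FALSE], 2, xm)
    fac <- nipals_pls(Xc, y[tr] - ym, max_ncomp)
    Xte <- sweep(X[te, , drop = FALSE], 2, xm)
    for (a in seq_len(fac$ncomp))
      pred[te, a] <- ym + as.vector(Xte %*% pls_coefficients(fac, a))
    if (fac$ncomp < max_ncomp)  # early stop: reuse the deepest model
      for (a in (fac$ncomp + 1):max_ncomp) pred[te, a] <- pred[te, fac$ncomp]
  }
  resid <- pred - y
  rmsecv <- sqrt(colMeans(resid^2))
  fold_rmse <- sapply(seq_len(folds), function(f)
    sqrt(colMeans(resid[fold_id == f, , drop = FALSE]^2)))
  se <- apply(matrix(fold_rmse, ncol = folds), 1, stats::sd) / sqrt(folds)
  structure(list(rmsecv = rmsecv, se = se,
                 ncomp_1se = choose_ncomp_1se(rmsecv, se),
                 ncomp_min = which.min(rmsecv),
                 folds = folds, assignments = fold_id,
                 predictions = pred),
            class = "plsr_cv")
}

#' @export
print.plsr_cv <- function(x, ...) {
  cat("PLSR cross-validation (", x$folds, "-fold):\n", sep = "")
  cat("  RMSECV min ", round(min(x$rmsecv), 4), " at A = ", x$ncomp_min,
      "; one-SE choice A = ", x$ncomp_1se, "\n", sep = "")
  invisible(x)
}

#' Fit a PLSR calibration model for protein content
#'
#' The central fitting function: NIPALS partial least squares regression of
#' a reference value (protein mass fraction, %) on preprocessed NIR
#' spectra. When \code{ncomp} is \code{NULL} the latent-variable count is
#' chosen by cross-validation with the one-standard-error rule
#' (\code{\link{choose_ncomp_1se}}); pass an integer to fix it.
#'
#' @param X a \code{\link{spectra_matrix}} or numeric matrix of predictors
#'   (already preprocessed; see \code{\link{apply_chain}}).
#' @param y numeric response vector (%).
#' @param ncomp latent-variable count, or \code{NULL} to select by
#'   cross-validation.
#' @param max_ncomp largest count considered during selection.
#' @param folds,seed cross-validation design (see \code{\link{plsr_cv}}).
#' @param chain optional chain label recorded as provenance.
#' @return An object of class \code{nir_plsr} with components
#'   \code{x_mean}, \code{y_mean}, \code{weights}, \code{x_loadings},
#'   \code{y_loadings}, \code{scores}, \code{coefficients} (collapsed,
#'   for centered data), \code{ncomp}, \code{cv} (a \code{plsr_cv} or
#'   \code{NULL}), \code{wavelengths_nm}, \code{fitted.values},
#'   \code{residuals}, \code{chain}.
#' @export
nir_plsr <- function(X, y, ncomp = NULL, max_ncomp = 12, folds = 10,
                     seed = 1, chain = NULL) {
  wl <- NULL
  if (inherits(X, "spectra_matrix")) {
    wl <- X$wavelengths_nm
    if (is.null(chain)) chain <- attr(X, "chain")
    X <- X$absorbance
  }
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  stopifnot(length(y) == n)
  if (stats::sd(y) == 0) stop("zero-variance response", call. = FALSE)

  cv <- NULL
  if (is.null(ncomp)) {
    cv <- plsr_cv(X, y, max_ncomp = max_ncomp, folds = folds, seed = seed)
    ncomp <- cv$ncomp_1se
  }
  ncomp <- as.integer(ncomp)
  if (n < ncomp + 1) stop("need at least ncomp + 1 samples", call. = FALSE)
  if (ncomp > min(n - 1, ncol(X)))
    stop("ncomp exceeds min(n - 1, m)", call. = FALSE)

  x_mean <- colMeans(X); y_mean <- mean(y)
  fac <- nipals_pls(sweep(X, 2, x_mean), y - y_mean, ncomp)
  beta <- pls_coefficients(fac)
  fitted <- y_mean + as.vector(sweep(X, 2, x_mean) %*% beta)
  structure(list(x_mean = x_mean, y_mean = y_mean,
                 weights = fac$W, x_loadings = fac$P,
                 y_loadings = fac$q, scores = fac$scores,
                 coefficients = beta, ncomp = fac$ncomp, cv = cv,
                 wavelengths_nm = wl, chain = chain,
                 fitted.values = fitted, residuals = y - fitted, y = y),
            class = "nir_plsr")
}

#' Predict protein content from spectra
#'
#' \eqn{\hat y = \bar y + (X - \bar x) B} with the collapsed regression
#' coefficients. When the model was trained on a \code{spectra_matrix},
#' the new spectra's wavelength axis must match the training axis.
#'
#' @param object a \code{nir_plsr} model.
#' @param newdata a \code{spectra_matrix} or numeric matrix; omit to return
#'   fitted values.
#' @param ... ignored.
#' @return Numeric vector of predicted protein values (%).
#' @export
predict.nir_plsr <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  if (inherits(newdata, "spectra_matrix")) {
    if (!is.null(object$wavelengths_nm) &&
        !isTRUE(all.equal(newdata$wavelengths_nm, object$wavelengths_nm)))
      stop("wavelength axis mismatch: model trained on ",
           length(object$wavelengths_nm), " points [",
           object$wavelengths_nm[1], "-",
           object$wavelengths_nm[length(object$wavelengths_nm)],
           " nm], new spectra have ", length(newdata$wavelengths_nm),
           " points [", newdata$wavelengths_nm[1], "-",
           newdata$wavelengths_nm[length(newdata$wavelengths_nm)], " nm]",
           call. = FALSE)
    newdata <- newdata$absorbance
  }
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_mean))
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         length(object$x_mean), call. = FALSE)
  object$y_mean + as.vector(sweep(newdata, 2, object$x_mean) %*%
                              object$coefficients)
}

#' @export
coef.nir_plsr <- function(object, intercept = FALSE, ...) {
  if (!intercept) return(object$coefficients)
  c(`(Intercept)` = object$y_mean -
      sum(object$x_mean * object$coefficients), object$coefficients)
}

#' @export
residuals.nir_plsr <- function(object, ...) object$residuals

#' @export
fitted.nir_plsr <- function(object, ...) object$fitted.values

#' @export
print.nir_plsr <- function(x, ...) {
  cat("NIPALS PLSR calibration\n")
  if (!is.null(x$chain)) cat("  preprocessing: ", x$chain, "\n", sep = "")
  cat("  latent variables: ", x$ncomp,
      if (!is.null(x$cv)) " (one-SE rule)", "\n", sep = "")
  cat("  training samples: ", length(x$y), ", predictors: ",
      length(x$x_mean), "\n", sep = "")
  cat("  RMSEC ", round(sqrt(mean(x$residuals^2)), 4), ", Rc2 ",
      round(r_squared(x$y, x$fitted.values), 4), "\n", sep = "")
  invisible(x)
}

#' @export
summary.nir_plsr <- function(object, ...) {
  print(object)
  if (!is.null(object$cv)) {
    cat("\nCross-validation:\n")
    tab <- data.frame(A = seq_along(object$cv$rmsecv),
                      RMSECV = round(object$cv$rmsecv, 4),
                      SE = round(object$cv$se, 4))
    print(tab, row.names = FALSE)
  }
  invisible(object)
}

#' Diagnostic plot for a fitted PLSR calibration
#'
#' Left panel: RMSECV against component count with the one-SE band (when
#' the model was cross-validated). Right panel: fitted against measured
#' values with the identity line.
#'
#' @param x a \code{nir_plsr} model.
#' @param ... passed to \code{plot}.
#' @export
plot.nir_plsr <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, if (is.null(x$cv)) 1 else 2))
  on.exit(graphics::par(op))
  if (!is.null(x$cv)) {
    graphics::plot(seq_along(x$cv$rmsecv), x$cv$rmsecv, type = "b",
                   xlab = "latent variables", ylab = "RMSECV (%)", ...)
    amin <- x$cv$ncomp_min
    graphics::abline(h = x$cv$rmsecv[amin] + x$cv$se[amin], lty = 2)
    graphics::points(x$ncomp, x$cv$rmsecv[x$ncomp], pch = 19)
  }
  graphics::plot(x$y, x$fitted.values, xlab = "measured protein (%)",
                 ylab = "fitted protein (%)", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
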