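# Model evaluation metrics for NIR calibration (Rc2/RMSEC on the
# calibration set, Rp2/RMSEP on the prediction set, RPD, RER) and the
# Kjeldahl reference-chemistry formula.

#' Protein mass fraction from Kjeldahl titration volumes
#'
#' \eqn{W = (v_1 - v_2) \cdot N \cdot 0.014 \cdot F / m \cdot 100}, where
#' 0.014 g/mmol is the millimolar mass of nitrogen and F the
#' nitrogen-to-protein conversion coefficient. A negative result (titration
#' inversion) is returned with a warning.
#'
#' @param v1 blank titration volume (mL).
#' @param v2 sample titration volume (mL).
#' @param N HCl standard solution concentration (mol/L).
#' @param F_coef protein conversion coefficient (dimensionless).
#' @param m sample mass (g), > 0.
#' @return Protein mass fraction (%).
#' @export
kjeldahl_protein <- function(v1, v2, N, F_coef, m) {
  if (any(m <= 0)) stop("sample mass must be positive", call. = FALSE)
  if (any(v1 < 0 | v2 < 0) || any(N <= 0))
    stop("volumes must be >= 0 and N > 0", call. = FALSE)
  W <- (v1 - v2) * N * 0.014 * F_coef / m * 100
  if (any(W < 0))
    warning("negative protein fraction: blank titration below sample ",
            "titration (titration inversion?)", call. = FALSE)
  W
}

#' Coefficient of determination
#'
#' \eqn{1 - \sum (p - \hat p)^2 / \sum (p - \bar p)^2}, with \eqn{\bar p}
#' the mean of the measured values of the set being evaluated. The same
#' formula serves the calibration set (Rc2) and the prediction set (Rp2).
#'
#' @param measured,predicted numeric vectors, equal length >= 2.
#' @return Scalar, at most 1.
#' @export
r_squared <- function(measured, predicted) {
  stopifnot(length(measured) == length(predicted), length(measured) >= 2)
  ss_tot <- sum((measured - mean(measured))^2)
  if (ss_tot == 0) stop("zero variance in measured values", call. = FALSE)
  1 - sum((measured - predicted)^2) / ss_tot
}

#' Root mean square error
#'
#' \eqn{\sqrt{\sum (p - \hat p)^2 / n}} — division by n, not n-1, following
#' the calibration-literature convention (RMSEC/RMSEP).
#'
#' @param measured,predicted numeric vectors, equal length.
#' @return Scalar (%), >= 0.
#' @export
rmse <- function(measured, predicted) {
  stopifnot(length(measured) == length(predicted), length(measured) >= 1)
  sqrt(mean((measured - predicted)^2))
}

#' Ratio of performance to deviation (RPD)
#'
#' Sample standard deviation (n-1) of the measured prediction-set values
#' divided by RMSEP. Either the measured vector or a precomputed SD may be
#' supplied, so the ratio can also be checked directly from reported
#' summary tables. Values above 2.5 are conventionally taken as good
#' quantitative performance.
#'
#' @param measured measured prediction-set values (%), length >= 2; ignored
#'   when \code{sd} is given.
#' @param rmsep root mean square error of prediction, > 0.
#' @param sd optional precomputed standard deviation (%).
#' @return Scalar ratio.
#' @export
rpd <- function(measured = NULL, rmsep, sd = NULL) {
  if (rmsep <= 0) stop("rmsep must be > 0", call. = FALSE)
  if (is.null(sd)) {
    stopifnot(length(measured) >= 2)
    sd <- stats::sd(measured)
  }
  sd / rmsep
}

#' Ratio of error range (RER)
#'
#' Range (max - min) of the measured prediction-set values divided by
#' RMSEP. As with \code{\link{rpd}}, a precomputed range may be supplied.
#' Values above 15 are conventionally taken as good.
#'
#' @param measured measured prediction-set values (%), length >= 2; ignored
#'   when \code{range} is given.
#' @param rmsep root mean square error of prediction, > 0.
#' @param range optional precomputed range (%).
#' @return Scalar ratio.
#' @export
rer <- function(measured = NULL, rmsep, range = NULL) {
  if (rmsep <= 0) stop("rmsep must be > 0", call. = FALSE)
  if (is.null(range)) {
    stopifnot(length(measured) >= 2)
    range <- max(measured) - min(measured)
  }
  range / rmsep
}

#' Slope and bias of the prediction fit
#'
#' Least-squares line \code{predicted ~ measured}; bias is the mean
#' difference \code{mean(predicted - measured)}.
#'
#' @param measured,predicted numeric vectors, equal length >= 2,
#'   nonconstant \code{measured}.
#' @return Named numeric vector \code{c(slope =, bias =)}.
#' @export
prediction_fit <- function(measured, predicted) {
  stopifnot(length(measured) == length(predicted), length(measured) >= 2)
  if (stats::sd(measured) == 0)
    stop("constant measured values: slope undefined", call. = FALSE)
  fit <- stats::lm(predicted ~ measured)
  c(slope = unname(stats::coef(fit)[2]),
    bias = mean(predicted - measured))
}

#' Full evaluation report for one calibration model
#'
#' Computes the complete metric suite from calibration- and prediction-set
#' measured/predicted pairs: Rc2, RMSEC, Rp2, RMSEP, RPD, RER, the
#' prediction-set summary statistics they derive from, and the slope/bias
#' of the prediction fit. Values are kept at full precision; rounding to
#' two decimals happens only at serialization.
#'
#' @param cal_measured,cal_predicted calibration-set vectors (%).
#' @param pred_measured,pred_predicted prediction-set vectors (%).
#' @param chain preprocessing chain label (provenance).
#' @param ncomp latent-variable count (provenance).
#' @return An object of class \code{eval_report} (a list).
#' @export
eval_report <- function(cal_measured, cal_predicted,
                        pred_measured, pred_predicted,
                        chain = NULL, ncomp = NA_integer_) {
  rmsep <- rmse(pred_measured, pred_predicted)
  fit <- prediction_fit(pred_measured, pred_predicted)
  structure(list(
    chain = chain, ncomp = ncomp,
    n_cal = length(cal_measured), n_pred = length(pred_measured),
    r2_cal = r_squared(cal_measured, cal_predicted),
    rmsec = rmse(cal_measured, cal_predicted),
    r2_pred = r_squared(pred_measured, pred_predicted),
    rmsep = rmsep,
    sd_pred_measured = stats::sd(pred_measured),
    range_pred_measured = max(pred_measured) - min(pred_measured),
    rpd = rpd(pred_measured, rmsep),
    rer = rer(pred_measured, rmsep),
    slope = unname(fit["slope"]), bias = unname(fit["bias"])),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Model evaluation", if (!is.null(x$chain)) paste0(" [", x$chain, "]"),
      ":\n", sep = "")
  cat(sprintf("  calibration (n=%d): Rc2 %.2f, RMSEC %.2f\n",
              x$n_cal, x$r2_cal, x$rmsec))
  cat(sprintf("  prediction  (n=%d): Rp2 %.2f, RMSEP %.2f, RPD %.2f, RER %.2f\n",
              x$n_pred, x$r2_pred, x$rmsep, x$rpd, x$rer))
  cat(sprintf("  prediction fit: slope %.2f, bias %.2f\n", x$slope, x$bias))
  invisible(x)
}

#' @export
as.data.frame.eval_report <- function(x, ...) {
  data.frame(chain = if (is.null(x$chain)) NA_character_ else x$chain,
             ncomp = x$ncomp,
             r2_cal = x$r2_cal, rmsec = x$rmsec,
             r2_pred = x$r2_pred, rmsep = x$rmsep,
             rpd = x$rpd, rer = x$rer)
}
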