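#' Standard normal variate (SNV)
#'
#' Standardizes each spectrum independently: subtract the row mean, divide
#' by the row sample standard deviation (n-1 denominator). Removes
#' per-spectrum additive offsets and multiplicative scaling — the classic
#' scatter correction that needs no reference spectrum.
#'
#' @param spectra a \code{\link{spectra_matrix}}.
#' @return A \code{spectra_matrix}; every row has mean 0 and sd 1.
#' @export
snv <- function(spectra) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  A <- spectra$absorbance
  mu <- rowMeans(A)
  s <- apply(A, 1, stats::sd)
  bad <- which(s == 0)
  if (length(bad))
    stop("SNV undefined for constant spectrum: sample ",
         paste(spectra$sample_ids[bad], collapse = ", "), call. = FALSE)
  spectra_matrix((A - mu) / s, spectra$wavelengths_nm, spectra$sample_ids)
}

#' Multiplicative scatter correction (MSC)
#'
#' Regresses each spectrum on a reference spectrum (default: the column-wise
#' mean of the input), \eqn{x \approx a + b \cdot ref}, and returns
#' \eqn{(x - a)/b}. Inverts per-spectrum affine scatter distortions exactly
#' when the reference is held fixed.
#'
#' @param spectra a \code{\link{spectra_matrix}}.
#' @param reference optional numeric reference spectrum (length m); default
#'   is the mean spectrum of \code{spectra}.
#' @param tol minimum |b| accepted before declaring the spectrum orthogonal
#'   to the reference.
#' @return A \code{spectra_matrix} with attribute \code{"msc_reference"}
#'   recording the reference used.
#' @export
msc <- function(spectra, reference = NULL, tol = 1e-12) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  A <- spectra$absorbance
  if (is.null(reference)) {
    if (nrow(A) < 2)
      stop("MSC needs >= 2 spectra when no reference is supplied", call. = FALSE)
    reference <- colMeans(A)
  }
  if (length(reference) != ncol(A))
    stop("reference length does not match wavelength axis", call. = FALSE)
  rc <- reference - mean(reference)
  denom <- sum(rc^2)
  if (denom == 0) stop("constant reference spectrum", call. = FALSE)
  b <- as.vector((A - rowMeans(A)) %*% rc) / denom
  if (any(abs(b) < tol))
    stop("spectrum orthogonal to the MSC reference: sample ",
         paste(spectra$sample_ids[abs(b) < tol], collapse = ", "),
         call. = FALSE)
  a <- rowMeans(A) - b * mean(reference)
  out <- spectra_matrix((A - a) / b, spectra$wavelengths_nm, spectra$sample_ids)
  attr(out, "msc_reference") <- reference
  out
}

#' Savitzky-Golay smoothing and derivatives
#'
#' Local polynomial least-squares filtering via the central row of the
#' \code{signal::sgolay} projection matrix, applied as a valid convolution:
#' the wavelength axis shrinks by half a window at each edge, so no edge
#' values are fabricated. Derivatives are scaled by the wavelength step, so
#' a first derivative is in AU/nm. \code{deriv_order = 0} is plain
#' smoothing; 1 and 2 are the first and second derivative operators.
#'
#' @param spectra a \code{\link{spectra_matrix}}.
#' @param window_points odd filter length, must exceed \code{polyorder}.
#' @param polyorder fitted polynomial degree.
#' @param deriv_order derivative order, 0, 1 or 2; must be
#'   \code{<= polyorder}.
#' @return A \code{spectra_matrix} on the shrunken axis.
#' @export
savitzky_golay <- function(spectra, window_points = 15, polyorder = 2,
                           deriv_order = 0) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  if (window_points %% 2 != 1) stop("window_points must be odd", call. = FALSE)
  if (polyorder >= window_points)
    stop("window_points must exceed polyorder", call. = FALSE)
  if (!deriv_order %in% 0:2 || deriv_order > polyorder)
    stop("deriv_order must be in {0,1,2} and <= polyorder", call. = FALSE)
  m <- ncol(spectra$absorbance)
  if (window_points > m)
    stop("window (", window_points, ") larger than spectrum length (", m, ")",
         call. = FALSE)
  wl <- spectra$wavelengths_nm
  step <- if (m > 1) wl[2] - wl[1] else 1
  if (window_points == 1) return(spectra)  # identity filter
  h <- (window_points - 1) / 2
  coefs <- signal::sgolay(p = polyorder, n = window_points,
                          m = deriv_order)[h + 1, ]
  # valid convolution: out[j] = sum coefs * row[(j-h)..(j+h)]
  idx <- (h + 1):(m - h)
  out <- matrix(0, nrow(spectra$absorbance), length(idx))
  for (k in seq_len(window_points))
    out <- out + spectra$absorbance[, idx + (k - h - 1), drop = FALSE] * coefs[k]
  out <- out / step^deriv_order
  spectra_matrix(out, wl[idx], spectra$sample_ids)
}

#' Normalize spectra
#'
#' \code{minmax} maps each row linearly onto [0, 1]; \code{vector} divides
#' each row by its Euclidean norm.
#'
#' @param spectra a \code{\link{spectra_matrix}}.
#' @param method \code{"minmax"} (default) or \code{"vector"}.
#' @return A \code{spectra_matrix}.
#' @export
normalize_spectra <- function(spectra, method = c("minmax", "vector")) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  method <- match.arg(method)
  A <- spectra$absorbance
  if (method == "minmax") {
    lo <- apply(A, 1, min); hi <- apply(A, 1, max)
    bad <- which(hi == lo)
    if (length(bad))
      stop("min-max normalization undefined for constant spectrum: sample ",
           paste(spectra$sample_ids[bad], collapse = ", "), call. = FALSE)
    out <- (A - lo) / (hi - lo)
  } else {
    nrm <- sqrt(rowSums(A^2))
    bad <- which(nrm == 0)
    if (length(bad))
      stop("vector normalization undefined for zero spectrum: sample ",
           paste(spectra$sample_ids[bad], collapse = ", "), call. = FALSE)
    out <- A / nrm
  }
  spectra_matrix(out, spectra$wavelengths_nm, spectra$sample_ids)
}

#' Linear baseline correction
#'
#' Subtracts from each spectrum its least-squares straight-line fit against
#' wavelength (linear detrend), leaving rows with zero linear trend.
#'
#' @param spectra a \code{\link{spectra_matrix}} with >= 3 points per row.
#' @return A \code{spectra_matrix}.
#' @export
baseline_correct <- function(spectra) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  wl <- spectra$wavelengths_nm
  if (length(wl) < 3) stop("need >= 3 points per spectrum", call. = FALSE)
  X <- cbind(1, wl)
  H <- X %*% solve(crossprod(X), t(X))        # hat matrix of the line fit
  A <- spectra$absorbance
  spectra_matrix(A - A %*% t(H), wl, spectra$sample_ids)
}

# operator registry: chain-label name -> function(spectra, params)
.chain_ops <- list(
  SG        = function(s, p) do.call(savitzky_golay, c(list(s), p, list(deriv_order = 0))),
  `1Der`    = function(s, p) do.call(savitzky_golay, c(list(s), p, list(deriv_order = 1))),
  `2Der`    = function(s, p) do.call(savitzky_golay, c(list(s), p, list(deriv_order = 2))),
  Normalize = function(s, p) do.call(normalize_spectra, c(list(s), p)),
  MSC       = function(s, p) do.call(msc, c(list(s), p)),
  SNV       = function(s, p) snv(s),
  Baseline  = function(s, p) baseline_correct(s))

#' Parse a preprocessing-chain label
#'
#' Chains are written as the field writes them: operator names joined by
#' \code{+}, applied left to right, e.g. \code{"1Der+SNV"} is derivative
#' first, then SNV. Optional parameters use function-call syntax:
#' \code{"SG(window=15,poly=2)+SNV"}. \code{"Original"} (or \code{""}) is
#' the empty chain.
#'
#' @param label chain label string.
#' @return An object of class \code{preprocess_chain}: list of steps, each
#'   with \code{op} and \code{params}, plus the canonical \code{label}.
#' @export
parse_chain <- function(label) {
  if (inherits(label, "preprocess_chain")) return(label)
  stopifnot(is.character(label), length(label) == 1)
  steps <- list()
  if (!label %in% c("", "Original")) {
    for (tok in strsplit(label, "+", fixed = TRUE)[[1]]) {
      tok <- trimws(tok)
      mt <- regmatches(tok, regexec("^([A-Za-z0-9]+)(\\((.*)\\))?$", tok))[[1]]
      if (!length(mt)) stop("cannot parse chain step '", tok, "'", call. = FALSE)
      op <- mt[2]
      if (!op %in% names(.chain_ops))
        stop("unknown preprocessing operator '", op, "'", call. = FALSE)
      params <- list()
      if (nzchar(mt[4])) {
        for (kv in strsplit(mt[4], ",", fixed = TRUE)[[1]]) {
          parts <- strsplit(kv, "=", fixed = TRUE)[[1]]
          key <- switch(trimws(parts[1]),
                        window = "window_points", poly = "polyorder",
                        trimws(parts[1]))
          val <- trimws(parts[2])
          params[[key]] <- if (grepl("^[0-9.eE+-]+$", val)) as.numeric(val) else val
        }
      }
      steps[[length(steps) + 1]] <- list(op = op, params = params)
    }
  }
  structure(list(steps = steps, label = chain_label(steps)),
            class = "preprocess_chain")
}

#' Canonical label of a chain's step list
#'
#' Pure function of the steps; round-trips through
#' \code{\link{parse_chain}}.
#'
#' @param steps list of steps (each with \code{op}, \code{params}), or a
#'   \code{preprocess_chain}.
#' @return Character label, \code{"Original"} for the empty chain.
#' @export
chain_label <- function(steps) {
  if (inherits(steps, "preprocess_chain")) steps <- steps$steps
  if (!length(steps)) return("Original")
  paste(vapply(steps, function(st) {
    if (length(st$params)) {
      nm <- vapply(names(st$params), function(k)
        switch(k, window_points = "window", polyorder = "poly", k), "")
      paste0(st$op, "(", paste0(nm, "=", unlist(st$params), collapse = ","), ")")
    } else st$op
  }, ""), collapse = "+")
}

#' @export
print.preprocess_chain <- function(x, ...) {
  cat("Preprocessing chain:", x$label, "\n")
  invisible(x)
}

#' Apply a preprocessing chain to spectra
#'
#' Operators run left to right in label order. Errors from an operator are
#' re-signalled with the step index attached. The chain label is recorded
#' on the result as attribute \code{"chain"}.
#'
#' @param chain a \code{preprocess_chain} or chain label string.
#' @param spectra a \code{\link{spectra_matrix}}.
#' @return The transformed \code{spectra_matrix}.
#' @export
apply_chain <- function(chain, spectra) {
  chain <- parse_chain(chain)
  out <- spectra
  for (i in seq_along(chain$steps)) {
    st <- chain$steps[[i]]
    out <- tryCatch(.chain_ops[[st$op]](out, st$params),
                    error = function(e)
                      stop("chain step ", i, " (", st$op, "): ",
                           conditionMessage(e), call. = FALSE))
  }
  attr(out, "chain") <- chain$label
  out
}
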