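#' Spectra matrix container
#'
#' Bundles an absorbance matrix with its wavelength axis and sample
#' identifiers. All preprocessing operators and models in the package accept
#' and return this class. The wavelength axis is strictly increasing;
#' amplitude transforms (SNV, MSC, normalization, baseline correction) never
#' alter it, while Savitzky-Golay filtering shrinks it by half a window at
#' each edge (valid convolution, no padded values).
#'
#' @param absorbance numeric matrix, samples in rows, wavelengths in columns.
#' @param wavelengths_nm strictly increasing numeric vector, one entry per
#'   column of \code{absorbance}.
#' @param sample_ids character or integer vector of row identifiers; defaults
#'   to \code{"S1"..."Sn"}.
#' @return An object of class \code{spectra_matrix}: a list with elements
#'   \code{absorbance}, \code{wavelengths_nm}, \code{sample_ids}.
#' @export
spectra_matrix <- function(absorbance, wavelengths_nm, sample_ids = NULL) {
  absorbance <- as.matrix(absorbance)
  wavelengths_nm <- as.numeric(wavelengths_nm)
  if (ncol(absorbance) != length(wavelengths_nm))
    stop("absorbance has ", ncol(absorbance), " columns but wavelength axis has ",
         length(wavelengths_nm), " points", call. = FALSE)
  if (length(wavelengths_nm) > 1 && any(diff(wavelengths_nm) <= 0))
    stop("wavelength axis must be strictly increasing", call. = FALSE)
  if (any(!is.finite(absorbance)))
    stop("absorbance contains non-finite values", call. = FALSE)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(absorbance)))
  if (length(sample_ids) != nrow(absorbance))
    stop("sample_ids length does not match number of spectra", call. = FALSE)
  rownames(absorbance) <- as.character(sample_ids)
  colnames(absorbance) <- as.character(wavelengths_nm)
  structure(list(absorbance = absorbance,
                 wavelengths_nm = wavelengths_nm,
                 sample_ids = as.character(sample_ids)),
            class = "spectra_matrix")
}

#' @export
print.spectra_matrix <- function(x, ...) {
  cat("NIR spectra: ", nrow(x$absorbance), " samples x ",
      length(x$wavelengths_nm), " wavelengths (",
      min(x$wavelengths_nm), "-", max(x$wavelengths_nm), " nm)\n", sep = "")
  invisible(x)
}

#' @export
dim.spectra_matrix <- function(x) dim(x$absorbance)

#' Subset spectra by sample
#'
#' @param x a \code{spectra_matrix}.
#' @param i row (sample) index vector.
#' @param ... ignored.
#' @return A \code{spectra_matrix} restricted to the selected samples.
#' @export
`[.spectra_matrix` <- function(x, i, ...) {
  spectra_matrix(x$absorbance[i, , drop = FALSE], x$wavelengths_nm,
                 x$sample_ids[i])
}

#' @rdname spectra_matrix
#' @param x a \code{spectra_matrix}.
#' @export
wavelengths <- function(x) x$wavelengths_nm

#' Read / write the wide spectra CSV
#'
#' The interchange format is a wide CSV: column 1 \code{sample_id}, column 2
#' \code{protein_pct}, remaining columns named by integer wavelength in nm.
#' UTF-8, comma separated, '.' decimal, header row mandatory.
#'
#' @param path file path.
#' @return \code{read_spectra_csv} returns a list with \code{spectra}
#'   (a \code{spectra_matrix}) and \code{samples} (data.frame with
#'   \code{sample_id}, \code{protein_pct}).
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("sample_id", "protein_pct") %in% names(df)[1:2]))
    stop("expected columns 'sample_id', 'protein_pct' then wavelengths", call. = FALSE)
  wl_cols <- names(df)[-(1:2)]
  spec <- spectra_matrix(as.matrix(df[, -(1:2), drop = FALSE]),
                         as.numeric(wl_cols), df$sample_id)
  list(spectra = spec,
       samples = data.frame(sample_id = df$sample_id,
                            protein_pct = df$protein_pct))
}

#' @rdname read_spectra_csv
#' @param spectra a \code{spectra_matrix}.
#' @param protein_pct numeric vector of reference protein values (%), one per
#'   sample.
#' @export
write_spectra_csv <- function(spectra, protein_pct, path) {
  stopifnot(inherits(spectra, "spectra_matrix"),
            length(protein_pct) == nrow(spectra$absorbance))
  df <- data.frame(sample_id = spectra$sample_ids,
                   protein_pct = protein_pct, check.names = FALSE)
  df <- cbind(df, as.data.frame(spectra$absorbance, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
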