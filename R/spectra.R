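#' Construct a spectral dataset
#'
#' Bundles a sample-by-wavenumber absorbance matrix with class labels and
#' sample identifiers, validating the structural invariants the rest of the
#' pipeline relies on: matching dimensions, strictly monotonic wavenumbers
#' (NIR spectrometer exports conventionally run from 12,000 down to
#' 3499 cm^-1) and finite absorbance values.
#'
#' @param wavenumbers numeric vector of spectral positions in cm^-1,
#'   strictly monotonic (ascending or descending).
#' @param absorbance numeric matrix, one row per sample, one column per
#'   wavenumber.
#' @param labels class label per sample (coerced to factor).
#' @param sample_ids optional character vector of per-sample identifiers;
#'   defaults to `"s1" ... "sN"`.
#' @return An object of class `spectra_set`: a list with elements
#'   `wavenumbers`, `absorbance`, `labels`, `sample_ids`.
#' @examples
#' ds <- spectra_set(5:1, matrix(rnorm(15), 3, 5), c("A", "A", "B"))
#' ds
#' @export
spectra_set <- function(wavenumbers, absorbance, labels, sample_ids = NULL) {
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  wavenumbers <- as.numeric(wavenumbers)
  n <- nrow(absorbance)
  p <- ncol(absorbance)
  if (length(wavenumbers) != p) {
    stopf("length(wavenumbers) is %d but absorbance has %d columns",
          length(wavenumbers), p)
  }
  if (length(labels) != n) {
    stopf("length(labels) is %d but absorbance has %d rows", length(labels), n)
  }
  d <- diff(wavenumbers)
  if (p > 1 && !(all(d > 0) || all(d < 0))) {
    stopf("wavenumbers must be strictly monotonic")
  }
  if (!all(is.finite(absorbance))) {
    bad <- which(!is.finite(absorbance), arr.ind = TRUE)[1L, ]
    stopf("non-finite absorbance at row %d, column %d", bad[1L], bad[2L])
  }
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != n) {
    stopf("length(sample_ids) is %d but absorbance has %d rows",
          length(sample_ids), n)
  }
  structure(
    list(wavenumbers = wavenumbers, absorbance = absorbance,
         labels = factor(labels), sample_ids = sample_ids),
    class = "spectra_set"
  )
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d samples x %d points, %.0f to %.0f cm^-1\n",
              nrow(x$absorbance), ncol(x$absorbance),
              x$wavenumbers[1L], x$wavenumbers[length(x$wavenumbers)]))
  tab <- table(x$labels)
  cat("classes:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$absorbance)

# Row subset that keeps all parallel fields aligned; order preserved.
subset_spectra <- function(ds, idx) {
  spectra_set(ds$wavenumbers, ds$absorbance[idx, , drop = FALSE],
              ds$labels[idx], ds$sample_ids[idx])
}

#' Read a spectral dataset from a wide CSV/TSV file
#'
#' Expected layout: first column sample identifiers, second column class
#' labels, remaining columns absorbance values with wavenumbers (cm^-1) as
#' column headers.  This matches the one-row-per-sample wide export common
#' to spectrometer software.
#'
#' @param path file to read.
#' @param sep field delimiter, `","` (default) or `"\t"`.
#' @param id_col,label_col column positions of the sample id and label
#'   columns (defaults 1 and 2).
#' @return A validated [spectra_set].
#' @seealso [write_spectra()]
#' @export
read_spectra <- function(path, sep = ",", id_col = 1L, label_col = 2L) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stopf("malformed header: need id, label and spectral columns")
  if (max(id_col, label_col) > ncol(df)) {
    stopf("missing label column: file has only %d columns", ncol(df))
  }
  spec_cols <- setdiff(seq_len(ncol(df)), c(id_col, label_col))
  wn <- suppressWarnings(as.numeric(names(df)[spec_cols]))
  if (anyNA(wn)) {
    stopf("malformed header: non-numeric wavenumber '%s'",
          names(df)[spec_cols][which(is.na(wn))[1L]])
  }
  abs_df <- df[spec_cols]
  for (j in seq_along(abs_df)) {
    col <- abs_df[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      if (anyNA(num)) {
        row <- which(is.na(num))[1L]
        stopf("non-numeric absorbance at row %d, column '%s'",
              row, names(abs_df)[j])
      }
      abs_df[[j]] <- num
    }
  }
  spectra_set(wn, as.matrix(abs_df), df[[label_col]], df[[id_col]])
}

#' Write a spectral dataset to a wide CSV/TSV file
#'
#' Inverse of [read_spectra()]: the written file round-trips to an equal
#' `spectra_set` up to floating-point representation.
#'
#' @param ds a [spectra_set].
#' @param path output file.
#' @param sep field delimiter.
#' @export
write_spectra <- function(ds, path, sep = ",") {
  stopifnot(inherits(ds, "spectra_set"))
  if (nrow(ds$absorbance) == 0L) stopf("refusing to write a dataset with 0 samples")
  if (anyDuplicated(ds$sample_ids)) {
    warnf("duplicated sample_ids in dataset written to %s", path)
  }
  df <- data.frame(sample_id = ds$sample_ids,
                   label = as.character(ds$labels),
                   ds$absorbance, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[-(1:2)] <- format(ds$wavenumbers, trim = TRUE, digits = 15)
  ok <- tryCatch({
    write.table(df, path, sep = sep, row.names = FALSE, qmethod = "double")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stopf("could not write %s: %s", path, conditionMessage(ok))
  invisible(path)
}
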