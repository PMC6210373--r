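#' Savitzky-Golay smoothing configuration
#'
#' The smoother replaces each point by the value of a least-squares
#' polynomial fitted over a sliding window centred on it.  The defaults —
#' quadratic polynomial, 121-point window — are the standard de-noising
#' settings for high-resolution NIR absorbance spectra, wide enough to
#' suppress detector noise while leaving the broad overtone/combination
#' bands intact.
#'
#' @param window odd window length in points (default 121).
#' @param poly_order polynomial order (default 2).
#' @return An object of class `sg_config`.
#' @export
sg_config <- function(window = 121L, poly_order = 2L) {
  if (!is_count(window) || !is_count(poly_order)) {
    stopf("window and poly_order must be integers")
  }
  window <- as.integer(window)
  poly_order <- as.integer(poly_order)
  if (window %% 2L == 0L) stopf("window must be odd, got %d", window)
  if (window <= poly_order) stopf("window (%d) must exceed poly_order (%d)",
                                  window, poly_order)
  structure(list(window = window, poly_order = poly_order),
            class = "sg_config")
}

#' Savitzky-Golay de-noising of a spectral dataset
#'
#' Applies the Savitzky-Golay filter row-wise.  Interior points are the
#' centred least-squares polynomial value; within the first and last
#' half-window the same window polynomial is evaluated off-centre, so the
#' output has the full input length and polynomials up to `poly_order` are
#' reproduced exactly everywhere.
#'
#' @param ds a [spectra_set].
#' @param cfg an [sg_config]; the default is a quadratic over 121 points.
#' @return A [spectra_set] of identical shape with smoothed absorbance;
#'   labels and sample ids untouched.
#' @examples
#' ds <- spectra_set(1:200, matrix(rnorm(400), 2, 200), c("A", "B"))
#' sm <- sg_smooth(ds, sg_config(window = 21))
#' @export
sg_smooth <- function(ds, cfg = sg_config()) {
  stopifnot(inherits(ds, "spectra_set"))
  if (!inherits(cfg, "sg_config")) stopf("cfg must be an sg_config")
  p <- ncol(ds$absorbance)
  if (cfg$window > p) {
    stopf("window (%d) exceeds the number of spectral points (%d)",
          cfg$window, p)
  }
  smoothed <- t(apply(ds$absorbance, 1L, signal::sgolayfilt,
                      p = cfg$poly_order, n = cfg$window))
  spectra_set(ds$wavenumbers, smoothed, ds$labels, ds$sample_ids)
}

#' Mahalanobis distance of each spectrum to the dataset mean
#'
#' Computes per-sample Mahalanobis distances
#' \eqn{d_i = \sqrt{(z_i - \bar z)^\top S^{-1} (z_i - \bar z)}} in either
#' the raw spectral space or (default) a principal-component score space.
#' Raw NIR spectra have far more points than samples, so the raw-space
#' covariance is singular; the default therefore measures distance in the
#' top-K PC score space, and the covariance is shrunk as
#' \eqn{S + \lambda I} with \eqn{\lambda = 10^{-6}\,\mathrm{tr}(S)/d}
#' for numerical stability.
#'
#' @param ds a [spectra_set].
#' @param space `"pc"` (default) to measure in PC-score space, `"raw"` for
#'   the raw point space.
#' @param pca optional fitted [fit_pca()] model; if `NULL` and
#'   `space = "pc"`, a model with `n_components` components is fitted to
#'   `ds` first.
#' @param n_components PC count when fitting internally (default 25).
#' @return An object of class `outlier_report` with elements `distances`,
#'   `threshold` (NA here; set by [remove_outliers()]), `flagged`
#'   (empty here) and `dim` (the space dimension).
#' @export
mahalanobis_distances <- function(ds, space = c("pc", "raw"), pca = NULL,
                                  n_components = 25L) {
  stopifnot(inherits(ds, "spectra_set"))
  space <- match.arg(space)
  n <- nrow(ds$absorbance)
  if (n < 3L) stopf("need at least 3 samples for a covariance estimate, got %d", n)
  if (space == "pc") {
    if (is.null(pca)) {
      pca <- fit_pca(ds, k = min(n_components, n - 1L, ncol(ds$absorbance)))
    }
    z <- transform_spectra(ds, pca)$scores
  } else {
    z <- ds$absorbance
    if (ncol(z) >= n) {
      stopf("raw-space covariance is singular for N <= P; use space = 'pc'")
    }
  }
  s <- cov(z)
  lambda <- 1e-6 * sum(diag(s)) / ncol(z)
  s <- s + diag(lambda, ncol(z))
  d2 <- mahalanobis(z, colMeans(z), s)
  structure(list(distances = sqrt(pmax(d2, 0)), threshold = NA_real_,
                 flagged = integer(0), dim = ncol(z)),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("<outlier_report> %d samples, dim %d, threshold %.3f, %d flagged\n",
              length(x$distances), x$dim, x$threshold, length(x$flagged)))
  invisible(x)
}

#' Remove outlying spectra by Mahalanobis distance
#'
#' Flags every sample whose Mahalanobis distance to the mean spectrum
#' exceeds a threshold and drops it.  The default threshold is the square
#' root of the chi-squared quantile at `quantile` with `dim` degrees of
#' freedom — the distribution squared Mahalanobis distances follow for
#' multivariate-normal data — so under clean data almost nothing is
#' removed.
#'
#' @param ds a [spectra_set].
#' @param space,pca,n_components passed to [mahalanobis_distances()].
#' @param quantile chi-squared quantile for the default threshold
#'   (default 0.999).
#' @param threshold explicit distance cutoff; overrides `quantile`.
#' @return A list with elements `spectra` (the retained [spectra_set],
#'   original order preserved) and `report` (an `outlier_report` with the
#'   threshold and flagged indices filled in).
#' @export
remove_outliers <- function(ds, space = c("pc", "raw"), pca = NULL,
                            n_components = 25L, quantile = 0.999,
                            threshold = NULL) {
  space <- match.arg(space)
  report <- mahalanobis_distances(ds, space = space, pca = pca,
                                  n_components = n_components)
  if (is.null(threshold)) threshold <- sqrt(qchisq(quantile, df = report$dim))
  flagged <- which(report$distances > threshold)
  if (length(flagged) == nrow(ds$absorbance)) {
    stopf("outlier policy flags all %d samples; nothing would remain",
          length(flagged))
  }
  report$threshold <- threshold
  report$flagged <- flagged
  keep <- setdiff(seq_len(nrow(ds$absorbance)), flagged)
  list(spectra = subset_spectra(ds, keep), report = report)
}
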