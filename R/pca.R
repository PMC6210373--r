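#' Principal component analysis of a spectral dataset
#'
#' Mean-centres the absorbance matrix and eigendecomposes its sample
#' covariance (1/(N-1) normalisation).  When the spectra have more points
#' than there are samples — the usual NIR situation, e.g. 2084 points for a
#' few hundred samples — the equivalent N x N Gram-matrix eigenproblem is
#' solved instead and loadings recovered from it, which is exact and far
#' cheaper than the P x P decomposition.  Components are ordered by
#' descending eigenvalue; each loading's sign is fixed so its
#' largest-magnitude element is positive, making results platform-stable.
#'
#' @param ds a [spectra_set], or a plain numeric matrix (rows = samples).
#' @param k number of components to retain; at most `min(N - 1, P)`.
#' @return An object of class `nir_pca`: list with `mean` (length-P centre),
#'   `loadings` (P x k orthonormal matrix), `eigenvalues` (descending),
#'   `explained_ratio` (eigenvalue / total variance, so the ratios over all
#'   components sum to 1), `total_variance` and `k`.
#' @examples
#' x <- matrix(rnorm(200), 20, 10)
#' ds <- spectra_set(1:10, x, rep(c("a", "b"), 10))
#' m <- fit_pca(ds, k = 5)
#' m$explained_ratio
#' @export
fit_pca <- function(ds, k) {
  x <- if (inherits(ds, "spectra_set")) ds$absorbance else as.matrix(ds)
  n <- nrow(x)
  p <- ncol(x)
  if (n < 2L) stopf("need at least 2 samples, got %d", n)
  kmax <- min(n - 1L, p)
  if (!is_count(k) || k < 1L || k > kmax) {
    stopf("k must be in 1..%d (min(N - 1, P)), got %s", kmax, format(k))
  }
  k <- as.integer(k)
  centre <- colMeans(x)
  xc <- sweep(x, 2L, centre)
  total_var <- sum(xc^2) / (n - 1L)

  if (p <= n) {
    ev <- eigen(crossprod(xc) / (n - 1L), symmetric = TRUE)
    vals <- ev$values[seq_len(k)]
    vecs <- ev$vectors[, seq_len(k), drop = FALSE]
  } else {
    # Gram trick: eigenvectors u of X X' / (N-1) give loadings X'u (scaled).
    ev <- eigen(tcrossprod(xc) / (n - 1L), symmetric = TRUE)
    vals <- ev$values[seq_len(k)]
    u <- ev$vectors[, seq_len(k), drop = FALSE]
    vecs <- crossprod(xc, u)
    norms <- sqrt(colSums(vecs^2))
    norms[norms < 1e-300] <- 1
    vecs <- sweep(vecs, 2L, norms, "/")
  }
  vals <- pmax(vals, 0)

  # Deterministic sign: largest-magnitude loading element is positive.
  for (j in seq_len(k)) {
    col <- vecs[, j]
    if (col[which.max(abs(col))] < 0) vecs[, j] <- -col
  }
  dimnames(vecs) <- list(NULL, paste0("PC", seq_len(k)))
  structure(
    list(mean = centre, loadings = vecs, eigenvalues = vals,
         explained_ratio = vals / total_var, total_variance = total_var,
         k = k),
    class = "nir_pca"
  )
}

#' @export
print.nir_pca <- function(x, ...) {
  cat(sprintf("<nir_pca> %d components over %d points; top-%d variance %.1f%%\n",
              x$k, length(x$mean), x$k, 100 * sum(x$explained_ratio)))
  invisible(x)
}

#' Project spectra onto a fitted PC basis
#'
#' Centres the spectra with the model mean and projects onto the loadings:
#' `scores = (absorbance - mean) %*% loadings`.
#'
#' @param ds a [spectra_set] (or numeric matrix) with the same point count
#'   as the model.
#' @param model a fitted [fit_pca()].
#' @return An object of class `score_set`: list with `scores` (N x k),
#'   `labels`, `sample_ids`, and `model`.
#' @export
transform_spectra <- function(ds, model) {
  stopifnot(inherits(model, "nir_pca"))
  x <- if (inherits(ds, "spectra_set")) ds$absorbance else as.matrix(ds)
  if (ncol(x) != length(model$mean)) {
    stopf("dataset has %d points but model was fitted on %d",
          ncol(x), length(model$mean))
  }
  scores <- sweep(x, 2L, model$mean) %*% model$loadings
  labels <- if (inherits(ds, "spectra_set")) ds$labels else
    factor(rep(NA_character_, nrow(x)))
  ids <- if (inherits(ds, "spectra_set")) ds$sample_ids else
    paste0("s", seq_len(nrow(x)))
  score_set(scores, labels, ids, model)
}

#' Construct a PC score set
#'
#' @param scores numeric N x k matrix of PC scores.
#' @param labels per-sample class labels.
#' @param sample_ids optional sample identifiers.
#' @param model optional source [fit_pca()] model.
#' @return An object of class `score_set`.
#' @export
score_set <- function(scores, labels, sample_ids = NULL, model = NULL) {
  scores <- as.matrix(scores)
  if (length(labels) != nrow(scores)) {
    stopf("length(labels) is %d but scores has %d rows",
          length(labels), nrow(scores))
  }
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(scores)))
  structure(list(scores = scores, labels = factor(labels),
                 sample_ids = as.character(sample_ids), model = model),
            class = "score_set")
}

#' @export
print.score_set <- function(x, ...) {
  cat(sprintf("<score_set> %d samples x %d components\n",
              nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

#' @export
dim.score_set <- function(x) dim(x$scores)

subset_scores <- function(ss, idx) {
  score_set(ss$scores[idx, , drop = FALSE], ss$labels[idx],
            ss$sample_ids[idx], ss$model)
}

#' Explained-variance fraction of a PC subset
#'
#' Sums the model's explained-variance ratios over the components a binary
#' mask selects — the "amount of information" a candidate subset carries.
#'
#' @param model a fitted [fit_pca()].
#' @param mask binary 0/1 vector of length `model$k` (or a logical vector).
#' @return Fraction in `[0, 1]`; monotone non-decreasing under supersets.
#' @export
explained_information <- function(model, mask) {
  stopifnot(inherits(model, "nir_pca"))
  mask <- as.integer(as.logical(mask))
  if (length(mask) != model$k) {
    stopf("mask length %d does not match model k = %d", length(mask), model$k)
  }
  sum(model$explained_ratio[mask == 1L])
}
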