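#' Configuration for the synthetic NIR spectra generator
#'
#' Describes a tobacco-like four-class NIR dataset: a shared absorbance
#' envelope with the characteristic hydrogen-group absorption peaks near
#' 4004, 4313, 4727 and 5163 cm^-1 on a descending 12,000 to 3499 cm^-1
#' grid of 2084 points, plus sample-level variation carried by smooth
#' orthonormal latent directions with a fixed descending variance ladder,
#' a small linear baseline drift and additive detector noise.
#'
#' Class structure is planted only in the latent directions named by
#' `informative_ranks` (ranks in the variance order, i.e. the expected PCA
#' ranks — by default 1, 6, 7, 8, 10 and 11, so most of the signal sits in
#' low-variance, "less information" components).  Because the sample
#' covariance of a location mixture picks up every cross-product of class
#' means, informative directions must stay *decorrelated* in aggregate or
#' PCA mixes them and the planted ranks lose their meaning; with `m`
#' classes only `m - 1` such mean directions exist.  The generator
#' therefore plants two kinds of signal: the first `m - 1` informative
#' directions carry class-mean contrasts (recursive halving of the class
#' set, orthogonalised under the class weights so their aggregate
#' cross-covariance is exactly zero), and any further informative
#' directions carry *sub-cluster* structure — one class per direction
#' splits into two tight sub-populations at symmetric offsets, the way a
#' growing region splits into sub-sites — which has zero class-mean
#' signal and therefore no cross-covariance.  Every informative
#' direction's total variance is renormalised onto the ladder so its PCA
#' rank is preserved.
#'
#' @param n_per_class samples per class (default `c(38, 144, 70, 80)`,
#'   the unbalanced four-region layout).
#' @param p number of spectral points (default 2084).
#' @param wn_max,wn_min grid endpoints in cm^-1 (defaults 12,000 and 3499;
#'   stored descending).
#' @param n_latent latent direction count (default 25).
#' @param informative_ranks variance ranks carrying class signal (default
#'   `c(1, 6, 7, 8, 10, 11)`).
#' @param effect_size signal strength: mean contrasts separate their two
#'   class groups by `effect_size` within-class standard deviations, and
#'   sub-cluster directions place the split class's two modes at
#'   `+- 0.95 * (effect_size / 3)` of the direction's total standard
#'   deviation (capped so the variance budget holds).  0 removes all
#'   class signal.  Default 3.
#' @param latent_var_max,latent_var_decay variance ladder
#'   `latent_var_max * latent_var_decay^(rank - 1)` (defaults 2 and 0.8;
#'   the ~25% gap between neighbours keeps the sample eigenvalue order
#'   stable at a few hundred samples, and the resulting score scale suits
#'   a radial-basis kernel of width ~2).
#' @param noise_sd additive i.i.d. noise per point (default 0.002
#'   absorbance units).
#' @param baseline_amp amplitude of the per-sample linear baseline drift
#'   (default 0.001).
#' @param peak_centers,peak_widths,peak_amps envelope peaks in cm^-1 /
#'   cm^-1 / absorbance units.
#' @param offset constant absorbance offset keeping spectra positive
#'   (default 1.5).
#' @param seed generator seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_per_class = c(38L, 144L, 70L, 80L),
                             p = 2084L, wn_max = 12000, wn_min = 3499,
                             n_latent = 25L,
                             informative_ranks = c(1L, 6L, 7L, 8L, 10L, 11L),
                             effect_size = 3,
                             latent_var_max = 2, latent_var_decay = 0.8,
                             noise_sd = 0.002, baseline_amp = 0.001,
                             peak_centers = c(4004, 4313, 4727, 5163),
                             peak_widths = c(90, 110, 130, 160),
                             peak_amps = c(0.55, 0.40, 0.45, 0.35),
                             offset = 1.5, seed = 1L) {
  if (any(n_per_class <= 0)) stopf("class counts must be positive")
  if (!is_count(p) || p < 10L) stopf("p must be an integer >= 10")
  if (n_latent > p) stopf("cannot orthogonalize %d latent directions in %d points",
                          n_latent, p)
  if (any(informative_ranks < 1L) || any(informative_ranks > n_latent)) {
    stopf("informative_ranks must lie in 1..n_latent")
  }
  if (effect_size < 0) stopf("effect_size must be >= 0")
  if (any(peak_centers < min(wn_min, wn_max)) ||
      any(peak_centers > max(wn_min, wn_max))) {
    stopf("peak centers must lie within the wavenumber range")
  }
  structure(
    list(n_per_class = as.integer(n_per_class), p = as.integer(p),
         wn_max = wn_max, wn_min = wn_min, n_latent = as.integer(n_latent),
         informative_ranks = as.integer(sort(informative_ranks)),
         effect_size = effect_size,
         latent_var_max = latent_var_max,
         latent_var_decay = latent_var_decay, noise_sd = noise_sd,
         baseline_amp = baseline_amp, peak_centers = peak_centers,
         peak_widths = peak_widths, peak_amps = peak_amps, offset = offset,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# Orthogonal class contrasts by recursive halving: the first splits the
# class set in half (+1 / -1), later ones recurse within each half.
# n classes yield n - 1 contrasts (orthogonalised later under weights).
halving_contrasts <- function(n_classes) {
  out <- list()
  recurse <- function(cls) {
    if (length(cls) < 2L) return(invisible())
    left <- cls[seq_len(ceiling(length(cls) / 2))]
    v <- numeric(n_classes)
    v[left] <- 1
    v[setdiff(cls, left)] <- -1
    out[[length(out) + 1L]] <<- v
    recurse(left)
    recurse(setdiff(cls, left))
  }
  recurse(seq_len(n_classes))
  out
}

# Smooth orthonormal latent directions: random Gaussian bumps,
# Gram-Schmidt orthonormalised.  Columns are unit-norm length-p curves.
# Bump widths are kept well above the default Savitzky-Golay window so
# smoothing passes the directions through almost unattenuated and the
# configured variance ladder survives de-noising.
latent_directions <- function(wn, n_latent) {
  p <- length(wn)
  lo <- min(wn); hi <- max(wn)
  raw <- vapply(seq_len(n_latent), function(j) {
    centers <- runif(3, lo + 0.05 * (hi - lo), hi - 0.05 * (hi - lo))
    widths <- runif(3, 0.08 * (hi - lo), 0.2 * (hi - lo))
    amps <- rnorm(3)
    rowSums(vapply(1:3, function(b) {
      amps[b] * exp(-(wn - centers[b])^2 / (2 * widths[b]^2))
    }, numeric(p)))
  }, numeric(p))
  for (j in seq_len(n_latent)) {
    v <- raw[, j]
    if (j > 1L) {
      prev <- raw[, seq_len(j - 1L), drop = FALSE]
      v <- v - prev %*% crossprod(prev, v)
    }
    nv <- sqrt(sum(v^2))
    if (nv < 1e-8) stopf("degenerate latent direction %d; use another seed", j)
    raw[, j] <- v / nv
  }
  raw
}


#' Generate a synthetic NIR spectral dataset
#'
#' Draws spectra according to a [synthetic_config]:
#' `spectrum_i = envelope + sum_j z_ij v_j + baseline_i + noise_i`, with
#' smooth orthonormal latent directions `v_j` whose total variances follow
#' the configured descending ladder and latent coordinates `z_ij` whose
#' class structure (weight-orthogonal mean contrasts plus sub-cluster
#' splits, see [synthetic_config()]) lives only on the informative ranks.
#'
#' @param cfg a [synthetic_config].
#' @return A list with `spectra` (a [spectra_set]) and `truth`
#'   (latent coordinates `z`, `directions`, `variances`,
#'   `informative_ranks`, per-class latent means `class_means`, standard
#'   deviations `class_sds` and sub-cluster half-offsets
#'   `subcluster_offsets`).
#' @examples
#' small <- synthetic_config(n_per_class = c(5, 6, 7, 8), p = 120,
#'                           n_latent = 8, informative_ranks = c(1, 4),
#'                           seed = 7)
#' gen <- generate_spectra(small)
#' dim(gen$spectra)
#' @export
generate_spectra <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_rng(cfg$seed, {
    n_classes <- length(cfg$n_per_class)
    n <- sum(cfg$n_per_class)
    wn <- seq(cfg$wn_max, cfg$wn_min, length.out = cfg$p)
    labels <- factor(rep(paste0("class", seq_len(n_classes)),
                         cfg$n_per_class))
    w <- cfg$n_per_class / n

    envelope <- cfg$offset +
      0.25 * exp(-((wn - 5500) / 2500)^2) +
      rowSums(vapply(seq_along(cfg$peak_centers), function(b) {
        cfg$peak_amps[b] *
          exp(-(wn - cfg$peak_centers[b])^2 / (2 * cfg$peak_widths[b]^2))
      }, numeric(cfg$p)))

    v <- latent_directions(wn, cfg$n_latent)
    vars <- cfg$latent_var_max *
      cfg$latent_var_decay^(seq_len(cfg$n_latent) - 1L)

    # Mean contrasts: recursive halving of the class set, then weighted
    # Gram-Schmidt (weights = class frequencies) so the aggregate
    # cross-covariance between informative directions is exactly zero
    # and PCA cannot mix them.  At most n_classes - 1 such contrasts
    # exist; later informative directions get sub-cluster structure.
    contrasts <- halving_contrasts(n_classes)
    cb <- cbind(rep(1, n_classes), do.call(cbind, contrasts))
    for (jj in 2:ncol(cb)) {
      for (ii in 1:(jj - 1L)) {
        cb[, jj] <- cb[, jj] -
          sum(w * cb[, ii] * cb[, jj]) / sum(w * cb[, ii]^2) * cb[, ii]
      }
    }
    contrasts <- lapply(2:ncol(cb), function(jj) {
      cb[, jj] / sqrt(sum(w * cb[, jj]^2))  # unit weighted norm
    })

    e <- cfg$effect_size
    n_mean <- length(contrasts)
    class_means <- matrix(0, n_classes, cfg$n_latent)
    class_sds <- matrix(rep(sqrt(vars), each = n_classes),
                        n_classes, cfg$n_latent)
    bimode <- matrix(0, n_classes, cfg$n_latent)  # sub-cluster half-offsets
    for (r in seq_along(cfg$informative_ranks)) {
      j <- cfg$informative_ranks[r]
      if (r <= n_mean) {
        # Unit-weighted-norm contrast: between-class variance (e*s/2)^2,
        # within-sd s shrunk so total variance stays on the ladder.
        ctr <- contrasts[[r]]
        s <- sqrt(vars[j] / (1 + (e / 2)^2))
        class_means[, j] <- (e * s / 2) * ctr
        class_sds[, j] <- s
      } else {
        # Sub-cluster direction: one class (cycled) splits into two modes
        # at +-m; its residual jitter keeps the class variance m^2 +
        # jitter^2 = ladder variance, so the PCA rank is unchanged and
        # the class means stay zero.
        cl <- ((r - n_mean - 1L) %% n_classes) + 1L
        m <- min(0.95, 0.95 * e / 3) * sqrt(vars[j])
        bimode[cl, j] <- m
        class_sds[cl, j] <- sqrt(vars[j] - m^2)
      }
    }

    ci <- as.integer(labels)
    z <- matrix(rnorm(n * cfg$n_latent), n, cfg$n_latent) *
      class_sds[ci, , drop = FALSE] + class_means[ci, , drop = FALSE] +
      bimode[ci, , drop = FALSE] *
        matrix(sample(c(-1, 1), n * cfg$n_latent, replace = TRUE),
               n, cfg$n_latent)

    baseline <- outer(rnorm(n, sd = cfg$baseline_amp), rep(1, cfg$p)) +
      outer(rnorm(n, sd = cfg$baseline_amp),
            seq(-1, 1, length.out = cfg$p))
    absorbance <- matrix(rep(envelope, each = n), n, cfg$p) +
      z %*% t(v) + baseline +
      matrix(rnorm(n * cfg$p, sd = cfg$noise_sd), n, cfg$p)

    list(
      spectra = spectra_set(wn, absorbance, labels),
      truth = list(z = z, directions = v, variances = vars,
                   informative_ranks = cfg$informative_ranks,
                   class_means = class_means, class_sds = class_sds,
                   subcluster_offsets = bimode)
    )
  })
}

#' Inject a synthetic outlier spectrum
#'
#' Displaces one randomly chosen spectrum by `magnitude` times the
#' per-point standard deviation over a random contiguous wavenumber band —
#' the shape of a gross acquisition artefact — for exercising the
#' Mahalanobis outlier filter.
#'
#' @param ds a [spectra_set].
#' @param magnitude displacement in per-point-sd units (0 leaves the data
#'   unchanged).
#' @param seed RNG seed.
#' @return List with `spectra` (modified [spectra_set]) and `index` (the
#'   injected sample's row).
#' @export
inject_outlier <- function(ds, magnitude, seed = 1L) {
  stopifnot(inherits(ds, "spectra_set"))
  if (magnitude < 0) stopf("magnitude must be >= 0")
  with_rng(seed, {
    n <- nrow(ds$absorbance)
    p <- ncol(ds$absorbance)
    idx <- sample.int(n, 1L)
    if (magnitude > 0) {
      band_len <- max(2L, as.integer(round(p * runif(1, 0.1, 0.3))))
      start <- sample.int(p - band_len + 1L, 1L)
      band <- start:(start + band_len - 1L)
      point_sd <- apply(ds$absorbance[, band, drop = FALSE], 2L, sd)
      point_sd[point_sd == 0] <- mean(point_sd[point_sd > 0], na.rm = TRUE)
      ds$absorbance[idx, band] <- ds$absorbance[idx, band] +
        magnitude * point_sd
    }
    list(spectra = ds, index = idx)
  })
}
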