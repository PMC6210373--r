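# Shared fixtures, built in code.

# Small well-separated 4-class score cloud (2-D), deterministic.
toy_scores_4class <- function(n_per = 12L, sep = 4, seed = 42L) {
  set.seed(seed)
  centres <- sep * rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  x <- do.call(rbind, lapply(1:4, function(c) {
    matrix(rnorm(2 * n_per, sd = 0.4), n_per, 2) +
      matrix(centres[c, ], n_per, 2, byrow = TRUE)
  }))
  score_set(x, rep(paste0("c", 1:4), each = n_per))
}

# Tiny spectra set with a quadratic-in-index spectrum family.
toy_spectra <- function(n = 6L, p = 60L, seed = 7L) {
  set.seed(seed)
  idx <- seq_len(p)
  absorb <- t(vapply(seq_len(n), function(i) {
    0.5 + 0.01 * i + 1e-4 * idx + rnorm(p, sd = 0.01)
  }, numeric(p)))
  spectra_set(seq(8000, 4000, length.out = p), absorb,
              rep(c("A", "B"), length.out = n))
}

# Savitzky-Golay smoothing coefficients built independently from the
# least-squares normal equations on a centred window: the fitted value at
# the window centre is e1' (A'A)^-1 A' x with A the Vandermonde matrix.
sg_coeffs_oracle <- function(window, poly_order) {
  half <- (window - 1L) / 2L
  t <- (-half):half
  a <- outer(t, 0:poly_order, "^")
  (solve(crossprod(a)) %*% t(a))[1L, ]
}

# Brute-force solver for the SVM dual on tiny problems: enumerates active
# sets (each alpha at 0, at C, or free), solves the equality-constrained
# stationarity system for the free block, keeps feasible candidates and
# returns the lowest dual objective.  Exact for convex QPs up to ~6 points.
brute_force_dual <- function(kmat, y, C) {
  n <- length(y)
  q <- outer(y, y) * kmat
  obj <- function(a) 0.5 * drop(a %*% q %*% a) - sum(a)
  best <- list(objective = Inf, alpha = NULL)
  states <- expand.grid(rep(list(0:2), n))  # 0: at 0, 1: at C, 2: free
  for (r in seq_len(nrow(states))) {
    st <- as.integer(states[r, ])
    a <- numeric(n)
    a[st == 1L] <- C
    free <- which(st == 2L)
    fixed_contrib <- if (any(st == 1L)) {
      colSums(q[st == 1L, , drop = FALSE] * C)
    } else numeric(n)
    if (length(free) > 0L) {
      # Stationarity on the free block with multiplier nu for y'a = 0:
      # Q_ff a_f + q_fixed - 1 + nu * y_f = 0, y_f' a_f = -sum(C y_fixed).
      kkt <- rbind(cbind(q[free, free, drop = FALSE], y[free]),
                   c(y[free], 0))
      rhs <- c(1 - fixed_contrib[free], -sum(C * y[st == 1L]))
      sol <- tryCatch(solve(kkt, rhs), error = function(e) NULL)
      if (is.null(sol)) {
        sol <- tryCatch(MASS::ginv(kkt) %*% rhs, error = function(e) NULL)
        if (is.null(sol)) next
      }
      a[free] <- sol[seq_along(free)]
    } else if (abs(sum(a * y)) > 1e-9) {
      next
    }
    if (any(a < -1e-9) || any(a > C + 1e-9)) next
    if (abs(sum(a * y)) > 1e-7) next
    o <- obj(pmin(pmax(a, 0), C))
    if (o < best$objective) best <- list(objective = o, alpha = a)
  }
  best
}

# Small synthetic preset for fast end-to-end tests.
small_preset <- function(seed = 5L, effect_size = 3) {
  synthetic_config(n_per_class = c(12L, 18L, 14L, 16L), p = 300L,
                   n_latent = 10L, informative_ranks = c(1L, 3L, 4L),
                   effect_size = effect_size, seed = seed)
}
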