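# Internal fast path for GA fitness evaluation.
#
# The wrapper fitness retrains the SVM tree once per fold for every mask
# the GA visits.  Because the RBF kernel factorises over score dimensions
# as ||x - y||^2 = sum_d (x_d - y_d)^2, the per-dimension squared
# differences can be computed once per run; the Gram matrix of any mask is
# then one matrix-vector product and an exp().  Training and prediction
# work directly on rows/columns of that precomputed Gram matrix, using the
# same SMO solver and class-split policy as build_tree(), so the engine is
# algebraically identical to the plain path (asserted in the tests).

# n^2 x d matrix of per-dimension squared differences, column-major over
# the flattened n x n index.
dim_sq_diffs <- function(x) {
  n <- nrow(x)
  out <- matrix(0, n * n, ncol(x))
  for (d in seq_len(ncol(x))) {
    diff <- outer(x[, d], x[, d], "-")
    out[, d] <- diff * diff
  }
  out
}

# Kernel-space SVM tree: same recursion as build_tree(), but every node
# stores support-vector indices into the global training rows, so
# prediction needs only the test-vs-train Gram rows.
train_tree_kernel <- function(kmat, labels, C, class_means, split_policy,
                              tol = 1e-3) {
  classes <- levels(droplevels(labels))
  grow <- function(cls) {
    if (length(cls) == 1L) return(list(leaf = TRUE, class = cls))
    halves <- split_classes(cls, class_means, split_policy)
    idx <- which(labels %in% cls)
    ysign <- ifelse(labels[idx] %in% halves$left, 1, -1)
    sol <- smo_solve_cpp(kmat[idx, idx, drop = FALSE], ysign, C, tol,
                         1000000L)
    if (!sol$converged) {
      stopf("SMO did not converge in %d iterations", sol$iterations)
    }
    sv <- sol$alpha > 1e-8
    list(leaf = FALSE, sv_rows = idx[sv],
         coefs = sol$alpha[sv] * ysign[sv], b = sol$b,
         left = grow(halves$left), right = grow(halves$right))
  }
  list(root = grow(classes), classes = classes)
}

# kte: Gram rows test x train (global training columns).
predict_tree_kernel <- function(tree, kte) {
  out <- character(nrow(kte))
  route <- function(node, idx) {
    if (length(idx) == 0L) return(invisible())
    if (node$leaf) {
      out[idx] <<- node$class
      return(invisible())
    }
    g <- drop(kte[idx, node$sv_rows, drop = FALSE] %*% node$coefs) + node$b
    route(node$left, idx[g >= 0])
    route(node$right, idx[g < 0])
  }
  route(tree$root, seq_len(nrow(kte)))
  factor(out, levels = tree$classes)
}

# Returns function(mask) -> pooled CV accuracy over the fixed folds.
make_fitness_engine <- function(scores, params, fold_ids,
                                split_policy = "centroid") {
  stopifnot(inherits(scores, "score_set"))
  x <- scores$scores
  labels <- droplevels(scores$labels)
  n <- nrow(x)
  d2 <- dim_sq_diffs(x)
  denom <- 2 * params$sigma^2
  folds <- sort(unique(fold_ids))
  test_idx <- lapply(folds, function(f) which(fold_ids == f))
  train_idx <- lapply(folds, function(f) which(fold_ids != f))

  function(mask) {
    mask <- as.numeric(mask)
    kmat <- matrix(exp(-(d2 %*% mask) / denom), n, n)
    xm <- x[, mask == 1, drop = FALSE]
    correct <- 0L
    for (f in seq_along(folds)) {
      tr <- train_idx[[f]]
      te <- test_idx[[f]]
      cm <- t(vapply(levels(labels), function(cl) {
        colMeans(xm[tr[labels[tr] == cl], , drop = FALSE])
      }, numeric(ncol(xm))))
      tree <- train_tree_kernel(kmat[tr, tr, drop = FALSE], labels[tr],
                                params$C, cm, split_policy)
      pred <- predict_tree_kernel(tree, kmat[te, tr, drop = FALSE])
      correct <- correct + sum(pred == labels[te])
    }
    correct / n
  }
}
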