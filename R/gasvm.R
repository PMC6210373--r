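#' Fit a GA-SVM classifier on principal-component scores
#'
#' The package's core estimator.  Starting from a candidate set of PC
#' score columns, a genetic algorithm searches for the `k`-subset whose
#' decision-tree RBF-SVM achieves the best cross-validated prediction
#' accuracy ([run_ga()]); the final SVM tree is then trained on all
#' supplied samples restricted to the winning subset.  The selected
#' components are typically *not* the top-variance ones — components low
#' on the variance ladder can be the most class-discriminative — which is
#' the point of wrapper selection over simply taking the first `k` PCs.
#'
#' @param x a [score_set], or a numeric score matrix (rows = samples,
#'   columns = candidate PCs).
#' @param labels class labels (ignored when `x` is a `score_set` carrying
#'   labels).
#' @param k subset size to select (default 14).
#' @param params an [svm_params]; default `C = 2`, `sigma = 2`.
#' @param ga a [ga_config] for the search; its `k` is overridden by `k`.
#' @param cv_folds folds of the fitness cross-validation (default 5).
#' @param split_policy class split policy of the SVM tree, see
#'   [build_tree()].
#' @param seed convenience override for `ga$seed`.
#' @return An object of class `ga_svm` with components `mask` (0/1 over
#'   candidates), `selected` (indices), `tree` (the fitted [build_tree()]),
#'   `cv_accuracy` (best GA fitness), `trace` (GA fitness trace),
#'   `information` (explained-variance fraction of the selection, when the
#'   score set carries its PCA model), `params`, `ga`.
#' @examples
#' gen <- generate_spectra(synthetic_config(n_per_class = c(12, 12, 12, 12),
#'                                          p = 150, n_latent = 6,
#'                                          informative_ranks = c(1, 3, 4),
#'                                          seed = 2))
#' sc <- transform_spectra(gen$spectra, fit_pca(gen$spectra, 6))
#' fit <- ga_svm(sc, k = 3, ga = ga_config(k = 3, pop_size = 12,
#'                                         max_generations = 8, seed = 1))
#' fit$selected
#' @export
ga_svm <- function(x, labels = NULL, k = 14L, params = svm_params(),
                   ga = ga_config(k = k), cv_folds = 5L,
                   split_policy = "centroid", seed = NULL) {
  if (!inherits(x, "score_set")) {
    x <- score_set(x, labels)
  }
  ga$k <- as.integer(k)
  if (!is.null(seed)) ga$seed <- as.integer(seed)
  if (ga$k > ncol(x$scores)) {
    stopf("k = %d exceeds the %d candidate components", ga$k, ncol(x$scores))
  }
  res <- run_ga(x, params, ga, cv_folds = cv_folds,
                split_policy = split_policy)
  sel <- which(res$best_mask == 1L)
  tree <- build_tree(x$scores[, sel, drop = FALSE], x$labels, params,
                     split_policy = split_policy)
  info <- if (!is.null(x$model)) explained_information(x$model, res$best_mask)
          else NA_real_
  structure(
    list(mask = res$best_mask, selected = sel, tree = tree,
         cv_accuracy = res$best_fitness, trace = res$trace,
         generations = res$generations, information = info,
         params = params, ga = ga, n_candidates = ncol(x$scores),
         classes = levels(x$labels)),
    class = "ga_svm"
  )
}

#' @export
print.ga_svm <- function(x, ...) {
  cat("GA-SVM classifier\n")
  cat(sprintf("  selected %d of %d PCs: %s\n", length(x$selected),
              x$n_candidates, paste(x$selected, collapse = ", ")))
  cat(sprintf("  mask: %s\n", mask_string(x$mask)))
  cat(sprintf("  CV accuracy (fitness): %.3f after %d generations\n",
              x$cv_accuracy, x$generations))
  if (!is.na(x$information)) {
    cat(sprintf("  information (explained variance) of selection: %.1f%%\n",
                100 * x$information))
  }
  cat(sprintf("  SVM: C = %g, sigma = %g, %d classes\n", x$params$C,
              x$params$sigma, length(x$classes)))
  invisible(x)
}

#' @export
summary.ga_svm <- function(object, ...) {
  structure(list(fit = object), class = "summary.ga_svm")
}

#' @export
print.summary.ga_svm <- function(x, ...) {
  print(x$fit)
  tr <- x$fit$trace
  cat("\nGA trace (last generations):\n")
  print(tail(tr, 5L), row.names = FALSE)
  invisible(x)
}

#' Predict classes from a fitted GA-SVM
#'
#' @param object a [ga_svm()] fit.
#' @param newdata a [score_set] or score matrix over the *full* candidate
#'   PC set (the fit subsets to its selected columns), or already
#'   restricted to `length(object$selected)` columns.
#' @param ... unused.
#' @return Factor of predicted class labels.
#' @export
predict.ga_svm <- function(object, newdata, ...) {
  if (inherits(newdata, "score_set")) newdata <- newdata$scores
  newdata <- rbind(as.matrix(newdata))
  if (ncol(newdata) == object$n_candidates) {
    newdata <- newdata[, object$selected, drop = FALSE]
  } else if (ncol(newdata) != length(object$selected)) {
    stopf("newdata has %d columns; expected %d candidates or %d selected",
          ncol(newdata), object$n_candidates, length(object$selected))
  }
  predict(object$tree, newdata)
}

#' @export
coef.ga_svm <- function(object, ...) {
  stats::setNames(object$mask, paste0("PC", seq_along(object$mask)))
}

#' Plot the GA fitness trace of a fitted GA-SVM
#'
#' Best-so-far and population-mean fitness per generation; with elitism
#' the best trace is non-decreasing.
#'
#' @param x a [ga_svm()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ga_svm <- function(x, ...) {
  tr <- x$trace
  plot(tr$generation, tr$best, type = "s", ylim = range(tr$mean, tr$best),
       xlab = "generation", ylab = "fitness (CV accuracy)",
       main = "GA-SVM fitness trace", ...)
  lines(tr$generation, tr$mean, lty = 2)
  legend("bottomright", legend = c("best", "population mean"),
         lty = c(1, 2), bty = "n")
  invisible(x)
}
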