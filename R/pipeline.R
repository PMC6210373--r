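#' Run the full NIR classification pipeline
#'
#' End-to-end orchestration: Savitzky-Golay de-noising, Mahalanobis
#' outlier removal, PCA to `n_components` candidate PCs, a stratified
#' 80/20 train/test split, then for every requested subset size `k` both a
#' GA-selected subset model ([ga_svm()]) and the baseline using the first
#' `k` PCs, each trained on the training scores and measured on the
#' held-out test scores.  One global seed fans out deterministically to
#' the split and the per-`k` GA runs, so the whole report is reproducible.
#'
#' @param ds a [spectra_set], or a list as returned by
#'   [generate_spectra()] (its `$spectra` is used).
#' @param subset_sizes PC subset sizes to sweep (default
#'   `c(6, 8, 10, 12, 14, 16)`).
#' @param n_components candidate PC count (default 25).
#' @param params an [svm_params] used throughout; alternatively set
#'   `grid_search = TRUE` to pick it by [grid_search_params()] on the
#'   training scores first.
#' @param ga_template a [ga_config] whose settings (population, rates,
#'   generations) are reused for every `k`; its `k` and `seed` fields are
#'   overridden per run.
#' @param sg a [sg_config] (or `NULL` to skip smoothing).
#' @param outlier_quantile chi-squared quantile for outlier removal
#'   (`NULL` skips removal).
#' @param train_fraction training fraction of the split (default 0.8).
#' @param grid_search pick `(C, sigma)` by grid search before the sweep.
#' @param cv_folds folds for GA fitness (and grid search).
#' @param seed global seed.
#' @return An object of class `nir_pipeline_run`: `accuracy_by_k` (data
#'   frame with GA-SVM and first-k test accuracies and information
#'   fractions, in percent), `masks` (candidate x subset-size 0/1 matrix),
#'   `fits` (the [ga_svm()] objects), `metrics` (per-class test
#'   [metrics()] for the best GA-SVM k), `pca`, `outliers`, `split`,
#'   `params` and `manifest`.
#' @export
run_pipeline <- function(ds, subset_sizes = c(6L, 8L, 10L, 12L, 14L, 16L),
                         n_components = 25L, params = svm_params(),
                         ga_template = ga_config(k = 1L),
                         sg = sg_config(), outlier_quantile = 0.999,
                         train_fraction = 0.8, grid_search = FALSE,
                         cv_folds = 5L, seed = 1L) {
  if (is.list(ds) && !inherits(ds, "spectra_set") && !is.null(ds$spectra)) {
    ds <- ds$spectra
  }
  stopifnot(inherits(ds, "spectra_set"))
  if (any(subset_sizes > n_components)) {
    stopf("subset sizes %s exceed the %d candidate components",
          paste(subset_sizes[subset_sizes > n_components], collapse = ", "),
          n_components)
  }

  if (!is.null(sg)) ds <- sg_smooth(ds, sg)
  outrep <- NULL
  if (!is.null(outlier_quantile)) {
    out <- remove_outliers(ds, n_components = n_components,
                           quantile = outlier_quantile)
    ds <- out$spectra
    outrep <- out$report
  }
  pca <- fit_pca(ds, k = min(n_components, nrow(ds$absorbance) - 1L))
  scores <- transform_spectra(ds, pca)
  split <- split_train_test(scores$labels, train_fraction = train_fraction,
                            seed = derive_seed(seed, 2L))
  train <- subset_scores(scores, split$train)
  test <- subset_scores(scores, split$test)

  if (grid_search) {
    gs <- grid_search_params(train, folds = cv_folds,
                             seed = derive_seed(seed, 3L))
    params <- gs$params
  }

  rows <- list()
  masks <- matrix(0L, ncol(scores$scores), length(subset_sizes),
                  dimnames = list(paste0("PC", seq_len(ncol(scores$scores))),
                                  as.character(subset_sizes)))
  fits <- list()
  for (i in seq_along(subset_sizes)) {
    k <- subset_sizes[i]
    ga <- ga_template
    ga$k <- as.integer(k)
    ga$seed <- derive_seed(seed, 10L + i)
    fit <- ga_svm(train, k = k, params = params, ga = ga,
                  cv_folds = cv_folds)
    ga_acc <- mean(predict(fit, test) == test$labels)

    first_mask <- as.integer(seq_len(ncol(scores$scores)) <= k)
    first_tree <- build_tree(train$scores[, seq_len(k), drop = FALSE],
                             train$labels, params)
    first_acc <- mean(predict(first_tree,
                              test$scores[, seq_len(k), drop = FALSE]) ==
                        test$labels)

    masks[, i] <- fit$mask
    fits[[as.character(k)]] <- fit
    rows[[i]] <- data.frame(
      k = k,
      ga_svm_accuracy = 100 * ga_acc,
      ga_svm_information = 100 * explained_information(pca, fit$mask),
      svm_accuracy = 100 * first_acc,
      svm_information = 100 * explained_information(pca, first_mask)
    )
  }
  accuracy_by_k <- do.call(rbind, rows)

  best_i <- which.max(accuracy_by_k$ga_svm_accuracy)
  best_fit <- fits[[best_i]]
  cm <- confusion(test$labels, predict(best_fit, test))
  structure(
    list(accuracy_by_k = accuracy_by_k, masks = masks, fits = fits,
         metrics = metrics(cm), confusion = cm,
         best_k = subset_sizes[best_i], pca = pca, outliers = outrep,
         split = split, params = params,
         manifest = list(seed = seed, subset_sizes = subset_sizes,
                         n_components = n_components,
                         n_samples = length(scores$labels),
                         n_train = length(split$train),
                         n_test = length(split$test),
                         C = params$C, sigma = params$sigma,
                         ga = unclass(ga_template)[c(
                           "pop_size", "max_generations", "p_crossover",
                           "p_mutation", "elitism_count",
                           "stagnation_limit")])),
    class = "nir_pipeline_run"
  )
}

#' @export
print.nir_pipeline_run <- function(x, ...) {
  cat("NIR GA-SVM pipeline run\n")
  cat(sprintf("  %d train / %d test samples, %d candidate PCs\n",
              x$manifest$n_train, x$manifest$n_test,
              x$manifest$n_components))
  if (!is.null(x$outliers)) {
    cat(sprintf("  outliers removed: %d\n", length(x$outliers$flagged)))
  }
  cat(sprintf("  SVM parameters: C = %g, sigma = %g\n", x$params$C,
              x$params$sigma))
  cat("\nTest accuracy by subset size (percent):\n")
  print(x$accuracy_by_k, row.names = FALSE, digits = 4)
  cat(sprintf("\nBest GA-SVM subset size: k = %d\n", x$best_k))
  invisible(x)
}

#' Write pipeline artifacts to a directory
#'
#' Emits `accuracy_by_k.csv` (test accuracy and information per subset
#' size), `masks.csv` (the 0/1 selection matrix, candidates x subset
#' sizes), `metrics.csv` (per-class test criteria for the best subset
#' size), `outliers.csv` and `manifest.json`.
#'
#' @param run a [run_pipeline()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(run, dir) {
  stopifnot(inherits(run, "nir_pipeline_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(run$accuracy_by_k, file.path(dir, "accuracy_by_k.csv"),
            row.names = FALSE)
  write.csv(data.frame(PC = rownames(run$masks), run$masks,
                       check.names = FALSE),
            file.path(dir, "masks.csv"), row.names = FALSE)
  write.csv(run$metrics$per_class, file.path(dir, "metrics.csv"),
            row.names = FALSE)
  if (!is.null(run$outliers)) {
    write.csv(data.frame(sample = seq_along(run$outliers$distances),
                         distance = run$outliers$distances,
                         flagged = seq_along(run$outliers$distances) %in%
                           run$outliers$flagged),
              file.path(dir, "outliers.csv"), row.names = FALSE)
  }
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Sweep one GA hyperparameter and collect fitness traces
#'
#' Re-runs the GA on the same training scores for each value of one
#' hyperparameter axis (population size, crossover probability or mutation
#' probability) and returns the per-generation best-fitness traces, the
#' raw material for convergence-versus-setting comparisons.
#'
#' @param scores a [score_set] of training samples.
#' @param axis `"population"`, `"crossover"` or `"mutation"`.
#' @param values numeric values to try on that axis.
#' @param params an [svm_params].
#' @param base_cfg a [ga_config] providing all other settings.
#' @param cv_folds fitness CV folds.
#' @return A data frame with columns `axis`, `value`, `generation`,
#'   `best`, `mean`.
#' @export
sweep_ga_hyperparams <- function(scores, axis = c("population", "crossover",
                                                  "mutation"),
                                 values, params = svm_params(),
                                 base_cfg = ga_config(k = 6L),
                                 cv_folds = 5L) {
  axis <- match.arg(axis)
  if (length(values) == 0L) stopf("no axis values supplied")
  out <- lapply(values, function(v) {
    cfg <- base_cfg
    switch(axis,
           population = {
             if (!is_count(v) || v < 4L || v %% 2 != 0) {
               stopf("population values must be even integers >= 4")
             }
             cfg$pop_size <- as.integer(v)
           },
           crossover = {
             if (v <= 0 || v > 1) stopf("crossover values must be in (0, 1]")
             cfg$p_crossover <- v
           },
           mutation = {
             if (v < 0 || v >= 1) stopf("mutation values must be in [0, 1)")
             cfg$p_mutation <- v
           })
    res <- run_ga(scores, params, cfg, cv_folds = cv_folds)
    data.frame(axis = axis, value = v, res$trace)
  })
  do.call(rbind, out)
}
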