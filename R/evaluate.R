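#' Random train/test split
#'
#' Draws a seeded random split with `ceiling(train_fraction * N)` training
#' samples (so 332 samples at 0.8 give the conventional 266/66).  The
#' stratified default allocates the training count across classes by
#' largest-remainder rounding of the per-class targets, keeping every
#' class represented on both sides even under strong imbalance.
#'
#' @param labels class label per sample (or a [spectra_set] / [score_set],
#'   whose labels are used).
#' @param train_fraction fraction assigned to training (default 0.8).
#' @param stratified draw within classes (default `TRUE`).
#' @param seed RNG seed.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   covering all samples).
#' @examples
#' sp <- split_train_test(rep(letters[1:4], c(38, 144, 70, 80)), seed = 1)
#' lengths(sp)  # 266, 66
#' @export
split_train_test <- function(labels, train_fraction = 0.8, stratified = TRUE,
                             seed = 1L) {
  if (inherits(labels, "spectra_set") || inherits(labels, "score_set")) {
    labels <- labels$labels
  }
  labels <- factor(labels)
  n <- length(labels)
  if (n < 5L) stopf("need at least 5 samples to split, got %d", n)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stopf("train_fraction must be strictly between 0 and 1")
  }
  n_train <- as.integer(ceiling(train_fraction * n))

  with_rng(seed, {
    if (!stratified) {
      train <- sort(sample.int(n, n_train))
    } else {
      counts <- table(labels)
      if (any(counts < 2L)) {
        stopf("stratified split needs >= 2 samples per class; class '%s' has %d",
              names(counts)[counts < 2L][1L], min(counts))
      }
      targets <- as.numeric(counts) * train_fraction
      base <- floor(targets)
      short <- n_train - sum(base)
      if (short > 0) {
        extra <- order(targets - base, decreasing = TRUE)[seq_len(short)]
        base[extra] <- base[extra] + 1L
      } else if (short < 0) {
        trim <- order(targets - base)[seq_len(-short)]
        base[trim] <- base[trim] - 1L
      }
      # every class keeps at least one training sample; re-balance the
      # total if that floor binds
      base <- pmax(base, 1L)
      over <- sum(base) - n_train
      while (over > 0) {
        cand <- which(base > 1L)
        drop_i <- cand[which.max(base[cand] - targets[cand])]
        base[drop_i] <- base[drop_i] - 1L
        over <- over - 1L
      }
      train <- integer(0)
      for (ci in seq_along(counts)) {
        idx <- which(labels == names(counts)[ci])
        train <- c(train, sample(idx, base[ci]))
      }
      train <- sort(train)
    }
    list(train = train, test = setdiff(seq_len(n), train))
  })
}

#' Grid search for the SVM parameter pair
#'
#' Evaluates every `(C, sigma)` cell of a grid by stratified k-fold
#' cross-validated accuracy of the decision-tree RBF-SVM and returns the
#' maximising pair; ties break towards smaller `C`, then smaller `sigma`.
#' The default grid spans half-powers of two around 1, which covers the
#' 0.7 / 1.4 / 2.0 values typical for PC-score inputs.
#'
#' @param scores a [score_set] of training samples.
#' @param C_grid,sigma_grid candidate values (default `2^(seq(-2, 2, 0.5))`).
#' @param folds CV folds (default 5).
#' @param seed fold-assignment seed.
#' @param split_policy tree split policy, see [build_tree()].
#' @return List with `params` (the winning [svm_params]), `accuracy` (its
#'   CV accuracy) and `table` (data frame C, sigma, cv_accuracy for every
#'   cell).
#' @export
grid_search_params <- function(scores, C_grid = 2^seq(-2, 2, by = 0.5),
                               sigma_grid = 2^seq(-2, 2, by = 0.5),
                               folds = 5L, seed = 1L,
                               split_policy = "centroid") {
  stopifnot(inherits(scores, "score_set"))
  if (length(C_grid) == 0L || length(sigma_grid) == 0L) {
    stopf("parameter grid is empty")
  }
  fold_ids <- stratified_folds(scores$labels, folds, seed = seed)
  full_mask <- rep(1L, ncol(scores$scores))
  grid <- expand.grid(C = sort(C_grid), sigma = sort(sigma_grid),
                      KEEP.OUT.ATTRS = FALSE)
  grid$cv_accuracy <- vapply(seq_len(nrow(grid)), function(i) {
    evaluate_fitness(full_mask, scores,
                     svm_params(grid$C[i], grid$sigma[i]),
                     fold_ids = fold_ids, split_policy = split_policy)
  }, numeric(1))
  best <- grid[order(-grid$cv_accuracy, grid$C, grid$sigma), ][1L, ]
  list(params = svm_params(best$C, best$sigma),
       accuracy = best$cv_accuracy, table = grid)
}

#' Confusion matrix with one-vs-rest counts
#'
#' Cross-tabulates true against predicted labels and derives, for each
#' class treated as the positive pattern, the counts nTP (true positives),
#' nFN (false negatives), nFP (false positives) and nTN (true negatives).
#'
#' @param truth true labels.
#' @param predicted predicted labels (levels must be a subset of the truth
#'   levels union).
#' @return An object of class `confusion_matrix`: `table` (classes x
#'   classes), `counts` (per-class data frame of nTP/nFN/nFP/nTN),
#'   `n_correct`, `n_total`.
#' @export
confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stopf("truth and predicted lengths differ (%d vs %d)",
          length(truth), length(predicted))
  }
  lev_of <- function(x) if (is.factor(x)) levels(x) else
    sort(unique(as.character(x)))
  classes <- union(lev_of(truth), lev_of(predicted))
  truth <- factor(truth, levels = classes)
  predicted <- factor(predicted, levels = classes)
  tab <- table(truth = truth, predicted = predicted)
  n_total <- length(truth)
  counts <- data.frame(
    class = classes,
    nTP = vapply(classes, function(cl) sum(truth == cl & predicted == cl),
                 numeric(1)),
    nFN = vapply(classes, function(cl) sum(truth == cl & predicted != cl),
                 numeric(1)),
    nFP = vapply(classes, function(cl) sum(truth != cl & predicted == cl),
                 numeric(1)),
    nTN = vapply(classes, function(cl) sum(truth != cl & predicted != cl),
                 numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(table = tab, counts = counts,
                 n_correct = sum(diag(tab)), n_total = n_total),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  print(x$table)
  cat(sprintf("accuracy %d / %d = %.3f\n", x$n_correct, x$n_total,
              x$n_correct / x$n_total))
  invisible(x)
}

#' Per-class evaluation criteria from a confusion matrix
#'
#' Computes, per class in the one-vs-rest convention:
#' sensitivity \eqn{\gamma_{TP} = n_{TP}/(n_{TP}+n_{FN})},
#' specificity \eqn{\gamma_{TN} = n_{TN}/(n_{TN}+n_{FP})},
#' precision \eqn{\gamma_{PP} = n_{TP}/(n_{TP}+n_{FP})} and
#' F1 \eqn{\gamma = 2 n_{TP}/(2 n_{TP}+n_{FP}+n_{FN})},
#' plus the overall prediction accuracy \eqn{P_a = n_r / N_t}.  Ratios with
#' a zero denominator are reported as `NA` with a warning.
#'
#' @param cm a [confusion()] result.
#' @return An object of class `metrics_report`: `per_class` data frame
#'   (class, sensitivity, specificity, precision, f1) and `accuracy`.
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$n_total == 0L) stopf("empty confusion matrix")
  safe_div <- function(num, den, what) {
    out <- num / den
    if (any(den == 0)) {
      warnf("%s undefined (zero denominator) for class(es) %s", what,
            paste(cm$counts$class[den == 0], collapse = ", "))
      out[den == 0] <- NA_real_
    }
    out
  }
  with(cm$counts, {
    sens <- safe_div(nTP, nTP + nFN, "sensitivity")
    spec <- safe_div(nTN, nTN + nFP, "specificity")
    prec <- safe_div(nTP, nTP + nFP, "precision")
    f1 <- safe_div(2 * nTP, 2 * nTP + nFP + nFN, "F1")
    structure(
      list(per_class = data.frame(class = class, sensitivity = sens,
                                  specificity = spec, precision = prec,
                                  f1 = f1, row.names = NULL),
           accuracy = cm$n_correct / cm$n_total),
      class = "metrics_report"
    )
  })
}

#' @export
print.metrics_report <- function(x, ...) {
  print(x$per_class, digits = 3)
  cat(sprintf("overall prediction accuracy: %.3f\n", x$accuracy))
  invisible(x)
}

#' F1 score from sensitivity and precision
#'
#' Harmonic mean `2 * precision * sensitivity / (precision + sensitivity)`,
#' algebraically identical to the count form
#' `2 nTP / (2 nTP + nFP + nFN)`.
#'
#' @param sensitivity,precision rates in `[0, 1]` (vectorised).
#' @return F1 values; `NA` where both rates are zero.
#' @export
f1_from_rates <- function(sensitivity, precision) {
  out <- 2 * precision * sensitivity / (precision + sensitivity)
  out[precision + sensitivity == 0] <- NA_real_
  out
}
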