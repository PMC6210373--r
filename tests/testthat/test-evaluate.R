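test_that("split sizes follow the ceiling rule, including 332 -> 266/66", {
  labels332 <- rep(paste0("c", 1:4), c(38, 144, 70, 80))
  sp <- split_train_test(labels332, seed = 1)
  expect_length(sp$train, 266L)
  expect_length(sp$test, 66L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), seq_len(332))
  # every class present on both sides
  expect_equal(sort(unique(as.character(labels332[sp$test]))),
               paste0("c", 1:4))

  tiny <- split_train_test(rep(c("a", "b"), c(3, 2)), seed = 2)
  expect_length(tiny$train, 4L)
  expect_length(tiny$test, 1L)

  expect_identical(split_train_test(labels332, seed = 7),
                   split_train_test(labels332, seed = 7))
  expect_false(identical(split_train_test(labels332, seed = 7)$train,
                         split_train_test(labels332, seed = 8)$train))
  expect_error(split_train_test(rep("a", 4)), "at least 5")
  expect_error(split_train_test(c("a", "a", "a", "a", "b")), "2 samples")
})

test_that("non-stratified splits keep the same arithmetic", {
  sp <- split_train_test(rep("x", 25), stratified = FALSE, seed = 3)
  expect_length(sp$train, 20L)
  expect_length(sp$test, 5L)
})

test_that("grid search returns the argmax with deterministic tie-breaks", {
  ss <- toy_scores_4class(n_per = 10)
  gs <- grid_search_params(ss, C_grid = c(0.5, 2), sigma_grid = c(1, 2),
                           folds = 3, seed = 5)
  expect_equal(nrow(gs$table), 4L)
  expect_equal(gs$accuracy, max(gs$table$cv_accuracy))
  # independent re-evaluation of every cell reproduces the table
  fold_ids <- nirselect:::stratified_folds(ss$labels, 3, seed = 5)
  for (r in seq_len(nrow(gs$table))) {
    again <- evaluate_fitness(rep(1L, 2), ss,
                              svm_params(gs$table$C[r], gs$table$sigma[r]),
                              fold_ids = fold_ids)
    expect_equal(gs$table$cv_accuracy[r], again, tolerance = 1e-12)
  }
  # single-cell grid returns that cell
  one <- grid_search_params(ss, C_grid = 2, sigma_grid = 2, folds = 3,
                            seed = 5)
  expect_equal(one$params$C, 2)
  expect_equal(one$params$sigma, 2)
  # ties break towards smaller C then smaller sigma
  tied <- data.frame(C = c(2, 1), sigma = c(2, 1), cv_accuracy = c(0.9, 0.9))
  best <- tied[order(-tied$cv_accuracy, tied$C, tied$sigma), ][1, ]
  expect_equal(best$C, 1)
  expect_error(grid_search_params(ss, C_grid = numeric(0)), "empty")
})

test_that("confusion counts match a brute-force tally", {
  set.seed(20)
  classes <- paste0("c", 1:4)
  truth <- factor(sample(classes, 100, replace = TRUE), levels = classes)
  pred <- factor(sample(classes, 100, replace = TRUE), levels = classes)
  cm <- confusion(truth, pred)
  for (cl in classes) {
    tp <- fn <- fp <- tn <- 0
    for (i in 1:100) {
      is_pos <- truth[i] == cl
      said_pos <- pred[i] == cl
      if (is_pos && said_pos) tp <- tp + 1
      if (is_pos && !said_pos) fn <- fn + 1
      if (!is_pos && said_pos) fp <- fp + 1
      if (!is_pos && !said_pos) tn <- tn + 1
    }
    row <- cm$counts[cm$counts$class == cl, ]
    expect_equal(unlist(row[c("nTP", "nFN", "nFP", "nTN")]),
                 c(nTP = tp, nFN = fn, nFP = fp, nTN = tn))
    expect_equal(sum(row[c("nTP", "nFN", "nFP", "nTN")]), 100)
  }
  expect_equal(sum(cm$counts$nTP), cm$n_correct)
  expect_error(confusion(truth, pred[-1]), "lengths differ")
})

test_that("degenerate predictions produce the forced confusion counts", {
  truth <- rep(paste0("c", 1:4), each = 10)
  pred <- rep("c2", 40)
  cm <- confusion(truth, factor(pred, levels = paste0("c", 1:4)))
  c2 <- cm$counts[cm$counts$class == "c2", ]
  expect_equal(c2$nTP, 10)
  expect_equal(c2$nFP, 30)
  others <- cm$counts[cm$counts$class != "c2", ]
  expect_true(all(others$nTP == 0) && all(others$nFN == 10))

  perfect <- confusion(truth, truth)
  expect_true(all(perfect$counts$nFP == 0) && all(perfect$counts$nFN == 0))
  m <- metrics(perfect)
  expect_true(all(unlist(m$per_class[, -1]) == 1))
  expect_equal(m$accuracy, 1)
})

test_that("metrics reproduce the four criteria and the F1 identity", {
  # worked per-class examples: sensitivity/precision pairs -> F1 at
  # 2-decimal rounding
  expect_equal(round(f1_from_rates(0.92, 1.00), 2), 0.96)
  expect_equal(round(f1_from_rates(0.88, 1.00), 2), 0.94)
  expect_equal(round(f1_from_rates(0.67, 0.67), 2), 0.67)
  expect_equal(round(f1_from_rates(0.84, 0.75), 2), 0.79)

  set.seed(42)
  truth <- factor(sample(paste0("c", 1:3), 60, replace = TRUE))
  pred <- factor(sample(paste0("c", 1:3), 60, replace = TRUE),
                 levels = levels(truth))
  m <- metrics(confusion(truth, pred))
  cm <- confusion(truth, pred)
  with(cm$counts, {
    expect_equal(m$per_class$sensitivity, nTP / (nTP + nFN))
    expect_equal(m$per_class$specificity, nTN / (nTN + nFP))
    expect_equal(m$per_class$precision, nTP / (nTP + nFP))
    expect_equal(m$per_class$f1, 2 * nTP / (2 * nTP + nFP + nFN))
  })
  # accuracy from counts equals the direct mean
  expect_equal(m$accuracy, mean(pred == truth))
  # count-form F1 equals the harmonic mean wherever both are defined
  ok <- !is.na(m$per_class$precision) & m$per_class$precision +
    m$per_class$sensitivity > 0
  expect_equal(m$per_class$f1[ok],
               f1_from_rates(m$per_class$sensitivity,
                             m$per_class$precision)[ok])
})

test_that("zero-denominator rates become NA with a warning", {
  truth <- factor(c("a", "a", "b"), levels = c("a", "b", "c"))
  pred <- factor(c("a", "a", "a"), levels = c("a", "b", "c"))
  w <- capture_warnings(m <- metrics(confusion(truth, pred)))
  expect_true(any(grepl("undefined", w)))
  expect_true(is.na(m$per_class$precision[m$per_class$class == "c"]))
  expect_true(is.na(m$per_class$f1[m$per_class$class == "c"]))
})
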