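test_that("rbf_kernel matches its closed form and is a valid kernel", {
  expect_equal(rbf_kernel(c(1, 2), c(1, 2), sigma = 3), 1)
  expect_equal(rbf_kernel(c(0, 0), c(0, 2), sigma = sqrt(2)), exp(-1),
               tolerance = 1e-12)
  expect_error(rbf_kernel(1:3, 1:2, 1), "dimension mismatch")
  expect_error(rbf_kernel(1:3, 1:3, -1), "sigma")

  set.seed(6)
  x <- matrix(rnorm(10 * 4), 10, 4)
  gram <- rbf_kernel(x, x, sigma = 1.3)
  expect_equal(gram, t(gram), tolerance = 1e-12)
  expect_true(all(gram > 0 & gram <= 1))
  expect_gte(min(eigen(gram, symmetric = TRUE)$values), -1e-10)
})

test_that("train_binary solves separable and XOR problems", {
  set.seed(2)
  x <- rbind(matrix(rnorm(40, -2, 0.4), 20), matrix(rnorm(40, 2, 0.4), 20))
  y <- rep(c("neg", "pos"), each = 20)
  fit <- train_binary(x, y, svm_params(C = 2, sigma = 2))
  expect_equal(as.character(predict(fit, x)), y)
  g <- decision_values(fit, x)
  expect_true(all(g[1:20] < 0) && all(g[21:40] > 0))

  xor_x <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  xor_y <- c(1, 1, -1, -1)
  xf <- train_binary(xor_x, xor_y, svm_params(C = 10, sigma = 0.5))
  expect_equal(sign(decision_values(xf, xor_x)), xor_y)

  expect_error(train_binary(x, rep("a", 40)), "2 classes|single class")
  expect_error(train_binary(x, c(y, "c")), "differ|2 classes")
})

test_that("dual solutions satisfy the KKT constraints and match a
           brute-force QP oracle on tiny problems", {
  skip_if_not_installed("MASS")
  set.seed(123)
  for (rep in 1:12) {
    n <- sample(4:6, 1)
    x <- matrix(rnorm(n * 2), n, 2)
    y <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1] <- -y[1]
    C <- sample(c(0.5, 1, 2, 10), 1)
    sigma <- sample(c(0.7, 1, 2), 1)
    fit <- train_binary(x, y, svm_params(C, sigma), tol = 1e-6)
    # KKT: box and equality at tight tolerance
    expect_true(all(fit$alpha >= -1e-9 & fit$alpha <= C + 1e-9))
    expect_lt(abs(sum(fit$dual_coefs)), 1e-6)
    # objective matches exhaustive active-set enumeration
    kmat <- rbf_kernel(x, x, sigma)
    oracle <- brute_force_dual(kmat, y, C)
    expect_equal(fit$objective, oracle$objective, tolerance = 1e-4)
  }
})

test_that("decisions agree with an independent SVM implementation", {
  skip_if_not_installed("e1071")
  set.seed(10)
  x <- rbind(matrix(rnorm(60, -1), 30), matrix(rnorm(60, 1), 30))
  y <- factor(rep(c("a", "b"), each = 30))
  mine <- train_binary(x, y, svm_params(C = 2, sigma = 2), tol = 1e-6)
  ref <- e1071::svm(x, y, kernel = "radial", gamma = 1 / (2 * 2^2),
                    cost = 2, scale = FALSE)
  expect_equal(as.character(predict(mine, x)),
               as.character(predict(ref, x)))
})

test_that("the decision tree partitions classes and predicts determinately", {
  ss <- toy_scores_4class()
  tree <- build_tree(ss, params = svm_params(C = 10, sigma = 2))
  expect_equal(nirselect:::count_internal_nodes(tree$root), 3L)
  pred <- predict(tree, ss)
  expect_equal(mean(pred == ss$labels), 1)              # separable data
  # permutation equivariance
  perm <- sample(nrow(ss$scores))
  expect_equal(predict(tree, ss$scores[perm, ]), pred[perm])
  # listed-order policy forces {1,2} vs {3,4} at the root
  tl <- build_tree(ss, params = svm_params(), split_policy = "listed")
  expect_setequal(tl$root$left_classes, c("c1", "c2"))
  expect_setequal(tl$root$right_classes, c("c3", "c4"))
  # 2 classes: single node behaves like a binary machine
  two <- score_set(ss$scores[1:24, ], ss$labels[1:24])
  t2 <- build_tree(two, params = svm_params(C = 10, sigma = 2))
  expect_equal(nirselect:::count_internal_nodes(t2$root), 1L)
  b2 <- train_binary(two$scores,
                     factor(ifelse(two$labels == "c1", "left", "right"),
                            levels = c("right", "left")),
                     svm_params(C = 10, sigma = 2))
  expect_equal(as.character(predict(t2, two$scores) == "c1"),
               as.character(predict(b2, two$scores) == "left"))
  expect_error(predict(tree, ss$scores[, 1, drop = FALSE]), "dimension")
  expect_error(build_tree(ss$scores, rep("only", nrow(ss$scores))),
               "2 classes")
})
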