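test_that("ga_config validates its fields", {
  expect_error(ga_config(k = 0), "positive")
  expect_error(ga_config(k = 3, pop_size = 5), "even")
  expect_error(ga_config(k = 3, p_crossover = 0), "p_crossover")
  expect_error(ga_config(k = 3, p_mutation = 1), "p_mutation")
  expect_s3_class(ga_config(k = 6), "ga_config")
})

test_that("repair restores cardinality and leaves compliant masks alone", {
  set.seed(1)
  for (rep in 1:50) {
    n <- sample(5:25, 1)
    k <- sample(seq_len(n), 1)
    mask <- as.integer(runif(n) < runif(1))
    fixed <- repair_mask(mask, k)
    expect_equal(sum(fixed), k)
    expect_true(all(fixed %in% c(0L, 1L)))
    if (sum(mask) == k) expect_identical(fixed, mask)
    # repair only flips as many bits as needed
    expect_equal(sum(fixed != mask), abs(sum(mask) - k))
  }
})

test_that("roulette selection is fitness-proportionate", {
  set.seed(2)
  pairs <- roulette_select(c(1, 0, 0, 0), 100)
  expect_true(all(pairs == 1L))

  draws <- as.vector(roulette_select(c(3, 1), 50000))
  expect_equal(mean(draws == 1L), 0.75, tolerance = 0.01)

  eq <- as.vector(roulette_select(rep(2, 4), 50000))
  expect_equal(unname(table(eq) / length(eq)), rep(0.25, 4),
               tolerance = 0.02, ignore_attr = TRUE)

  expect_warning(z <- roulette_select(c(0, 0, 0), 10), "uniform")
  expect_true(all(z %in% 1:3))
  expect_error(roulette_select(c(-1, 2), 5), "non-negative")
})

test_that("one-point crossover exchanges tails and repair keeps k", {
  a <- c(1L, 1L, 1L, 0L, 0L, 0L)
  b <- c(0L, 0L, 0L, 1L, 1L, 1L)
  # identical parents: children equal parents whatever the cut
  set.seed(3)
  kids <- crossover_one_point(a, a, k = 3, p_crossover = 1)
  expect_identical(kids[[1]], a)
  expect_identical(kids[[2]], a)
  # cardinality is preserved across a full sweep
  for (rep in 1:30) {
    kids <- crossover_one_point(a, b, k = 3, p_crossover = 1)
    expect_equal(sum(kids[[1]]), 3L)
    expect_equal(sum(kids[[2]]), 3L)
  }
  # p_crossover = 0 is the identity
  kids0 <- crossover_one_point(a, b, k = 3, p_crossover = 0)
  expect_identical(kids0, list(a, b))
  expect_error(crossover_one_point(a, b[-1], 3), "length")
})

test_that("uniform mutation flips at the configured rate", {
  mask <- c(rep(1L, 3), rep(0L, 22))
  set.seed(4)
  expect_identical(mutate_uniform(mask, k = 3, p_mutation = 0), mask)
  m1 <- mutate_uniform(mask, k = 3, p_mutation = 1)
  expect_equal(sum(m1), 3L)
  # expected pre-repair flip count ~ Binomial(25, 0.01)
  flips <- replicate(10000, {
    flip <- runif(25) < 0.01
    sum(flip)
  })
  expect_equal(mean(flips), 0.25, tolerance = 3 * sqrt(0.25 / 10000) + 0.02)
  # through the public operator, cardinality always holds
  muts <- replicate(200, sum(mutate_uniform(mask, k = 3, p_mutation = 0.05)))
  expect_true(all(muts == 3L))
})

test_that("CV fitness is deterministic given a seed and detects signal", {
  gen <- generate_spectra(small_preset())
  sc <- transform_spectra(gen$spectra, fit_pca(gen$spectra, 10))
  informative <- as.integer(seq_len(10) %in% c(1, 3, 4))
  noise <- as.integer(seq_len(10) %in% c(6, 8, 9))
  f1 <- evaluate_fitness(informative, sc, svm_params(), cv_folds = 3,
                         seed = 9)
  f1b <- evaluate_fitness(informative, sc, svm_params(), cv_folds = 3,
                          seed = 9)
  expect_identical(f1, f1b)
  f0 <- evaluate_fitness(noise, sc, svm_params(), cv_folds = 3, seed = 9)
  expect_gt(f1, f0)
  expect_error(evaluate_fitness(rep(0L, 10), sc), "no components")
})

test_that("informative masks beat noise masks across seeds (sign test)", {
  wins <- 0L
  for (s in 1:10) {
    gen <- generate_spectra(small_preset(seed = 100 + s))
    sc <- transform_spectra(gen$spectra, fit_pca(gen$spectra, 10))
    informative <- as.integer(seq_len(10) %in% c(1, 3, 4))
    noise <- as.integer(seq_len(10) %in% c(6, 8, 9))
    f1 <- evaluate_fitness(informative, sc, svm_params(), cv_folds = 3,
                           seed = s)
    f0 <- evaluate_fitness(noise, sc, svm_params(), cv_folds = 3, seed = s)
    wins <- wins + (f1 > f0)
  }
  # one-sided binomial: 10/10 wins has p = 2^-10 under the null
  expect_equal(wins, 10L)
})

test_that("fitness on coin-flip labels sits at the chance level", {
  set.seed(55)
  x <- matrix(rnorm(120 * 6), 120, 6)
  labels <- factor(sample(paste0("c", 1:4), 120, replace = TRUE,
                          prob = rep(0.25, 4)))
  sc <- score_set(x, labels)
  f <- evaluate_fitness(rep(1L, 6), sc, svm_params(), cv_folds = 3,
                        seed = 1)
  # within 3 binomial sd of 1/4
  expect_lt(abs(f - 0.25), 3 * sqrt(0.25 * 0.75 / 120))
})

test_that("the kernel-caching fitness engine equals the plain-tree CV loop", {
  gen <- generate_spectra(small_preset(seed = 77))
  sc <- transform_spectra(gen$spectra, fit_pca(gen$spectra, 10))
  fold_ids <- nirselect:::stratified_folds(sc$labels, 3, seed = 4)
  engine <- nirselect:::make_fitness_engine(sc, svm_params(), fold_ids)
  set.seed(8)
  for (rep in 1:5) {
    mask <- integer(10); mask[sample(10, 4)] <- 1L
    plain <- 0L
    x <- sc$scores[, mask == 1, drop = FALSE]
    for (f in 1:3) {
      tr <- fold_ids != f
      tree <- build_tree(x[tr, , drop = FALSE], sc$labels[tr], svm_params())
      plain <- plain + sum(predict(tree, x[!tr, , drop = FALSE]) ==
                             sc$labels[!tr])
    }
    expect_equal(engine(mask), plain / length(fold_ids), tolerance = 1e-12)
  }
})

test_that("run_ga is reproducible, keeps cardinality and is elitist", {
  weights <- c(9, 2, 7, 1, 6, 1, 1, 5, 1, 1)
  fit_fn <- function(m) sum(weights[m == 1]) / sum(weights)
  cfg <- ga_config(k = 4, pop_size = 16, max_generations = 20, seed = 31)
  r1 <- run_ga(NULL, cfg = cfg, n_candidates = 10, fitness_fn = fit_fn)
  r2 <- run_ga(NULL, cfg = cfg, n_candidates = 10, fitness_fn = fit_fn)
  expect_identical(r1$best_mask, r2$best_mask)
  expect_identical(r1$trace, r2$trace)
  expect_equal(sum(r1$best_mask), 4L)
  expect_true(all(diff(r1$trace$best) >= 0))       # elitism invariant
  expect_error(run_ga(NULL, cfg = ga_config(k = 11), n_candidates = 10,
                      fitness_fn = fit_fn), "infeasible")
})

test_that("run_ga finds the optimum of an additive objective", {
  # deterministic additive fitness; exhaustive optimum = top-k weights
  set.seed(17)
  weights <- c(5, 1, 4, 1, 3, 1, 1, 1)
  fit_fn <- function(m) sum(weights[m == 1]) / sum(weights)
  hits <- 0L
  for (s in 1:20) {
    res <- run_ga(NULL, cfg = ga_config(k = 3, pop_size = 20,
                                        max_generations = 25, seed = s),
                  n_candidates = 8, fitness_fn = fit_fn)
    hits <- hits + identical(which(res$best_mask == 1L), c(1L, 3L, 5L))
  }
  expect_gte(hits, 19L)
})
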