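#' Genetic-algorithm configuration
#'
#' Settings of the wrapper feature selection: a population of fixed-size
#' binary masks over the candidate PCs evolves by fitness-proportionate
#' (roulette) selection, one-point crossover and uniform mutation, with
#' elitism.  The defaults — population 200, 100 generations, crossover
#' probability 0.6, mutation probability 0.01 — are the settings that a
#' hyperparameter sweep over population size and operator rates identifies
#' as the most reliable for PC-subset selection on NIR score data.
#'
#' @param k subset cardinality every chromosome must keep.
#' @param pop_size population size, even and >= 4 (default 200).
#' @param max_generations generation cap (default 100).
#' @param p_crossover per-pair crossover probability in (0, 1] (default 0.6).
#' @param p_mutation per-bit flip probability in `[0, 1)` (default 0.01).
#' @param elitism_count individuals copied unchanged into the next
#'   generation (default 1).
#' @param stagnation_limit stop early after this many generations without a
#'   best-fitness improvement > 1e-6 (default 20).
#' @param seed RNG seed for the run.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(k, pop_size = 200L, max_generations = 100L,
                      p_crossover = 0.6, p_mutation = 0.01,
                      elitism_count = 1L, stagnation_limit = 20L,
                      seed = 1L) {
  if (!is_count(k) || k < 1L) stopf("k must be a positive integer")
  if (!is_count(pop_size) || pop_size < 4L || pop_size %% 2L != 0L) {
    stopf("pop_size must be an even integer >= 4")
  }
  if (!is_count(max_generations) || max_generations < 1L) {
    stopf("max_generations must be a positive integer")
  }
  if (p_crossover <= 0 || p_crossover > 1) stopf("p_crossover must be in (0, 1]")
  if (p_mutation < 0 || p_mutation >= 1) stopf("p_mutation must be in [0, 1)")
  if (!is_count(elitism_count) || elitism_count < 0L) {
    stopf("elitism_count must be a non-negative integer")
  }
  structure(list(k = as.integer(k), pop_size = as.integer(pop_size),
                 max_generations = as.integer(max_generations),
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 elitism_count = as.integer(elitism_count),
                 stagnation_limit = as.integer(stagnation_limit),
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Repair a mask to a fixed cardinality
#'
#' Chromosomes are binary masks constrained to exactly `k` selected bits.
#' After crossover or mutation the count can drift; repair removes random
#' selected bits while the count exceeds `k` and adds random unselected
#' bits while it falls short, using the run's RNG stream.
#'
#' @param mask integer 0/1 vector.
#' @param k target cardinality.
#' @return A 0/1 vector with exactly `k` ones.
#' @export
repair_mask <- function(mask, k) {
  mask <- as.integer(mask)
  s <- sum(mask)
  if (s > k) {
    on_bits <- which(mask == 1L)
    drop_n <- s - k
    drop <- if (length(on_bits) == 1L) on_bits else
      sample(on_bits, drop_n)
    mask[drop] <- 0L
  } else if (s < k) {
    off_bits <- which(mask == 0L)
    add_n <- k - s
    add <- if (length(off_bits) == 1L) off_bits else
      sample(off_bits, add_n)
    mask[add] <- 1L
  }
  mask
}

random_mask <- function(n, k) {
  mask <- integer(n)
  mask[sample.int(n, k)] <- 1L
  mask
}

#' Roulette (fitness-proportionate) parent selection
#'
#' Draws `2 * n_pairs` parent indices with probability proportional to
#' fitness; consecutive draws form mating pairs.  If every fitness is zero
#' the draw falls back to uniform selection with a warning.
#'
#' @param fitnesses non-negative fitness per individual.
#' @param n_pairs number of parent pairs to form.
#' @return An `n_pairs` x 2 integer matrix of parent indices.
#' @export
roulette_select <- function(fitnesses, n_pairs) {
  if (any(fitnesses < 0)) stopf("fitnesses must be non-negative")
  total <- sum(fitnesses)
  prob <- if (total <= 0) {
    warnf("all fitnesses are zero; falling back to uniform selection")
    rep(1 / length(fitnesses), length(fitnesses))
  } else {
    fitnesses / total
  }
  cum <- cumsum(prob)
  draws <- findInterval(runif(2L * n_pairs), cum) + 1L
  matrix(draws, ncol = 2L, byrow = TRUE)
}

#' One-point crossover of two masks
#'
#' With probability `p_crossover` a cut point is drawn uniformly between
#' positions and the tails beyond it exchanged; both children are then
#' repaired back to cardinality `k`.  Otherwise the parents are returned
#' unchanged.
#'
#' @param a,b equal-length 0/1 vectors.
#' @param k target cardinality for repair.
#' @param p_crossover crossover probability.
#' @return List of two 0/1 vectors, each summing to `k`.
#' @export
crossover_one_point <- function(a, b, k, p_crossover = 0.6) {
  if (length(a) != length(b)) stopf("parents differ in length")
  if (runif(1) >= p_crossover || length(a) < 2L) {
    return(list(a, b))
  }
  cut <- sample.int(length(a) - 1L, 1L)
  tail_idx <- (cut + 1L):length(a)
  c1 <- a; c1[tail_idx] <- b[tail_idx]
  c2 <- b; c2[tail_idx] <- a[tail_idx]
  list(repair_mask(c1, k), repair_mask(c2, k))
}

#' Uniform mutation of a mask
#'
#' Flips each bit independently with probability `p_mutation`, then repairs
#' the cardinality back to `k`.
#'
#' @param mask 0/1 vector.
#' @param k target cardinality.
#' @param p_mutation per-bit flip probability.
#' @return Mutated 0/1 vector summing to `k`.
#' @export
mutate_uniform <- function(mask, k, p_mutation = 0.01) {
  if (p_mutation > 0) {
    flip <- runif(length(mask)) < p_mutation
    mask <- as.integer(xor(mask == 1L, flip))
  }
  repair_mask(mask, k)
}

#' Cross-validated fitness of a PC mask
#'
#' The wrapper criterion: prediction accuracy of the decision-tree RBF-SVM
#' trained on the score columns the mask selects, estimated by stratified
#' k-fold cross-validation (pooled accuracy over held-out folds).
#'
#' @param mask 0/1 vector over the score columns, at least one bit set.
#' @param scores a [score_set] of training samples.
#' @param params an [svm_params].
#' @param cv_folds number of folds (default 5).
#' @param seed seed for the fold assignment (ignored when `fold_ids` is
#'   given).
#' @param fold_ids optional precomputed fold assignment, so a GA run can
#'   score every mask against the same folds.
#' @param split_policy tree split policy, see [build_tree()].
#' @return Accuracy in `[0, 1]`; deterministic given `(mask, data, seed)`.
#' @export
evaluate_fitness <- function(mask, scores, params = svm_params(),
                             cv_folds = 5L, seed = 1L, fold_ids = NULL,
                             split_policy = "centroid") {
  stopifnot(inherits(scores, "score_set"))
  mask <- as.integer(mask)
  if (sum(mask) < 1L) stopf("mask selects no components")
  if (length(mask) != ncol(scores$scores)) {
    stopf("mask length %d does not match %d score columns",
          length(mask), ncol(scores$scores))
  }
  if (is.null(fold_ids)) {
    fold_ids <- stratified_folds(scores$labels, cv_folds, seed = seed)
  }
  engine <- make_fitness_engine(scores, params, fold_ids, split_policy)
  engine(mask)
}

#' Run the genetic algorithm over PC masks
#'
#' Evolves a population of fixed-cardinality binary masks to maximise a
#' fitness function — by default the cross-validated accuracy of the
#' decision-tree RBF-SVM on the selected score columns
#' ([evaluate_fitness()]).  Selection is roulette, variation one-point
#' crossover plus uniform mutation with cardinality repair, and the best
#' `elitism_count` individuals survive unchanged, so the best-so-far
#' fitness trace is non-decreasing.  The run stops at `max_generations` or
#' after `stagnation_limit` generations without improvement.  Fitness
#' values are cached by mask, and the whole run is reproducible from
#' `cfg$seed`.
#'
#' @param scores a [score_set] of training samples (may be `NULL` when a
#'   custom `fitness_fn` is supplied).
#' @param params an [svm_params] for the default fitness.
#' @param cfg a [ga_config]; `cfg$k` is the subset size.
#' @param n_candidates number of candidate components (defaults to the
#'   score column count).
#' @param fitness_fn optional replacement fitness `function(mask) -> value
#'   in [0, 1]`; useful for testing the optimiser against known objectives.
#' @param cv_folds folds for the default fitness (default 5).
#' @param split_policy tree split policy for the default fitness.
#' @return A list of class `ga_result`: `best_mask`, `best_fitness`,
#'   `trace` (data frame: generation, best, mean), `generations`, `cfg`.
#' @examples
#' weights <- c(5, 1, 4, 1, 3, 1, 1, 1)
#' res <- run_ga(NULL, cfg = ga_config(k = 3, pop_size = 20,
#'                                     max_generations = 15, seed = 1),
#'               n_candidates = 8,
#'               fitness_fn = function(m) sum(weights[m == 1]) / sum(weights))
#' which(res$best_mask == 1)  # 1, 3, 5
#' @export
run_ga <- function(scores, params = svm_params(), cfg, n_candidates = NULL,
                   fitness_fn = NULL, cv_folds = 5L,
                   split_policy = "centroid") {
  stopifnot(inherits(cfg, "ga_config"))
  if (is.null(n_candidates)) {
    if (is.null(scores)) stopf("n_candidates required when scores is NULL")
    n_candidates <- ncol(scores$scores)
  }
  if (cfg$k > n_candidates) {
    stopf("infeasible subset size: k = %d > %d candidates",
          cfg$k, n_candidates)
  }

  with_rng(cfg$seed, {
    if (is.null(fitness_fn)) {
      fold_ids <- stratified_folds(scores$labels, cv_folds,
                                   seed = derive_seed(cfg$seed, 1L))
      fitness_fn <- make_fitness_engine(scores, params, fold_ids,
                                        split_policy)
    }
    cache <- new.env(parent = emptyenv())
    score_mask <- function(mask) {
      key <- paste(mask, collapse = "")
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
      val <- fitness_fn(mask)
      cache[[key]] <- val
      val
    }

    pop <- replicate(cfg$pop_size, random_mask(n_candidates, cfg$k),
                     simplify = FALSE)
    best_mask <- NULL
    best_fit <- -Inf
    stagnant <- 0L
    trace <- vector("list", cfg$max_generations)
    gen <- 0L

    for (g in seq_len(cfg$max_generations)) {
      gen <- g
      fits <- vapply(pop, score_mask, numeric(1))
      gen_best <- max(fits)
      if (gen_best > best_fit + 1e-6) {
        stagnant <- 0L
      } else {
        stagnant <- stagnant + 1L
      }
      if (gen_best > best_fit) {
        best_fit <- gen_best
        best_mask <- pop[[which.max(fits)]]
      }
      trace[[g]] <- data.frame(generation = g, best = best_fit,
                               mean = mean(fits))
      if (g == cfg$max_generations || stagnant >= cfg$stagnation_limit) break

      pairs <- roulette_select(fits, cfg$pop_size %/% 2L)
      children <- vector("list", cfg$pop_size)
      for (p in seq_len(nrow(pairs))) {
        kids <- crossover_one_point(pop[[pairs[p, 1L]]], pop[[pairs[p, 2L]]],
                                    cfg$k, cfg$p_crossover)
        children[[2L * p - 1L]] <- mutate_uniform(kids[[1L]], cfg$k,
                                                  cfg$p_mutation)
        children[[2L * p]] <- mutate_uniform(kids[[2L]], cfg$k,
                                             cfg$p_mutation)
      }
      if (cfg$elitism_count > 0L) {
        elite <- order(fits, decreasing = TRUE)[seq_len(cfg$elitism_count)]
        for (e in seq_along(elite)) children[[e]] <- pop[[elite[e]]]
      }
      pop <- children
    }

    structure(
      list(best_mask = best_mask, best_fitness = best_fit,
           trace = do.call(rbind, trace[seq_len(gen)]),
           generations = gen, cfg = cfg),
      class = "ga_result"
    )
  })
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<ga_result> k = %d, best fitness %.4f after %d generations\n",
              x$cfg$k, x$best_fitness, x$generations))
  cat("best mask:", paste(x$best_mask, collapse = ""), "\n")
  invisible(x)
}

#' Encode a mask as a 0/1 string
#'
#' @param mask 0/1 vector.
#' @return Single string such as `"1000011101100..."`.
#' @export
mask_string <- function(mask) paste(as.integer(mask), collapse = "")
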