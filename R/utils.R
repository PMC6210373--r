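# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards, so seeded routines do not perturb each other.
with_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic fan-out of one user seed into per-stage seeds, kept well
# inside 32-bit integer range.
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1103L + stage * 7919L) %% 2147483563)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}

# Stratified fold assignment: per class, samples are shuffled and dealt
# round-robin into `folds` folds.  Returns an integer vector of fold ids.
stratified_folds <- function(labels, folds, seed = NULL) {
  labels <- as.factor(labels)
  if (any(table(labels) < folds)) {
    stopf("every class needs at least %d samples for %d-fold CV", folds, folds)
  }
  assign_folds <- function() {
    ids <- integer(length(labels))
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      ids[idx] <- rep_len(seq_len(folds), length(idx))
    }
    ids
  }
  if (is.null(seed)) assign_folds() else with_rng(seed, assign_folds())
}
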