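#' Configuration for GA descriptor selection
#'
#' Settings for the binary-chromosome genetic algorithm that searches
#' descriptor subsets. Defaults follow the method's stated GA settings
#' (mutation probability 0.03, population 100, up to 1000 generations) plus
#' standard simple-GA operator choices.
#'
#' @param population_size chromosomes per generation; usage frequencies range
#'   over `0..population_size`.
#' @param mutation_prob per-bit flip probability.
#' @param max_generations generation cap.
#' @param crossover_prob probability a child pair is produced by uniform
#'   crossover rather than copied.
#' @param elitism_count chromosomes copied unchanged each generation.
#' @param ttest_alpha Welch t-test prefilter level; descriptors with
#'   `p >= ttest_alpha` never enter the GA (default 0.001).
#' @param usage_cutoff minimum usage frequency for a descriptor to enter the
#'   selected subset (default 90, i.e. present in at least 90 of 100 final
#'   chromosomes). Dataset-dependent; tune as needed.
#' @param usage_mode `"final"` counts usage over the final generation's
#'   population (default); `"cumulative"` averages bit counts over all
#'   generations (rounded), for diagnostics.
#' @param stagnation_limit stop early after this many generations without
#'   improvement of the best fitness.
#' @param seed RNG seed; the whole selection is deterministic given the seed.
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(population_size = 100, mutation_prob = 0.03,
                             max_generations = 1000, crossover_prob = 0.8,
                             elitism_count = 2, ttest_alpha = 0.001,
                             usage_cutoff = 90, usage_mode = c("final", "cumulative"),
                             stagnation_limit = 200, seed = 1) {
  usage_mode <- match.arg(usage_mode)
  elm_assert(usage_cutoff >= 0 && usage_cutoff <= population_size,
             "elm_config_error", "usage_cutoff must lie in [0, population_size]")
  elm_assert(elitism_count < population_size, "elm_config_error",
             "elitism_count must be smaller than population_size")
  elm_assert(ttest_alpha > 0 && ttest_alpha <= 1, "elm_config_error",
             "ttest_alpha must lie in (0, 1]")
  elm_assert(mutation_prob > 0 && mutation_prob < 1 &&
               crossover_prob > 0 && crossover_prob < 1,
             "elm_config_error", "mutation/crossover probabilities must lie in (0, 1)")
  structure(list(population_size = as.integer(population_size),
                 mutation_prob = mutation_prob,
                 max_generations = as.integer(max_generations),
                 crossover_prob = crossover_prob,
                 elitism_count = as.integer(elitism_count),
                 ttest_alpha = ttest_alpha, usage_cutoff = as.integer(usage_cutoff),
                 usage_mode = usage_mode,
                 stagnation_limit = as.integer(stagnation_limit),
                 seed = as.integer(seed)),
            class = "selection_config")
}

#' Welch t-test prefilter
#'
#' Two-sample unequal-variance (Welch) t-test of each descriptor between the
#' active and inactive classes. Descriptors with `p < alpha` are kept; the
#' rest never enter the GA search. Descriptors that are (numerically)
#' constant within both classes get `p = 1`.
#'
#' @param dataset a curated [labeled_dataset()]; each class needs at least 2
#'   compounds.
#' @param alpha significance level (default 0.001).
#' @return A list with `pvalues` (named, all descriptors), `kept` (names with
#'   `p < alpha`) and `alpha`. A warning is raised when nothing survives.
#' @export
ttest_prefilter <- function(dataset, alpha = 0.001) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  assert_trainable(dataset)
  g1 <- dataset$labels == 1L
  elm_assert(sum(g1) >= 2 && sum(!g1) >= 2, "elm_empty_class_error",
             "each class needs >= 2 compounds for the t-test prefilter")
  pvals <- vapply(seq_len(ncol(dataset$x)), function(j) {
    v <- dataset$x[, j]
    tryCatch(stats::t.test(v[g1], v[!g1])$p.value,
             error = function(e) 1)  # constant within both classes
  }, numeric(1))
  names(pvals) <- colnames(dataset$x)
  kept <- names(pvals)[pvals < alpha]
  if (length(kept) == 0)
    warning("ttest_prefilter: no descriptor passed the prefilter at alpha = ", alpha)
  list(pvalues = pvals, kept = kept, alpha = alpha)
}

#' AIC of a linear fit of the class codes on a descriptor subset
#'
#' Fitness used to score candidate subsets:
#' `AIC = n * ln(RSS / n) + 2 (k + 1)`, with RSS from the ordinary
#' least-squares fit (with intercept) of the 1/2 class codes on the `k`
#' included descriptors. A floor of 1e-12 on RSS guards `ln(0)` for perfect
#' fits. Collinear subsets fall back to a tiny-ridge fit.
#'
#' @param x descriptor matrix restricted to the subset (non-empty).
#' @param y numeric class codes; `length(y) > ncol(x) + 2` is required.
#' @param quiet suppress the collinearity message (used inside the GA loop).
#' @return The AIC, a scalar (lower is better).
#' @export
aic_linear <- function(x, y, quiet = FALSE) {
  x <- as.matrix(x)
  k <- ncol(x)
  n <- length(y)
  elm_assert(k >= 1, "elm_empty_selection_error", "AIC needs a non-empty subset")
  elm_assert(n == nrow(x) && n > k + 2, "elm_dimension_error",
             "AIC needs n > k + 2 observations")
  X <- cbind(1, x)
  fit <- stats::.lm.fit(X, y)
  if (fit$rank < ncol(X)) {
    if (!quiet) message("aic_linear: collinear subset, using ridge fallback")
    b <- solve(crossprod(X) + diag(1e-8, ncol(X)), crossprod(X, y))
    res <- y - X %*% b
  } else res <- fit$residuals
  rss <- max(sum(res^2), 1e-12)
  n * log(rss / n) + 2 * (k + 1)
}

#' GA descriptor-subset selection with usage-frequency importance
#'
#' Runs a binary-chromosome genetic algorithm over the descriptors that
#' survive the Welch t-test prefilter. Each chromosome encodes a subset (one
#' bit per descriptor); its fitness is `-AIC` of the least-squares fit of the
#' class codes on the included descriptors ([aic_linear()]). Descriptor
#' importance is the usage frequency: the number of chromosomes in the final
#' population whose subset includes the descriptor, so usage ranges from 0
#' (worst) to `population_size` (best). The selected subset contains every
#' descriptor with usage at or above `usage_cutoff`, sorted by usage
#' (descending) then name.
#'
#' Operators: rank-proportional parent selection, uniform crossover, per-bit
#' mutation, elitism; chromosomes are repaired to carry at least one set bit.
#' Stops early when the best fitness stagnates.
#'
#' @param dataset a curated [labeled_dataset()], descriptors on a common
#'   (standardized) scale.
#' @param config a [selection_config()].
#' @return An object of class `selection_result`: `usage` (named counts over
#'   all descriptors; prefiltered-out descriptors have usage 0), `selected`,
#'   `prefilter_pvalues`, `best_fitness_trace`, `best_subset` (descriptor
#'   names of the best-ever chromosome), `generations`, and `seed`.
#' @export
select_descriptors_ga <- function(dataset, config = selection_config()) {
  stopifnot(inherits(dataset, "labeled_dataset"), inherits(config, "selection_config"))
  assert_trainable(dataset)
  pre <- ttest_prefilter(dataset, config$ttest_alpha)
  keep <- pre$kept
  elm_assert(length(keep) >= 2, "elm_empty_selection_error",
             sprintf("only %d descriptor(s) survive the prefilter; need >= 2",
                     length(keep)))
  x <- dataset$x[, keep, drop = FALSE]
  y <- as.double(dataset$labels)
  p <- length(keep)
  pop_n <- config$population_size

  chrom_fitness <- function(bits) -aic_linear(x[, bits, drop = FALSE], y, quiet = TRUE)

  with_seed(config$seed, {
    pop <- matrix(stats::runif(pop_n * p) < 0.5, pop_n, p)
    empty <- rowSums(pop) == 0
    if (any(empty))  # repair: every chromosome encodes a non-empty subset
      pop[cbind(which(empty), sample.int(p, sum(empty), replace = TRUE))] <- TRUE
    fitness <- apply(pop, 1, chrom_fitness)
    best_f <- max(fitness)
    best_bits <- pop[which.max(fitness), ]
    trace <- numeric(config$max_generations)
    usage_accum <- colSums(pop)
    stagnant <- 0L
    gen <- 0L
    while (gen < config$max_generations) {
      gen <- gen + 1L
      elite_idx <- order(fitness, decreasing = TRUE)[seq_len(config$elitism_count)]
      elites <- pop[elite_idx, , drop = FALSE]
      prob <- rank(fitness, ties.method = "first")
      prob <- prob / sum(prob)
      n_child <- pop_n - config$elitism_count
      i1 <- sample.int(pop_n, n_child, replace = TRUE, prob = prob)
      i2 <- sample.int(pop_n, n_child, replace = TRUE, prob = prob)
      cross <- stats::runif(n_child) < config$crossover_prob
      take1 <- matrix(stats::runif(n_child * p) < 0.5, n_child, p)
      take1[!cross, ] <- TRUE  # no crossover: copy parent 1
      children <- ifelse(take1, pop[i1, , drop = FALSE], pop[i2, , drop = FALSE])
      flip <- matrix(stats::runif(n_child * p) < config$mutation_prob, n_child, p)
      children <- xor(children, flip)
      empty <- rowSums(children) == 0
      if (any(empty))
        children[cbind(which(empty), sample.int(p, sum(empty), replace = TRUE))] <- TRUE
      newpop <- rbind(elites, children)
      newfit <- c(fitness[elite_idx], apply(children, 1, chrom_fitness))
      pop <- newpop
      fitness <- newfit
      gen_best <- max(fitness)
      if (gen_best > best_f) {
        best_f <- gen_best
        best_bits <- pop[which.max(fitness), ]
        stagnant <- 0L
      } else stagnant <- stagnant + 1L
      trace[gen] <- best_f
      usage_accum <- usage_accum + colSums(pop)
      if (stagnant >= config$stagnation_limit) break
    }
    usage_kept <- if (config$usage_mode == "final") colSums(pop)
                  else round(usage_accum / (gen + 1))
    usage <- stats::setNames(integer(ncol(dataset$x)), colnames(dataset$x))
    usage[keep] <- as.integer(usage_kept)
    sel <- names(usage)[usage >= config$usage_cutoff]
    sel <- sel[order(-usage[sel], sel)]
    structure(list(usage = usage, selected = sel,
                   prefilter_pvalues = pre$pvalues,
                   best_fitness_trace = trace[seq_len(gen)],
                   best_subset = keep[best_bits],
                   generations = gen, usage_mode = config$usage_mode,
                   usage_cutoff = config$usage_cutoff, seed = config$seed),
              class = "selection_result")
  })
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("GA descriptor selection: %d generations over %d descriptors\n",
              x$generations, length(x$usage)))
  top <- sort(x$usage, decreasing = TRUE)
  top <- top[top > 0]
  top <- utils::head(top, 10)
  cat("  top usage:", paste(names(top), top, sep = "=", collapse = ", "), "\n")
  cat(sprintf("  selected (usage >= %d): %s\n", x$usage_cutoff,
              if (length(x$selected)) paste(x$selected, collapse = ", ") else "<none>"))
  invisible(x)
}
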