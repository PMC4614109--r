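#' Optimizer configuration for GA weight refinement
#'
#' Hyperparameters of the real-coded genetic algorithm that refines the
#' weight vector of the linear score. The mutation probability, population
#' size and generation cap default to 0.03, 100 and 1000 — the standard
#' simple-GA settings this method was designed around. The fitness is either
#' the (negated) Andrews' sine robust loss of the residuals between class
#' codes and scores, or the plain negative residual sum of squares.
#'
#' @param population_size number of chromosomes (weight vectors) per
#'   generation.
#' @param mutation_prob per-gene Gaussian mutation probability.
#' @param max_generations generation cap; 0 returns the initial weights
#'   unchanged.
#' @param fitness_kind `"andrews_sine"` (robust, default) or
#'   `"sum_of_squares"`.
#' @param andrews_a Andrews tuning constant; 1.339 gives 95% Gaussian
#'   efficiency.
#' @param search_halfwidth_sds half-width of the per-weight search box in
#'   units of the weight scale (see [optimize_weights_ga()]).
#' @param crossover_alpha BLX-alpha blend-crossover expansion factor.
#' @param elitism_count chromosomes copied unchanged into the next
#'   generation.
#' @param stagnation_limit stop early after this many generations without
#'   improvement of the best fitness.
#' @param seed RNG seed: the whole optimization is deterministic given the
#'   seed.
#' @return An object of class `optimizer_config`.
#' @export
optimizer_config <- function(population_size = 100, mutation_prob = 0.03,
                             max_generations = 1000,
                             fitness_kind = c("andrews_sine", "sum_of_squares"),
                             andrews_a = 1.339, search_halfwidth_sds = 5,
                             crossover_alpha = 0.5, elitism_count = 2,
                             stagnation_limit = 200, seed = 1) {
  fitness_kind <- match.arg(fitness_kind)
  elm_assert(population_size >= 4 && elitism_count < population_size,
             "elm_config_error", "population must exceed elitism count (and be >= 4)")
  elm_assert(mutation_prob > 0 && mutation_prob < 1, "elm_config_error",
             "mutation_prob must lie in (0, 1)")
  elm_assert(andrews_a > 0 && search_halfwidth_sds > 0, "elm_config_error",
             "andrews_a and search_halfwidth_sds must be positive")
  structure(list(population_size = as.integer(population_size),
                 mutation_prob = mutation_prob,
                 max_generations = as.integer(max_generations),
                 fitness_kind = fitness_kind, andrews_a = andrews_a,
                 search_halfwidth_sds = search_halfwidth_sds,
                 crossover_alpha = crossover_alpha,
                 elitism_count = as.integer(elitism_count),
                 stagnation_limit = as.integer(stagnation_limit),
                 seed = as.integer(seed)),
            class = "optimizer_config")
}

#' Weighted-sum score f(C)
#'
#' The linear score of the method: `f(C) = sum_i w_i x_i`, a pure weighted
#' sum with no intercept (standardization supplies centering). `x` may be a
#' single descriptor vector or a matrix with one compound per row; columns
#' must already be on the model's standardized scale.
#'
#' @param weights numeric weight vector, one weight per descriptor.
#' @param x numeric vector of length `length(weights)` or matrix with
#'   `length(weights)` columns.
#' @return A numeric score (or vector of scores, one per row of `x`).
#' @export
weighted_sum <- function(weights, x) {
  elm_assert(all(is.finite(weights)), "elm_nonfinite_error", "weights must be finite")
  if (is.matrix(x)) {
    elm_assert(ncol(x) == length(weights), "elm_dimension_error",
               "descriptor matrix width must match the number of weights")
    elm_assert(all(is.finite(x)), "elm_nonfinite_error", "descriptors must be finite")
    return(drop(x %*% weights))
  }
  elm_assert(length(x) == length(weights), "elm_dimension_error",
             "descriptor vector length must match the number of weights")
  elm_assert(all(is.finite(x)), "elm_nonfinite_error", "descriptors must be finite")
  sum(weights * x)
}

#' Residual sum of squares of a weight vector
#'
#' `sum_j (y_j - f(C_j))^2` where `y_j` is the 1/2 class code and `f` the
#' weighted-sum score.
#'
#' @param weights numeric weight vector.
#' @param x descriptor matrix (compounds x descriptors).
#' @param y numeric class codes.
#' @return The residual sum of squares, a non-negative scalar.
#' @export
elm_rss <- function(weights, x, y) {
  r <- y - weighted_sum(weights, x)
  sum(r * r)
}

#' Closed-form initial weights
#'
#' Each initial weight is the univariate least-squares slope of the class
#' code on that descriptor alone:
#' `w_i = sum_j (x_ij - xbar_i)(y_j - ybar) / sum_j (x_ij - xbar_i)^2`,
#' i.e. the minimizer of the per-descriptor residual sum of squares. The
#' weights are computed independently per descriptor.
#'
#' @param x descriptor matrix (n >= 2 rows); every column must have nonzero
#'   variance (zero-variance columns are excluded by
#'   [standardize_descriptors()] upstream).
#' @param y numeric class codes (1 = active, 2 = inactive).
#' @return Named numeric vector of slopes, one per descriptor column.
#' @export
fit_initial_weights <- function(x, y) {
  x <- as.matrix(x)
  elm_assert(nrow(x) >= 2 && nrow(x) == length(y), "elm_dimension_error",
             "need n >= 2 compounds with one label each")
  xc <- sweep(x, 2, colMeans(x), "-")
  den <- colSums(xc * xc)
  elm_assert(all(den > 0), "elm_zero_variance_error",
             sprintf("zero-variance descriptor(s): %s",
                     paste(colnames(x)[den == 0], collapse = ", ")))
  drop(crossprod(xc, y - mean(y))) / den
}

#' Andrews' sine robust fitness
#'
#' The Andrews wave loss `rho(r) = a^2 (1 - cos(r/a))` for `|r| <= pi*a` and
#' `rho(r) = 2 a^2` beyond (a bounded, redescending M-estimator loss). The
#' fitness is the negated total loss, `-sum_j rho(r_j)`, so larger is better
#' and 0 (all residuals zero) is the maximum. As `a -> Inf` the fitness
#' approaches `-RSS/2`, recovering least squares.
#'
#' @param residuals numeric residual vector.
#' @param a positive tuning constant (default 1.339, the conventional
#'   95%-efficiency choice).
#' @return Scalar fitness, `<= 0`.
#' @export
andrews_fitness <- function(residuals, a = 1.339) {
  elm_assert(a > 0, "elm_config_error", "Andrews constant a must be positive")
  # a^2 (1 - cos(r/a)) written as 2 a^2 sin^2(r/2a): identical analytically,
  # but immune to the 1 - cos cancellation when r/a is tiny (large a limit)
  rho <- ifelse(abs(residuals) <= pi * a,
                2 * a^2 * sin(residuals / (2 * a))^2,
                2 * a^2)
  -sum(rho)
}

# fitness of a whole population at once; scores is n x pop
population_fitness <- function(scores, y, fitness_kind, a) {
  r <- y - scores
  if (fitness_kind == "andrews_sine") {
    rho <- ifelse(abs(r) <= pi * a, 2 * a^2 * sin(r / (2 * a))^2, 2 * a^2)
    -colSums(rho)
  } else {
    -colSums(r * r)
  }
}

#' Refine ELM weights with a real-coded genetic algorithm
#'
#' Searches the box `[w_i - h*s_i, w_i + h*s_i]` around the initial weights
#' (`h` = `search_halfwidth_sds`, `s_i = |w_i| +` the mean absolute initial
#' weight, so zero-initialized weights still get a nonzero box). The initial
#' weight vector is seeded into generation 0 and elites are copied unchanged,
#' so the returned best-ever chromosome can never be worse than the
#' initialization. Operators: rank-proportional selection, BLX-alpha blend
#' crossover, per-gene Gaussian mutation with sd 10% of the box width,
#' clipping to the box.
#'
#' @param x standardized descriptor matrix restricted to the model
#'   descriptors.
#' @param y numeric class codes.
#' @param init_weights finite initial weight vector (see
#'   [fit_initial_weights()]).
#' @param config an [optimizer_config()].
#' @return A list of class `elm_optimization`: `weights` (best-ever
#'   chromosome), `fitness` (its fitness), `initial_fitness`,
#'   `best_fitness_trace` (best-ever fitness per generation), `generations`
#'   run, and `seed`.
#' @export
optimize_weights_ga <- function(x, y, init_weights, config = optimizer_config()) {
  stopifnot(inherits(config, "optimizer_config"))
  x <- as.matrix(x)
  M <- length(init_weights)
  elm_assert(M >= 1 && ncol(x) == M, "elm_dimension_error",
             "init_weights must match the descriptor matrix width")
  elm_assert(all(is.finite(init_weights)), "elm_nonfinite_error",
             "initial weights must be finite")
  fit1 <- function(w) population_fitness(x %*% w, y, config$fitness_kind, config$andrews_a)
  init_fit <- fit1(init_weights)
  if (config$max_generations == 0L) {
    return(structure(list(weights = init_weights, fitness = init_fit,
                          initial_fitness = init_fit,
                          best_fitness_trace = numeric(0), generations = 0L,
                          seed = config$seed),
                     class = "elm_optimization"))
  }
  pop_n <- config$population_size
  pooled <- mean(abs(init_weights))
  if (pooled == 0) pooled <- 1
  half <- config$search_halfwidth_sds * (abs(init_weights) + pooled)
  lo <- init_weights - half
  hi <- init_weights + half
  width <- hi - lo
  mut_sd <- 0.1 * width

  with_seed(config$seed, {
    pop <- matrix(stats::runif(pop_n * M, rep(lo, each = pop_n), rep(hi, each = pop_n)),
                  nrow = pop_n, ncol = M)
    pop[1, ] <- init_weights
    fitness <- population_fitness(x %*% t(pop), y, config$fitness_kind, config$andrews_a)
    best_w <- pop[which.max(fitness), ]
    best_f <- max(fitness)
    trace <- numeric(config$max_generations)
    stagnant <- 0L
    gen <- 0L
    while (gen < config$max_generations) {
      gen <- gen + 1L
      elite_idx <- order(fitness, decreasing = TRUE)[seq_len(config$elitism_count)]
      elites <- pop[elite_idx, , drop = FALSE]
      # rank-proportional parent selection
      prob <- rank(fitness, ties.method = "first")
      prob <- prob / sum(prob)
      n_child <- pop_n - config$elitism_count
      p1 <- pop[sample.int(pop_n, n_child, replace = TRUE, prob = prob), , drop = FALSE]
      p2 <- pop[sample.int(pop_n, n_child, replace = TRUE, prob = prob), , drop = FALSE]
      # BLX-alpha: child gene uniform in the parent interval expanded by alpha
      cmin <- pmin(p1, p2)
      cmax <- pmax(p1, p2)
      d <- (cmax - cmin) * config$crossover_alpha
      children <- matrix(stats::runif(n_child * M), n_child, M) *
        (cmax - cmin + 2 * d) + (cmin - d)
      # Gaussian mutation
      mask <- matrix(stats::runif(n_child * M) < config$mutation_prob, n_child, M)
      if (any(mask)) {
        idx <- which(mask)
        col <- (idx - 1L) %/% n_child + 1L
        children[idx] <- children[idx] + stats::rnorm(length(idx), sd = mut_sd[col])
      }
      # clip to the search box
      children <- pmin(pmax(children, rep(lo, each = n_child)), rep(hi, each = n_child))
      pop <- rbind(elites, children)
      fitness <- population_fitness(x %*% t(pop), y, config$fitness_kind, config$andrews_a)
      gen_best <- max(fitness)
      if (gen_best > best_f) {
        best_f <- gen_best
        best_w <- pop[which.max(fitness), ]
        stagnant <- 0L
      } else stagnant <- stagnant + 1L
      trace[gen] <- best_f
      if (stagnant >= config$stagnation_limit) break
    }
    names(best_w) <- colnames(x)
    structure(list(weights = best_w, fitness = max(best_f, init_fit),
                   initial_fitness = init_fit,
                   best_fitness_trace = trace[seq_len(gen)], generations = gen,
                   seed = config$seed),
              class = "elm_optimization")
  })
}

#' Decision threshold from training scores
#'
#' Computes the class-score threshold from the per-class mean scores.
#' `"midpoint"` (default) uses the midpoint of the active- and inactive-class
#' mean scores, which lies between the two score distributions whenever they
#' separate. `"literal_difference"` uses the active mean minus the inactive
#' mean; it is retained for fidelity experiments but generally does not fall
#' between the class distributions.
#'
#' @param scores numeric weighted-sum scores.
#' @param labels class codes in `{1, 2}` (1 = active).
#' @param mode `"midpoint"` or `"literal_difference"`.
#' @return The threshold, a scalar.
#' @export
compute_threshold <- function(scores, labels,
                              mode = c("midpoint", "literal_difference")) {
  mode <- match.arg(mode)
  elm_assert(length(scores) == length(labels), "elm_dimension_error",
             "scores and labels must have equal length")
  elm_assert(any(labels == 1) && any(labels == 2), "elm_empty_class_error",
             "both classes are needed to compute a threshold")
  m_act <- mean(scores[labels == 1])
  m_inact <- mean(scores[labels == 2])
  if (mode == "midpoint") (m_act + m_inact) / 2 else m_act - m_inact
}

new_elm_model <- function(descriptor_names, weights, initial_weights, threshold,
                          threshold_mode, standardization, fitness_kind,
                          andrews_a, seed, optimization = NULL,
                          rss_initial = NA_real_, rss_optimized = NA_real_) {
  structure(list(descriptor_names = descriptor_names,
                 weights = stats::setNames(weights, descriptor_names),
                 initial_weights = stats::setNames(initial_weights, descriptor_names),
                 threshold = threshold, threshold_mode = threshold_mode,
                 standardization = standardization,
                 fitness_kind = fitness_kind, andrews_a = andrews_a,
                 seed = seed, optimization = optimization,
                 rss_initial = rss_initial, rss_optimized = rss_optimized,
                 class_encoding = "1=active,2=inactive"),
            class = "elm_model")
}

#' @export
print.elm_model <- function(x, ...) {
  cat(sprintf("ELM model: %d descriptors, threshold %.4g (%s)\n",
              length(x$weights), x$threshold, x$threshold_mode))
  cat("  score: f(C) = sum_i w_i x_i; predict active (1) when f(C) < threshold\n")
  if (is.finite(x$rss_initial))
    cat(sprintf("  training RSS: initial %.4g -> optimized %.4g\n",
                x$rss_initial, x$rss_optimized))
  invisible(x)
}

#' Train an ELM classifier
#'
#' Composes the full training procedure: (optional) z-score standardization
#' of the selected descriptors, closed-form initialization of the weights
#' ([fit_initial_weights()]), GA refinement under the configured robust
#' fitness ([optimize_weights_ga()]), and threshold computation from the
#' optimized training scores ([compute_threshold()]).
#'
#' @param dataset a curated [labeled_dataset()] (labels in `{1, 2}`, both
#'   classes present).
#' @param descriptors character vector of descriptor names to use, or a
#'   `selection_result` from [select_descriptors_ga()] (its `selected` set is
#'   used).
#' @param config an [optimizer_config()]; `max_generations = 0` yields the
#'   pure initial-parameter model.
#' @param standardize fit z-score standardization on this training data and
#'   store it in the model (default TRUE). New data passed to [predict()] is
#'   standardized with these stored statistics.
#' @param threshold_mode see [compute_threshold()].
#' @return An object of class `elm_model`.
#' @export
elm_train <- function(dataset, descriptors, config = optimizer_config(),
                      standardize = TRUE,
                      threshold_mode = c("midpoint", "literal_difference")) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  threshold_mode <- match.arg(threshold_mode)
  assert_trainable(dataset)
  if (inherits(descriptors, "selection_result")) descriptors <- descriptors$selected
  descriptors <- as.character(descriptors)
  elm_assert(length(descriptors) >= 1, "elm_empty_selection_error",
             "descriptor subset is empty; nothing to train on")
  elm_assert(all(descriptors %in% colnames(dataset$x)), "elm_missing_column_error",
             sprintf("dataset lacks descriptor(s): %s",
                     paste(setdiff(descriptors, colnames(dataset$x)), collapse = ", ")))
  x <- dataset$x[, descriptors, drop = FALSE]
  st <- NULL
  if (standardize) {
    std <- standardize_descriptors(x)
    elm_assert(length(std$stats$dropped) == 0, "elm_zero_variance_error",
               sprintf("selected descriptor(s) constant on this training set: %s",
                       paste(std$stats$dropped, collapse = ", ")))
    x <- std$values
    st <- std$stats
  }
  y <- as.double(dataset$labels)
  w0 <- fit_initial_weights(x, y)
  opt <- optimize_weights_ga(x, y, w0, config)
  scores <- weighted_sum(opt$weights, x)
  thr <- compute_threshold(scores, dataset$labels, threshold_mode)
  new_elm_model(descriptor_names = descriptors, weights = opt$weights,
                initial_weights = w0, threshold = thr,
                threshold_mode = threshold_mode, standardization = st,
                fitness_kind = config$fitness_kind, andrews_a = config$andrews_a,
                seed = config$seed, optimization = opt,
                rss_initial = elm_rss(w0, x, y),
                rss_optimized = elm_rss(opt$weights, x, y))
}

#' Predict activity classes with an ELM model
#'
#' Scores compounds with the model's weighted sum (after applying the stored
#' standardization, if any) and assigns class 1 (active) when
#' `f(C) < threshold`, class 2 (inactive) otherwise. A score exactly at the
#' threshold is called inactive — actives carry the lower class code, so
#' low scores indicate activity, and the tie goes to the conservative call.
#'
#' @param object an `elm_model`.
#' @param newdata matrix or data frame containing (at least) the model's
#'   descriptor columns, on the raw scale the model was trained from.
#' @param type `"class"` for 1/2 labels, `"score"` for the raw weighted sums.
#' @param ... unused.
#' @return Integer class labels or numeric scores, one per row of `newdata`.
#' @export
predict.elm_model <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "labeled_dataset")) newdata <- newdata$x
  x <- as.matrix(newdata)
  elm_assert(all(object$descriptor_names %in% colnames(x)),
             "elm_missing_column_error",
             sprintf("new data lacks descriptor(s): %s",
                     paste(setdiff(object$descriptor_names, colnames(x)), collapse = ", ")))
  x <- x[, object$descriptor_names, drop = FALSE]
  if (!is.null(object$standardization))
    x <- apply_standardization(object$standardization, x)
  scores <- weighted_sum(object$weights, x)
  if (type == "score") return(scores)
  unname(ifelse(scores < object$threshold, 1L, 2L))
}
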