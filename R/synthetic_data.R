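#' Configuration of the synthetic descriptor-table generator
#'
#' The generator emulates the structure of a curated aromatase-inhibitor
#' descriptor table: a few hundred compounds, hundreds of candidate
#' descriptors of which only a small block carries class signal, and
#' imbalanced classes. Defaults mirror the steroidal set (180 compounds with
#' an 81/99 active/inactive split, 637 candidate descriptors).
#'
#' Informative descriptors are class-conditional Gaussians whose class means
#' differ by `effect_size` within-class standard deviations (optionally
#' equicorrelated within the informative block); noise descriptors are
#' standard Gaussians independent of class. Class counts are allocated
#' deterministically (`round(active_fraction * n)` actives), not drawn.
#'
#' @param n_compounds number of compounds.
#' @param n_descriptors total number of descriptors.
#' @param n_informative size of the informative block
#'   (`<= n_descriptors`).
#' @param effect_size standardized mean class difference per informative
#'   descriptor.
#' @param active_fraction fraction of active compounds, in (0, 1).
#' @param descriptor_correlation equicorrelation within the informative
#'   block, in `[0, 1)`.
#' @param noise_sd within-class standard deviation of informative
#'   descriptors.
#' @param pic50_mode emit pIC50 potencies instead of hard labels: actives
#'   get pIC50 >= 6, inactives <= 5, and `intermediate_fraction` of the
#'   compounds fall strictly inside (5, 6) with `NA` labels, to exercise
#'   activity curation.
#' @param intermediate_fraction fraction of intermediate-activity compounds
#'   in `pic50_mode` (default 0.33, the removal rate of the curation this
#'   emulates).
#' @param seed RNG seed; generation is fully deterministic given the seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_compounds = 180, n_descriptors = 637,
                             n_informative = 10, effect_size = 1.0,
                             active_fraction = 81 / 180,
                             descriptor_correlation = 0, noise_sd = 1,
                             pic50_mode = FALSE, intermediate_fraction = 0.33,
                             seed = 1) {
  elm_assert(n_informative <= n_descriptors && n_informative >= 0,
             "elm_config_error", "need 0 <= n_informative <= n_descriptors")
  elm_assert(active_fraction > 0 && active_fraction < 1, "elm_config_error",
             "active_fraction must lie in (0, 1)")
  elm_assert(descriptor_correlation >= 0 && descriptor_correlation < 1,
             "elm_config_error", "descriptor_correlation must lie in [0, 1)")
  elm_assert(noise_sd > 0 && effect_size >= 0, "elm_config_error",
             "noise_sd must be positive and effect_size non-negative")
  elm_assert(!pic50_mode ||
               (intermediate_fraction >= 0 && intermediate_fraction < 1),
             "elm_config_error", "intermediate_fraction must lie in [0, 1)")
  structure(list(n_compounds = as.integer(n_compounds),
                 n_descriptors = as.integer(n_descriptors),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size, active_fraction = active_fraction,
                 descriptor_correlation = descriptor_correlation,
                 noise_sd = noise_sd, pic50_mode = pic50_mode,
                 intermediate_fraction = intermediate_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic labeled descriptor table with planted signal
#'
#' See [synthetic_config()] for the generative model. Alongside the dataset,
#' the ground truth is returned: the informative descriptor names, the true
#' discriminant weight vector (direction `Sigma^-1 * delta` of the
#' class-conditional Gaussian model, on the standardized scale), and the
#' Bayes accuracy of the optimal linear rule,
#' `Phi(Delta/2)` with `Delta` the Mahalanobis distance between the class
#' means.
#'
#' In `pic50_mode`, active compounds get `pIC50 = 6 + |potency margin|`,
#' inactive compounds `5 - |margin|` (margins half-normal with sd 1), and a
#' fraction of intermediate compounds uniform in (5.05, 5.95) with
#' signal-free descriptors and `NA` labels, so the dataset must pass through
#' [curate_by_activity()] before training.
#'
#' @param config a [synthetic_config()].
#' @return A list of class `synthetic_dataset`: `dataset` (a
#'   [labeled_dataset()]), `informative` (descriptor names),
#'   `true_weights` (named, informative descriptors only), `bayes_accuracy`
#'   (percent), and `config`.
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_compounds
  p <- config$n_descriptors
  m <- config$n_informative
  with_seed(config$seed, {
    n_int <- if (config$pic50_mode) floor(config$intermediate_fraction * n) else 0L
    n_lab <- n - n_int
    n_act <- round(config$active_fraction * n_lab)
    elm_assert(n_act >= 1 && n_lab - n_act >= 1, "elm_config_error",
               "config yields an empty class")
    labels <- rep(NA_integer_, n)
    lab_pos <- if (n_int > 0) sort(sample.int(n, n_lab)) else seq_len(n)
    labels[lab_pos] <- sample(rep(c(1L, 2L), c(n_act, n_lab - n_act)))

    x <- matrix(stats::rnorm(n * p), n, p)
    rho <- config$descriptor_correlation
    if (m > 0) {
      if (rho > 0) {  # equicorrelated block via a shared factor
        z <- stats::rnorm(n)
        x[, 1:m] <- sqrt(rho) * z + sqrt(1 - rho) * x[, 1:m, drop = FALSE]
      }
      # class shift: actives low, inactives high (class codes 1 < 2, and the
      # score tracks the codes, so actives sit at the low end of the score)
      delta <- config$effect_size * config$noise_sd
      shift <- ifelse(is.na(labels) | labels == 1L, -delta / 2, +delta / 2)
      x[, 1:m] <- config$noise_sd * x[, 1:m, drop = FALSE] + shift
      if (n_int > 0)  # intermediates carry no class signal
        x[is.na(labels), 1:m] <- config$noise_sd *
          matrix(stats::rnorm(n_int * m), n_int, m)
    }
    desc_names <- c(if (m > 0) sprintf("INF%03d", 1:m),
                    if (p > m) sprintf("NOISE%03d", seq_len(p - m)))
    dimnames(x) <- list(sprintf("CMP%04d", seq_len(n)), desc_names)

    pic50 <- NULL
    if (config$pic50_mode) {
      pic50 <- numeric(n)
      margin <- abs(stats::rnorm(n))
      pic50[!is.na(labels) & labels == 1L] <- 6 + margin[!is.na(labels) & labels == 1L]
      pic50[!is.na(labels) & labels == 2L] <- 5 - margin[!is.na(labels) & labels == 2L]
      pic50[is.na(labels)] <- stats::runif(n_int, 5.05, 5.95)
    }

    # ground truth on the standardized (unit within-class sd) scale
    true_w <- NULL
    bayes_acc <- 50
    if (m > 0 && config$effect_size > 0) {
      delta_vec <- rep(config$effect_size, m)
      sigma <- matrix(rho, m, m); diag(sigma) <- 1
      w <- solve(sigma, delta_vec)
      true_w <- stats::setNames(w, desc_names[1:m])
      maha <- sqrt(sum(delta_vec * w))
      bayes_acc <- 100 * stats::pnorm(maha / 2)
    }
    structure(list(dataset = labeled_dataset(x, labels, pic50),
                   informative = if (m > 0) desc_names[1:m] else character(0),
                   true_weights = true_w, bayes_accuracy = bayes_acc,
                   config = config),
              class = "synthetic_dataset")
  })
}

#' Tiny fixed worked-example dataset
#'
#' A constant 12-compound, 4-descriptor dataset whose per-descriptor
#' least-squares slopes are round numbers, used in the documentation and in
#' exact tests. Descriptor `D1` equals the class code (slope 1), `D2` is half
#' the class code (slope 2), `D3` alternates within each class so its
#' covariance with the class code is exactly zero (slope 0), and `D4` is a
#' fixed arbitrary column. Six compounds are active (pIC50 7) and six
#' inactive (pIC50 4). Byte-identical on every call.
#'
#' @return A [labeled_dataset()] with 12 compounds, 4 descriptors and pIC50.
#' @export
generate_worked_example <- function() {
  y <- c(rep(1, 6), rep(2, 6))
  x <- cbind(D1 = y,
             D2 = y / 2,
             D3 = rep(c(-1, 1), 6),
             D4 = c(0.2, -0.4, 1.1, 0.5, -0.9, 0.3, 1.4, -0.2, 0.8, -1.0, 0.6, 0.1))
  rownames(x) <- sprintf("WX%02d", 1:12)
  labeled_dataset(x, as.integer(y), pic50 = c(rep(7, 6), rep(4, 6)))
}
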