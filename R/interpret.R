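#' Baseline specification for attribution methods
#'
#' The baseline `x'` is the reference input against which attribution
#' methods measure change. `uniform_random` draws every coordinate from
#' U[0, 1] (the convention used for methods that need a generic reference on
#' normalised inputs); `zeros` is the all-zero vector (the choice the
#' squared discrete-derivative method fixes); `fixed_vector` uses a supplied
#' vector; `distribution_sampler` draws baselines from a user function
#' `function(n, d)`.
#'
#' @param mode Baseline mode.
#' @param vector Baseline vector for `fixed_vector`.
#' @param sampler Function `(n, d) -> matrix` for `distribution_sampler`.
#' @param n_draws Number of baseline draws where the method averages over
#'   baselines.
#' @param seed Seed for random baselines.
#' @return A list of class `baseline_spec`.
#' @export
baseline_spec <- function(mode = c("uniform_random", "zeros", "fixed_vector",
                                   "distribution_sampler"),
                          vector = NULL, sampler = NULL, n_draws = 20L,
                          seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "fixed_vector" && is.null(vector))
    config_error("vector", "fixed_vector baseline needs `vector`")
  if (mode == "distribution_sampler" && !is.function(sampler))
    config_error("sampler", "distribution_sampler baseline needs `sampler`")
  structure(list(mode = mode, vector = vector, sampler = sampler,
                 n_draws = as.integer(n_draws), seed = as.integer(seed)),
            class = "baseline_spec")
}

resolve_baseline <- function(baseline, d, n = 1L) {
  switch(baseline$mode,
    zeros = matrix(0, n, d),
    uniform_random = withr::with_seed(baseline$seed,
                                      matrix(runif(n * d), n, d)),
    fixed_vector = {
      if (length(baseline$vector) != d)
        abort(sprintf("baseline vector length %d does not match input width %d",
                      length(baseline$vector), d),
              class = "icufair_argument_error")
      matrix(baseline$vector, n, d, byrow = TRUE)
    },
    distribution_sampler = withr::with_seed(baseline$seed, {
      b <- baseline$sampler(n, d)
      matrix(b, n, d)
    }))
}

new_attribution <- function(scores, method, feature_names = NULL) {
  scores <- as.matrix(scores)
  if (!is.null(feature_names)) colnames(scores) <- feature_names
  structure(list(scores = scores, method = method), class = "attribution")
}

#' Absolute importance scores of an attribution
#'
#' Methods return signed per-entry scores; importance is their absolute
#' value.
#' @param attr An `attribution`.
#' @return Nonnegative matrix `(n_samples, d_in)`.
#' @export
importance <- function(attr) {
  stopifnot(inherits(attr, "attribution"))
  abs(attr$scores)
}

#' @export
print.attribution <- function(x, ...) {
  cat(sprintf("<attribution: %s> %d samples x %d inputs\n", x$method,
              nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

#' @method tidy attribution
#' @export
tidy.attribution <- function(x, ...) {
  sc <- x$scores
  feats <- colnames(sc)
  if (is.null(feats)) feats <- paste0("x", seq_len(ncol(sc)))
  tibble(sample = rep(seq_len(nrow(sc)), ncol(sc)),
         feature = rep(feats, each = nrow(sc)),
         score = as.vector(sc),
         importance = abs(as.vector(sc)),
         method = x$method)
}

check_gradient_capability <- function(model, method) {
  ok <- any(vapply(class(model), function(cl)
    !is.null(utils::getS3method("input_gradient", cl, optional = TRUE)),
    logical(1)))
  if (!ok)
    abort(sprintf("%s requires a model with input gradients", method),
          class = "icufair_capability_error")
}

prep_inputs <- function(model, inputs) {
  x <- coerce_inputs(inputs)
  shp <- model_input_shape(model, x)
  if (!is.null(shp) && prod(shp) != ncol(x))
    abort(sprintf("input width %d does not match model input shape (%d x %d)",
                  ncol(x), shp[1], shp[2]), class = "icufair_argument_error")
  x
}

model_input_shape <- function(model, x = NULL) {
  shp <- tryCatch(model$config$input_shape, error = function(e) NULL)
  if (is.null(shp) && !is.null(x)) shp <- attr(x, "input_shape")
  shp
}

#' Saliency: raw input gradients
#'
#' Signed score = the gradient of the positive-class probability with
#' respect to each input entry.
#'
#' @param model Gradient-capable model.
#' @param inputs `(n, d)` input matrix.
#' @return An `attribution`.
#' @export
saliency <- function(model, inputs) {
  check_gradient_capability(model, "saliency")
  x <- prep_inputs(model, inputs)
  new_attribution(input_gradient(model, x), "saliency", colnames(x))
}

#' Integrated gradients
#'
#' Signed score `s_i = (x_i - x'_i) * integral_0^1 dM/dx_i along the
#' straight path from the baseline to the input`, approximated by a
#' left-Riemann quadrature with `steps` points. For linear models this is
#' exact; in general the scores satisfy the completeness identity
#' `sum(s) ~= M(x) - M(x')` as `steps` grows.
#'
#' @inheritParams saliency
#' @param baseline A [baseline_spec()].
#' @param steps Quadrature points (>= 1).
#' @return An `attribution`.
#' @export
integrated_gradients <- function(model, inputs,
                                 baseline = baseline_spec(), steps = 50L) {
  check_gradient_capability(model, "integrated_gradients")
  stopifnot(steps >= 1)
  x <- prep_inputs(model, inputs)
  b <- resolve_baseline(baseline, ncol(x), nrow(x))
  diff <- x - b
  acc <- matrix(0, nrow(x), ncol(x))
  for (k in seq_len(steps)) {
    alpha <- (k - 1) / steps
    acc <- acc + input_gradient(model, b + alpha * diff)
  }
  new_attribution(diff * acc / steps, "integrated_gradients", colnames(x))
}

#' Gradient SHAP
#'
#' Monte-Carlo estimate of expected gradients: for each draw a baseline is
#' sampled, white noise is added to the input, a random point on the path
#' between them is taken, and the gradient there is recorded. The signed
#' score is the mean gradient times `(x_i - mean baseline_i)`.
#'
#' @inheritParams integrated_gradients
#' @param n_draws Monte-Carlo draws.
#' @param noise_sd Standard deviation of the input noise.
#' @param seed Seed controlling noise, baselines and path points.
#' @return An `attribution`.
#' @export
gradient_shap <- function(model, inputs, baseline = baseline_spec(),
                          n_draws = 20L, noise_sd = 0.1, seed = 1L) {
  check_gradient_capability(model, "gradient_shap")
  x <- prep_inputs(model, inputs)
  n <- nrow(x); d <- ncol(x)
  withr::with_seed(as.integer(seed), {
    acc <- matrix(0, n, d)
    bsum <- matrix(0, n, d)
    for (k in seq_len(n_draws)) {
      b <- baseline_draw(baseline, n, d)
      xt <- x + matrix(rnorm(n * d, 0, noise_sd), n, d)
      alpha <- runif(n)
      acc <- acc + input_gradient(model, b + alpha * (xt - b))
      bsum <- bsum + b
    }
    new_attribution((acc / n_draws) * (x - bsum / n_draws), "gradient_shap",
                    colnames(x))
  })
}

# a baseline draw inside an already-seeded context
baseline_draw <- function(baseline, n, d) {
  switch(baseline$mode,
    zeros = matrix(0, n, d),
    uniform_random = matrix(runif(n * d), n, d),
    fixed_vector = matrix(baseline$vector, n, d, byrow = TRUE),
    distribution_sampler = matrix(baseline$sampler(n, d), n, d))
}

#' Saliency with a noise tunnel
#'
#' Averages saliency over `n_draws` Gaussian perturbations of the input
#' (`x + N(0, noise_sd^2)`), smoothing gradient noise.
#'
#' @inheritParams gradient_shap
#' @return An `attribution`.
#' @export
saliency_noise_tunnel <- function(model, inputs, n_draws = 20L,
                                  noise_sd = 0.1, seed = 1L) {
  check_gradient_capability(model, "saliency_noise_tunnel")
  x <- prep_inputs(model, inputs)
  n <- nrow(x); d <- ncol(x)
  withr::with_seed(as.integer(seed), {
    acc <- matrix(0, n, d)
    for (k in seq_len(n_draws)) {
      acc <- acc + input_gradient(model,
                                  x + matrix(rnorm(n * d, 0, noise_sd), n, d))
    }
    new_attribution(acc / n_draws, "saliency_noise_tunnel", colnames(x))
  })
}

#' Shapley value sampling
#'
#' Unbiased Monte-Carlo estimate of Shapley values: for each sampled
#' permutation of the features, features are switched one by one from the
#' baseline to the input and the marginal output changes are recorded; the
#' signed score is the average marginal contribution.
#'
#' @inheritParams integrated_gradients
#' @param n_perms Number of sampled permutations.
#' @param seed Seed for the permutation draws.
#' @return An `attribution`.
#' @export
shapley_sampling <- function(model, inputs, baseline = baseline_spec(),
                             n_perms = 25L, seed = 1L) {
  x <- prep_inputs(model, inputs)
  n <- nrow(x); d <- ncol(x)
  b <- resolve_baseline(baseline, d, 1L)[1, ]
  withr::with_seed(as.integer(seed), {
    scores <- matrix(0, n, d)
    for (i in seq_len(n)) {
      xi <- x[i, ]
      acc <- rep(0, d)
      for (k in seq_len(n_perms)) {
        perm <- sample.int(d)
        grid <- matrix(b, d + 1L, d, byrow = TRUE)
        for (pos in seq_len(d)) {
          grid[(pos + 1L):(d + 1L), perm[pos]] <- xi[perm[pos]]
        }
        preds <- predict_proba(model, grid)
        acc[perm] <- acc[perm] + diff(preds)
      }
      scores[i, ] <- acc / n_perms
    }
    new_attribution(scores, "shapley_sampling", colnames(x))
  })
}

#' Feature permutation importance
#'
#' Shuffles each feature's column across the batch (one seeded shuffle per
#' feature) and scores the feature by the mean absolute change in the model
#' output over the batch; the batch is the full evaluation set, and the
#' batch-level score is broadcast to every sample.
#'
#' @inheritParams saliency
#' @param seed Seed for the shuffles.
#' @return An `attribution`.
#' @export
feature_permutation <- function(model, inputs, seed = 1L) {
  x <- prep_inputs(model, inputs)
  n <- nrow(x); d <- ncol(x)
  p0 <- predict_proba(model, x)
  withr::with_seed(as.integer(seed), {
    sc <- numeric(d)
    for (j in seq_len(d)) {
      x2 <- x
      x2[, j] <- x[sample.int(n), j]
      sc[j] <- mean(abs(p0 - predict_proba(model, x2)))
    }
    new_attribution(matrix(sc, n, d, byrow = TRUE), "feature_permutation",
                    colnames(x))
  })
}

#' Feature ablation
#'
#' Signed score `s_i = M(x) - M(x with x_i replaced by the baseline
#' value)`; identical to occlusion with a 1x1 window.
#'
#' @inheritParams integrated_gradients
#' @return An `attribution`.
#' @export
feature_ablation <- function(model, inputs, baseline = baseline_spec()) {
  x <- prep_inputs(model, inputs)
  d <- ncol(x)
  b <- resolve_baseline(baseline, d, 1L)[1, ]
  p0 <- predict_proba(model, x)
  sc <- matrix(0, nrow(x), d)
  for (j in seq_len(d)) {
    x2 <- x
    x2[, j] <- b[j]
    sc[, j] <- p0 - predict_proba(model, x2)
  }
  new_attribution(sc, "feature_ablation", colnames(x))
}

#' Occlusion
#'
#' Slides a `window = c(time_span, feature_span)` rectangle over the
#' `(T, F)` input grid with stride 1, replaces the covered block by the
#' baseline, and scores every cell by the mean output change over all
#' windows covering it.
#'
#' @inheritParams integrated_gradients
#' @param window Integer `(time_span, feature_span)` window.
#' @param input_shape `(T, F)` grid; defaults to the model's input shape, or
#'   a `1 x d` grid for flat inputs.
#' @return An `attribution`.
#' @export
occlusion <- function(model, inputs, baseline = baseline_spec(),
                      window = c(1L, 1L), input_shape = NULL) {
  x <- prep_inputs(model, inputs)
  d <- ncol(x)
  if (is.null(input_shape)) input_shape <- model_input_shape(model, x)
  if (is.null(input_shape)) input_shape <- c(1L, d)
  t_len <- input_shape[1]; f_len <- input_shape[2]
  stopifnot(t_len * f_len == d, window[1] <= t_len, window[2] <= f_len)
  b <- resolve_baseline(baseline, d, 1L)[1, ]
  p0 <- predict_proba(model, x)
  acc <- matrix(0, nrow(x), d)
  cov <- numeric(d)
  cell <- function(t, f) (f - 1L) * t_len + t
  for (t0 in seq_len(t_len - window[1] + 1L)) {
    for (f0 in seq_len(f_len - window[2] + 1L)) {
      idx <- as.vector(outer(t0:(t0 + window[1] - 1L),
                             f0:(f0 + window[2] - 1L), cell))
      x2 <- x
      x2[, idx] <- matrix(b[idx], nrow(x), length(idx), byrow = TRUE)
      delta <- p0 - predict_proba(model, x2)
      acc[, idx] <- acc[, idx] + delta
      cov[idx] <- cov[idx] + 1
    }
  }
  new_attribution(sweep(acc, 2, cov, "/"), "occlusion", colnames(x))
}

#' Squared discrete-derivative importance (single-feature interaction
#' detection)
#'
#' With the all-zero baseline fixed by the method, the signed score of
#' feature `i` is the squared discrete partial derivative
#' `((M(x_i e_i) - M(0)) / x_i)^2`; entries with `|x_i| < 1e-12` score 0 by
#' convention (the quotient is otherwise undefined at the baseline).
#'
#' @inheritParams saliency
#' @return An `attribution` (scores are already nonnegative).
#' @export
arch_detect <- function(model, inputs) {
  x <- prep_inputs(model, inputs)
  n <- nrow(x); d <- ncol(x)
  m0 <- predict_proba(model, matrix(0, 1, d))
  sc <- matrix(0, n, d)
  for (j in seq_len(d)) {
    xj <- matrix(0, n, d)
    xj[, j] <- x[, j]
    num <- predict_proba(model, xj) - m0
    ok <- abs(x[, j]) >= 1e-12
    sc[ok, j] <- (num[ok] / x[ok, j])^2
  }
  new_attribution(sc, "arch_detect", colnames(x))
}

#' Glassbox attribution
#'
#' Broadcasts the model's built-in per-feature importance to every sample;
#' for sequence input the per-feature weight is spread uniformly over the
#' feature's time steps so each sample's scores still sum to 1.
#'
#' @inheritParams saliency
#' @return An `attribution`.
#' @export
glassbox_attribution <- function(model, inputs) {
  x <- prep_inputs(model, inputs)
  imp <- glassbox_importance(model)
  shp <- model_input_shape(model, x)
  row <- if (!is.null(shp) && length(imp) == shp[2]) {
    rep(imp / shp[1], each = shp[1])
  } else if (length(imp) == ncol(x)) {
    imp
  } else {
    abort("glassbox importance length does not match the input width",
          class = "icufair_argument_error")
  }
  new_attribution(matrix(row, nrow(x), ncol(x), byrow = TRUE), "glassbox",
                  colnames(x))
}

#' Random importance baseline
#'
#' A seeded random permutation of ranks, identical for every sample: the
#' reference ranking any informative method must beat.
#'
#' @param d_in Number of input entries.
#' @param n_samples Number of samples to broadcast over.
#' @param seed Integer seed.
#' @param feature_names Optional column names.
#' @return An `attribution` whose importance row is a permutation of
#'   `1..d_in`.
#' @export
random_ranking <- function(d_in, n_samples = 1L, seed = 1L,
                           feature_names = NULL) {
  ranks <- withr::with_seed(as.integer(seed), sample.int(d_in))
  new_attribution(matrix(as.numeric(ranks), n_samples, d_in, byrow = TRUE),
                  "random", feature_names)
}

#' Aggregate per-sample importance into a global feature ordering
#'
#' For each sample, features are ranked by importance (rank 1 = most
#' important; ties resolved to the lower feature index); ranks are averaged
#' over samples and sorted ascending.
#'
#' @param attr An `attribution`.
#' @return Tibble with columns `feature`, `mean_rank`, `global_rank`,
#'   ordered from most to least important.
#' @export
aggregate_global_rank <- function(attr) {
  imp <- importance(attr)
  d <- ncol(imp)
  ranks <- t(apply(imp, 1, function(row) {
    ord <- order(-row, seq_len(d))
    r <- integer(d)
    r[ord] <- seq_len(d)
    r
  }))
  if (nrow(imp) == 1) ranks <- matrix(ranks, 1, d)
  feats <- colnames(imp)
  if (is.null(feats)) feats <- paste0("x", seq_len(d))
  tibble(feature = feats, mean_rank = colMeans(ranks)) %>%
    arrange(.data$mean_rank, match(.data$feature, feats)) %>%
    mutate(global_rank = row_number())
}

#' Unified attribution front-end
#'
#' Dispatches to the individual attribution methods by name with a shared
#' configuration list.
#'
#' @param model Model obeying the classifier contract.
#' @param inputs `(n, d)` input matrix.
#' @param method Method name.
#' @param baseline A [baseline_spec()].
#' @param config Optional list of method parameters (`steps`, `n_perms`,
#'   `n_draws`, `noise_sd`, `window`, `seed`).
#' @return An `attribution`.
#' @export
attribute <- function(model, inputs,
                      method = c("saliency", "integrated_gradients",
                                 "gradient_shap", "saliency_noise_tunnel",
                                 "shapley_sampling", "feature_permutation",
                                 "feature_ablation", "occlusion",
                                 "arch_detect", "glassbox", "random"),
                      baseline = baseline_spec(), config = list()) {
  method <- match.arg(method)
  cfg <- utils::modifyList(list(steps = 50L, n_perms = 25L, n_draws = 20L,
                                noise_sd = 0.1, window = c(1L, 1L),
                                seed = 1L), config)
  switch(method,
    saliency = saliency(model, inputs),
    integrated_gradients = integrated_gradients(model, inputs, baseline,
                                                cfg$steps),
    gradient_shap = gradient_shap(model, inputs, baseline, cfg$n_draws,
                                  cfg$noise_sd, cfg$seed),
    saliency_noise_tunnel = saliency_noise_tunnel(model, inputs, cfg$n_draws,
                                                  cfg$noise_sd, cfg$seed),
    shapley_sampling = shapley_sampling(model, inputs, baseline, cfg$n_perms,
                                        cfg$seed),
    feature_permutation = feature_permutation(model, inputs, cfg$seed),
    feature_ablation = feature_ablation(model, inputs, baseline),
    occlusion = occlusion(model, inputs, baseline, cfg$window),
    arch_detect = arch_detect(model, inputs),
    glassbox = glassbox_attribution(model, inputs),
    random = random_ranking(ncol(coerce_inputs(inputs)),
                            nrow(coerce_inputs(inputs)), cfg$seed,
                            colnames(coerce_inputs(inputs))))
}
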