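bz <- baseline_spec("zeros")

test_that("gradient methods refuse models without input gradients", {
  m <- fn_model(function(x) rowSums(x)) # predict only, no gradient
  x <- matrix(1, 2, 3)
  expect_error(saliency(m, x), class = "icufair_capability_error")
  expect_error(integrated_gradients(m, x), class = "icufair_capability_error")
  expect_error(gradient_shap(m, x), class = "icufair_capability_error")
  expect_error(saliency_noise_tunnel(m, x),
               class = "icufair_capability_error")
  # perturbation methods still work
  expect_s3_class(feature_ablation(m, x, bz), "attribution")
})

test_that("saliency returns exact gradients", {
  m <- linear_fn_model(c(2, 3))
  x <- matrix(c(1, -4, 2, 9), 2, 2)
  s <- saliency(m, x)
  expect_equal(importance(s), matrix(c(2, 2, 3, 3), 2, 2))
  const <- fn_model(function(x) rep(5, nrow(x)),
                    grad = function(x) matrix(0, nrow(x), ncol(x)))
  expect_equal(saliency(const, x)$scores, matrix(0, 2, 2))
  # against finite differences on a trained network
  set.seed(3)
  xx <- matrix(runif(12), 3, 4)
  mm <- fit(make_model("mlp", list(hidden = 4L)), xx, c(0, 1, 1), seed = 1,
            epochs = 20)
  g <- saliency(mm, xx)$scores
  eps <- 1e-5
  xp <- xx; xp[2, 3] <- xp[2, 3] + eps
  xm <- xx; xm[2, 3] <- xm[2, 3] - eps
  fd <- (predict_proba(mm, xp)[2] - predict_proba(mm, xm)[2]) / (2 * eps)
  expect_equal(g[2, 3], fd, tolerance = 1e-3)
})

test_that("integrated gradients are exact for linear maps and complete in the limit", {
  m <- linear_fn_model(c(2, 3))
  x <- matrix(c(1, 2), 1, 2)
  ig <- integrated_gradients(m, x, bz, steps = 5)
  expect_equal(ig$scores, matrix(c(2, 6), 1, 2), ignore_attr = TRUE)
  expect_equal(sum(ig$scores), 8) # completeness: M(x) - M(0)
  expect_equal(integrated_gradients(m, x, baseline_spec("fixed_vector",
                                                        vector = c(1, 2)),
                                    steps = 3)$scores,
               matrix(0, 1, 2), ignore_attr = TRUE) # x = x'
  sq <- fn_model(function(x) x[, 1]^2, grad = function(x) cbind(2 * x[, 1]))
  igq <- integrated_gradients(sq, matrix(1, 1, 1), bz, steps = 200)
  expect_equal(drop(igq$scores), 1, tolerance = 1e-2) # closed form: int 2a da
})

test_that("gradient SHAP converges to the analytic linear expectation", {
  m <- linear_fn_model(c(2, -1))
  x <- matrix(c(0.8, 0.5), 1, 2)
  zero_mean <- baseline_spec("distribution_sampler",
                             sampler = function(n, d) matrix(rnorm(n * d), n, d))
  gs <- gradient_shap(m, x, zero_mean, n_draws = 200, noise_sd = 0, seed = 2)
  expected <- c(2, -1) * c(0.8, 0.5)
  expect_equal(drop(gs$scores), expected, tolerance = 0.05 * max(abs(expected)),
               ignore_attr = TRUE)
  # zero noise, one fixed baseline, linear map: equals integrated gradients
  fixed <- baseline_spec("fixed_vector", vector = c(0.1, 0.9))
  gs2 <- gradient_shap(m, x, fixed, n_draws = 10, noise_sd = 0, seed = 5)
  ig <- integrated_gradients(m, x, fixed, steps = 10)
  expect_equal(gs2$scores, ig$scores)
  expect_identical(gradient_shap(m, x, fixed, seed = 9)$scores,
                   gradient_shap(m, x, fixed, seed = 9)$scores)
})

test_that("the noise tunnel reduces to saliency and its variance shrinks", {
  m <- linear_fn_model(c(1, 4))
  x <- matrix(c(2, 3), 1, 2)
  expect_equal(saliency_noise_tunnel(m, x, n_draws = 8, noise_sd = 2,
                                     seed = 1)$scores,
               saliency(m, x)$scores) # constant gradient
  set.seed(5)
  xx <- matrix(runif(8), 2, 4)
  mm <- fit(make_model("mlp", list(hidden = 6L)), matrix(runif(80), 20, 4),
            rbinom(20, 1, 0.5), seed = 2, epochs = 30)
  expect_equal(saliency_noise_tunnel(mm, xx, n_draws = 5, noise_sd = 0,
                                     seed = 3)$scores,
               saliency(mm, xx)$scores)
  few <- sapply(1:20, function(s)
    saliency_noise_tunnel(mm, xx, n_draws = 5, noise_sd = 0.3,
                          seed = s)$scores[1, 1])
  many <- sapply(1:20, function(s)
    saliency_noise_tunnel(mm, xx, n_draws = 400, noise_sd = 0.3,
                          seed = s)$scores[1, 1])
  expect_lt(stats::var(many), stats::var(few))
})

test_that("Shapley sampling matches enumeration and additivity", {
  prod2 <- fn_model(function(x) x[, 1] * x[, 2])
  x <- matrix(c(1, 1), 1, 2)
  ss <- shapley_sampling(prod2, x, bz, n_perms = 400, seed = 3)
  expect_equal(drop(ss$scores), c(0.5, 0.5), tolerance = 0.06,
               ignore_attr = TRUE)
  expect_equal(sum(ss$scores), 1, tolerance = 1e-12) # efficiency per perm
  # additive model: exact for any permutation set
  lin <- linear_fn_model(c(3, -2), b = 1)
  xa <- matrix(c(2, 5), 1, 2)
  sa <- shapley_sampling(lin, xa, bz, n_perms = 3, seed = 1)
  expect_equal(drop(sa$scores), c(3 * 2, -2 * 5), ignore_attr = TRUE)
  expect_identical(shapley_sampling(lin, xa, bz, n_perms = 5, seed = 2)$scores,
                   shapley_sampling(lin, xa, bz, n_perms = 5, seed = 2)$scores)
})

test_that("feature permutation scores vanish for constant columns and ignored features", {
  m <- linear_fn_model(c(1, 0))
  x_same <- matrix(c(3, 3, 3, 7, 7, 7), 3, 2)
  fp <- feature_permutation(m, x_same, seed = 1)
  expect_equal(fp$scores, matrix(0, 3, 2))
  withr::with_seed(2, x <- matrix(runif(20), 10, 2))
  fp2 <- feature_permutation(m, x, seed = 4)
  expect_equal(fp2$scores[, 2], rep(0, 10)) # feature absent from the model
  # batch {0, 1} on M = x1: the two equally likely shuffles score 0 or 1
  m1 <- linear_fn_model(1)
  xb <- matrix(c(0, 1), 2, 1)
  draws <- sapply(1:400, function(s)
    feature_permutation(m1, xb, seed = s)$scores[1, 1])
  expect_true(all(draws %in% c(0, 1)))
  expect_lt(abs(mean(draws) - 0.5), 0.1)
})

test_that("feature ablation equals the baseline-substitution difference", {
  m <- linear_fn_model(c(2, 3))
  x <- matrix(c(1, 1), 1, 2)
  fa <- feature_ablation(m, x, bz)
  expect_equal(fa$scores, matrix(c(2, 3), 1, 2), ignore_attr = TRUE)
  fb <- feature_ablation(m, matrix(c(0, 1), 1, 2), bz)
  expect_equal(fb$scores[1, 1], 0) # x_i already at the baseline
  # definitional equivalence with a 1x1 occlusion window on a network
  set.seed(7)
  xx <- matrix(runif(12), 3, 4)
  mm <- fit(make_model("mlp", list(hidden = 5L)), matrix(runif(60), 15, 4),
            rbinom(15, 1, 0.5), seed = 3, epochs = 20)
  expect_equal(feature_ablation(mm, xx, bz)$scores,
               occlusion(mm, xx, bz, window = c(1, 1),
                         input_shape = c(1, 4))$scores)
})

test_that("occlusion averages overlapping window deltas over a (T, F) grid", {
  w <- c(1, 2, 4)
  m <- fn_model(function(x) drop(x %*% w),
                grad = function(x) matrix(w, nrow(x), 3, byrow = TRUE))
  x <- matrix(c(1, 1, 1), 1, 3) # T = 3, F = 1
  oc <- occlusion(m, x, bz, window = c(2, 1), input_shape = c(3, 1))
  # windows: {1,2} delta 3 and {2,3} delta 6; cells get the mean of covering deltas
  expect_equal(drop(oc$scores), c(3, (3 + 6) / 2, 6), ignore_attr = TRUE)
  all_w <- occlusion(m, x, bz, window = c(3, 1), input_shape = c(3, 1))
  expect_equal(drop(all_w$scores), rep(7, 3), ignore_attr = TRUE) # M(x)-M(0)
})

test_that("squared discrete derivatives recover squared linear coefficients", {
  m <- fn_model(function(x) 2 * x[, 1] + 3 * x[, 2] + 1)
  x <- matrix(c(1, 1), 1, 2)
  expect_equal(arch_detect(m, x)$scores, matrix(c(4, 9), 1, 2),
               ignore_attr = TRUE)
  x0 <- matrix(c(0, 1), 1, 2)
  expect_equal(arch_detect(m, x0)$scores[1, 1], 0) # degenerate-input rule
  sq <- fn_model(function(x) x[, 1]^2)
  expect_equal(drop(arch_detect(sq, matrix(2, 1, 1))$scores), 4)
})

test_that("glassbox attribution broadcasts normalised model weights", {
  x <- matrix(runif(36), 3, 12)
  m <- make_model("attention_glassbox", list(input_shape = c(4L, 3L)))
  m <- fit(m, x, c(0, 1, 0), seed = 1, epochs = 5)
  ga <- glassbox_attribution(m, x)
  expect_equal(ga$scores[1, ], ga$scores[3, ])
  expect_equal(rowSums(ga$scores), rep(1, 3), tolerance = 1e-9)
  expect_error(glassbox_attribution(fit(make_model("mlp"), x, c(0, 1, 0),
                                        seed = 1, epochs = 0), x),
               class = "icufair_capability_error")
})

test_that("the random baseline is a seeded rank permutation", {
  r <- random_ranking(6, n_samples = 3, seed = 2)
  expect_identical(r$scores, random_ranking(6, 3, seed = 2)$scores)
  expect_setequal(r$scores[1, ], 1:6)
  expect_equal(r$scores[1, ], r$scores[3, ])
  expect_false(identical(random_ranking(6, 1, seed = 2)$scores,
                         random_ranking(6, 1, seed = 3)$scores))
})

test_that("global rank aggregation averages per-sample dense ranks", {
  # sample 1 ranks: a=1, b=2, c=3; sample 2: a=3, b=1, c=2
  imp <- rbind(c(9, 5, 1), c(1, 9, 5))
  colnames(imp) <- c("a", "b", "c")
  attr_obj <- structure(list(scores = imp, method = "test"),
                        class = "attribution")
  out <- aggregate_global_rank(attr_obj)
  expect_identical(out$feature, c("b", "a", "c"))
  expect_equal(out$mean_rank, c(1.5, 2, 2.5))
  one <- aggregate_global_rank(structure(list(scores = imp[1, , drop = FALSE],
                                              method = "t"),
                                         class = "attribution"))
  expect_identical(one$feature, c("a", "b", "c"))
  # ties go to the lower feature index
  tied <- structure(list(scores = matrix(c(1, 1, 1), 1), method = "t"),
                    class = "attribution")
  expect_equal(aggregate_global_rank(tied)$mean_rank, c(1, 2, 3))
})

test_that("provably ignored features receive (near) zero importance", {
  # an mlp whose first-layer weights for feature 3 are exactly zero
  m <- make_model("mlp", list(hidden = 4L))
  m <- fit(m, matrix(runif(40), 10, 4), rbinom(10, 1, 0.5), seed = 1,
           epochs = 5)
  m$params$W1[3, ] <- 0
  x <- matrix(runif(8), 2, 4)
  expect_equal(saliency(m, x)$scores[, 3], c(0, 0))
  expect_equal(feature_ablation(m, x, bz)$scores[, 3], c(0, 0))
  expect_equal(arch_detect(m, x)$scores[, 3], c(0, 0))
  expect_equal(integrated_gradients(m, x, bz, steps = 20)$scores[, 3],
               c(0, 0))
  ss <- shapley_sampling(m, x, bz, n_perms = 50, seed = 1)
  expect_equal(ss$scores[, 3], c(0, 0), tolerance = 1e-12)
})

test_that("linear concordance: all methods rank features identically", {
  w <- c(0.5, 2, -1, 3)
  m <- linear_fn_model(w)
  x <- matrix(1, 1, 4)
  ords <- list(
    order(-importance(saliency(m, x))[1, ]),
    order(-importance(feature_ablation(m, x, bz))[1, ]),
    order(-importance(arch_detect(m, x))[1, ]),
    order(-importance(integrated_gradients(m, x, bz, steps = 10))[1, ]))
  for (o in ords) expect_equal(o, order(-abs(w)))
})

test_that("the attribute() front-end dispatches consistently", {
  m <- linear_fn_model(c(2, 3))
  x <- matrix(c(1, 2), 1, 2)
  expect_equal(attribute(m, x, "feature_ablation", baseline = bz)$scores,
               feature_ablation(m, x, bz)$scores)
  expect_equal(attribute(m, x, "arch_detect")$scores,
               arch_detect(m, x)$scores)
  td <- tidy(arch_detect(m, x))
  expect_identical(names(td),
                   c("sample", "feature", "score", "importance", "method"))
})
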