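# Raw scoring models obeying the classifier contract (predict_proba /
# input_gradient), used to exercise interpreters against closed forms where
# the output need not be a probability.

fn_model <- function(f, grad = NULL, input_shape = NULL) {
  structure(list(f = f, grad = grad,
                 config = list(input_shape = input_shape)),
            class = if (is.null(grad)) "nograd_model" else "fn_model")
}

.fn_predict <- function(model, inputs) {
  x <- if (is.matrix(inputs)) inputs else matrix(inputs, nrow = 1)
  as.numeric(model$f(x))
}
.fn_gradient <- function(model, inputs) {
  x <- if (is.matrix(inputs)) inputs else matrix(inputs, nrow = 1)
  g <- model$grad(x)
  matrix(g, nrow(x), ncol(x))
}
registerS3method("predict_proba", "fn_model", .fn_predict,
                 envir = asNamespace("icufair"))
registerS3method("input_gradient", "fn_model", .fn_gradient,
                 envir = asNamespace("icufair"))
registerS3method("predict_proba", "nograd_model", .fn_predict,
                 envir = asNamespace("icufair"))

linear_fn_model <- function(w, b = 0) {
  fn_model(f = function(x) drop(x %*% w) + b,
           grad = function(x) matrix(w, nrow(x), length(w), byrow = TRUE))
}

# All permutations of 1..d (d <= 7), for brute-force Shapley values.
all_perms <- function(d) {
  if (d == 1) return(list(1L))
  sub <- all_perms(d - 1L)
  out <- list()
  for (p in sub) {
    for (pos in 0:(d - 1L)) {
      out[[length(out) + 1L]] <- append(p, d, after = pos)
    }
  }
  out
}

brute_shapley <- function(f, x, baseline) {
  d <- length(x)
  perms <- all_perms(d)
  acc <- numeric(d)
  for (perm in perms) {
    cur <- baseline
    prev <- f(matrix(cur, 1))
    for (j in perm) {
      cur[j] <- x[j]
      val <- f(matrix(cur, 1))
      acc[j] <- acc[j] + (val - prev)
      prev <- val
    }
  }
  acc / length(perms)
}

# Generate a planted-signal cohort and run it through the full preprocessing
# pipeline to a tabular design matrix.
build_cohort_tabular <- function(n, n_temporal = 20L, seed = 1L,
                                 planted = default_planted_features(),
                                 demographic = 0L, missing_rate = 0,
                                 base_mortality = 0.07,
                                 demographic_effects = list(),
                                 split_seed = seed) {
  cfg <- sim_config(
    n_stays = n,
    feature_counts = c(temporal = n_temporal, demographic = demographic,
                       admission = 0L, comorbidity = 0L),
    base_mortality = base_mortality,
    planted_features = planted,
    demographic_effects = demographic_effects,
    missing_rate = missing_rate,
    seed = seed
  )
  co <- generate_cohort(cfg)
  spec <- default_feature_spec(cfg$feature_counts, sum_features = character(0))
  ev <- clean_events(co$events, spec)
  st <- filter_stays(ev, select_cohort(co$stays))
  fm <- build_matrix(ev, st, spec)
  sp <- split_dataset(nrow(st), seed = split_seed)
  fm <- impute(fm, compute_train_means(fm, sp$train))
  ts <- summarize_tabular(fm)
  list(cohort = co, stays = st,
       x = tabular_matrix(ts),
       y = co$labels$label[match(st$stay_id, co$labels$stay_id)],
       split = sp,
       col_info = attr(ts, "col_info"))
}
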