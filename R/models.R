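#' Construct a reference mortality classifier
#'
#' All models share one contract: [fit()] trains in place-by-copy,
#' [predict_proba()] returns the positive-class probability per sample,
#' [input_gradient()] returns the gradient of that probability with respect
#' to every input entry (exactly, by backpropagation), and glassbox models
#' additionally expose [glassbox_importance()]. The reference architectures
#' are deliberately small: they stand in for the large sequence models an
#' audit would target, so that remove-and-retrain loops stay desk-scale.
#'
#' * `linear`: logistic regression on flat input.
#' * `mlp`: one tanh hidden layer (default 16 units) on flat input.
#' * `recurrent`: Elman recurrent network over `(T, F)` sequences
#'   (flattened input, time fastest within feature), sigmoid read-out of the
#'   last hidden state.
#' * `attention_glassbox`: softmax attention over per-feature time averages
#'   with per-feature weights; its own importance (attention x |weight|,
#'   normalised to sum 1) is exposed as the glassbox interpretation.
#'
#' @param kind One of `"linear"`, `"mlp"`, `"recurrent"`,
#'   `"attention_glassbox"`.
#' @param config Optional list overriding defaults: `hidden` (units),
#'   `epochs`, `lr`, `l2`, `patience` (epochs without validation improvement
#'   before training stops; the default `Inf` runs the full budget and keeps
#'   the best-validation-epoch parameters), `valid_frac` (fraction of
#'   training rows held out for validation), `input_shape` (`c(T, F)`,
#'   required for sequence kinds), `init_seed`.
#' @return An untrained model of class `mortality_model` with declared
#'   capabilities; parameters are initialised (seeded) so `predict_proba`
#'   is usable even before training.
#' @export
make_model <- function(kind = c("linear", "mlp", "recurrent",
                                "attention_glassbox"),
                       config = list()) {
  if (length(kind) != 1 || !kind %in% c("linear", "mlp", "recurrent",
                                        "attention_glassbox"))
    config_error("kind", sprintf("unknown model kind '%s'",
                                 paste(kind, collapse = "/")))
  defaults <- list(hidden = 16L, epochs = 200L, lr = 0.1, l2 = 1e-2,
                   patience = Inf, valid_frac = 0.2, input_shape = NULL,
                   init_seed = 1L)
  config <- utils::modifyList(defaults, config)
  if (kind %in% c("recurrent", "attention_glassbox") &&
      is.null(config$input_shape))
    config_error("input_shape",
                 sprintf("model kind '%s' needs input_shape = c(T, F)", kind))
  m <- structure(list(kind = kind, config = config, params = NULL,
                      trained = FALSE, history = NULL),
                 class = "mortality_model")
  m$params <- NULL
  m
}

#' @export
print.mortality_model <- function(x, ...) {
  cat(sprintf("<mortality_model: %s>%s\n", x$kind,
              if (x$trained) " (trained)" else " (untrained)"))
  invisible(x)
}

model_capabilities <- function(model) {
  c(gradient_available = TRUE,
    glassbox_available = model$kind == "attention_glassbox")
}

coerce_inputs <- function(x) {
  if (is.data.frame(x)) x <- tabular_matrix_like(x)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  storage.mode(x) <- "double"
  x
}

tabular_matrix_like <- function(x) {
  if (inherits(x, "tabular_summary")) return(tabular_matrix(x))
  as.matrix(as.data.frame(x[setdiff(names(x), "stay_id")]))
}

init_params <- function(kind, d, config) {
  h <- config$hidden
  sc <- function(nr, nc, s) matrix(rnorm(nr * nc, 0, s), nr, nc)
  switch(kind,
    linear = list(W = sc(d, 1, 0.01), b = 0),
    mlp = list(W1 = sc(d, h, sqrt(1 / d)), b1 = rep(0, h),
               W2 = sc(h, 1, sqrt(1 / h)), b2 = 0),
    recurrent = {
      tf <- config$input_shape
      list(W = sc(tf[2], h, sqrt(1 / tf[2])), U = sc(h, h, sqrt(1 / h)),
           b = rep(0, h), v = sc(h, 1, sqrt(1 / h)), c = 0)
    },
    attention_glassbox = {
      f <- config$input_shape[2]
      list(u = rep(0, f), w = rnorm(f, 0, 0.1), b = 0)
    })
}

seq_slices <- function(x, input_shape) {
  # flattened column (f-1)*T + t -> list of T matrices (n x F)
  t_len <- input_shape[1]; f_len <- input_shape[2]
  lapply(seq_len(t_len), function(t) x[, (seq_len(f_len) - 1) * t_len + t,
                                       drop = FALSE])
}

forward_model <- function(model, x) {
  p <- model$params
  switch(model$kind,
    linear = {
      z <- drop(x %*% p$W) + p$b
      list(prob = plogis(z), cache = list(z = z))
    },
    mlp = {
      a1 <- sweep(x %*% p$W1, 2, p$b1, "+")
      h1 <- tanh(a1)
      z <- drop(h1 %*% p$W2) + p$b2
      list(prob = plogis(z), cache = list(h1 = h1))
    },
    recurrent = {
      shp <- model$config$input_shape
      xs <- seq_slices(x, shp)
      n <- nrow(x); hdim <- length(p$b)
      hs <- vector("list", shp[1])
      h <- matrix(0, n, hdim)
      for (t in seq_len(shp[1])) {
        h <- tanh(sweep(xs[[t]] %*% p$W + h %*% p$U, 2, p$b, "+"))
        hs[[t]] <- h
      }
      z <- drop(h %*% p$v) + p$c
      list(prob = plogis(z), cache = list(hs = hs, xs = xs))
    },
    attention_glassbox = {
      shp <- model$config$input_shape
      s <- feature_time_means(x, shp)
      a <- softmax_vec(p$u)
      z <- drop(s %*% (a * p$w)) + p$b
      list(prob = plogis(z), cache = list(s = s, a = a))
    })
}

feature_time_means <- function(x, input_shape) {
  t_len <- input_shape[1]; f_len <- input_shape[2]
  out <- matrix(0, nrow(x), f_len)
  for (f in seq_len(f_len))
    out[, f] <- rowMeans(x[, (f - 1) * t_len + seq_len(t_len), drop = FALSE])
  out
}

softmax_vec <- function(u) {
  e <- exp(u - max(u))
  e / sum(e)
}

param_gradients <- function(model, x, y, fwd) {
  p <- model$params
  n <- nrow(x)
  dz <- (fwd$prob - y) / n # d(mean BCE)/dz
  switch(model$kind,
    linear = list(W = crossprod(x, dz), b = sum(dz)),
    mlp = {
      h1 <- fwd$cache$h1
      dh <- (dz %*% t(p$W2)) * (1 - h1^2)
      list(W1 = crossprod(x, dh), b1 = colSums(dh),
           W2 = crossprod(h1, matrix(dz)), b2 = sum(dz))
    },
    recurrent = {
      shp <- model$config$input_shape
      hs <- fwd$cache$hs; xs <- fwd$cache$xs
      t_len <- shp[1]
      gW <- p$W * 0; gU <- p$U * 0; gb <- p$b * 0
      delta <- (matrix(dz) %*% t(p$v)) * (1 - hs[[t_len]]^2)
      for (t in rev(seq_len(t_len))) {
        gW <- gW + crossprod(xs[[t]], delta)
        gb <- gb + colSums(delta)
        h_prev <- if (t > 1) hs[[t - 1]] else matrix(0, n, ncol(p$U))
        gU <- gU + crossprod(h_prev, delta)
        if (t > 1) delta <- (delta %*% t(p$U)) * (1 - hs[[t - 1]]^2)
      }
      list(W = gW, U = gU, b = gb,
           v = crossprod(hs[[t_len]], matrix(dz)), c = sum(dz))
    },
    attention_glassbox = {
      s <- fwd$cache$s; a <- fwd$cache$a
      ds <- colSums(s * dz) # d loss / d (a_f w_f)
      gw <- ds * a
      # d loss / d u via the softmax Jacobian diag(a) - a a^T
      cw <- p$w * ds
      gu <- a * (cw - sum(a * cw))
      list(u = gu, w = gw, b = sum(dz))
    })
}

#' Train a mortality model
#'
#' Full-batch Adam on binary cross-entropy with L2 weight decay, a held-out
#' validation fraction for early stopping, and a single seed controlling
#' initialisation and the validation split. Refitting with the same data and
#' seed reproduces the same parameters.
#'
#' @param object A `mortality_model`.
#' @param inputs Numeric matrix (or tabular summary tibble) of shape
#'   `(n, d)`.
#' @param labels Binary 0/1 vector of length `n`.
#' @param seed Integer seed for initialisation and the validation split.
#' @param epochs,lr Optional overrides of the configured budget.
#' @param valid_inputs,valid_labels Optional explicit validation split for
#'   early stopping; when absent, `valid_frac` of the training rows is held
#'   out internally.
#' @param ... Unused.
#' @return The fitted model.
#' @method fit mortality_model
#' @export
fit.mortality_model <- function(object, inputs, labels, seed = 1L,
                                epochs = NULL, lr = NULL,
                                valid_inputs = NULL, valid_labels = NULL,
                                ...) {
  x <- coerce_inputs(inputs)
  y <- as.numeric(labels)
  stopifnot(length(y) == nrow(x))
  cfg <- object$config
  if (!is.null(epochs)) cfg$epochs <- epochs
  if (!is.null(lr)) cfg$lr <- lr
  object$config <- cfg
  # standardise inputs internally (kept with the model; gradients are
  # chain-ruled back to the raw input scale)
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[!is.finite(sdv) | sdv < 1e-8] <- 1
  object$scaler <- list(mu = mu, sd = sdv)
  x <- scale_inputs(x, object$scaler)
  if (!is.null(valid_inputs))
    valid_inputs <- scale_inputs(coerce_inputs(valid_inputs), object$scaler)
  withr::with_seed(as.integer(seed), {
    object$params <- init_params(object$kind, ncol(x), cfg)
    object$params <- init_output_bias(object$kind, object$params, y)
    if (cfg$epochs >= 1) {
    n <- nrow(x)
    if (!is.null(valid_inputs)) {
      xt <- x; yt <- y
      xv <- coerce_inputs(valid_inputs); yv <- as.numeric(valid_labels)
      n_val <- nrow(xv)
    } else {
      n_val <- if (cfg$valid_frac > 0 && n >= 20) floor(cfg$valid_frac * n) else 0
      val_idx <- if (n_val > 0) sample.int(n, n_val) else integer(0)
      tr_idx <- setdiff(seq_len(n), val_idx)
      xt <- x[tr_idx, , drop = FALSE]; yt <- y[tr_idx]
      xv <- x[val_idx, , drop = FALSE]; yv <- y[val_idx]
    }

    mstate <- vstate <- lapply(object$params, function(p) p * 0)
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    best <- list(loss = Inf, params = object$params, epoch = 0L)
    wait <- 0L
    for (ep in seq_len(cfg$epochs)) {
      fwd <- forward_model(object, xt)
      g <- param_gradients(object, xt, yt, fwd)
      for (nm in names(object$params)) {
        decay <- if (nm %in% c("b", "b2", "c")) 0 else cfg$l2
        grad <- g[[nm]] + decay * object$params[[nm]]
        mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * grad
        vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * grad^2
        mhat <- mstate[[nm]] / (1 - b1^ep)
        vhat <- vstate[[nm]] / (1 - b2^ep)
        object$params[[nm]] <- object$params[[nm]] -
          cfg$lr * mhat / (sqrt(vhat) + eps)
      }
      if (n_val > 0) {
        pv <- forward_model(object, xv)$prob
        vloss <- bce_loss(pv, yv)
        if (vloss < best$loss - 1e-6) {
          best <- list(loss = vloss, params = object$params, epoch = ep)
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= cfg$patience) break
        }
      }
    }
    if (n_val > 0) object$params <- best$params
    ptr <- forward_model(object, xt)$prob
    object$history <- list(train_loss = bce_loss(ptr, yt),
                           valid_loss = if (n_val > 0) best$loss else NA_real_,
                           epochs_run = if (n_val > 0) best$epoch else cfg$epochs)
    }
  })
  object$trained <- TRUE
  object
}

scale_inputs <- function(x, scaler) {
  if (is.null(scaler)) return(x)
  sweep(sweep(x, 2, scaler$mu, "-"), 2, scaler$sd, "/")
}

init_output_bias <- function(kind, params, y) {
  b0 <- qlogis(min(max(mean(y), 1e-3), 1 - 1e-3))
  switch(kind,
         linear = { params$b <- b0; params },
         mlp = { params$b2 <- b0; params },
         recurrent = { params$c <- b0; params },
         attention_glassbox = { params$b <- b0; params })
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Positive-class probability
#'
#' @param model A model obeying the classifier contract.
#' @param inputs `(n, d)` matrix (or tabular summary tibble).
#' @return Numeric vector of probabilities in [0, 1].
#' @export
predict_proba <- function(model, inputs) UseMethod("predict_proba")

#' @export
predict_proba.mortality_model <- function(model, inputs) {
  x <- coerce_inputs(inputs)
  if (is.null(model$params))
    model$params <- withr::with_seed(model$config$init_seed,
                                     init_params(model$kind, ncol(x),
                                                 model$config))
  forward_model(model, scale_inputs(x, model$scaler))$prob
}

#' Gradient of the positive-class probability w.r.t. each input entry
#'
#' @inheritParams predict_proba
#' @return Matrix of the same shape as `inputs`.
#' @export
input_gradient <- function(model, inputs) UseMethod("input_gradient")

#' @export
input_gradient.mortality_model <- function(model, inputs) {
  x <- coerce_inputs(inputs)
  if (is.null(model$params))
    model$params <- withr::with_seed(model$config$init_seed,
                                     init_params(model$kind, ncol(x),
                                                 model$config))
  p <- model$params
  x <- scale_inputs(x, model$scaler)
  fwd <- forward_model(model, x)
  dp <- fwd$prob * (1 - fwd$prob) # d sigmoid(z) / dz
  g <- switch(model$kind,
    linear = outer(dp, drop(p$W)),
    mlp = {
      h1 <- fwd$cache$h1
      dh <- ((1 - h1^2) * matrix(p$W2[, 1], nrow(x), ncol(h1),
                                 byrow = TRUE)) %*% t(p$W1)
      dp * dh
    },
    recurrent = {
      shp <- model$config$input_shape
      hs <- fwd$cache$hs
      t_len <- shp[1]; f_len <- shp[2]
      out <- matrix(0, nrow(x), t_len * f_len)
      delta <- (matrix(dp) %*% t(p$v)) * (1 - hs[[t_len]]^2)
      for (t in rev(seq_len(t_len))) {
        out[, (seq_len(f_len) - 1) * t_len + t] <- delta %*% t(p$W)
        if (t > 1) delta <- (delta %*% t(p$U)) * (1 - hs[[t - 1]]^2)
      }
      out
    },
    attention_glassbox = {
      shp <- model$config$input_shape
      a <- fwd$cache$a
      coef <- rep(a * p$w / shp[1], each = shp[1]) # d z / d x_{t,f}
      outer(dp, coef)
    })
  if (!is.null(model$scaler)) g <- sweep(g, 2, model$scaler$sd, "/")
  g
}

#' Built-in feature importance of a glassbox model
#'
#' For the attention model: the attention weight times the absolute
#' per-feature weight, normalised to sum to 1.
#'
#' @param model A fitted model with the glassbox capability.
#' @return Nonnegative per-feature weights summing to 1.
#' @export
glassbox_importance <- function(model) UseMethod("glassbox_importance")

#' @export
glassbox_importance.mortality_model <- function(model) {
  if (!model_capabilities(model)[["glassbox_available"]])
    abort(sprintf("model kind '%s' has no glassbox interpretation", model$kind),
          class = "icufair_capability_error")
  if (is.null(model$params))
    abort("model must be fitted (or at least initialised) first",
          class = "icufair_capability_error")
  a <- softmax_vec(model$params$u)
  imp <- a * abs(model$params$w)
  if (sum(imp) == 0) imp <- a
  imp / sum(imp)
}

#' @method tidy mortality_model
#' @export
tidy.mortality_model <- function(x, ...) {
  if (is.null(x$params)) return(tibble(term = character(0),
                                       estimate = numeric(0)))
  flat <- unlist(x$params)
  tibble(term = names(flat), estimate = unname(flat))
}

#' @method glance mortality_model
#' @export
glance.mortality_model <- function(x, ...) {
  tibble(kind = x$kind, trained = x$trained,
         n_params = if (is.null(x$params)) 0L else length(unlist(x$params)),
         train_loss = if (is.null(x$history)) NA_real_ else x$history$train_loss,
         valid_loss = if (is.null(x$history)) NA_real_ else x$history$valid_loss,
         epochs_run = if (is.null(x$history)) NA_integer_ else
           as.integer(x$history$epochs_run))
}

#' Split sample indices into train / validation / test sets
#'
#' Sizes are `floor(f_train * n)`, `floor(f_valid * n)` and the remainder
#' (defaults 60/20/20). The three sets are disjoint, cover `1..n`, and are
#' reproducible from the seed.
#'
#' @param n Number of samples (>= 5).
#' @param fractions Length-3 positive fractions summing to 1.
#' @param seed Integer seed.
#' @return List with integer index vectors `train`, `valid`, `test`.
#' @export
split_dataset <- function(n, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  if (n < 5) abort("need at least 5 samples to split",
                   class = "icufair_argument_error")
  if (any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-9)
    config_error("fractions", "must be positive and sum to 1")
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  n_tr <- floor(fractions[1] * n)
  n_va <- floor(fractions[2] * n)
  list(train = sort(perm[seq_len(n_tr)]),
       valid = sort(perm[n_tr + seq_len(n_va)]),
       test = sort(perm[(n_tr + n_va + 1):n]))
}

#' Binary classification metrics
#'
#' AUROC is the probability that a random positive outranks a random
#' negative, with ties counting one half (midrank Mann-Whitney); AUPRC is
#' the step integral of the precision-recall curve over distinct score
#' thresholds.
#'
#' @param scores Predicted positive-class probabilities.
#' @param labels Binary 0/1 labels; both classes must be present.
#' @return Tibble with columns `auprc`, `auroc`.
#' @export
binary_metrics <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    abort("metrics undefined: only one class present in labels",
          class = "icufair_metric_error")
  tibble(auprc = pr_auc(scores, labels), auroc = roc_auc(scores, labels))
}

roc_auc <- function(scores, labels) {
  np <- sum(labels == 1); nn <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

pr_auc <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  np <- sum(y)
  last_of_thr <- !duplicated(s, fromLast = TRUE) # last index per threshold
  tp <- tp[last_of_thr]; fp <- fp[last_of_thr]
  prec <- tp / (tp + fp)
  rec <- tp / np
  sum(diff(c(0, rec)) * prec)
}
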