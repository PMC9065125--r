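#' Uninformative filler values
#'
#' The fixed uninformative value used when a feature is removed: its mean
#' over the training rows, per flattened input column.
#'
#' @param train_inputs `(n_train, d)` matrix of training inputs.
#' @return Numeric vector of length `d`.
#' @export
uninformative_values <- function(train_inputs) {
  colMeans(coerce_inputs(train_inputs))
}

#' Replace each sample's most important features with fillers
#'
#' For every sample, its own top `k = round(ratio * d)` input entries by
#' importance (ties resolved to the lower index; `k` is at least 1 whenever
#' `ratio > 0`) are replaced by the filler values. The same operation is
#' applied to training and test rows so both stay on the modified
#' distribution.
#'
#' @param inputs `(n, d)` matrix.
#' @param importance An `attribution`, or an importance matrix with 1 or `n`
#'   rows, or an importance vector of length `d`.
#' @param ratio Feature drop ratio in [0, 1].
#' @param fillers Per-column fillers from [uninformative_values()].
#' @return The modified input matrix.
#' @export
ablate_topk <- function(inputs, importance, ratio, fillers) {
  stopifnot(ratio >= 0, ratio <= 1)
  x <- coerce_inputs(inputs)
  d <- ncol(x)
  imp <- importance_matrix(importance, nrow(x), d)
  k <- round(ratio * d)
  if (ratio > 0) k <- max(1L, k)
  k <- min(k, d)
  if (k == 0) return(x)
  filler_mat <- matrix(fillers, nrow(x), d, byrow = TRUE)
  if (nrow(imp) == 1) {
    top <- order(-imp[1, ], seq_len(d))[seq_len(k)]
    x[, top] <- filler_mat[, top]
  } else {
    for (i in seq_len(nrow(x))) {
      top <- order(-imp[i, ], seq_len(d))[seq_len(k)]
      x[i, top] <- filler_mat[i, top]
    }
  }
  x
}

importance_matrix <- function(importance, n, d) {
  imp <- if (inherits(importance, "attribution")) importance(importance)
         else if (is.matrix(importance)) abs(importance)
         else matrix(abs(as.numeric(importance)), 1, byrow = TRUE)
  if (ncol(imp) != d)
    abort(sprintf("importance width %d does not match input width %d",
                  ncol(imp), d), class = "icufair_argument_error")
  if (!nrow(imp) %in% c(1L, n))
    abort("importance must have 1 row or one row per sample",
          class = "icufair_argument_error")
  imp
}

#' Model trustworthiness score
#'
#' Reward/penalty-weighted confidence in the true class: for each sample the
#' model's confidence `C` in its predicted class contributes `C^alpha` when
#' the prediction is correct and `(1 - C)^beta` when it is wrong. With
#' `alpha = beta = 1` this is the mean probability assigned to the true
#' class.
#'
#' @param scores Positive-class probabilities.
#' @param labels True 0/1 labels.
#' @param alpha Reward exponent (default 1).
#' @param beta Penalty exponent (default 1).
#' @return Scalar in [0, 1].
#' @export
trust_score <- function(scores, labels, alpha = 1, beta = 1) {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= 0.5)
  conf <- ifelse(pred == 1L, scores, 1 - scores)
  q <- ifelse(pred == labels, conf^alpha, (1 - conf)^beta)
  mean(q)
}

#' Remove-and-retrain evaluation curve
#'
#' The core remove-and-retrain loop shared by the performance and
#' trustworthiness analyses. For each drop ratio, the most important
#' features of every sample (train and test alike) are replaced by their
#' training-set means, the model is retrained from scratch with a
#' deterministic per-ratio seed derived from `(label, ratio, base_seed)`,
#' and AUPRC, AUROC and the trustworthiness score are recorded on the
#' modified test set. Because the retraining seed is deterministic, the
#' performance and trustworthiness readings at every ratio come from the
#' same retrained model.
#'
#' @param inputs `(n, d)` input matrix covering all samples.
#' @param labels 0/1 labels aligned with `inputs`.
#' @param split Index sets from [split_dataset()].
#' @param importance Importance source for [ablate_topk()] (an
#'   `attribution` over all samples, an oracle vector, or a random ranking).
#' @param model_kind Reference model kind to retrain.
#' @param ratios Strictly increasing drop ratios in [0, 1]; the default grid
#'   includes the 0 anchor so the trapezoid is anchored at the unablated
#'   model.
#' @param base_seed Base seed for the per-ratio retraining seeds.
#' @param model_config Configuration passed to [make_model()].
#' @param label Name of the importance source (enters the seed derivation
#'   and the output).
#' @param alpha,beta Trust-score exponents.
#' @return A tibble of class `roar_curve` with columns `method`, `ratio`,
#'   `auprc`, `auroc`, `trust`.
#' @export
run_ablation_curve <- function(inputs, labels, split, importance,
                               model_kind = "mlp",
                               ratios = seq(0, 1, by = 0.1),
                               base_seed = 1L, model_config = list(),
                               label = "attribution", alpha = 1, beta = 1) {
  if (any(diff(ratios) <= 0) || any(ratios < 0 | ratios > 1))
    config_error("ratios", "must be strictly increasing within [0, 1]")
  x <- coerce_inputs(inputs)
  y <- as.integer(labels)
  fillers <- uninformative_values(x[split$train, , drop = FALSE])
  label_hash <- sum(utf8ToInt(label)) %% 10000L
  rows <- purrr::map(seq_along(ratios), function(i) {
    r <- ratios[i]
    xa <- ablate_topk(x, importance, r, fillers)
    seed_r <- (as.integer(base_seed) * 131L + i * 7919L + label_hash) %%
      .Machine$integer.max
    model <- make_model(model_kind, model_config)
    model <- fit(model, xa[split$train, , drop = FALSE], y[split$train],
                 seed = seed_r,
                 valid_inputs = xa[split$valid, , drop = FALSE],
                 valid_labels = y[split$valid])
    p <- predict_proba(model, xa[split$test, , drop = FALSE])
    met <- binary_metrics(p, y[split$test])
    tibble(method = label, ratio = r, auprc = met$auprc, auroc = met$auroc,
           trust = trust_score(p, y[split$test], alpha, beta))
  })
  out <- bind_rows(rows)
  class(out) <- c("roar_curve", class(out))
  out
}

#' @rdname run_ablation_curve
#' @param ... Passed to [run_ablation_curve()].
#' @export
run_roar <- function(inputs, labels, split, importance, ...) {
  run_ablation_curve(inputs, labels, split, importance, ...)
}

#' @rdname run_ablation_curve
#' @export
run_trust_curve <- function(inputs, labels, split, importance, ...) {
  run_ablation_curve(inputs, labels, split, importance, ...)
}

#' Area under a metric-vs-drop-ratio curve
#'
#' Trapezoidal area normalised by the ratio span, so a constant curve at
#' value `c` scores exactly `c`. Lower areas mean faster information loss,
#' i.e. a better importance ranking.
#'
#' @param curve A `roar_curve`.
#' @param metric `"auprc"`, `"auroc"` or `"trust"`.
#' @return Scalar curve area.
#' @export
curve_auc <- function(curve, metric = c("auroc", "auprc", "trust")) {
  metric <- match.arg(metric)
  trapz_norm(curve$ratio, curve[[metric]])
}

trapz_norm <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2) /
    (max(x) - min(x))
}

#' @method glance roar_curve
#' @export
glance.roar_curve <- function(x, ...) {
  x %>%
    group_by(.data$method) %>%
    summarise(auc_auprc = trapz_norm(.data$ratio, .data$auprc),
              auc_auroc = trapz_norm(.data$ratio, .data$auroc),
              auc_trust = trapz_norm(.data$ratio, .data$trust),
              .groups = "drop")
}

#' Plot remove-and-retrain curves
#'
#' @param object A `roar_curve` (possibly several methods row-bound).
#' @param metric Which metric to draw.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot roar_curve
#' @export
autoplot.roar_curve <- function(object, metric = c("auroc", "auprc", "trust"),
                                ...) {
  metric <- match.arg(metric)
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$ratio, y = .data[[metric]],
                               colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "feature drop ratio", y = metric,
                  colour = "importance source") +
    ggplot2::theme_minimal()
}
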