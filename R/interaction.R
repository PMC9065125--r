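#' Group feature importance
#'
#' The mean per-sample importance of each input column within each
#' protected-group level, plus the per-column disparity (max minus min of
#' the group means). Parity of the group means indicates a feature is used
#' equally across subgroups.
#'
#' @param attr An `attribution` (or importance matrix) whose rows align
#'   with `group`.
#' @param group Group level per sample.
#' @param features Optional subset of columns to report.
#' @return Tibble with columns `feature`, `group`, `n`, `g` (group mean
#'   importance) and `disparity` (per feature, repeated across its groups).
#' @export
group_feature_importance <- function(attr, group, features = NULL) {
  imp <- if (inherits(attr, "attribution")) importance(attr) else abs(attr)
  stopifnot(nrow(imp) == length(group))
  feats <- colnames(imp)
  if (is.null(feats)) feats <- paste0("x", seq_len(ncol(imp)))
  colnames(imp) <- feats
  if (!is.null(features)) imp <- imp[, features, drop = FALSE]
  group <- as.character(group)
  keep <- !is.na(group)
  imp <- imp[keep, , drop = FALSE]
  group <- group[keep]
  levels <- sort(unique(group))
  rows <- purrr::map(levels, function(g) {
    idx <- group == g
    tibble(feature = colnames(imp), group = g, n = sum(idx),
           g_importance = unname(colMeans(imp[idx, , drop = FALSE])))
  })
  out <- bind_rows(rows)
  out %>%
    group_by(.data$feature) %>%
    mutate(disparity = max(.data$g_importance) - min(.data$g_importance)) %>%
    ungroup()
}

#' Permutation null for group-importance disparity
#'
#' Reassigns group labels at random `n_perm` times and records each
#' feature's disparity under the null of no group structure; returns the
#' observed disparity with the null band and a permutation p-value
#' (observed included in the null set, so p >= 1/(n_perm + 1)).
#'
#' @inheritParams group_feature_importance
#' @param n_perm Number of label permutations.
#' @param level Confidence level of the null band.
#' @param seed Seed for the permutations.
#' @return Tibble with columns `feature`, `observed`, `lo`, `hi`,
#'   `p_value`.
#' @export
disparity_permutation_null <- function(attr, group, n_perm = 200L,
                                       level = 0.95, seed = 1L) {
  imp <- if (inherits(attr, "attribution")) importance(attr) else abs(attr)
  group <- as.character(group)
  obs <- disparity_vec(imp, group)
  null <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(k)
      disparity_vec(imp, sample(group)), numeric(ncol(imp)))
  })
  null <- matrix(null, nrow = ncol(imp))
  a <- (1 - level) / 2
  feats <- colnames(imp)
  if (is.null(feats)) feats <- paste0("x", seq_len(ncol(imp)))
  tibble(
    feature = feats,
    observed = obs,
    lo = apply(null, 1, quantile, probs = a, names = FALSE),
    hi = apply(null, 1, quantile, probs = 1 - a, names = FALSE),
    p_value = vapply(seq_along(obs), function(j)
      (1 + sum(null[j, ] >= obs[j])) / (n_perm + 1), numeric(1))
  )
}

disparity_vec <- function(imp, group) {
  levels <- unique(group)
  means <- vapply(levels, function(g)
    colMeans(imp[group == g, , drop = FALSE]), numeric(ncol(imp)))
  means <- matrix(means, nrow = ncol(imp))
  apply(means, 1, max) - apply(means, 1, min)
}

#' Demographic rank profiles by subgroup
#'
#' Averages importance across time steps to get one score per feature, then,
#' within each subgroup of the protected attribute, dense-ranks every
#' feature (rank 1 = most important; tied features share a rank) and
#' reports the ranks of the demographic features. A low rank for a feature
#' in one subgroup means the model leans on that feature more for that
#' subgroup.
#'
#' @param attr `attribution` over flattened `(T, F)` input.
#' @param group Group level per sample.
#' @param col_info Column metadata (`column`, `feature_id`) from
#'   [flatten_sequences()] (or `summarize_tabular()`).
#' @param features Features whose ranks to report (defaults to the
#'   demographic attributes present).
#' @return Tibble with columns `feature`, `group`, `g_importance`, `rank`,
#'   `n_features`.
#' @export
rank_profile <- function(attr, group, col_info, features = NULL) {
  imp <- if (inherits(attr, "attribution")) importance(attr) else abs(attr)
  stopifnot(ncol(imp) == nrow(col_info))
  # average importance across time steps -> per-feature importance
  fid <- col_info$feature_id
  ufid <- unique(fid)
  per_feat <- vapply(ufid, function(f)
    rowMeans(imp[, fid == f, drop = FALSE]), numeric(nrow(imp)))
  per_feat <- matrix(per_feat, nrow = nrow(imp),
                     dimnames = list(NULL, ufid))
  if (is.null(features))
    features <- intersect(c("age", "ethnicity", "gender", "marital_status",
                            "insurance"), ufid)
  group <- as.character(group)
  levels <- sort(unique(group[!is.na(group)]))
  rows <- purrr::map(levels, function(g) {
    m <- colMeans(per_feat[group == g, , drop = FALSE])
    rk <- dplyr::dense_rank(-m)
    tibble(feature = ufid, group = g, g_importance = unname(m),
           rank = rk, n_features = length(ufid))
  })
  bind_rows(rows) %>% filter(.data$feature %in% features)
}

#' Pair protected-attribute importance with minimum group AUC
#'
#' For each protected attribute: x = its time-and-sample-averaged
#' importance, y = the minimum AUC over its groups. A decreasing trend
#' means more heavily used attributes coincide with larger subgroup
#' performance divergence. Both Pearson and Spearman coefficients are
#' reported since importance scales differ across interpreters.
#'
#' @param importance_by_attr Tibble with columns `attribute`, `importance`.
#' @param min_auc_by_attr Tibble with columns `attribute`, `auc_min`.
#' @return A list with `pairs` (joined tibble) and `correlations`
#'   (tibble with `pearson`, `spearman`; NA with a warning when undefined).
#' @export
importance_fairness_pairs <- function(importance_by_attr, min_auc_by_attr) {
  pairs <- dplyr::inner_join(importance_by_attr, min_auc_by_attr,
                             by = "attribute")
  if (nrow(pairs) < 3 || sd(pairs$importance) == 0 || sd(pairs$auc_min) == 0) {
    warn("correlation undefined over the importance/fairness pairs")
    cors <- tibble(pearson = NA_real_, spearman = NA_real_)
  } else {
    cors <- tibble(pearson = cor(pairs$importance, pairs$auc_min),
                   spearman = cor(pairs$importance, pairs$auc_min,
                                  method = "spearman"))
  }
  list(pairs = pairs, correlations = cors)
}

#' Jaccard similarity of top-k feature sets
#'
#' `|top_k(A) intersect top_k(B)| / |top_k(A) union top_k(B)|` over the k
#' most important features of two orderings.
#'
#' @param a,b Feature orderings, most important first (character vectors or
#'   tibbles from [aggregate_global_rank()]).
#' @param k Set size (default 50).
#' @return Similarity in [0, 1].
#' @export
jaccard_topk <- function(a, b, k = 50L) {
  a <- ordering_vector(a); b <- ordering_vector(b)
  ta <- utils::head(a, k); tb <- utils::head(b, k)
  length(intersect(ta, tb)) / length(union(ta, tb))
}

ordering_vector <- function(x) {
  if (is.data.frame(x)) x$feature else as.character(x)
}

#' Compare identified features with a domain-knowledge set
#'
#' Partitions the domain-knowledge feature set DK and the identified set I
#' into DK intersect I, DK \ I and I \ DK, with counts and the overlap
#' fraction |DK intersect I| / |DK|.
#'
#' @param dk Domain-knowledge feature ids.
#' @param identified Identified important feature ids.
#' @return List with `both`, `dk_only`, `identified_only`, `counts`,
#'   `overlap_fraction`.
#' @export
compare_domain_knowledge <- function(dk, identified) {
  dk <- unique(as.character(dk)); identified <- unique(as.character(identified))
  both <- intersect(dk, identified)
  list(both = both,
       dk_only = setdiff(dk, identified),
       identified_only = setdiff(identified, dk),
       counts = c(both = length(both),
                  dk_only = length(dk) - length(both),
                  identified_only = length(identified) - length(both)),
       overlap_fraction = if (length(dk) > 0) length(both) / length(dk)
                          else NA_real_)
}
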