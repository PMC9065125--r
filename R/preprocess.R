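#' Default feature specification
#'
#' Describes every feature entering the pipeline: id, block (temporal /
#' demographic / admission / comorbidity), kind (numeric / categorical) and
#' whether the feature gets an extra `sum` column in the tabular summary.
#' With the default 122/5/4/33 block sizes and one sum-flagged temporal
#' feature (an accumulating urinary-output-style measurement) the tabular
#' summary has 122 x 3 + 1 + 5 + 4 + 33 = 409 columns.
#'
#' @param feature_counts Named counts per block, as in [sim_config()].
#' @param sum_features Feature ids that receive a `sum` summary in addition
#'   to min/max/mean; defaults to the last temporal feature.
#' @return Tibble with columns `feature_id`, `name`, `block`, `kind`,
#'   `has_sum`.
#' @export
default_feature_spec <- function(feature_counts = c(temporal = 122L,
                                                    demographic = 5L,
                                                    admission = 4L,
                                                    comorbidity = 33L),
                                 sum_features = NULL) {
  ids <- feature_ids_for(feature_counts)
  block <- rep(NA_character_, length(ids))
  block[grepl("^temp_", ids)] <- "temporal"
  block[ids %in% c("age", "ethnicity", "gender", "marital_status", "insurance")] <- "demographic"
  block[grepl("^adm_", ids)] <- "admission"
  block[grepl("^com_", ids)] <- "comorbidity"
  kind <- ifelse(ids %in% c("ethnicity", "gender", "marital_status", "insurance"),
                 "categorical", "numeric")
  if (is.null(sum_features)) {
    tmp <- ids[block == "temporal"]
    sum_features <- if (length(tmp) > 0) tmp[length(tmp)] else character(0)
  }
  tibble(feature_id = ids, name = ids, block = block, kind = kind,
         has_sum = ids %in% sum_features)
}

spec_error <- function(msg) abort(msg, class = "icufair_spec_error")

#' Select the study cohort from stay records
#'
#' Keeps adult first-known ICU stays of plausible length: age at admission at
#' least `min_age` years, stay order 1, and total ICU duration inside
#' `duration_bounds` hours (defaults 12 h to 10 days). Row order is
#' preserved; an empty result is allowed.
#'
#' @param stays Tibble with columns `age`, `stay_order`, `icu_duration`.
#' @param min_age Minimum age in years (inclusive).
#' @param duration_bounds Length-2 numeric, inclusive bounds on
#'   `icu_duration` in hours.
#' @return The qualifying rows of `stays`.
#' @export
select_cohort <- function(stays, min_age = 15, duration_bounds = c(12, 240)) {
  stopifnot(duration_bounds[1] < duration_bounds[2])
  stays %>%
    filter(.data$age >= min_age,
           .data$stay_order == 1L,
           .data$icu_duration >= duration_bounds[1],
           .data$icu_duration <= duration_bounds[2])
}

#' Clean a raw clinical event table
#'
#' Applies the standard cleaning conventions: unit conversion via an optional
#' per-feature factor table, range tokens `"lo-hi"` replaced by their
#' midpoint, duplicate (stay, feature, time) numeric recordings collapsed to
#' their mean and categorical ones to the first-appearing value. Rows whose
#' value cannot be parsed for a numeric feature are dropped with a warning
#' reporting the count. The result has unique (stay, feature, time) keys and
#' carries the parsed numeric value in `value_num` (NA for categorical
#' features).
#'
#' @param events Tibble with columns `stay_id`, `feature_id`, `time_hours`,
#'   `value` (character or numeric).
#' @param spec Feature specification covering every `feature_id` present.
#' @param unit_map Optional tibble (`feature_id`, `factor`) of multiplicative
#'   unit conversions, applied before duplicates are averaged.
#' @return Cleaned event tibble with columns `stay_id`, `feature_id`,
#'   `time_hours`, `value`, `value_num`.
#' @export
clean_events <- function(events, spec, unit_map = NULL) {
  unknown <- setdiff(unique(events$feature_id), spec$feature_id)
  if (length(unknown) > 0)
    spec_error(paste("feature id(s) not in spec:",
                     paste(unknown, collapse = ", ")))
  ev <- events %>%
    mutate(value = as.character(.data$value),
           .row_order = row_number()) %>%
    left_join(select(spec, "feature_id", "kind"), by = "feature_id")

  is_num <- ev$kind == "numeric"
  val <- suppressWarnings(as.numeric(ev$value))
  range_tok <- is_num & is.na(val) &
    grepl("^\\s*[0-9]*\\.?[0-9]+\\s*-\\s*[0-9]*\\.?[0-9]+\\s*$", ev$value)
  if (any(range_tok)) {
    parts <- strsplit(trimws(ev$value[range_tok]), "\\s*-\\s*")
    val[range_tok] <- vapply(parts,
                             function(p) mean(as.numeric(p)), numeric(1))
  }
  bad <- is_num & is.na(val)
  if (any(bad)) {
    warn(sprintf("dropped %d event row(s) with unparsable numeric values",
                 sum(bad)))
    ev <- ev[!bad, , drop = FALSE]
    val <- val[!bad]
    is_num <- is_num[!bad]
  }
  ev$value_num <- val
  if (!is.null(unit_map)) {
    fac <- unit_map$factor[match(ev$feature_id, unit_map$feature_id)]
    fac[is.na(fac)] <- 1
    ev$value_num <- ev$value_num * fac
  }

  # Duplicate (stay, feature, time) keys are rare; only they need group-wise
  # collapsing, the rest pass through untouched.
  key <- paste(ev$stay_id, ev$feature_id, ev$time_hours, sep = "\r")
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  uniq <- ev[!dup, , drop = FALSE]
  if (any(dup)) {
    collapsed <- ev[dup, , drop = FALSE] %>%
      group_by(.data$stay_id, .data$feature_id, .data$time_hours) %>%
      arrange(.data$.row_order, .by_group = TRUE) %>%
      summarise(kind = first(.data$kind),
                value_num = mean(.data$value_num),
                value = first(.data$value),
                .row_order = first(.data$.row_order),
                .groups = "drop") %>%
      mutate(value = ifelse(.data$kind == "numeric",
                            sprintf("%.17g", .data$value_num), .data$value))
    ev <- bind_rows(uniq, collapsed)
  } else {
    ev <- uniq
  }
  ev %>%
    mutate(value_num = ifelse(.data$kind == "numeric", .data$value_num,
                              NA_real_)) %>%
    arrange(.data$stay_id, .data$feature_id, .data$time_hours) %>%
    select("stay_id", "feature_id", "time_hours", "value", "value_num")
}

compute_anchors <- function(events, lookback = 6) {
  events %>%
    filter(.data$time_hours >= -lookback) %>%
    group_by(.data$stay_id) %>%
    summarise(anchor = min(.data$time_hours),
              span = max(.data$time_hours) - min(.data$time_hours),
              .groups = "drop")
}

#' Filter stays by event coverage
#'
#' For each stay the anchor is the earliest event time within `lookback`
#' hours prior to ICU admission; stays are kept when their event span from
#' the anchor covers at least `min_cov` and at most `max_cov` hours
#' (defaults: 24 h to 10 days). Stays with no events inside the window are
#' excluded with a warning. The returned stay records gain an `anchor`
#' column used by [build_matrix()].
#'
#' @param events Cleaned event tibble.
#' @param stays Stay records.
#' @param min_cov,max_cov Coverage bounds in hours.
#' @param lookback Hours before admission from which records may anchor the
#'   observation window.
#' @return Filtered `stays` with an `anchor` column, order preserved.
#' @export
filter_stays <- function(events, stays, min_cov = 24, max_cov = 240,
                         lookback = 6) {
  anch <- compute_anchors(events, lookback)
  missing_ev <- setdiff(stays$stay_id, anch$stay_id)
  if (length(missing_ev) > 0)
    warn(sprintf("excluded %d stay(s) with no events within %g h of admission",
                 length(missing_ev), lookback))
  stays %>%
    dplyr::inner_join(anch, by = "stay_id") %>%
    filter(.data$span >= min_cov, .data$span <= max_cov) %>%
    select(-"span")
}

#' Build the hourly feature array
#'
#' Bins each stay's events into half-open hourly windows
#' `[anchor + h, anchor + h + 1)` for `h = 0, ..., t_hours - 1`, averaging
#' multiple values per bin; events at or beyond `anchor + t_hours` are
#' dropped. Static (demographic, admission, comorbidity) features are
#' broadcast across all time steps. Categorical features are label-encoded
#' to integers over their sorted observed levels; the encoding dictionaries
#' travel with the result. Empty bins are `NA` until [impute()].
#'
#' @param events Cleaned event tibble.
#' @param stays Stay records, ideally from [filter_stays()] (an `anchor`
#'   column is used when present, otherwise anchors are recomputed).
#' @param spec Feature specification.
#' @param t_hours Number of hourly steps.
#' @param lookback Anchoring window in hours (used only when anchors are
#'   recomputed).
#' @return An object of class `feature_matrix` wrapping the
#'   `(N, t_hours, F)` array plus stay ids, spec, anchors and encodings.
#' @export
build_matrix <- function(events, stays, spec, t_hours = 24, lookback = 6) {
  if (!"anchor" %in% names(stays)) {
    stays <- stays %>%
      dplyr::inner_join(compute_anchors(events, lookback) %>%
                          select("stay_id", "anchor"), by = "stay_id")
  }
  stay_ids <- stays$stay_id
  fids <- spec$feature_id
  ev <- events %>%
    semi_join(stays, by = "stay_id") %>%
    left_join(select(spec, "feature_id", "block", "kind"), by = "feature_id")

  # Label-encode categorical values over sorted observed levels.
  encodings <- list()
  cat_ids <- spec$feature_id[spec$kind == "categorical"]
  if (length(cat_ids) > 0) {
    for (fid in intersect(cat_ids, unique(ev$feature_id))) {
      rows <- ev$feature_id == fid
      levs <- sort(unique(ev$value[rows]))
      encodings[[fid]] <- levs
      ev$value_num[rows] <- match(ev$value[rows], levs)
    }
  }

  arr <- array(NA_real_,
               dim = c(length(stay_ids), t_hours, length(fids)),
               dimnames = list(stay_ids,
                               sprintf("h%02d", seq_len(t_hours) - 1), fids))
  anchor_of <- setNames(stays$anchor, stays$stay_id)
  ev$hour <- floor(ev$time_hours - anchor_of[ev$stay_id])

  tmp <- ev %>%
    filter(.data$block == "temporal",
           .data$hour >= 0, .data$hour < t_hours)
  if (nrow(tmp) > 0) {
    # Hourly-bin averaging via linear array indices (fast path for millions
    # of rows): rowsum of values / rowsum of counts per cell.
    li <- match(tmp$stay_id, stay_ids) +
      tmp$hour * length(stay_ids) +
      (match(tmp$feature_id, fids) - 1) * length(stay_ids) * t_hours
    sums <- rowsum(tmp$value_num, li)
    cnts <- rowsum(rep(1, nrow(tmp)), li)
    arr[as.numeric(rownames(sums))] <- sums[, 1] / cnts[, 1]
  }

  stat <- ev %>%
    filter(.data$block != "temporal") %>%
    group_by(.data$stay_id, .data$feature_id) %>%
    arrange(.data$time_hours, .by_group = TRUE) %>%
    summarise(value_num = first(.data$value_num), .groups = "drop")
  if (nrow(stat) > 0) {
    si <- match(stat$stay_id, stay_ids)
    fi <- match(stat$feature_id, fids)
    for (h in seq_len(t_hours)) {
      arr[cbind(si, h, fi)] <- stat$value_num
    }
  }

  structure(list(values = arr, stay_ids = stay_ids, spec = spec,
                 anchors = anchor_of, t_hours = t_hours,
                 encodings = encodings),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<feature_matrix> %d stays x %d hours x %d features (%.1f%% missing)\n",
              d[1], d[2], d[3], 100 * mean(is.na(x$values))))
  invisible(x)
}

#' Per-feature means over training stays
#'
#' Computes the training-set mean of every feature (over stays and time,
#' ignoring missing cells), the fill value used by [impute()] for features
#' entirely missing within a stay. Restricting to the training split keeps
#' test information out of the imputation.
#'
#' @param matrix A `feature_matrix`.
#' @param train_ids Stay ids (character) or row indices of the training
#'   split.
#' @return Named numeric vector, one mean per feature.
#' @export
compute_train_means <- function(matrix, train_ids) {
  idx <- if (is.character(train_ids)) match(train_ids, matrix$stay_ids)
         else as.integer(train_ids)
  sub <- matrix$values[idx, , , drop = FALSE]
  apply(sub, 3, mean, na.rm = TRUE)
}

#' Impute missing cells of a feature array
#'
#' Per stay and feature: forward-fill along time, then backward-fill;
#' features entirely missing for a stay are filled with the training-set
#' mean. The result contains no missing entries. Imputation is idempotent.
#'
#' @param matrix A `feature_matrix`.
#' @param train_means Named per-feature means from [compute_train_means()];
#'   must cover every feature in the spec.
#' @return The imputed `feature_matrix`.
#' @export
impute <- function(matrix, train_means) {
  fids <- matrix$spec$feature_id
  missing_feat <- setdiff(fids, names(train_means))
  if (length(missing_feat) > 0)
    spec_error(paste("train_means missing feature(s):",
                     paste(missing_feat, collapse = ", ")))
  arr <- matrix$values
  d <- dim(arr) # (N, T, F)
  m <- matrix(aperm(arr, c(2, 1, 3)), nrow = d[2]) # T x (N*F), stay fastest
  if (d[2] > 1) {
    for (t in 2:d[2]) { # forward fill
      na <- is.na(m[t, ])
      m[t, na] <- m[t - 1, na]
    }
    for (t in (d[2] - 1):1) { # backward fill
      na <- is.na(m[t, ])
      m[t, na] <- m[t + 1, na]
    }
  }
  all_na <- is.na(m[d[2], ]) # column entirely missing iff still NA after fills
  if (any(all_na)) {
    feat_of_col <- rep(seq_len(d[3]), each = d[1])
    fill <- train_means[fids][feat_of_col]
    m[, all_na] <- rep(fill[all_na], each = d[2])
  }
  out <- aperm(array(m, dim = c(d[2], d[1], d[3])), c(2, 1, 3))
  dimnames(out) <- dimnames(arr)
  matrix$values <- out
  matrix
}

#' Summarise the hourly array into tabular form
#'
#' Each temporal feature contributes its min, max and mean over the time
#' axis (plus a sum for sum-flagged features); static features pass through
#' once. Column order is deterministic: spec order, then summary kind
#' (min, max, mean, sum). Requires an imputed array.
#'
#' @param matrix An imputed `feature_matrix`.
#' @param spec Feature specification (defaults to the one attached to
#'   `matrix`).
#' @return A tibble (`stay_id` + one column per summary) of class
#'   `tabular_summary`, with a `col_info` attribute mapping columns to
#'   source features and summary kinds.
#' @export
summarize_tabular <- function(matrix, spec = matrix$spec) {
  arr <- matrix$values
  n <- dim(arr)[1]
  cols <- list()
  info <- list()
  for (j in seq_len(nrow(spec))) {
    fid <- spec$feature_id[j]
    x <- arr[, , j, drop = FALSE]
    dim(x) <- dim(arr)[1:2]
    if (spec$block[j] == "temporal") {
      kinds <- c("min", "max", "mean", if (spec$has_sum[j]) "sum")
      for (k in kinds) {
        cn <- paste0(fid, "_", k)
        cols[[cn]] <- switch(k,
                             min = apply(x, 1, min),
                             max = apply(x, 1, max),
                             mean = rowMeans(x),
                             sum = rowSums(x))
        info[[cn]] <- tibble(column = cn, feature_id = fid, summary = k)
      }
    } else {
      cols[[fid]] <- x[, 1]
      info[[fid]] <- tibble(column = fid, feature_id = fid,
                            summary = NA_character_)
    }
  }
  out <- tibble(stay_id = matrix$stay_ids, !!!cols)
  attr(out, "col_info") <- bind_rows(info)
  class(out) <- c("tabular_summary", class(out))
  out
}

#' Flatten the hourly array for flat-input models
#'
#' Returns the `(N, T x F)` matrix fed to models and interpreters that work
#' on flattened inputs; column `(f - 1) * T + t` holds feature `f` at hour
#' `t`, i.e. time runs fastest within each feature.
#'
#' @param matrix An imputed `feature_matrix`.
#' @return Numeric matrix with attributes `col_info` (column, feature_id,
#'   hour), `input_shape` (`c(T, F)`) and `stay_ids`.
#' @export
flatten_sequences <- function(matrix) {
  arr <- matrix$values
  d <- dim(arr)
  out <- matrix(aperm(arr, c(1, 2, 3)), nrow = d[1]) # cols: t fastest, then f
  fids <- matrix$spec$feature_id
  colnames(out) <- paste0(rep(fids, each = d[2]), "@h",
                          rep(seq_len(d[2]) - 1, d[3]))
  attr(out, "col_info") <- tibble(column = colnames(out),
                                  feature_id = rep(fids, each = d[2]),
                                  hour = rep(seq_len(d[2]) - 1, d[3]))
  attr(out, "input_shape") <- c(d[2], d[3])
  attr(out, "stay_ids") <- matrix$stay_ids
  out
}

#' Strip metadata columns from a tabular summary
#'
#' @param x A `tabular_summary` tibble.
#' @return Numeric matrix of the summary columns, rownames = stay ids.
#' @export
tabular_matrix <- function(x) {
  m <- as.matrix(as.data.frame(x[setdiff(names(x), "stay_id")]))
  rownames(m) <- x$stay_id
  ci <- attr(x, "col_info")
  attr(m, "col_info") <- ci
  m
}
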