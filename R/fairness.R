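#' Resolve protected-attribute group labels
#'
#' Maps each stay to a protected-group level. Stays with unclear labels
#' ('None', 'Unknown', 'Unable to obtain', case-insensitive, plus anything
#' in `extra_unclear`) are excluded from all group statistics. Age is binned
#' into the printed quartile-style bins `<55 / 55-67 / 67-78 / >=78` years
#' (left-closed) by default; pass `age_breaks = "quartiles"` together with
#' reference ages to recompute cut points from a training split instead.
#'
#' @param stays Stay records containing the attribute column.
#' @param attribute One of `"ethnicity"`, `"gender"`, `"marital_status"`,
#'   `"age"`, `"insurance"` (any categorical column works).
#' @param age_breaks Numeric cut points for age (left-closed bins), or
#'   `"quartiles"` to derive them from `reference_ages`.
#' @param reference_ages Ages used when `age_breaks = "quartiles"`
#'   (typically the training split).
#' @param mapping Optional named character vector collapsing raw labels to
#'   levels; raw labels with no mapping are reported and treated as unclear.
#' @param extra_unclear Additional labels to treat as unclear.
#' @return Tibble with columns `stay_id`, `group`; unclear stays are
#'   dropped (with a warning if nothing remains).
#' @export
resolve_groups <- function(stays, attribute,
                           age_breaks = c(-Inf, 55, 67, 78, Inf),
                           reference_ages = NULL,
                           mapping = NULL,
                           extra_unclear = character(0)) {
  unclear <- tolower(c("None", "Unknown", "Unable to obtain", extra_unclear))
  if (attribute == "age") {
    if (identical(age_breaks, "quartiles")) {
      ages <- if (is.null(reference_ages)) stays$age else reference_ages
      qs <- quantile(ages, c(0.25, 0.5, 0.75), names = FALSE)
      age_breaks <- c(-Inf, qs, Inf)
      labels <- c(sprintf("<%.0f YRS", qs[1]),
                  sprintf("%.0f-%.0f YRS", qs[1], qs[2]),
                  sprintf("%.0f-%.0f YRS", qs[2], qs[3]),
                  sprintf(">=%.0f YRS", qs[3]))
    } else if (identical(unname(age_breaks), c(-Inf, 55, 67, 78, Inf))) {
      labels <- c("<55 YRS", "55-67 YRS", "67-78 YRS", ">=78 YRS")
    } else {
      labels <- NULL
    }
    grp <- as.character(cut(stays$age, breaks = age_breaks, labels = labels,
                            right = FALSE))
  } else {
    raw <- as.character(stays[[attribute]])
    if (!is.null(mapping)) {
      mapped <- unname(mapping[raw])
      unknown <- unique(raw[is.na(mapped) & !tolower(raw) %in% unclear])
      if (length(unknown) > 0)
        warn(sprintf("unmapped %s label(s) treated as unclear: %s", attribute,
                     paste(unknown, collapse = ", ")))
      raw <- ifelse(is.na(mapped), NA_character_, mapped)
    }
    grp <- ifelse(!is.na(raw) & tolower(raw) %in% unclear, NA_character_, raw)
  }
  out <- tibble(stay_id = stays$stay_id, group = grp) %>%
    filter(!is.na(.data$group))
  if (nrow(out) == 0)
    warn(sprintf("all stays have unclear '%s' labels; empty group table",
                 attribute))
  out
}

#' Treatment adoption and duration by group
#'
#' Per ventilation category and protected group: the adoption rate
#' (fraction of the group's stays with at least one span; stays with no
#' recorded span count as no adoption) and the mean summed span duration.
#' Because the convention for non-adopters is ambiguous, both the
#' per-patient mean (non-adopters contribute 0 hours) and the per-adopter
#' mean (non-adopters excluded) are reported.
#'
#' @param treatments Tibble with columns `stay_id`, `category`,
#'   `start_hours`, `end_hours` (`end > start`).
#' @param stays Stay records (denominator population).
#' @param groups Group table from [resolve_groups()].
#' @return Tibble with columns `category`, `group`, `n`, `n_adopters`,
#'   `adoption_rate`, `mean_duration_all`, `mean_duration_adopters`.
#' @export
treatment_summary <- function(treatments, stays, groups) {
  stopifnot(all(treatments$end_hours > treatments$start_hours))
  pop <- groups %>% semi_join(stays, by = "stay_id")
  per_stay <- treatments %>%
    mutate(span = .data$end_hours - .data$start_hours) %>%
    group_by(.data$stay_id, .data$category) %>%
    summarise(duration = sum(.data$span), .groups = "drop")
  cats <- sort(unique(treatments$category))
  grid <- tidyr::expand_grid(category = cats, pop)
  grid %>%
    left_join(per_stay, by = c("stay_id", "category")) %>%
    mutate(adopted = !is.na(.data$duration),
           duration = tidyr::replace_na(.data$duration, 0)) %>%
    group_by(.data$category, .data$group) %>%
    summarise(n = n(),
              n_adopters = sum(.data$adopted),
              adoption_rate = mean(.data$adopted),
              mean_duration_all = mean(.data$duration),
              mean_duration_adopters = ifelse(sum(.data$adopted) > 0,
                                              sum(.data$duration) /
                                                sum(.data$adopted), NA_real_),
              .groups = "drop")
}

#' Per-group classification AUC
#'
#' Stratifies the predictions by protected group and computes the binary
#' metrics within each group. Groups with a single class are flagged
#' undefined (with a warning) and must be excluded from fairness summaries.
#'
#' @param scores Positive-class probabilities.
#' @param labels 0/1 labels.
#' @param group Group level per sample (aligned with `scores`).
#' @return Tibble with columns `group`, `n`, `mortality_rate`, `auroc`,
#'   `auprc`, `defined`.
#' @export
group_auc <- function(scores, labels, group) {
  labels <- as.integer(labels)
  levels <- sort(unique(as.character(group)))
  rows <- purrr::map(levels, function(g) {
    idx <- which(group == g)
    y <- labels[idx]
    if (length(unique(y)) < 2) {
      tibble(group = g, n = length(idx), mortality_rate = mean(y),
             auroc = NA_real_, auprc = NA_real_, defined = FALSE)
    } else {
      met <- binary_metrics(scores[idx], y)
      tibble(group = g, n = length(idx), mortality_rate = mean(y),
             auroc = met$auroc, auprc = met$auprc, defined = TRUE)
    }
  })
  out <- bind_rows(rows)
  if (any(!out$defined))
    warn(sprintf("group(s) with a single class excluded from summaries: %s",
                 paste(out$group[!out$defined], collapse = ", ")))
  out
}

#' Fairness summary over group AUCs
#'
#' The three AUC-based group-fairness summaries: the minimum AUC over all
#' (defined) protected groups, their unweighted macro-average, and the AUC
#' of the smallest defined group. Undefined (single-class) groups are
#' excluded rather than imputed.
#'
#' @param group_aucs Tibble from [group_auc()].
#' @return Tibble with columns `auc_min`, `auc_macro`, `auc_minority`,
#'   `n_groups`.
#' @export
fairness_summary <- function(group_aucs) {
  ok <- group_aucs %>% filter(.data$defined)
  if (nrow(ok) == 0)
    return(tibble(auc_min = NA_real_, auc_macro = NA_real_,
                  auc_minority = NA_real_, n_groups = 0L))
  tibble(auc_min = min(ok$auroc),
         auc_macro = mean(ok$auroc),
         auc_minority = ok$auroc[which.min(ok$n)],
         n_groups = nrow(ok))
}

#' Correlation between group mortality rates and group AUCs
#'
#' Pearson correlation over (mortality rate, AUC) pairs pooled across
#' attributes and models as configured by the caller. Degenerate inputs
#' (constant rates or AUCs) give an undefined correlation, reported as NA.
#'
#' @param rates Per-group mortality rates.
#' @param aucs Per-group AUCs, aligned with `rates`.
#' @return Tibble with columns `r`, `p_value`, `n_pairs`.
#' @export
mortality_auc_correlation <- function(rates, aucs) {
  keep <- complete.cases(rates, aucs)
  rates <- rates[keep]; aucs <- aucs[keep]
  if (length(rates) < 3 || sd(rates) == 0 || sd(aucs) == 0) {
    warn("correlation undefined (fewer than 3 pairs or a constant margin)")
    return(tibble(r = NA_real_, p_value = NA_real_,
                  n_pairs = length(rates)))
  }
  ct <- cor.test(rates, aucs, method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value,
         n_pairs = length(rates))
}

#' Full fairness audit across protected attributes
#'
#' Convenience wrapper: per attribute, resolves groups, stratifies the test
#' predictions, and collects group AUCs plus the min/macro/minority
#' summaries; also pools (mortality rate, AUC) pairs for the
#' rate-AUC correlation.
#'
#' @param scores,labels Test-set predictions and labels.
#' @param stays Stay records aligned *by `stay_id`* with the predictions.
#' @param stay_ids Stay ids aligned with `scores`.
#' @param attributes Protected attributes to audit.
#' @return A list of class `group_report` with elements `by_group`,
#'   `summaries`, `correlation`.
#' @export
group_report <- function(scores, labels, stays, stay_ids,
                         attributes = c("ethnicity", "gender",
                                        "marital_status", "age",
                                        "insurance")) {
  by_group <- purrr::map(attributes, function(a) {
    grp <- resolve_groups(stays, a)
    m <- match(stay_ids, grp$stay_id)
    keep <- !is.na(m)
    ga <- group_auc(scores[keep], labels[keep], grp$group[m[keep]])
    mutate(ga, attribute = a, .before = 1)
  }) %>% bind_rows()
  summaries <- by_group %>%
    group_by(.data$attribute) %>%
    dplyr::group_modify(~ fairness_summary(.x)) %>%
    ungroup()
  ok <- by_group %>% filter(.data$defined)
  correlation <- suppressWarnings(
    mortality_auc_correlation(ok$mortality_rate, ok$auroc))
  structure(list(by_group = by_group, summaries = summaries,
                 correlation = correlation), class = "group_report")
}

#' @export
print.group_report <- function(x, ...) {
  cat("<group_report>\n")
  print(x$summaries)
  invisible(x)
}

#' Plot per-group AUCs of a fairness audit
#'
#' @param object A `group_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot group_report
#' @export
autoplot.group_report <- function(object, ...) {
  ggplot2::ggplot(object$by_group,
                  ggplot2::aes(x = .data$group, y = .data$auroc)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~ .data$attribute, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "group AUROC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
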