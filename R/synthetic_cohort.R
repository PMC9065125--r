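#' Simulation configuration for a synthetic ICU cohort
#'
#' Builds and validates the configuration driving [generate_cohort()]. The
#' defaults emulate the shape of a preprocessed intensive-care mortality
#' cohort: `t_hours = 24` hourly steps, 164 features split into
#' 122 temporal / 5 demographic / 4 admission / 33 comorbidity blocks, and a
#' low (~7%) mortality prevalence. Mortality labels are drawn from a logistic
#' model whose logit combines planted feature effects (the recoverable ground
#' truth) with additive demographic offsets, so downstream attribution,
#' remove-and-retrain and fairness analyses can be validated against a known
#' answer.
#'
#' @param n_stays Number of ICU stays to simulate.
#' @param t_hours Number of hourly time steps retained per stay.
#' @param feature_counts Named integer vector with elements `temporal`,
#'   `demographic`, `admission`, `comorbidity`. Blocks may be zero except
#'   that `demographic` must be 0 or 5 (age, ethnicity, gender,
#'   marital_status, insurance).
#' @param base_mortality Target marginal mortality probability in (0, 1). The
#'   logistic intercept is calibrated so the Monte-Carlo average of the
#'   logistic over the simulated covariates equals this value.
#' @param planted_features Tibble with columns `feature_id`, `coef`,
#'   `summary` (`"mean"`, `"max"` or `"min"`); each row adds
#'   `coef * summary(feature)` to the mortality logit. Temporal features are
#'   summarised over the `t_hours` window; static features use their value.
#' @param demographic_effects Named list mapping a demographic attribute to a
#'   named numeric vector of additive logit offsets per group level. Age uses
#'   the default quartile-style bins (see [resolve_groups()]).
#' @param group_levels Named list mapping each categorical demographic
#'   attribute to `list(levels =, probs =)`; probabilities must sum to 1.
#' @param treatment_config Tibble with columns `category`, `attribute`,
#'   `level`, `adoption`, `mean_duration`: per ventilation category, the
#'   adoption probability and mean summed span duration (hours), optionally
#'   varying by a demographic level (`level = NA` rows give the default).
#' @param missing_rate Probability in [0, 1) that each clinical event is
#'   independently deleted (exercises imputation downstream).
#' @param temporal_model Tibble with columns `feature_id`, `mean`, `sd`,
#'   `rho` describing the stationary lag-1 autoregressive process per
#'   temporal feature; missing features default to mean 0, sd 1, rho 0.5.
#' @param comorbidity_prevalence Bernoulli prevalence of each binary
#'   comorbidity flag.
#' @param admission_prevalence Bernoulli prevalence of each binary admission
#'   flag.
#' @param event_jitter If `TRUE`, temporal event timestamps receive a uniform
#'   within-hour offset (exercising hourly binning); if `FALSE` (default)
#'   events sit exactly on hour marks so preprocessing round-trips the latent
#'   array.
#' @param seed Integer seed; identical configurations (including seed) yield
#'   bit-identical cohorts.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_stays = 500L,
                       t_hours = 24L,
                       feature_counts = c(temporal = 122L, demographic = 5L,
                                          admission = 4L, comorbidity = 33L),
                       base_mortality = 0.07,
                       planted_features = default_planted_features(),
                       demographic_effects = default_demographic_effects(),
                       group_levels = default_group_levels(),
                       treatment_config = default_treatment_config(),
                       missing_rate = 0,
                       temporal_model = NULL,
                       comorbidity_prevalence = 0.1,
                       admission_prevalence = 0.3,
                       event_jitter = FALSE,
                       seed = 1L) {
  cfg <- list(
    n_stays = as.integer(n_stays), t_hours = as.integer(t_hours),
    feature_counts = feature_counts, base_mortality = base_mortality,
    planted_features = planted_features,
    demographic_effects = demographic_effects,
    group_levels = group_levels, treatment_config = treatment_config,
    missing_rate = missing_rate, temporal_model = temporal_model,
    comorbidity_prevalence = comorbidity_prevalence,
    admission_prevalence = admission_prevalence,
    event_jitter = isTRUE(event_jitter), seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

config_error <- function(field, msg) {
  abort(sprintf("invalid `%s`: %s", field, msg), class = "icufair_config_error")
}

validate_sim_config <- function(cfg) {
  if (is.na(cfg$n_stays) || cfg$n_stays < 1)
    config_error("n_stays", "must be a positive count")
  if (is.na(cfg$t_hours) || cfg$t_hours < 1)
    config_error("t_hours", "must be a positive count")
  fc <- cfg$feature_counts
  need <- c("temporal", "demographic", "admission", "comorbidity")
  if (!all(need %in% names(fc)))
    config_error("feature_counts",
                 "must name temporal, demographic, admission, comorbidity")
  if (any(fc < 0)) config_error("feature_counts", "counts must be >= 0")
  if (!fc[["demographic"]] %in% c(0L, 5L))
    config_error("feature_counts",
                 "demographic block must be 0 or 5 (age, ethnicity, gender, marital_status, insurance)")
  if (!is.numeric(cfg$base_mortality) || cfg$base_mortality <= 0 ||
      cfg$base_mortality >= 1)
    config_error("base_mortality", "must be a probability in (0, 1)")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    config_error("missing_rate", "must be a probability in [0, 1)")
  pf <- cfg$planted_features
  if (!is.null(pf) && nrow(pf) > 0) {
    if (!all(c("feature_id", "coef", "summary") %in% names(pf)))
      config_error("planted_features",
                   "needs columns feature_id, coef, summary")
    if (!all(pf$summary %in% c("mean", "max", "min")))
      config_error("planted_features", "summary must be mean, max or min")
    known <- feature_ids_for(cfg$feature_counts)
    bad <- setdiff(pf$feature_id, known)
    if (length(bad) > 0)
      config_error("planted_features",
                   paste("unknown feature id(s):", paste(bad, collapse = ", ")))
  }
  for (attr_name in names(cfg$group_levels)) {
    gl <- cfg$group_levels[[attr_name]]
    if (abs(sum(gl$probs) - 1) > 1e-9)
      config_error("group_levels",
                   sprintf("probabilities for %s must sum to 1", attr_name))
    if (any(gl$probs < 0 | gl$probs > 1))
      config_error("group_levels",
                   sprintf("probabilities for %s must lie in [0, 1]", attr_name))
  }
  tc <- cfg$treatment_config
  if (!is.null(tc) && nrow(tc) > 0) {
    if (any(tc$adoption < 0 | tc$adoption > 1))
      config_error("treatment_config", "adoption probabilities must lie in [0, 1]")
    if (any(tc$mean_duration <= 0))
      config_error("treatment_config", "mean_duration must be > 0 hours")
  }
  tm <- cfg$temporal_model
  if (!is.null(tm)) {
    if (any(tm$sd < 0)) config_error("temporal_model", "sd must be >= 0")
    if (any(abs(tm$rho) >= 1))
      config_error("temporal_model", "rho must lie in (-1, 1)")
  }
  cfg
}

#' Default planted feature effects
#'
#' Five temporal features with logit coefficients of magnitude 1 to 2 on
#' mean/max/min 24-hour summaries; the recoverable signal every downstream
#' evaluation is validated against.
#' @return Tibble with columns `feature_id`, `coef`, `summary`.
#' @export
default_planted_features <- function() {
  tibble(
    feature_id = sprintf("temp_%03d", 1:5),
    coef = c(2, -2, 1.5, -1.5, 1),
    summary = c("mean", "mean", "max", "min", "mean")
  )
}

#' @rdname sim_config
#' @export
default_group_levels <- function() {
  list(
    ethnicity = list(
      levels = c("ASIAN", "BLACK/AFRICAN AMERICAN", "HISPANIC/LATINO",
                 "OTHER", "WHITE", "UNKNOWN"),
      probs = c(0.04, 0.12, 0.06, 0.08, 0.68, 0.02)
    ),
    gender = list(levels = c("FEMALE", "MALE"), probs = c(0.48, 0.52)),
    marital_status = list(
      levels = c("MARRIED", "SINGLE", "DIVORCED/WIDOWED"),
      probs = c(0.45, 0.35, 0.20)
    ),
    insurance = list(levels = c("MEDICAID/MEDICARE", "PRIVATE"),
                     probs = c(0.6, 0.4))
  )
}

#' @rdname sim_config
#' @export
default_demographic_effects <- function() {
  list(
    age = c("<55 YRS" = -0.5, ">=78 YRS" = 0.5),
    ethnicity = c("BLACK/AFRICAN AMERICAN" = 0.3)
  )
}

#' Default ventilation treatment configuration
#'
#' Five ventilation categories; invasive ventilation is planted with a 0.3
#' adoption-probability gap and an 18-hour mean-duration gap between the
#' WHITE and BLACK/AFRICAN AMERICAN ethnicity levels so the fairness module's
#' disparity estimates can be checked against ground truth.
#' @return Tibble with columns `category`, `attribute`, `level`, `adoption`,
#'   `mean_duration`.
#' @export
default_treatment_config <- function() {
  tibble(
    category = c("InvasiveVent", "InvasiveVent", "InvasiveVent",
                 "NonInvasiveVent", "HighFlow", "Oxygen", "Trach"),
    attribute = c("ethnicity", "ethnicity", NA, NA, NA, NA, NA),
    level = c("WHITE", "BLACK/AFRICAN AMERICAN", NA, NA, NA, NA, NA),
    adoption = c(0.5, 0.2, 0.35, 0.25, 0.15, 0.6, 0.05),
    mean_duration = c(48, 30, 40, 20, 12, 24, 72)
  )
}

block_prefix <- c(temporal = "temp", admission = "adm", comorbidity = "com")

feature_ids_for <- function(feature_counts) {
  ids <- character(0)
  nt <- feature_counts[["temporal"]]
  if (nt > 0) ids <- c(ids, sprintf("temp_%03d", seq_len(nt)))
  if (feature_counts[["demographic"]] == 5L)
    ids <- c(ids, c("age", "ethnicity", "gender", "marital_status", "insurance"))
  na <- feature_counts[["admission"]]
  if (na > 0) ids <- c(ids, sprintf("adm_%03d", seq_len(na)))
  nc <- feature_counts[["comorbidity"]]
  if (nc > 0) ids <- c(ids, sprintf("com_%03d", seq_len(nc)))
  ids
}

#' Generate a synthetic ICU cohort with known ground truth
#'
#' Simulates stays, hourly clinical measurements, demographics, ventilation
#' treatment spans and binary in-hospital mortality labels. Temporal features
#' follow a stationary Gaussian lag-1 autoregressive process; mortality is
#' drawn from a logistic model over the configured planted feature summaries
#' plus demographic offsets, with the intercept calibrated to the target
#' prevalence. Events are emitted for hours 0..`t_hours` (the extra hour
#' exercises truncation downstream) plus one time-0 event per static feature.
#' The function is a pure function of its configuration: identical
#' configurations give bit-identical cohorts.
#'
#' @param config A [sim_config()].
#' @return An object of class `synthetic_cohort`: a list with elements
#'   `events` (long tibble: `stay_id`, `feature_id`, `time_hours`, `value`
#'   as character tokens), `stays`, `labels`, `treatments`, `ground_truth`,
#'   `latent` (the pre-missingness `(N, T, F_temporal)` hourly array) and
#'   `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_stays
  t_hours <- cfg$t_hours
  fc <- cfg$feature_counts
  stay_ids <- sprintf("stay_%05d", seq_len(n))

  stays <- tibble(
    stay_id = stay_ids,
    patient_id = sprintf("pat_%05d", seq_len(n)),
    age = pmin(pmax(rnorm(n, 65, 17), 15), 95),
    stay_order = 1L,
    icu_duration = runif(n, t_hours, 240),
    admission_time = 0
  )
  for (attr_name in names(cfg$group_levels)) {
    gl <- cfg$group_levels[[attr_name]]
    stays[[attr_name]] <- sample(gl$levels, n, replace = TRUE, prob = gl$probs)
  }

  # Temporal latent process: stationary AR(1) per feature, T+1 hourly steps.
  nt <- fc[["temporal"]]
  t1 <- t_hours + 1L
  temp_ids <- if (nt > 0) sprintf("temp_%03d", seq_len(nt)) else character(0)
  tm <- tibble(feature_id = temp_ids, mean = 0, sd = 1, rho = 0.5)
  if (!is.null(cfg$temporal_model)) {
    usr <- cfg$temporal_model
    idx <- match(usr$feature_id, tm$feature_id)
    tm$mean[idx] <- usr$mean; tm$sd[idx] <- usr$sd; tm$rho[idx] <- usr$rho
  }
  latent <- array(NA_real_, dim = c(n, t1, nt),
                  dimnames = list(stay_ids, NULL, temp_ids))
  if (nt > 0) {
    for (f in seq_len(nt)) {
      mu <- tm$mean[f]; sdev <- tm$sd[f]; rho <- tm$rho[f]
      z <- matrix(0, n, t1)
      z[, 1] <- rnorm(n, 0, sdev)
      innov_sd <- sdev * sqrt(1 - rho^2)
      for (t in 2:t1) z[, t] <- rho * z[, t - 1] + rnorm(n, 0, innov_sd)
      latent[, , f] <- mu + z
    }
  }

  # Static feature values (admission / comorbidity binary flags).
  adm_ids <- if (fc[["admission"]] > 0) sprintf("adm_%03d", seq_len(fc[["admission"]])) else character(0)
  com_ids <- if (fc[["comorbidity"]] > 0) sprintf("com_%03d", seq_len(fc[["comorbidity"]])) else character(0)
  adm_vals <- matrix(rbinom(n * length(adm_ids), 1, cfg$admission_prevalence),
                     n, length(adm_ids), dimnames = list(stay_ids, adm_ids))
  com_vals <- matrix(rbinom(n * length(com_ids), 1, cfg$comorbidity_prevalence),
                     n, length(com_ids), dimnames = list(stay_ids, com_ids))

  # Mortality logit: planted feature summaries + demographic offsets.
  eta <- rep(0, n)
  pf <- cfg$planted_features
  if (!is.null(pf) && nrow(pf) > 0) {
    for (j in seq_len(nrow(pf))) {
      fid <- pf$feature_id[j]
      val <- if (fid %in% temp_ids) {
        x <- latent[, seq_len(t_hours), match(fid, temp_ids), drop = TRUE]
        switch(pf$summary[j],
               mean = rowMeans(x),
               max = apply(x, 1, max),
               min = apply(x, 1, min))
      } else if (fid %in% adm_ids) {
        adm_vals[, fid]
      } else if (fid %in% com_ids) {
        com_vals[, fid]
      } else if (fid == "age") {
        as.numeric(scale(stays$age))
      } else {
        abort(sprintf("cannot plant a coefficient on categorical feature '%s'", fid),
              class = "icufair_config_error")
      }
      eta <- eta + pf$coef[j] * val
    }
  }
  for (attr_name in names(cfg$demographic_effects)) {
    offs <- cfg$demographic_effects[[attr_name]]
    lev <- if (attr_name == "age") {
      as.character(bin_age(stays$age))
    } else {
      stays[[attr_name]]
    }
    hit <- match(lev, names(offs))
    eta <- eta + ifelse(is.na(hit), 0, offs[hit])
  }
  intercept <- uniroot(function(b) mean(plogis(b + eta)) - cfg$base_mortality,
                       interval = c(-30, 30), tol = 1e-10)$root
  labels <- tibble(stay_id = stay_ids,
                   label = rbinom(n, 1, plogis(intercept + eta)))

  # Long event table. Temporal events cover hours 0..t_hours (one beyond the
  # modelling window so coverage-based filtering keeps the stay); static
  # features are emitted once at time 0.
  events <- NULL
  if (nt > 0) {
    times <- rep(rep(0:t_hours, each = n), nt)
    if (cfg$event_jitter) times <- times + runif(length(times), 0, 0.999)
    events <- tibble(
      stay_id = rep(stay_ids, t1 * nt),
      feature_id = rep(temp_ids, each = n * t1),
      time_hours = as.numeric(times),
      value = sprintf("%.17g", as.vector(latent))
    )
  }
  static_events <- tibble(
    stay_id = rep(stay_ids, 5 + length(adm_ids) + length(com_ids)),
    feature_id = rep(c("age", "ethnicity", "gender", "marital_status",
                       "insurance", adm_ids, com_ids), each = n),
    time_hours = 0,
    value = c(sprintf("%.17g", stays$age), stays$ethnicity, stays$gender,
              stays$marital_status, stays$insurance,
              sprintf("%.17g", as.vector(adm_vals)),
              sprintf("%.17g", as.vector(com_vals)))
  )
  if (fc[["demographic"]] == 0L)
    static_events <- static_events %>%
      filter(!.data$feature_id %in% c("age", "ethnicity", "gender",
                                      "marital_status", "insurance"))
  events <- bind_rows(events, static_events)

  treatments <- simulate_treatments(cfg$treatment_config, stays)

  if (cfg$missing_rate > 0) {
    drop_seed <- sample.int(.Machine$integer.max, 1)
    events <- inject_missingness(events, cfg$missing_rate, drop_seed)
  }

  truth <- list(
    planted_features = pf,
    logit_intercept = intercept,
    oracle_ranking = oracle_ranking(pf, feature_ids_for(fc))
  )
  class(truth) <- "ground_truth"

  out <- list(events = events, stays = stays, labels = labels,
              treatments = treatments, ground_truth = truth,
              latent = latent[, seq_len(t_hours), , drop = FALSE],
              config = cfg)
  class(out) <- "synthetic_cohort"
  out
}

simulate_treatments <- function(tc, stays) {
  if (is.null(tc) || nrow(tc) == 0)
    return(tibble(stay_id = character(0), category = character(0),
                  start_hours = numeric(0), end_hours = numeric(0)))
  out <- list()
  for (cat in unique(tc$category)) {
    rows <- tc[tc$category == cat, ]
    adopt_p <- rep(NA_real_, nrow(stays))
    mean_dur <- rep(NA_real_, nrow(stays))
    for (j in seq_len(nrow(rows))) {
      if (is.na(rows$level[j])) next
      hit <- stays[[rows$attribute[j]]] == rows$level[j]
      adopt_p[hit] <- rows$adoption[j]
      mean_dur[hit] <- rows$mean_duration[j]
    }
    dflt <- rows[is.na(rows$level), ]
    if (nrow(dflt) > 0) {
      adopt_p[is.na(adopt_p)] <- dflt$adoption[1]
      mean_dur[is.na(mean_dur)] <- dflt$mean_duration[1]
    }
    adopt_p[is.na(adopt_p)] <- 0
    mean_dur[is.na(mean_dur)] <- 1
    adopted <- runif(nrow(stays)) < adopt_p
    idx <- which(adopted)
    if (length(idx) == 0) next
    total <- pmax(rexp(length(idx), rate = 1 / mean_dur[idx]), 0.25)
    two <- runif(length(idx)) < 0.3
    frac <- ifelse(two, runif(length(idx), 0.2, 0.8), 1)
    len1 <- total * frac
    start1 <- runif(length(idx), 0, pmax(stays$icu_duration[idx] - total, 0.1))
    spans <- tibble(stay_id = stays$stay_id[idx], category = cat,
                    start_hours = start1, end_hours = start1 + len1)
    if (any(two)) {
      len2 <- total[two] * (1 - frac[two])
      start2 <- spans$end_hours[two] + runif(sum(two), 0.5, 4)
      spans <- bind_rows(spans,
                         tibble(stay_id = stays$stay_id[idx][two],
                                category = cat,
                                start_hours = start2,
                                end_hours = start2 + len2))
    }
    out[[cat]] <- spans
  }
  bind_rows(out) %>% arrange(.data$stay_id, .data$category, .data$start_hours)
}

oracle_ranking <- function(planted, all_ids) {
  if (is.null(planted) || nrow(planted) == 0) return(sort(all_ids))
  ord <- planted[order(-abs(planted$coef), planted$feature_id), ]
  c(ord$feature_id, sort(setdiff(all_ids, ord$feature_id)))
}

#' Delete clinical events completely at random
#'
#' Each event row is independently deleted with probability `rate`,
#' exercising forward/backward imputation downstream. Missingness is
#' completely at random by design (informative mechanisms are out of scope).
#'
#' @param events Event tibble (any columns).
#' @param rate Deletion probability in [0, 1).
#' @param seed Integer seed; identical seeds give identical deletions.
#' @return The retained rows of `events`.
#' @export
inject_missingness <- function(events, rate, seed) {
  if (!is.numeric(rate) || rate < 0 || rate >= 1)
    config_error("rate", "must be a probability in [0, 1)")
  if (rate == 0) return(events)
  keep <- withr::with_seed(seed, runif(nrow(events)) >= rate)
  events[keep, , drop = FALSE]
}

#' Top planted features by coefficient magnitude
#'
#' The oracle importance set for remove-and-retrain and recovery tests: the
#' `top_k` planted feature ids ordered by |coefficient| descending, ties
#' broken by feature id ascending.
#'
#' @param truth A `ground_truth` object from [generate_cohort()].
#' @param top_k Number of features to return; at most the planted count.
#' @return Character vector of feature ids.
#' @export
planted_importance <- function(truth, top_k) {
  stopifnot(inherits(truth, "ground_truth"))
  pf <- truth$planted_features
  n_planted <- if (is.null(pf)) 0L else nrow(pf)
  if (top_k > n_planted)
    abort(sprintf("top_k (%d) exceeds the planted feature count (%d)",
                  top_k, n_planted), class = "icufair_argument_error")
  ord <- pf[order(-abs(pf$coef), pf$feature_id), ]
  ord$feature_id[seq_len(top_k)]
}

#' Oracle importance scores over model input columns
#'
#' Maps the planted ground truth onto a flat importance vector aligned with
#' the columns a model sees: each planted feature's |coefficient| is placed
#' on its matching column(s) (the exact summary column for tabular input, or
#' every hourly cell of the feature for flattened sequence input); all other
#' columns score 0.
#'
#' @param truth A `ground_truth` object.
#' @param col_info Tibble with columns `column`, `feature_id` and (for
#'   tabular input) `summary`, as attached by [summarize_tabular()] or
#'   [flatten_sequences()].
#' @return Numeric importance vector named by column.
#' @export
oracle_importance <- function(truth, col_info) {
  stopifnot(inherits(truth, "ground_truth"))
  imp <- setNames(rep(0, nrow(col_info)), col_info$column)
  pf <- truth$planted_features
  if (is.null(pf) || nrow(pf) == 0) return(imp)
  for (j in seq_len(nrow(pf))) {
    hit <- col_info$feature_id == pf$feature_id[j]
    if ("summary" %in% names(col_info)) {
      hit_sum <- hit & !is.na(col_info$summary) &
        col_info$summary == pf$summary[j]
      if (any(hit_sum)) hit <- hit_sum
    }
    imp[hit] <- abs(pf$coef[j])
  }
  imp
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d stays, %d events, %d features, mortality %.1f%%\n",
    nrow(x$stays), nrow(x$events),
    length(feature_ids_for(x$config$feature_counts)),
    100 * mean(x$labels$label)))
  invisible(x)
}

bin_age <- function(age, breaks = c(-Inf, 55, 67, 78, Inf),
                    labels = c("<55 YRS", "55-67 YRS", "67-78 YRS", ">=78 YRS")) {
  cut(age, breaks = breaks, labels = labels, right = FALSE)
}
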