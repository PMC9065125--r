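toy_spec <- function() {
  tibble::tibble(
    feature_id = c("hr", "rx", "note"),
    name = feature_id,
    block = c("temporal", "temporal", "demographic"),
    kind = c("numeric", "numeric", "categorical"),
    has_sum = c(FALSE, TRUE, FALSE))
}

toy_stays <- function(ids = "s1") {
  tibble::tibble(stay_id = ids, age = 50, stay_order = 1L,
                 icu_duration = 100, anchor = 0)
}

test_that("cohort selection applies the age, first-stay and duration rules", {
  stays <- tibble::tibble(
    stay_id = paste0("s", 1:5),
    age = c(14.9, 15, 40, 40, 40),
    stay_order = c(1L, 1L, 2L, 1L, 1L),
    icu_duration = c(48, 48, 48, 11, 12))
  kept <- select_cohort(stays)
  expect_identical(kept$stay_id, c("s2", "s5"))
  expect_identical(select_cohort(stays[0, ])$stay_id, character(0))
})

test_that("event cleaning averages numeric duplicates, keeps first categorical, splits ranges", {
  ev <- tibble::tibble(
    stay_id = "s1",
    feature_id = c("hr", "hr", "note", "note", "rx"),
    time_hours = c(1, 1, 2, 2, 3),
    value = c("4", "6", "A", "B", "2-4"))
  out <- clean_events(ev, toy_spec())
  expect_equal(out$value_num[out$feature_id == "hr"], 5)
  expect_identical(out$value[out$feature_id == "note"], "A")
  expect_equal(out$value_num[out$feature_id == "rx"], 3.0)
  expect_equal(nrow(out), 3)
  # idempotence
  expect_equal(clean_events(out, toy_spec()), out)
})

test_that("cleaning reports spec and parse problems", {
  ev <- tibble::tibble(stay_id = "s1", feature_id = "bogus",
                       time_hours = 0, value = "1")
  expect_error(clean_events(ev, toy_spec()), class = "icufair_spec_error")
  ev2 <- tibble::tibble(stay_id = "s1", feature_id = c("hr", "hr"),
                        time_hours = c(0, 1), value = c("ok?", "7"))
  expect_warning(out <- clean_events(ev2, toy_spec()), "1 event row")
  expect_equal(nrow(out), 1)
})

test_that("unit conversion happens before duplicate averaging", {
  ev <- tibble::tibble(stay_id = "s1", feature_id = "hr",
                       time_hours = c(1, 1), value = c("4", "6"))
  out <- clean_events(ev, toy_spec(),
                      unit_map = tibble::tibble(feature_id = "hr",
                                                factor = 10))
  expect_equal(out$value_num, 50)
})

test_that("stay filtering anchors within the lookback and bounds coverage", {
  spec <- toy_spec()
  mk <- function(id, times) tibble::tibble(stay_id = id, feature_id = "hr",
                                           time_hours = times, value = "1")
  ev <- dplyr::bind_rows(
    mk("short", c(0, 23)),          # span 23 h -> excluded
    mk("long", c(0, 241)),          # span 241 h -> excluded
    mk("ok", c(0, 24)),             # span 24 h -> kept
    mk("early", c(-7, -5, 30)))     # -7 ignored, anchor -5, span 35 -> kept
  ev <- clean_events(ev, spec)
  stays <- tibble::tibble(stay_id = c("short", "long", "ok", "early", "none"),
                          age = 50, stay_order = 1L, icu_duration = 100)
  expect_warning(kept <- filter_stays(ev, stays), "no events")
  expect_identical(kept$stay_id, c("ok", "early"))
  expect_equal(kept$anchor[kept$stay_id == "early"], -5)
})

test_that("hourly binning averages within bins and truncates at the window", {
  ev <- tibble::tibble(
    stay_id = "s1", feature_id = "hr",
    time_hours = c(0.2, 0.7, 24.5),
    value = c("4", "6", "99"))
  ev <- clean_events(ev, toy_spec())
  fm <- build_matrix(ev, toy_stays(), toy_spec(), t_hours = 24)
  expect_equal(dim(fm$values), c(1, 24, 3))
  expect_equal(fm$values[1, 1, "hr"], 5)
  expect_true(all(is.na(fm$values[1, 2:24, "hr"]))) # 24.5 h event dropped
})

test_that("binning conserves information: every cell is the mean of its bin", {
  set.seed(4)
  times <- runif(60, 0, 24)
  vals <- rnorm(60)
  ev <- tibble::tibble(stay_id = "s1", feature_id = "hr",
                       time_hours = times, value = sprintf("%.17g", vals))
  ev <- clean_events(ev, toy_spec())
  fm <- build_matrix(ev, toy_stays(), toy_spec(), t_hours = 24)
  for (h in 0:23) {
    inb <- floor(times) == h
    if (any(inb)) expect_equal(fm$values[1, h + 1, "hr"], mean(vals[inb]))
    else expect_true(is.na(fm$values[1, h + 1, "hr"]))
  }
})

test_that("static features broadcast and categoricals are label-encoded", {
  ev <- tibble::tibble(
    stay_id = c("s1", "s2", "s1", "s2"),
    feature_id = c("note", "note", "hr", "hr"),
    time_hours = 0,
    value = c("B", "A", "1", "2"))
  ev <- clean_events(ev, toy_spec())
  fm <- build_matrix(ev, toy_stays(c("s1", "s2")), toy_spec(), t_hours = 4)
  expect_equal(fm$encodings$note, c("A", "B"))
  expect_equal(fm$values[1, , "note"], rep(2, 4), ignore_attr = TRUE)
  expect_equal(fm$values[2, , "note"], rep(1, 4), ignore_attr = TRUE)
})

test_that("imputation forward/backward fills then falls back to train means", {
  spec <- toy_spec()
  arr <- array(NA_real_, c(1, 3, 3),
               dimnames = list("s1", NULL, spec$feature_id))
  arr[1, , "hr"] <- c(NA, 5, NA)
  fm <- structure(list(values = arr, stay_ids = "s1", spec = spec,
                       anchors = c(s1 = 0), t_hours = 3, encodings = list()),
                  class = "feature_matrix")
  tm <- c(hr = 1, rx = 2.5, note = 9)
  out <- impute(fm, tm)
  expect_equal(out$values[1, , "hr"], c(5, 5, 5), ignore_attr = TRUE)
  expect_equal(out$values[1, , "rx"], rep(2.5, 3), ignore_attr = TRUE)
  expect_false(anyNA(out$values))
  # idempotence and the no-missing identity
  expect_identical(impute(out, tm)$values, out$values)
  expect_error(impute(fm, c(hr = 1)), class = "icufair_spec_error")
})

test_that("imputation matches the zoo locf oracle on random series", {
  skip_if_not_installed("zoo")
  set.seed(8)
  spec <- toy_spec()[1, ]
  arr <- array(rnorm(5 * 24), c(5, 24, 1),
               dimnames = list(paste0("s", 1:5), NULL, "hr"))
  arr[sample(length(arr), 40)] <- NA
  fm <- structure(list(values = arr, stay_ids = paste0("s", 1:5),
                       spec = spec, anchors = NULL, t_hours = 24,
                       encodings = list()),
                  class = "feature_matrix")
  out <- impute(fm, c(hr = 0))$values
  for (i in 1:5) {
    ref <- zoo::na.locf(zoo::na.locf(arr[i, , 1], na.rm = FALSE),
                        fromLast = TRUE, na.rm = FALSE)
    ref[is.na(ref)] <- 0
    expect_equal(out[i, , 1], ref, ignore_attr = TRUE)
  }
})

test_that("tabular summary emits min/max/mean (+sum) in deterministic order", {
  spec <- toy_spec()
  arr <- array(0, c(1, 3, 3), dimnames = list("s1", NULL, spec$feature_id))
  arr[1, , "hr"] <- c(1, 2, 3)
  arr[1, , "rx"] <- c(1, 2, 3)
  arr[1, , "note"] <- 7
  fm <- structure(list(values = arr, stay_ids = "s1", spec = spec,
                       anchors = NULL, t_hours = 3, encodings = list()),
                  class = "feature_matrix")
  ts <- summarize_tabular(fm)
  expect_identical(setdiff(names(ts), "stay_id"),
                   c("hr_min", "hr_max", "hr_mean",
                     "rx_min", "rx_max", "rx_mean", "rx_sum", "note"))
  expect_equal(ts$hr_min, 1); expect_equal(ts$hr_max, 3)
  expect_equal(ts$hr_mean, 2); expect_equal(ts$rx_sum, 6)
  expect_equal(ts$note, 7)
})

test_that("a missing-free on-grid cohort round-trips the latent array", {
  cfg <- sim_config(n_stays = 15,
                    feature_counts = c(temporal = 6, demographic = 5,
                                       admission = 1, comorbidity = 2),
                    seed = 3)
  co <- generate_cohort(cfg)
  spec <- default_feature_spec(cfg$feature_counts)
  ev <- clean_events(co$events, spec)
  st <- filter_stays(ev, select_cohort(co$stays))
  fm <- build_matrix(ev, st, spec)
  expect_equal(nrow(st), 15)
  expect_equal(max(abs(fm$values[, , 1:6] - co$latent[st$stay_id, , ])), 0)
})
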