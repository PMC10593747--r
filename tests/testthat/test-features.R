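# Feature pipeline: imputation rules, forward filling, indicators,
# normalization round-trip, column accounting, leakage, and masking identity.

make_stats <- function(sessions = NULL, schema = default_schema()) {
  if (is.null(sessions)) {
    co <- generate_cohort(synth_config(n_patients = 60, seed = 8))
    sessions <- co$sessions
  }
  fit_feature_stats(sessions, schema)
}

test_that("time-invariant imputation follows the mean/median/categorical rules", {
  st <- hd_cached("feat_stats", make_stats())
  schema <- default_schema()
  v <- st$static$age
  expect_true(v$normal_flag)          # age is roughly symmetric
  vals <- c(age = NA, sex = 1, diabetes = NA, hypertension = 0,
            dialysis_vintage_years = NA, dry_weight = 61, hemoglobin = 10,
            albumin = 3.5, calcium = 9, phosphate = 4, sodium = 137,
            potassium = 4.5)
  out <- impute_time_invariant(vals, schema, st)
  expect_identical(out[["age"]], st$static$age$fill)
  expect_identical(out[["age"]], st$static$age$mean)   # normal -> mean
  # vintage is right-skewed -> median
  expect_false(st$static$dialysis_vintage_years$normal_flag)
  expect_identical(out[["dialysis_vintage_years"]],
                   st$static$dialysis_vintage_years$median)
  # categorical -> value whose frequency-ordered code is the median code
  cs <- st$static$diabetes
  expect_identical(out[["diabetes"]],
                   as.numeric(names(cs$codes)[cs$fill_code]))
  # no missing values -> identity
  out2 <- impute_time_invariant(out, schema, st)
  expect_identical(out2, out)
  st2 <- st
  st2$static$age <- NULL
  expect_error(impute_time_invariant(vals, schema, st2),
               class = "hdtft_schema_error")
})

test_that("imputation equals a per-cell rule oracle over random patterns", {
  st <- hd_cached("feat_stats", make_stats())
  schema <- default_schema()
  base <- c(age = 60, sex = 1, diabetes = 0, hypertension = 1,
            dialysis_vintage_years = 3, dry_weight = 61, hemoglobin = 10,
            albumin = 3.5, calcium = 9, phosphate = 4, sodium = 137,
            potassium = 4.5)
  set.seed(4)
  for (i in 1:200) {
    v <- base
    drop <- runif(length(v)) < 0.4
    drop[names(v) == "age" & runif(1) < 0.5] <- TRUE
    v[drop] <- NA
    out <- impute_time_invariant(v, schema, st)
    for (nm in names(v)) {
      s <- st$static[[nm]]
      want <- if (!is.na(v[[nm]])) v[[nm]]
      else if (s$dtype == "categorical") as.numeric(names(s$codes)[s$fill_code])
      else s$fill
      expect_identical(out[[nm]], want)
    }
  }
})

test_that("forward fill carries last values, uses the previous session, then medians", {
  st <- hd_cached("feat_stats", make_stats())
  ser <- data.frame(elapsed_min = c(0, 60, 120, 180),
                    sbp = c(120, NA, NA, 110))
  out <- forward_fill_time_varying(ser, st)
  expect_identical(out$series$sbp, c(120, 120, 120, 110))
  expect_identical(unname(out$observed[, "sbp"]), c(TRUE, FALSE, FALSE, TRUE))
  # leading gap with previous-session fallback
  ser2 <- data.frame(elapsed_min = c(0, 60), heart_rate = c(NA, 80))
  prev <- data.frame(elapsed_min = c(0, 60), heart_rate = c(70, 72))
  out2 <- forward_fill_time_varying(ser2, st, prev_series = prev)
  expect_identical(out2$series$heart_rate, c(72, 80))
  # leading gap without a previous session falls back to the training median
  out3 <- forward_fill_time_varying(ser2, st)
  expect_identical(out3$series$heart_rate[1], st$tv$heart_rate$median)
  # fully observed input is returned unchanged
  out4 <- forward_fill_time_varying(data.frame(elapsed_min = 0:2,
                                               sbp = c(1, 2, 3) + 100), st)
  expect_identical(out4$series$sbp, c(101, 102, 103))
  expect_true(all(out4$observed))
})

test_that("forward fill equals a linear-scan oracle on random series", {
  st <- hd_cached("feat_stats", make_stats())
  set.seed(11)
  for (i in 1:100) {
    n <- sample(2:12, 1)
    x <- round(runif(n, 60, 120), 1)
    x[runif(n) < 0.4] <- NA
    ser <- data.frame(elapsed_min = seq(0, by = 30, length.out = n),
                      heart_rate = x)
    out <- forward_fill_time_varying(ser, st)
    want <- x
    last <- NA
    for (j in seq_len(n)) {
      if (is.na(want[j])) want[j] <- last else last <- want[j]
    }
    want[is.na(want)] <- st$tv$heart_rate$median
    expect_identical(out$series$heart_rate, want)
    expect_identical(unname(out$observed[, "heart_rate"]), !is.na(x))
  }
})

test_that("auxiliary indicators copy the observation mask with 1 = observed", {
  m <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2,
              dimnames = list(NULL, c("sbp", "dbp")))
  aux <- build_auxiliary_indicators(m)
  expect_identical(colnames(aux), c("aux_sbp", "aux_dbp"))
  expect_identical(as.vector(aux), c(1, 0, 1, 1))
  expect_identical(build_auxiliary_indicators(m & FALSE), aux * 0)
  expect_error(build_auxiliary_indicators(c(TRUE, FALSE)),
               class = "hdtft_shape_error")
})

test_that("normalization is exact at the moments and round-trips", {
  expect_identical(normalize_continuous(5, 5, 2), 0)
  expect_identical(normalize_continuous(7, 5, 2), 1)
  expect_error(normalize_continuous(1, 0, 0), class = "hdtft_schema_error")
  set.seed(2)
  x <- rnorm(10000, 50, 9)
  z <- normalize_continuous(x, 50, 9)
  expect_lt(max(abs(denormalize_continuous(z, 50, 9) - x)), 1e-10)
})

test_that("feature-column accounting: 78 for the full schema, 38 for slim-30", {
  expect_identical(schema_feature_count(default_schema(full = TRUE)), 78L)
  co <- hd_cached("full_cohort", {
    generate_cohort(synth_config(n_patients = 10, seed = 6,
                                 n_extra_static = 44L))
  })
  expect_identical(nrow(co$schema), 66L)
  ds <- prepare_dataset(co, split_seed = 1, k = 2)
  b <- c(ds$train, ds$validation, ds$test)[[1]]
  expect_identical(b$feature_count, 78L)
  expect_identical(length(b$static) + ncol(b$xtv), 78L)
  # slim-30 layout: 24 time-invariant + 6 time-varying -> 30 + 6 + 2
  slim <- co$schema[c(which(co$schema$kind == "time_invariant")[1:24],
                      which(co$schema$kind == "time_varying")[1:6]), ]
  class(slim) <- c("hd_schema", "data.frame")
  expect_identical(schema_feature_count(slim), 38L)
  ds2 <- prepare_dataset(co, schema = slim, split_seed = 1, k = 2)
  b2 <- c(ds2$train, ds2$validation, ds2$test)[[1]]
  expect_identical(b2$feature_count, 38L)
})

test_that("bundles contain no nulls and indicators match the injected truth mask", {
  co <- generate_cohort(synth_config(n_patients = 12, seed = 14))
  ds <- prepare_dataset(co, split_seed = 2, k = 3)
  sid_mask <- list()
  for (i in seq_along(co$sessions))
    sid_mask[[co$sessions[[i]]$session_id]] <- co$missing_mask[[i]]$series
  for (b in c(ds$train, ds$validation, ds$test)) {
    expect_false(anyNA(b$xtv))
    expect_false(anyNA(b$static))
    m <- sid_mask[[b$session_id]]
    n_tv <- b$n_tv
    aux <- b$xtv[, (n_tv + 1):(2 * n_tv), drop = FALSE]
    expect_identical(unname(aux), unname(m[seq_len(b$T), ] * 1))
  }
})

test_that("normalization/imputation statistics depend on the training split only", {
  co <- generate_cohort(synth_config(n_patients = 30, seed = 19))
  ds <- prepare_dataset(co, split_seed = 5, k = 2)
  train_ids <- ds$split$patient_id[ds$split$split == "train"]
  kept <- filter_sessions(co$sessions)$sessions
  train_sessions <- Filter(function(s) s$patient_id %in% train_ids, kept)
  re <- fit_feature_stats(train_sessions, ds$schema)
  expect_equal(re$tv, ds$stats$tv)
  expect_equal(re$static, ds$stats$static)
  expect_equal(re$elapsed, ds$stats$elapsed)
})

test_that("a bundle with an all-false previous mask equals one with no previous sessions", {
  co <- generate_cohort(synth_config(n_patients = 10, seed = 23))
  ds <- prepare_dataset(co, split_seed = 1, k = 3)
  b <- NULL
  for (cand in ds$train) if (any(cand$prev_avail)) { b <- cand; break }
  expect_false(is.null(b))
  sets <- ds$sets
  idx <- which(vapply(sets, function(s) s$current$session_id, "") ==
                 b$session_id)
  set_none <- sets[[idx]]
  set_none$previous <- list()
  set_none$availability <- rep(FALSE, 3)
  b2 <- assemble_feature_bundle(set_none, ds$tracks[[idx]], ds$schema,
                                ds$stats)
  # current-session content is identical except cells that are defined FROM
  # the previous session: the interval channel and leading-gap fallbacks
  expect_identical(b2$static, b$static)
  n_tv <- b$n_tv
  aux <- b$xtv[, (n_tv + 1):(2 * n_tv), drop = FALSE]
  obs <- aux == 1
  expect_identical(b2$xtv[, 1:n_tv][obs], b$xtv[, 1:n_tv][obs])
  expect_identical(b2$xtv[, (n_tv + 1):(2 * n_tv + 1)],
                   b$xtv[, (n_tv + 1):(2 * n_tv + 1)])
  expect_false(any(b2$prev_avail))
})
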