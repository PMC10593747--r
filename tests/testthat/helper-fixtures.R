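# Shared fixtures. Everything is generated in code; trained models used by
# several test files are cached in `hd_cache` so each configuration is
# trained exactly once per test run.

hd_cache <- new.env(parent = emptyenv())

hd_cached <- function(key, expr) {
  if (is.null(hd_cache[[key]])) hd_cache[[key]] <- force(expr)
  hd_cache[[key]]
}

# A tiny deterministic session built by hand.
make_session <- function(patient_id = "P1", session_id = "S1",
                         start_day = 10, age = 60, duration_min = 240,
                         elapsed = c(0, 60, 120, 180, 240),
                         sbp = c(140, 130, 120, 110, 100),
                         dbp = 0.55 * sbp + 8,
                         static = NULL) {
  ser <- data.frame(elapsed_min = elapsed, sbp = sbp, dbp = dbp,
                    heart_rate = 75, respiratory_rate = 18,
                    body_temp = 36.3, blood_flow_rate = 250,
                    ultrafiltration_rate = 10, spo2 = 97,
                    venous_pressure = 120, dialysate_temp = 36.5)
  if (is.null(static)) {
    static <- c(age = age, sex = 1, diabetes = 0, hypertension = 1,
                dialysis_vintage_years = 4, dry_weight = 60,
                hemoglobin = 10.4, albumin = 3.7, calcium = 8.9,
                phosphate = 4.4, sodium = 137, potassium = 4.6)
  }
  structure(list(patient_id = patient_id, session_id = session_id,
                 start_day = start_day, age = age,
                 duration_min = duration_min, static = static, series = ser),
            class = "hd_session")
}

# Random BP series for label-oracle tests.
random_bp_series <- function(n = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- sort(sample(0:300, n))
  t[1] <- 0
  sbp <- round(runif(n, 70, 180), 1)
  dbp <- round(pmin(0.6 * sbp + runif(n, -5, 10), sbp - 5), 1)
  data.frame(elapsed_min = t, sbp = sbp, dbp = dbp)
}

# Brute-force labeling oracle: scans every reading in the window directly.
oracle_labels <- function(series, horizon = 60) {
  bp <- series[!is.na(series$sbp), ]
  init <- bp[bp$elapsed_min == 0, ][1, ]
  map0 <- (2 * init$dbp + init$sbp) / 3
  out <- data.frame(elapsed_min = bp$elapsed_min, idh1 = NA, idh2 = NA,
                    idhtn = NA, valid = FALSE)
  for (i in seq_len(nrow(bp))) {
    t <- bp$elapsed_min[i]
    win <- bp[bp$elapsed_min > t & bp$elapsed_min <= t + horizon, ]
    if (!nrow(win)) next
    out$valid[i] <- TRUE
    out$idh1[i] <- any(win$sbp < 90)
    mapw <- (2 * win$dbp + win$sbp) / 3
    out$idh2[i] <- any(init$sbp - win$sbp >= 20 |
                         (!is.na(win$dbp) & (map0 - mapw >= 10)))
    out$idhtn[i] <- any(win$sbp - init$sbp >= 10)
  }
  out
}

# Small prepared dataset shared across model tests.
small_dataset <- function() {
  hd_cached("small_ds", {
    co <- generate_cohort(synth_config(n_patients = 25, seed = 5))
    prepare_dataset(co, split_seed = 1, k = 3)
  })
}

small_model <- function() {
  hd_cached("small_model", {
    ds <- small_dataset()
    cfg <- model_config(hidden = 8, k_prev = 3, max_epochs = 2,
                        batch_size = 16, seed = 2, dropout = 0)
    train_model(ds$train, ds$validation, cfg)
  })
}
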