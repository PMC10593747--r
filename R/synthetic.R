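# Synthetic hemodialysis cohort generator.
#
# The generator produces per-patient sequences of dialysis sessions with a
# known, closed-form systolic-pressure trajectory so that every downstream
# stage (filters, labeling, feature assembly, model training, importance
# recovery) can be tested against ground truth. The trajectory for patient p,
# session s at elapsed time t minutes is
#
#   SBP(t) = 139 + b_p + carry_s + (r_p + r_s) * t/60
#            - sum_v coef_v * sens_p * driver_v * t/60 + eps(t)
#
# where b_p ~ N(0, patient_effect_sd) is a patient level, carry_s is the
# carryover term  carryover_coefficient * (previous-session nadir SBP - 115)
# (zero when no previous session lies within the matching window), r_p and
# r_s are patient- and session-level linear trends (scaled from
# patient_effect_sd and noise_sd so that zeroing those parameters yields flat
# series), sens_p is a log-normal patient sensitivity to the drivers, and
# eps(t) ~ N(0, noise_sd) is reading noise drawn on a fine fixed grid so that
# the realized noise at a given timestamp does not depend on how many
# readings precede it. Diastolic pressure is a fraction of systolic plus
# noise. Readings are hourly, switching to the denser interval whenever the
# last systolic reading fell below `unstable_sbp_threshold`.

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe a cohort of 200 prevalent hemodialysis patients with
#' 4-8 sessions each, 3-5 h long, hourly vitals (denser when systolic BP is
#' below 100 mmHg), an ultrafiltration-volume driver of systolic decline, and
#' a carryover effect of the previous session's nadir on the current level.
#'
#' @param n_patients number of patients (positive integer)
#' @param sessions_per_patient integer range `c(min, max)` of sessions drawn
#'   uniformly per patient
#' @param session_duration_h continuous range within `[2, 6]` hours
#' @param base_sampling_interval_min routine vitals interval (default 60)
#' @param unstable_sampling_interval_min denser interval used after a
#'   systolic reading below `unstable_sbp_threshold`; must be smaller than the
#'   base interval
#' @param unstable_sbp_threshold mmHg threshold that triggers dense sampling
#' @param driver_coefficients named numeric: mmHg of systolic decline per
#'   (driver unit x hour) per unit patient sensitivity; names must be
#'   time-varying variables
#' @param carryover_coefficient effect of (previous-session nadir - 110) mmHg
#'   on the current session's systolic level
#' @param missing_rate_invariant,missing_rate_varying MCAR cell-missingness
#'   probabilities in `[0, 1]`
#' @param patient_effect_sd sd (mmHg) of the patient systolic level
#' @param noise_sd sd (mmHg) of reading noise
#' @param uf_sensitivity_sd log-sd of the patient driver-sensitivity
#'   multiplier
#' @param instability_noise_power exponent linking the sensitivity trait to
#'   the reading-excursion scale (noise sd is multiplied by
#'   `sens^instability_noise_power`)
#' @param thermal_interaction strength of the dialysate-temperature
#'   amplification of the ultrafiltration effect: the decline rate is
#'   multiplied by `1 + thermal_interaction * (dialysate_temp - 36.5)`
#'   (warm dialysate promotes vasodilation and deepens hypovolemic falls)
#' @param long_gap_prob probability that an inter-session gap exceeds the
#'   1-month matching window
#' @param n_extra_static number of additional pure-noise time-invariant lab
#'   covariates (44 pads the schema to the full 56 + 10 layout)
#' @param seed integer RNG seed; a fixed seed gives byte-identical cohorts
#' @return An object of class `hd_synth_config`.
#' @export
synth_config <- function(n_patients = 200L,
                         sessions_per_patient = c(4L, 8L),
                         session_duration_h = c(3, 5),
                         base_sampling_interval_min = 60L,
                         unstable_sampling_interval_min = 30L,
                         unstable_sbp_threshold = 100,
                         driver_coefficients = c(ultrafiltration_rate = 0.5),
                         carryover_coefficient = 0.25,
                         missing_rate_invariant = 0.10,
                         missing_rate_varying = 0.10,
                         patient_effect_sd = 8,
                         noise_sd = 6.5,
                         uf_sensitivity_sd = 0.2,
                         instability_noise_power = 0.8,
                         thermal_interaction = 0.25,
                         long_gap_prob = 0.08,
                         n_extra_static = 0L,
                         seed = 1L) {
  if (n_patients < 1L) hd_stop("n_patients must be positive", "hdtft_config_error")
  if (length(sessions_per_patient) != 2L || any(sessions_per_patient < 1L))
    hd_stop("sessions_per_patient must be a positive integer range",
            "hdtft_config_error")
  if (session_duration_h[1] < 2 || session_duration_h[2] > 6 ||
      session_duration_h[1] > session_duration_h[2])
    hd_stop("session_duration_h must be an increasing range within [2, 6]",
            "hdtft_config_error")
  if (base_sampling_interval_min < 1L ||
      unstable_sampling_interval_min >= base_sampling_interval_min)
    hd_stop("unstable interval must be a positive integer below the base interval",
            "hdtft_config_error")
  for (r in c(missing_rate_invariant, missing_rate_varying))
    if (r < 0 || r > 1) hd_stop("missing rates must lie in [0, 1]",
                                "hdtft_config_error")
  if (length(driver_coefficients) &&
      !all(names(driver_coefficients) %in% hd_tv_names()))
    hd_stop("driver_coefficients must name time-varying variables",
            "hdtft_config_error")
  structure(list(
    n_patients = as.integer(n_patients),
    sessions_per_patient = as.integer(sessions_per_patient),
    session_duration_h = as.numeric(session_duration_h),
    base_sampling_interval_min = as.integer(base_sampling_interval_min),
    unstable_sampling_interval_min = as.integer(unstable_sampling_interval_min),
    unstable_sbp_threshold = unstable_sbp_threshold,
    driver_coefficients = driver_coefficients,
    carryover_coefficient = carryover_coefficient,
    missing_rate_invariant = missing_rate_invariant,
    missing_rate_varying = missing_rate_varying,
    patient_effect_sd = patient_effect_sd,
    noise_sd = noise_sd,
    uf_sensitivity_sd = uf_sensitivity_sd,
    instability_noise_power = instability_noise_power,
    thermal_interaction = thermal_interaction,
    long_gap_prob = long_gap_prob,
    n_extra_static = as.integer(n_extra_static),
    seed = as.integer(seed)
  ), class = "hd_synth_config")
}

# Per-patient time-invariant covariates, loosely centred on values typical of
# a prevalent in-centre hemodialysis population.
hd_draw_patient <- function(cfg) {
  age <- round(hd_clip(stats::rnorm(1, 62, 15), 20, 90))
  static <- c(
    age = age,
    sex = stats::rbinom(1, 1, 0.577),
    diabetes = stats::rbinom(1, 1, 0.487),
    hypertension = stats::rbinom(1, 1, 0.729),
    dialysis_vintage_years = round(stats::rexp(1, 1 / 5), 1),
    dry_weight = round(hd_clip(stats::rnorm(1, 59.5, 12), 35, 110), 1),
    hemoglobin = round(stats::rnorm(1, 10.4, 1.3), 1),
    albumin = round(stats::rnorm(1, 3.7, 0.5), 2),
    calcium = round(stats::rnorm(1, 8.9, 0.8), 1),
    phosphate = round(stats::rnorm(1, 4.4, 1.4), 1),
    sodium = round(stats::rnorm(1, 137, 3), 0),
    potassium = round(stats::rnorm(1, 4.6, 0.8), 1)
  )
  if (cfg$n_extra_static > 0L) {
    extra <- round(stats::rnorm(cfg$n_extra_static), 3)
    names(extra) <- sprintf("lab_extra_%02d", seq_len(cfg$n_extra_static))
    static <- c(static, extra)
  }
  list(
    static = static,
    effect = stats::rnorm(1, 0, cfg$patient_effect_sd),
    # patient-level linear trend (mmHg/h); hypertensive patients drift up a
    # little more often, linking one static covariate to IDHTN risk
    # expressed in units of the patient-effect scale so that a degenerate
    # configuration (patient_effect_sd = 0) yields trend-free patients
    rise = stats::rnorm(1,
                        (if (static[["hypertension"]] > 0) 0.5 else 0.25) *
                          cfg$patient_effect_sd,
                        0.5 * cfg$patient_effect_sd),
    sens = exp(stats::rnorm(1, 0, cfg$uf_sensitivity_sd))
  )
}

# Simulate one session. Noise is pre-drawn on the dense fixed grid so the
# realized values at a timestamp are invariant to the sampling pattern.
hd_draw_session <- function(cfg, pat, prev_nadir, start_day, sid) {
  dur_h <- stats::runif(1, cfg$session_duration_h[1], cfg$session_duration_h[2])
  dur_min <- round(dur_h * 60)
  fine <- seq(0, dur_min, by = cfg$unstable_sampling_interval_min)
  nf <- length(fine)

  ufr <- hd_clip(stats::rnorm(1, 10, 5), 2, 22)        # mL/kg/h
  rise_s <- pat$rise + stats::rnorm(1, 0, 0.6 * cfg$noise_sd)
  carry <- if (is.na(prev_nadir)) 0 else
    cfg$carryover_coefficient * (prev_nadir - 115)

  # reading-to-reading excursions scale with the patient sensitivity trait:
  # unstable patients both respond more to fluid removal and swing more,
  # so instability is learnable from session history (and prior sessions)
  eps_sbp <- stats::rnorm(nf, 0, cfg$noise_sd * pat$sens^cfg$instability_noise_power)
  eps_dbp <- stats::rnorm(nf, 0, 1.4 * cfg$noise_sd)
  eps_hr <- stats::rnorm(nf, 0, 4)
  eps_rr <- stats::rnorm(nf, 0, 1.2)
  eps_bt <- stats::rnorm(nf, 0, 0.2)
  eps_bf <- stats::rnorm(nf, 0, 12)
  eps_uf <- stats::rnorm(nf, 0, 0.5)
  eps_sp <- stats::rnorm(nf, 0, 1)
  eps_vp <- stats::rnorm(nf, 0, 10)
  eps_dt <- stats::rnorm(nf, 0, 0.1)
  bf0 <- hd_clip(stats::rnorm(1, 250, 25), 150, 350)

  dtemp <- stats::rnorm(1, 36.5, 0.4)                    # dialysate temperature
  thermal <- max(1 + cfg$thermal_interaction * (dtemp - 36.5), 0.1)
  drop_rate <- 0                                         # mmHg per hour
  for (v in names(cfg$driver_coefficients)) {
    dv <- if (v == "ultrafiltration_rate") ufr else 1
    drop_rate <- drop_rate + cfg$driver_coefficients[[v]] * pat$sens * dv *
      thermal
  }
  level <- function(t) 139 + pat$effect + carry + (rise_s - drop_rate) * t / 60

  # adaptive sampling over the fine grid
  keep <- logical(nf)
  keep[1L] <- TRUE
  i <- 1L
  step_base <- cfg$base_sampling_interval_min %/% cfg$unstable_sampling_interval_min
  while (i < nf) {
    sbp_i <- level(fine[i]) + eps_sbp[i]
    step <- if (sbp_i < cfg$unstable_sbp_threshold) 1L else step_base
    i <- min(i + step, nf)
    keep[i] <- TRUE
  }
  idx <- which(keep)
  t <- fine[idx]
  lev <- level(t)
  sbp <- hd_clip(lev + eps_sbp[idx], 40, 260)
  # diastolic and heart rate track the underlying level with independent
  # noise (not the recorded systolic value), so the systolic reading remains
  # the most informative single channel
  dbp <- hd_clip(pmin(0.55 * lev + 8 + eps_dbp[idx], sbp - 5), 20, 250)
  series <- data.frame(
    elapsed_min = t,
    sbp = round(sbp, 1),
    dbp = round(dbp, 1),
    heart_rate = round(75 + 0.15 * (120 - lev) + eps_hr[idx], 1),
    respiratory_rate = round(18 + eps_rr[idx], 1),
    body_temp = round(36.3 + eps_bt[idx], 2),
    blood_flow_rate = round(bf0 + eps_bf[idx], 0),
    ultrafiltration_rate = round(ufr + eps_uf[idx], 2),
    spo2 = round(hd_clip(97 + eps_sp[idx], 80, 100), 1),
    venous_pressure = round(120 + eps_vp[idx], 0),
    dialysate_temp = round(dtemp + eps_dt[idx], 2)
  )
  list(
    session = structure(list(
      patient_id = pat$id, session_id = sid, start_day = start_day,
      age = pat$static[["age"]], duration_min = dur_min,
      static = pat$static, series = series
    ), class = "hd_session"),
    nadir = min(series$sbp),
    carry = carry, ufr = ufr, rise = rise_s, drop_rate = drop_rate
  )
}

#' Generate a synthetic hemodialysis cohort
#'
#' @param config an [synth_config()] object
#' @return A list of class `hd_cohort` with elements `sessions` (list of
#'   `hd_session`), `complete_sessions` (the same sessions before missingness
#'   injection), `schema`, `truth` (ground-truth sidecar: driver names,
#'   patient effects and sensitivities, per-session carryover terms and event
#'   occurrences computed from the complete series), `missing_mask`, and
#'   `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "hd_synth_config"))
    hd_stop("config must be created with synth_config()", "hdtft_config_error")
  cfg <- config
  set.seed(cfg$seed)

  sessions <- list()
  truth_rows <- list()
  patient_tab <- list()
  for (p in seq_len(cfg$n_patients)) {
    pat <- hd_draw_patient(cfg)
    pat$id <- sprintf("P%04d", p)
    n_s <- sample(seq(cfg$sessions_per_patient[1], cfg$sessions_per_patient[2]), 1L)
    day <- stats::runif(1, 0, 30)
    prev_nadir <- NA_real_
    prev_day <- NA_real_
    for (s in seq_len(n_s)) {
      if (s > 1L) {
        gap <- if (stats::runif(1) < cfg$long_gap_prob)
          stats::runif(1, 33, 60) else sample(2:4, 1L)
        day <- day + gap
      }
      carry_src <- if (!is.na(prev_day) && (day - prev_day) <= 31)
        prev_nadir else NA_real_
      sid <- sprintf("%s_S%02d", pat$id, s)
      out <- hd_draw_session(cfg, pat, carry_src, day, sid)
      sessions[[length(sessions) + 1L]] <- out$session
      ev <- session_event_flags(out$session)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        patient_id = pat$id, session_id = sid, start_day = day,
        carry = out$carry, ufr = out$ufr, rise = out$rise,
        drop_rate = out$drop_rate, nadir = out$nadir,
        idh1 = ev[["idh1"]], idh2 = ev[["idh2"]], idhtn = ev[["idhtn"]],
        stringsAsFactors = FALSE
      )
      prev_nadir <- out$nadir
      prev_day <- day
    }
    patient_tab[[p]] <- data.frame(
      patient_id = pat$id, effect = pat$effect, sens = pat$sens,
      rise = pat$rise, stringsAsFactors = FALSE
    )
  }
  complete <- sessions
  masked <- inject_missingness(sessions,
                               rate_invariant = cfg$missing_rate_invariant,
                               rate_varying = cfg$missing_rate_varying,
                               seed = hd_seed(cfg$seed, 2L))
  schema <- default_schema(full = cfg$n_extra_static >= 44L)
  structure(list(
    sessions = masked$sessions,
    complete_sessions = complete,
    schema = schema,
    truth = list(
      drivers = names(cfg$driver_coefficients),
      events = do.call(rbind, truth_rows),
      patients = do.call(rbind, patient_tab)
    ),
    missing_mask = masked$mask,
    config = cfg
  ), class = "hd_cohort")
}

#' Inject missing-completely-at-random cells into sessions
#'
#' The initial systolic/diastolic readings (elapsed 0) and patient age are
#' never removed, so that the cohort filters remain satisfiable. By default
#' the whole systolic/diastolic columns are protected (`protect`): BP anchors
#' the recording grid, and sessions with BP gaps above 1.5 h are excluded by
#' the cohort filter anyway.
#'
#' @param sessions list of `hd_session`
#' @param rate_invariant,rate_varying probabilities in `[0, 1]`
#' @param seed integer seed
#' @param protect time-varying columns exempt from missingness (the initial
#'   BP row is always exempt regardless)
#' @return list with `sessions` (masked), `complete` (input), and `mask`
#'   (per session: `static` named logical, `series` logical matrix; TRUE =
#'   observed).
#' @export
inject_missingness <- function(sessions, rate_invariant, rate_varying,
                               seed = 1L, protect = c("sbp", "dbp")) {
  for (r in c(rate_invariant, rate_varying))
    if (is.na(r) || r < 0 || r > 1)
      hd_stop("missingness rates must lie in [0, 1]", "hdtft_config_error")
  set.seed(as.integer(seed))
  masks <- vector("list", length(sessions))
  out <- sessions
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    st <- s$static
    keep_static <- names(st) != "age"
    m_st <- stats::runif(length(st)) >= rate_invariant
    m_st[!keep_static] <- TRUE
    st[!m_st] <- NA_real_
    names(m_st) <- names(st)

    ser <- s$series
    vcols <- setdiff(names(ser), "elapsed_min")
    m_se <- matrix(stats::runif(nrow(ser) * length(vcols)) >= rate_varying,
                   nrow(ser), length(vcols), dimnames = list(NULL, vcols))
    m_se[, colnames(m_se) %in% protect] <- TRUE
    init_row <- which(ser$elapsed_min == 0)
    if (length(init_row))
      m_se[init_row, colnames(m_se) %in% c("sbp", "dbp")] <- TRUE
    for (v in vcols) ser[[v]][!m_se[, v]] <- NA_real_

    s$static <- st
    s$series <- ser
    out[[i]] <- s
    masks[[i]] <- list(static = m_st, series = m_se)
  }
  list(sessions = out, complete = sessions, mask = masks)
}
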