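# Feature pipeline: imputation, auxiliary indicators, normalization,
# elapsed-time channels, and previous-session stacking.
#
# Conventions fixed here (and relied on by the model):
#  * statistics (means, sds, medians, categorical code maps, normality flags)
#    are fitted on the TRAINING split only and applied to all splits;
#  * time-invariant continuous variables are imputed with the training mean
#    when approximately normal (|skewness| < 1) and the training median
#    otherwise; categorical variables with the median of their ordinal codes
#    after frequency-ordered encoding;
#  * time-varying variables are forward-filled; a leading gap falls back to
#    the most recent matched previous session, then to the training median;
#  * every time-varying variable gets an auxiliary indicator column that is
#    1 where the original value was observed and 0 where it was imputed;
#  * two elapsed-time channels are appended (minutes on dialysis, and days
#    since the previous session) and are normalized like other continuous
#    variables;
#  * the total feature-column count is |time_invariant| + 2 * |time_varying|
#    + 2 (originals + indicators + elapsed channels).

#' Fit feature statistics on the training split
#'
#' @param sessions list of training-split `hd_session`
#' @param schema an `hd_schema`
#' @param window_days previous-session window used for the interval channel
#' @return object of class `hd_feature_stats`
#' @export
fit_feature_stats <- function(sessions, schema, window_days = 31) {
  hd_schema_check(schema)
  st_vars <- schema[schema$kind == "time_invariant", ]
  tv_vars <- schema[schema$kind == "time_varying", ]

  static_stats <- list()
  smat <- do.call(rbind, lapply(sessions, function(s)
    s$static[st_vars$name]))
  colnames(smat) <- st_vars$name
  for (i in seq_len(nrow(st_vars))) {
    v <- st_vars$name[i]
    x <- smat[, v]
    obs <- x[!is.na(x)]
    if (!length(obs))
      hd_stop(paste0("no observed training values for ", v),
              "hdtft_schema_error")
    if (st_vars$dtype[i] == "categorical") {
      tab <- table(obs)
      vals <- names(tab)[order(-as.vector(tab), names(tab))]
      codes <- stats::setNames(seq_along(vals), vals)
      obs_codes <- codes[as.character(obs)]
      md <- round(stats::median(obs_codes))
      static_stats[[v]] <- list(dtype = "categorical", codes = codes,
                                fill_code = md,
                                mean = mean(obs_codes),
                                sd = max(stats::sd(obs_codes), 1e-8))
    } else {
      sdv <- stats::sd(obs)
      if (!is.finite(sdv) || sdv == 0)
        hd_stop(paste0("constant training column: ", v), "hdtft_schema_error")
      sk <- hd_skewness(obs)
      normal <- abs(sk) < 1
      static_stats[[v]] <- list(dtype = "continuous", mean = mean(obs),
                                sd = sdv, median = stats::median(obs),
                                skewness = sk, normal_flag = normal,
                                fill = if (normal) mean(obs) else
                                  stats::median(obs))
    }
  }

  tv_stats <- list()
  for (v in tv_vars$name) {
    x <- unlist(lapply(sessions, function(s) s$series[[v]]), use.names = FALSE)
    obs <- x[!is.na(x)]
    if (!length(obs))
      hd_stop(paste0("no observed training values for ", v),
              "hdtft_schema_error")
    sdv <- stats::sd(obs)
    if (!is.finite(sdv) || sdv == 0)
      hd_stop(paste0("constant training column: ", v), "hdtft_schema_error")
    tv_stats[[v]] <- list(mean = mean(obs), sd = sdv,
                          median = stats::median(obs))
  }

  el <- unlist(lapply(sessions, function(s) s$series$elapsed_min),
               use.names = FALSE)
  pid <- vapply(sessions, function(s) s$patient_id, "")
  day <- vapply(sessions, function(s) s$start_day, 0)
  gaps <- c()
  for (p in unique(pid)) {
    d <- sort(day[pid == p])
    if (length(d) > 1L) {
      g <- diff(d)
      gaps <- c(gaps, g[g <= window_days])
    }
  }
  if (!length(gaps)) gaps <- 3
  structure(list(
    schema = schema,
    static = static_stats,
    tv = tv_stats,
    elapsed = list(mean = mean(el), sd = max(stats::sd(el), 1e-8)),
    interval = list(mean = mean(gaps), sd = max(stats::sd(gaps), 1e-8),
                    median = stats::median(gaps)),
    window_days = window_days
  ), class = "hd_feature_stats")
}

#' Impute time-invariant values
#'
#' Normal-flagged continuous variables receive the training mean, other
#' continuous variables the training median, and categorical variables the
#' value whose ordinal code is the training median code.
#'
#' @param values named vector of raw time-invariant values (NA = missing)
#' @param schema an `hd_schema`
#' @param stats an `hd_feature_stats` fitted on the training split
#' @return completed named vector (same encoding as the input)
#' @export
impute_time_invariant <- function(values, schema, stats) {
  st <- schema[schema$kind == "time_invariant", ]
  out <- values[st$name]
  names(out) <- st$name
  for (v in st$name) {
    if (is.null(stats$static[[v]]))
      hd_stop(paste0("variable absent from fitted statistics: ", v),
              "hdtft_schema_error")
    if (!is.na(out[[v]])) next
    s <- stats$static[[v]]
    out[[v]] <- if (s$dtype == "categorical")
      as.numeric(names(s$codes)[s$fill_code]) else s$fill
  }
  out
}

# Encode completed raw statics to model scale: continuous -> z-score,
# categorical -> frequency-ordered ordinal code.
hd_encode_static <- function(values, schema, stats) {
  st <- schema[schema$kind == "time_invariant", ]
  out <- numeric(nrow(st))
  names(out) <- st$name
  for (v in st$name) {
    s <- stats$static[[v]]
    if (s$dtype == "categorical") {
      code <- s$codes[as.character(values[[v]])]
      if (is.na(code)) code <- s$fill_code   # unseen level
      out[[v]] <- as.numeric(code)
    } else {
      out[[v]] <- normalize_continuous(values[[v]], s$mean, s$sd)
    }
  }
  out
}

#' Forward-fill time-varying series
#'
#' Each missing cell takes the most recent prior observed value of the same
#' variable within the session; a leading gap falls back to the most recent
#' value in `prev_series` (the matched previous session) when available, and
#' otherwise to the training median.
#'
#' @param series measurement data.frame (`elapsed_min` plus variable columns)
#' @param stats an `hd_feature_stats`
#' @param prev_series optional previous-session measurement data.frame
#' @return list with `series` (completed) and `observed` (logical matrix,
#'   TRUE where the original value was observed)
#' @export
forward_fill_time_varying <- function(series, stats, prev_series = NULL) {
  vcols <- intersect(names(stats$tv), names(series))
  obs <- matrix(FALSE, nrow(series), length(vcols),
                dimnames = list(NULL, vcols))
  out <- series
  for (v in vcols) {
    x <- series[[v]]
    obs[, v] <- !is.na(x)
    last <- NA_real_
    for (i in seq_along(x)) {
      if (is.na(x[i])) x[i] <- last else last <- x[i]
    }
    lead <- is.na(x)
    if (any(lead)) {
      fb <- NA_real_
      if (!is.null(prev_series) && v %in% names(prev_series)) {
        pv <- prev_series[[v]]
        pv <- pv[!is.na(pv)]
        if (length(pv)) fb <- pv[length(pv)]
      }
      if (is.na(fb)) fb <- stats$tv[[v]]$median
      x[lead] <- fb
    }
    out[[v]] <- x
  }
  list(series = out, observed = obs)
}

#' Auxiliary imputation-indicator columns
#'
#' One column per time-varying variable: 1 where the original observed value
#' was used, 0 where the cell was imputed.
#'
#' @param observed logical matrix from [forward_fill_time_varying()]
#' @return numeric 0/1 matrix with columns `aux_<variable>`
#' @export
build_auxiliary_indicators <- function(observed) {
  if (!is.matrix(observed))
    hd_stop("observed mask must be a matrix", "hdtft_shape_error")
  out <- observed * 1
  colnames(out) <- paste0("aux_", colnames(observed))
  out
}

#' Z-score normalization
#'
#' @param x values
#' @param mean,sd training-split statistics; `sd` must be positive
#' @return `(x - mean) / sd`
#' @export
normalize_continuous <- function(x, mean, sd) {
  if (!is.finite(sd) || sd <= 0)
    hd_stop("sd must be positive for normalization", "hdtft_schema_error")
  (x - mean) / sd
}

#' @rdname normalize_continuous
#' @param z z-scores to map back to the original scale
#' @export
denormalize_continuous <- function(z, mean, sd) z * sd + mean

# Temporal channel block for one session: originals (z), indicators, elapsed.
hd_temporal_block <- function(session, stats, prev_series, interval_days,
                              max_timesteps) {
  ser <- session$series
  if (nrow(ser) > max_timesteps) ser <- ser[seq_len(max_timesteps), ]
  ff <- forward_fill_time_varying(ser, stats, prev_series)
  tvn <- names(stats$tv)
  xz <- sapply(tvn, function(v)
    normalize_continuous(ff$series[[v]], stats$tv[[v]]$mean, stats$tv[[v]]$sd))
  xz <- matrix(xz, nrow = nrow(ser), dimnames = list(NULL, tvn))
  aux <- build_auxiliary_indicators(ff$observed)
  e1 <- normalize_continuous(ser$elapsed_min, stats$elapsed$mean,
                             stats$elapsed$sd)
  e2 <- rep(normalize_continuous(interval_days, stats$interval$mean,
                                 stats$interval$sd), nrow(ser))
  x <- cbind(xz, aux, elapsed_hd = e1, interval_prev = e2)
  if (anyNA(x))
    hd_stop("nulls remain after temporal assembly", "hdtft_assembly_error")
  list(x = x, elapsed_min = ser$elapsed_min)
}

#' Assemble a model-ready feature bundle for one session set
#'
#' @param session_set one element from [match_previous_sessions()]
#' @param track label track for the current session ([label_track()])
#' @param schema an `hd_schema`
#' @param stats an `hd_feature_stats` fitted on the training split
#' @param max_timesteps maximum sequence length (default 24); longer sessions
#'   are truncated
#' @return list of class `hd_bundle`: `xtv` (T x (2*n_tv + 2) temporal
#'   matrix), `static` (encoded named vector), `labels`/`lmask` (T x 3),
#'   `prev` (list of temporal stacks for available previous sessions, most
#'   recent first), `prev_avail`, `feature_count`, ids and sizes.
#' @export
assemble_feature_bundle <- function(session_set, track, schema, stats,
                                    max_timesteps = 24L) {
  cur <- session_set$current
  prevs <- session_set$previous
  avail <- session_set$availability
  k <- length(avail)

  prev1 <- if (length(prevs)) prevs[[1L]]$series else NULL
  interval_days <- if (length(prevs))
    cur$start_day - prevs[[1L]]$start_day else stats$interval$median
  blk <- hd_temporal_block(cur, stats, prev1, interval_days, max_timesteps)

  raw <- impute_time_invariant(cur$static, schema, stats)
  static <- hd_encode_static(raw, schema, stats)
  if (anyNA(static))
    hd_stop("nulls remain after static assembly", "hdtft_assembly_error")

  tmap <- match(blk$elapsed_min, track$elapsed_min)
  Tn <- nrow(blk$x)
  labels <- matrix(0, Tn, 3L, dimnames = list(NULL, c("idh1", "idh2", "idhtn")))
  lmask <- matrix(0, Tn, 3L)
  for (i in seq_len(Tn)) {
    j <- tmap[i]
    if (!is.na(j) && isTRUE(track$valid[j])) {
      labels[i, ] <- as.numeric(track[j, c("idh1", "idh2", "idhtn")])
      lmask[i, ] <- 1
    }
  }

  prev_stacks <- vector("list", k)
  for (p in seq_along(prevs)) {
    ps <- prevs[[p]]
    gap <- cur$start_day - ps$start_day
    pb <- hd_temporal_block(ps, stats, NULL, gap, max_timesteps)
    prev_stacks[[p]] <- list(x = pb$x, T = nrow(pb$x))
  }

  n_tv <- length(stats$tv)
  structure(list(
    session_id = cur$session_id, patient_id = cur$patient_id,
    T = Tn, xtv = blk$x, elapsed_min = blk$elapsed_min, static = static,
    labels = labels, lmask = lmask,
    prev = prev_stacks, prev_avail = avail,
    n_tv = n_tv,
    feature_count = length(static) + 2L * n_tv + 2L
  ), class = "hd_bundle")
}

#' Run the full data pipeline on a cohort
#'
#' Filters sessions, splits patients, matches previous sessions, labels
#' timestamps, fits feature statistics on the training split, and assembles
#' bundles for the three splits.
#'
#' @param cohort an `hd_cohort` (or plain list of `hd_session`)
#' @param schema variable schema (defaults to the cohort's)
#' @param criteria exclusion criteria
#' @param k,window_days previous-session matching parameters
#' @param horizon labeling horizon in minutes
#' @param fractions patient split fractions
#' @param split_seed seed for the patient split
#' @param max_timesteps maximum sequence length
#' @return list with `train`, `validation`, `test` (bundle lists), `stats`,
#'   `schema`, `split`, `filter` (tally), `sets`, `tracks`
#' @export
prepare_dataset <- function(cohort, schema = NULL,
                            criteria = filter_criteria(),
                            k = 5L, window_days = 31, horizon = 60,
                            fractions = c(train = 0.7, validation = 0.1,
                                          test = 0.2),
                            split_seed = 1L, max_timesteps = 24L) {
  sessions <- if (inherits(cohort, "hd_cohort")) cohort$sessions else cohort
  schema <- schema %||%
    (if (inherits(cohort, "hd_cohort")) cohort$schema else default_schema())
  flt <- filter_sessions(sessions, criteria)
  kept <- flt$sessions
  pid <- vapply(kept, function(s) s$patient_id, "")
  split <- split_by_patient(pid, fractions, split_seed)
  smap <- stats::setNames(split$split, split$patient_id)

  sets <- match_previous_sessions(kept, k = k, window_days = window_days)
  tracks <- lapply(kept, label_track, horizon = horizon)

  train_sessions <- kept[smap[pid] == "train"]
  stats <- fit_feature_stats(train_sessions, schema, window_days)

  bundles <- lapply(seq_along(sets), function(i)
    assemble_feature_bundle(sets[[i]], tracks[[i]], schema, stats,
                            max_timesteps))
  by_split <- split(bundles, smap[pid])
  keep_labeled <- function(bs) Filter(function(b) sum(b$lmask) > 0, bs)
  list(train = keep_labeled(by_split$train %||% list()),
       validation = keep_labeled(by_split$validation %||% list()),
       test = keep_labeled(by_split$test %||% list()),
       stats = stats, schema = schema, split = split, filter = flt$tally,
       sets = sets, tracks = tracks)
}
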