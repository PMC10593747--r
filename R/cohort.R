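# Cohort construction: exclusion filters, previous-session matching, and the
# patient-level train/validation/test split.

#' Session exclusion criteria
#'
#' The four exclusion rules, applied in a fixed order so that a session
#' failing several rules is counted once, at the first rule it fails:
#' age below 18 years, no BP record at session start, duration below 2 h or
#' above 6 h, and any gap between consecutive BP recordings above 1.5 h.
#'
#' @param min_age_years minimum age (default 18)
#' @param require_initial_bp require systolic and diastolic readings at
#'   elapsed minute 0 (default TRUE)
#' @param min_duration_h,max_duration_h admissible session duration in hours
#' @param max_bp_gap_h maximum gap between consecutive BP recordings in hours
#' @return list of class `hd_filter_criteria`
#' @export
filter_criteria <- function(min_age_years = 18, require_initial_bp = TRUE,
                            min_duration_h = 2, max_duration_h = 6,
                            max_bp_gap_h = 1.5) {
  if (min_duration_h >= max_duration_h)
    hd_stop("min_duration_h must be below max_duration_h", "hdtft_config_error")
  if (min_age_years <= 0 || min_duration_h <= 0 || max_bp_gap_h <= 0)
    hd_stop("criteria thresholds must be positive", "hdtft_config_error")
  structure(list(min_age_years = min_age_years,
                 require_initial_bp = require_initial_bp,
                 min_duration_h = min_duration_h,
                 max_duration_h = max_duration_h,
                 max_bp_gap_h = max_bp_gap_h),
            class = "hd_filter_criteria")
}

# First failed criterion for one session, or NA if the session is kept.
hd_first_failure <- function(s, cr) {
  if (is.null(s$duration_min) || is.na(s$duration_min))
    hd_stop(paste0("session ", s$session_id %||% "?", " has no duration"),
            "hdtft_malformed_record")
  if (is.na(s$age) || s$age < cr$min_age_years) return("age")
  if (cr$require_initial_bp) {
    i0 <- which(s$series$elapsed_min == 0)
    if (!length(i0) || is.na(s$series$sbp[i0[1L]]) ||
        is.na(s$series$dbp[i0[1L]])) return("initial_bp")
  }
  dur_h <- s$duration_min / 60
  if (dur_h < cr$min_duration_h || dur_h > cr$max_duration_h) return("duration")
  bp_t <- s$series$elapsed_min[!is.na(s$series$sbp)]
  if (length(bp_t) >= 2L && any(diff(sort(bp_t)) > cr$max_bp_gap_h * 60))
    return("bp_gap")
  NA_character_
}

#' Apply the exclusion filters to a list of sessions
#'
#' @param sessions list of `hd_session`
#' @param criteria an [filter_criteria()] object
#' @return list with `sessions` (kept), `tally` (named integer counts of
#'   exclusions per criterion, in application order), and `n_input`
#' @export
filter_sessions <- function(sessions, criteria = filter_criteria()) {
  tally <- c(age = 0L, initial_bp = 0L, duration = 0L, bp_gap = 0L)
  keep <- logical(length(sessions))
  for (i in seq_along(sessions)) {
    f <- hd_first_failure(sessions[[i]], criteria)
    if (is.na(f)) keep[i] <- TRUE else tally[[f]] <- tally[[f]] + 1L
  }
  list(sessions = sessions[keep], tally = tally, n_input = length(sessions))
}

#' Sequential exclusion accounting
#'
#' Subtracts per-criterion exclusion counts (applied disjointly, in order)
#' from an initial session count.
#'
#' @param n_initial initial number of retrieved sessions
#' @param exclusions numeric vector of per-criterion exclusion counts
#' @return number of sessions remaining
#' @export
exclusion_accounting <- function(n_initial, exclusions) {
  n_initial - sum(exclusions)
}

#' Match each session with up to k previous sessions within a window
#'
#' For every session, the `k` most recent sessions of the same patient that
#' started strictly before it and within `window_days` are attached, most
#' recent first. Missing slots are marked unavailable in the mask and are
#' zero-masked downstream.
#'
#' @param sessions list of `hd_session` (any patient order)
#' @param k maximum number of previous sessions (default 5)
#' @param window_days matching window; "1 month" is interpreted as 31
#'   calendar days
#' @return list of session sets: each is a list with `current`, `previous`
#'   (list of up to `k` sessions, most recent first) and `availability`
#'   (logical of length `k`)
#' @export
match_previous_sessions <- function(sessions, k = 5L, window_days = 31) {
  pid <- vapply(sessions, function(s) s$patient_id, "")
  day <- vapply(sessions, function(s) s$start_day, 0)
  out <- vector("list", length(sessions))
  for (p in unique(pid)) {
    ix <- which(pid == p)
    ix <- ix[order(day[ix])]
    for (j in seq_along(ix)) {
      cur <- ix[j]
      cand <- ix[seq_len(j - 1L)]
      cand <- cand[day[cur] - day[cand] <= window_days & day[cand] < day[cur]]
      cand <- rev(cand)                      # most recent first
      cand <- cand[seq_len(min(k, length(cand)))]
      avail <- c(rep(TRUE, length(cand)), rep(FALSE, k - length(cand)))
      out[[cur]] <- list(current = sessions[[cur]],
                         previous = sessions[cand],
                         availability = avail)
    }
  }
  out
}

#' Patient-level random split
#'
#' Patients (never sessions) are assigned uniformly at random to the three
#' splits, which makes session-level leakage impossible by construction.
#' Counts are the largest-remainder apportionment of `n * fractions`.
#'
#' @param patient_ids character vector (duplicates collapsed)
#' @param fractions named numeric `c(train=, validation=, test=)` summing to 1
#' @param seed integer seed
#' @return data.frame with columns `patient_id`, `split`
#' @export
split_by_patient <- function(patient_ids,
                             fractions = c(train = 0.7, validation = 0.1,
                                           test = 0.2),
                             seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9)
    hd_stop("split fractions must sum to 1", "hdtft_config_error")
  ids <- unique(patient_ids)
  n <- length(ids)
  set.seed(as.integer(seed))
  ids <- sample(ids)
  base <- floor(n * fractions)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- n * fractions - base
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[add] <- base[add] + 1L
  }
  split <- rep(names(fractions), times = base)
  data.frame(patient_id = ids, split = split, stringsAsFactors = FALSE)
}
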