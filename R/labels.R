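# Outcome labeling.
#
# Three per-timestamp binary outcomes under a prospective 1-hour horizon:
#   IDH-1  : any future systolic BP reading  < 90 mmHg
#   IDH-2  : any future reading with a systolic drop >= 20 mmHg and/or a
#            mean-arterial-pressure drop >= 10 mmHg from the initial reading
#   IDHTN  : any future systolic reading >= initial systolic + 10 mmHg
# plus the session-level sensitivity outcome
#   IDHTN-2: IDHTN occurring in >= 4 of 6 consecutive sessions (the index
#            session and the 5 preceding ones).
#
# The lookahead window is half-open, (t, t + horizon]: the reading at t never
# labels itself, since the task is prospective prediction. "Initial BP" is the
# recording at elapsed minute 0 of the current session. Labels are computed
# from recorded readings only (no interpolation), and a timestamp with no BP
# recording inside the horizon has an undefined label, which is excluded from
# training and evaluation via the label mask.

#' Mean arterial pressure
#'
#' `MAP = (2 * DBP + SBP) / 3`, the standard one-third/two-thirds weighting
#' of systolic and diastolic pressure.
#'
#' @param sbp,dbp systolic and diastolic pressure (mmHg); vectorized
#' @return MAP in mmHg
#' @export
#' @examples
#' compute_map(139, 73)  # 95
compute_map <- function(sbp, dbp) {
  if (any(!is.na(sbp) & !is.na(dbp) & (dbp >= sbp | dbp <= 0)))
    hd_stop("invalid BP reading: require sbp > dbp > 0", "hdtft_reading_error")
  (2 * dbp + sbp) / 3
}

# Readings = rows of a session series with an observed systolic value.
hd_bp_readings <- function(series) {
  keep <- !is.na(series$sbp)
  data.frame(elapsed_min = series$elapsed_min[keep],
             sbp = series$sbp[keep],
             dbp = series$dbp[keep])
}

hd_future_idx <- function(times, t, horizon) {
  which(times > t & times <= t + horizon)
}

#' Label IDH-1 at one timestamp
#'
#' TRUE iff any systolic reading in `(t, t + horizon]` is strictly below
#' `threshold` (default 90 mmHg). `NA` when no reading falls in the window.
#'
#' @param series session measurement data.frame (needs `elapsed_min`, `sbp`)
#' @param t prediction timestamp (minutes from session start)
#' @param horizon lookahead in minutes (default 60)
#' @param threshold systolic threshold in mmHg
#' @export
label_idh1 <- function(series, t, horizon = 60, threshold = 90) {
  bp <- hd_bp_readings(series)
  j <- hd_future_idx(bp$elapsed_min, t, horizon)
  if (!length(j)) return(NA)
  any(bp$sbp[j] < threshold)
}

#' Label IDH-2 at one timestamp
#'
#' TRUE iff any reading in `(t, t + horizon]` shows a systolic drop of at
#' least `sbp_drop` (20 mmHg) and/or a MAP drop of at least `map_drop`
#' (10 mmHg) from the initial reading. The MAP clause is evaluated only where
#' both the initial and the future diastolic values are observed.
#'
#' @inheritParams label_idh1
#' @param initial list/row with `sbp` and `dbp` of the session-initial reading
#' @param sbp_drop,map_drop inclusive drop thresholds in mmHg
#' @export
label_idh2 <- function(series, initial, t, horizon = 60,
                       sbp_drop = 20, map_drop = 10) {
  bp <- hd_bp_readings(series)
  j <- hd_future_idx(bp$elapsed_min, t, horizon)
  if (!length(j)) return(NA)
  hit <- (initial$sbp - bp$sbp[j]) >= sbp_drop
  if (!is.null(initial$dbp) && !is.na(initial$dbp)) {
    map0 <- compute_map(initial$sbp, initial$dbp)
    ok <- !is.na(bp$dbp[j])
    hit[ok] <- hit[ok] |
      (map0 - compute_map(bp$sbp[j][ok], bp$dbp[j][ok])) >= map_drop
  }
  any(hit)
}

#' Label IDHTN at one timestamp
#'
#' TRUE iff any systolic reading in `(t, t + horizon]` is at least
#' `sbp_rise` (10 mmHg) above the initial systolic value.
#'
#' @inheritParams label_idh2
#' @param initial_sbp session-initial systolic pressure (mmHg)
#' @param sbp_rise inclusive rise threshold in mmHg
#' @export
label_idhtn <- function(series, initial_sbp, t, horizon = 60, sbp_rise = 10) {
  bp <- hd_bp_readings(series)
  j <- hd_future_idx(bp$elapsed_min, t, horizon)
  if (!length(j)) return(NA)
  any((bp$sbp[j] - initial_sbp) >= sbp_rise)
}

#' Per-timestamp label track for one session
#'
#' Computes IDH-1, IDH-2 and IDHTN at every recorded BP timestamp of the
#' session under the prospective horizon, together with a `valid` flag that
#' is FALSE where no future BP recording falls inside the horizon.
#'
#' @param session an `hd_session`
#' @param horizon lookahead in minutes (default 60)
#' @return data.frame with columns `elapsed_min`, `idh1`, `idh2`, `idhtn`,
#'   `valid`
#' @export
label_track <- function(session, horizon = 60) {
  bp <- hd_bp_readings(session$series)
  init <- which(bp$elapsed_min == 0)
  if (!length(init))
    hd_stop(paste0("session ", session$session_id, " has no initial BP"),
            "hdtft_label_error")
  initial <- bp[init[1L], ]
  t <- bp$elapsed_min
  n <- length(t)
  # one pass: W[i, j] = TRUE iff reading j falls in (t[i], t[i] + horizon]
  W <- outer(t, t, function(a, b) b > a & b <= a + horizon)
  valid <- rowSums(W) > 0
  hit1 <- bp$sbp < 90
  drop_hit <- (initial$sbp - bp$sbp) >= 20
  if (!is.na(initial$dbp)) {
    map0 <- compute_map(initial$sbp, initial$dbp)
    ok <- !is.na(bp$dbp)
    drop_hit[ok] <- drop_hit[ok] |
      (map0 - compute_map(bp$sbp[ok], bp$dbp[ok])) >= 10
  }
  rise_hit <- (bp$sbp - initial$sbp) >= 10
  any_in_window <- function(hit) as.vector(W %*% hit) > 0
  out <- data.frame(elapsed_min = t,
                    idh1 = ifelse(valid, any_in_window(hit1), NA),
                    idh2 = ifelse(valid, any_in_window(drop_hit), NA),
                    idhtn = ifelse(valid, any_in_window(rise_hit), NA),
                    valid = valid)
  out
}

#' Session-level event occurrence flags
#'
#' Whether each outcome occurred at any point of the session (any recorded
#' reading after the initial one satisfying the definition).
#'
#' @param session an `hd_session`
#' @return named logical vector `c(idh1, idh2, idhtn)`
#' @export
session_event_flags <- function(session) {
  bp <- hd_bp_readings(session$series)
  init <- which(bp$elapsed_min == 0)
  if (!length(init)) return(c(idh1 = NA, idh2 = NA, idhtn = NA))
  initial <- bp[init[1L], ]
  later <- bp[bp$elapsed_min > 0, , drop = FALSE]
  if (!nrow(later)) return(c(idh1 = FALSE, idh2 = FALSE, idhtn = FALSE))
  idh1 <- any(later$sbp < 90)
  drop_hit <- (initial$sbp - later$sbp) >= 20
  if (!is.na(initial$dbp)) {
    map0 <- compute_map(initial$sbp, initial$dbp)
    ok <- !is.na(later$dbp)
    drop_hit[ok] <- drop_hit[ok] |
      (map0 - compute_map(later$sbp[ok], later$dbp[ok])) >= 10
  }
  c(idh1 = idh1, idh2 = any(drop_hit),
    idhtn = any((later$sbp - initial$sbp) >= 10))
}

#' Session-level IDHTN-2 labels over an ordered session sequence
#'
#' For the i-th session of a patient, IDHTN-2 is TRUE iff IDHTN occurred in
#' at least `min_count` of the `window` consecutive sessions ending at i.
#' Undefined (`NA`) while fewer than `window` sessions exist.
#'
#' @param idhtn_flags logical vector of per-session IDHTN occurrence, in
#'   session order
#' @param window number of consecutive sessions (default 6)
#' @param min_count minimum number of IDHTN sessions in the window (default 4)
#' @return logical vector the same length as `idhtn_flags` (with `NA` for the
#'   first `window - 1` sessions)
#' @export
label_idhtn2 <- function(idhtn_flags, window = 6L, min_count = 4L) {
  n <- length(idhtn_flags)
  out <- rep(NA, n)
  if (n >= window) {
    for (i in seq.int(window, n)) {
      out[i] <- sum(idhtn_flags[(i - window + 1L):i]) >= min_count
    }
  }
  out
}
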