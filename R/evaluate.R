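# Evaluation: AUROC with DeLong variance and test, AUPRC with bootstrap CI,
# threshold metrics, calibration, elapsed-time stratification, and the
# flattened-table logistic baseline.

# DeLong placement values: V10 (per positive) and V01 (per negative).
hd_delong_placements <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  if (m == 0L || n == 0L)
    hd_stop("both classes must be present", "hdtft_metric_error")
  all <- c(pos, neg)
  r_all <- rank(all, ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  list(v10 = v10, v01 = v01, m = m, n = n, auc = mean(v10))
}

#' AUROC with DeLong confidence interval
#'
#' The area under the ROC curve equals the pairwise concordance probability
#' (ties counted one half); the confidence interval uses the DeLong
#' placement-value variance estimator.
#'
#' @param scores numeric scores
#' @param labels 0/1 labels
#' @param conf confidence level (default 0.95)
#' @return list with `auc`, `ci` (length 2), `se`, `n_pos`, `n_neg`
#' @export
auroc <- function(scores, labels, conf = 0.95) {
  pl <- hd_delong_placements(scores, labels)
  v <- stats::var(pl$v10) / pl$m + stats::var(pl$v01) / pl$n
  se <- sqrt(max(v, 0))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(auc = pl$auc, ci = hd_clip(pl$auc + c(-1, 1) * z * se, 0, 1),
       se = se, n_pos = pl$m, n_neg = pl$n)
}

#' DeLong test for two correlated AUROCs
#'
#' Two-sided p-value for the difference between the AUROCs of two score
#' vectors evaluated on the same examples.
#'
#' @param scores_a,scores_b paired score vectors
#' @param labels 0/1 labels shared by both
#' @return list with `auc_a`, `auc_b`, `difference`, `se`, `z`, `p_value`
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b))
    hd_stop("score vectors must be paired", "hdtft_metric_error")
  pa <- hd_delong_placements(scores_a, labels)
  pb <- hd_delong_placements(scores_b, labels)
  d <- pa$auc - pb$auc
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / pa$m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / pa$n
  if (!is.finite(v) || v <= 0) {
    # identical (or degenerate) score vectors: no evidence of a difference
    return(list(auc_a = pa$auc, auc_b = pb$auc, difference = d, se = 0,
                z = 0, p_value = 1))
  }
  z <- d / sqrt(v)
  list(auc_a = pa$auc, auc_b = pb$auc, difference = d, se = sqrt(v), z = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

# Area under the precision-recall step curve (average precision over
# distinct-score blocks; ties handled as single blocks).
hd_auprc_point <- function(scores, labels) {
  m <- sum(labels == 1)
  if (m == 0L || m == length(labels))
    hd_stop("both classes must be present", "hdtft_metric_error")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  blk <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(blk, fromLast = TRUE)   # end of each tie block
  tp <- tp[last]; fp <- fp[last]
  recall <- tp / m
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' AUPRC with bootstrap confidence interval
#'
#' @param scores numeric scores
#' @param labels 0/1 labels
#' @param n_boot bootstrap resamples for the CI (default 2000; 0 disables)
#' @param conf confidence level
#' @param seed bootstrap seed
#' @return list with `auprc`, `ci`, `n_pos`, `n_neg`
#' @export
auprc <- function(scores, labels, n_boot = 2000L, conf = 0.95, seed = 1L) {
  pt <- hd_auprc_point(scores, labels)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L) {
    set.seed(as.integer(seed))
    n <- length(scores)
    bs <- numeric(n_boot)
    for (i in seq_len(n_boot)) {
      ix <- sample.int(n, n, replace = TRUE)
      if (!any(labels[ix] == 1) || !any(labels[ix] == 0)) {
        bs[i] <- NA_real_
      } else bs[i] <- hd_auprc_point(scores[ix], labels[ix])
    }
    a <- (1 - conf) / 2
    ci <- stats::quantile(bs, c(a, 1 - a), na.rm = TRUE, names = FALSE)
  }
  list(auprc = pt, ci = ci, n_pos = sum(labels == 1),
       n_neg = sum(labels == 0))
}

#' Precision, recall and F1 at a fixed threshold
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `F1 = 2 * precision * recall / (precision + recall)`; a zero denominator
#' yields 0 with a warning.
#'
#' @param probabilities predicted probabilities
#' @param labels 0/1 labels
#' @param threshold decision threshold in `(0, 1)` (default 0.5)
#' @return named numeric `c(precision, recall, f1)`
#' @export
precision_recall_f1 <- function(probabilities, labels, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1)
    hd_stop("threshold must lie in (0, 1)", "hdtft_metric_error")
  pred <- probabilities >= threshold
  tp <- sum(pred & labels == 1)
  fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1)
  zdiv <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("zero denominator for %s; reporting 0", what))
      return(0)
    }
    num / den
  }
  precision <- zdiv(tp, tp + fp, "precision")
  recall <- zdiv(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) {
    warning("zero denominator for F1; reporting 0")
    0
  } else 2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

#' Full metric panel for one outcome
#'
#' @inheritParams auprc
#' @param threshold decision threshold
#' @return list with AUROC/AUPRC points and intervals, threshold metrics and
#'   class counts
#' @export
metric_result <- function(scores, labels, threshold = 0.5, n_boot = 2000L,
                          seed = 1L) {
  a <- auroc(scores, labels)
  p <- auprc(scores, labels, n_boot = n_boot, seed = seed)
  prf <- suppressWarnings(precision_recall_f1(scores, labels, threshold))
  list(auroc = a$auc, auroc_ci = a$ci, auprc = p$auprc, auprc_ci = p$ci,
       precision = prf[["precision"]], recall = prf[["recall"]],
       f1 = prf[["f1"]], n_pos = a$n_pos, n_neg = a$n_neg)
}

#' Calibration curve
#'
#' Equal-width probability bins on `[0, 1]`; empty bins are omitted.
#'
#' @param probabilities predicted probabilities
#' @param labels 0/1 labels
#' @param n_bins number of bins (default 10, minimum 2)
#' @return data.frame with `bin`, `mean_predicted`, `observed_rate`, `count`
#' @export
calibration_curve <- function(probabilities, labels, n_bins = 10L) {
  if (n_bins < 2L) hd_stop("n_bins must be >= 2", "hdtft_metric_error")
  br <- seq(0, 1, length.out = n_bins + 1L)
  bin <- cut(probabilities, br, include.lowest = TRUE, labels = FALSE)
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    ix <- bin == b
    data.frame(bin = b, mean_predicted = mean(probabilities[ix]),
               observed_rate = mean(labels[ix]), count = sum(ix))
  }))
  out
}

#' Metrics stratified by elapsed dialysis time
#'
#' @param scores,labels per-timestamp scores and 0/1 labels
#' @param elapsed_min per-timestamp elapsed minutes
#' @param bin_width_min bin width (default 30)
#' @return data.frame per bin: `bin_start`, `bin_end`, `n`, `n_pos`,
#'   `auroc`, `auprc` (NA where a bin lacks one of the classes)
#' @export
metrics_by_elapsed_time <- function(scores, labels, elapsed_min,
                                    bin_width_min = 30) {
  bin <- floor(elapsed_min / bin_width_min)
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    ix <- bin == b
    y <- labels[ix]
    ok <- any(y == 1) && any(y == 0)
    data.frame(bin_start = b * bin_width_min,
               bin_end = (b + 1) * bin_width_min,
               n = sum(ix), n_pos = sum(y == 1),
               auroc = if (ok) auroc(scores[ix], y)$auc else NA_real_,
               auprc = if (ok) hd_auprc_point(scores[ix], y) else NA_real_)
  }))
  out
}

## ---- tabular baseline ----

#' Flattened three-timestamp feature table
#'
#' For every labeled timestamp the table holds the time-invariant vector plus
#' each original time-varying variable at three timestamps (session start,
#' prediction time, and the immediately previous recording) plus the two
#' elapsed-time channels, giving `3 * n_tv + n_static + 2` columns.
#'
#' @param bundles list of `hd_bundle`
#' @return list with `x` (feature matrix), `labels`, `mask`, `session_id`,
#'   `elapsed_min`
#' @export
tabular_features <- function(bundles) {
  n_tv <- bundles[[1L]]$n_tv
  rows <- list(); labs <- list(); msk <- list(); sid <- c(); el <- c()
  for (bd in bundles) {
    tv <- bd$xtv[, seq_len(n_tv), drop = FALSE]
    elapsed <- bd$xtv[, (2L * n_tv + 1L):(2L * n_tv + 2L), drop = FALSE]
    for (t in seq_len(bd$T)) {
      if (sum(bd$lmask[t, ]) == 0) next
      prev_t <- max(t - 1L, 1L)
      rows[[length(rows) + 1L]] <-
        c(bd$static, tv[1L, ], tv[t, ], tv[prev_t, ], elapsed[t, ])
      labs[[length(labs) + 1L]] <- bd$labels[t, ]
      msk[[length(msk) + 1L]] <- bd$lmask[t, ]
      sid <- c(sid, bd$session_id); el <- c(el, bd$elapsed_min[t])
    }
  }
  x <- do.call(rbind, rows)
  colnames(x) <- c(names(bundles[[1L]]$static),
                   paste0(colnames(tv), "_t0"),
                   paste0(colnames(tv), "_now"),
                   paste0(colnames(tv), "_prev"),
                   "elapsed_hd", "interval_prev")
  list(x = x, labels = do.call(rbind, labs), mask = do.call(rbind, msk),
       session_id = sid, elapsed_min = el)
}

#' Logistic-regression baseline on the flattened table
#'
#' One binomial GLM per outcome head, fitted on the training table and
#' evaluated on the test table.
#'
#' @param train,test lists of `hd_bundle`
#' @return data.frame like [predict_model()] (per labeled timestamp)
#' @export
baseline_logistic <- function(train, test) {
  tr <- tabular_features(train)
  te <- tabular_features(test)
  heads <- c("idh1", "idh2", "idhtn")
  out <- data.frame(session_id = te$session_id, elapsed_min = te$elapsed_min)
  for (h in seq_along(heads)) {
    ix <- tr$mask[, h] == 1
    df <- as.data.frame(tr$x[ix, , drop = FALSE])
    df$y <- tr$labels[ix, h]
    fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                       family = stats::binomial()))
    pr <- suppressWarnings(
      stats::predict(fit, newdata = as.data.frame(te$x), type = "response"))
    out[[paste0("prob_", heads[h])]] <- as.numeric(pr)
    out[[paste0("label_", heads[h])]] <- te$labels[, h]
    out[[paste0("mask_", heads[h])]] <- te$mask[, h]
  }
  out
}

#' Write evaluation plots as SVG
#'
#' ROC, precision-recall, calibration and elapsed-time-stratified AUROC
#' panels for the three outcome heads.
#'
#' @param pred prediction data.frame from [predict_model()]
#' @param dir output directory
#' @return invisibly, the files written
#' @export
write_evaluation_plots <- function(pred, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  heads <- c("idh1", "idh2", "idhtn")
  cols <- c(idh1 = "#D55E00", idh2 = "#0072B2", idhtn = "#009E73")
  get <- function(h) {
    mk <- pred[[paste0("mask_", h)]] == 1
    list(p = pred[[paste0("prob_", h)]][mk],
         y = pred[[paste0("label_", h)]][mk],
         t = pred$elapsed_min[mk])
  }
  roc_xy <- function(p, y) {
    o <- order(p, decreasing = TRUE)
    tpr <- cumsum(y[o] == 1) / sum(y == 1)
    fpr <- cumsum(y[o] == 0) / sum(y == 0)
    list(x = c(0, fpr), y = c(0, tpr))
  }
  pr_xy <- function(p, y) {
    o <- order(p, decreasing = TRUE)
    tp <- cumsum(y[o] == 1)
    list(x = tp / sum(y == 1), y = tp / seq_along(tp))
  }
  files <- character(0)
  draw <- function(name, fn) {
    path <- file.path(dir, name)
    grDevices::svg(path, width = 5, height = 5)
    on.exit(grDevices::dev.off())
    fn()
    files <<- c(files, path)
  }
  draw("roc.svg", function() {
    graphics::plot(0:1, 0:1, type = "l", lty = 3, col = "grey",
         xlab = "False positive rate", ylab = "True positive rate",
         main = "ROC")
    for (h in heads) {
      g <- get(h); xy <- roc_xy(g$p, g$y)
      graphics::lines(xy$x, xy$y, col = cols[[h]])
    }
    graphics::legend("bottomright", legend = toupper(heads),
                     col = cols, lty = 1, bty = "n")
  })
  draw("pr.svg", function() {
    graphics::plot(NULL, xlim = c(0, 1), ylim = c(0, 1), xlab = "Recall",
         ylab = "Precision", main = "Precision-recall")
    for (h in heads) {
      g <- get(h); xy <- pr_xy(g$p, g$y)
      graphics::lines(xy$x, xy$y, col = cols[[h]])
    }
    graphics::legend("topright", legend = toupper(heads),
                     col = cols, lty = 1, bty = "n")
  })
  draw("calibration.svg", function() {
    graphics::plot(0:1, 0:1, type = "l", lty = 3, col = "grey",
         xlab = "Mean predicted probability", ylab = "Observed rate",
         main = "Calibration")
    for (h in heads) {
      g <- get(h)
      cc <- calibration_curve(g$p, g$y)
      graphics::lines(cc$mean_predicted, cc$observed_rate, col = cols[[h]],
                      type = "b", pch = 16)
    }
    graphics::legend("topleft", legend = toupper(heads),
                     col = cols, lty = 1, bty = "n")
  })
  draw("elapsed.svg", function() {
    graphics::plot(NULL, xlim = range(pred$elapsed_min), ylim = c(0.4, 1),
         xlab = "Elapsed time (min)", ylab = "AUROC",
         main = "AUROC by elapsed time")
    for (h in heads) {
      g <- get(h)
      st <- metrics_by_elapsed_time(g$p, g$y, g$t)
      graphics::lines((st$bin_start + st$bin_end) / 2, st$auroc,
                      col = cols[[h]], type = "b", pch = 16)
    }
    graphics::legend("bottomright", legend = toupper(heads),
                     col = cols, lty = 1, bty = "n")
  })
  invisible(files)
}
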