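# Attention-based explainability: variable-importance aggregation, per-session
# explanation reports, and slim-schema selection.

#' Mean attention-weight variable importance
#'
#' Selection weights are extracted for every example; time-varying weights
#' are averaged over valid timesteps within each example first, then over
#' examples (order documented in the methods vignette), and each reported
#' table is renormalized to sum to one. A higher weight indicates a higher
#' contribution to the prediction.
#'
#' @param model trained `hd_model` (full variant)
#' @param bundles non-empty list of `hd_bundle`
#' @param batch_size sessions per forward pass
#' @return list with data.frames `static` (variable, weight) including the
#'   `prev_session_k` context slots, and `time_varying` (channel, weight)
#'   covering original variables, auxiliary indicators and elapsed channels;
#'   both sorted by decreasing weight with lexicographic tie-break
#' @export
variable_importance <- function(model, bundles, batch_size = 64L) {
  if (!length(bundles)) hd_stop("empty dataset", "hdtft_explain_error")
  if (model$config$variant != "tft")
    hd_stop("importance requires the full model variant", "hdtft_explain_error")
  st_names <- c(model$static_names,
                if (model$K > 0L) paste0("prev_session_", seq_len(model$K)))
  st_sum <- numeric(length(st_names))
  tv_sum <- numeric(model$V)
  n_ex <- 0L
  for (start in seq(1L, length(bundles), by = batch_size)) {
    ix <- start:min(start + batch_size - 1L, length(bundles))
    batch <- hd_make_batch(bundles[ix], model$K, model$config$max_timesteps)
    fw <- hd_forward(model, batch, train = FALSE, collect = TRUE)
    B <- batch$B
    st_sum <- st_sum + colSums(fw$static_weights)
    for (b in seq_len(B)) {
      rows <- b + B * (seq_len(batch$Tb[b]) - 1L)
      tv_sum <- tv_sum + colMeans(fw$tv_weights[rows, , drop = FALSE])
    }
    n_ex <- n_ex + B
  }
  mk <- function(names, w) {
    w <- w / sum(w)
    df <- data.frame(variable = names, weight = w, stringsAsFactors = FALSE)
    df[order(-df$weight, df$variable), , drop = FALSE]
  }
  list(static = mk(st_names, st_sum / n_ex),
       time_varying = mk(model$tv_channels, tv_sum / n_ex))
}

#' Per-session explanation report
#'
#' Real-time probability track for the three outcomes plus the attention
#' weights behind it: per-timestep time-varying selection weights, static
#' selection weights, and the causal temporal-attention matrix whose
#' strictly-future positions are exactly zero.
#'
#' @param model trained `hd_model` (full variant)
#' @param bundle one `hd_bundle`
#' @return list with `probabilities` (data.frame elapsed_min + prob_*),
#'   `static_weights` (named numeric), `tv_weights` (T x channels matrix),
#'   `temporal_attention` (T x T lower-triangular matrix)
#' @export
session_explanation <- function(model, bundle) {
  if (model$config$variant != "tft")
    hd_stop("explanation requires the full model variant",
            "hdtft_explain_error")
  batch <- hd_make_batch(list(bundle), model$K, model$config$max_timesteps)
  fw <- hd_forward(model, batch, train = FALSE, collect = TRUE)
  Tn <- batch$Tb[1L]
  probs <- data.frame(elapsed_min = bundle$elapsed_min[seq_len(Tn)],
                      prob_idh1 = fw$prob[seq_len(Tn), 1L],
                      prob_idh2 = fw$prob[seq_len(Tn), 2L],
                      prob_idhtn = fw$prob[seq_len(Tn), 3L])
  stw <- as.numeric(fw$static_weights[1L, ])
  names(stw) <- c(model$static_names,
                  if (model$K > 0L) paste0("prev_session_", seq_len(model$K)))
  tvw <- fw$tv_weights[seq_len(Tn), , drop = FALSE]
  colnames(tvw) <- model$tv_channels
  list(probabilities = probs, static_weights = stw, tv_weights = tvw,
       temporal_attention = fw$attention[[1L]])
}

#' Select a slim variable schema from importance tables
#'
#' Ranks the original schema variables by mean selection weight (static
#' variables by their static weight; time-varying variables by the weight of
#' their original channel), breaks ties lexicographically, and keeps the top
#' `k`. The time-varying / time-invariant split of the slim schema is the one
#' induced by the ranking; auxiliary-indicator and elapsed-time columns are
#' recomputed accordingly by the feature pipeline.
#'
#' @param importance output of [variable_importance()]
#' @param schema the parent `hd_schema`
#' @param k number of variables to keep (`1 <= k <= nrow(schema)`)
#' @return slim `hd_schema`
#' @export
select_slim_schema <- function(importance, schema, k) {
  hd_schema_check(schema)
  if (k < 1L) hd_stop("k must be >= 1", "hdtft_explain_error")
  if (k > nrow(schema))
    hd_stop("k exceeds the number of schema variables", "hdtft_explain_error")
  # restrict each table to schema variables and renormalize before mixing,
  # so that context slots / indicator channels do not distort the shared
  # ranking scale
  st <- importance$static
  st <- st[st$variable %in% schema$name, , drop = FALSE]
  st$weight <- st$weight / sum(st$weight)
  tv <- importance$time_varying
  tv <- tv[tv$variable %in% schema$name, , drop = FALSE]
  tv$weight <- tv$weight / sum(tv$weight)
  all <- rbind(st, tv)
  all <- all[order(-all$weight, all$variable), , drop = FALSE]
  keep <- all$variable[seq_len(k)]
  out <- schema[schema$name %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hd_schema", "data.frame")
  out
}
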