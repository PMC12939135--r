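#' Filter trials to the analyzable set
#'
#' Keeps trials that were answered correctly with a reaction time strictly
#' below the response window (default 2000 ms). Incorrect trials are
#' counted first, then slow trials among the correct ones; the report gives
#' exclusion counts by reason.
#'
#' @param trials trial-level data.frame with at least `rt_ms` and `correct`.
#' @param rt_ceiling_ms response window in ms; trials with
#'   `rt_ms >= rt_ceiling_ms` are excluded (strict "smaller than").
#' @return list with `trials` (retained rows) and `report` (data.frame of
#'   reason / n, including the retained count).
#' @export
filter_trials <- function(trials, rt_ceiling_ms = 2000) {
  need <- c("rt_ms", "correct")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("trial table lacks column(s): ",
                         paste(miss, collapse = ", "))
  incorrect <- !trials$correct
  slow <- trials$correct & trials$rt_ms >= rt_ceiling_ms
  keep <- trials$correct & trials$rt_ms < rt_ceiling_ms
  list(trials = trials[keep, , drop = FALSE],
       report = data.frame(
         reason = c("retained", "incorrect", "too_slow"),
         n = c(sum(keep), sum(incorrect), sum(slow))))
}

#' Per-subject cell means
#'
#' Aggregates filtered trials to the subject-by-condition mean reaction
#' times that every ANOVA design consumes. Cells are defined by the
#' requested factors (any subset of `block`, `event`, `last_var`); the
#' subject and group columns are always kept. When `last_var` is a factor,
#' trials before the first variable event (`last_var == "NONE"`) are
#' excluded, as that design conditions on an observed last variable event.
#'
#' When `block` is not among the factors, `collapse` selects how the block
#' dimension is removed: `"pooled"` (default) averages all retained trials
#' of a cell with equal weight per trial — appropriate because variable
#' events are unevenly spread over blocks — while `"block_mean"` first
#' averages within block and then averages the block means.
#'
#' @param trials filtered trial data.frame.
#' @param factors character subset of `c("block", "event", "last_var")`.
#' @param collapse `"pooled"` or `"block_mean"`; only relevant when `block`
#'   is not in `factors`.
#' @return data.frame with columns `subject_id`, `group`, the factors,
#'   `mean_rt` and `n_trials` (for `"block_mean"`, `n_trials` is the number
#'   of contributing trials, while `mean_rt` weights blocks equally).
#' @export
cell_means <- function(trials, factors = c("block", "event"),
                       collapse = c("pooled", "block_mean")) {
  collapse <- match.arg(collapse)
  allowed <- c("block", "event", "last_var")
  if (length(factors) && !all(factors %in% allowed)) {
    stop("factors must be a subset of: ", paste(allowed, collapse = ", "))
  }
  miss <- setdiff(c("subject_id", "group", "rt_ms", factors), names(trials))
  if (length(miss)) stop("trial table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if ("last_var" %in% factors) {
    trials <- trials[trials$last_var != "NONE", , drop = FALSE]
  }
  inner_factors <- factors
  if (collapse == "block_mean" && !"block" %in% factors) {
    inner_factors <- c("block", factors)
  }
  key_cols <- c("subject_id", "group", inner_factors)
  agg <- stats::aggregate(trials$rt_ms, trials[key_cols],
                          function(x) c(mean(x), length(x)))
  out <- agg[key_cols]
  out$mean_rt <- agg$x[, 1L]
  out$n_trials <- agg$x[, 2L]
  if (collapse == "block_mean" && !"block" %in% factors) {
    key_cols <- c("subject_id", "group", factors)
    agg2 <- stats::aggregate(out$mean_rt, out[key_cols], mean)
    n2 <- stats::aggregate(out$n_trials, out[key_cols], sum)
    out <- agg2[key_cols]
    out$mean_rt <- agg2$x
    out$n_trials <- n2$x
  }
  ord <- do.call(order, out[c("subject_id", intersect(allowed, factors))])
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sub-block mean reaction times
#'
#' Splits every block into consecutive, non-overlapping 50-trial sub-blocks
#' (sub-block = ceiling(trial_in_block / 50)), disregarding event type, and
#' returns per-subject sub-block mean RTs. Excluded trials simply reduce a
#' cell's trial count. Feeds the within-block learning (slope) analysis.
#'
#' @param trials filtered trial data.frame with `trial_in_block`.
#' @param sub_block_len sub-block length in trials (default 50); the block
#'   length must be divisible by it.
#' @return data.frame with `subject_id`, `group`, `block`, `sub_block`,
#'   `mean_rt`, `n_trials`.
#' @export
subblock_means <- function(trials, sub_block_len = 50L) {
  miss <- setdiff(c("subject_id", "group", "block", "trial_in_block",
                    "rt_ms"), names(trials))
  if (length(miss)) stop("trial table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (max(trials$trial_in_block) %% sub_block_len != 0) {
    stop("block length is not divisible by the sub-block length")
  }
  trials$sub_block <- ceiling(trials$trial_in_block / sub_block_len)
  key_cols <- c("subject_id", "group", "block", "sub_block")
  agg <- stats::aggregate(trials$rt_ms, trials[key_cols],
                          function(x) c(mean(x), length(x)))
  out <- agg[key_cols]
  out$mean_rt <- agg$x[, 1L]
  out$n_trials <- agg$x[, 2L]
  out <- out[do.call(order, out[key_cols]), , drop = FALSE]
  rownames(out) <- NULL
  out
}
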