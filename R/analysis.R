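#' Model-based classification of retrieval trials
#'
#' For each episode, locates the first correct response and asks whether the
#' model, teacher-forced through the subject's own history, would have
#' retrieved the upcoming association by chunking. The trial after the first
#' correct response (the prediction trial) is labeled `"chunked"` when the
#' first correct trial was rewarded and the TN activation closure from its
#' realized conjunction contains a population whose stimulus is the
#' prediction trial's stimulus; otherwise `"independent"`. Prediction trials
#' repeating the same stimulus are excluded, as are episodes with no correct
#' response. Chunked retrieval predicts higher accuracy on the prediction
#' trial.
#'
#' @param dataset a [behavior_dataset()].
#' @param params fitted [model_params()] used for the teacher-forced replay.
#' @param trace optional precomputed [teacher_forced_run()] trace (with
#'   inference) to avoid recomputation.
#' @param scorer_trace optional second trace whose `p_correct` scores the
#'   prediction trials (e.g. an AN-only replay), added as
#'   `model_p_correct`.
#' @return A data.frame of trial labels: `subject`, `episode`, `trial` (the
#'   prediction trial), `position` (within-episode index), `kind`, `label`,
#'   `outcome_correct`, and optionally `model_p_correct`.
#' @export
label_retrieval_trials <- function(dataset, params, trace = NULL,
                                   scorer_trace = NULL) {
  if (is.null(trace))
    trace <- teacher_forced_run(params, dataset, with_inference = TRUE)
  n_a <- attr(dataset, "n_actions")
  rows <- list()
  for (e in unique(dataset$episode)) {
    idx <- which(dataset$episode == e)
    firsts <- idx[!is.na(dataset$action[idx]) & dataset$correct[idx] == 1]
    if (!length(firsts)) next
    t0 <- firsts[1]
    t1 <- t0 + 1L
    if (!(t1 %in% idx)) next
    if (is.na(dataset$action[t1])) next
    if (dataset$stimulus[t1] == dataset$stimulus[t0]) next
    pops <- mask_to_pops(trace$active_mask[t0])
    pop_stims <- (pops - 1L) %/% n_a + 1L
    chunked <- dataset$reward[t0] == 1 &&
      dataset$stimulus[t1] %in% pop_stims
    rows[[length(rows) + 1L]] <- data.frame(
      subject = attr(dataset, "subject"), episode = e, trial = t1,
      position = match(t1, idx), kind = "retrieval",
      label = if (chunked) "chunked" else "independent",
      outcome_correct = dataset$correct[t1] == 1)
  }
  finish_labels(rows, scorer_trace)
}

#' Model-based classification of misleading-reward trials
#'
#' A noisy trial can reward an incorrect response; if the TN closure from
#' that (incorrect) conjunction reaches a population matching the next
#' trial's stimulus, the model maladaptively retrieves the wrong task-set
#' and predicts reduced accuracy on that next trial. Such prediction trials
#' are labeled `"chunked"`, the remaining misleadingly rewarded-incorrect
#' cases `"independent"`. Same-stimulus prediction trials are excluded so
#' the effect is not confounded with the AN's own (mis)potentiation.
#'
#' @inheritParams label_retrieval_trials
#' @return A data.frame in the same format, `kind = "misleading"`.
#' @export
label_misleading_trials <- function(dataset, params, trace = NULL,
                                    scorer_trace = NULL) {
  if (is.null(trace))
    trace <- teacher_forced_run(params, dataset, with_inference = TRUE)
  n_a <- attr(dataset, "n_actions")
  rows <- list()
  cand <- which(!is.na(dataset$action) & dataset$correct == 0 &
                  dataset$reward == 1)
  for (t0 in cand) {
    t1 <- t0 + 1L
    if (t1 > nrow(dataset) || dataset$episode[t1] != dataset$episode[t0]) next
    if (is.na(dataset$action[t1])) next
    if (dataset$stimulus[t1] == dataset$stimulus[t0]) next
    pops <- mask_to_pops(trace$active_mask[t0])
    pop_stims <- (pops - 1L) %/% n_a + 1L
    chunked <- dataset$stimulus[t1] %in% pop_stims
    idx <- which(dataset$episode == dataset$episode[t0])
    rows[[length(rows) + 1L]] <- data.frame(
      subject = attr(dataset, "subject"), episode = dataset$episode[t0],
      trial = t1, position = match(t1, idx), kind = "misleading",
      label = if (chunked) "chunked" else "independent",
      outcome_correct = dataset$correct[t1] == 1)
  }
  finish_labels(rows, scorer_trace)
}

finish_labels <- function(rows, scorer_trace) {
  if (!length(rows))
    return(data.frame(subject = character(), episode = integer(),
                      trial = integer(), position = integer(),
                      kind = character(), label = character(),
                      outcome_correct = logical()))
  out <- do.call(rbind, rows)
  if (!is.null(scorer_trace))
    out$model_p_correct <- scorer_trace$p_correct[out$trial]
  out
}

#' Event-aligned performance curves
#'
#' Averages performance at fixed trial offsets around task events:
#' `"episode_switch"` (offset 0 = first trial of the new episode; negative
#' offsets reach into the previous episode), `"first_correct"` (each
#' episode's first correct response, offsets restricted to the episode), or
#' `"misleading_late"` (correct-but-unrewarded trials in the last third of
#' an episode, offsets restricted to the episode).
#'
#' @param datasets a [behavior_dataset()] or list of them.
#' @param alignment event type.
#' @param offsets integer trial offsets to report.
#' @param performance optional list (matched to `datasets`) of per-trial
#'   numeric performance (e.g. a trace's `p_correct`); defaults to the
#'   recorded `correct` flag.
#' @return A data.frame of class `aligned_curve`: `offset`, `mean`, `sem`,
#'   `n`.
#' @export
aligned_performance <- function(datasets,
                                alignment = c("episode_switch",
                                              "first_correct",
                                              "misleading_late"),
                                offsets = -5:5, performance = NULL) {
  alignment <- match.arg(alignment)
  if (inherits(datasets, "behavior_dataset")) datasets <- list(datasets)
  if (!is.null(performance) && !is.list(performance))
    performance <- list(performance)
  acc <- lapply(offsets, function(o) numeric(0))
  names(acc) <- as.character(offsets)
  for (d in seq_along(datasets)) {
    ds <- datasets[[d]]
    perf <- if (is.null(performance)) as.numeric(ds$correct)
            else performance[[d]]
    events <- switch(alignment,
      episode_switch = which(c(FALSE, diff(ds$episode) != 0)),
      first_correct = unlist(lapply(unique(ds$episode), function(e) {
        idx <- which(ds$episode == e)
        f <- idx[!is.na(ds$action[idx]) & ds$correct[idx] == 1]
        if (length(f)) f[1] else integer(0)
      })),
      misleading_late = which(!is.na(ds$action) & ds$correct == 1 &
                                ds$reward == 0 &
                                stats::ave(seq_len(nrow(ds)), ds$episode,
                                           FUN = function(i)
                                             seq_along(i) / length(i)) > 2 / 3))
    if (!length(events)) next
    within_episode <- alignment != "episode_switch"
    for (t0 in events) {
      for (o in offsets) {
        t <- t0 + o
        if (t < 1 || t > nrow(ds)) next
        if (within_episode && ds$episode[t] != ds$episode[t0]) next
        if (is.na(perf[t])) next
        acc[[as.character(o)]] <- c(acc[[as.character(o)]], perf[t])
      }
    }
  }
  n <- vapply(acc, length, 0L)
  if (all(n == 0))
    stop("aligned_performance: no alignment events found")
  out <- data.frame(
    offset = offsets,
    mean = vapply(acc, function(v) if (length(v)) mean(v) else NA_real_, 0),
    sem = vapply(acc, function(v) if (length(v) > 1) sd(v) / sqrt(length(v))
                                  else NA_real_, 0),
    n = n)
  out <- out[out$n > 0, ]
  rownames(out) <- NULL
  class(out) <- c("aligned_curve", "data.frame")
  out
}

#' Performance on newly seen stimuli after the first correct response
#'
#' Restricted to the last third of a session's episodes: within each
#' episode, find the first correct response; stimuli with no presentation
#' up to and including that trial are "newly seen", labeled second or third
#' by order of first appearance, and their first presentations are scored
#' for correctness. A task-set learner that retrieves the whole rule from
#' one confirmed association performs at ceiling here; an independent
#' associator starts from scratch on each new stimulus.
#'
#' @param datasets a [behavior_dataset()] or list of them.
#' @return A list with `second` and `third` (proportion correct),
#'   `n_second`, `n_third`.
#' @export
newly_seen_performance <- function(datasets) {
  if (inherits(datasets, "behavior_dataset")) datasets <- list(datasets)
  second <- numeric(0); third <- numeric(0)
  for (ds in datasets) {
    n_ep <- max(ds$episode)
    for (e in unique(ds$episode)) {
      if (e <= 2 * n_ep / 3) next
      idx <- which(ds$episode == e)
      f <- idx[!is.na(ds$action[idx]) & ds$correct[idx] == 1]
      if (!length(f)) next
      t0 <- f[1]
      seen_before <- unique(ds$stimulus[idx[idx <= t0]])
      eligible <- setdiff(unique(ds$stimulus[idx]), seen_before)
      if (!length(eligible)) next
      firsts <- vapply(eligible, function(s) {
        w <- idx[idx > t0 & ds$stimulus[idx] == s]
        if (length(w)) w[1] else NA_integer_
      }, 0L)
      ok <- !is.na(firsts)
      eligible <- eligible[ok]; firsts <- firsts[ok]
      ord <- order(firsts)
      for (j in seq_along(ord)) {
        t <- firsts[ord[j]]
        if (is.na(ds$action[t])) next
        val <- as.numeric(ds$correct[t])
        if (j == 1) second <- c(second, val)
        else if (j == 2) third <- c(third, val)
      }
    }
  }
  list(second = if (length(second)) mean(second) else NA_real_,
       third = if (length(third)) mean(third) else NA_real_,
       n_second = length(second), n_third = length(third))
}
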