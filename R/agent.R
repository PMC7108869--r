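#' Behavioral dataset container
#'
#' A per-trial behavioral log, the common currency of simulation and
#' fitting. One row per trial, trials ordered, episodes contiguous. For
#' non-lapse trials the invariant `reward == xor(correct, noisy)` must hold.
#'
#' @param trials data.frame with columns `episode`, `trial`, `stimulus`,
#'   `action` (NA = lapse), `reward`, `correct`, `noisy`, and optionally
#'   `rt` and `correct_action`.
#' @param n_stimuli,n_actions set sizes of the session.
#' @param subject subject identifier.
#' @param session_type `"recurrent"` or `"open_ended"`.
#' @return A data.frame of class `behavior_dataset`.
#' @export
behavior_dataset <- function(trials, n_stimuli, n_actions,
                             subject = "s1", session_type = "recurrent") {
  req <- c("episode", "trial", "stimulus", "action", "reward", "correct",
           "noisy")
  miss <- setdiff(req, names(trials))
  if (length(miss))
    stop("behavior_dataset: missing columns: ", paste(miss, collapse = ", "))
  if (!"rt" %in% names(trials)) trials$rt <- NA_real_
  if (is.unsorted(trials$episode))
    stop("behavior_dataset: episodes must be contiguous and ordered")
  has_a <- !is.na(trials$action)
  if (any(trials$stimulus < 1L | trials$stimulus > n_stimuli))
    stop("behavior_dataset: stimulus id out of range")
  if (any(trials$action[has_a] < 1L | trials$action[has_a] > n_actions))
    stop("behavior_dataset: action id out of range")
  bad <- which(has_a &
                 trials$reward != as.integer(xor(trials$correct == 1,
                                                 trials$noisy == 1)))
  if (length(bad))
    stop("behavior_dataset: reward != xor(correct, noisy) at row ", bad[1])
  structure(as.data.frame(trials),
            n_stimuli = as.integer(n_stimuli),
            n_actions = as.integer(n_actions),
            subject = subject, session_type = session_type,
            class = c("behavior_dataset", "data.frame"))
}

#' @export
print.behavior_dataset <- function(x, ...) {
  cat("<behavior_dataset> subject ", attr(x, "subject"), " (",
      attr(x, "session_type"), "): ", nrow(x), " trials, ",
      max(x$episode), " episodes, ", sum(is.na(x$action)), " lapses\n",
      sep = "")
  invisible(x)
}

#' Decode an active-set bitmask
#'
#' Trace rows store the TN active set as a bitmask over population indices
#' (bit `k-1` set means population `k` active), which restricts the engines
#' to at most 31 conjunction populations.
#'
#' @param mask integer bitmask.
#' @return Integer vector of active 1-based population indices.
#' @export
mask_to_pops <- function(mask) {
  which(bitwAnd(mask, bitwShiftL(1L, 0:30)) != 0L)
}

pops_to_mask <- function(pops) {
  if (!length(pops)) return(0L)
  sum(bitwShiftL(1L, as.integer(pops) - 1L))
}

#' One trial of the full two-network model
#'
#' Executes, in order: action selection (forced or sampled from the
#' winner-take-all rule), reward, AN plasticity, TN activation closure from
#' the realized (stimulus, action) conjunction using start-of-trial TN
#' weights, TN temporal plasticity, and — on rewarded trials, when inference
#' is enabled — the inference signal that moves the AN weight of every
#' active TN conjunction toward 1 at rate `j_inc`. A lapse (forced action
#' `NA`) performs no updates and clears the previous-pair memory.
#'
#' @param an,tn current weight matrices.
#' @param params a [model_params()].
#' @param prev_pop previous trial's TN population index, or `NULL`.
#' @param stimulus presented stimulus (1-based).
#' @param forced_action recorded action to force (teacher mode), `NA` for a
#'   lapse, or `NULL` to sample from the policy.
#' @param reward recorded reward (teacher mode), or `NULL` to compute from
#'   `correct_action`/`noisy`.
#' @param correct_action,noisy environment feedback inputs (simulation mode).
#' @param with_inference apply the TN-to-AN inference signal.
#' @param freeze_tn skip TN plasticity (idealized-TN runs).
#' @return A list with updated `an`, `tn`, `prev_pop`, the trial `record`
#'   (action, reward, correct) and the `trace` row (probability vector,
#'   `w_chosen`, active-set mask, inference magnitude).
#' @export
step <- function(an, tn, params, prev_pop, stimulus,
                 forced_action = NULL, reward = NULL,
                 correct_action = NULL, noisy = FALSE,
                 with_inference = TRUE, freeze_tn = FALSE) {
  n_actions <- ncol(an)
  p <- action_probabilities(an, stimulus, params$beta, params$epsilon)

  if (!is.null(forced_action) && is.na(forced_action)) {
    # lapse: no action, no updates, previous-pair memory cleared
    return(list(an = an, tn = tn, prev_pop = NULL,
                record = list(stimulus = stimulus, action = NA_integer_,
                              reward = NA_integer_, correct = NA),
                trace = list(p = p, p_action = NA_real_,
                             p_correct = if (is.null(correct_action) ||
                                             is.na(correct_action)) NA_real_
                                         else p[correct_action],
                             w_chosen = NA_real_, active_mask = 0L,
                             inference_magnitude = 0)))
  }
  action <- if (is.null(forced_action)) sample_action(p)
            else as.integer(forced_action)
  if (is.null(reward)) {
    stopifnot(!is.null(correct_action))
    reward <- as.integer(xor(action == correct_action, noisy))
  }
  correct <- if (!is.null(correct_action)) action == correct_action else NA

  w_chosen <- an[stimulus, action]
  an <- an_update(an, stimulus, action, reward, params$alpha)

  curr <- pop_index(stimulus, action, n_actions)
  active <- tn_activate(tn, curr, params$g_i)
  if (!freeze_tn)
    tn <- tn_update(tn, prev_pop, curr, params$qp, params$qm)

  inf_mag <- 0
  if (with_inference && reward == 1) {
    pairs <- pop_pair(active, n_actions)
    idx <- cbind(pairs[, "stimulus"], pairs[, "action"])
    inf_mag <- mean(params$j_inc * (1 - an[idx]))
    an[idx] <- params$j_inc + (1 - params$j_inc) * an[idx]
  }

  list(an = an, tn = tn, prev_pop = curr,
       record = list(stimulus = stimulus, action = action,
                     reward = reward, correct = correct),
       trace = list(p = p, p_action = p[action],
                    p_correct = if (is.null(correct_action) ||
                                    is.na(correct_action)) NA_real_
                                else p[correct_action],
                    w_chosen = w_chosen, active_mask = pops_to_mask(active),
                    inference_magnitude = inf_mag))
}

run_engine_r <- function(params, n_s, n_a, stimulus, episode,
                         teacher, action = NULL, reward = NULL,
                         correct_action = NULL, noisy = NULL,
                         with_inference = TRUE, tn0 = NULL,
                         freeze_tn = FALSE) {
  n <- length(stimulus)
  an <- an_init(n_s, n_a)
  tn <- if (is.null(tn0)) tn_init(n_s, n_a) else tn0
  prev <- NULL
  out_action <- integer(n); out_reward <- integer(n)
  out_correct <- rep(NA, n)
  p_mat <- matrix(NA_real_, n, n_a)
  p_action <- p_correct <- w_chosen <- inf_mag <- rep(NA_real_, n)
  active_mask <- integer(n)
  for (t in seq_len(n)) {
    st <- step(an, tn, params, prev, stimulus[t],
               forced_action = if (teacher) action[t] else NULL,
               reward = if (teacher && !is.na(action[t])) reward[t] else NULL,
               correct_action = if (!is.null(correct_action))
                 correct_action[t] else NULL,
               noisy = if (is.null(noisy)) FALSE else noisy[t],
               with_inference = with_inference, freeze_tn = freeze_tn)
    an <- st$an; tn <- st$tn; prev <- st$prev_pop
    out_action[t] <- st$record$action
    out_reward[t] <- st$record$reward
    out_correct[t] <- st$record$correct
    p_mat[t, ] <- st$trace$p
    p_action[t] <- st$trace$p_action
    p_correct[t] <- st$trace$p_correct
    w_chosen[t] <- st$trace$w_chosen
    active_mask[t] <- st$trace$active_mask
    inf_mag[t] <- st$trace$inference_magnitude
  }
  list(action = out_action, reward = out_reward, correct = out_correct,
       p = p_mat, p_action = p_action, p_correct = p_correct,
       w_chosen = w_chosen, active_mask = active_mask,
       inference_magnitude = inf_mag, an = an, tn = tn)
}

run_engine <- function(params, n_s, n_a, stimulus, episode, teacher,
                       action = NULL, reward = NULL, correct_action = NULL,
                       noisy = NULL, with_inference = TRUE, tn0 = NULL,
                       freeze_tn = FALSE, engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  if (n_s * n_a > 31L)
    stop("engines support at most 31 conjunction populations")
  n <- length(stimulus)
  if (engine == "R")
    return(run_engine_r(params, n_s, n_a, stimulus, episode, teacher,
                        action, reward, correct_action, noisy,
                        with_inference, tn0, freeze_tn))
  res <- cn_engine(
    as.integer(stimulus) - 1L,
    if (is.null(action)) rep.int(-1L, n) else {
      a <- as.integer(action); a[is.na(a)] <- 0L; a - 1L
    },
    if (is.null(reward)) rep.int(-1L, n) else {
      r <- as.integer(reward); r[is.na(r)] <- -1L; r
    },
    if (is.null(correct_action)) rep.int(-1L, n)
    else as.integer(correct_action) - 1L,
    if (is.null(noisy)) rep(FALSE, n) else as.logical(noisy),
    as.integer(n_s), as.integer(n_a),
    params$alpha, params$beta, params$epsilon, params$qp, params$qm,
    params$g_i, params$j_inc,
    isTRUE(with_inference), isTRUE(teacher), isTRUE(freeze_tn),
    if (is.null(tn0)) matrix(0, 0, 0) else tn0)
  res$action <- ifelse(res$action < 0L, NA_integer_, res$action + 1L)
  res$reward <- ifelse(res$reward < 0L, NA_integer_, res$reward)
  res$correct <- ifelse(is.na(res$action), NA,
                        as.logical(res$correct))
  res
}

engine_trace <- function(res, episode, stimulus, n_a) {
  tr <- data.frame(episode = episode, trial = seq_along(stimulus),
                   stimulus = stimulus, action = res$action,
                   p_action = res$p_action, p_correct = res$p_correct,
                   w_chosen = res$w_chosen, active_mask = res$active_mask,
                   n_active = vapply(res$active_mask,
                                     function(m) length(mask_to_pops(m)), 0L),
                   inference_magnitude = res$inference_magnitude)
  p <- res$p
  colnames(p) <- paste0("p_a", seq_len(n_a))
  tr <- cbind(tr, as.data.frame(p))
  class(tr) <- c("model_trace", "data.frame")
  tr
}

#' Simulate a free-running agent on a session plan
#'
#' The agent samples its own actions from the winner-take-all rule and
#' receives (possibly misleading) feedback from the plan. Per-trial model
#' performance is recorded as the probability assigned to the correct
#' action.
#'
#' @param params a [model_params()].
#' @param plan a [generate_session()] plan.
#' @param with_inference apply the TN-to-AN inference signal.
#' @param tn0 optional initial TN matrix (e.g. [tn_idealized()]).
#' @param freeze_tn hold the TN fixed (idealized-observer runs).
#' @param subject subject id stored in the dataset.
#' @param engine `"cpp"` (compiled trial loop) or `"R"` (reference loop
#'   built from [step()]); both consume the random stream identically.
#' @return A list with `dataset` (a [behavior_dataset()]) and `trace`
#'   (a `model_trace` data.frame: probabilities, `w_chosen`, active-set
#'   mask, inference magnitude per trial).
#' @export
simulate_session <- function(params, plan, with_inference = TRUE,
                             tn0 = NULL, freeze_tn = FALSE, subject = "sim",
                             engine = c("cpp", "R")) {
  cfg <- plan$config
  res <- run_engine(params, cfg$n_stimuli, cfg$n_actions, plan$stimulus,
                    plan$episode, teacher = FALSE,
                    correct_action = plan$correct_action, noisy = plan$noisy,
                    with_inference = with_inference, tn0 = tn0,
                    freeze_tn = freeze_tn, engine = engine)
  trials <- data.frame(
    episode = plan$episode,
    trial = seq_along(plan$stimulus),
    stimulus = plan$stimulus,
    action = res$action,
    reward = res$reward,
    correct = as.integer(res$correct),
    noisy = as.integer(plan$noisy),
    rt = NA_real_,
    correct_action = plan$correct_action)
  ds <- behavior_dataset(trials, cfg$n_stimuli, cfg$n_actions,
                         subject = subject,
                         session_type = cfg$session_type)
  list(dataset = ds,
       trace = engine_trace(res, plan$episode, plan$stimulus, cfg$n_actions))
}

#' Teacher-forced replay of a behavioral dataset
#'
#' Evolves the model's internal state under the subject's recorded actions
#' and rewards and returns the per-trial probability the model assigned to
#' the recorded action — the quantity maximized when fitting. Lapse trials
#' (missing action) trigger no state updates and get probability `NA`.
#'
#' @param params a [model_params()].
#' @param dataset a [behavior_dataset()].
#' @inheritParams simulate_session
#' @return A `model_trace` data.frame, with `p_action` the probability of
#'   the recorded action, and `p_correct` filled when the dataset carries a
#'   `correct_action` column.
#' @export
teacher_forced_run <- function(params, dataset, with_inference = TRUE,
                               tn0 = NULL, freeze_tn = FALSE,
                               engine = c("cpp", "R")) {
  n_s <- attr(dataset, "n_stimuli"); n_a <- attr(dataset, "n_actions")
  if (max(dataset$stimulus) > n_s ||
      max(dataset$action, na.rm = TRUE) > n_a)
    stop("teacher_forced_run: dataset ids exceed the declared set sizes")
  res <- run_engine(params, n_s, n_a, dataset$stimulus, dataset$episode,
                    teacher = TRUE, action = dataset$action,
                    reward = dataset$reward,
                    correct_action = dataset[["correct_action"]],
                    with_inference = with_inference, tn0 = tn0,
                    freeze_tn = freeze_tn, engine = engine)
  engine_trace(res, dataset$episode, dataset$stimulus, n_a)
}
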