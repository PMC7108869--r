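#' Construct a task-set
#'
#' A task-set is a complete, injective map from the session's stimuli to
#' actions: every stimulus has exactly one correct action and no two stimuli
#' share an action.
#'
#' @param actions integer vector, `actions[s]` is the correct action for
#'   stimulus `s` (1-based ids).
#' @param n_actions size of the action set the map draws from.
#' @return An integer vector of class `task_set` with attribute `n_actions`.
#' @examples
#' task_set(c(2, 4, 1), n_actions = 4)
#' @export
task_set <- function(actions, n_actions = max(actions)) {
  actions <- as.integer(actions)
  if (anyNA(actions) || any(actions < 1L) || any(actions > n_actions))
    stop("task_set: action ids must lie in 1..n_actions")
  if (anyDuplicated(actions))
    stop("task_set: map must be injective (two stimuli mapped to one action)")
  structure(actions, n_actions = as.integer(n_actions), class = "task_set")
}

#' @export
print.task_set <- function(x, ...) {
  cat("<task_set> ", paste0("S", seq_along(x), "->A", unclass(x),
                            collapse = "  "), "\n", sep = "")
  invisible(x)
}

#' Number of shared stimulus-action pairs between two task-sets
#'
#' @param a,b task-sets over the same stimulus set.
#' @return Integer count of stimuli for which the two maps agree.
#' @export
taskset_overlap <- function(a, b) {
  if (length(a) != length(b))
    stop("taskset_overlap: task-sets have different stimulus sets")
  sum(unclass(a) == unclass(b))
}

#' Session configuration
#'
#' Collects the design constants of an experimental session. The defaults are
#' the experiment modeled throughout: 3 stimuli, 4 actions, 25 episodes of
#' 36-54 trials, 10% misleading feedback.
#'
#' @param n_stimuli,n_actions sizes of the stimulus and action sets.
#' @param n_episodes episodes per session.
#' @param episode_length_range integer `c(min, max)` trials per episode.
#' @param noise_fraction fraction of trials whose feedback is inverted.
#' @param session_type `"recurrent"` (3 task-sets reoccur) or `"open_ended"`
#'   (a novel task-set every episode).
#' @param n_recurrent_tasksets size of the recurrent pool.
#' @return A list of class `session_config`.
#' @export
session_config <- function(n_stimuli = 3, n_actions = 4, n_episodes = 25,
                           episode_length_range = c(36L, 54L),
                           noise_fraction = 0.10,
                           session_type = c("recurrent", "open_ended"),
                           n_recurrent_tasksets = 3) {
  session_type <- match.arg(session_type)
  stopifnot(n_actions >= n_stimuli, n_stimuli >= 1, n_episodes >= 1,
            length(episode_length_range) == 2,
            episode_length_range[1] <= episode_length_range[2],
            episode_length_range[1] >= 1,
            noise_fraction >= 0, noise_fraction < 1,
            n_recurrent_tasksets >= 1)
  structure(list(
    n_stimuli = as.integer(n_stimuli),
    n_actions = as.integer(n_actions),
    n_episodes = as.integer(n_episodes),
    episode_length_range = as.integer(episode_length_range),
    noise_fraction = noise_fraction,
    session_type = session_type,
    n_recurrent_tasksets = as.integer(n_recurrent_tasksets)
  ), class = "session_config")
}

random_taskset <- function(n_stimuli, n_actions) {
  task_set(sample.int(n_actions, n_stimuli), n_actions)
}

# all injective maps from n_stimuli stimuli into n_actions actions,
# as a list of integer vectors
injective_maps <- function(n_stimuli, n_actions) {
  grow <- function(prefix, depth) {
    if (depth == 0L) return(list(prefix))
    out <- list()
    for (a in setdiff(seq_len(n_actions), prefix))
      out <- c(out, grow(c(prefix, a), depth - 1L))
    out
  }
  grow(integer(0), n_stimuli)
}

#' Draw the pool of recurrent task-sets
#'
#' Returns pairwise non-overlapping injective task-sets: no two sets in the
#' pool share a single stimulus-action pair, so switching between any two of
#' them changes the correct response to every stimulus. Pairwise-disjoint
#' injective maps form a Latin-rectangle-like structure, which exists
#' whenever the number of sets does not exceed the number of actions.
#'
#' @param n_stimuli,n_actions stimulus/action set sizes.
#' @param n_sets number of task-sets to draw.
#' @return A list of `task_set` objects.
#' @export
make_recurrent_tasksets <- function(n_stimuli, n_actions, n_sets = 3) {
  if (n_actions < n_stimuli)
    stop("make_recurrent_tasksets: need n_actions >= n_stimuli")
  if (n_sets > n_actions)
    stop("make_recurrent_tasksets: at most n_actions pairwise-disjoint ",
         "injective task-sets exist")
  # greedy rejection sampling with restarts; feasibility guaranteed by
  # n_sets <= n_actions (Latin rectangle extension)
  for (attempt in seq_len(1000L)) {
    pool <- list(random_taskset(n_stimuli, n_actions))
    while (length(pool) < n_sets) {
      cand <- NULL
      for (tries in seq_len(500L)) {
        cand <- random_taskset(n_stimuli, n_actions)
        if (all(vapply(pool, taskset_overlap, 0L, cand) == 0L)) break
        cand <- NULL
      }
      if (is.null(cand)) break
      pool[[length(pool) + 1L]] <- cand
    }
    if (length(pool) == n_sets) return(pool)
  }
  stop("make_recurrent_tasksets: failed to build a disjoint pool")
}

#' Task-set for the next episode
#'
#' Episode switches are non-overlapping: the returned set shares zero
#' stimulus-action pairs with the previous episode's set. In the recurrent
#' session the draw is uniform over the other pool members; in the open-ended
#' session a fresh injective map is rejection-sampled, also rejecting exact
#' repeats of any set in `exclude`.
#'
#' @param session_type `"recurrent"` or `"open_ended"`.
#' @param previous previous episode's `task_set`, or `NULL` for the first
#'   episode.
#' @param pool recurrent pool (required for `"recurrent"`).
#' @param n_stimuli,n_actions set sizes (open-ended).
#' @param exclude list of task-sets that must not be repeated exactly
#'   (open-ended).
#' @return A `task_set`.
#' @export
next_episode_taskset <- function(session_type, previous = NULL, pool = NULL,
                                 n_stimuli = 3, n_actions = 4,
                                 exclude = list()) {
  if (session_type == "recurrent") {
    if (is.null(pool) || !length(pool))
      stop("next_episode_taskset: recurrent session needs a task-set pool")
    cand <- if (is.null(previous)) pool else
      Filter(function(ts) taskset_overlap(ts, previous) == 0L, pool)
    if (!length(cand))
      stop("next_episode_taskset: no pool member is non-overlapping ",
           "with the previous task-set")
    return(cand[[sample.int(length(cand), 1L)]])
  }
  # enumerate all injective maps and sample uniformly among the admissible
  # ones; the space is tiny (n_actions permute n_stimuli, 24 for 3/4)
  all_maps <- injective_maps(n_stimuli, n_actions)
  keys <- vapply(exclude, function(ts)
    paste(unclass(ts), collapse = ","), "")
  admissible <- Filter(function(m) {
    if (!is.null(previous) && sum(m == unclass(previous)) > 0L) return(FALSE)
    !(paste(m, collapse = ",") %in% keys)
  }, all_maps)
  if (!length(admissible))
    stop("next_episode_taskset: no admissible task-set ",
         "(all injective maps overlap the previous set or are excluded)")
  task_set(admissible[[sample.int(length(admissible), 1L)]], n_actions)
}

#' Generate a session plan
#'
#' Lays out a full session: episode task-sets and lengths, the per-trial
#' stimulus sequence (i.i.d. uniform over stimuli), and the misleading-trial
#' mask. Exactly `round(noise_fraction * n_trials)` trials are noisy, at
#' shuffled positions. Consecutive episodes never share a stimulus-action
#' pair unless an explicit `taskset_schedule` override is given (used to
#' study schedules with overlapping task-sets).
#'
#' @param config a [session_config()].
#' @param taskset_schedule optional list of `task_set`s, one per episode,
#'   overriding the generated schedule (non-overlap is then not enforced).
#' @param pool optional recurrent pool to reuse; drawn if missing.
#' @return A list of class `session_plan` with elements `config`, `pool`,
#'   `tasksets` (per episode), `lengths`, and the per-trial vectors
#'   `episode`, `stimulus`, `correct_action`, `noisy`.
#' @export
generate_session <- function(config = session_config(),
                             taskset_schedule = NULL, pool = NULL) {
  stopifnot(inherits(config, "session_config"))
  nE <- config$n_episodes
  len_min <- config$episode_length_range[1]
  len_max <- config$episode_length_range[2]
  lengths <- len_min + sample.int(len_max - len_min + 1L, nE,
                                  replace = TRUE) - 1L
  if (is.null(taskset_schedule)) {
    tasksets <- vector("list", nE)
    if (config$session_type == "recurrent") {
      if (is.null(pool))
        pool <- make_recurrent_tasksets(config$n_stimuli, config$n_actions,
                                        config$n_recurrent_tasksets)
      prev <- NULL
      for (e in seq_len(nE)) {
        tasksets[[e]] <- next_episode_taskset("recurrent", prev, pool = pool)
        prev <- tasksets[[e]]
      }
    } else {
      prev <- NULL
      for (e in seq_len(nE)) {
        # avoid exact repeats of earlier sets while any admissible novel
        # map remains; with few stimuli/actions the pool of injective maps
        # is finite (4*3*2 = 24 here), so long sessions must eventually
        # relax the novelty constraint and keep only the non-overlap rule
        tasksets[[e]] <- tryCatch(
          next_episode_taskset(
            "open_ended", prev,
            n_stimuli = config$n_stimuli, n_actions = config$n_actions,
            exclude = tasksets[seq_len(e - 1L)]),
          error = function(err) next_episode_taskset(
            "open_ended", prev,
            n_stimuli = config$n_stimuli, n_actions = config$n_actions))
        prev <- tasksets[[e]]
      }
    }
  } else {
    if (length(taskset_schedule) != nE)
      stop("generate_session: taskset_schedule must have one set per episode")
    tasksets <- taskset_schedule
  }
  n <- sum(lengths)
  episode <- rep.int(seq_len(nE), lengths)
  stimulus <- sample.int(config$n_stimuli, n, replace = TRUE)
  correct_action <- vapply(seq_len(n), function(t)
    unclass(tasksets[[episode[t]]])[stimulus[t]], 0L)
  n_noisy <- round(config$noise_fraction * n)
  noisy <- logical(n)
  if (n_noisy > 0) noisy[sample.int(n, n_noisy)] <- TRUE
  structure(list(config = config, pool = pool, tasksets = tasksets,
                 lengths = lengths, episode = episode, stimulus = stimulus,
                 correct_action = correct_action, noisy = noisy),
            class = "session_plan")
}

#' @export
print.session_plan <- function(x, ...) {
  cat("<session_plan> ", x$config$session_type, " session: ",
      length(x$lengths), " episodes, ", sum(x$lengths), " trials, ",
      sum(x$noisy), " noisy\n", sep = "")
  invisible(x)
}

#' Trial feedback
#'
#' Reward is 1 for the correct action and 0 otherwise, inverted on noisy
#' (misleading) trials: `reward = correct XOR noisy`.
#'
#' @param task_set the episode's `task_set`.
#' @param stimulus,action 1-based ids.
#' @param noisy whether this trial's feedback is inverted.
#' @return 0 or 1.
#' @export
feedback <- function(task_set, stimulus, action, noisy = FALSE) {
  n_actions <- attr(task_set, "n_actions")
  if (stimulus < 1L || stimulus > length(task_set))
    stop("feedback: stimulus id out of range")
  if (action < 1L || action > n_actions)
    stop("feedback: action id out of range")
  as.integer(xor(unclass(task_set)[stimulus] == action, noisy))
}

#' Serialize / restore a session plan as JSON
#'
#' @param plan a `session_plan`.
#' @param path file path; `plan_to_json` returns the JSON string invisibly.
#' @return `plan_from_json` returns the restored `session_plan`.
#' @export
plan_to_json <- function(plan, path = NULL) {
  obj <- list(
    config = unclass(plan$config),
    tasksets = lapply(plan$tasksets, function(ts) as.integer(unclass(ts))),
    lengths = plan$lengths,
    stimulus = plan$stimulus,
    noisy = plan$noisy
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) writeLines(js, path)
  invisible(js)
}

#' @rdname plan_to_json
#' @export
plan_from_json <- function(path) {
  obj <- jsonlite::fromJSON(if (file.exists(path)) paste(readLines(path),
                                                         collapse = "") else path,
                            simplifyVector = TRUE)
  cfg <- do.call(session_config, obj$config[c(
    "n_stimuli", "n_actions", "n_episodes", "episode_length_range",
    "noise_fraction", "session_type", "n_recurrent_tasksets")])
  ts_mat <- obj$tasksets
  tasksets <- if (is.matrix(ts_mat))
    lapply(seq_len(nrow(ts_mat)), function(i) task_set(ts_mat[i, ], cfg$n_actions))
  else lapply(ts_mat, task_set, n_actions = cfg$n_actions)
  lengths <- as.integer(obj$lengths)
  episode <- rep.int(seq_along(lengths), lengths)
  stimulus <- as.integer(obj$stimulus)
  correct_action <- vapply(seq_along(stimulus), function(t)
    unclass(tasksets[[episode[t]]])[stimulus[t]], 0L)
  structure(list(config = cfg, pool = NULL, tasksets = tasksets,
                 lengths = lengths, episode = episode, stimulus = stimulus,
                 correct_action = correct_action,
                 noisy = as.logical(obj$noisy)),
            class = "session_plan")
}
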