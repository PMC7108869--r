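# shared fixtures: small task pools, hand-built datasets, independent oracles

fixed_pool <- function() {
  # three pairwise-disjoint task-sets over 3 stimuli / 4 actions
  list(task_set(c(1, 2, 3), 4), task_set(c(2, 3, 4), 4),
       task_set(c(3, 4, 1), 4))
}

small_config <- function(...) {
  session_config(n_episodes = 5, episode_length_range = c(10, 14), ...)
}

# assemble a behavior_dataset from parallel vectors (rewards consistent
# with correct XOR noisy)
make_dataset <- function(episode, stimulus, action, correct_action,
                         noisy = rep(0L, length(stimulus)),
                         n_stimuli = 3, n_actions = 4, subject = "t1") {
  correct <- ifelse(is.na(action), NA_integer_,
                    as.integer(action == correct_action))
  reward <- ifelse(is.na(action), NA_integer_,
                   as.integer(xor(correct == 1, noisy == 1)))
  behavior_dataset(
    data.frame(episode = episode, trial = seq_along(stimulus),
               stimulus = stimulus, action = action, reward = reward,
               correct = correct, noisy = noisy,
               correct_action = correct_action),
    n_stimuli, n_actions, subject = subject)
}

# all permutations of 1..n as a list of integer vectors (tiny n only)
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1)) {
    for (pos in 0:(n - 1))
      out[[length(out) + 1L]] <- append(p, n, after = pos)
  }
  lapply(out, as.integer)
}

# independent softmax-with-lapse evaluation (direct formula, no log-sum-exp)
softmax_oracle <- function(w_row, beta, epsilon) {
  e <- exp(beta * w_row)
  epsilon / length(w_row) + (1 - epsilon) * e / sum(e)
}

# independent directed reachability via boolean matrix powers
reach_oracle <- function(tn, seed, g_i = 0.5) {
  adj <- (tn >= g_i) * 1
  n <- nrow(adj)
  reach <- diag(n)
  for (i in seq_len(n)) reach <- (reach %*% (diag(n) + adj) > 0) * 1
  which(reach[seed, ] > 0)
}

# hand-coded teacher-forced likelihood: re-implements the update equations
# directly from their algebraic form, independent of the package's engines
nll_oracle <- function(params, ds, with_inference = TRUE) {
  n_s <- attr(ds, "n_stimuli"); n_a <- attr(ds, "n_actions")
  an <- matrix(0, n_s, n_a)
  np <- n_s * n_a
  tn <- matrix(0, np, np)
  prev <- NULL
  total <- 0
  for (t in seq_len(nrow(ds))) {
    s <- ds$stimulus[t]; a <- ds$action[t]; r <- ds$reward[t]
    p <- softmax_oracle(an[s, ], params$beta, params$epsilon)
    if (is.na(a)) { prev <- NULL; next }
    total <- total - log(p[a])
    old <- an[s, ]
    if (r == 1) {
      an[s, ] <- old * (1 - params$alpha)
      an[s, a] <- old[a] + params$alpha * (1 - old[a])
    } else {
      an[s, ] <- old + params$alpha * (1 - old)
      an[s, a] <- old[a] * (1 - params$alpha)
    }
    curr <- (s - 1) * n_a + a
    active <- reach_oracle(tn, curr, params$g_i)
    tn[curr, ] <- tn[curr, ] * (1 - params$qm)
    if (!is.null(prev) && prev != curr)
      tn[prev, curr] <- tn[prev, curr] + params$qp * (1 - tn[prev, curr])
    diag(tn) <- 0
    if (with_inference && r == 1) {
      for (k in active) {
        ks <- (k - 1) %/% n_a + 1; ka <- (k - 1) %% n_a + 1
        an[ks, ka] <- an[ks, ka] + params$j_inc * (1 - an[ks, ka])
      }
    }
    prev <- curr
  }
  total
}

default_grid_for_test <- function(variant) chunknet:::default_grid(variant)

# random session + simulated subject, used by several suites
quick_subject <- function(params, config = session_config(), ...) {
  plan <- generate_session(config)
  simulate_session(params, plan, ...)
}
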