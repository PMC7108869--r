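#' Conjunction population indexing
#'
#' TN populations are selective to one (stimulus, action) conjunction. They
#' are indexed `pop = (stimulus - 1) * n_actions + action` (1-based), the
#' row/column order of the TN weight matrix.
#'
#' @param stimulus,action 1-based ids.
#' @param n_actions size of the action set.
#' @return 1-based population index.
#' @export
pop_index <- function(stimulus, action, n_actions) {
  (as.integer(stimulus) - 1L) * as.integer(n_actions) + as.integer(action)
}

#' @rdname pop_index
#' @param pop 1-based population index.
#' @return `pop_pair` returns a `cbind(stimulus, action)` matrix.
#' @export
pop_pair <- function(pop, n_actions) {
  pop <- as.integer(pop) - 1L
  n_actions <- as.integer(n_actions)
  cbind(stimulus = pop %/% n_actions + 1L, action = pop %% n_actions + 1L)
}

#' Initialize task-set-network weights
#'
#' Directed, fully connected weights between all conjunction populations,
#' in \[0, 1\], zero diagonal (no self-synapses). Weights start at 0.
#'
#' @param n_stimuli,n_actions set sizes.
#' @return A `(n_stimuli * n_actions)` square numeric matrix of zeros.
#' @export
tn_init <- function(n_stimuli, n_actions) {
  n <- n_stimuli * n_actions
  matrix(0, n, n)
}

#' Idealized fully chunked task-set network
#'
#' The hand-built TN used to study retrieval in isolation: within each
#' task-set the three conjunction populations are mutually connected at a
#' fixed supra-threshold weight, all other weights are 0. Activating any
#' member of a task-set then retrieves the whole set.
#'
#' @param tasksets list of `task_set`s (e.g. the recurrent pool).
#' @param n_stimuli,n_actions set sizes.
#' @param weight within-cluster weight (default 0.7, above `g_I = 0.5`).
#' @return A TN weight matrix.
#' @export
tn_idealized <- function(tasksets, n_stimuli, n_actions, weight = 0.7) {
  tn <- tn_init(n_stimuli, n_actions)
  for (ts in tasksets) {
    pops <- pop_index(seq_len(n_stimuli), unclass(ts), n_actions)
    tn[pops, pops] <- weight
  }
  diag(tn) <- 0
  tn
}

#' Activation closure in the task-set network
#'
#' The presented (stimulus, action) conjunction activates its population;
#' any population receiving a synapse of weight `>= g_I` from an active
#' population is activated in turn, iterated until no population is added.
#' Equivalently: directed-graph reachability from the seed over the
#' thresholded adjacency matrix. `g_I` plays the role of a uniform
#' inhibitory threshold implementing competition between populations.
#'
#' @param tn TN weight matrix.
#' @param seed 1-based population index of the directly driven conjunction.
#' @param g_i activation threshold (default 0.5).
#' @return Sorted integer vector of active population indices (includes
#'   `seed`).
#' @export
tn_activate <- function(tn, seed, g_i = 0.5) {
  n <- nrow(tn)
  stopifnot(seed >= 1, seed <= n)
  active <- logical(n)
  active[seed] <- TRUE
  frontier <- seed
  while (length(frontier)) {
    reached <- if (length(frontier) == 1L) tn[frontier, ] >= g_i
               else apply(tn[frontier, , drop = FALSE] >= g_i, 2L, any)
    new <- which(reached & !active)
    active[new] <- TRUE
    frontier <- new
  }
  which(active)
}

#' Temporal Hebbian plasticity in the task-set network
#'
#' Two updates per trial: (i) pre-activated depression — every outgoing
#' synapse of the currently driven population decays by factor `(1 - QM)`;
#' (ii) temporal potentiation — the synapse from the previous trial's
#' population to the current one moves toward 1 at rate `QP` (no
#' self-synapse, so a repeated pair is only depressed). The two touch
#' disjoint entries.
#'
#' @param tn TN weight matrix.
#' @param prev previous trial's population index, or `NULL`.
#' @param curr current trial's population index.
#' @param qp potentiation rate in \[0, 1\].
#' @param qm depression rate in \[0, 1\] (default `qp / 10`).
#' @return The updated TN matrix.
#' @export
tn_update <- function(tn, prev, curr, qp, qm = qp / 10) {
  stopifnot(qp >= 0, qp <= 1, qm >= 0, qm <= 1)
  tn[curr, ] <- (1 - qm) * tn[curr, ]
  if (!is.null(prev) && prev != curr)
    tn[prev, curr] <- qp + (1 - qp) * tn[prev, curr]
  diag(tn) <- 0
  tn
}

#' Equilibrium task-set-network weight
#'
#' Under stationary pair statistics where the source pair occurs with
#' probability `p` per trial (and the source-target transition with
#' probability `p^2`, i.i.d. pairs), the expected one-trial update
#' `p^2 * QP * (1 - J) - p * QM * J` vanishes at the fixed point
#' `J* = p * QP / (p * QP + QM)`. Chunking requires `J* > g_I`, which ties
#' the usable `QP/QM` ratio to the threshold.
#'
#' @param p_transition stationary pair probability `p` in \[0, 1\].
#' @param qp,qm potentiation/depression rates.
#' @return The equilibrium weight.
#' @export
tn_equilibrium <- function(p_transition, qp, qm = qp / 10) {
  stopifnot(p_transition >= 0, p_transition <= 1)
  if (p_transition == 0) return(0)
  if (qm == 0) return(1)
  p_transition * qp / (p_transition * qp + qm)
}
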