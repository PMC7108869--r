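#' Initialize associative-network weights
#'
#' The AN holds one plastic weight per stimulus-action synapse, bounded in
#' \[0, 1\] by the soft-bound plasticity rule. Weights start at 0: the policy
#' is then uniform and the first potentiation has maximal head-room.
#'
#' @param n_stimuli,n_actions set sizes.
#' @return A numeric `n_stimuli x n_actions` matrix of zeros.
#' @export
an_init <- function(n_stimuli, n_actions) {
  matrix(0, n_stimuli, n_actions,
         dimnames = list(paste0("S", seq_len(n_stimuli)),
                         paste0("A", seq_len(n_actions))))
}

#' Soft, noisy winner-take-all action probabilities
#'
#' Given the presented stimulus, action `j` is selected with probability
#' `eps/nA + (1 - eps) * exp(beta * J[s, j]) / sum_k exp(beta * J[s, k])`:
#' a softmax over the stimulus's synaptic weights with inverse decision
#' noise `beta`, mixed with a uniform lapse component `eps`. Computed via
#' log-sum-exp for numerical stability.
#'
#' @param an AN weight matrix.
#' @param stimulus 1-based stimulus id.
#' @param beta inverse decision noise (>= 0).
#' @param epsilon undirected-exploration (lapse) probability in \[0, 1\].
#' @return A probability vector over actions (sums to 1).
#' @export
action_probabilities <- function(an, stimulus, beta, epsilon) {
  stopifnot(beta >= 0, epsilon >= 0, epsilon <= 1)
  z <- beta * an[stimulus, ]
  m <- max(z)
  p <- exp(z - m)
  p <- p / sum(p)
  epsilon / ncol(an) + (1 - epsilon) * p
}

#' Sample an action from a probability vector
#'
#' Categorical draw consuming a single uniform variate, so that the R and
#' compiled trial loops consume the random stream identically.
#'
#' @param p probability vector over actions.
#' @return A 1-based action id.
#' @export
sample_action <- function(p) {
  if (abs(sum(p) - 1) > 1e-8 || any(p < 0))
    stop("sample_action: not a probability vector")
  u <- runif(1)
  cum <- cumsum(p)
  a <- findInterval(u, cum) + 1L
  min(a, length(p))
}

#' Reward-modulated Hebbian update of the associative network
#'
#' Only the presented stimulus's row is touched. On reward, the chosen
#' synapse is potentiated toward 1 and the row's other synapses are
#' depressed toward 0; on null reward the roles are exactly reversed. All
#' rates equal the single learning rate `alpha`, and the soft-bound form
#' `J <- rate + (1 - rate) * J` (potentiation) / `J <- (1 - rate) * J`
#' (depression) keeps every weight in \[0, 1\] exactly.
#'
#' @param an AN weight matrix.
#' @param stimulus,action presented stimulus / chosen action (1-based).
#' @param reward 0 or 1.
#' @param alpha learning rate in \[0, 1\].
#' @return The updated weight matrix.
#' @export
an_update <- function(an, stimulus, action, reward, alpha) {
  stopifnot(alpha >= 0, alpha <= 1, reward %in% c(0, 1))
  row <- an[stimulus, ]
  if (reward == 1) {
    row <- (1 - alpha) * row            # depress non-chosen
    row[action] <- alpha + (1 - alpha) * an[stimulus, action]
  } else {
    row <- alpha + (1 - alpha) * row    # potentiate non-chosen
    row[action] <- (1 - alpha) * an[stimulus, action]
  }
  an[stimulus, ] <- row
  an
}
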