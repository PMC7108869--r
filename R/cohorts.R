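#' Synthetic-cohort specification
#'
#' Describes a cohort of simulated subjects standing in for the original
#' participants. Each free parameter is either a point value or a
#' `c(mean, sd)` pair drawn per subject from a normal distribution clipped
#' to the parameter's range. Defaults center on the fitted group means of
#' the modeled experiment (`alpha` 0.35, `qp` 0.17, `j_inc` 0.70 recurrent /
#' 0.16 open-ended), with subject-level spreads on the scale of the
#' reported between-subject variability.
#'
#' @param n_subjects number of subjects.
#' @param session_type `"recurrent"` or `"open_ended"`.
#' @param alpha,beta,epsilon,qp,j_inc point value or `c(mean, sd)`.
#' @param lapse_rate fraction of trials whose action is deleted post hoc
#'   (missing responses).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 22,
                        session_type = c("recurrent", "open_ended"),
                        alpha = c(0.35, 0.034), beta = 7, epsilon = 0.05,
                        qp = c(0.17, 0.033),
                        j_inc = NULL, lapse_rate = 0) {
  session_type <- match.arg(session_type)
  if (is.null(j_inc))
    j_inc <- if (session_type == "recurrent") c(0.70, 0.17) else c(0.16, 0.03)
  stopifnot(n_subjects >= 0, lapse_rate >= 0, lapse_rate < 1)
  structure(list(n_subjects = as.integer(n_subjects),
                 session_type = session_type,
                 alpha = alpha, beta = beta, epsilon = epsilon,
                 qp = qp, j_inc = j_inc, lapse_rate = lapse_rate),
            class = "cohort_spec")
}

draw_param <- function(x, lower = 0, upper = 1) {
  v <- if (length(x) == 1) x else rnorm(1, x[1], x[2])
  min(max(v, lower), upper)
}

#' Generate a synthetic behavioral cohort
#'
#' Draws per-subject parameters from the spec, generates a fresh session
#' plan per subject, simulates the full model on it, and optionally deletes
#' actions at the lapse rate (those trials keep their stimulus but lose
#' action, reward and correctness). Ground-truth parameters are returned
#' alongside the datasets, enabling parameter- and model-recovery
#' experiments.
#'
#' @param spec a [cohort_spec()].
#' @param config [session_config()]; its `session_type` is overridden by
#'   the spec's.
#' @return A list with `datasets` (list of [behavior_dataset()]) and
#'   `truth` (data.frame of generating parameters per subject).
#' @export
generate_cohort <- function(spec = cohort_spec(),
                            config = session_config()) {
  config$session_type <- spec$session_type
  datasets <- vector("list", spec$n_subjects)
  truth <- vector("list", spec$n_subjects)
  for (i in seq_len(spec$n_subjects)) {
    pars <- model_params(
      alpha = draw_param(spec$alpha),
      beta = draw_param(spec$beta, 0, 50),
      epsilon = draw_param(spec$epsilon),
      qp = draw_param(spec$qp),
      j_inc = draw_param(spec$j_inc))
    plan <- generate_session(config)
    sim <- simulate_session(pars, plan, with_inference = TRUE,
                            subject = sprintf("sub%02d", i))
    ds <- sim$dataset
    if (spec$lapse_rate > 0) {
      n_lapse <- round(spec$lapse_rate * nrow(ds))
      if (n_lapse > 0) {
        rows <- sample.int(nrow(ds), n_lapse)
        ds$action[rows] <- NA_integer_
        ds$reward[rows] <- NA_integer_
        ds$correct[rows] <- NA_integer_
      }
    }
    datasets[[i]] <- ds
    truth[[i]] <- data.frame(subject = attr(ds, "subject"),
                             alpha = pars$alpha, beta = pars$beta,
                             epsilon = pars$epsilon, qp = pars$qp,
                             j_inc = pars$j_inc)
  }
  list(datasets = datasets, truth = do.call(rbind, truth))
}

#' Write / read behavioral data as CSV
#'
#' One row per trial with columns `subject`, `session`, `episode`, `trial`,
#' `stimulus`, `action`, `reward`, `correct`, `noisy`, `rt` (plus
#' `correct_action` when available). Missing actions are written as empty
#' fields. Reading validates the `reward == xor(correct, noisy)` invariant
#' and names the offending row on failure.
#'
#' @param dataset a [behavior_dataset()] or list of them (combined into one
#'   file).
#' @param path file path.
#' @export
write_behavior_csv <- function(dataset, path) {
  if (inherits(dataset, "behavior_dataset")) dataset <- list(dataset)
  rows <- lapply(dataset, function(ds) {
    out <- data.frame(subject = attr(ds, "subject"),
                      session = attr(ds, "session_type"),
                      ds[, intersect(c("episode", "trial", "stimulus",
                                       "action", "reward", "correct",
                                       "noisy", "rt", "correct_action"),
                                     names(ds))])
    out
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_behavior_csv
#' @param n_stimuli,n_actions set sizes; inferred from the data when `NULL`.
#' @return `read_behavior_csv` returns a [behavior_dataset()], or a list of
#'   them when the file holds several subjects.
#' @export
read_behavior_csv <- function(path, n_stimuli = NULL, n_actions = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject", "session", "episode", "trial", "stimulus", "action",
           "reward", "correct", "noisy")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("read_behavior_csv: missing columns: ", paste(miss, collapse = ", "))
  if (is.null(n_stimuli)) n_stimuli <- max(df$stimulus)
  if (is.null(n_actions))
    n_actions <- max(c(df$action, df$correct_action), na.rm = TRUE)
  for (col in c("action", "reward", "correct"))
    df[[col]] <- suppressWarnings(as.integer(df[[col]]))
  if (!"rt" %in% names(df)) df$rt <- NA_real_
  out <- lapply(split(df, df$subject), function(sub) {
    sub <- sub[order(sub$trial), ]
    tryCatch(
      behavior_dataset(sub[, setdiff(names(sub), c("subject", "session"))],
                       n_stimuli, n_actions,
                       subject = sub$subject[1],
                       session_type = sub$session[1]),
      error = function(e)
        stop("read_behavior_csv: subject ", sub$subject[1], ": ",
             conditionMessage(e), call. = FALSE))
  })
  if (length(out) == 1) out[[1]] else out
}
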