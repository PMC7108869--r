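#' Negative log-likelihood of a subject's choices
#'
#' Teacher-forces the model through the recorded actions and rewards and
#' accumulates `-log P(recorded action)` over non-lapse trials (Eq.-3
#' probabilities at the evolving weights). Lapse trials are excluded from
#' both the likelihood and the state updates.
#'
#' @param params a [model_params()] (for `"without_inference"` only
#'   `alpha`, `beta`, `epsilon` matter).
#' @param dataset a [behavior_dataset()], or a list of them (e.g. both
#'   sessions of a subject); for a list the model state is re-initialized
#'   per session and the likelihoods summed.
#' @param variant `"with_inference"` or `"without_inference"`.
#' @return Negative log-likelihood in nats.
#' @export
negative_log_likelihood <- function(params, dataset,
                                    variant = c("with_inference",
                                                "without_inference")) {
  variant <- match.arg(variant)
  if (!inherits(dataset, "behavior_dataset") && is.list(dataset))
    return(sum(vapply(dataset, negative_log_likelihood, 0,
                      params = params, variant = variant)))
  if (!nrow(dataset)) stop("negative_log_likelihood: empty dataset")
  a <- as.integer(dataset$action); a[is.na(a)] <- 0L
  r <- as.integer(dataset$reward); r[is.na(r)] <- -1L
  cn_nll(as.integer(dataset$stimulus) - 1L, a - 1L, r,
         attr(dataset, "n_stimuli"), attr(dataset, "n_actions"),
         params$alpha, params$beta, params$epsilon,
         if (variant == "with_inference") params$qp else 0,
         if (variant == "with_inference") params$qm else 0,
         params$g_i,
         if (variant == "with_inference") params$j_inc else 0,
         variant == "with_inference")
}

#' Information criteria (halved-deviance convention)
#'
#' `BIC = -logL + (k/2) * log(n)` and `AIC = -logL + k`, i.e. the negative
#' of the Laplace-approximation model-evidence expression rather than the
#' common `-2 logL` scaling. Only differences between models matter for
#' selection, and on this scale `BIC_with - BIC_without` equals the usual
#' half-deviance difference plus `log(n)` for the two extra parameters.
#' Lower is better.
#'
#' @param logL maximized log-likelihood (nats).
#' @param k number of free parameters (5 with inference, 3 without).
#' @param n number of non-lapse trials.
#' @return A list with `bic` and `aic`.
#' @export
information_criteria <- function(logL, k, n) {
  stopifnot(n >= 1, k >= 1)
  list(bic = -logL + (k / 2) * log(n), aic = -logL + k)
}

free_params <- function(variant) {
  if (variant == "with_inference") c("alpha", "beta", "epsilon", "qp", "j_inc")
  else c("alpha", "beta", "epsilon")
}

param_bounds <- function(variant) {
  nm <- free_params(variant)
  lower <- setNames(rep(0, length(nm)), nm)
  upper <- setNames(rep(1, length(nm)), nm)
  upper["beta"] <- 50
  list(lower = lower, upper = upper)
}

default_grid <- function(variant) {
  g <- list(alpha = c(0.1, 0.35, 0.7), beta = c(2, 7, 15),
            epsilon = c(0.02, 0.1, 0.3), qp = c(0.05, 0.17, 0.4),
            j_inc = c(0.1, 0.4, 0.8))
  g[free_params(variant)]
}

vec_to_params <- function(x, variant) {
  x <- as.list(x)
  if (variant == "without_inference") { x$qp <- 0; x$j_inc <- 0 }
  model_params(alpha = x$alpha, beta = x$beta, epsilon = x$epsilon,
               qp = x$qp, j_inc = x$j_inc)
}

#' Fit the model to one subject by maximum likelihood
#'
#' Grid-seeded multi-start bounded optimization: the negative log-likelihood
#' is evaluated on a coarse factorial grid, the best `n_starts` grid points
#' seed `L-BFGS-B` runs within the parameter bounds
#' (`alpha, epsilon, qp, j_inc` in \[0, 1\], `beta` in \[0, 50\]), and the
#' best converged optimum is returned. Deterministic given the grid,
#' bounds and dataset; ties are broken by lowest negative log-likelihood,
#' then by grid order.
#'
#' @param dataset a [behavior_dataset()] (one subject, one session; sessions
#'   are fitted separately by default), or a list of datasets for a joint
#'   fit across sessions.
#' @param variant `"with_inference"` (5 free parameters) or
#'   `"without_inference"` (3).
#' @param grid named list of candidate values per free parameter; the
#'   default places 3 values per parameter.
#' @param n_starts number of grid points carried into local optimization.
#' @return A list of class `fit_result`: `variant`, `params`,
#'   `log_likelihood`, `n` (non-lapse trials), `k`, `bic`, `aic`, and a
#'   `diagnostics` data.frame of starts and convergence codes.
#' @export
fit_subject <- function(dataset, variant = c("with_inference",
                                             "without_inference"),
                        grid = default_grid(variant), n_starts = 3) {
  variant <- match.arg(variant)
  n_used <- as.integer(if (inherits(dataset, "behavior_dataset"))
    sum(!is.na(dataset$action))
  else sum(vapply(dataset, function(d) sum(!is.na(d$action)), 0)))
  if (n_used < 1) stop("fit_subject: no non-lapse trials to fit")
  nm <- free_params(variant)
  stopifnot(setequal(names(grid), nm))
  b <- param_bounds(variant)
  gpts <- expand.grid(grid[nm], KEEP.OUT.ATTRS = FALSE)
  obj <- function(x) {
    x <- pmin(pmax(x, b$lower), b$upper)
    negative_log_likelihood(vec_to_params(setNames(x, nm), variant),
                            dataset, variant)
  }
  gnll <- vapply(seq_len(nrow(gpts)), function(i)
    obj(as.numeric(gpts[i, ])), 0)
  ord <- order(gnll)
  starts <- ord[seq_len(min(n_starts, length(ord)))]
  runs <- lapply(starts, function(i) {
    res <- tryCatch(
      optim(as.numeric(gpts[i, ]), obj, method = "L-BFGS-B",
            lower = b$lower, upper = b$upper,
            control = list(maxit = 200)),
      error = function(e) NULL)
    if (is.null(res))
      list(par = as.numeric(gpts[i, ]), value = gnll[i],
           convergence = 52L, failed = TRUE)
    else c(res[c("par", "value", "convergence")], failed = FALSE)
  })
  vals <- vapply(runs, function(r) r$value, 0)
  if (all(vapply(runs, function(r) isTRUE(r$failed), TRUE)))
    stop("fit_subject: all optimization starts failed")
  best <- runs[[which.min(vals)]]
  par <- setNames(pmin(pmax(best$par, b$lower), b$upper), nm)
  logL <- -best$value
  k <- length(nm)
  ic <- information_criteria(logL, k, n_used)
  diagnostics <- data.frame(
    start = starts, start_nll = gnll[starts], final_nll = vals,
    convergence = vapply(runs, function(r) as.integer(r$convergence), 0L))
  structure(list(variant = variant, params = vec_to_params(par, variant),
                 free = par, log_likelihood = logL, n = n_used, k = k,
                 bic = ic$bic, aic = ic$aic, diagnostics = diagnostics),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s: logL=%.2f (n=%d, k=%d) BIC=%.2f AIC=%.2f\n",
              x$variant, x$log_likelihood, x$n, x$k, x$bic, x$aic))
  print(x$params)
  invisible(x)
}

#' Fit both model variants and select by BIC
#'
#' @param dataset a [behavior_dataset()].
#' @param ... passed to [fit_subject()].
#' @return A list with both `fit_result`s and `selected`
#'   (`"with_inference"`/`"without_inference"`, lower BIC wins).
#' @export
compare_variants <- function(dataset, ...) {
  fw <- fit_subject(dataset, "with_inference", ...)
  fo <- fit_subject(dataset, "without_inference", ...)
  list(with_inference = fw, without_inference = fo,
       selected = if (fw$bic < fo$bic) "with_inference"
                  else "without_inference")
}

#' Model-recovery experiment
#'
#' Simulates synthetic subjects under each generating variant, fits both
#' variants to every synthetic dataset, and tabulates which variant BIC
#' selects — the sanity check that the two models are distinguishable from
#' behavior of the experiment's size.
#'
#' @param n_subjects subjects per generating variant.
#' @param gen_with,gen_without generating [model_params()] for the two
#'   variants.
#' @param config [session_config()] of the simulated sessions.
#' @param ... passed to [fit_subject()].
#' @return A list with `table` (generator x selected counts) and the
#'   per-subject `details` data.frame.
#' @export
model_recovery <- function(n_subjects,
                           gen_with = model_params(0.35, 7, 0.05,
                                                   qp = 0.17, j_inc = 0.7),
                           gen_without = model_params(0.35, 7, 0.05),
                           config = session_config(), ...) {
  generators <- list(with_inference = gen_with,
                     without_inference = gen_without)
  rows <- list()
  for (g in names(generators)) {
    for (i in seq_len(n_subjects)) {
      plan <- generate_session(config)
      sim <- simulate_session(generators[[g]], plan,
                              with_inference = (g == "with_inference"),
                              subject = paste0(g, "_", i))
      cmp <- compare_variants(sim$dataset, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        generator = g, subject = i, selected = cmp$selected,
        bic_with = cmp$with_inference$bic,
        bic_without = cmp$without_inference$bic)
    }
  }
  details <- if (length(rows)) do.call(rbind, rows) else
    data.frame(generator = character(), subject = integer(),
               selected = character(), bic_with = numeric(),
               bic_without = numeric())
  tab <- table(generator = factor(details$generator,
                                  levels = names(generators)),
               selected = factor(details$selected,
                                 levels = names(generators)))
  list(table = tab, details = details)
}
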