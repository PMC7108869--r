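#' Model parameters
#'
#' The five free parameters of the full model: AN learning rate `alpha`,
#' inverse decision noise `beta` (the fitted quantity is often reported as
#' the noise `1/beta`), lapse probability `epsilon`, TN potentiation rate
#' `qp`, and inference strength `j_inc`. The TN depression rate and the
#' activation threshold are fixed by convention (`qm = qp / 10`,
#' `g_i = 0.5`) so that `qp` is the TN's only free parameter. The
#' without-inference variant is the same model with `j_inc = 0` (equivalently
#' no TN feedback); the equivalence is a tested property.
#'
#' @param alpha AN learning rate in \[0, 1\].
#' @param beta inverse decision noise, >= 0.
#' @param epsilon lapse/uncertainty probability in \[0, 1\].
#' @param qp TN potentiation rate in \[0, 1\].
#' @param j_inc inference strength in \[0, 1\].
#' @param qm TN depression rate (default `qp / 10`).
#' @param g_i TN activation threshold (default 0.5).
#' @return A list of class `model_params`.
#' @export
model_params <- function(alpha, beta, epsilon = 0, qp = 0, j_inc = 0,
                         qm = qp / 10, g_i = 0.5) {
  stopifnot(alpha >= 0, alpha <= 1, beta >= 0,
            epsilon >= 0, epsilon <= 1,
            qp >= 0, qp <= 1, j_inc >= 0, j_inc <= 1,
            qm >= 0, qm <= 1, g_i > 0, g_i <= 1)
  structure(list(alpha = alpha, beta = beta, epsilon = epsilon,
                 qp = qp, j_inc = j_inc, qm = qm, g_i = g_i),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "<model_params> alpha=%.3g beta=%.3g epsilon=%.3g qp=%.3g j_inc=%.3g (qm=%.3g, g_i=%.2g)\n",
    x$alpha, x$beta, x$epsilon, x$qp, x$j_inc, x$qm, x$g_i))
  invisible(x)
}
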