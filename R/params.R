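#' Model parameters for the reinforcement meta-learner
#'
#' Bundles the six fixed scalars of the discrete model together with its
#' structural constants. The defaults are the single parameter set used for
#' every simulation; none of the protocol runners retune them.
#'
#' @param rho Temporal-difference discount factor applied to the successor
#'   value in the dopamine teaching signal (dimensionless, in `[0, 1)`).
#' @param mu Scaling factor distributing the boost modulation `b` between the
#'   primary reward term and the non-primary (TD) term of the dopamine signal
#'   (dimensionless, in `[0, 1]`).
#' @param tau Softmax temperature shared by action selection and boost
#'   selection (value units, > 0).
#' @param alpha Low-pass meta-parameter of the learning-rate filter
#'   (dimensionless, in `(0, 1)`). Encodes the assumption that noise
#'   fluctuates faster than genuine environmental change.
#' @param beta Lower bound on the adaptive learning rate (dimensionless,
#'   in `(0, 1]`).
#' @param omega Cost per unit of catecholamine boosting, charged against the
#'   reward signal sent to the boost controller (value units per boost unit).
#' @param n_boost_levels Number of discrete boost actions (integers
#'   `1..n_boost_levels`).
#'
#' @return An object of class `rml_params` (a validated named list).
#' @examples
#' p <- rml_params()
#' p$tau
#' @export
rml_params <- function(rho = 0.2, mu = 0.1, tau = 0.6, alpha = 0.3,
                       beta = 0.2, omega = 0.15, n_boost_levels = 10L) {
  p <- list(rho = as.numeric(rho), mu = as.numeric(mu), tau = as.numeric(tau),
            alpha = as.numeric(alpha), beta = as.numeric(beta),
            omega = as.numeric(omega),
            n_boost_levels = as.integer(n_boost_levels))
  validate_rml_params(p)
  class(p) <- "rml_params"
  p
}

validate_rml_params <- function(p) {
  num <- c(p$rho, p$mu, p$tau, p$alpha, p$beta, p$omega)
  if (!all(is.finite(num)))
    stop("all model parameters must be finite", call. = FALSE)
  if (p$beta <= 0 || p$beta > 1) stop("beta must be in (0, 1]", call. = FALSE)
  if (p$mu < 0 || p$mu > 1) stop("mu must be in [0, 1]", call. = FALSE)
  if (p$rho < 0 || p$rho >= 1) stop("rho must be in [0, 1)", call. = FALSE)
  if (p$tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (p$alpha <= 0 || p$alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (p$omega < 0) stop("omega must be >= 0", call. = FALSE)
  if (is.na(p$n_boost_levels) || p$n_boost_levels < 1L)
    stop("n_boost_levels must be a positive integer", call. = FALSE)
  invisible(p)
}

#' @export
print.rml_params <- function(x, ...) {
  cat("Reinforcement meta-learner parameters:\n")
  cat(sprintf("  rho=%g mu=%g tau=%g alpha=%g beta=%g omega=%g boost levels=%d\n",
              x$rho, x$mu, x$tau, x$alpha, x$beta, x$omega, x$n_boost_levels))
  invisible(x)
}

#' Lesion specification
#'
#' Multiplicative attenuation of either the dopaminergic (VTA) outputs or of
#' all cortical (dACC) activations. `(1, 1)` is an intact agent.
#'
#' @param da_gain Gain in `(0, 1]` applied to all VTA outputs (both teaching
#'   signals' reward components).
#' @param dacc_gain Gain in `(0, 1]` applied to all dACC value readouts: the
#'   inputs to both softmaxes, the successor value relayed to the VTA, and
#'   the expectation/prediction-error copies relayed to the LC.
#' @return An object of class `rml_lesion`.
#' @examples
#' lesion_spec(da_gain = 0.5)   # dopamine-depleted agent
#' @export
lesion_spec <- function(da_gain = 1, dacc_gain = 1) {
  if (!is.finite(da_gain) || da_gain <= 0 || da_gain > 1)
    stop("da_gain must be in (0, 1]", call. = FALSE)
  if (!is.finite(dacc_gain) || dacc_gain <= 0 || dacc_gain > 1)
    stop("dacc_gain must be in (0, 1]", call. = FALSE)
  structure(list(da_gain = as.numeric(da_gain),
                 dacc_gain = as.numeric(dacc_gain)),
            class = "rml_lesion")
}
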