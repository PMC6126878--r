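# Core module equations: softmax policy, cost-discounted preferences, the
# delta-rule value update, the approximate-Kalman learning-rate filter, and
# the two dopaminergic teaching signals.

#' Softmax choice probabilities
#'
#' `softmax(x_i, tau) = exp(x_i/tau) / sum_j exp(x_j/tau)`, computed with the
#' usual max-subtraction for numerical stability.
#'
#' @param values Finite numeric vector of preferences.
#' @param tau Temperature (> 0). Lower values give greedier choice.
#' @return Probability vector of the same length, summing to 1.
#' @examples
#' softmax_policy(c(0.6, 0), tau = 0.6)
#' @export
softmax_policy <- function(values, tau) {
  if (length(values) == 0L) stop("values must be non-empty", call. = FALSE)
  if (!all(is.finite(values))) stop("values must be finite", call. = FALSE)
  if (!is.finite(tau) || tau <= 0) stop("tau must be > 0", call. = FALSE)
  z <- values / tau
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Cost-discounted action preferences
#'
#' The preference of each action is its (possibly lesion-attenuated) value
#' minus its action cost discounted by the current norepinephrine level:
#' `dacc_gain * v - C / NE`. High NE lowers perceived costs, energizing
#' effortful actions.
#'
#' @param v_row Action values for the current state.
#' @param costs Non-negative action costs `C(s, a)`.
#' @param ne Norepinephrine level (equal to the selected boost level; >= 1).
#' @param dacc_gain Cortical activation gain (1 = intact).
#' @return Numeric preference vector, one entry per action.
#' @export
action_preferences <- function(v_row, costs, ne, dacc_gain = 1) {
  if (length(v_row) != length(costs))
    stop("v_row and costs must have the same length", call. = FALSE)
  if (!is.finite(ne) || ne < 1) stop("ne must be >= 1", call. = FALSE)
  if (any(costs < 0)) stop("costs must be >= 0", call. = FALSE)
  dacc_gain * v_row - costs / ne
}

#' Delta-rule value update
#'
#' `v' = v + lam * (signal - v)`; the prediction error `signal - v` is
#' returned alongside the updated value.
#'
#' @param old_v Stored value.
#' @param signal Teaching signal (dopaminergic input).
#' @param lam Learning rate, already clamped to `[beta, 1]` by the LC filter.
#' @param beta Lower admissible bound for `lam` (validation only).
#' @return `list(value = updated value, pe = prediction error)`.
#' @export
update_value <- function(old_v, signal, lam, beta = 0) {
  if (!is.finite(old_v) || !is.finite(signal))
    stop("value and signal must be finite", call. = FALSE)
  if (!is.finite(lam) || lam < beta || lam > 1)
    stop("lam must lie in [beta, 1]", call. = FALSE)
  pe <- signal - old_v
  list(value = old_v + lam * pe, pe = pe)
}

#' Initialize a learning-rate filter state
#'
#' The filter starts with zero running estimates and the learning rate at its
#' floor `beta`.
#' @param beta Learning-rate floor.
#' @return `list(v_hat, delta_hat, lam)`.
#' @export
rate_filter_state <- function(beta) {
  list(v_hat = 0, delta_hat = 0, lam = beta)
}

#' Approximate-Kalman learning-rate update
#'
#' One step of the noradrenergic learning-rate controller. The process
#' variance is estimated as the squared deviation of the tracked value from
#' its low-passed estimate, the total variance as the squared low-passed
#' unsigned prediction error, and the learning rate as their ratio, clamped
#' to `[beta, 1]`:
#' \preformatted{
#'   Var  = (v_now - v_hat_prev)^2
#'   v_hat'     = v_hat + alpha * (v_now - v_hat)
#'   delta_hat' = delta_hat + alpha * (|delta_now| - delta_hat)
#'   lam        = clamp(Var / delta_hat'^2, beta, 1)
#' }
#' A vanishing `delta_hat'` never divides: the rate clamps to 1 when the
#' process variance is positive and to `beta` when it is zero.
#'
#' @param state Filter state as returned by [rate_filter_state()].
#' @param v_now Currently tracked value readout.
#' @param delta_now Current signed prediction error.
#' @param alpha Low-pass meta-parameter in `(0, 1)`.
#' @param beta Learning-rate floor.
#' @return Updated filter state (`v_hat`, `delta_hat`, `lam`).
#' @export
update_rate_filter <- function(state, v_now, delta_now, alpha, beta) {
  if (!is.finite(v_now) || !is.finite(delta_now))
    stop("filter inputs must be finite", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  var_hat <- (v_now - state$v_hat)^2
  v_hat <- state$v_hat + alpha * (v_now - state$v_hat)
  delta_hat <- state$delta_hat + alpha * (abs(delta_now) - state$delta_hat)
  if (delta_hat == 0) {
    lam <- if (var_hat > 0) 1 else beta
  } else {
    lam <- min(1, max(beta, var_hat / delta_hat^2))
  }
  list(v_hat = v_hat, delta_hat = delta_hat, lam = lam)
}

#' Dopamine teaching signal for the action system
#'
#' `DA = da_gain * [ r * (R + mu*b) + (1 - mu) * b * rho * max_next_v ]`.
#' The boost level `b` amplifies both the primary reward term (through `mu`)
#' and the non-primary TD term carrying conditioned reinforcement. With
#' `mu = 0` and `b = 1` the expression reduces to the standard Q-learning
#' target `r*R + rho * max_a v(s', a)`.
#'
#' @param r Reward-presence indicator (0 or 1).
#' @param R Reward magnitude (>= 0).
#' @param b Boost level (>= 1).
#' @param max_next_v Maximum successor-state value readout (0 at terminal
#'   states).
#' @param params An [rml_params()] object (uses `mu`, `rho`).
#' @param da_gain Dopaminergic gain (1 = intact).
#' @return The scalar dopamine signal.
#' @export
compute_da_act <- function(r, R, b, max_next_v, params, da_gain = 1) {
  stopifnot(r %in% c(0, 1), b >= 1, is.finite(R), is.finite(max_next_v))
  da_gain * (r * (R + params$mu * b) +
               (1 - params$mu) * b * params$rho * max_next_v)
}

#' Dopamine teaching signal for the boost controller
#'
#' `DA_B = r * (da_gain * R - omega * b)`: the primary reward discounted by
#' the cost of catecholamine boosting, charged on reward-presence steps. A
#' dopaminergic lesion attenuates the reward component but leaves the
#' boosting cost intact, which is what makes the lesioned cost-benefit curve
#' decrease monotonically with `b`.
#'
#' @inheritParams compute_da_act
#' @param omega Boosting cost per unit of `b`.
#' @return The scalar dopamine signal to the boost controller.
#' @export
compute_da_boost <- function(r, R, b, omega, da_gain = 1) {
  stopifnot(r %in% c(0, 1), b >= 1, is.finite(R))
  r * (da_gain * R - omega * b)
}
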