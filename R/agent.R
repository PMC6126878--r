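# The agent: mutable value stores, per-module learning-rate filters, and the
# within-trial update loop wiring the four modules together.

#' Construct a reinforcement meta-learner agent
#'
#' The agent holds an action-value table `v(s, a)`, a boost-value table
#' `v_B(s, b)` over the discrete boost levels, and one learning-rate filter
#' per cortical module. All values start at zero and both learning rates at
#' their floor `beta`. The agent is a mutable environment: [run_trial()]
#' updates it in place.
#'
#' @param task An `rml_task` (supplies state and action labels), or `NULL`
#'   if `states`/`actions` are given directly.
#' @param params An [rml_params()] object.
#' @param lesion An [lesion_spec()] object; the default is intact.
#' @param states,actions Character vectors of state and action labels
#'   (ignored when `task` is given).
#' @param boost_clamp Optional integer: clamp the boost level to this value
#'   and take the boost controller offline (used by [boost_sweep()]).
#' @return An object of class `rml_agent`.
#' @examples
#' ag <- rml_agent(states = "s", actions = c("a1", "a2", "stay"))
#' ag$v
#' @export
rml_agent <- function(task = NULL, params = rml_params(),
                      lesion = lesion_spec(), states = NULL, actions = NULL,
                      boost_clamp = NULL) {
  if (!is.null(task)) {
    states <- task$states
    actions <- task$actions
  }
  if (is.null(states) || is.null(actions))
    stop("either a task or explicit states/actions must be supplied",
         call. = FALSE)
  if (!is.null(boost_clamp)) {
    boost_clamp <- as.integer(boost_clamp)
    if (boost_clamp < 1L || boost_clamp > params$n_boost_levels)
      stop("boost_clamp outside the admissible boost range", call. = FALSE)
  }
  ag <- new.env(parent = emptyenv())
  ag$params <- params
  ag$lesion <- lesion
  ag$v <- matrix(0, length(states), length(actions),
                 dimnames = list(states, actions))
  ag$v_B <- matrix(0, length(states), params$n_boost_levels,
                   dimnames = list(states, seq_len(params$n_boost_levels)))
  ag$f_act <- rate_filter_state(params$beta)
  ag$f_boost <- rate_filter_state(params$beta)
  # per-entry low-pass value estimates feeding the process-variance term of
  # the learning-rate filters (lambda and delta_hat remain module-level)
  ag$vhat_act <- ag$v
  ag$vhat_boost <- ag$v_B
  ag$boost_clamp <- boost_clamp
  class(ag) <- "rml_agent"
  ag
}

#' @export
print.rml_agent <- function(x, ...) {
  cat(sprintf("<rml_agent: %d states x %d actions, %d boost levels%s>\n",
              nrow(x$v), ncol(x$v), ncol(x$v_B),
              if (is.null(x$boost_clamp)) ""
              else sprintf(", boost clamped at %d", x$boost_clamp)))
  invisible(x)
}

#' Deep-copy an agent
#'
#' Agents mutate in place; use this to branch a trained agent into
#' independent continuations (e.g. the post-lesion recovery protocols).
#' @param agent An `rml_agent`.
#' @return An independent copy with identical state.
#' @export
clone_agent <- function(agent) {
  ag <- new.env(parent = emptyenv())
  for (nm in ls(agent)) assign(nm, get(nm, envir = agent), envir = ag)
  class(ag) <- "rml_agent"
  ag
}

#' Run one trial
#'
#' Executes a full trial (one step in a bandit, a state chain in a maze) in
#' the fixed module order: the boost controller samples `b` from a softmax
#' over its (gain-scaled) boost values at the trial's initial state; the
#' norepinephrine level is set to `b`; then, for each state until a terminal
#' outcome, the action system samples an action from the cost-discounted
#' softmax, the environment returns an outcome, the VTA computes the
#' dopamine signal, the noradrenergic filter yields the current learning
#' rate, and the action value is updated by the delta rule. At the end of
#' the trial the boost value of the selected `b` is updated with the
#' cost-discounted primary-reward signal.
#'
#' @param agent An [rml_agent()]; mutated in place.
#' @param task An `rml_task`.
#' @param trial 1-based trial index within the task.
#' @return A `trial_record` list: scalars `trial`, `boost`, `ne`, `da_b`,
#'   `pe_boost`, `lam_boost`, and per-step vectors `state`, `action`, `r`,
#'   `R`, `cost`, `next_state`, `da`, `pe_act`, `lam_act`, `v_after` (the
#'   stored value right after its update, for audit replays).
#' @export
run_trial <- function(agent, task, trial = 1L) {
  p <- agent$params
  g_da <- agent$lesion$da_gain
  g_cx <- agent$lesion$dacc_gain
  s0 <- task$start(trial)
  if (!s0 %in% rownames(agent$v)) stop("unknown state: ", s0, call. = FALSE)

  # boost selection (or clamp), then NE = b for the whole trial
  if (is.null(agent$boost_clamp)) {
    pb <- softmax_policy(g_cx * agent$v_B[s0, ], p$tau)
    b <- sample.int(p$n_boost_levels, 1L, prob = pb)
  } else {
    b <- agent$boost_clamp
  }
  ne <- b

  n_act <- ncol(agent$v)
  state <- character(0); action <- character(0)
  r_v <- numeric(0); R_v <- numeric(0); cost_v <- numeric(0)
  nxt_v <- character(0); da_v <- numeric(0); pe_v <- numeric(0)
  lam_v <- numeric(0); vafter_v <- numeric(0)

  s <- s0
  final_r <- 0; final_R <- 0
  repeat {
    costs <- task$costs(s, trial)
    prefs <- action_preferences(agent$v[s, ], costs, ne, g_cx)
    a_idx <- if (n_act == 1L) 1L else
      sample.int(n_act, 1L, prob = softmax_policy(prefs, p$tau))
    a <- colnames(agent$v)[a_idx]
    out <- task$step(s, a, trial)

    max_next_v <- if (is.na(out$next_state)) 0 else
      g_cx * max(agent$v[out$next_state, ])
    da <- compute_da_act(out$r, out$R, b, max_next_v, p, g_da)
    pe <- da - agent$v[s, a_idx]                     # pre-update PE
    # Delta-rule update with the rate currently held by the LC; the filter
    # then ingests the post-update value readout. (The printed recurrences
    # are simultaneous and must be broken one way; ingesting the post-update
    # value keeps the process-variance estimator sensitive to the update
    # steps themselves, which is what lets the rate escalate under genuine
    # environmental change.) The readout is compared against that entry's
    # own low-passed estimate, so switching between actions of unequal
    # value does not masquerade as process variance.
    lam <- agent$f_act$lam
    agent$v[s, a_idx] <- agent$v[s, a_idx] + lam * pe
    fs <- list(v_hat = g_cx * agent$vhat_act[s, a_idx],
               delta_hat = agent$f_act$delta_hat)
    fs <- update_rate_filter(fs, g_cx * agent$v[s, a_idx], g_cx * pe,
                             p$alpha, p$beta)
    agent$vhat_act[s, a_idx] <- fs$v_hat / g_cx
    agent$f_act <- fs

    state <- c(state, s); action <- c(action, a)
    r_v <- c(r_v, out$r); R_v <- c(R_v, out$R); cost_v <- c(cost_v, out$cost)
    nxt_v <- c(nxt_v, out$next_state)
    da_v <- c(da_v, da); pe_v <- c(pe_v, pe); lam_v <- c(lam_v, lam)
    vafter_v <- c(vafter_v, agent$v[s, a_idx])

    if (out$r == 1) { final_r <- 1; final_R <- out$R }
    if (is.na(out$next_state)) break
    s <- out$next_state
  }

  # boost-value update from the trial's primary-reward outcome
  da_b <- compute_da_boost(final_r, final_R, b, p$omega, g_da)
  if (is.null(agent$boost_clamp)) {
    pe_b <- da_b - agent$v_B[s0, b]
    lam_b <- agent$f_boost$lam
    agent$v_B[s0, b] <- agent$v_B[s0, b] + lam_b * pe_b
    fsb <- list(v_hat = g_cx * agent$vhat_boost[s0, b],
                delta_hat = agent$f_boost$delta_hat)
    fsb <- update_rate_filter(fsb, g_cx * agent$v_B[s0, b], g_cx * pe_b,
                              p$alpha, p$beta)
    agent$vhat_boost[s0, b] <- fsb$v_hat / g_cx
    agent$f_boost <- fsb
  } else {
    pe_b <- NA_real_; lam_b <- NA_real_
  }

  structure(list(trial = trial, boost = b, ne = ne, da_b = da_b,
                 pe_boost = pe_b, lam_boost = lam_b,
                 state = state, action = action, r = r_v, R = R_v,
                 cost = cost_v, next_state = nxt_v, da = da_v,
                 pe_act = pe_v, lam_act = lam_v, v_after = vafter_v),
            class = "trial_record")
}

#' Run a block of trials and collect the trace
#'
#' @param agent An [rml_agent()]; mutated in place.
#' @param task An `rml_task`.
#' @param trials Integer vector of trial indices (default: all trials of the
#'   task).
#' @return A long-format data frame with one row per within-trial step and
#'   columns `trial`, `step`, `state`, `boost`, `ne`, `action`, `r`, `R`,
#'   `cost`, `next_state`, `da`, `da_b`, `pe_act`, `pe_boost`, `lam_act`,
#'   `lam_boost`, `v_after`. Boost-side quantities are recorded on each
#'   trial's final step and `NA` elsewhere.
#' @export
run_trials <- function(agent, task, trials = seq_len(task$n_trials)) {
  recs <- vector("list", length(trials))
  for (i in seq_along(trials)) recs[[i]] <- run_trial(agent, task, trials[i])
  trace_from_records(recs)
}

trace_from_records <- function(recs) {
  nsteps <- vapply(recs, function(r) length(r$state), integer(1))
  last <- cumsum(nsteps)
  n <- sum(nsteps)
  boost_col <- rep(vapply(recs, function(r) as.integer(r$boost), integer(1)),
                   nsteps)
  da_b <- pe_b <- lam_b <- rep(NA_real_, n)
  da_b[last] <- vapply(recs, `[[`, numeric(1), "da_b")
  pe_b[last] <- vapply(recs, `[[`, numeric(1), "pe_boost")
  lam_b[last] <- vapply(recs, `[[`, numeric(1), "lam_boost")
  data.frame(
    trial = rep(vapply(recs, function(r) as.numeric(r$trial), numeric(1)),
                nsteps),
    step = unlist(lapply(nsteps, seq_len)),
    state = unlist(lapply(recs, `[[`, "state")),
    boost = boost_col,
    ne = boost_col,
    action = unlist(lapply(recs, `[[`, "action")),
    r = unlist(lapply(recs, `[[`, "r")),
    R = unlist(lapply(recs, `[[`, "R")),
    cost = unlist(lapply(recs, `[[`, "cost")),
    next_state = unlist(lapply(recs, `[[`, "next_state")),
    da = unlist(lapply(recs, `[[`, "da")),
    da_b = da_b,
    pe_act = unlist(lapply(recs, `[[`, "pe_act")),
    pe_boost = pe_b,
    lam_act = unlist(lapply(recs, `[[`, "lam_act")),
    lam_boost = lam_b,
    v_after = unlist(lapply(recs, `[[`, "v_after")),
    stringsAsFactors = FALSE)
}
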