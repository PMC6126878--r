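# Task environments: multi-regime two-armed bandits, effort/reward choice
# tasks, and higher-order conditioning chains (classical and instrumental).
# Every task is a plain list with a common surface: `states`, `actions`,
# `n_trials`, `start(trial)`, `costs(state, trial)`, `step(state, action,
# trial)`. Steppers draw from R's current RNG stream, so a seeded replay is
# bit-identical.

new_task <- function(kind, states, actions, n_trials, start, costs, step,
                     ...) {
  structure(list(kind = kind, states = states, actions = actions,
                 n_trials = as.integer(n_trials), start = start,
                 costs = costs, step = step, ...),
            class = "rml_task")
}

#' @export
print.rml_task <- function(x, ...) {
  cat(sprintf("<rml_task '%s': %d trials, actions: %s>\n", x$kind,
              x$n_trials, paste(x$actions, collapse = ", ")))
  invisible(x)
}

#' Two-armed bandit block in one statistical regime
#'
#' Builds the per-trial reward schedule of one block. Three regimes are
#' supported: `Stat` (stable 70/30 reward probabilities), `Stat2` (stable
#' 60/60, maximal outcome noise, no optimal arm) and `Vol` (the 70/30
#' probability-to-arm mapping permutes on a switch schedule). The
#' lower-probability arm always carries the larger magnitude, while the
#' expected value (probability x magnitude) stays higher for the
#' higher-probability arm, so reward probability is the variable worth
#' tracking.
#'
#' Which arm starts as the high-probability arm is drawn at random, as is
#' the first switch position of a `Vol` block.
#'
#' @param regime One of `"Stat"`, `"Stat2"`, `"Vol"`.
#' @param n_trials Block length.
#' @param p_levels Probabilities of the (high, low) arms in `Stat`/`Vol`.
#' @param m_levels Reward magnitudes tied to the (high, low) probability
#'   arms.
#' @param stat2_p,stat2_m Common probability and magnitude of both arms in
#'   `Stat2`.
#' @param switch_period Trials between mapping permutations in `Vol`.
#' @return A `bandit_block` list with per-trial matrices `p` and `M`
#'   (`n_trials` x 2), the regime label, the scheduled switch trials, and
#'   the per-trial optimal arm (`NA` when there is none).
#' @export
bandit_block <- function(regime = c("Stat", "Stat2", "Vol"), n_trials = 144L,
                         p_levels = c(0.7, 0.3), m_levels = c(1.0, 1.5),
                         stat2_p = 0.6, stat2_m = 1.25,
                         switch_period = 30L) {
  regime <- match.arg(regime)
  n_trials <- as.integer(n_trials)
  p <- matrix(NA_real_, n_trials, 2)
  M <- matrix(NA_real_, n_trials, 2)
  switches <- integer(0)
  if (regime == "Stat2") {
    p[] <- stat2_p
    M[] <- stat2_m
  } else {
    hi <- sample.int(2L, 1L)            # which arm starts high
    if (regime == "Vol") {
      first <- sample.int(switch_period, 1L)
      switches <- seq(first, n_trials, by = switch_period)
      switches <- switches[switches > 1L]
    }
    cur <- hi
    for (t in seq_len(n_trials)) {
      if (t %in% switches) cur <- 3L - cur
      lo <- 3L - cur
      p[t, c(cur, lo)] <- p_levels
      M[t, c(cur, lo)] <- m_levels
    }
  }
  ev <- p * M
  optimal <- ifelse(abs(ev[, 1] - ev[, 2]) < 1e-12, NA_integer_,
                    ifelse(ev[, 1] > ev[, 2], 1L, 2L))
  structure(list(regime = regime, n_trials = n_trials, p = p, M = M,
                 switches = switches, optimal = optimal),
            class = "bandit_block")
}

#' One bandit trial outcome
#'
#' Draws the reward of the chosen arm on a given trial from the block's
#' schedule. The `stay` action returns an all-zero outcome. Arm choices are
#' cost-free.
#'
#' @param block A [bandit_block()] (or the session task built from blocks).
#' @param trial Trial index within the block.
#' @param action `"arm1"`, `"arm2"` or `"stay"`.
#' @return `list(r, R, next_state = NA, cost = 0)`.
#' @export
bandit_step <- function(block, trial, action) {
  if (trial > block$n_trials)
    stop("bandit block exhausted at trial ", trial, call. = FALSE)
  if (action == "stay")
    return(list(r = 0, R = 0, next_state = NA_character_, cost = 0))
  arm <- match(action, c("arm1", "arm2"))
  if (is.na(arm)) stop("unknown bandit action: ", action, call. = FALSE)
  r <- as.numeric(stats::runif(1) < block$p[trial, arm])
  list(r = r, R = block$M[trial, arm], next_state = NA_character_, cost = 0)
}

#' Assemble the three-regime bandit session
#'
#' Concatenates one block per regime (144 trials each by default) into a
#' single 432-trial task sharing one state, so learned arm values carry
#' across regime boundaries as in a continuous session. Block order is
#' supplied by the caller (typically a random permutation per subject).
#'
#' @param order Character permutation of `c("Stat", "Stat2", "Vol")`.
#' @param n_trials Total session length; must be divisible by the number of
#'   regimes.
#' @param ... Passed to [bandit_block()] (schedule parameters).
#' @return An `rml_task` with extra fields `regime` (per-trial label),
#'   `optimal` (per-trial optimal arm index or `NA`), `p`, `M`, `switches`.
#' @export
make_sim1_session <- function(order = c("Stat", "Stat2", "Vol"),
                              n_trials = 432L, ...) {
  order <- match.arg(order, c("Stat", "Stat2", "Vol"), several.ok = TRUE)
  if (length(order) != 3L || anyDuplicated(order))
    stop("order must be a permutation of the three regimes", call. = FALSE)
  n_trials <- as.integer(n_trials)
  if (n_trials %% length(order) != 0L)
    stop("n_trials must be divisible by the number of regimes", call. = FALSE)
  len <- n_trials %/% length(order)
  blocks <- lapply(order, function(rg) bandit_block(rg, n_trials = len, ...))
  p <- do.call(rbind, lapply(blocks, `[[`, "p"))
  M <- do.call(rbind, lapply(blocks, `[[`, "M"))
  regime <- rep(order, each = len)
  optimal <- unlist(lapply(blocks, `[[`, "optimal"))
  offsets <- (seq_along(blocks) - 1L) * len
  switches <- unlist(Map(function(bl, off) bl$switches + off, blocks,
                         offsets))
  sched <- list(n_trials = n_trials, p = p, M = M)
  new_task(kind = "bandit_session", states = "s",
           actions = c("arm1", "arm2", "stay"), n_trials = n_trials,
           start = function(trial) "s",
           costs = function(state, trial) c(0, 0, 0),
           step = function(state, action, trial)
             bandit_step(sched, trial, action),
           regime = regime, optimal = optimal, p = p, M = M,
           switches = switches, order = order)
}

#' Effort/reward two-option choice task
#'
#' A high-reward option and a low-reward option, each with an action cost
#' set by the task variant, plus the always-available zero-cost, zero-reward
#' `stay` option. Rewards are delivered deterministically on choice. In the
#' `Effort` variant the high-reward option is costly and the low-reward
#' option cheap; `NoEffort` makes both cheap; `DoubleEffort` makes both
#' costly.
#'
#' The reward/cost table is a calibrated default of this package (the
#' variant structure is fixed; the numbers are configurable).
#'
#' @param variant `"Effort"`, `"NoEffort"` or `"DoubleEffort"`.
#' @param n_trials Number of trials.
#' @param hr_magnitude,lr_magnitude Reward magnitudes of the two options.
#' @param high_cost,low_cost Action costs of the two effort levels.
#' @return An `rml_task` with actions `HR`, `LR`, `stay`.
#' @export
effort_task <- function(variant = c("Effort", "NoEffort", "DoubleEffort"),
                        n_trials = 150L, hr_magnitude = 1.3,
                        lr_magnitude = 0.4, high_cost = 2.5,
                        low_cost = 0.2) {
  variant <- match.arg(variant)
  cost_hr <- switch(variant, Effort = high_cost, NoEffort = low_cost,
                    DoubleEffort = high_cost)
  cost_lr <- switch(variant, Effort = low_cost, NoEffort = low_cost,
                    DoubleEffort = high_cost)
  opts <- list(HR = list(R = hr_magnitude, cost = cost_hr),
               LR = list(R = lr_magnitude, cost = cost_lr))
  new_task(kind = paste0("effort_", variant), states = "s",
           actions = c("HR", "LR", "stay"), n_trials = n_trials,
           start = function(trial) "s",
           costs = function(state, trial) c(cost_hr, cost_lr, 0),
           step = function(state, action, trial) effort_step(opts, action),
           variant = variant, options = opts)
}

#' One effort-task trial outcome
#'
#' @param opts Option table (`HR`, `LR` entries with `R` and `cost`).
#' @param action `"HR"`, `"LR"` or `"stay"`.
#' @return `list(r, R, next_state = NA, cost)`.
#' @export
effort_step <- function(opts, action) {
  if (action == "stay")
    return(list(r = 0, R = 0, next_state = NA_character_, cost = 0))
  o <- opts[[action]]
  if (is.null(o)) stop("unknown effort action: ", action, call. = FALSE)
  list(r = 1, R = o$R, next_state = NA_character_, cost = o$cost)
}

#' Higher-order conditioning chain
#'
#' A chain of cue states `C<depth>, ..., C2, C1` ending in a primary reward.
#' In the classical paradigm the agent passively observes the cue sequence
#' (one action channel, transitions independent of behaviour; reward rate
#' 100% after the final cue). In the instrumental paradigm every cue state
#' is a binary choice: the correct action advances the chain (and the final
#' correct choice yields the reward with probability 1), any wrong choice
#' terminates the trial unrewarded, and `stay` disengages. All transitions
#' are deterministic and all action costs are zero.
#'
#' @param paradigm `"classical"` or `"instrumental"`.
#' @param depth Conditioning order of the chain (number of cue states).
#' @param start_depth Cue at which trials begin (stage-wise training starts
#'   shallow and moves outward). Defaults to `depth`.
#' @param n_trials Number of trials.
#' @param reward_magnitude Primary reward magnitude at the end of a correct
#'   traversal.
#' @return An `rml_task` whose states cover the full chain depth, so one
#'   agent can be trained stage by stage on tasks of increasing
#'   `start_depth`.
#' @export
chain_task <- function(paradigm = c("classical", "instrumental"), depth = 3L,
                       start_depth = depth, n_trials = 100L,
                       reward_magnitude = 1.0) {
  paradigm <- match.arg(paradigm)
  depth <- as.integer(depth)
  start_depth <- as.integer(start_depth)
  if (start_depth < 1L || start_depth > depth)
    stop("start_depth must be in 1..depth", call. = FALSE)
  states <- paste0("C", seq_len(depth))    # C1 adjacent to reward
  actions <- if (paradigm == "classical") "observe"
             else c("a1", "a2", "stay")
  spec <- list(paradigm = paradigm, depth = depth,
               reward_magnitude = reward_magnitude, correct = "a1")
  new_task(kind = paste0("chain_", paradigm), states = states,
           actions = actions, n_trials = n_trials,
           start = function(trial) paste0("C", start_depth),
           costs = function(state, trial) rep(0, length(actions)),
           step = function(state, action, trial)
             chain_step(spec, state, action),
           paradigm = paradigm, depth = depth, start_depth = start_depth,
           correct = spec$correct)
}

#' One conditioning-chain transition
#'
#' @param spec Chain description (`paradigm`, `depth`, `reward_magnitude`,
#'   `correct` action).
#' @param state Current cue state, `"C<k>"`.
#' @param action Chosen action (ignored in the classical paradigm).
#' @return `list(r, R, next_state, cost)`; `next_state` is `NA` when the
#'   trial terminates.
#' @export
chain_step <- function(spec, state, action) {
  k <- as.integer(sub("^C", "", state))
  if (is.na(k) || k < 1L || k > spec$depth)
    stop("cannot step state ", state, call. = FALSE)
  advance <- spec$paradigm == "classical" || action == spec$correct
  if (!advance)   # wrong choice or disengagement terminates unrewarded
    return(list(r = 0, R = 0, next_state = NA_character_, cost = 0))
  if (k == 1L)
    return(list(r = 1, R = spec$reward_magnitude,
                next_state = NA_character_, cost = 0))
  list(r = 0, R = 0, next_state = paste0("C", k - 1L), cost = 0)
}
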