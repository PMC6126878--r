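# Protocol runners: multi-subject cohorts for the bandit session, the
# effort/lesion battery, the recovery protocols, higher-order conditioning,
# and the clamped-boost cost-benefit sweep.

subject_seed <- function(base_seed, i) as.integer(base_seed) + as.integer(i)

late_window <- function(trials, frac = 0.25) {
  n <- max(trials)
  trials > n - ceiling(frac * n)
}

new_cohort <- function(kind, summary, logs, seeds, ...) {
  structure(list(kind = kind, summary = summary, logs = logs, seeds = seeds,
                 ...),
            class = "rml_cohort")
}

#' @export
print.rml_cohort <- function(x, ...) {
  cat(sprintf("<rml_cohort '%s': %d subjects>\n", x$kind, length(x$seeds)))
  print(utils::head(x$summary, 20))
  invisible(x)
}

#' Simulation of learning-rate adaptation across statistical environments
#'
#' Runs a cohort of intact agents through the 432-trial session made of
#' three 144-trial regimes (stable 70/30, stable 60/60, volatile) in an
#' order randomized per subject. Reports, per subject and regime: the mean
#' learning rate of the action system, the mean unsigned prediction error
#' (the action-system activity proxy), and the optimal-choice percentage
#' among engaged (non-`stay`) trials — scored against the currently
#' higher-expected-value arm, so volatile-block accuracy accounts for all
#' contingency switches. The 60/60 regime has no optimal choice and gets
#' `NA`.
#'
#' @param n_subjects Number of simulated subjects.
#' @param seed Base seed; subject `i` uses `seed + i`.
#' @param params,lesion Model configuration.
#' @param n_trials Session length (divisible by 3).
#' @param ... Schedule parameters passed to [bandit_block()].
#' @return An `rml_cohort` with per-subject `summary` (columns `subject`,
#'   `regime`, `mean_lam`, `mean_abs_pe`, `accuracy` in percent,
#'   `n_engaged`, `mean_boost`) and per-subject trial `logs`.
#' @export
run_simulation1 <- function(n_subjects = 12L, seed = 1L,
                            params = rml_params(), lesion = lesion_spec(),
                            n_trials = 432L, ...) {
  stopifnot(n_subjects >= 1L)
  seeds <- subject_seed(seed, seq_len(n_subjects))
  logs <- vector("list", n_subjects)
  rows <- list()
  for (i in seq_len(n_subjects)) {
    set.seed(seeds[i])
    order <- sample(c("Stat", "Stat2", "Vol"))
    task <- make_sim1_session(order = order, n_trials = n_trials, ...)
    agent <- rml_agent(task, params = params, lesion = lesion)
    log <- run_trials(agent, task)
    log$regime <- task$regime[log$trial]
    log$optimal <- task$optimal[log$trial]
    # scheduled contingencies, for audit replay of the session
    log$p_arm1 <- task$p[log$trial, 1]
    log$p_arm2 <- task$p[log$trial, 2]
    log$m_arm1 <- task$M[log$trial, 1]
    log$m_arm2 <- task$M[log$trial, 2]
    log$switch <- log$trial %in% task$switches
    logs[[i]] <- log
    for (rg in c("Stat", "Stat2", "Vol")) {
      sl <- log[log$regime == rg, ]
      engaged <- sl$action != "stay"
      acc <- if (all(is.na(sl$optimal))) NA_real_ else
        100 * mean(match(sl$action[engaged], c("arm1", "arm2")) ==
                     sl$optimal[engaged])
      rows[[length(rows) + 1L]] <- data.frame(
        subject = i, regime = rg, mean_lam = mean(sl$lam_act),
        mean_abs_pe = mean(abs(sl$pe_act)), accuracy = acc,
        n_engaged = sum(engaged), mean_boost = mean(sl$boost))
    }
  }
  new_cohort("simulation1", do.call(rbind, rows), logs, seeds)
}

effort_phase <- function(agent, variant, n_trials, cfg) {
  task <- effort_task(variant, n_trials = n_trials,
                      hr_magnitude = cfg$hr_magnitude,
                      lr_magnitude = cfg$lr_magnitude,
                      high_cost = cfg$high_cost, low_cost = cfg$low_cost)
  log <- run_trials(agent, task)
  log$phase <- variant
  log
}

effort_defaults <- function() {
  list(hr_magnitude = 1.3, lr_magnitude = 0.4, high_cost = 2.5,
       low_cost = 0.2, n_trials = 150L)
}

effort_metrics <- function(log, frac = 0.25) {
  win <- log[late_window(log$trial, frac), ]
  n_hr <- sum(win$action == "HR"); n_lr <- sum(win$action == "LR")
  data.frame(hr_pref = n_hr / max(1L, n_hr + n_lr),
             stay_frac = mean(win$action == "stay"),
             mean_boost = mean(win$boost),
             mean_reward = mean(win$r * win$R))
}

#' Effort battery with lesion conditions
#'
#' Each subject in each lesion condition first learns the option values in a
#' low-effort task, then faces the effort/reward trade-off task. Reported
#' per phase, over the late-training window: the high-reward preference
#' `HR/(HR+LR)`, the disengagement (`stay`) fraction, and the mean boost
#' level.
#'
#' @param n_subjects Subjects per condition.
#' @param seed Base seed; condition `c`, subject `i` uses the same subject
#'   seed so conditions are paired.
#' @param lesions Named list of [lesion_spec()] conditions.
#' @param params Model parameters.
#' @param effort Task reward/cost table (see `effort_task()` defaults).
#' @param keep_agents Return the trained post-Effort agents (used by the
#'   recovery protocol).
#' @return An `rml_cohort`; `summary` has one row per subject x condition x
#'   phase.
#' @export
run_simulation2a <- function(n_subjects = 12L, seed = 1L,
                             lesions = list(intact = lesion_spec(),
                                            DA = lesion_spec(da_gain = 0.5),
                                            dACC = lesion_spec(dacc_gain = 0.5)),
                             params = rml_params(),
                             effort = effort_defaults(),
                             keep_agents = FALSE) {
  seeds <- subject_seed(seed, seq_len(n_subjects))
  rows <- list(); logs <- list(); agents <- list()
  for (cond in names(lesions)) {
    for (i in seq_len(n_subjects)) {
      set.seed(seeds[i])
      agent <- rml_agent(states = "s", actions = c("HR", "LR", "stay"),
                         params = params, lesion = lesions[[cond]])
      log_ne <- effort_phase(agent, "NoEffort", effort$n_trials, effort)
      log_ef <- effort_phase(agent, "Effort", effort$n_trials, effort)
      for (log in list(log_ne, log_ef)) {
        m <- effort_metrics(log)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(subject = i, condition = cond, phase = log$phase[1]), m)
      }
      key <- sprintf("%s_s%02d", cond, i)
      log_ne$subject <- log_ef$subject <- i
      log_ne$condition <- log_ef$condition <- cond
      logs[[key]] <- rbind(log_ne, log_ef)
      if (keep_agents) agents[[key]] <- agent
    }
  }
  new_cohort("simulation2a", do.call(rbind, rows), logs, seeds,
             agents = if (keep_agents) agents else NULL,
             conditions = names(lesions))
}

#' Recovery protocol after dopaminergic lesion
#'
#' Subjects (dopamine-lesioned and intact controls) complete the effort
#' trade-off phase and are then branched into either a low-effort task
#' (both options cheap) or a double-effort task (both options costly).
#' Reports the high-reward preference and `stay` fraction in each branch.
#'
#' @inheritParams run_simulation2a
#' @return An `rml_cohort`; `summary` has one row per subject x condition x
#'   branch.
#' @export
run_simulation2b <- function(n_subjects = 12L, seed = 1L,
                             params = rml_params(),
                             effort = effort_defaults()) {
  base <- run_simulation2a(n_subjects, seed,
                           lesions = list(intact = lesion_spec(),
                                          DA = lesion_spec(da_gain = 0.5)),
                           params = params, effort = effort,
                           keep_agents = TRUE)
  rows <- list(); logs <- list()
  for (key in names(base$agents)) {
    trained <- base$agents[[key]]
    cond <- sub("_s[0-9]+$", "", key)
    i <- as.integer(sub("^.*_s", "", key))
    for (branch in c("NoEffort", "DoubleEffort")) {
      set.seed(subject_seed(seed, i) + 100000L * match(branch,
                                                       c("NoEffort",
                                                         "DoubleEffort")))
      agent <- clone_agent(trained)
      log <- effort_phase(agent, branch, effort$n_trials, effort)
      m <- effort_metrics(log)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(subject = i, condition = cond, branch = branch), m)
      log$subject <- i; log$condition <- cond
      logs[[paste0(key, "_", branch)]] <- log
    }
  }
  new_cohort("simulation2b", do.call(rbind, rows), logs,
             subject_seed(seed, seq_len(n_subjects)),
             conditions = c("intact", "DA"))
}

#' Higher-order conditioning, classical or instrumental
#'
#' Stage-wise training on a cue chain: first-order conditioning on the cue
#' adjacent to reward, then each successive stage starts one cue further
#' away, using the previously conditioned cue as a non-primary reward. In
#' the classical paradigm the agent passively observes the cue sequence; in
#' the instrumental paradigm each cue is a binary choice and only correct
#' paths are rewarded.
#'
#' The cue-locked dopaminergic response of order `k` is the non-primary
#' (TD) term of the dopamine signal evaluated at that cue —
#' `da_gain * (1-mu) * b_t * rho * dacc_gain * max_a v(C_k, a)` — logged per
#' trial and averaged over the late-training window of the final stage.
#'
#' @param paradigm `"classical"` or `"instrumental"`.
#' @param max_order Number of conditioning stages (chain depth).
#' @param n_subjects,seed Cohort size and base seed.
#' @param params,lesion Model configuration.
#' @param n_trials_per_stage Training trials per conditioning stage.
#' @param window Late-training fraction used for reporting.
#' @return An `rml_cohort`; `summary` has one row per subject x order with
#'   the cue-locked dopamine response, the per-level choice accuracy
#'   (instrumental; `NA` for classical), and the mean boost level of the
#'   final stage.
#' @export
run_simulation3 <- function(paradigm = c("classical", "instrumental"),
                            max_order = 3L, n_subjects = 12L, seed = 1L,
                            params = rml_params(), lesion = lesion_spec(),
                            n_trials_per_stage = 100L, window = 0.25) {
  paradigm <- match.arg(paradigm)
  seeds <- subject_seed(seed, seq_len(n_subjects))
  rows <- list(); logs <- list()
  for (i in seq_len(n_subjects)) {
    set.seed(seeds[i])
    proto <- chain_task(paradigm, depth = max_order)
    agent <- rml_agent(proto, params = params, lesion = lesion)
    cue_resp <- NULL; final_log <- NULL
    for (stage in seq_len(max_order)) {
      task <- chain_task(paradigm, depth = max_order, start_depth = stage,
                         n_trials = n_trials_per_stage)
      recs <- vector("list", task$n_trials)
      resp <- matrix(NA_real_, task$n_trials, max_order)
      for (t in seq_len(task$n_trials)) {
        recs[[t]] <- run_trial(agent, task, t)
        resp[t, ] <- agent$lesion$da_gain * (1 - params$mu) *
          recs[[t]]$boost * params$rho * agent$lesion$dacc_gain *
          apply(agent$v, 1, max)[paste0("C", seq_len(max_order))]
      }
      log <- trace_from_records(recs)
      log$stage <- stage
      if (stage == max_order) { cue_resp <- resp; final_log <- log }
      logs[[sprintf("s%02d_stage%d", i, stage)]] <- log
    }
    win <- late_window(final_log$trial, window)
    win_trials <- unique(final_log$trial[win])
    for (k in seq_len(max_order)) {
      st <- paste0("C", k)
      sl <- final_log[win & final_log$state == st, ]
      chosen <- sl$action[sl$action != "stay"]
      acc <- if (paradigm == "instrumental" && length(chosen) > 0)
        100 * mean(chosen == "a1") else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        subject = i, order = k,
        cue_da = mean(cue_resp[win_trials, k]),
        accuracy = acc,
        mean_boost = mean(final_log$boost[win]),
        n_visits = nrow(sl))
    }
  }
  new_cohort(paste0("simulation3_", paradigm), do.call(rbind, rows), logs,
             seeds, paradigm = paradigm)
}

#' Clamped-boost cost-benefit sweep
#'
#' Clamps the boost level at each value in `b_values` (taking the boost
#' controller offline), runs the effort protocol (low-effort pre-training
#' followed by the given task variant), and reports, per clamped level:
#' performance (mean reward signal reaching the boost controller), boosting
#' cost (mean `omega * b` on rewarded trials), and their difference, the net
#' value. The free-running counterpart of the same protocol is available
#' via [run_simulation2a()].
#'
#' @param variant Effort-task variant for the measured phase.
#' @param lesion Lesion condition.
#' @param b_values Boost levels to clamp.
#' @param n_runs Independent runs per level.
#' @param seed Base seed.
#' @param params Model parameters.
#' @param effort Task reward/cost table.
#' @param window Late-training fraction used for measurement.
#' @return A data frame with one row per clamped level: `b`, `performance`,
#'   `cost`, `net_value`, `hr_pref`, `stay_frac`.
#' @export
boost_sweep <- function(variant = "Effort", lesion = lesion_spec(),
                        b_values = 1:10, n_runs = 40L, seed = 1L,
                        params = rml_params(), effort = effort_defaults(),
                        window = 0.25) {
  if (any(b_values < 1L | b_values > params$n_boost_levels))
    stop("b_values outside the admissible boost range", call. = FALSE)
  out <- lapply(b_values, function(b) {
    perf <- cost <- hr <- stay <- numeric(n_runs)
    for (j in seq_len(n_runs)) {
      set.seed(subject_seed(seed, j) + 1000L * b)
      agent <- rml_agent(states = "s", actions = c("HR", "LR", "stay"),
                         params = params, lesion = lesion, boost_clamp = b)
      effort_phase(agent, "NoEffort", effort$n_trials, effort)
      log <- effort_phase(agent, variant, effort$n_trials, effort)
      win <- log[late_window(log$trial, window), ]
      perf[j] <- mean(win$r * lesion$da_gain * win$R)
      cost[j] <- mean(win$r * params$omega * b)
      n_hr <- sum(win$action == "HR"); n_lr <- sum(win$action == "LR")
      hr[j] <- n_hr / max(1L, n_hr + n_lr)
      stay[j] <- mean(win$action == "stay")
    }
    data.frame(b = b, performance = mean(perf), cost = mean(cost),
               net_value = mean(perf) - mean(cost), hr_pref = mean(hr),
               stay_frac = mean(stay))
  })
  do.call(rbind, out)
}

#' Cohort summary statistics
#'
#' Per-condition means with standard errors, all pairwise paired contrasts
#' (t statistics), and a one-way repeated-measures F test. Statistics are
#' descriptive outputs over whatever per-subject summaries are supplied.
#'
#' @param data Data frame of per-subject, per-condition values.
#' @param value,condition,subject Column names.
#' @return `list(summary, contrasts, anova)`; with a single subject the
#'   standard errors are `NA` and inferential entries are flagged `NA`
#'   rather than failing.
#' @export
summarize_cohort <- function(data, value = "value", condition = "condition",
                             subject = "subject") {
  v <- data[[value]]; cond <- factor(data[[condition]])
  subj <- factor(data[[subject]])
  if (anyNA(v)) stop("summaries contain NA values", call. = FALSE)
  tab <- table(cond, subj)
  if (any(tab != 1L))
    stop("each subject must appear exactly once per condition",
         call. = FALSE)
  agg <- do.call(rbind, lapply(levels(cond), function(cl) {
    x <- v[cond == cl]
    data.frame(condition = cl, mean = mean(x),
               sem = if (length(x) > 1) stats::sd(x) / sqrt(length(x))
                     else NA_real_,
               n = length(x))
  }))
  pairs <- utils::combn(levels(cond), 2, simplify = FALSE)
  contrasts <- do.call(rbind, lapply(pairs, function(pr) {
    x <- v[cond == pr[1]][order(subj[cond == pr[1]])]
    y <- v[cond == pr[2]][order(subj[cond == pr[2]])]
    d <- x - y
    if (length(d) < 2 || stats::sd(d) == 0) {
      tt <- if (all(d == 0)) 0 else NA_real_
      pv <- NA_real_
    } else {
      ht <- stats::t.test(x, y, paired = TRUE)
      tt <- unname(ht$statistic); pv <- ht$p.value
    }
    data.frame(a = pr[1], b = pr[2], mean_diff = mean(d), t = tt, p = pv)
  }))
  aov_tab <- if (nlevels(subj) > 1 && nlevels(cond) > 1) {
    fit <- stats::aov(v ~ cond + Error(subj))
    s <- summary(fit)[["Error: Within"]][[1]]
    data.frame(F = s["cond", "F value"], df1 = s["cond", "Df"],
               df2 = s["Residuals", "Df"], p = s["cond", "Pr(>F)"])
  } else data.frame(F = NA_real_, df1 = NA_real_, df2 = NA_real_,
                    p = NA_real_)
  list(summary = agg, contrasts = contrasts, anova = aov_tab)
}
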