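# Independent straight-line oracles used to cross-check the agent's
# recurrences. These re-implement the update rules directly from their
# printed definitions and are kept free of any package internals.

# Learning-rate filter recurrence applied to a logged (value, PE) trace.
# `entry` identifies which value-table cell each step updated, so the
# low-passed value estimate is kept per entry while delta_hat and lambda
# stay shared, mirroring the module contract. Returns the lambda sequence
# that the module must reproduce bit-identically. `lam[t]` is the rate in
# force BEFORE ingesting step t, starting at beta.
oracle_lam_trace <- function(v_post, delta, entry, alpha, beta) {
  v_hat <- new.env(parent = emptyenv())
  delta_hat <- 0
  lam_cur <- beta
  lams <- numeric(length(v_post))
  for (t in seq_along(v_post)) {
    lams[t] <- lam_cur
    key <- as.character(entry[t])
    vh <- if (is.null(v_hat[[key]])) 0 else v_hat[[key]]
    var_hat <- (v_post[t] - vh)^2
    v_hat[[key]] <- vh + alpha * (v_post[t] - vh)
    delta_hat <- delta_hat + alpha * (abs(delta[t]) - delta_hat)
    lam_cur <- if (delta_hat == 0) {
      if (var_hat > 0) 1 else beta
    } else min(1, max(beta, var_hat / delta_hat^2))
  }
  lams
}

# Closed-form delta rule: after k updates toward a constant target T with
# constant rate lam, the error shrinks by (1 - lam)^k.
oracle_delta_rule <- function(v0, target, lam, k) {
  target - (target - v0) * (1 - lam)^k
}

# Direct evaluation of the printed softmax definition (no max-shift).
oracle_softmax <- function(x, tau) exp(x / tau) / sum(exp(x / tau))

# Mode of a discrete sample (smallest value on ties).
sample_mode <- function(x) {
  tb <- table(x)
  as.integer(names(tb)[which.max(tb)])
}

# Free-running boost levels from an effort-battery cohort log, late window.
late_boosts <- function(cohort, condition, phase, frac = 0.25) {
  keys <- grep(paste0("^", condition, "_"), names(cohort$logs), value = TRUE)
  unlist(lapply(cohort$logs[keys], function(l) {
    ph <- l[l$phase == phase, ]
    n <- max(ph$trial)
    ph$boost[ph$trial > n - ceiling(frac * n)]
  }))
}
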