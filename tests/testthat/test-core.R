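# Module equations: softmax, cost-discounted preferences, delta rule,
# learning-rate filter, and the two dopaminergic teaching signals.

test_that("softmax is a valid, order-preserving, shift-invariant policy", {
  expect_equal(softmax_policy(c(0, 0), 0.6), c(0.5, 0.5))
  expect_equal(softmax_policy(c(3, 3, 3), 1.7), rep(1 / 3, 3))
  # direct evaluation of the printed definition
  expect_equal(softmax_policy(c(0.6, 0), 0.6),
               c(exp(1) / (exp(1) + 1), 1 / (exp(1) + 1)),
               tolerance = 1e-12)
  set.seed(11)
  for (i in 1:25) {
    x <- rnorm(sample(2:6, 1), sd = 3)
    tau <- runif(1, 0.05, 5)
    p <- softmax_policy(x, tau)
    expect_true(all(p >= 0))
    expect_lt(abs(sum(p) - 1), 1e-9)
    expect_equal(order(p), order(x))
    expect_equal(p, softmax_policy(x + rnorm(1, sd = 10), tau),
                 tolerance = 1e-9)
    expect_equal(p, oracle_softmax(x, tau), tolerance = 1e-12)
  }
  expect_error(softmax_policy(c(1, NA), 1), "finite")
  expect_error(softmax_policy(c(1, 2), 0), "tau")
  expect_error(softmax_policy(numeric(0), 1), "non-empty")
})

test_that("norepinephrine divides action costs in the preferences", {
  expect_equal(action_preferences(c(0.3, -1), c(0, 0), ne = 4), c(0.3, -1))
  expect_equal(action_preferences(0.8, 2, ne = 10, dacc_gain = 1), 0.6)
  # low NE makes the effortful action unattractive
  expect_equal(action_preferences(0.5, 2, ne = 1), -1.5)
  expect_equal(action_preferences(c(1, 0.4), c(2, 0.2), ne = 5,
                                  dacc_gain = 0.5),
               c(0.5 - 0.4, 0.2 - 0.04))
  expect_error(action_preferences(1, 1, ne = 0.5), "ne")
  expect_error(action_preferences(1, -1, ne = 2), "costs")
})

test_that("delta rule moves values toward the teaching signal", {
  up <- update_value(0, 1, 0.2)
  expect_equal(up$value, 0.2)
  expect_equal(up$pe, 1)
  expect_equal(update_value(0.7, 0.7, 0.5)$value, 0.7)   # zero PE
  expect_equal(update_value(-2, 3.5, 1)$value, 3.5)      # full update
  expect_error(update_value(0, 1, 0.1, beta = 0.2), "lam")
  expect_error(update_value(0, 1, 1.2), "lam")
  # fixed point: error decays by (1 - lam) per step
  v <- 0.3
  for (k in 1:7) v <- update_value(v, 2, 0.35)$value
  expect_equal(v, oracle_delta_rule(0.3, 2, 0.35, 7), tolerance = 1e-12)
})

test_that("rate filter follows the printed low-pass recurrences", {
  st <- list(v_hat = 0, delta_hat = 0.5, lam = 0.2)
  out <- update_rate_filter(st, v_now = 1, delta_now = 1, alpha = 0.3,
                            beta = 0.2)
  expect_equal(out$v_hat, 0.3)
  expect_equal(out$delta_hat, 0.65)
  expect_equal(out$lam, 1)     # min(1, 1 / 0.65^2)
  # converged tracked value with zero PE pins the rate at the floor
  st <- list(v_hat = 0.8, delta_hat = 0.4, lam = 1)
  for (k in 1:50) {
    st <- update_rate_filter(st, 0.8, 0, alpha = 0.3, beta = 0.2)
    expect_equal(st$lam, 0.2)
  }
  # vanishing delta_hat clamps instead of dividing
  z <- update_rate_filter(rate_filter_state(0.2), v_now = 0.4,
                          delta_now = 0, alpha = 0.3, beta = 0.2)
  expect_equal(z$lam, 1)
  z <- update_rate_filter(rate_filter_state(0.2), v_now = 0, delta_now = 0,
                          alpha = 0.3, beta = 0.2)
  expect_equal(z$lam, 0.2)
  expect_error(update_rate_filter(rate_filter_state(0.2), Inf, 0, 0.3, 0.2),
               "finite")
})

test_that("rate filter raises the learning rate after a mean shift", {
  # oracle simulation: delta-rule learner driven by the filter, i.i.d.
  # Gaussian outcomes with an abrupt mean shift halfway through
  lam_stat <- lam_shift <- numeric(50)
  for (s in 1:50) {
    set.seed(s)
    st <- rate_filter_state(0.2)
    vhat <- 0; v <- 0
    lams <- numeric(1000)
    for (t in 1:1000) {
      mu_t <- if (t <= 500) 0 else 3
      y <- rnorm(1, mu_t, 1)
      d <- y - v
      v <- v + st$lam * d
      st2 <- update_rate_filter(list(v_hat = vhat,
                                     delta_hat = st$delta_hat),
                                v, d, alpha = 0.3, beta = 0.2)
      vhat <- st2$v_hat
      st <- st2
      lams[t] <- st$lam
    }
    lam_stat[s] <- mean(lams[300:500])
    lam_shift[s] <- mean(lams[501:540])
  }
  expect_gt(mean(lam_shift), mean(lam_stat))
})

test_that("dopamine signal to the action system follows the printed form", {
  p <- rml_params()
  expect_equal(compute_da_act(1, 1, 1, 0, p), 1.1)
  expect_equal(compute_da_act(0, 0, 3, 0, p), 0)
  # with mu = 0 and b = 1 the signal is the Q-learning target
  p0 <- rml_params(mu = 0)
  expect_equal(compute_da_act(1, 1, 1, 0.5, p0), 1 + 0.2 * 0.5)
  expect_equal(compute_da_act(1, 1, 1, 0.5, p0),
               1 * 1 + p0$rho * 0.5)
  # gain scales the whole signal
  expect_equal(compute_da_act(1, 2, 4, 0.5, p, da_gain = 0.5),
               0.5 * compute_da_act(1, 2, 4, 0.5, p))
  expect_error(compute_da_act(2, 1, 1, 0, p))
})

test_that("boost teaching signal charges the boosting cost on rewarded steps", {
  expect_equal(compute_da_boost(1, 1, 10, omega = 0.15), -0.5)
  expect_equal(compute_da_boost(0, 1, 7, omega = 0.15), 0)
  expect_equal(compute_da_boost(1, 1, 1, omega = 0.15), 0.85)
  # dopaminergic lesion attenuates the reward component, not the cost
  expect_equal(compute_da_boost(1, 1, 4, omega = 0.15, da_gain = 0.5),
               0.5 - 0.6)
})
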