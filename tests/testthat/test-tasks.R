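# Task generators and steppers: bandit schedules, effort options,
# conditioning chains.

test_that("bandit rewards follow the scheduled probabilities", {
  set.seed(101)
  bl <- bandit_block("Stat", n_trials = 144)
  hi <- bl$optimal[1]
  draws <- replicate(10000, bandit_step(bl, 1, paste0("arm", hi))$r)
  ci <- qbinom(c(0.005, 0.995), 10000, 0.7)
  expect_gte(sum(draws), ci[1])
  expect_lte(sum(draws), ci[2])
  # maximal-uncertainty regime: both arms reward at the same 60% rate
  b2 <- bandit_block("Stat2")
  expect_true(all(b2$p == 0.6))
  d1 <- replicate(5000, bandit_step(b2, 3, "arm1")$r)
  d2 <- replicate(5000, bandit_step(b2, 3, "arm2")$r)
  ci2 <- qbinom(c(0.005, 0.995), 5000, 0.6)
  expect_true(sum(d1) >= ci2[1] && sum(d1) <= ci2[2])
  expect_true(sum(d2) >= ci2[1] && sum(d2) <= ci2[2])
  expect_true(all(is.na(b2$optimal)))
})

test_that("volatile schedule permutes the probability-arm mapping", {
  set.seed(7)
  bl <- bandit_block("Vol", n_trials = 144)
  expect_gt(length(bl$switches), 2)
  for (sw in bl$switches) {
    expect_equal(bl$p[sw, ], bl$p[sw - 1, c(2, 1)])
    expect_equal(bl$M[sw, ], bl$M[sw - 1, c(2, 1)])
  }
  # between switches the mapping is constant
  seg <- bl$p[seq(bl$switches[1], bl$switches[2] - 1), ]
  expect_true(all(seg[, 1] == seg[1, 1]))
})

test_that("expected values favour the high-probability arm in every regime", {
  set.seed(55)
  for (k in 1:10) {
    task <- make_sim1_session(order = sample(c("Stat", "Stat2", "Vol")))
    ev <- task$p * task$M
    vol <- task$regime != "Stat2"
    # high-probability arm has the higher expected value...
    hi <- ifelse(task$p[, 1] > task$p[, 2], 1L, 2L)
    expect_true(all(ev[cbind(seq_len(432), hi)][vol] >
                      ev[cbind(seq_len(432), 3L - hi)][vol]))
    # ...while the low-probability arm carries the larger magnitude
    expect_true(all(task$M[cbind(seq_len(432), 3L - hi)][vol] >
                      task$M[cbind(seq_len(432), hi)][vol]))
    expect_equal(task$optimal[vol], hi[vol])
  }
})

test_that("session assembly respects order, length and determinism", {
  set.seed(2)
  task <- make_sim1_session(order = c("Stat", "Stat2", "Vol"))
  expect_equal(task$n_trials, 432L)
  expect_equal(task$regime, rep(c("Stat", "Stat2", "Vol"), each = 144))
  expect_true(all(task$switches > 288))
  expect_error(make_sim1_session(n_trials = 431L), "divisible")
  expect_error(make_sim1_session(order = c("Stat", "Stat", "Vol")),
               "permutation")
  mk <- function() { set.seed(42); make_sim1_session(order = c("Vol", "Stat",
                                                               "Stat2")) }
  expect_identical(mk()$switches, mk()$switches)
  expect_identical(mk()$p, mk()$p)
  # stepping beyond the schedule is refused
  expect_error(bandit_step(list(n_trials = 10), 11, "arm1"), "exhausted")
})

test_that("effort options pay their scheduled reward and cost", {
  ef <- effort_task("Effort")
  expect_equal(ef$step("s", "stay", 1),
               list(r = 0, R = 0, next_state = NA_character_, cost = 0))
  hr <- ef$step("s", "HR", 1)
  expect_equal(hr$r, 1)
  expect_equal(hr$R, 1.3)
  expect_equal(hr$cost, 2.5)
  expect_equal(ef$step("s", "LR", 1)$cost, 0.2)
  ne <- effort_task("NoEffort")
  expect_equal(ne$costs("s", 1), c(0.2, 0.2, 0))
  de <- effort_task("DoubleEffort")
  expect_equal(de$costs("s", 1), c(2.5, 2.5, 0))
  expect_equal(de$step("s", "HR", 1)$cost, de$step("s", "LR", 1)$cost)
  expect_error(effort_step(ef$options, "jump"), "unknown")
})

test_that("conditioning chains step deterministically", {
  ins <- chain_task("instrumental", depth = 3)
  # correct three-choice path ends in certain primary reward
  s <- "C3"
  for (k in 3:2) {
    out <- ins$step(s, "a1", 1)
    expect_equal(out$r, 0)
    expect_equal(out$next_state, paste0("C", k - 1))
    s <- out$next_state
  }
  out <- ins$step("C1", "a1", 1)
  expect_equal(out$r, 1)
  expect_equal(out$R, 1)
  expect_true(is.na(out$next_state))
  # any wrong choice terminates unrewarded
  for (st in c("C3", "C2", "C1")) {
    out <- ins$step(st, "a2", 1)
    expect_equal(out$r, 0)
    expect_true(is.na(out$next_state))
  }
  expect_error(chain_step(list(paradigm = "classical", depth = 3,
                               reward_magnitude = 1, correct = "a1"),
                          "C4", "a1"), "cannot step")
})

test_that("classical chains are insensitive to behaviour", {
  cl <- chain_task("classical", depth = 3)
  expect_equal(cl$actions, "observe")
  walk <- function(acts) {
    s <- "C3"; seq <- character(0)
    repeat {
      out <- cl$step(s, sample(acts, 1), 1)
      seq <- c(seq, out$next_state)
      if (is.na(out$next_state)) return(list(seq = seq, r = out$r))
      s <- out$next_state
    }
  }
  set.seed(1)
  w1 <- walk("observe")
  w2 <- walk(c("anything", "else"))
  expect_identical(w1$seq, w2$seq)
  expect_equal(w1$r, 1)   # reward rate after the final cue is 100%
  expect_error(chain_task("instrumental", start_depth = 5), "start_depth")
})
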