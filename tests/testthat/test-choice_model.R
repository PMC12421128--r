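test_that("anchored utilities trade points against the aversion value", {
  u4 <- outcome_utilities(4)
  expect_equal(u4[["neg4"]], 0)        # EC = 4: four points exactly offset
  expect_equal(u4[["pos0"]], 0)        # safe anchor
  expect_equal(u4[["starting"]], 0)
  u0 <- outcome_utilities(0)
  expect_equal(u0[["neg6"]], 6)
  expect_equal(u0[["pos2"]], 2)
  expect_equal(outcome_utilities(2)[["neg6"]], 4)
  expect_error(outcome_utilities(-1), "non-negative")
})

test_that("preference log-probabilities are a log-softmax of the utilities", {
  for (ec in c(0, 1, 2.5, 4, 10)) {
    lnC <- preference_log_probs(ec)
    expect_equal(sum(exp(lnC)), 1, tolerance = 1e-12)
    # independent one-liner softmax oracle
    expect_equal(unname(lnC), log(oracle_softmax(oracle_utilities(ec))),
                 tolerance = 1e-12)
  }
  lnC4 <- preference_log_probs(4)
  expect_equal(lnC4[["neg4"]], lnC4[["pos0"]])  # indifference at EC = 4
})

test_that("position values have the expected shape per trial type", {
  # CONF4 at EC = 4: both outcomes equally preferred, so the expected
  # log-preference is constant in position
  v <- action_values(agent_params(1, 4), "CONF4", form = "logpref")
  expect_equal(diff(range(v)), 0, tolerance = 1e-12)
  # risk form on the same trial: symmetric about the midpoint
  vr <- action_values(agent_params(1, 4), "CONF4", form = "risk")
  expect_equal(vr, rev(vr), tolerance = 1e-12)
  # AV trial with a strong aversion: value strictly decreasing toward the
  # aversive cue under both forms
  for (form in c("risk", "logpref")) {
    va <- action_values(agent_params(1, 3), "AV", form = form)
    expect_true(all(diff(va) < 0))
  }
  # expected-log-preference form is strictly decreasing for any ec > 0
  expect_true(all(diff(action_values(agent_params(1, 0.2), "AV",
                                     form = "logpref")) < 0))
})

test_that("choice policies are normalized and match the brute-force oracle", {
  withr::with_seed(11, {
    for (i in 1:40) {
      du <- exp(runif(1, -2, 2))
      ec <- exp(runif(1, -2, 2))
      tt <- sample(aac_trial_types(), 1)
      form <- sample(c("risk", "logpref"), 1)
      p <- choice_policy(agent_params(du, ec), tt, form)
      expect_equal(sum(p), 1, tolerance = 1e-12)
      expect_true(all(p >= 0))  # may underflow to 0 at extreme sharpness
      expect_true(max(p) > 0)
      # oracle enumerates the 2 outcomes x 9 positions directly, without
      # normalizing the preference softmax (checks shift invariance too)
      expect_equal(p, oracle_policy(du, ec, tt, form), tolerance = 1e-10)
    }
  })
})

test_that("temperature limits give uniform and argmax policies", {
  p_hot <- choice_policy(agent_params(1e8, 2), "CONF2")
  expect_equal(p_hot, rep(1 / 9, 9), tolerance = 1e-6)
  p_cold <- choice_policy(agent_params(1e-3, 0), "APP")
  expect_equal(p_cold[9], 1, tolerance = 1e-6)
  expect_error(choice_policy(list(du = 0, ec = 1), "APP"), "positive")
  # CONF4 at EC = 4 is symmetric under the risk form
  p_sym <- choice_policy(agent_params(2, 4), "CONF4")
  expect_equal(p_sym, rev(p_sym), tolerance = 1e-12)
})

test_that("approach mass is non-increasing in EC and entropy non-decreasing in DU", {
  for (tt in c("CONF2", "CONF4", "CONF6")) {
    approach <- vapply(seq(0, 8, by = 0.5), function(ec) {
      sum(choice_policy(agent_params(50, ec), tt)[6:9])
    }, numeric(1))
    expect_true(all(diff(approach) <= 1e-12))
  }
  for (ec in c(0, 2, 5)) {
    ents <- vapply(exp(seq(-2, 3, by = 0.25)), function(du) {
      choice_entropy(choice_policy(agent_params(du, ec), "CONF6"))
    }, numeric(1))
    expect_true(all(diff(ents) >= -1e-12))
  }
})

test_that("choice entropy handles uniform, degenerate and two-point cases", {
  expect_equal(choice_entropy(rep(1 / 9, 9)), log(9))
  expect_equal(choice_entropy(c(1, rep(0, 8))), 0)
  expect_equal(choice_entropy(c(0.5, 0.5, rep(0, 7))), log(2))
  expect_error(choice_entropy(c(0.5, 0.4)), "probability")
})
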