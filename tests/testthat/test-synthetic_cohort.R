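test_that("subject simulation has the right structure and determinism", {
  design <- build_task_design(seed = 1)
  dat <- simulate_subject(agent_params(40, 3), design, seed = 9)
  expect_equal(nrow(dat), 60L)
  expect_true(all(dat$chosen_position %in% 1:9))
  expect_true(all(dat$rt >= 0.1))
  expect_identical(dat, simulate_subject(agent_params(40, 3), design, seed = 9))
  expect_false(identical(dat$chosen_position,
                         simulate_subject(agent_params(40, 3), design,
                                          seed = 10)$chosen_position))
  # realized outcomes lie in the trial's two-outcome support
  hi <- c(AV = "neg0", APP = "pos2", CONF2 = "neg2", CONF4 = "neg4",
          CONF6 = "neg6")
  expect_true(all(dat$outcome_name == hi[dat$trial_type] |
                    dat$outcome_name == "pos0"))
})

test_that("a near-greedy reward-seeking agent approaches on APP trials", {
  dat <- simulate_subject(agent_params(0.01, 1e-8),
                          build_task_design(seed = 2, n_per_type = 40),
                          seed = 3)
  app <- dat[dat$trial_type == "APP", ]
  expect_gte(mean(app$chosen_position == 9L), 0.95)
})

test_that("simulated choice frequencies converge to the policy", {
  params <- agent_params(40, 2.5)
  dat <- simulate_subject(params, build_task_design(seed = 4, n_per_type = 2000),
                          seed = 5)
  for (tt in c("AV", "CONF4")) {
    obs <- tabulate(dat$chosen_position[dat$trial_type == tt], nbins = 9)
    expected <- choice_policy(params, tt)
    gof <- suppressWarnings(chisq.test(obs, p = expected))
    expect_gt(gof$p.value, 0.001)
  }
})

test_that("cohort moments, attrition and coupling match the group spec", {
  spec <- group_spec("HC", 1000, ec_mean = 3.53, ec_sd = 3.57,
                     du_mean = 3.96, du_sd = 4.65, attrition_prob = 0.25)
  # moment check on the latent draws only (no task simulation needed)
  ln <- withr::with_seed(61, {
    s2 <- log(1 + (3.57 / 3.53)^2)
    exp(rnorm(1e5, log(3.53) - s2 / 2, sqrt(s2)))
  })
  expect_lt(abs(mean(ln) - 3.53), 3 * 3.57 / sqrt(1e5))

  small <- group_spec("HC", 300, ec_mean = 3.53, ec_sd = 3.57,
                      du_mean = 3.96, du_sd = 4.65, attrition_prob = 0.25)
  cohort <- sample_cohort(list(small), seed = 7, n_per_type = 2)
  base <- cohort$subjects[cohort$subjects$visit == "baseline", ]
  expect_equal(nrow(base), 300L)
  expect_lt(abs(mean(base$true_ec) - 3.53), 3 * 3.57 / sqrt(300))
  expect_lt(abs(mean(base$true_du) - 3.96), 3 * 4.65 / sqrt(300))
  # realized attrition within a binomial CI of the spec
  n_fu <- sum(cohort$subjects$visit == "followup")
  expect_lt(abs((300 - n_fu) / 300 - 0.25), 3 * sqrt(0.25 * 0.75 / 300))
  # zero attrition keeps everyone
  cohort0 <- sample_cohort(list(group_spec("SUD", 40, 1.69, 1.94, 5.26, 5.72,
                                           attrition_prob = 0)),
                           seed = 8, n_per_type = 1)
  expect_equal(sum(cohort0$subjects$visit == "followup"), 40L)
  expect_warning(sample_cohort(list(group_spec("HC", 0, 1, 1, 1, 1))), "n = 0")
})

test_that("perfect cross-visit correlation yields near-perfect latent ICC", {
  spec <- group_spec("HC", 200, ec_mean = 3.53, ec_sd = 3.57,
                     du_mean = 3.96, du_sd = 4.65, attrition_prob = 0,
                     visit_param_correlation = 1)
  cohort <- sample_cohort(list(spec), seed = 9, n_per_type = 1)
  w <- reshape(cohort$subjects[, c("subject_id", "visit", "true_ec")],
               idvar = "subject_id", timevar = "visit", direction = "wide")
  expect_gt(icc_3_1(log(w$true_ec.baseline), log(w$true_ec.followup))$icc,
            0.99)
})

test_that("entropy-RT coupling is monotone in the target and hits group presets", {
  realized_r <- function(target, n = 150, seed0 = 70) {
    spec <- group_spec("SUD", n, ec_mean = 1.69, ec_sd = 1.94,
                       du_mean = 5.26, du_sd = 5.72, attrition_prob = 0.9,
                       rt_target_r = target)
    cohort <- sample_cohort(list(spec), seed = seed0)
    base <- cohort$trials[cohort$trials$visit == "baseline", ]
    truth <- cohort$subjects[cohort$subjects$visit == "baseline", ]
    rs <- vapply(seq_len(nrow(truth)), function(i) {
      sub <- base[base$subject_id == truth$subject_id[i], ]
      as.numeric(suppressWarnings(entropy_rt_correlation(
        sub, agent_params(truth$true_du[i], truth$true_ec[i]))))
    }, numeric(1))
    mean(rs, na.rm = TRUE)
  }
  r_low <- realized_r(0.05)
  r_high <- realized_r(0.40)
  expect_lt(r_low, r_high)
  # group presets reproduce the target mean correlations
  expect_lt(abs(realized_r(0.16, n = 300) - 0.16), 0.03)
  expect_lt(abs(realized_r(0.11, n = 300, seed0 = 71) - 0.11), 0.03)
})

test_that("cohort serialization round-trips through the trial CSV", {
  cohort <- sample_cohort(list(group_spec("DEP_ANX", 4, 2.97, 3.06, 4.14,
                                          4.57, attrition_prob = 0.3)),
                          seed = 11, n_per_type = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(cohort$trials, path)
  back <- read_trials(path)
  expect_equal(attr(back, "n_rejected"), 0L)
  expect_equal(nrow(back), nrow(cohort$trials))
  expect_equal(back$chosen_position, cohort$trials$chosen_position)
})
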