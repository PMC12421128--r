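make_dataset <- function(du, ec, n_per_type = 12, seed = 1) {
  simulate_subject(agent_params(du, ec),
                   build_task_design(seed = seed, n_per_type = n_per_type),
                   seed = seed + 100)
}

test_that("log-likelihood matches the brute-force per-trial sum", {
  withr::with_seed(21, {
    for (i in 1:10) {
      du <- exp(runif(1, -1.5, 1.5))
      ec <- exp(runif(1, -1.5, 1.5))
      dat <- make_dataset(2, 2, seed = i)
      expect_equal(log_likelihood(agent_params(du, ec), dat),
                   oracle_loglik(du, ec, dat), tolerance = 1e-10)
    }
  })
})

test_that("log-likelihood is trial-order invariant and hits the uniform limit", {
  dat <- make_dataset(2, 3)
  perm <- withr::with_seed(5, dat[sample.int(nrow(dat)), ])
  p <- agent_params(1.3, 2.2)
  expect_equal(log_likelihood(p, dat), log_likelihood(p, perm))
  # near-infinite temperature: every choice has probability 1/9
  expect_equal(log_likelihood(agent_params(1e9, 1), dat), 60 * log(1 / 9),
               tolerance = 1e-4)
  expect_error(log_likelihood(p, dat[0, ]), "at least one trial")
})

test_that("MAP fit recovers generating parameters and dominates the grid oracle", {
  dat <- make_dataset(8, 2.5, n_per_type = 120, seed = 3)  # 600 trials
  fit <- fit_map(dat)
  expect_true(fit$converged)
  expect_lt(abs(fit$du_hat - 8) / 8, 0.2)
  expect_lt(abs(fit$ec_hat - 2.5) / 2.5, 0.2)
  expect_true(all(eigen(fit$posterior_cov, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
  g <- fit_grid(dat)
  expect_gte(fit$log_joint, g$log_joint - 1e-3)
  # a single-node grid returns that node
  g1 <- fit_grid(dat, log_du = 0.5, log_ec = 0.7)
  expect_equal(unname(g1$log_params), c(0.5, 0.7))
  expect_error(fit_grid(dat, log_du = numeric(0)), "grid")
})

test_that("grid profile over EC peaks near the symmetric truth", {
  # CONF4-heavy data generated at EC = 4: profile maximized near log(4)
  design <- build_task_design(seed = 9, n_per_type = 60)
  dat <- simulate_subject(agent_params(1, 4), design, seed = 10)
  dat <- dat[dat$trial_type == "CONF4", ]
  g <- fit_grid(dat, log_du = 0, log_ec = seq(0.5, 2.5, length.out = 41))
  expect_lt(abs(g$log_params[["log_ec"]] - log(4)), 0.4)
})

test_that("posterior variance shrinks with more trials on average", {
  vars <- vapply(1:10, function(s) {
    small <- fit_map(make_dataset(8, 2.5, n_per_type = 12, seed = s))
    big <- fit_map(make_dataset(8, 2.5, n_per_type = 48, seed = s))
    c(diag(small$posterior_cov), diag(big$posterior_cov))
  }, numeric(4))
  # mean variance over seeds, per parameter: 4x the data should not inflate
  expect_lt(mean(vars[3, ]), mean(vars[1, ]))  # log-DU
  expect_lt(mean(vars[4, ]), mean(vars[2, ]))  # log-EC
})

test_that("fit metrics match hand computation and the chance construction", {
  # hand-built 3-trial example at EC = 0, low temperature: position 9 is
  # the unique argmax on APP trials
  p <- agent_params(0.5, 0)
  pol <- choice_policy(p, "APP")
  dat <- data.frame(trial_type = "APP", chosen_position = c(9L, 9L, 1L))
  m <- fit_metrics(p, dat)
  expect_equal(m[["avg_action_probability"]],
               mean(pol[c(9, 9, 1)]), tolerance = 1e-12)
  expect_equal(m[["accuracy"]], 2 / 3)
  # balanced chance construction: one trial per (type, position) pair gives
  # accuracy exactly 1/9 whenever each type's argmax is unique
  chance <- expand.grid(trial_type = aac_trial_types(),
                        chosen_position = 1:9, stringsAsFactors = FALSE)
  mc <- fit_metrics(agent_params(1e5, 2), chance)
  expect_equal(mc[["accuracy"]], 1 / 9)
  expect_equal(mc[["avg_action_probability"]], 1 / 9, tolerance = 1e-3)
})

test_that("the skew-minimizing log transform behaves", {
  x <- withr::with_seed(31, rlnorm(1000, 0, 1))
  tr <- optlog_transform(x)
  expect_lt(abs(tr$skewness), abs(tr$skewness_before))
  expect_equal(length(tr$values), 1000L)
  # already-symmetric input is not made materially worse
  y <- withr::with_seed(32, rnorm(500, 10, 1))
  tr2 <- optlog_transform(y)
  expect_lt(abs(tr2$skewness), abs(tr2$skewness_before) + 0.05)
  # constant input: skewness defined as 0, transform monotone
  tr3 <- optlog_transform(rep(2, 10))
  expect_equal(tr3$skewness, 0)
  expect_true(all(diff(tr3$values) == 0))
  expect_error(optlog_transform(c(-200, 1)), "positive")
})
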