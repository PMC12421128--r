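make_fit_table <- function(n, seed) {
  withr::with_seed(seed, {
    ids <- sprintf("S%03d", seq_len(n))
    do.call(rbind, lapply(c("baseline", "followup"), function(v) {
      data.frame(subject_id = ids, visit = v,
                 log_du = rnorm(n), log_ec = rnorm(n))
    }))
  })
}

test_that("feature tables carry exactly the chosen predictor set", {
  n <- 30
  fits <- make_fit_table(n, 81)
  demo <- withr::with_seed(82, data.frame(
    subject_id = sprintf("S%03d", 1:n),
    label = rep(0:1, length.out = n),
    sex = sample(c("female", "male"), n, replace = TRUE),
    age = runif(n, 18, 55)))
  beh <- data.frame(subject_id = sprintf("S%03d", 1:n),
                    entropy_rt_r = withr::with_seed(83, runif(n, -0.2, 0.5)))
  t1 <- build_feature_table(fits, demo, predictor_set = 1)
  expect_setequal(attr(t1, "features"), c("age", "sex"))
  t5 <- build_feature_table(fits, demo, beh, predictor_set = 5)
  expect_length(attr(t5, "features"), 7L)
  expect_true(all(t5$sex %in% c(-1, 1)))
  expect_equal(mean(demo$age) + mean(t5$age) * 0, mean(demo$age))  # centered
  expect_lt(abs(mean(t5$age)), 1e-9)
  # subject missing follow-up: excluded from set 2, retained in set 1
  fits_miss <- fits[!(fits$subject_id == "S001" & fits$visit == "followup"), ]
  t1m <- build_feature_table(fits_miss, demo, predictor_set = 1)
  expect_equal(nrow(t1m), n)
  t2m <- suppressMessages(build_feature_table(fits_miss, demo,
                                              predictor_set = 2))
  expect_equal(nrow(t2m), n - 1L)
  expect_false("S001" %in% t2m$subject_id)
})

test_that("prediction metrics match hand computation and a reference AUC", {
  perfect <- evaluate_predictions(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$balanced_accuracy, 1)
  flat <- evaluate_predictions(rep(0.5, 6), c(1, 1, 1, 0, 0, 0))
  expect_equal(flat$auc, 0.5)
  expect_equal(flat$sensitivity, 1)   # >= threshold counts positive
  expect_equal(flat$specificity, 0)
  expect_equal(flat$balanced_accuracy, 0.5)
  # toy confusion TP=3 FN=1 TN=2 FP=2
  probs <- c(0.9, 0.8, 0.7, 0.2, 0.6, 0.9, 0.1, 0.3)
  labs <- c(1, 1, 1, 1, 0, 0, 0, 0)
  m <- evaluate_predictions(probs, labs)
  expect_equal(c(m$tp, m$fn, m$tn, m$fp), c(3, 1, 2, 2))
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 0.5)
  expect_equal(m$balanced_accuracy, 0.625)
  # rank AUC agrees with an established implementation
  withr::with_seed(84, {
    p <- runif(200)
    y <- rbinom(200, 1, 0.4)
  })
  expect_equal(evaluate_predictions(p, y)$auc,
               as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE))),
               tolerance = 1e-10)
  expect_true(is.na(evaluate_predictions(c(0.2, 0.8), c(1, 1))$auc))
})

test_that("the bagged AdaBoost learner separates a separable problem", {
  withr::with_seed(85, {
    x <- matrix(rnorm(200 * 3), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- as.integer(x[, 1] + 0.5 * x[, 2] > 0)
    fit <- fit_adabag(x[1:150, ], y[1:150], mfinal = 20, maxdepth = 2,
                      n_bags = 3)
    p <- predict(fit, x[151:200, ])
  })
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(auc_rank <- evaluate_predictions(p, y[151:200])$auc, 0.85)
})

test_that("a perfect separator yields near-perfect stacked accuracy", {
  tab <- make_noise_table(80, seed = 86)
  tab$f1 <- tab$label + withr::with_seed(87, rnorm(80, 0, 0.01))
  rep_obj <- suppressWarnings(
    stacked_classify(tab, seed = 1, folds = 5, repeats = 1,
                     control = test_stack_control()))
  expect_gte(rep_obj$stacked$balanced_accuracy, 0.95)
  expect_equal(sum(rep_obj$weights), 1, tolerance = 1e-12)
  expect_true(all(rep_obj$weights >= 0))
})

test_that("up-sampled duplicates never reach test folds", {
  tab <- make_noise_table(60, seed = 88)
  # imbalance forces up-sampling
  tab$label <- rep(c(0L, 0L, 0L, 1L), length.out = 60)
  rep_obj <- suppressWarnings(
    stacked_classify(tab, seed = 2, folds = 5, repeats = 2,
                     control = test_stack_control()))
  for (d in rep_obj$fold_detail) {
    expect_length(intersect(d$train_upsampled, d$test_idx), 0)
    expect_gt(length(d$train_upsampled), length(d$train_idx))  # upsampling ran
    for (tu in d$tune_train_upsampled) {
      expect_length(intersect(tu, d$test_idx), 0)
      expect_length(intersect(tu, d$val_idx), 0)
    }
  }
})

test_that("a single informative feature dominates variable importance", {
  tab <- make_noise_table(100, seed = 89)
  tab$f2 <- ifelse(tab$label == 1, 2, -2) + withr::with_seed(90, rnorm(100, 0, 0.3))
  rep_obj <- suppressWarnings(
    stacked_classify(tab, seed = 3, folds = 5, repeats = 1,
                     control = test_stack_control()))
  vi <- rep_obj$variable_importance
  expect_true(all(vi >= 0 & vi <= 100))
  expect_equal(names(which.max(vi)), "f2")
  expect_equal(max(vi), 100)
})

test_that("stacking is not catastrophically worse than its base learners", {
  tab <- make_noise_table(80, seed = 91)
  tab$f1 <- ifelse(tab$label == 1, 1.5, -1.5) +
    withr::with_seed(92, rnorm(80, 0, 0.5))
  rep_obj <- suppressWarnings(
    stacked_classify(tab, seed = 4, folds = 5, repeats = 1,
                     control = test_stack_control()))
  expect_gte(rep_obj$stacked$auc, min(rep_obj$per_algorithm$auc) - 0.02)
})

test_that("degenerate inputs are rejected", {
  tab <- make_noise_table(10, seed = 93)
  expect_error(stacked_classify(tab, seed = 1), "at least 20")
  tab2 <- make_noise_table(30, seed = 94)
  tab2$label <- c(rep(0L, 27), rep(1L, 3))
  expect_error(stacked_classify(tab2, seed = 1), "at least 5")
})
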