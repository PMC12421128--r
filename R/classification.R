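#' Stacked ensemble diagnostic classification
#'
#' Out-of-sample binary classification of diagnostic group from
#' computational and demographic features, using three base learners —
#' elastic-net logistic regression (ENET), k-nearest neighbors (KNN) and
#' bagged AdaBoost (ADABAG) — combined by AUC-weighted linear stacking.
#' Evaluation is by repeated stratified 5-fold cross-validation; within
#' each training fold an inner 80/20 training/validation split drives
#' hyperparameter tuning (randomly seeded starting values forming a grid),
#' the minority class is up-sampled with replacement inside training
#' portions only, and performance is reported as AUC, balanced accuracy
#' (mean of sensitivity and specificity), sensitivity and specificity
#' averaged over folds and repeats.
#'
#' @name classification
NULL

#' Assemble a feature table for classification
#'
#' Predictor sets: 1 = age and sex alone; 2 = model parameters (log-scale
#' EC and DU at baseline and follow-up); 3 = set 2 plus age and sex;
#' 4 = set 2 plus the per-subject entropy-RT correlation; 5 = all seven
#' predictors. Sex is coded -1 (female) / +1 (male); age is centered.
#' Subjects missing follow-up fits (or the correlation, where required)
#' are excluded from sets 2-5 with a reported count.
#'
#' @param fits Per subject-visit fit table (as from [fit_cohort()]) with
#'   `subject_id`, `visit`, `log_du`, `log_ec`.
#' @param demographics data.frame with `subject_id`, `label` (binary),
#'   `sex`, `age`.
#' @param behavioral Optional data.frame with `subject_id`,
#'   `entropy_rt_r` (required for sets 4-5).
#' @param predictor_set Integer 1..5.
#' @return data.frame of class `feature_table`: `subject_id`, `label` and
#'   the chosen feature columns, no missing cells.
#' @export
build_feature_table <- function(fits, demographics, behavioral = NULL,
                                predictor_set = 5L) {
  stopifnot(predictor_set %in% 1:5)
  stopifnot(all(c("subject_id", "label", "sex", "age") %in% names(demographics)))
  tab <- demographics[, c("subject_id", "label", "sex", "age")]
  tab$sex <- ifelse(tab$sex %in% c("female", -1), -1, 1)
  tab$age <- tab$age - mean(tab$age)
  if (predictor_set >= 2L) {
    stopifnot(all(c("subject_id", "visit", "log_du", "log_ec") %in% names(fits)))
    wide <- merge(
      stats::setNames(fits[fits$visit == "baseline",
                           c("subject_id", "log_ec", "log_du")],
                      c("subject_id", "ec_baseline", "du_baseline")),
      stats::setNames(fits[fits$visit == "followup",
                           c("subject_id", "log_ec", "log_du")],
                      c("subject_id", "ec_followup", "du_followup")),
      by = "subject_id")
    tab <- merge(tab, wide, by = "subject_id")
  }
  if (predictor_set %in% c(4L, 5L)) {
    if (is.null(behavioral)) stop("behavioral table required for sets 4-5")
    tab <- merge(tab, behavioral[, c("subject_id", "entropy_rt_r")],
                 by = "subject_id")
  }
  feature_cols <- switch(predictor_set,
    c("age", "sex"),
    c("ec_baseline", "ec_followup", "du_baseline", "du_followup"),
    c("ec_baseline", "ec_followup", "du_baseline", "du_followup", "age", "sex"),
    c("ec_baseline", "ec_followup", "du_baseline", "du_followup",
      "entropy_rt_r"),
    c("ec_baseline", "ec_followup", "du_baseline", "du_followup",
      "entropy_rt_r", "age", "sex")
  )
  for (cc in feature_cols) {
    if (all(is.na(tab[[cc]]))) stop("feature column all-missing: ", cc)
  }
  complete <- stats::complete.cases(tab[, c("label", feature_cols)])
  n_excluded <- sum(!complete) + (nrow(demographics) - nrow(tab))
  if (n_excluded > 0) {
    message(n_excluded, " subjects excluded (missing follow-up or features)")
  }
  tab <- tab[complete, c("subject_id", "label", feature_cols)]
  if (length(unique(tab$label)) != 2L) {
    stop("label must have both classes present")
  }
  structure(tab, class = c("feature_table", "data.frame"),
            features = feature_cols)
}

#' Tuning and ensemble settings
#'
#' Hyperparameter search draws `n_starts` random starting values per
#' hyperparameter over the declared ranges; two-parameter algorithms search
#' the resulting grid. Defaults: alpha in [0, 1], log10-lambda in [-4, 1],
#' k in 1..25, mfinal in 10..150, maxdepth in 1..5.
#'
#' @param n_starts Starting values per hyperparameter (default 7).
#' @param alpha_range,log_lambda_range ENET ranges.
#' @param k_range KNN neighbor range (integers).
#' @param mfinal_range,maxdepth_range ADABAG ranges (integers).
#' @param n_bags Bootstrap bags for ADABAG.
#' @param algorithms Subset of `c("enet", "knn", "adabag")`.
#' @param threshold Classification threshold on the stacked probability.
#' @return List of class `stack_control`.
#' @export
stack_control <- function(n_starts = 7L,
                          alpha_range = c(0, 1),
                          log_lambda_range = c(-4, 1),
                          k_range = c(1L, 25L),
                          mfinal_range = c(10L, 150L),
                          maxdepth_range = c(1L, 5L),
                          n_bags = 5L,
                          algorithms = c("enet", "knn", "adabag"),
                          threshold = 0.5) {
  algorithms <- match.arg(algorithms, c("enet", "knn", "adabag"),
                          several.ok = TRUE)
  structure(list(n_starts = as.integer(n_starts), alpha_range = alpha_range,
                 log_lambda_range = log_lambda_range, k_range = k_range,
                 mfinal_range = mfinal_range, maxdepth_range = maxdepth_range,
                 n_bags = as.integer(n_bags), algorithms = algorithms,
                 threshold = threshold), class = "stack_control")
}

#' Classification metrics from predicted probabilities
#'
#' AUC is rank-based (Mann-Whitney, average ranks for ties). Predictions at
#' or above `threshold` count as positive, so an uninformative constant 0.5
#' classifies everything positive (sensitivity 1, specificity 0, balanced
#' accuracy 0.5).
#'
#' @param probabilities Numeric in [0, 1].
#' @param labels Binary labels (0/1, logical, or 2-level factor whose
#'   second level is positive).
#' @param threshold Decision threshold (default 0.5).
#' @return List: `auc` (NA if one class absent), `sensitivity`,
#'   `specificity`, `balanced_accuracy`, `tp`, `fp`, `tn`, `fn`.
#' @export
evaluate_predictions <- function(probabilities, labels, threshold = 0.5) {
  y <- as_binary_label(labels)
  stopifnot(length(probabilities) == length(y),
            all(probabilities >= 0 & probabilities <= 1))
  pred <- probabilities >= threshold
  tp <- sum(pred & y == 1)
  fp <- sum(pred & y == 0)
  tn <- sum(!pred & y == 0)
  fn <- sum(!pred & y == 1)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  list(auc = auc_rank(probabilities, y), sensitivity = sens,
       specificity = spec, balanced_accuracy = mean(c(sens, spec)),
       tp = tp, fp = fp, tn = tn, fn = fn)
}

as_binary_label <- function(labels) {
  if (is.factor(labels)) {
    as.integer(labels == levels(labels)[2L])
  } else if (is.logical(labels)) {
    as.integer(labels)
  } else {
    u <- sort(unique(labels))
    if (length(u) > 2L) stop("labels must be binary")
    as.integer(labels == max(u))
  }
}

auc_rank <- function(p, y) {
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(p)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# stratified fold assignment; every fold gets members of both classes
# whenever each class has >= k members
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(sample.int(k), length(idx))
  }
  fold
}

# duplicate minority-class indices with replacement to match the majority
upsample_indices <- function(idx, y) {
  counts <- table(y[idx])
  if (length(counts) < 2L || counts[1] == counts[2]) return(idx)
  minority <- names(counts)[which.min(counts)]
  min_idx <- idx[y[idx] == minority]
  extra <- sample(min_idx, max(counts) - min(counts), replace = TRUE)
  c(idx, extra)
}

# ---- base learners ---------------------------------------------------------

fit_predict_enet <- function(xtr, ytr, xnew, alpha, lambda) {
  fit <- glmnet::glmnet(xtr, factor(ytr, levels = c(0, 1)),
                        family = "binomial", alpha = alpha,
                        lambda = sort(unique(c(lambda, lambda * 2)),
                                      decreasing = TRUE))
  as.numeric(stats::predict(fit, xnew, s = lambda, type = "response"))
}

enet_coefficients <- function(xtr, ytr, alpha, lambda) {
  fit <- glmnet::glmnet(xtr, factor(ytr, levels = c(0, 1)),
                        family = "binomial", alpha = alpha,
                        lambda = sort(unique(c(lambda, lambda * 2)),
                                      decreasing = TRUE))
  as.numeric(stats::coef(fit, s = lambda))[-1L]
}

predict_knn <- function(xtr, ytr, xnew, k, scale_stats) {
  tr <- scale(xtr, scale_stats$center, scale_stats$scale)
  nw <- scale(xnew, scale_stats$center, scale_stats$scale)
  pred <- class::knn(tr, nw, factor(ytr, levels = c(0, 1)), k = k,
                     prob = TRUE, use.all = TRUE)
  vote <- attr(pred, "prob")
  ifelse(pred == "1", vote, 1 - vote)
}

#' Bagged AdaBoost classifier
#'
#' AdaBoost.M1 with depth-limited rpart trees as weak learners, trained on
#' `n_bags` bootstrap resamples of the training data; predicted probability
#' is the bag-averaged weighted vote share for the positive class. Boosting
#' stops early on a weighted error of 0 or >= 0.5.
#'
#' @param x Numeric feature matrix.
#' @param y Binary labels (see [evaluate_predictions()]).
#' @param mfinal Boosting iterations per bag.
#' @param maxdepth Maximum tree depth.
#' @param n_bags Bootstrap bags.
#' @return Object of class `adabag_fit`.
#' @export
fit_adabag <- function(x, y, mfinal, maxdepth, n_bags = 5L) {
  y01 <- as_binary_label(y)
  n <- nrow(x)
  ctrl <- rpart::rpart.control(maxdepth = maxdepth, cp = 0, minsplit = 5L,
                               xval = 0L)
  bags <- lapply(seq_len(n_bags), function(b) {
    bidx <- sample.int(n, n, replace = TRUE)
    df <- data.frame(.y = factor(y01[bidx], levels = c(0, 1)),
                     x[bidx, , drop = FALSE])
    yb <- y01[bidx]
    w <- rep(1 / n, n)
    trees <- list()
    alphas <- numeric(0)
    for (m in seq_len(mfinal)) {
      fit <- rpart::rpart(.y ~ ., data = df, weights = w * n,
                          method = "class", control = ctrl)
      pred <- stats::predict(fit, df, type = "class") == "1"
      err <- sum(w[pred != (yb == 1)])
      if (err >= 0.5) {
        if (length(trees) == 0L) {
          trees <- list(fit)
          alphas <- 1e-3
        }
        break
      }
      trees[[length(trees) + 1L]] <- fit
      if (err <= 1e-10) {
        alphas <- c(alphas, 10)
        break
      }
      a <- 0.5 * log((1 - err) / err)
      alphas <- c(alphas, a)
      w <- w * exp(a * ifelse(pred != (yb == 1), 1, -1))
      w <- w / sum(w)
    }
    list(trees = trees, alphas = alphas)
  })
  structure(list(bags = bags, features = colnames(x)), class = "adabag_fit")
}

#' @param object An `adabag_fit`.
#' @param newdata Numeric feature matrix.
#' @param ... Unused.
#' @rdname fit_adabag
#' @export
predict.adabag_fit <- function(object, newdata, ...) {
  df <- as.data.frame(newdata)
  scores <- vapply(object$bags, function(bag) {
    votes <- vapply(seq_along(bag$trees), function(m) {
      as.numeric(stats::predict(bag$trees[[m]], df, type = "class") == "1")
    }, numeric(nrow(df)))
    votes <- matrix(votes, nrow = nrow(df))
    as.numeric(votes %*% bag$alphas) / sum(bag$alphas)
  }, numeric(nrow(df)))
  rowMeans(matrix(scores, nrow = nrow(df)))
}

# ---- nested CV + stacking --------------------------------------------------

draw_candidates <- function(control) {
  n <- control$n_starts
  list(
    alpha = stats::runif(n, control$alpha_range[1], control$alpha_range[2]),
    lambda = 10^stats::runif(n, control$log_lambda_range[1],
                             control$log_lambda_range[2]),
    k = unique(pmax(1L, round(stats::runif(n, control$k_range[1],
                                           control$k_range[2])))),
    mfinal = unique(pmax(1L, round(stats::runif(n, control$mfinal_range[1],
                                                control$mfinal_range[2])))),
    maxdepth = unique(pmax(1L, round(stats::runif(n, control$maxdepth_range[1],
                                                  control$maxdepth_range[2]))))
  )
}

tune_algorithm <- function(algo, x, y, tr_idx, val_idx, cand, control) {
  tr_up <- upsample_indices(tr_idx, y)
  xval <- x[val_idx, , drop = FALSE]
  yval <- y[val_idx]
  best <- list(auc = -Inf)
  if (algo == "enet") {
    for (a in cand$alpha) {
      for (l in cand$lambda) {
        p <- fit_predict_enet(x[tr_up, , drop = FALSE], y[tr_up], xval, a, l)
        auc <- auc_rank(p, yval)
        if (is.finite(auc) && auc > best$auc) {
          best <- list(auc = auc, params = list(alpha = a, lambda = l))
        }
      }
    }
  } else if (algo == "knn") {
    ss <- list(center = colMeans(x[tr_up, , drop = FALSE]),
               scale = pmax(apply(x[tr_up, , drop = FALSE], 2, stats::sd),
                            1e-8))
    for (k in cand$k) {
      p <- predict_knn(x[tr_up, , drop = FALSE], y[tr_up], xval, k, ss)
      auc <- auc_rank(p, yval)
      if (is.finite(auc) && auc > best$auc) {
        best <- list(auc = auc, params = list(k = k))
      }
    }
  } else {
    for (mf in cand$mfinal) {
      for (md in cand$maxdepth) {
        fit <- fit_adabag(x[tr_up, , drop = FALSE], y[tr_up], mf, md,
                          control$n_bags)
        p <- predict(fit, xval)
        auc <- auc_rank(p, yval)
        if (is.finite(auc) && auc > best$auc) {
          best <- list(auc = auc, params = list(mfinal = mf, maxdepth = md),
                       tuned_fit = fit)
        }
      }
    }
  }
  best$tr_up <- tr_up
  best
}

refit_predict <- function(algo, x, y, train_up, test_idx, params, control) {
  xtr <- x[train_up, , drop = FALSE]
  ytr <- y[train_up]
  xte <- x[test_idx, , drop = FALSE]
  if (algo == "enet") {
    list(prob = fit_predict_enet(xtr, ytr, xte, params$alpha, params$lambda),
         coefs = enet_coefficients(xtr, ytr, params$alpha, params$lambda),
         sds = apply(xtr, 2, stats::sd))
  } else if (algo == "knn") {
    ss <- list(center = colMeans(xtr),
               scale = pmax(apply(xtr, 2, stats::sd), 1e-8))
    list(prob = predict_knn(xtr, ytr, xte, params$k, ss))
  } else {
    fit <- fit_adabag(xtr, ytr, params$mfinal, params$maxdepth, control$n_bags)
    list(prob = predict(fit, xte), fit = fit)
  }
}

# permutation importance on the validation split: drop in AUC when one
# feature column is shuffled
permutation_importance <- function(predict_fun, xval, yval) {
  base <- auc_rank(predict_fun(xval), yval)
  vapply(seq_len(ncol(xval)), function(j) {
    xp <- xval
    xp[, j] <- sample(xp[, j])
    max(0, base - auc_rank(predict_fun(xp), yval))
  }, numeric(1))
}

#' Stacked ensemble classification with nested cross-validation
#'
#' Outer stratified `folds`-fold cross-validation, repeated `repeats` times
#' with fresh fold assignments. Within each training fold: an inner
#' stratified 80/20 training/validation split; per algorithm, randomly
#' drawn hyperparameter starting values (see [stack_control()]) searched as
#' a grid on the validation split; minority-class up-sampling applied to
#' training portions only; the tuned learners are refit on the up-sampled
#' full training fold and their test-fold probability predictions combined
#' linearly with weights proportional to `max(validation AUC - 0.5, 1e-6)`,
#' normalized to sum to 1. Variable importance combines |standardized ENET
#' coefficients| with permutation importance (KNN, ADABAG) using the stack
#' weights, min-max rescaled to 0-100.
#'
#' @param table A [build_feature_table()] result (or data.frame with
#'   `label` plus numeric feature columns).
#' @param seed Integer seed; determines folds, splits, tuning draws and
#'   up-sampling.
#' @param folds Outer folds (default 5).
#' @param repeats Repeats of the whole CV (default 5).
#' @param control A [stack_control()].
#' @return List of class `stack_report`: `per_algorithm` (metric means),
#'   `stacked`, `weights`, `confusion` (summed over folds, averaged over
#'   repeats), `variable_importance` (0-100), `fold_metrics`, and
#'   `fold_detail` (test indices and up-sampled training indices per fold,
#'   for leakage audits).
#' @export
stacked_classify <- function(table, seed = 1L, folds = 5L, repeats = 5L,
                             control = stack_control()) {
  feats <- attr(table, "features")
  if (is.null(feats)) feats <- setdiff(names(table), c("subject_id", "label"))
  x <- as.matrix(table[, feats, drop = FALSE])
  storage.mode(x) <- "double"
  y <- as_binary_label(table$label)
  if (nrow(x) < 20L) stop("need at least 20 rows")
  if (min(table(y)) < 5L) stop("each class needs at least 5 members")
  algos <- control$algorithms
  withr::with_seed(as.integer(seed), {
    fold_rows <- list()
    detail <- list()
    vi_acc <- matrix(0, 0, ncol(x))
    weight_acc <- NULL
    confusion <- c(tp = 0, fp = 0, tn = 0, fn = 0)
    for (rep_i in seq_len(repeats)) {
      fold_id <- stratified_folds(y, folds)
      for (f in seq_len(folds)) {
        test_idx <- which(fold_id == f)
        train_idx <- which(fold_id != f)
        if (length(unique(y[test_idx])) < 2L ||
            length(unique(y[train_idx])) < 2L) {
          stop("degenerate fold: a class is absent; reduce folds")
        }
        # inner stratified 80/20 split of the training fold
        inner <- stratified_folds(y[train_idx], 5L)
        val_idx <- train_idx[inner == 1L]
        tr_idx <- train_idx[inner != 1L]
        cand <- draw_candidates(control)
        tuned <- lapply(algos, function(a) {
          tune_algorithm(a, x, y, tr_idx, val_idx, cand, control)
        })
        names(tuned) <- algos
        val_auc <- vapply(tuned, function(t) t$auc, numeric(1))
        w <- pmax(val_auc - 0.5, 1e-6)
        w <- w / sum(w)
        train_up <- upsample_indices(train_idx, y)
        refits <- lapply(algos, function(a) {
          refit_predict(a, x, y, train_up, test_idx, tuned[[a]]$params,
                        control)
        })
        names(refits) <- algos
        probs <- vapply(refits, function(r) r$prob,
                        numeric(length(test_idx)))
        probs <- matrix(probs, nrow = length(test_idx),
                        dimnames = list(NULL, algos))
        stacked_prob <- as.numeric(probs %*% w)
        # per-fold metrics
        row_metrics <- lapply(algos, function(a) {
          m <- evaluate_predictions(probs[, a], y[test_idx],
                                    control$threshold)
          data.frame(repeat_i = rep_i, fold = f, algorithm = a,
                     auc = m$auc, balanced_accuracy = m$balanced_accuracy,
                     sensitivity = m$sensitivity, specificity = m$specificity,
                     val_auc = val_auc[[a]], weight = w[[a]])
        })
        ms <- evaluate_predictions(stacked_prob, y[test_idx],
                                   control$threshold)
        row_metrics[[length(row_metrics) + 1L]] <- data.frame(
          repeat_i = rep_i, fold = f, algorithm = "stack",
          auc = ms$auc, balanced_accuracy = ms$balanced_accuracy,
          sensitivity = ms$sensitivity, specificity = ms$specificity,
          val_auc = NA_real_, weight = NA_real_)
        fold_rows[[length(fold_rows) + 1L]] <- do.call(rbind, row_metrics)
        confusion <- confusion +
          c(tp = ms$tp, fp = ms$fp, tn = ms$tn, fn = ms$fn) / repeats
        weight_acc <- rbind(weight_acc, w)
        # variable importance for this fold
        xval <- x[val_idx, , drop = FALSE]
        yval <- y[val_idx]
        vi_fold <- matrix(0, length(algos), ncol(x),
                          dimnames = list(algos, feats))
        for (a in algos) {
          if (a == "enet") {
            vi_fold[a, ] <- abs(refits[[a]]$coefs) * refits[[a]]$sds
          } else if (a == "knn") {
            tr_up <- tuned[[a]]$tr_up
            ss <- list(center = colMeans(x[tr_up, , drop = FALSE]),
                       scale = pmax(apply(x[tr_up, , drop = FALSE], 2,
                                          stats::sd), 1e-8))
            k <- tuned[[a]]$params$k
            vi_fold[a, ] <- permutation_importance(function(xx) {
              predict_knn(x[tr_up, , drop = FALSE], y[tr_up], xx, k, ss)
            }, xval, yval)
          } else {
            fit <- tuned[[a]]$tuned_fit
            vi_fold[a, ] <- permutation_importance(function(xx) {
              predict(fit, xx)
            }, xval, yval)
          }
        }
        # scale each algorithm's importances to max 1 before weighting
        for (a in algos) {
          mx <- max(vi_fold[a, ])
          if (mx > 0) vi_fold[a, ] <- vi_fold[a, ] / mx
        }
        vi_acc <- rbind(vi_acc, as.numeric(w %*% vi_fold))
        detail[[length(detail) + 1L]] <- list(
          repeat_i = rep_i, fold = f, test_idx = test_idx,
          train_idx = train_idx, train_upsampled = train_up,
          tune_train_upsampled = lapply(tuned, function(t) t$tr_up),
          val_idx = val_idx)
      }
    }
  })
  fold_metrics <- do.call(rbind, fold_rows)
  agg <- stats::aggregate(
    cbind(auc, balanced_accuracy, sensitivity, specificity) ~ algorithm,
    data = fold_metrics, FUN = mean, na.action = stats::na.omit)
  per_algorithm <- agg[agg$algorithm != "stack", , drop = FALSE]
  stacked <- agg[agg$algorithm == "stack", , drop = FALSE]
  weights <- colMeans(weight_acc)
  names(weights) <- algos
  vi_mean <- colMeans(vi_acc)
  rng <- range(vi_mean)
  if (diff(rng) <= 0) {
    if (max(vi_mean) <= 0) warning("all variable importances are zero")
    vi_scaled <- rep(0, length(vi_mean))
  } else {
    vi_scaled <- 100 * (vi_mean - rng[1]) / diff(rng)
  }
  names(vi_scaled) <- feats
  structure(list(per_algorithm = per_algorithm, stacked = stacked,
                 weights = weights, confusion = confusion,
                 variable_importance = vi_scaled,
                 fold_metrics = fold_metrics, fold_detail = detail,
                 n = nrow(x), features = feats),
            class = "stack_report")
}

#' @export
print.stack_report <- function(x, ...) {
  cat(sprintf("Stacked ensemble report (n = %d)\n", x$n))
  cat("Per-algorithm (mean over folds):\n")
  print(x$per_algorithm, row.names = FALSE)
  cat("Stacked:\n")
  print(x$stacked, row.names = FALSE)
  cat("Stack weights:\n")
  print(round(x$weights, 3))
  cat("Variable importance (0-100):\n")
  print(round(sort(x$variable_importance, decreasing = TRUE), 1))
  invisible(x)
}
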