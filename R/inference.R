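#' Parameter estimation for the AAC choice model
#'
#' Per subject-visit, (DU, EC) are estimated by maximizing the log joint
#' (choice log-likelihood plus a Gaussian log-prior on log-scale parameters)
#' with a quasi-Newton search, and the posterior is approximated by a
#' Gaussian centered at the optimum with covariance equal to the inverse
#' negative Hessian (a Laplace approximation). A brute-force grid optimizer
#' is provided as an oracle, along with the action-probability/accuracy fit
#' metrics and a skew-minimizing log transform for group-level analyses.
#'
#' A subject dataset is a data.frame with one row per trial and at least
#' columns `trial_type` and `chosen_position` (1..9); `rt` is carried for
#' the behavioral measures.
#'
#' @name inference
NULL

check_trials <- function(data) {
  if (!is.data.frame(data) || nrow(data) == 0L) {
    stop("dataset must contain at least one trial")
  }
  if (!all(c("trial_type", "chosen_position") %in% names(data))) {
    stop("dataset needs columns trial_type and chosen_position")
  }
  if (!all(data$chosen_position %in% 1:9)) {
    stop("chosen_position values must be integers in 1..9")
  }
  invisible(data)
}

# 5 x 9 table of choice counts by trial type; the sufficient statistic for
# the likelihood (policies depend on the trial only through its type).
choice_count_matrix <- function(data) {
  check_trials(data)
  tt <- factor(data$trial_type, levels = aac_trial_types())
  pos <- factor(data$chosen_position, levels = 1:9)
  table(tt, pos)
}

#' Choice log-likelihood
#'
#' Sum over trials of the log policy probability of the chosen position.
#' Log-probabilities are computed directly by log-softmax, so they stay
#' finite (if very negative) even where the policy underflows — a floor on
#' the probabilities would silently cap the penalty for choices in a sharp
#' policy's tail and bias the temperature estimate downward.
#'
#' @param params An [agent_params()].
#' @param data Trial data.frame (see [inference]).
#' @param form Value form passed to [choice_policy()].
#' @return Scalar log-likelihood (<= 0).
#' @export
log_likelihood <- function(params, data, form = "risk") {
  counts <- choice_count_matrix(data)
  sum(counts * log_policy_matrix(params, form))
}

#' Prior over log-scale parameters
#'
#' Independent Gaussians on (log DU, log EC). The default mean (0, 0) and
#' variance (4, 4) is weakly informative: +/- 2 SD spans raw parameter
#' values from about 0.02 to 55.
#'
#' @param mean Length-2 numeric, log-space prior mean.
#' @param variance Length-2 positive numeric, log-space prior variances.
#' @return A list of class `prior_spec`.
#' @export
prior_spec <- function(mean = c(0, 0), variance = c(4, 4)) {
  stopifnot(length(mean) == 2L, length(variance) == 2L, all(variance > 0))
  structure(list(mean = as.numeric(mean), variance = as.numeric(variance)),
            class = "prior_spec")
}

log_prior <- function(theta, prior) {
  sum(stats::dnorm(theta, prior$mean, sqrt(prior$variance), log = TRUE))
}

#' Optimizer settings for [fit_map()]
#'
#' @param max_iter Maximum BFGS iterations per start.
#' @param rel_tol Relative log-joint convergence tolerance.
#' @param form Value form ("risk" or "logpref").
#' @return A list of class `fit_control`.
#' @export
fit_control <- function(max_iter = 64L, rel_tol = 1e-6, form = "risk") {
  structure(list(max_iter = as.integer(max_iter), rel_tol = rel_tol,
                 form = form), class = "fit_control")
}

# central-difference gradient
num_grad <- function(fn, theta, h = 1e-5) {
  vapply(seq_along(theta), function(i) {
    e <- replace(numeric(length(theta)), i, h)
    (fn(theta + e) - fn(theta - e)) / (2 * h)
  }, numeric(1))
}

num_hessian <- function(fn, theta, h = 1e-4) {
  d <- length(theta)
  H <- matrix(NA_real_, d, d)
  for (i in seq_len(d)) {
    ei <- replace(numeric(d), i, h)
    for (j in i:d) {
      ej <- replace(numeric(d), j, h)
      H[i, j] <- H[j, i] <-
        (fn(theta + ei + ej) - fn(theta + ei - ej) -
           fn(theta - ei + ej) + fn(theta - ei - ej)) / (4 * h * h)
    }
  }
  H
}

#' MAP fit with Laplace posterior approximation
#'
#' Maximizes the log joint over log-space parameters theta = (log DU, log EC)
#' by BFGS with central-difference gradients, restarting deterministically
#' from the prior mean and the four +/- 1 SD corners and keeping the best
#' optimum. The posterior covariance is the inverse negative Hessian at the
#' optimum; if the Hessian is singular or not negative definite the
#' Moore-Penrose pseudo-inverse is used and flagged (`hessian_ok = FALSE`).
#'
#' @param data Trial data.frame.
#' @param prior A [prior_spec()].
#' @param config A [fit_control()].
#' @return A list of class `aac_fit`: `du_hat`, `ec_hat`, `log_params`,
#'   `posterior_cov`, `log_joint`, `avg_action_probability`, `accuracy`,
#'   `n_trials`, `converged`, `hessian_ok`.
#' @export
fit_map <- function(data, prior = prior_spec(), config = fit_control()) {
  check_trials(data)
  counts <- choice_count_matrix(data)
  obj <- function(theta) {
    params <- list(du = exp(theta[1]), ec = exp(theta[2]))
    sum(counts * log_policy_matrix(params, config$form)) +
      log_prior(theta, prior)
  }
  sd1 <- sqrt(prior$variance)
  starts <- rbind(
    prior$mean,
    prior$mean + c(sd1[1], sd1[2]),
    prior$mean + c(sd1[1], -sd1[2]),
    prior$mean + c(-sd1[1], sd1[2]),
    prior$mean + c(-sd1[1], -sd1[2])
  )
  best <- NULL
  any_converged <- FALSE
  for (s in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(starts[s, ], fn = obj, gr = function(th) num_grad(obj, th),
                   method = "BFGS",
                   control = list(fnscale = -1, maxit = config$max_iter,
                                  reltol = config$rel_tol)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (res$convergence == 0L) any_converged <- TRUE
    if (is.null(best) || res$value > best$value) best <- res
  }
  if (is.null(best)) stop("all optimizer starts failed")
  theta_hat <- best$par
  H <- num_hessian(obj, theta_hat)
  neg_H <- -H
  hessian_ok <- TRUE
  cov <- tryCatch(chol2inv(chol(neg_H)), error = function(e) NULL)
  if (is.null(cov) || any(!is.finite(cov))) {
    cov <- MASS::ginv(neg_H)
    hessian_ok <- FALSE
  }
  cov <- (cov + t(cov)) / 2
  params_hat <- agent_params(exp(theta_hat[1]), exp(theta_hat[2]))
  metrics <- fit_metrics(params_hat, data, config$form)
  structure(list(
    du_hat = params_hat$du,
    ec_hat = params_hat$ec,
    log_params = stats::setNames(theta_hat, c("log_du", "log_ec")),
    posterior_cov = cov,
    log_joint = best$value,
    avg_action_probability = metrics[["avg_action_probability"]],
    accuracy = metrics[["accuracy"]],
    n_trials = nrow(data),
    converged = any_converged,
    hessian_ok = hessian_ok
  ), class = "aac_fit")
}

#' @export
print.aac_fit <- function(x, ...) {
  cat(sprintf(
    "AAC model fit (%d trials)\n  DU = %.3f  EC = %.3f\n  log-joint = %.3f\n  avg action prob = %.3f  accuracy = %.3f\n  converged: %s\n",
    x$n_trials, x$du_hat, x$ec_hat, x$log_joint,
    x$avg_action_probability, x$accuracy, x$converged))
  invisible(x)
}

#' Exhaustive grid optimizer (oracle)
#'
#' Evaluates the log joint on a log-space lattice and returns the argmax
#' node. Serves as a brute-force check on [fit_map()].
#'
#' @param data Trial data.frame.
#' @param prior A [prior_spec()].
#' @param log_du,log_ec Numeric grids of log-space values.
#' @param form Value form.
#' @return A list: `log_params`, `du_hat`, `ec_hat`, `log_joint`.
#' @export
fit_grid <- function(data, prior = prior_spec(),
                     log_du = seq(-3, 3, length.out = 50),
                     log_ec = seq(-3, 3, length.out = 50),
                     form = "risk") {
  check_trials(data)
  if (length(log_du) == 0L || length(log_ec) == 0L) {
    stop("grid must contain at least one node")
  }
  counts <- choice_count_matrix(data)
  best <- list(log_joint = -Inf)
  for (ld in log_du) {
    for (le in log_ec) {
      params <- list(du = exp(ld), ec = exp(le))
      lj <- sum(counts * log_policy_matrix(params, form)) +
        log_prior(c(ld, le), prior)
      if (lj > best$log_joint) {
        best <- list(log_params = stats::setNames(c(ld, le),
                                                  c("log_du", "log_ec")),
                     du_hat = params$du, ec_hat = params$ec, log_joint = lj)
      }
    }
  }
  best
}

#' Model-validity fit metrics
#'
#' `avg_action_probability`: mean over trials of the policy probability of
#' the chosen position. `accuracy`: fraction of trials on which the chosen
#' position attains the policy's maximum (any member of a tied argmax set
#' counts as correct). A uniform policy gives 1/9 for both in expectation —
#' the task's 11% chance level.
#'
#' @param params An [agent_params()].
#' @param data Trial data.frame.
#' @param form Value form.
#' @return Named numeric `c(avg_action_probability=, accuracy=)`.
#' @export
fit_metrics <- function(params, data, form = "risk") {
  check_trials(data)
  pm <- policy_matrix(params, form)
  rows <- match(data$trial_type, aac_trial_types())
  chosen_p <- pm[cbind(rows, data$chosen_position)]
  row_max <- apply(pm, 1, max)
  is_argmax <- chosen_p >= row_max[rows] - 1e-12
  c(avg_action_probability = mean(chosen_p), accuracy = mean(is_argmax))
}

# adjusted Fisher-Pearson sample skewness; 0 for (near-)constant input
sample_skewness <- function(x) {
  n <- length(x)
  if (n < 3L) return(0)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 < .Machine$double.eps) return(0)
  g1 <- mean((x - m)^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Skew-minimizing log transform
#'
#' Returns `log(values + c)` with the offset `c` chosen from `{0}` plus a
#' geometric grid (25 log-spaced points in 1e-3..1e2) to minimize the
#' absolute adjusted Fisher-Pearson sample skewness of the transformed
#' values. Mirrors the usual practice of log-transforming positively skewed
#' parameter estimates before group-level analysis.
#'
#' @param values Numeric vector; `values + c` must be positive for at least
#'   one candidate `c`.
#' @param c_grid Candidate offsets.
#' @return A list: `values` (transformed), `offset`, `skewness` (after),
#'   `skewness_before`.
#' @export
optlog_transform <- function(values,
                             c_grid = c(0, 10^seq(-3, 2, length.out = 25))) {
  if (!is.numeric(values) || length(values) == 0L || any(!is.finite(values))) {
    stop("values must be a finite numeric vector")
  }
  valid <- c_grid[vapply(c_grid, function(cc) all(values + cc > 0), logical(1))]
  if (length(valid) == 0L) {
    stop("no candidate offset keeps all values positive")
  }
  skews <- vapply(valid, function(cc) abs(sample_skewness(log(values + cc))),
                  numeric(1))
  cc <- valid[[which.min(skews)]]
  list(values = log(values + cc), offset = cc,
       skewness = sample_skewness(log(values + cc)),
       skewness_before = sample_skewness(values))
}
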