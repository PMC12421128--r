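#' Power analysis by simulation for a random-intercept LME
#'
#' Post-hoc power for the group term of `y ~ group*time + (1|subject)` under
#' follow-up attrition. Outcomes are generated with between- and
#' within-subject variances 0.1 and 0.9 (total variance 1), group and visit
#' coded -1/+1 (so the group coefficient is 1/4 of the visit-averaged mean
#' difference between groups), and follow-up observations deleted with
#' group-specific probability. Power is the proportion of replications with
#' a group-term p-value below alpha.
#'
#' @name power_sim
NULL

#' Specification for the power simulation
#'
#' @param n_hc,n_clinical Subjects per group.
#' @param between_var,within_var Random-intercept and residual variances
#'   (defaults 0.1 and 0.9, total 1).
#' @param missing_prob_hc,missing_prob_clinical Follow-up missingness
#'   probabilities (defaults 0.25; clinical attrition in the study band
#'   0.32-0.64).
#' @param effect_beta Group coefficient under the -1/+1 coding.
#' @param time_beta Visit coefficient.
#' @param intercept Grand mean.
#' @param reps Simulation replications (default 4000).
#' @param alpha Significance level (default 0.05).
#' @return List of class `power_sim_spec`.
#' @export
power_sim_spec <- function(n_hc = 100L, n_clinical = 100L,
                           between_var = 0.1, within_var = 0.9,
                           missing_prob_hc = 0.25,
                           missing_prob_clinical = 0.48,
                           effect_beta = 0, time_beta = 0, intercept = 0,
                           reps = 4000L, alpha = 0.05) {
  stopifnot(n_hc >= 2, n_clinical >= 2, between_var >= 0, within_var > 0,
            missing_prob_hc >= 0, missing_prob_hc < 1,
            missing_prob_clinical >= 0, missing_prob_clinical < 1,
            reps >= 1, alpha > 0, alpha < 1)
  structure(list(n_hc = as.integer(n_hc), n_clinical = as.integer(n_clinical),
                 between_var = between_var, within_var = within_var,
                 missing_prob_hc = missing_prob_hc,
                 missing_prob_clinical = missing_prob_clinical,
                 effect_beta = effect_beta, time_beta = time_beta,
                 intercept = intercept, reps = as.integer(reps),
                 alpha = alpha), class = "power_sim_spec")
}

#' Simulate one long-format dataset
#'
#' @param spec A [power_sim_spec()].
#' @param rep_seed Integer seed for this replication.
#' @return Long data.frame: `subject`, `group` (-1 HC / +1 clinical),
#'   `time` (-1 baseline / +1 follow-up), `y`; follow-up rows removed per
#'   the group's missingness probability.
#' @export
simulate_lme_dataset <- function(spec, rep_seed = 1L) {
  n <- spec$n_hc + spec$n_clinical
  g <- rep(c(-1, 1), times = c(spec$n_hc, spec$n_clinical))
  withr::with_seed(as.integer(rep_seed), {
    b <- stats::rnorm(n, 0, sqrt(spec$between_var))
    dat <- data.frame(
      subject = rep(seq_len(n), each = 2L),
      group = rep(g, each = 2L),
      time = rep(c(-1, 1), times = n)
    )
    dat$y <- spec$intercept + spec$effect_beta * dat$group +
      spec$time_beta * dat$time + b[dat$subject] +
      stats::rnorm(nrow(dat), 0, sqrt(spec$within_var))
    miss_p <- ifelse(dat$group == -1, spec$missing_prob_hc,
                     spec$missing_prob_clinical)
    drop <- dat$time == 1 & stats::runif(nrow(dat)) < miss_p
    dat <- dat[!drop, , drop = FALSE]
  })
  dat
}

#' Estimate power for the group term
#'
#' Each replication fits `y ~ group*time + (1|subject)` by REML and records
#' the group-term p-value. The default `"wald"` method uses the t-statistic
#' with a between-subject degrees-of-freedom approximation (number of
#' subjects minus 2, appropriate for a between-subject term in a
#' random-intercept model); `"satterthwaite"` uses the lmerTest
#' approximation at roughly 15x the cost. Replications whose fit errors
#' out are skipped and counted (warning above 5%).
#'
#' @param spec A [power_sim_spec()].
#' @param seed Integer seed; replication seeds are derived from it.
#' @param method `"wald"` (default) or `"satterthwaite"`.
#' @return List of class `power_result`: `power`, `ci` (95% binomial),
#'   `n_significant`, `reps_used`, `n_failed`, `spec`.
#' @export
estimate_power <- function(spec, seed = 1L,
                           method = c("wald", "satterthwaite")) {
  method <- match.arg(method)
  pvals <- rep(NA_real_, spec$reps)
  base <- as.integer(seed) %% 1000000L
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular =
                              lme4::.makeCC("ignore", tol = 1e-4))
  df_group <- spec$n_hc + spec$n_clinical - 2L
  for (i in seq_len(spec$reps)) {
    dat <- simulate_lme_dataset(spec, rep_seed = base + i)
    p <- tryCatch({
      if (method == "satterthwaite") {
        fit <- suppressMessages(suppressWarnings(
          lmerTest::lmer(y ~ group * time + (1 | subject), data = dat,
                         REML = TRUE, control = ctrl)))
        stats::coef(summary(fit))["group", "Pr(>|t|)"]
      } else {
        fit <- suppressMessages(suppressWarnings(
          lme4::lmer(y ~ group * time + (1 | subject), data = dat,
                     REML = TRUE, control = ctrl)))
        tt <- stats::coef(summary(fit))["group", "t value"]
        2 * stats::pt(-abs(tt), df = df_group)
      }
    }, error = function(e) NA_real_)
    pvals[i] <- p
  }
  ok <- is.finite(pvals)
  n_failed <- sum(!ok)
  if (n_failed > 0.05 * spec$reps) {
    warning(n_failed, " of ", spec$reps, " replications failed to fit")
  }
  n_used <- sum(ok)
  n_sig <- sum(pvals[ok] < spec$alpha)
  power <- n_sig / n_used
  se <- sqrt(power * (1 - power) / n_used)
  structure(list(power = power,
                 ci = c(max(0, power - 1.96 * se), min(1, power + 1.96 * se)),
                 n_significant = n_sig, reps_used = n_used,
                 n_failed = n_failed, spec = spec),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("Simulated power = %.3f (95%% CI %.3f-%.3f), %d/%d reps, %d failed\n",
              x$power, x$ci[1], x$ci[2], x$n_significant, x$reps_used,
              x$n_failed))
  invisible(x)
}
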