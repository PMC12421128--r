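#' Synthetic cohort generation
#'
#' Generates cohorts with the statistical structure the analysis assumes:
#' three groups (HC, DEP/ANX, SUD) by two visits (baseline, 1-year
#' follow-up) on the 60-trial task, subject-level (DU, EC) drawn from
#' log-normal distributions moment-matched to group raw-scale means/SDs,
#' cross-visit correlation of latent log-parameters, group-specific
#' follow-up attrition, and RTs coupled to trial-level choice uncertainty
#' with a configurable target correlation.
#'
#' @name synthetic_cohort
NULL

#' Group specification
#'
#' Raw-scale parameter moments are converted internally to log-normal
#' (mu, sigma) by moment matching. `rt_target_r` sets the expected
#' per-subject Pearson correlation between choice uncertainty and RT; the
#' per-subject RT slope is derived from it given the subject's entropy
#' spread and `rt_noise_sd`.
#'
#' @param name One of `"HC"`, `"DEP_ANX"`, `"SUD"`.
#' @param n Number of subjects.
#' @param ec_mean,ec_sd,du_mean,du_sd Raw-scale moments of EC and DU.
#' @param attrition_prob Probability a subject misses follow-up.
#' @param rt_intercept Mean RT (seconds) at zero entropy.
#' @param rt_target_r Target entropy-RT correlation.
#' @param rt_noise_sd RT noise SD (seconds).
#' @param visit_param_correlation Correlation of latent log-parameters
#'   across visits.
#' @param ec_female_mult Optional multiplicative EC shift for females
#'   (default 1: off), a hook for studying sex effects.
#' @param prop_female Probability a subject is female.
#' @return A list of class `group_spec`.
#' @export
group_spec <- function(name, n,
                       ec_mean, ec_sd, du_mean, du_sd,
                       attrition_prob = 0.25,
                       rt_intercept = 1.5,
                       rt_target_r = 0.11,
                       rt_noise_sd = 0.5,
                       visit_param_correlation = 0.8,
                       ec_female_mult = 1,
                       prop_female = 0.65) {
  stopifnot(name %in% c("HC", "DEP_ANX", "SUD"),
            n >= 0, ec_mean > 0, ec_sd > 0, du_mean > 0, du_sd > 0,
            attrition_prob >= 0, attrition_prob < 1,
            rt_intercept > 0, rt_noise_sd > 0,
            visit_param_correlation >= 0, visit_param_correlation <= 1,
            abs(rt_target_r) < 1)
  structure(list(
    name = name, n = as.integer(n),
    ec_mean = ec_mean, ec_sd = ec_sd, du_mean = du_mean, du_sd = du_sd,
    attrition_prob = attrition_prob,
    rt_intercept = rt_intercept, rt_target_r = rt_target_r,
    rt_noise_sd = rt_noise_sd,
    visit_param_correlation = visit_param_correlation,
    ec_female_mult = ec_female_mult, prop_female = prop_female
  ), class = "group_spec")
}

#' Default group specifications
#'
#' Parameter moments match the study-scale baseline group descriptives
#' (EC mean (SD): HC 3.53 (3.57), DEP/ANX 2.97 (3.06), SUD 1.69 (1.94);
#' DU: HC 3.96 (4.65), DEP/ANX 4.14 (4.57), SUD 5.26 (5.72)). Attrition is
#' 0.25 for HC and the clinical rates implied by the printed
#' baseline/follow-up group sizes (0.35 and 0.53). Entropy-RT coupling
#' targets are 0.11 (HC, DEP/ANX) and 0.16 (SUD).
#'
#' @param n_hc,n_depanx,n_sud Group sizes.
#' @return List of three [group_spec()] objects.
#' @export
default_group_specs <- function(n_hc = 97, n_depanx = 208, n_sud = 175) {
  list(
    group_spec("HC", n_hc, ec_mean = 3.53, ec_sd = 3.57,
               du_mean = 3.96, du_sd = 4.65,
               attrition_prob = 0.25, rt_target_r = 0.11),
    group_spec("DEP_ANX", n_depanx, ec_mean = 2.97, ec_sd = 3.06,
               du_mean = 4.14, du_sd = 4.57,
               attrition_prob = 0.35, rt_target_r = 0.11),
    group_spec("SUD", n_sud, ec_mean = 1.69, ec_sd = 1.94,
               du_mean = 5.26, du_sd = 5.72,
               attrition_prob = 0.53, rt_target_r = 0.16)
  )
}

# log-normal (mu, sigma) matching a raw-scale mean and SD
lnorm_params <- function(m, s) {
  sigma2 <- log(1 + (s / m)^2)
  list(mu = log(m) - sigma2 / 2, sigma = sqrt(sigma2))
}

#' Simulate one subject-visit on the task
#'
#' Per trial: the position is sampled from the agent's choice policy, the
#' outcome from the position's outcome lottery, and
#' `RT = intercept + slope * entropy + N(0, noise_sd)` truncated below at
#' 0.1 s. If `rt_model$target_r` is given, the slope is derived so the
#' expected entropy-RT correlation equals the target.
#'
#' @param params An [agent_params()] (the subject's true parameters).
#' @param design An `aac_design` from [build_task_design()].
#' @param rt_model List with `intercept`, `noise_sd`, and either `slope` or
#'   `target_r`.
#' @param seed Integer seed.
#' @param form Value form for [choice_policy()].
#' @return Trial data.frame: design columns plus `chosen_position`,
#'   `outcome_name`, `outcome_valence`, `outcome_points`, `entropy`, `rt`.
#' @export
simulate_subject <- function(params, design,
                             rt_model = list(intercept = 1.5, target_r = 0.11,
                                             noise_sd = 0.5),
                             seed = 1L, form = "risk") {
  validate_task_design(design)
  pm <- policy_matrix(params, form)
  ent_by_type <- apply(pm, 1, choice_entropy)
  rows <- match(design$trial_type, aac_trial_types())
  outcomes <- aac_outcomes()
  withr::with_seed(as.integer(seed), {
    chosen <- vapply(rows, function(r) sample.int(9L, 1L, prob = pm[r, ]),
                     integer(1))
    p_high <- chosen / 10
    got_high <- stats::runif(length(chosen)) < p_high
    out_idx <- integer(length(chosen))
    for (i in seq_along(chosen)) {
      idx <- trial_outcome_indices(design$trial_type[i])
      out_idx[i] <- if (got_high[i]) idx$high else idx$low
    }
    ent <- ent_by_type[rows]
    slope <- rt_model$slope
    if (is.null(slope)) {
      r <- rt_model$target_r
      s_ent <- stats::sd(ent)
      slope <- if (is.null(r) || !is.finite(s_ent) || s_ent < 1e-10) 0 else
        r / sqrt(1 - r^2) * rt_model$noise_sd / s_ent
    }
    rt <- rt_model$intercept + slope * ent +
      stats::rnorm(length(ent), 0, rt_model$noise_sd)
    rt <- pmax(rt, 0.1)
  })
  data.frame(
    as.data.frame(design),
    chosen_position = chosen,
    outcome_name = outcomes$name[out_idx],
    outcome_valence = outcomes$valence[out_idx],
    outcome_points = outcomes$points[out_idx],
    entropy = unname(ent),
    rt = rt,
    row.names = NULL
  )
}

#' Sample a full cohort
#'
#' Draws subject-level latent log-parameters per visit from a bivariate
#' normal with cross-visit correlation `visit_param_correlation` (matched
#' marginal moments at each visit), simulates 60-trial data at each visit,
#' and drops follow-up data for attrited subjects. Ages are uniform on
#' 18..55; sex is Bernoulli(`prop_female`).
#'
#' @param specs List of [group_spec()] objects.
#' @param seed Integer seed; fully determines the cohort.
#' @param n_per_type Trials per type per visit (default 12).
#' @param form Value form.
#' @return A list of class `aac_cohort`: `trials` (long trial-level
#'   data.frame) and `subjects` (one row per subject-visit with true
#'   parameters and demographics).
#' @export
sample_cohort <- function(specs, seed = 1L, n_per_type = 12L, form = "risk") {
  if (inherits(specs, "group_spec")) specs <- list(specs)
  trials_list <- list()
  subj_list <- list()
  sid <- 0L
  base_seed <- as.integer(seed) %% 100000L
  for (spec in specs) {
    if (spec$n == 0L) {
      warning("group ", spec$name, " has n = 0; skipped")
      next
    }
    ln_ec <- lnorm_params(spec$ec_mean, spec$ec_sd)
    ln_du <- lnorm_params(spec$du_mean, spec$du_sd)
    rho <- spec$visit_param_correlation
    draws <- withr::with_seed(base_seed + match(spec$name, c("HC", "DEP_ANX", "SUD")), {
      z <- function() {
        zb <- stats::rnorm(spec$n)
        zf <- rho * zb + sqrt(1 - rho^2) * stats::rnorm(spec$n)
        cbind(zb, zf)
      }
      list(z_ec = z(), z_du = z(),
           female = stats::runif(spec$n) < spec$prop_female,
           age = round(stats::runif(spec$n, 18, 55), 1),
           attrited = stats::runif(spec$n) < spec$attrition_prob)
    })
    for (i in seq_len(spec$n)) {
      sid <- sid + 1L
      subject_id <- sprintf("%s_%03d", spec$name, i)
      sex <- if (draws$female[i]) "female" else "male"
      sex_mult <- if (draws$female[i]) spec$ec_female_mult else 1
      visits <- if (draws$attrited[i]) "baseline" else c("baseline", "followup")
      for (v in seq_along(visits)) {
        zcol <- v  # 1 = baseline, 2 = followup
        ec_i <- exp(ln_ec$mu + ln_ec$sigma * draws$z_ec[i, zcol]) * sex_mult
        du_i <- exp(ln_du$mu + ln_du$sigma * draws$z_du[i, zcol])
        params <- agent_params(du_i, max(ec_i, 1e-8))
        vseed <- (base_seed * 7L + sid * 13L + zcol * 104729L) %% .Machine$integer.max
        design <- build_task_design(seed = vseed, n_per_type = n_per_type)
        tr <- simulate_subject(params, design,
                               rt_model = list(intercept = spec$rt_intercept,
                                               target_r = spec$rt_target_r,
                                               noise_sd = spec$rt_noise_sd),
                               seed = vseed + 1L, form = form)
        tr <- data.frame(subject_id = subject_id, group = spec$name,
                         sex = sex, age = draws$age[i], visit = visits[v],
                         tr, row.names = NULL)
        trials_list[[length(trials_list) + 1L]] <- tr
        subj_list[[length(subj_list) + 1L]] <- data.frame(
          subject_id = subject_id, group = spec$name, sex = sex,
          age = draws$age[i], visit = visits[v],
          true_du = du_i, true_ec = ec_i, stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(trials = do.call(rbind, trials_list),
                 subjects = do.call(rbind, subj_list)),
            class = "aac_cohort")
}

#' @export
print.aac_cohort <- function(x, ...) {
  cat(sprintf("AAC synthetic cohort: %d subject-visits, %d trials\n",
              nrow(x$subjects), nrow(x$trials)))
  print(table(x$subjects$group, x$subjects$visit))
  invisible(x)
}

#' Prior centered on a cohort specification
#'
#' Moment-matches each group's raw-scale (DU, EC) moments to log-normal
#' parameters and centers a weakly informative prior (default variance 4 on
#' each log parameter) at the pooled log-scale means. This is the natural
#' prior for parameter-recovery experiments, where the generating
#' population is known by construction; for real data, where it is not,
#' the uncentered [prior_spec()] default applies.
#'
#' @param specs List of [group_spec()] objects.
#' @param variance Log-space prior variances (default `c(4, 4)`).
#' @return A [prior_spec()].
#' @export
cohort_prior <- function(specs, variance = c(4, 4)) {
  if (inherits(specs, "group_spec")) specs <- list(specs)
  mus <- vapply(specs, function(s) {
    c(lnorm_params(s$du_mean, s$du_sd)$mu, lnorm_params(s$ec_mean, s$ec_sd)$mu)
  }, numeric(2))
  prior_spec(mean = rowMeans(mus), variance = variance)
}

#' Parameter-recovery experiment
#'
#' Simulates a cohort, fits every subject-visit by [fit_map()], and scores
#' recovery of the log-scale parameters: Pearson correlation, median bias
#' and RMSE of (fitted - true), plus recovered group means for comparison
#' with the injected ordering.
#'
#' @param specs List of [group_spec()] objects.
#' @param prior A [prior_spec()]; defaults to [cohort_prior()] of `specs`.
#' @param seed Integer seed.
#' @param n_per_type Trials per type.
#' @param form Value form.
#' @return A list of class `recovery_report`: `fits` (per subject-visit
#'   data.frame with true and fitted values), `correlations`, `median_bias`,
#'   `rmse`, `group_means`, `n_failed`.
#' @export
recovery_experiment <- function(specs, prior = cohort_prior(specs), seed = 1L,
                                n_per_type = 12L, form = "risk") {
  if (inherits(specs, "group_spec")) specs <- list(specs)
  cohort <- sample_cohort(specs, seed = seed, n_per_type = n_per_type,
                          form = form)
  fits <- fit_cohort(cohort$trials, prior = prior,
                     config = fit_control(form = form))
  merged <- merge(cohort$subjects, fits, by = c("subject_id", "visit"))
  ok <- is.finite(merged$log_du) & is.finite(merged$log_ec)
  n_failed <- sum(!ok)
  merged <- merged[ok, , drop = FALSE]
  tl_du <- log(merged$true_du)
  tl_ec <- log(merged$true_ec)
  correlations <- c(log_du = stats::cor(tl_du, merged$log_du),
                    log_ec = stats::cor(tl_ec, merged$log_ec))
  median_bias <- c(log_du = stats::median(merged$log_du - tl_du),
                   log_ec = stats::median(merged$log_ec - tl_ec))
  rmse <- c(log_du = sqrt(mean((merged$log_du - tl_du)^2)),
            log_ec = sqrt(mean((merged$log_ec - tl_ec)^2)))
  group_means <- stats::aggregate(
    cbind(ec_hat, du_hat, true_ec, true_du) ~ group, data = merged, FUN = mean)
  structure(list(fits = merged, correlations = correlations,
                 median_bias = median_bias, rmse = rmse,
                 group_means = group_means, n_failed = n_failed),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(
    "Parameter recovery (%d subject-visits, %d failed)\n  r(true, fitted): log-DU %.3f, log-EC %.3f\n  median bias:     log-DU %+.3f, log-EC %+.3f\n  RMSE:            log-DU %.3f, log-EC %.3f\n",
    nrow(x$fits), x$n_failed,
    x$correlations[["log_du"]], x$correlations[["log_ec"]],
    x$median_bias[["log_du"]], x$median_bias[["log_ec"]],
    x$rmse[["log_du"]], x$rmse[["log_ec"]]))
  invisible(x)
}

#' Fit every subject-visit in a trial table
#'
#' @param trials Long trial-level data.frame with `subject_id` and `visit`
#'   columns plus the per-trial columns [fit_map()] needs.
#' @param prior A [prior_spec()].
#' @param config A [fit_control()].
#' @return data.frame with one row per subject-visit: estimates, SEs from
#'   the Laplace covariance, fit metrics and convergence flags.
#' @export
fit_cohort <- function(trials, prior = prior_spec(), config = fit_control()) {
  stopifnot(all(c("subject_id", "visit") %in% names(trials)))
  keys <- unique(trials[, c("subject_id", "visit")])
  res <- lapply(seq_len(nrow(keys)), function(i) {
    rows <- trials$subject_id == keys$subject_id[i] &
      trials$visit == keys$visit[i]
    fit <- tryCatch(fit_map(trials[rows, , drop = FALSE], prior, config),
                    error = function(e) NULL)
    if (is.null(fit)) {
      return(data.frame(subject_id = keys$subject_id[i], visit = keys$visit[i],
                        du_hat = NA_real_, ec_hat = NA_real_,
                        log_du = NA_real_, log_ec = NA_real_,
                        se_log_du = NA_real_, se_log_ec = NA_real_,
                        avg_action_prob = NA_real_, accuracy = NA_real_,
                        converged = FALSE, stringsAsFactors = FALSE))
    }
    data.frame(subject_id = keys$subject_id[i], visit = keys$visit[i],
               du_hat = fit$du_hat, ec_hat = fit$ec_hat,
               log_du = fit$log_params[["log_du"]],
               log_ec = fit$log_params[["log_ec"]],
               se_log_du = sqrt(max(fit$posterior_cov[1, 1], 0)),
               se_log_ec = sqrt(max(fit$posterior_cov[2, 2], 0)),
               avg_action_prob = fit$avg_action_probability,
               accuracy = fit$accuracy,
               converged = fit$converged, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
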