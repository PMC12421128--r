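#' Readers, writers and the pipeline driver
#'
#' Trial-level data interchange is plain CSV with a fixed schema; nested
#' reports are JSON; configuration is YAML. A single global seed in the
#' pipeline configuration determines every stochastic output.
#'
#' @name io_and_cli
NULL

trials_schema <- c("subject_id", "group", "sex", "age", "visit",
                   "trial_index", "trial_type", "chosen_position",
                   "outcome_valence", "outcome_points", "rt")

#' Write cohort trials to CSV
#'
#' @param trials Trial-level data.frame (as in an `aac_cohort`'s `trials`).
#' @param path Output file.
#' @export
write_trials <- function(trials, path) {
  missing_cols <- setdiff(trials_schema, names(trials))
  if (length(missing_cols)) {
    stop("trials table missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  utils::write.csv(trials[, union(trials_schema,
                                  intersect(names(trials),
                                            c("high_cue_side",
                                              "start_position", "entropy")))],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read trial-level CSV
#'
#' Validates the schema (missing columns are a named error), rejects rows
#' whose chosen position falls outside 1..9 (count reported via message and
#' the `n_rejected` attribute), and returns the validated table.
#'
#' @param path CSV file written by [write_trials()] or with the same
#'   columns.
#' @return data.frame of class `aac_trials` with attribute `n_rejected`.
#' @export
read_trials <- function(path) {
  trials <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                     error = function(e) stop("cannot read ", path, ": ",
                                              conditionMessage(e)))
  if (nrow(trials) == 0L) stop("empty trials file: ", path)
  missing_cols <- setdiff(trials_schema, names(trials))
  if (length(missing_cols)) {
    stop("schema error, missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- !(trials$chosen_position %in% 1:9)
  if (any(bad)) {
    message(sum(bad), " rows rejected (chosen_position outside 1..9)")
    trials <- trials[!bad, , drop = FALSE]
  }
  attr(trials, "n_rejected") <- sum(bad)
  class(trials) <- c("aac_trials", "data.frame")
  trials
}

#' Read / write a pipeline configuration
#'
#' YAML round-trip of the pipeline settings (seed, cohort sizes, model
#' form, prior, stage switches).
#'
#' @param path YAML file.
#' @param config Configuration list.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Default pipeline configuration
#'
#' @param seed Global seed.
#' @param n_hc,n_depanx,n_sud Cohort sizes.
#' @param form Value form ("risk" or "logpref").
#' @param classify,power Stage switches.
#' @return Configuration list.
#' @export
default_config <- function(seed = 7L, n_hc = 30L, n_depanx = 30L,
                           n_sud = 30L, form = "risk",
                           classify = FALSE, power = FALSE) {
  list(seed = as.integer(seed),
       cohort = list(n_hc = as.integer(n_hc), n_depanx = as.integer(n_depanx),
                     n_sud = as.integer(n_sud)),
       model = list(form = form),
       prior = list(mean = c(0, 0), variance = c(4, 4)),
       stages = list(classify = classify, power = power),
       classifier = list(predictor_set = 5L, folds = 5L, repeats = 1L),
       power = list(n_hc = 60L, n_clinical = 60L, effect_beta = 0.25,
                    reps = 200L))
}

#' Run the full analysis pipeline
#'
#' simulate -> fit -> behavioral measures (-> classify) (-> power), writing
#' `trials.csv`, `fits.csv`, `measures.csv`, `recovery.json`, optionally
#' `stack_report.json` and `power.json`, and a `manifest.json` recording
#' the seed, package version and md5 hashes of every output.
#'
#' @param config Configuration list (see [default_config()]) or a YAML
#'   path.
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  if (is.character(config)) config <- read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  form <- config$model$form
  prior <- prior_spec(config$prior$mean, config$prior$variance)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    out
  }
  specs <- default_group_specs(config$cohort$n_hc, config$cohort$n_depanx,
                               config$cohort$n_sud)
  cohort <- stage("simulate", sample_cohort(specs, seed = seed, form = form))
  write_trials(cohort$trials, file.path(out_dir, "trials.csv"))
  fits <- stage("fit", fit_cohort(cohort$trials, prior = prior,
                                  config = fit_control(form = form)))
  utils::write.csv(fits, file.path(out_dir, "fits.csv"), row.names = FALSE)

  measures <- stage("measures", {
    keys <- unique(cohort$trials[, c("subject_id", "visit")])
    do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
      rows <- cohort$trials$subject_id == keys$subject_id[i] &
        cohort$trials$visit == keys$visit[i]
      sub <- cohort$trials[rows, , drop = FALSE]
      s <- suppressWarnings(summarize_choices(sub))
      fit_row <- fits[fits$subject_id == keys$subject_id[i] &
                        fits$visit == keys$visit[i], ]
      r <- if (is.finite(fit_row$du_hat[1])) {
        as.numeric(entropy_rt_correlation(
          sub, agent_params(fit_row$du_hat[1], max(fit_row$ec_hat[1], 1e-8)),
          form))
      } else NA_real_
      all_row <- s[s$condition == "all", ]
      data.frame(subject_id = keys$subject_id[i], visit = keys$visit[i],
                 mean_position = all_row$mean_position,
                 position_sd = all_row$position_sd,
                 mean_rt = all_row$mean_rt, entropy_rt_r = r)
    }))
  })
  utils::write.csv(measures, file.path(out_dir, "measures.csv"),
                   row.names = FALSE)

  recovery <- stage("recover", {
    merged <- merge(cohort$subjects, fits, by = c("subject_id", "visit"))
    ok <- is.finite(merged$log_du) & is.finite(merged$log_ec)
    merged <- merged[ok, ]
    list(
      r_log_du = stats::cor(log(merged$true_du), merged$log_du),
      r_log_ec = stats::cor(log(merged$true_ec), merged$log_ec),
      median_bias_log_du = stats::median(merged$log_du - log(merged$true_du)),
      median_bias_log_ec = stats::median(merged$log_ec - log(merged$true_ec)),
      n = nrow(merged)
    )
  })
  jsonlite::write_json(recovery, file.path(out_dir, "recovery.json"),
                       auto_unbox = TRUE, digits = NA)

  if (isTRUE(config$stages$classify)) {
    stage("classify", {
      demo <- unique(cohort$subjects[cohort$subjects$group != "HC",
                                     c("subject_id", "group", "sex", "age")])
      demo$label <- as.integer(demo$group == "SUD")
      ft <- build_feature_table(fits, demo, behavioral = measures,
                                predictor_set = config$classifier$predictor_set)
      rep_obj <- stacked_classify(ft, seed = seed,
                                  folds = config$classifier$folds,
                                  repeats = config$classifier$repeats,
                                  control = stack_control(
                                    n_starts = 3L,
                                    mfinal_range = c(5L, 30L),
                                    maxdepth_range = c(1L, 3L),
                                    n_bags = 3L))
      jsonlite::write_json(
        list(per_algorithm = rep_obj$per_algorithm, stacked = rep_obj$stacked,
             weights = as.list(rep_obj$weights),
             variable_importance = as.list(rep_obj$variable_importance)),
        file.path(out_dir, "stack_report.json"), auto_unbox = TRUE,
        digits = NA)
      utils::write.csv(rep_obj$fold_metrics,
                       file.path(out_dir, "stack_folds.csv"),
                       row.names = FALSE)
    })
  }
  if (isTRUE(config$stages$power)) {
    stage("power", {
      spec <- power_sim_spec(n_hc = config$power$n_hc,
                             n_clinical = config$power$n_clinical,
                             effect_beta = config$power$effect_beta,
                             reps = config$power$reps)
      pw <- estimate_power(spec, seed = seed)
      jsonlite::write_json(list(power = pw$power, ci = pw$ci,
                                reps_used = pw$reps_used,
                                n_failed = pw$n_failed,
                                spec = unclass(spec)),
                           file.path(out_dir, "power.json"),
                           auto_unbox = TRUE, digits = NA)
    })
  }
  files <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("aacpomdp")),
    files = as.list(tools::md5sum(file.path(out_dir, files)))
  )
  names(manifest$files) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
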