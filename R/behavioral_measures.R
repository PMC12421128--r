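#' Model-free task measures, entropy-RT coupling, and reliability
#'
#' Model-free summaries are the average chosen runway position, choice
#' variability (the within-subject SD of chosen position) and mean response
#' time, overall and per task condition. The model-based companion is the
#' per-subject Pearson correlation between trial-by-trial choice uncertainty
#' (policy entropy) and RTs. Longitudinal reliability uses the two-way
#' mixed, consistency, single-measure intraclass correlation ICC(3,1).
#'
#' @name behavioral_measures
NULL

#' Per-condition choice summaries
#'
#' Mean and SD (n-1 denominator) of chosen canonical position and mean RT,
#' for each trial type present plus an `"all"` row. Conditions requested but
#' absent from the data are omitted with a warning.
#'
#' @param data Trial data.frame with `trial_type`, `chosen_position` and
#'   optionally `rt`.
#' @param conditions Conditions to summarize (default: the five trial
#'   types).
#' @return data.frame with columns `condition`, `n_trials`, `mean_position`,
#'   `position_sd`, `mean_rt`.
#' @export
summarize_choices <- function(data, conditions = aac_trial_types()) {
  check_trials(data)
  has_rt <- "rt" %in% names(data)
  present <- intersect(conditions, unique(data$trial_type))
  absent <- setdiff(conditions, present)
  if (length(absent)) {
    warning("conditions absent from data, omitted: ",
            paste(absent, collapse = ", "))
  }
  one <- function(rows, label) {
    data.frame(
      condition = label,
      n_trials = nrow(rows),
      mean_position = mean(rows$chosen_position),
      position_sd = if (nrow(rows) > 1L) stats::sd(rows$chosen_position) else 0,
      mean_rt = if (has_rt) mean(rows$rt) else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, lapply(present, function(cc) {
    one(data[data$trial_type == cc, , drop = FALSE], cc)
  }))
  rbind(out, one(data, "all"))
}

#' Entropy-RT correlation for one subject
#'
#' Pearson correlation between trial-by-trial choice uncertainty (policy
#' entropy under `params`) and RT. Non-positive or non-finite RTs are
#' dropped (count reported via the `n_dropped` attribute). If either series
#' has zero variance the correlation is undefined and `NA` is returned with
#' a `reason` attribute.
#'
#' @param data Trial data.frame with `trial_type`, `chosen_position`, `rt`.
#' @param params An [agent_params()] giving the policies whose entropy is
#'   used (typically the subject's fitted parameters).
#' @param form Value form for [choice_policy()].
#' @return Scalar correlation in [-1, 1], or `NA` with attribute `reason`.
#' @export
entropy_rt_correlation <- function(data, params, form = "risk") {
  check_trials(data)
  if (!"rt" %in% names(data)) stop("dataset needs an rt column")
  keep <- is.finite(data$rt) & data$rt > 0
  n_dropped <- sum(!keep)
  data <- data[keep, , drop = FALSE]
  if (nrow(data) < 3L) {
    stop("need at least 3 trials with usable RTs")
  }
  pm <- policy_matrix(params, form)
  ent_by_type <- apply(pm, 1, choice_entropy)
  ent <- ent_by_type[match(data$trial_type, aac_trial_types())]
  out <- if (stats::sd(ent) == 0) {
    structure(NA_real_, reason = "zero variance in entropy")
  } else if (stats::sd(data$rt) == 0) {
    structure(NA_real_, reason = "zero variance in rt")
  } else {
    stats::cor(ent, data$rt)
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' ICC(3,1): two-way mixed, consistency, single measures
#'
#' Computed directly from the two-way ANOVA decomposition with k = 2
#' occasions: `ICC = (MS_subjects - MS_error) / (MS_subjects + (k-1) MS_error)`,
#' where MS_error is the residual after removing subject and occasion
#' effects. Consistency form: invariant to adding a constant to one visit.
#' Labels follow the conventional cutoffs: poor below 0.4, fair 0.4-0.6,
#' good above 0.6.
#'
#' @param visit1,visit2 Numeric vectors paired by subject; pairs with a
#'   missing value in either visit are excluded listwise.
#' @return A list of class `icc_result`: `icc`, `n_pairs`, `label`.
#' @export
icc_3_1 <- function(visit1, visit2) {
  if (length(visit1) != length(visit2)) {
    stop("visit vectors must be the same length")
  }
  ok <- is.finite(visit1) & is.finite(visit2)
  x <- visit1[ok]
  y <- visit2[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete subject pairs")
  k <- 2L
  dat <- cbind(x, y)
  grand <- mean(dat)
  row_means <- rowMeans(dat)
  col_means <- colMeans(dat)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_tot <- sum((dat - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc <- if (msr + (k - 1) * mse == 0) 1 else (msr - mse) / (msr + (k - 1) * mse)
  label <- if (icc < 0.4) "poor" else if (icc <= 0.6) "fair" else "good"
  structure(list(icc = icc, n_pairs = n, label = label),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(3,1) = %.3f (%s), n = %d pairs\n",
              x$icc, x$label, x$n_pairs))
  invisible(x)
}
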