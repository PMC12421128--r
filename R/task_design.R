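#' The approach-avoidance runway task
#'
#' On each trial an avatar is moved to one of nine runway positions. A cue at
#' each end signals the outcome delivered with probability increasing in 10%
#' steps (10% to 90%) as the avatar approaches that end. Five trial types
#' define the outcome pair at stake: avoid-threat (AV), approach-reward (APP)
#' and three conflict levels (CONF2, CONF4, CONF6) that pit an aversive
#' stimulus worth 2, 4 or 6 reward points against a safe 0-point positive
#' stimulus.
#'
#' Positions are canonical 1..9 with position 9 adjacent to the high-end cue
#' (the rewarded/aversive option), so larger mean position means more
#' approach. The physical left/right cue side is recorded for display
#' semantics only; the model operates in this canonical frame.
#'
#' @name task_design
NULL

#' Trial types of the AAC task
#' @return Character vector of the five trial types.
#' @export
aac_trial_types <- function() c("AV", "APP", "CONF2", "CONF4", "CONF6")

#' Enumerate the task's outcome set
#'
#' The model's observation space at trial end: a "starting" sentinel, the
#' positive stimulus with 0 or 2 points, and the negative affective stimulus
#' with 0, 2, 4 or 6 points — seven observations in a fixed order.
#'
#' @return A data.frame with columns `name`, `valence`
#'   (`"none"`/`"positive"`/`"negative"`) and `points`, 7 rows.
#' @export
aac_outcomes <- function() {
  data.frame(
    name    = c("starting", "pos0", "pos2", "neg0", "neg2", "neg4", "neg6"),
    valence = c("none", "positive", "positive",
                "negative", "negative", "negative", "negative"),
    points  = c(0L, 0L, 2L, 0L, 2L, 4L, 6L),
    stringsAsFactors = FALSE
  )
}

# high/low outcome row indices (into aac_outcomes()) for each trial type.
# The low end is always the safe positive 0-point stimulus.
trial_outcome_indices <- function(trial_type) {
  high <- switch(as.character(trial_type),
    AV    = 4L,  # neg0
    APP   = 3L,  # pos2
    CONF2 = 5L,
    CONF4 = 6L,
    CONF6 = 7L,
    stop("unknown trial type: ", trial_type)
  )
  list(high = high, low = 2L)
}

#' Outcome probabilities at a runway position
#'
#' Position 9 is adjacent to the high-end cue: ending there delivers the
#' high-end outcome with probability 0.9 and the low-end outcome with
#' probability 0.1; each step away shifts 10% of mass to the other end.
#'
#' @param position Integer position 1..9.
#' @param trial Ignored except for interface symmetry; probabilities depend
#'   only on position.
#' @return Named numeric `c(p_high=, p_low=)` summing to 1.
#' @export
outcome_probabilities <- function(position, trial = NULL) {
  if (length(position) != 1L || is.na(position) ||
      position != as.integer(position) || position < 1 || position > 9) {
    stop("position must be a single integer in 1..9")
  }
  p_high <- position / 10
  c(p_high = p_high, p_low = 1 - p_high)
}

#' Build a counterbalanced task design
#'
#' Generates `n_per_type` trials of each of the five trial types (default 12,
#' giving the 60-trial design). Cue side alternates within type as evenly as
#' parity allows, start positions cycle through center/left end/right end,
#' and the trial order is shuffled deterministically by `seed`.
#'
#' @param seed Integer seed controlling the trial-order shuffle.
#' @param n_per_type Trials per type (default 12).
#' @return A data.frame of class `aac_design` with columns `trial_index`,
#'   `trial_type`, `high_cue_side`, `start_position`, and attribute
#'   `n_positions = 9`.
#' @export
build_task_design <- function(seed = 1L, n_per_type = 12L) {
  stopifnot(length(n_per_type) == 1L, n_per_type >= 1)
  n_per_type <- as.integer(n_per_type)
  types <- rep(aac_trial_types(), each = n_per_type)
  sides <- rep_len(c("left", "right"), n_per_type)
  starts <- rep_len(c("center", "left_end", "right_end"), n_per_type)
  design <- data.frame(
    trial_type = types,
    high_cue_side = rep(sides, times = 5L),
    start_position = rep(starts, times = 5L),
    stringsAsFactors = FALSE
  )
  ord <- withr::with_seed(as.integer(seed), sample.int(nrow(design)))
  design <- design[ord, , drop = FALSE]
  design <- data.frame(trial_index = seq_len(nrow(design)), design,
                       row.names = NULL)
  attr(design, "n_positions") <- 9L
  class(design) <- c("aac_design", "data.frame")
  design
}

#' Validate a task design
#'
#' Checks the structural invariants: equal trial counts per type, valid
#' type/side/start levels, and consecutive trial indices.
#'
#' @param design An `aac_design` (or plain data.frame with the same columns).
#' @return `design`, invisibly; errors describe the first violated invariant.
#' @export
validate_task_design <- function(design) {
  req <- c("trial_index", "trial_type", "high_cue_side", "start_position")
  missing_cols <- setdiff(req, names(design))
  if (length(missing_cols)) {
    stop("design is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!all(design$trial_type %in% aac_trial_types())) {
    stop("unknown trial types present")
  }
  counts <- table(design$trial_type)
  if (length(unique(as.integer(counts))) != 1L) {
    stop("unequal trial counts per type")
  }
  if (!all(design$high_cue_side %in% c("left", "right"))) {
    stop("invalid high_cue_side values")
  }
  if (!all(design$start_position %in% c("center", "left_end", "right_end"))) {
    stop("invalid start_position values")
  }
  if (!identical(as.integer(design$trial_index), seq_len(nrow(design)))) {
    stop("trial_index must be 1..n in order")
  }
  invisible(design)
}

#' Write / read a task design as CSV
#'
#' @param design An `aac_design`.
#' @param path File path.
#' @return `read_task_design` returns a validated `aac_design`.
#' @export
write_task_design <- function(design, path) {
  validate_task_design(design)
  utils::write.csv(as.data.frame(design), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_task_design
#' @export
read_task_design <- function(path) {
  design <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_task_design(design)
  attr(design, "n_positions") <- 9L
  class(design) <- c("aac_design", "data.frame")
  design
}
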