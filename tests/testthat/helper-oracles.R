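# Independent brute-force oracles, written directly from the task
# definition: two outcomes per trial, nine positions, outcome probability
# ladder k/10, anchored utilities, softmax choice. Deliberately kept free
# of any package internals.

oracle_utilities <- function(ec) {
  # order: starting, pos0, pos2, neg0, neg2, neg4, neg6
  c(0, 0, 2, 0 - ec, 2 - ec, 4 - ec, 6 - ec)
}

# the model's fixed utility-to-log-preference scale, restated here
ORACLE_PREF_SCALE <- 100

oracle_softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# index (into the 7-outcome order) of the high-end outcome per trial type
oracle_high_idx <- c(AV = 4, APP = 3, CONF2 = 5, CONF4 = 6, CONF6 = 7)

oracle_policy <- function(du, ec, trial_type, form = "risk",
                          scale = ORACLE_PREF_SCALE) {
  lnC <- log(oracle_softmax(scale * oracle_utilities(ec)))
  hi <- oracle_high_idx[[trial_type]]
  v <- vapply(1:9, function(k) {
    ph <- k / 10
    ev <- ph * lnC[hi] + (1 - ph) * lnC[2]
    if (form == "risk") ev <- ev - (ph * log(ph) + (1 - ph) * log(1 - ph))
    ev
  }, numeric(1))
  oracle_softmax(v / du)
}

oracle_log_policy <- function(du, ec, trial_type, form = "risk",
                              scale = ORACLE_PREF_SCALE) {
  lnC <- log(oracle_softmax(scale * oracle_utilities(ec)))
  hi <- oracle_high_idx[[trial_type]]
  v <- vapply(1:9, function(k) {
    ph <- k / 10
    ev <- ph * lnC[hi] + (1 - ph) * lnC[2]
    if (form == "risk") ev <- ev - (ph * log(ph) + (1 - ph) * log(1 - ph))
    ev
  }, numeric(1)) / du
  v - (max(v) + log(sum(exp(v - max(v)))))
}

oracle_loglik <- function(du, ec, data, form = "risk") {
  sum(vapply(seq_len(nrow(data)), function(i) {
    lp <- oracle_log_policy(du, ec, data$trial_type[i], form)
    lp[data$chosen_position[i]]
  }, numeric(1)))
}

# small, fast tuning settings for classifier tests; the properties under
# test (null AUC, separability, leakage) do not depend on grid richness
test_stack_control <- function(...) {
  stack_control(n_starts = 2L, mfinal_range = c(5L, 20L),
                maxdepth_range = c(1L, 2L), n_bags = 2L, ...)
}

# feature table with a pure-noise feature set and binary labels
make_noise_table <- function(n, seed, p = 4) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("f", seq_len(p))))
    tab <- data.frame(label = rep(c(0L, 1L), length.out = n), x)
  })
  structure(tab, class = c("feature_table", "data.frame"),
            features = paste0("f", seq_len(p)))
}
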