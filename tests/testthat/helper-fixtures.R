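# Shared fixtures: small synthetic cohorts and hand-built epoch frames.

behaviors <- c("sleep", "sed", "lpa", "mvpa")

# Cohort with no planted effects and configurable noise; single_group draws
# everyone from obesity I so group baselines cannot confound recovery tests.
make_cohort <- function(n = 93, seed = 1, noise_sd = 300,
                        effect_spec = NULL, single_group = FALSE, ...) {
  cfg <- generator_config(
    n_participants = n,
    group_proportions = if (single_group) c(0, 1, 0) else c(23, 41, 29) / 93,
    effect_spec = effect_spec,
    outcome_noise_sd = noise_sd,
    seed = seed, ...)
  generate_cohort(cfg)
}

effect_row <- function(behavior, slope, scale = "ilr", group = "all",
                       outcome = "gmv_right_hippocampus") {
  data.frame(group = group, behavior = behavior, outcome = outcome,
             scale = scale, slope = slope, stringsAsFactors = FALSE)
}

# Minimal epoch frame: one participant, explicit per-epoch values.
make_epochs <- function(enmo, start = "2020-01-06 08:00:00", epoch_s = 60,
                        wear = TRUE, sleep = FALSE, id = "T01") {
  n <- length(enmo)
  data.frame(
    id = rep_len(id, n),
    timestamp = as.POSIXct(start, tz = "UTC") + (seq_len(n) - 1) * epoch_s,
    enmo_mg = enmo,
    wear = rep_len(wear, n),
    sleep = rep_len(sleep, n),
    stringsAsFactors = FALSE)
}

# Full multi-day frame built from per-day minute prescriptions; each day is
# 1440 one-minute epochs starting at midnight of consecutive dates.
make_days <- function(day_specs, id = "T01") {
  out <- lapply(seq_along(day_specs), function(d) {
    sp <- day_specs[[d]]
    enmo <- c(rep(5, sp$sleep), rep(10, sp$sed), rep(100, sp$lpa),
              rep(300, sp$mvpa))
    pad <- 1440 - length(enmo)
    stopifnot(pad >= 0)
    enmo <- c(enmo, rep(10, pad))  # pad with sedentary
    df <- make_epochs(enmo, start = sprintf("2020-01-%02d 00:00:00", 5 + d),
                      epoch_s = 60, id = id)
    df$sleep <- seq_len(1440) <= sp$sleep
    if (!is.null(sp$nonwear)) df$wear[sp$nonwear] <- FALSE
    df
  })
  do.call(rbind, out)
}

# Brute-force normal-equations OLS used as the independent oracle.
ols_oracle <- function(X, y) {
  drop(solve(t(X) %*% X, t(X) %*% y))
}
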