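# Synthetic cohort generation: 4-part time-use compositions closing to
# 1440 min/day, a 33-band awake intensity spectrum, anthropometric and
# sociodemographic covariates, and hippocampal gray-matter outcomes with
# configurable planted effects.

#' Reference descriptive values used for generator defaults
#'
#' Published descriptive statistics (means, standard deviations and group
#' proportions) for a cohort of 93 children with overweight/obesity that the
#' synthetic-data generator emulates by default.  Behavior minutes are
#' averaged daily values; in-bed (sleep) time is the remainder of the 1440-min
#' day after sedentary time (SED), light physical activity (LPA) and
#' moderate-to-vigorous physical activity (MVPA).
#'
#' @return A list with components:
#'   \item{groups}{character vector of weight-status groups}
#'   \item{n_per_group}{named integer vector (sums to 93)}
#'   \item{girls_per_group}{named integer vector}
#'   \item{composition_means}{4-column matrix (sleep, sed, lpa, mvpa) of
#'     group mean minutes/day, rows closing to 1440}
#'   \item{whole_sample_minutes}{named vector of whole-sample mean
#'     minutes/day for sleep, sed, lpa, mvpa}
#'   \item{age, phv, height, bmi, tbv, gmv_left, gmv_right}{per-group
#'     mean/sd tables for covariates and outcomes}
#'   \item{education_props}{per-group proportions of parental university
#'     education (neither/one/both)}
#' @export
reference_descriptives <- function() {
  groups <- c("overweight", "obesity I", "obesity II-III")
  comp <- rbind(
    "overweight"     = c(sed = 534.25, lpa = 277.85, mvpa = 61.76),
    "obesity I"      = c(sed = 559.35, lpa = 273.16, mvpa = 53.84),
    "obesity II-III" = c(sed = 585.78, lpa = 276.49, mvpa = 50.05))
  comp <- cbind(sleep = 1440 - rowSums(comp), comp)
  ms <- function(...) {
    x <- matrix(c(...), ncol = 2, byrow = TRUE,
                dimnames = list(groups, c("mean", "sd")))
    x
  }
  list(
    groups = groups,
    n_per_group = c("overweight" = 23L, "obesity I" = 41L,
                    "obesity II-III" = 29L),
    girls_per_group = c("overweight" = 9L, "obesity I" = 15L,
                        "obesity II-III" = 13L),
    composition_means = comp,
    whole_sample_minutes = c(sleep = 1440 - (561.39 + 275.36 + 54.61),
                             sed = 561.39, lpa = 275.36, mvpa = 54.61),
    age    = ms(10.13, 1.08, 10.29, 1.04, 9.51, 1.14),
    phv    = ms(-2.36, 1.04, -2.10, 0.93, -2.58, 0.91),
    height = ms(142.16, 8.80, 146.59, 7.78, 141.84, 7.08),
    bmi    = ms(22.64, 1.41, 26.26, 2.06, 30.68, 2.36),
    tbv    = ms(1210.02, 99.41, 1221.03, 94.93, 1169.54, 122.50),
    gmv_left  = ms(3387.17, 348.96, 3572.49, 346.40, 3386.71, 397.67),
    gmv_right = ms(3568.46, 420.35, 3709.90, 354.77, 3463.19, 352.41),
    education_props = rbind(
      "overweight"     = c(neither = 0.57, one = 0.17, both = 0.26),
      "obesity I"      = c(neither = 0.59, one = 0.22, both = 0.19),
      "obesity II-III" = c(neither = 0.90, one = 0.07, both = 0.03))
  )
}

#' Default planted outcome effects
#'
#' One row per planted effect on a gray-matter outcome.  `scale = "ilr"`
#' plants the slope on the first pivot coordinate (focal behavior against the
#' geometric mean of the rest), i.e. a gamma-type compositional effect;
#' `scale = "absolute"` plants mm3 per min/day of the behavior.  Defaults
#' emulate the magnitudes the generator is calibrated against: an MVPA
#' compositional effect of 375.3 in obesity type I and an SED compositional
#' effect of -1838.4 in overweight, both on the right hippocampus.
#'
#' @return data.frame with columns `group`, `behavior`, `outcome`, `scale`,
#'   `slope`.
#' @export
default_effect_spec <- function() {
  data.frame(
    group    = c("obesity I", "overweight"),
    behavior = c("mvpa", "sed"),
    outcome  = c("gmv_right_hippocampus", "gmv_right_hippocampus"),
    scale    = c("ilr", "ilr"),
    slope    = c(375.3, -1838.4),
    stringsAsFactors = FALSE)
}

#' Default covariate effects on gray-matter outcomes
#'
#' Plausible nonzero effects (mm3 per unit of the centered covariate) used
#' when generating outcomes; fully config-controlled.
#'
#' @return named numeric vector with elements `sex_female`, `phv`, `edu_one`,
#'   `edu_both`, `tbv`.
#' @export
default_covariate_effects <- function() {
  c(sex_female = -40, phv = 25, edu_one = 20, edu_both = 40, tbv = 1.5)
}

# Log-scale dispersion (per-part sd) and correlation of the logistic-normal
# composition model, calibrated once so that minute-scale SDs approximate the
# reference SDs and pairwise SED/LPA/MVPA correlations fall in 0.3-0.5.
.comp_log_sd <- c(sleep = 0.064, sed = 0.135, lpa = 0.155, mvpa = 0.40)
.comp_log_cor <- local({
  R <- diag(4)
  dimnames(R) <- list(names(.comp_log_sd), names(.comp_log_sd))
  R["sed", "lpa"] <- R["lpa", "sed"] <- 0.10
  R["sed", "mvpa"] <- R["mvpa", "sed"] <- 0.10
  R["lpa", "mvpa"] <- R["mvpa", "lpa"] <- 0.50
  R
})

#' Build and validate a cohort generator configuration
#'
#' @param n_participants number of participants to generate.
#' @param group_proportions 3-vector of weight-status proportions
#'   (overweight, obesity I, obesity II-III); must sum to 1.
#' @param group_composition_means 3x4 matrix of per-group mean minutes for
#'   sleep, sed, lpa, mvpa; each row must sum to 1440.
#' @param composition_dispersion positive scalar multiplying the calibrated
#'   log-ratio-scale dispersion (1 reproduces reference SDs).
#' @param effect_spec data.frame of planted effects, see
#'   [default_effect_spec()]; group `"all"` applies to every group.
#' @param covariate_effects named vector, see [default_covariate_effects()].
#' @param outcome_noise_sd residual SD of the gray-matter outcomes (mm3).
#' @param spectrum_decay geometric decay of within-behavior minute allocation
#'   across intensity bands (0 < decay < 1); smaller concentrates time at low
#'   accelerations.
#' @param spectrum_jitter_sd log-normal jitter applied to the per-participant
#'   band allocation (0 gives a rank-3 spectrum matrix).
#' @param seed integer seed recorded in the config and used by
#'   [generate_cohort()].
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_participants = 93,
                             group_proportions = c(23, 41, 29) / 93,
                             group_composition_means =
                               reference_descriptives()$composition_means,
                             composition_dispersion = 1,
                             effect_spec = default_effect_spec(),
                             covariate_effects = default_covariate_effects(),
                             outcome_noise_sd = 300,
                             spectrum_decay = 0.75,
                             spectrum_jitter_sd = 0.3,
                             seed = 1L) {
  if (length(group_proportions) != 3 || any(group_proportions < 0) ||
      abs(sum(group_proportions) - 1) > 1e-8)
    stop("`group_proportions` must be 3 non-negative values summing to 1",
         call. = FALSE)
  gm <- as.matrix(group_composition_means)
  if (!all(dim(gm) == c(3, 4)) || any(gm <= 0))
    stop("`group_composition_means` must be a positive 3x4 matrix", call. = FALSE)
  if (any(abs(rowSums(gm) - 1440) > 1e-6))
    stop("each group mean composition must sum to 1440 minutes", call. = FALSE)
  if (!is.numeric(composition_dispersion) || composition_dispersion <= 0)
    stop("`composition_dispersion` must be a positive scalar", call. = FALSE)
  if (outcome_noise_sd < 0)
    stop("`outcome_noise_sd` must be non-negative", call. = FALSE)
  if (n_participants < 1)
    stop("`n_participants` must be at least 1", call. = FALSE)
  colnames(gm) <- c("sleep", "sed", "lpa", "mvpa")
  es <- effect_spec
  if (!is.null(es) && nrow(es)) {
    needed <- c("group", "behavior", "outcome", "scale", "slope")
    if (!all(needed %in% names(es)))
      stop("`effect_spec` must have columns ", paste(needed, collapse = ", "),
           call. = FALSE)
    if (!all(es$scale %in% c("ilr", "absolute")))
      stop("`effect_spec$scale` must be 'ilr' or 'absolute'", call. = FALSE)
  }
  structure(list(
    n_participants = as.integer(n_participants),
    group_proportions = stats::setNames(group_proportions,
                                        reference_descriptives()$groups),
    group_composition_means = gm,
    composition_dispersion = composition_dispersion,
    effect_spec = es,
    covariate_effects = covariate_effects,
    outcome_noise_sd = outcome_noise_sd,
    spectrum_decay = spectrum_decay,
    spectrum_jitter_sd = spectrum_jitter_sd,
    seed = as.integer(seed)), class = "generator_config")
}

#' Body mass index
#'
#' @param weight_kg body mass in kg.
#' @param height_cm standing height in cm.
#' @return BMI in kg/m2: weight divided by squared height in meters.
#' @export
compute_bmi <- function(weight_kg, height_cm) {
  if (any(weight_kg <= 0) || any(height_cm <= 0))
    stop("weight and height must be positive", call. = FALSE)
  weight_kg / (height_cm / 100)^2
}

#' Maturity offset from the age of peak height velocity
#'
#' Sex-specific Moore equations: boys use age x seated height,
#' girls use age x standing height.
#'
#' @param sex "male" or "female" (vectorized).
#' @param age decimal age in years.
#' @param height_cm standing height in cm (required for girls).
#' @param seated_height_cm seated height in cm (required for boys).
#' @return years from estimated peak height velocity (negative = before).
#' @export
compute_phv_offset <- function(sex, age, height_cm = NULL,
                               seated_height_cm = NULL) {
  sex <- as.character(sex)
  if (!all(sex %in% c("male", "female")))
    stop("`sex` must be 'male' or 'female'", call. = FALSE)
  if (any(age < 0)) stop("`age` must be non-negative", call. = FALSE)
  n <- max(length(sex), length(age))
  sex <- rep_len(sex, n); age <- rep_len(age, n)
  out <- numeric(n)
  boy <- sex == "male"
  if (any(boy)) {
    if (is.null(seated_height_cm))
      stop("seated height is required for boys", call. = FALSE)
    sh <- rep_len(seated_height_cm, n)
    if (any(sh[boy] <= 0 | is.na(sh[boy])))
      stop("seated height must be positive for boys", call. = FALSE)
    out[boy] <- -8.13 + 0.007 * (age[boy] * sh[boy])
  }
  if (any(!boy)) {
    if (is.null(height_cm))
      stop("standing height is required for girls", call. = FALSE)
    h <- rep_len(height_cm, n)
    if (any(h[!boy] <= 0 | is.na(h[!boy])))
      stop("height must be positive for girls", call. = FALSE)
    out[!boy] <- -7.71 + 0.004 * (age[!boy] * h[!boy])
  }
  out
}

# Largest-remainder rounding of a positive vector to integers with fixed sum.
round_preserving_sum <- function(x, total = round(sum(x))) {
  fl <- floor(x)
  rem <- total - sum(fl)
  if (rem > 0) {
    idx <- order(x - fl, decreasing = TRUE)[seq_len(rem)]
    fl[idx] <- fl[idx] + 1
  }
  fl
}

# Allocate behavior minutes across the 33 intensity bands with a geometric
# decay within each behavior's acceleration range.  Band 1 (25-50 mg)
# receives time from both SED (25-35) and LPA (35-50).
spectrum_from_composition <- function(sed, lpa, mvpa, decay = 0.75,
                                      jitter_sd = 0, n_bands = 33) {
  alloc <- function(minutes, bands, decay, jitter_sd) {
    w <- decay^(seq_along(bands) - 1)
    if (jitter_sd > 0)
      w <- w * exp(stats::rnorm(length(w), 0, jitter_sd))
    minutes * w / sum(w)
  }
  spec <- numeric(n_bands)
  sed_part <- alloc(sed, 1:2, 0.25, jitter_sd)          # bands 0-25, 25-35
  spec[1:2] <- spec[1:2] + sed_part
  lpa_part <- alloc(lpa, 2:8, decay, jitter_sd)         # 35-50 ... 175-200
  spec[2:8] <- spec[2:8] + lpa_part
  mvpa_part <- alloc(mvpa, 9:n_bands, decay, jitter_sd) # 200-225 ... 800+
  spec[9:n_bands] <- spec[9:n_bands] + mvpa_part
  spec
}

#' Column labels for the 33-band intensity spectrum
#'
#' @return character vector `spec_000_025` ... `spec_800_plus`.
#' @export
spectrum_band_labels <- function() {
  lo <- seq(0, 800, by = 25)
  hi <- lo + 25
  labs <- sprintf("spec_%03d_%03d", lo, hi)
  labs[33] <- "spec_800_plus"
  labs
}

#' Generate a synthetic cohort
#'
#' Draws participants group-by-group: compositions are logistic-normal on the
#' log scale around the group mean composition (guaranteeing positivity and
#' closure to 1440 min/day, with correlated behaviors), covariates follow the
#' reference per-group distributions, and gray-matter outcomes are built as
#' group baseline + centered covariate effects + planted compositional or
#' absolute effects + Gaussian noise.
#'
#' @param config a [generator_config()].
#' @return data.frame of class `movecomp_cohort`, one row per participant,
#'   with identification, covariates, behavior minutes (`sleep_min`,
#'   `sed_min`, `lpa_min`, `mvpa_min`), the 33 spectrum columns and the two
#'   hippocampal outcomes.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "generator_config"))
    config <- do.call(generator_config, config)
  ref <- reference_descriptives()
  set.seed(config$seed)
  n <- config$n_participants
  grp <- sample(ref$groups, n, replace = TRUE, prob = config$group_proportions)
  grp <- factor(grp, levels = ref$groups)

  s <- .comp_log_sd * config$composition_dispersion
  Sigma <- diag(s) %*% .comp_log_cor %*% diag(s)
  L <- chol(Sigma)
  E <- matrix(stats::rnorm(n * 4), n, 4) %*% L
  E <- sweep(E, 2, diag(Sigma) / 2, "-")
  M <- config$group_composition_means[as.integer(grp), , drop = FALSE]
  W <- M * exp(E)
  comp <- W / rowSums(W) * 1440
  colnames(comp) <- c("sleep", "sed", "lpa", "mvpa")

  g <- as.integer(grp)
  draw <- function(tab, clamp = NULL) {
    x <- stats::rnorm(n, tab[g, "mean"], tab[g, "sd"])
    if (!is.null(clamp)) x <- pmin(pmax(x, clamp[1]), clamp[2])
    x
  }
  p_girl <- (ref$girls_per_group / ref$n_per_group)[g]
  sex <- ifelse(stats::runif(n) < p_girl, "female", "male")
  age <- draw(ref$age, c(8, 11.99))
  height <- draw(ref$height)
  seated_height <- 0.52 * height + stats::rnorm(n, 0, 1.5)
  bmi <- draw(ref$bmi, c(18, 45))
  weight <- bmi * (height / 100)^2
  phv <- compute_phv_offset(sex, age, height_cm = height,
                            seated_height_cm = seated_height)
  edu <- character(n)
  for (k in seq_len(3)) {
    idx <- which(g == k)
    edu[idx] <- sample(c("neither", "one", "both"), length(idx),
                       replace = TRUE, prob = ref$education_props[k, ])
  }
  edu <- factor(edu, levels = c("neither", "one", "both"))
  tbv <- draw(ref$tbv)

  spec <- t(vapply(seq_len(n), function(i)
    spectrum_from_composition(comp[i, "sed"], comp[i, "lpa"], comp[i, "mvpa"],
                              decay = config$spectrum_decay,
                              jitter_sd = config$spectrum_jitter_sd),
    numeric(33)))
  colnames(spec) <- spectrum_band_labels()

  # centered covariate contribution so group outcome means stay at baseline
  ce <- config$covariate_effects
  edu_p <- ref$education_props[g, , drop = FALSE]
  cov_part <-
    ce[["sex_female"]] * ((sex == "female") - p_girl) +
    ce[["phv"]] * (phv - ref$phv[g, "mean"]) +
    ce[["edu_one"]] * ((edu == "one") - edu_p[, "one"]) +
    ce[["edu_both"]] * ((edu == "both") - edu_p[, "both"]) +
    ce[["tbv"]] * (tbv - ref$tbv[g, "mean"])

  planted <- function(outcome) {
    eff <- numeric(n)
    es <- config$effect_spec
    if (is.null(es) || !nrow(es)) return(eff)
    es <- es[es$outcome == outcome, , drop = FALSE]
    for (r in seq_len(nrow(es))) {
      rows <- if (es$group[r] == "all") seq_len(n) else which(grp == es$group[r])
      if (!length(rows)) next
      beh <- es$behavior[r]
      if (es$scale[r] == "absolute") {
        center <- config$group_composition_means[g[rows], beh]
        eff[rows] <- eff[rows] + es$slope[r] * (comp[rows, beh] - center)
      } else {
        ord <- c(beh, setdiff(c("sleep", "sed", "lpa", "mvpa"), beh))
        z1 <- ilr_pivot(comp[rows, ord, drop = FALSE])[, 1]
        z1_ref <- ilr_pivot(matrix(
          config$group_composition_means[g[rows], ord], ncol = 4,
          dimnames = list(NULL, ord)))[, 1]
        eff[rows] <- eff[rows] + es$slope[r] * (z1 - z1_ref)
      }
    }
    eff
  }
  gmv_l <- ref$gmv_left[g, "mean"] + cov_part +
    planted("gmv_left_hippocampus") +
    stats::rnorm(n, 0, config$outcome_noise_sd)
  gmv_r <- ref$gmv_right[g, "mean"] + cov_part +
    planted("gmv_right_hippocampus") +
    stats::rnorm(n, 0, config$outcome_noise_sd)

  out <- data.frame(
    id = sprintf("P%03d", seq_len(n)),
    sex = factor(sex, levels = c("male", "female")),
    age = age,
    height = height,
    seated_height = seated_height,
    weight = weight,
    bmi = bmi,
    phv_offset = phv,
    parental_education = edu,
    weight_status = grp,
    total_brain_volume = tbv,
    gmv_left_hippocampus = gmv_l,
    gmv_right_hippocampus = gmv_r,
    sleep_min = comp[, "sleep"],
    sed_min = comp[, "sed"],
    lpa_min = comp[, "lpa"],
    mvpa_min = comp[, "mvpa"],
    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(spec))
  class(out) <- c("movecomp_cohort", "data.frame")
  attr(out, "config") <- config
  out
}

#' Generate an epoch-level acceleration series for one participant
#'
#' Builds `n_days` of 1440 minutes each (starting on a Monday) whose epoch
#' magnitudes reproduce the participant's daily behavior minutes under the
#' standard non-dominant-wrist thresholds (<35 mg sedentary, 35-200 mg light,
#' >200 mg moderate-to-vigorous).  Sleep minutes are placed as an early-
#' morning block plus an end-of-day block and flagged; awake epochs are
#' shuffled within the day.  Optional non-wear gaps zero the wear flag.
#'
#' @param record single-row slice of a `movecomp_cohort` (or any list with
#'   `id`, `sleep_min`, `sed_min`, `lpa_min`, `mvpa_min`).
#' @param n_days number of full days (default 7: 5 weekdays + 2 weekend).
#' @param epoch_s epoch length in seconds; must divide 60.
#' @param seed integer seed.
#' @param nonwear optional data.frame with columns `day`, `start_min`,
#'   `duration_min` describing non-wear gaps.
#' @return data.frame with columns `id`, `timestamp` (POSIXct, UTC),
#'   `enmo_mg`, `wear`, `sleep`.
#' @export
generate_epoch_series <- function(record, n_days = 7, epoch_s = 5, seed = 1L,
                                  nonwear = NULL) {
  if (n_days < 1) stop("`n_days` must be at least 1", call. = FALSE)
  if (60 %% epoch_s != 0)
    stop("`epoch_s` must divide 60 seconds", call. = FALSE)
  set.seed(seed)
  mins <- round_preserving_sum(
    c(sleep = record$sleep_min, sed = record$sed_min,
      lpa = record$lpa_min, mvpa = record$mvpa_min), 1440)
  epm <- 60L %/% epoch_s                       # epochs per minute
  morning <- floor(mins["sleep"] * 0.6)
  evening <- mins["sleep"] - morning
  awake <- 1440L - mins["sleep"]

  day_labels <- function() {
    lab <- c(rep("SED", mins["sed"] * epm), rep("LPA", mins["lpa"] * epm),
             rep("MVPA", mins["mvpa"] * epm))
    sample(lab)
  }
  day_enmo <- function(lab) {
    e <- numeric(length(lab))
    e[lab == "SED"] <- stats::runif(sum(lab == "SED"), 1, 34)
    e[lab == "LPA"] <- stats::runif(sum(lab == "LPA"), 36, 199)
    e[lab == "MVPA"] <- 201 + stats::rexp(sum(lab == "MVPA"), 1 / 120)
    e
  }
  origin <- as.POSIXct("2020-01-06 00:00:00", tz = "UTC")   # a Monday
  per_day <- 1440L * epm
  days <- vector("list", n_days)
  for (d in seq_len(n_days)) {
    lab <- day_labels()
    enmo <- numeric(per_day)
    sleepf <- logical(per_day)
    i_morning <- seq_len(morning * epm)
    i_evening <- if (evening > 0)
      per_day - seq_len(evening * epm) + 1L else integer(0)
    i_sleep <- c(i_morning, i_evening)
    sleepf[i_sleep] <- TRUE
    enmo[i_sleep] <- stats::runif(length(i_sleep), 0, 15)
    enmo[!sleepf] <- day_enmo(lab)
    ts <- origin + (d - 1) * 86400 + (seq_len(per_day) - 1) * epoch_s
    days[[d]] <- data.frame(
      id = record$id, timestamp = ts, enmo_mg = enmo,
      wear = TRUE, sleep = sleepf, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, days)
  if (!is.null(nonwear) && nrow(nonwear)) {
    for (r in seq_len(nrow(nonwear))) {
      d0 <- nonwear$day[r]
      if (d0 > n_days) stop("non-wear day beyond series length", call. = FALSE)
      start <- (d0 - 1) * per_day + nonwear$start_min[r] * epm + 1L
      len <- nonwear$duration_min[r] * epm
      idx <- start:(start + len - 1L)
      out$wear[idx] <- FALSE
      out$enmo_mg[idx] <- 0
    }
  }
  out
}

#' @rdname cohort_io
#' @param cohort a `movecomp_cohort` data.frame.
#' @param path file path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Read and write participant tables and epoch series
#'
#' Participant tables are plain CSV, one row per participant with the column
#' schema produced by [generate_cohort()].  Epoch series are long CSV with
#' ISO-8601 timestamps.
#'
#' @name cohort_io
#' @return `read_cohort` returns a `movecomp_cohort`; `read_epochs` returns
#'   an epoch data.frame.
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$sex <- factor(x$sex, levels = c("male", "female"))
  x$parental_education <- factor(x$parental_education,
                                 levels = c("neither", "one", "both"))
  x$weight_status <- factor(x$weight_status,
                            levels = reference_descriptives()$groups)
  class(x) <- c("movecomp_cohort", "data.frame")
  x
}

#' @rdname cohort_io
#' @param epochs epoch data.frame from [generate_epoch_series()].
#' @export
write_epochs <- function(epochs, path) {
  out <- epochs
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_epochs <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$timestamp <- as.POSIXct(x$timestamp, format = "%Y-%m-%dT%H:%M:%S",
                            tz = "UTC")
  x
}
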