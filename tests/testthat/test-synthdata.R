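test_that("BMI follows weight over squared height in meters", {
  expect_equal(compute_bmi(22.64, 100), 22.64)
  expect_equal(compute_bmi(50, 141.42), 50 / 1.4142^2, tolerance = 1e-12)
  expect_equal(round(compute_bmi(50, 141.42), 2), 25.00)
  expect_error(compute_bmi(0, 150), "positive")
  expect_error(compute_bmi(50, -1), "positive")
})

test_that("peak-height-velocity offset applies the sex-specific equations", {
  expect_equal(compute_phv_offset("male", 10, seated_height_cm = 75),
               -8.13 + 0.007 * 750)
  expect_equal(compute_phv_offset("female", 10, height_cm = 140),
               -7.71 + 0.004 * 1400)
  # intercepts at age 0
  expect_equal(compute_phv_offset("male", 0, seated_height_cm = 75), -8.13)
  expect_equal(compute_phv_offset("female", 0, height_cm = 140), -7.71)
  expect_error(compute_phv_offset("male", 10, height_cm = 140),
               "seated height")
  expect_error(compute_phv_offset("other", 10), "male")
  # vectorized over mixed sexes
  got <- compute_phv_offset(c("male", "female"), c(10, 10),
                            height_cm = c(NA, 140),
                            seated_height_cm = c(75, NA))
  expect_equal(got, c(-2.88, -2.11), tolerance = 1e-9)
})

test_that("generator configuration is validated", {
  expect_error(generator_config(group_proportions = c(0.5, 0.5, 0.5)),
               "summing to 1")
  expect_error(generator_config(composition_dispersion = 0), "positive")
  bad_means <- reference_descriptives()$composition_means
  bad_means[1, 1] <- bad_means[1, 1] + 10
  expect_error(generator_config(group_composition_means = bad_means),
               "1440")
  expect_error(generator_config(effect_spec = data.frame(group = "all")),
               "columns")
})

test_that("cohorts are reproducible under a fixed seed", {
  a <- make_cohort(n = 40, seed = 7)
  b <- make_cohort(n = 40, seed = 7)
  expect_identical(a, b)
  c <- make_cohort(n = 40, seed = 8)
  expect_false(identical(a$gmv_right_hippocampus, c$gmv_right_hippocampus))
})

test_that("compositions close to 1440 and spectra sum to awake time", {
  coh <- make_cohort(n = 200, seed = 3)
  comp <- as.matrix(coh[, paste0(behaviors, "_min")])
  expect_true(all(comp > 0))
  expect_lt(max(abs(rowSums(comp) - 1440)), 1e-9)
  spec_sum <- rowSums(coh[, spectrum_band_labels()])
  expect_equal(spec_sum, 1440 - coh$sleep_min, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("zero effects and zero noise give the covariate-only predictor", {
  es <- effect_row("mvpa", 0)
  coh <- make_cohort(n = 60, seed = 5, noise_sd = 0, effect_spec = es)
  # outcome must then be an exact linear function of group + covariates
  fit <- lm(gmv_right_hippocampus ~ weight_status + sex + phv_offset +
              parental_education + total_brain_volume, data = coh)
  expect_lt(max(abs(resid(fit))), 1e-8)
})

test_that("group mean compositions track the configured targets", {
  coh <- make_cohort(n = 400, seed = 11, single_group = TRUE)
  target <- reference_descriptives()$composition_means["obesity I", ]
  comp <- as.matrix(coh[, paste0(behaviors, "_min")])
  se <- apply(comp, 2, sd) / sqrt(nrow(comp))
  expect_true(all(abs(colMeans(comp) - target) < 3 * se))
})

test_that("behaviors are mutually correlated at the calibrated dispersion", {
  coh <- make_cohort(n = 1000, seed = 2)
  cm <- cor(coh[, c("sed_min", "lpa_min", "mvpa_min")])
  rs <- abs(cm[upper.tri(cm)])
  expect_true(all(rs > 0.2 & rs < 0.6))
})

test_that("planted absolute effects appear in the outcome", {
  es <- effect_row("mvpa", 5, scale = "absolute")
  coh <- make_cohort(n = 80, seed = 9, noise_sd = 0, effect_spec = es,
                     single_group = TRUE)
  f <- suppressWarnings(fit_absolute(coh, "mvpa", "gmv_right_hippocampus"))
  expect_equal(f$B, 5, tolerance = 1e-8)
})

test_that("epoch series round-trips the composition and honors bounds", {
  rec <- list(id = "P001", sleep_min = 550, sed_min = 560, lpa_min = 275,
              mvpa_min = 55)
  ep <- generate_epoch_series(rec, n_days = 7, epoch_s = 5, seed = 4)
  summ <- summarize_participant(ep)
  for (b in behaviors)
    expect_lt(abs(summ[[paste0(b, "_min")]] - rec[[paste0(b, "_min")]]), 1)
  expect_true(summ$valid)

  # no MVPA -> no awake epoch above 200 mg
  rec0 <- list(id = "P002", sleep_min = 550, sed_min = 615, lpa_min = 275,
               mvpa_min = 0)
  ep0 <- generate_epoch_series(rec0, n_days = 2, epoch_s = 30, seed = 4)
  expect_true(all(ep0$enmo_mg[!ep0$sleep] <= 200))

  expect_error(generate_epoch_series(rec, epoch_s = 7), "divide 60")
  expect_error(generate_epoch_series(rec, n_days = 0), "at least 1")
})

test_that("an injected non-wear gap reduces wear time by its duration", {
  rec <- list(id = "P003", sleep_min = 550, sed_min = 560, lpa_min = 275,
              mvpa_min = 55)
  nw <- data.frame(day = 2, start_min = 600, duration_min = 60)
  ep <- generate_epoch_series(rec, n_days = 3, epoch_s = 5, seed = 6,
                              nonwear = nw)
  ep_full <- generate_epoch_series(rec, n_days = 3, epoch_s = 5, seed = 6)
  day <- as.Date(ep$timestamp, tz = "UTC")
  daily <- do.call(rbind, lapply(split(impute_nonwear(ep), day),
                                 summarize_day))
  daily_full <- do.call(rbind, lapply(split(ep_full, day), summarize_day))
  expect_equal(daily$wear_hours[2], daily_full$wear_hours[2] - 1.0)
  expect_equal(daily$wear_hours[c(1, 3)], daily_full$wear_hours[c(1, 3)])
})

test_that("cohort and epoch CSV round-trips preserve the data", {
  coh <- make_cohort(n = 10, seed = 13)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(back$sed_min, coh$sed_min, tolerance = 1e-9)
  expect_identical(as.character(back$weight_status),
                   as.character(coh$weight_status))
  ep <- generate_epoch_series(coh[1, ], n_days = 2, epoch_s = 60, seed = 1)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_epochs(ep, path2)
  back2 <- read_epochs(path2)
  expect_equal(back2$enmo_mg, ep$enmo_mg, tolerance = 1e-9)
  expect_identical(back2$timestamp, ep$timestamp)
})
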