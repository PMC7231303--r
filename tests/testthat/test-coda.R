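test_that("closure rescales to the day length", {
  parts <- c(sleep = 480, sed = 560, lpa = 275, mvpa = 55)  # sums to 1370
  closed <- close_composition(parts)
  expect_equal(sum(closed), 1440)
  expect_equal(closed, parts * 1440 / 1370, tolerance = 1e-12)
  expect_equal(close_composition(closed), closed, tolerance = 1e-12)
  expect_error(close_composition(c(sleep = 0, sed = 1, lpa = 1, mvpa = 1)),
               "zero-replacement")
})

test_that("pivot coordinates are symmetric, scale-invariant and match the
           hand-evaluated formula", {
  eq <- c(sleep = 360, sed = 360, lpa = 360, mvpa = 360)
  expect_equal(drop(ilr_pivot(eq)), c(ilr1 = 0, ilr2 = 0, ilr3 = 0))
  comp <- c(sleep = 480, sed = 560, lpa = 300, mvpa = 100)
  expect_equal(ilr_pivot(comp), ilr_pivot(comp * 2), tolerance = 1e-12)
  # focal part double the (equal) rest: sqrt(3/4) * ln(2)
  z <- ilr_pivot(c(sed = 720, sleep = 240, lpa = 240, mvpa = 240))
  expect_equal(unname(z[1, 1]), sqrt(3 / 4) * log(720 / 240),
               tolerance = 1e-9)
  expect_equal(round(unname(z[1, 1]), 4), 0.9514)
  expect_error(ilr_pivot(c(sleep = -1, sed = 1, lpa = 1, mvpa = 1)),
               "positive")
})

test_that("ilr round-trips through its inverse", {
  coh <- make_cohort(n = 50, seed = 31)
  ord <- c("mvpa", "sleep", "sed", "lpa")
  z <- ilr_pivot(coh, ordering = ord)
  back <- ilr_inverse(z, ordering = ord)
  orig <- as.matrix(coh[, paste0(ord, "_min")])
  expect_lt(max(abs(back - orig)), 1e-9)
})

test_that("the compositional mean is the closed geometric mean", {
  one <- c(sleep = 500, sed = 540, lpa = 330, mvpa = 70)
  m <- rbind(one, one, one)
  colnames(m) <- names(one)
  expect_equal(compositional_mean(m), one, tolerance = 1e-12)
  # symmetry under swapping two parts across observations
  two <- rbind(c(500, 540, 330, 70), c(540, 500, 330, 70))
  colnames(two) <- names(one)
  cm <- compositional_mean(two)
  expect_equal(unname(cm[1]), unname(cm[2]), tolerance = 1e-12)
  # recovers the generator's log-scale center within 3 SE (the geometric
  # mean of a log-normal part is its arithmetic target shrunk by half the
  # log-variance)
  coh <- make_cohort(n = 400, seed = 32, single_group = TRUE)
  arith <- reference_descriptives()$composition_means["obesity I", ]
  s2 <- movecomp:::.comp_log_sd^2
  target <- close_composition(arith * exp(-s2 / 2))
  cm2 <- compositional_mean(coh)
  comp <- as.matrix(coh[, paste0(behaviors, "_min")])
  gm_se <- cm2 * apply(log(comp), 2, sd) / sqrt(nrow(comp))
  expect_true(all(abs(cm2 - target) < 3 * gm_se))
})

test_that("reallocation moves minutes between two parts only", {
  base <- c(sleep = 548.6, sed = 561.4, lpa = 275.4, mvpa = 54.6)
  got <- reallocate(base, "sed", "mvpa", 20)
  expect_equal(unname(got),
               c(548.6, 541.4, 275.4, 74.6), tolerance = 1e-12)
  expect_equal(sum(got), sum(base))
  expect_equal(reallocate(base, "sed", "mvpa", 0), base)
  expect_error(reallocate(base, "sed", "mvpa", 561.4), "exhaust")
  expect_error(reallocate(base, "tv", "mvpa", 5), "unknown")
})

test_that("noiseless compositional effects are recovered exactly", {
  coh <- make_cohort(n = 70, seed = 33, noise_sd = 0,
                     effect_spec = effect_row("mvpa", 400),
                     single_group = TRUE)
  f <- suppressWarnings(
    fit_compositional(coh, "mvpa", "gmv_right_hippocampus"))
  expect_equal(f$gamma, 400, tolerance = 1e-7)
  expect_true(f$ci95[1] <= f$gamma && f$gamma <= f$ci95[2])
})

test_that("the model fit is invariant to the pivot ordering", {
  coh <- make_cohort(n = 60, seed = 34)
  fits <- lapply(behaviors, fit_compositional, cohort = coh,
                 outcome = "gmv_right_hippocampus")
  preds <- lapply(fits, function(f) unname(fitted(f$model)))
  for (i in 2:4) expect_equal(preds[[i]], preds[[1]], tolerance = 1e-8)
  r2 <- vapply(fits, function(f) summary(f$model)$r.squared, 0)
  expect_lt(diff(range(r2)), 1e-10)
})

test_that("fit_all_compositional reports one gamma per behavior", {
  coh <- make_cohort(n = 60, seed = 35)
  tab <- fit_all_compositional(coh, "gmv_left_hippocampus")
  expect_equal(tab$behavior, behaviors)
  expect_true(all(tab$ci_lower <= tab$gamma & tab$gamma <= tab$ci_upper))
})

test_that("substitution curves anchor at zero and follow the fitted model", {
  coh <- make_cohort(n = 80, seed = 36, noise_sd = 100,
                     effect_spec = effect_row("mvpa", 400),
                     single_group = TRUE)
  f <- fit_compositional(coh, "mvpa", "gmv_right_hippocampus")
  cv <- substitution_curve(f, donor = "sed", receiver = "mvpa", deltas = 0:20)
  expect_identical(cv$estimate[cv$delta == 0], 0)
  expect_true(all(cv$ci_lower <= cv$estimate & cv$estimate <= cv$ci_upper))
  # positive planted effect -> monotone increasing curve
  expect_true(all(diff(cv$estimate) > 0))

  # outcome built from covariates only -> flat zero curve
  coh0 <- make_cohort(n = 80, seed = 37, noise_sd = 0, single_group = TRUE)
  f0 <- suppressWarnings(
    fit_compositional(coh0, "mvpa", "gmv_right_hippocampus"))
  cv0 <- substitution_curve(f0, donor = "sed", receiver = "mvpa",
                            deltas = 0:20)
  expect_lt(max(abs(cv0$estimate)), 1e-6)
})

test_that("infeasible reallocation grids are truncated with a warning", {
  coh <- make_cohort(n = 40, seed = 38)
  f <- fit_compositional(coh, "mvpa", "gmv_right_hippocampus")
  base <- c(sleep = 500, sed = 30, lpa = 850, mvpa = 60)
  expect_warning(cv <- substitution_curve(f, base = base, donor = "sed",
                                          receiver = "mvpa", deltas = 0:40),
                 "truncated")
  expect_lt(max(cv$delta), 30)
})

test_that("gamma confidence intervals cover an outcome-independent truth", {
  covered <- 0L
  n_reps <- 60
  for (r in seq_len(n_reps)) {
    coh <- make_cohort(n = 93, seed = 4000 + r, noise_sd = 300,
                       single_group = TRUE)
    f <- fit_compositional(coh, "mvpa", "gmv_right_hippocampus")
    covered <- covered + (f$ci95[1] <= 0 && 0 <= f$ci95[2])
  }
  expect_gt(covered / n_reps, 0.85)   # full calibration check in acceptance
})
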