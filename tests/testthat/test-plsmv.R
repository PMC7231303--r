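random_pls_case <- function(seed, n = 40, p = 12, k_signal = 3,
                            noise = 0.5) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  beta <- rnorm(p)
  y <- drop(X[, seq_len(k_signal), drop = FALSE] %*%
              beta[seq_len(k_signal)]) + rnorm(n, 0, noise)
  list(X = X, y = y)
}

test_that("PLS concentrates weight on the informative column", {
  set.seed(51)
  n <- 500
  X <- cbind(sig = rnorm(n), matrix(rnorm(n * 32, 0, 1), n, 32))
  y <- 10 * X[, 1] + rnorm(n)     # SNR 10 on the single informative column
  fit <- pls_fit(X, y, k = 1)
  w <- abs(fit$W[, 1])
  expect_gt(w[1] / max(w[-1]), 5)
})

test_that("duplicated columns are tolerated and share weights", {
  case <- random_pls_case(52)
  X <- cbind(case$X, dup = case$X[, 1])
  fit <- pls_fit(X, case$y, k = 2)
  expect_equal(fit$W[1, ], fit$W[ncol(X), ], tolerance = 1e-10)
  expect_equal(fit$b[1], fit$b[ncol(X)], tolerance = 1e-10)
  expect_true(all(is.finite(predict(fit))))
})

test_that("a response orthogonal to X yields near-zero explained variance", {
  set.seed(53)
  X <- matrix(rnorm(50 * 8), 50, 8)
  y0 <- rnorm(50)
  # project y onto the orthogonal complement of the centered columns
  Xc <- scale(X, scale = FALSE)
  y <- y0 - Xc %*% solve(crossprod(Xc), crossprod(Xc, y0))
  expect_warning(fit <- pls_fit(X, drop(y), k = 1), "orthogonal")
  expect_equal(fit$n_components, 0)
  expl <- 1 - var(drop(y) - predict(fit)) / var(drop(y))
  expect_lt(expl, 1e-8)
  expect_error(target_project(fit), "zero regression vector")
})

test_that("k above the predictor rank is rejected", {
  set.seed(54)
  X <- matrix(rnorm(30), 30, 1)
  X <- cbind(X, X, X)    # rank 1
  y <- rnorm(30)
  expect_error(pls_fit(X, y, k = 2), "rank")
  expect_silent(pls_fit(X, y, k = 1))
})

test_that("target projection reproduces full-model predictions", {
  for (seed in 55:64) {
    case <- random_pls_case(seed, k_signal = sample(2:5, 1))
    k <- sample(1:4, 1)
    fit <- pls_fit(case$X, case$y, k)
    tp <- target_project(fit)
    pred_full <- predict(fit)
    pred_tp <- fit$y_mean + tp$scores * (sum(tp$scores * fit$y_centered) /
                                           sum(tp$scores^2))
    expect_equal(pred_tp, pred_full, tolerance = 1e-8)
  }
})

test_that("for k = 1 the TP component equals the PLS component up to sign", {
  case <- random_pls_case(65)
  fit <- pls_fit(case$X, case$y, k = 1)
  tp <- target_project(fit)
  cosang <- abs(sum(tp$scores * fit$Ts[, 1])) /
    sqrt(sum(tp$scores^2) * sum(fit$Ts[, 1]^2))
  expect_equal(cosang, 1, tolerance = 1e-10)
})

test_that("selectivity ratios are bounded and attain their limits", {
  set.seed(66)
  n <- 80
  v <- rnorm(n)
  cnoise <- rnorm(n)
  vc <- v - mean(v)
  # orthogonalize the noise column against v so its weight (and hence any
  # contribution to the TP scores) is exactly zero
  cnoise <- cnoise - vc * sum((cnoise - mean(cnoise)) * vc) / sum(vc^2)
  X <- cbind(a = v, b = 2 * v + 3, c = cnoise, neg = -0.5 * v)
  y <- v
  sr <- selectivity_ratios(X, y, k = 1)
  expect_true(all(abs(sr$sr) <= 1 + 1e-12, na.rm = TRUE))
  expect_equal(sr$sr[sr$band == "a"], 1, tolerance = 1e-8)
  expect_equal(sr$sr[sr$band == "b"], 1, tolerance = 1e-8)
  expect_equal(sr$sr[sr$band == "neg"], -1, tolerance = 1e-8)
  expect_equal(sr$sr[sr$band == "c"], 0, tolerance = 1e-8)

  # zero-variance band reported as missing
  X2 <- cbind(X, e = rep(1, n))
  sr2 <- selectivity_ratios(X2, y, k = 1)
  expect_true(is.na(sr2$sr[sr2$band == "e"]))
})

test_that("SR of uninformative bands stays small at large n", {
  set.seed(67)
  n <- 500
  X <- cbind(sig = rnorm(n), matrix(rnorm(n * 10), n, 10))
  y <- 3 * X[, 1] + rnorm(n)
  sr <- selectivity_ratios(X, y, k = 1)
  expect_true(all(abs(sr$sr[-1]) < 0.1))
  expect_gt(sr$sr[1], 0.8)
})

test_that("bounded SRs hold across random instances", {
  for (seed in 70:79) {
    case <- random_pls_case(seed)
    sr <- selectivity_ratios(case$X, case$y, k = 2)
    expect_true(all(abs(sr$sr) <= 1 + 1e-12, na.rm = TRUE))
  }
})

test_that("Monte-Carlo CV separates signal from noise and is reproducible", {
  set.seed(80)
  n <- 80
  plan <- mc_cv_plan(60, 0.5, seed = 5)
  # strong single-latent-component signal: X and y share one latent score
  t0 <- rnorm(n)
  X <- outer(t0, rnorm(15)) + matrix(rnorm(n * 15, 0, 0.1), n, 15)
  y <- 2 * t0 + rnorm(n, 0, 0.5)
  cv <- mc_cross_validate(X, y, k_max = 3, plan = plan)
  expect_equal(cv$selected_k, 1)
  # pure noise
  y0 <- rnorm(n)
  cv0 <- mc_cross_validate(X, y0, k_max = 3, plan = plan)
  expect_equal(cv0$selected_k, 0)
  # bit-reproducible under the same plan
  cv_again <- mc_cross_validate(X, y, k_max = 3, plan = plan)
  expect_identical(cv$msep, cv_again$msep)
  expect_error(mc_cross_validate(X[1:5, ], y[1:5], plan = plan),
               "at least 10")
})

test_that("degenerate plans are flagged", {
  expect_warning(mc_cv_plan(1), "unstable")
  expect_error(mc_cv_plan(10, holdout_fraction = 1), "in \\(0, 1\\)")
  expect_error(mc_cv_plan(0), "at least 1")
})

test_that("planted low-negative/high-positive band effects reproduce the
           sign pattern across the spectrum", {
  coh <- make_cohort(n = 120, seed = 81, single_group = TRUE)
  X <- as.matrix(coh[, spectrum_band_labels()])
  set.seed(82)
  # outcome lower with sedentary time, higher with vigorous activity
  y <- -scale(coh$sed_min)[, 1] + 2 * scale(coh$mvpa_min)[, 1] +
    rnorm(120, 0, 0.5)
  sr <- selectivity_ratios(X, y, k = 2)
  expect_lt(sr$sr[1], 0)                       # 0-25 mg band (sedentary)
  expect_true(all(sr$sr[9:30] > 0))            # >200 mg bands (MVPA)
  expect_gt(mean(sr$sr[9:30]), 0.3)
})

test_that("percentile CIs from the MC splits contain the point estimate", {
  case <- random_pls_case(82, n = 60)
  plan <- mc_cv_plan(40, 0.5, seed = 3)
  sr <- selectivity_ratios(case$X, case$y, k = 2, plan = plan)
  ok <- is.finite(sr$ci_lower)
  expect_true(any(ok))
  expect_true(all(sr$ci_lower[ok] <= sr$ci_upper[ok]))
  inside <- mean(sr$sr[ok] >= sr$ci_lower[ok] & sr$sr[ok] <= sr$ci_upper[ok])
  expect_gt(inside, 0.8)
})
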