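# Multivariate pattern analysis: single-response (PLS1) partial least
# squares regression of an outcome on the 33-band intensity spectrum,
# Monte-Carlo cross-validation for component selection, target projection,
# and selectivity ratios with resampling confidence intervals.

#' Fit a single-response PLS regression (NIPALS/PLS1)
#'
#' Columns of `X` are mean-centered and (by default) unit-variance scaled;
#' the response is centered.  Completely collinear predictor columns are
#' tolerated — that is the point of using PLS on the intensity spectrum.
#'
#' @param X numeric predictor matrix (n x p), e.g. spectrum minutes.
#' @param y numeric response (length n), typically covariate-residualized.
#' @param k number of latent components; must not exceed the rank of the
#'   centered predictor matrix.
#' @param scale logical; unit-variance scaling of the columns (columns with
#'   zero variance are left unscaled and carry no weight).
#' @return object of class `movecomp_pls`: scores `Ts`, weights `W`,
#'   x-loadings `P`, y-loadings `q`, regression vector `b` (scaled space),
#'   centering/scaling record, `Xc` (pre-treated matrix) and `y_centered`.
#' @export
pls_fit <- function(X, y, k, scale = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must match nrow(X)", call. = FALSE)
  if (k < 1) stop("`k` must be at least 1", call. = FALSE)
  if (n <= k) stop("need more observations than components", call. = FALSE)
  x_mean <- colMeans(X)
  Xc <- sweep(X, 2, x_mean)
  x_sd <- rep(1, p)
  if (scale) {
    x_sd <- apply(Xc, 2, stats::sd)
    x_sd[x_sd == 0] <- 1
    Xc <- sweep(Xc, 2, x_sd, "/")
  }
  rank_x <- qr(Xc)$rank
  if (k > rank_x)
    stop("`k` (", k, ") exceeds the rank of the centered predictors (",
         rank_x, ")", call. = FALSE)
  y_mean <- mean(y)
  yc <- y - y_mean
  W <- P <- matrix(0, p, k)
  Ts <- matrix(0, n, k)
  q <- numeric(k)
  Xd <- Xc; yd <- yc
  k_actual <- k
  for (a in seq_len(k)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-10 * max(1, sqrt(sum(yc^2)))) {
      # response (residual) orthogonal to the predictor space: stop early
      k_actual <- a - 1L
      if (k_actual == 0)
        warning("response is orthogonal to the predictors; ",
                "returning a 0-component (mean-only) model")
      break
    }
    w <- w / nw
    t_ <- Xd %*% w
    tt <- sum(t_^2)
    p_ <- crossprod(Xd, t_) / tt
    q[a] <- sum(yd * t_) / tt
    Xd <- Xd - tcrossprod(t_, p_)
    yd <- yd - q[a] * t_
    W[, a] <- w; P[, a] <- p_; Ts[, a] <- t_
  }
  W <- W[, seq_len(k_actual), drop = FALSE]
  P <- P[, seq_len(k_actual), drop = FALSE]
  Ts <- Ts[, seq_len(k_actual), drop = FALSE]
  q <- q[seq_len(k_actual)]
  # regression vector in the pre-treated X space
  b <- if (k_actual > 0) W %*% solve(crossprod(P, W), q) else numeric(p)
  structure(list(
    n_components = k_actual, W = W, P = P, Ts = Ts, q = q, b = drop(b),
    x_mean = x_mean, x_sd = x_sd, scale = scale,
    y_mean = y_mean, Xc = Xc, y_centered = yc,
    col_names = colnames(X)), class = "movecomp_pls")
}

#' Predict from a fitted PLS model
#'
#' @param object a `movecomp_pls` fit.
#' @param newdata predictor matrix on the original scale; defaults to the
#'   training matrix.
#' @param ... unused.
#' @return numeric predictions of the response.
#' @export
predict.movecomp_pls <- function(object, newdata = NULL, ...) {
  Xc <- if (is.null(newdata)) object$Xc else {
    Z <- sweep(as.matrix(newdata), 2, object$x_mean)
    sweep(Z, 2, object$x_sd, "/")
  }
  drop(Xc %*% object$b) + object$y_mean
}

#' Monte-Carlo cross-validation plan
#'
#' @param n_repetitions number of random splits (study default 1000).
#' @param holdout_fraction fraction of subjects kept as external validation
#'   set per repetition (study default 0.5).
#' @param seed integer seed making the split sequence reproducible.
#' @return object of class `mc_cv_plan`.
#' @export
mc_cv_plan <- function(n_repetitions = 1000, holdout_fraction = 0.5,
                       seed = 1L) {
  if (n_repetitions < 1) stop("need at least 1 repetition", call. = FALSE)
  if (holdout_fraction <= 0 || holdout_fraction >= 1)
    stop("`holdout_fraction` must be in (0, 1)", call. = FALSE)
  if (n_repetitions == 1)
    warning("a single Monte-Carlo repetition gives very unstable error ",
            "estimates and degenerate confidence intervals")
  structure(list(n_repetitions = as.integer(n_repetitions),
                 holdout_fraction = holdout_fraction,
                 seed = as.integer(seed)), class = "mc_cv_plan")
}

# Deterministic train/holdout index list for a plan.
mc_cv_splits <- function(n, plan) {
  n_hold <- max(1L, min(n - 2L, round(n * plan$holdout_fraction)))
  set.seed(plan$seed)
  lapply(seq_len(plan$n_repetitions), function(i) {
    hold <- sample.int(n, n_hold)
    list(train = setdiff(seq_len(n), hold), hold = hold)
  })
}

#' Select the number of PLS components by Monte-Carlo cross-validation
#'
#' For each repetition the subjects are split at random; models with
#' 1..`k_max` components are fitted on the training half and evaluated on
#' the held-out half, alongside the 0-component reference (training-mean
#' prediction).  The selected size is the smallest `k` whose mean validation
#' error is within one standard error of the minimum; `k = 0` means the
#' spectrum carries no validated predictive information ("no predictive
#' model").
#'
#' @param X predictor matrix.
#' @param y response vector.
#' @param k_max largest component count to consider.
#' @param plan an [mc_cv_plan()].
#' @return object of class `movecomp_mc_cv`: `selected_k`, `error_curve`
#'   (data.frame of k, mean MSEP, SE), `msep` (repetitions x (k_max+1)
#'   matrix), `plan`.
#' @export
mc_cross_validate <- function(X, y, k_max = 5, plan = mc_cv_plan()) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 10) stop("need at least 10 subjects to split", call. = FALSE)
  splits <- mc_cv_splits(n, plan)
  msep <- matrix(NA_real_, plan$n_repetitions, k_max + 1)
  for (i in seq_along(splits)) {
    tr <- splits[[i]]$train; ho <- splits[[i]]$hold
    ytr <- y[tr]; yho <- y[ho]
    msep[i, 1] <- mean((yho - mean(ytr))^2)
    kfit <- min(k_max, qr(scale(X[tr, , drop = FALSE], scale = FALSE))$rank,
                length(tr) - 1)
    if (kfit < 1) next
    fit <- suppressWarnings(pls_fit(X[tr, , drop = FALSE], ytr, kfit))
    if (fit$n_components == 0) {
      msep[i, -1] <- msep[i, 1]
      next
    }
    # predictions for every truncated component count from one fit
    Zho <- sweep(sweep(X[ho, , drop = FALSE], 2, fit$x_mean), 2, fit$x_sd, "/")
    R <- fit$W %*% solve(crossprod(fit$P, fit$W))   # p x k, scores = Xc R
    Tho <- Zho %*% R
    for (k in seq_len(k_max)) {
      kk <- min(k, fit$n_components)
      pred <- fit$y_mean + Tho[, seq_len(kk), drop = FALSE] %*%
        fit$q[seq_len(kk)]
      msep[i, k + 1] <- mean((yho - pred)^2)
    }
  }
  mean_err <- colMeans(msep, na.rm = TRUE)
  se_err <- apply(msep, 2, function(col)
    stats::sd(col, na.rm = TRUE) / sqrt(sum(is.finite(col))))
  best <- which.min(mean_err)
  threshold <- mean_err[best] + se_err[best]
  selected <- min(which(mean_err <= threshold)) - 1L
  structure(list(
    selected_k = selected,
    error_curve = data.frame(k = 0:k_max, msep = mean_err, se = se_err),
    msep = msep, plan = plan), class = "movecomp_mc_cv")
}

#' @export
print.movecomp_mc_cv <- function(x, ...) {
  if (x$selected_k == 0) {
    cat("Monte-Carlo CV: no predictive model (k = 0)\n")
  } else {
    cat(sprintf("Monte-Carlo CV: %d component(s) selected\n", x$selected_k))
  }
  print(x$error_curve, row.names = FALSE)
  invisible(x)
}

#' Target projection of a fitted PLS model
#'
#' Compresses a k-component model into a single component along the
#' normalized regression vector: scores `t_tp = Xc b / ||b||`, loadings
#' `p_tp = Xc' t_tp / (t_tp' t_tp)`.  The single component reproduces the
#' full model's predictions exactly.
#'
#' @param model a `movecomp_pls` fit.
#' @return object of class `movecomp_tp`: `scores`, `loadings`, `w_norm`.
#' @export
target_project <- function(model) {
  stopifnot(inherits(model, "movecomp_pls"))
  nb <- sqrt(sum(model$b^2))
  if (nb < 1e-12) stop("zero regression vector", call. = FALSE)
  w_tp <- model$b / nb
  t_tp <- drop(model$Xc %*% w_tp)
  p_tp <- drop(crossprod(model$Xc, t_tp)) / sum(t_tp^2)
  structure(list(scores = t_tp, loadings = p_tp, w_norm = nb,
                 col_names = model$col_names), class = "movecomp_tp")
}

# Point selectivity ratios for a pre-treated matrix and TP component.
sr_point <- function(Xc, tp) {
  expl <- outer(tp$scores, tp$loadings)
  v_expl <- apply(expl, 2, stats::var)
  v_tot <- apply(Xc, 2, stats::var)
  sr <- sign(tp$loadings) * v_expl / v_tot
  sr[v_tot == 0] <- NA_real_
  sr
}

#' Selectivity ratios with Monte-Carlo confidence intervals
#'
#' For each predictor band the selectivity ratio is the signed fraction of
#' its variance explained by the target-projection component:
#' `SR_j = sign(p_tp_j) * var(t_tp p_tp_j) / var(x_j)`, bounded in [-1, 1].
#' When a cross-validation plan is supplied, 95% intervals are the 2.5/97.5
#' percentiles of the ratios recomputed on each Monte-Carlo training split.
#'
#' @param X predictor matrix on the original scale.
#' @param y response vector.
#' @param k number of components (e.g. from [mc_cross_validate()]).
#' @param plan optional [mc_cv_plan()] for percentile intervals.
#' @return data.frame of class `movecomp_sr_profile`: `band`, `sr`,
#'   `ci_lower`, `ci_upper`; attributes `n_components` and
#'   `explained_variance` (fraction of response variance explained).
#' @export
selectivity_ratios <- function(X, y, k, plan = NULL) {
  X <- as.matrix(X)
  model <- pls_fit(X, y, k)
  tp <- target_project(model)
  sr <- sr_point(model$Xc, tp)
  ci <- matrix(NA_real_, ncol(X), 2)
  if (!is.null(plan)) {
    splits <- mc_cv_splits(nrow(X), plan)
    srs <- matrix(NA_real_, length(splits), ncol(X))
    for (i in seq_along(splits)) {
      tr <- splits[[i]]$train
      fit_i <- tryCatch(pls_fit(X[tr, , drop = FALSE], y[tr], k),
                        error = function(e) NULL)
      if (is.null(fit_i)) next
      # the TP direction follows the regression vector, so no sign ambiguity
      srs[i, ] <- sr_point(fit_i$Xc, target_project(fit_i))
    }
    ci <- t(apply(srs, 2, stats::quantile, probs = c(0.025, 0.975),
                  na.rm = TRUE))
  }
  pred <- predict(model)
  expl_var <- 1 - stats::var(y - pred) / stats::var(y)
  out <- data.frame(
    band = model$col_names %||% paste0("x", seq_along(sr)),
    sr = sr, ci_lower = ci[, 1], ci_upper = ci[, 2],
    stringsAsFactors = FALSE)
  attr(out, "n_components") <- k
  attr(out, "explained_variance") <- expl_var
  class(out) <- c("movecomp_sr_profile", "data.frame")
  out
}

#' Residualize an outcome on the standard covariates
#'
#' PLS has no native covariate slot, so confounders are regressed out of the
#' response before modelling the spectrum.
#'
#' @param cohort a `movecomp_cohort`.
#' @param outcome outcome column name.
#' @param covariates covariate set.
#' @return numeric vector of residuals.
#' @export
residualize_outcome <- function(cohort, outcome,
                                covariates = movecomp_covariates()) {
  cf <- covariate_frame(cohort, covariates)
  dat <- cbind(data.frame(.y = cohort[[outcome]]), cf)
  stats::resid(stats::lm(.y ~ ., data = dat))
}

#' Full multivariate pattern analysis of the intensity spectrum
#'
#' Residualizes the outcome on the covariates, selects the component count
#' by Monte-Carlo cross-validation, and (when a validated model exists)
#' computes the target-projection selectivity-ratio profile.
#'
#' @param cohort a `movecomp_cohort` (optionally a single weight-status
#'   group).
#' @param outcome outcome column name.
#' @param k_max largest component count considered.
#' @param plan an [mc_cv_plan()].
#' @param covariates covariate set.
#' @return list with `cv` (`movecomp_mc_cv`), `profile`
#'   (`movecomp_sr_profile` or `NULL` when no predictive model) and `n`.
#' @export
pls_spectrum_analysis <- function(cohort, outcome, k_max = 5,
                                  plan = mc_cv_plan(),
                                  covariates = movecomp_covariates()) {
  X <- as.matrix(cohort[, spectrum_band_labels()])
  y <- residualize_outcome(cohort, outcome, covariates)
  cv <- mc_cross_validate(X, y, k_max = k_max, plan = plan)
  profile <- NULL
  if (cv$selected_k >= 1)
    profile <- selectivity_ratios(X, y, cv$selected_k, plan = plan)
  list(cv = cv, profile = profile, n = nrow(cohort))
}
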