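# Compositional data analysis of the 4-part {sleep, SED, LPA, MVPA} daily
# composition: closure, isometric log-ratio pivot coordinates, covariate-
# adjusted compositional regression (gamma coefficients) and isotemporal-
# substitution reallocation curves.

.behaviors <- c("sleep", "sed", "lpa", "mvpa")

# Accept a named vector, matrix or cohort and return an n x D positive matrix
# in the requested part order.
as_comp_matrix <- function(x, parts = .behaviors) {
  if (inherits(x, "movecomp_cohort") || (is.data.frame(x) &&
      all(paste0(parts, "_min") %in% names(x)))) {
    m <- as.matrix(x[, paste0(parts, "_min")])
    colnames(m) <- parts
  } else if (is.matrix(x) || is.data.frame(x)) {
    m <- as.matrix(x)
    if (!is.null(colnames(m)) && all(parts %in% colnames(m)))
      m <- m[, parts, drop = FALSE]
    colnames(m) <- parts
  } else {
    m <- matrix(x, nrow = 1)
    if (!is.null(names(x)) && all(parts %in% names(x)))
      m <- matrix(x[parts], nrow = 1)
    colnames(m) <- parts
  }
  storage.mode(m) <- "double"
  m
}

#' Close a composition to a fixed total
#'
#' @param parts positive numeric vector (or matrix, row-wise) of part values.
#' @param total closure constant, default 1440 minutes/day.
#' @return parts rescaled to sum to `total`.
#' @export
close_composition <- function(parts, total = 1440) {
  m <- if (is.matrix(parts)) parts else matrix(parts, nrow = 1,
                                               dimnames = list(NULL, names(parts)))
  if (any(m <= 0))
    stop("compositions must be strictly positive; apply a zero-replacement ",
         "strategy before closure", call. = FALSE)
  out <- m / rowSums(m) * total
  if (!is.matrix(parts)) out <- stats::setNames(drop(out), colnames(m))
  out
}

#' Isometric log-ratio pivot coordinates
#'
#' Coordinate k of a D-part composition is
#' `sqrt((D-k)/(D-k+1)) * ln(x_k / gmean(x_{k+1}, ..., x_D))`, so the first
#' coordinate carries the first (focal) part against the geometric mean of
#' all remaining parts.  Scale-invariant: closure is not required.
#'
#' @param comp composition: named vector, n x D matrix, or cohort.
#' @param ordering character vector of part names placing the focal part
#'   first; defaults to the column order of `comp`.
#' @return n x (D-1) matrix of pivot coordinates (a 1-row matrix for a
#'   single composition).
#' @export
ilr_pivot <- function(comp, ordering = NULL) {
  default_parts <- if (is.matrix(comp)) colnames(comp) %||% .behaviors
  else if (!is.null(names(comp)) && !is.data.frame(comp)) names(comp)
  else .behaviors
  m <- as_comp_matrix(comp, parts = ordering %||% default_parts)
  if (any(m <= 0)) stop("composition parts must be strictly positive",
                        call. = FALSE)
  D <- ncol(m)
  lm_ <- log(m)
  z <- matrix(0, nrow(m), D - 1)
  for (k in seq_len(D - 1)) {
    rest <- rowMeans(lm_[, (k + 1):D, drop = FALSE])
    z[, k] <- sqrt((D - k) / (D - k + 1)) * (lm_[, k] - rest)
  }
  colnames(z) <- paste0("ilr", seq_len(D - 1))
  z
}

#' Inverse of the pivot-coordinate transform
#'
#' @param z (D-1)-vector or n x (D-1) matrix of pivot coordinates.
#' @param ordering part names in the order used by [ilr_pivot()].
#' @param total closure constant.
#' @return composition matrix closed to `total`, columns in `ordering`.
#' @export
ilr_inverse <- function(z, ordering = .behaviors, total = 1440) {
  zm <- if (is.matrix(z)) z else matrix(z, nrow = 1)
  D <- ncol(zm) + 1
  lx <- matrix(0, nrow(zm), D)
  for (k in seq_len(D - 1)) {
    a <- sqrt((D - k) / (D - k + 1))
    lx[, k] <- lx[, k] + zm[, k] / a * ((D - k) / (D - k + 1))
    add <- zm[, k] / a / (D - k + 1)
    lx[, (k + 1):D] <- lx[, (k + 1):D, drop = FALSE] - add
  }
  x <- exp(lx)
  x <- x / rowSums(x) * total
  colnames(x) <- ordering
  x
}

#' Compositional (geometric) mean of a cohort's behaviors
#'
#' Component-wise geometric mean, re-closed to the day length.
#'
#' @param x cohort or composition matrix.
#' @param total closure constant.
#' @return named 4-part composition summing to `total`.
#' @export
compositional_mean <- function(x, total = 1440) {
  m <- as_comp_matrix(x)
  if (any(m <= 0)) stop("composition parts must be strictly positive",
                        call. = FALSE)
  g <- exp(colMeans(log(m)))
  close_composition(g, total)
}

#' Move minutes from one behavior to another
#'
#' @param base named 4-part composition (minutes/day).
#' @param donor,receiver behavior names among sleep/sed/lpa/mvpa.
#' @param delta_min minutes to move; must leave the donor strictly positive.
#' @return reallocated composition (same total).
#' @export
reallocate <- function(base, donor, receiver, delta_min) {
  comp <- drop(as_comp_matrix(base)[1, ])
  if (!donor %in% names(comp) || !receiver %in% names(comp))
    stop("unknown donor/receiver behavior", call. = FALSE)
  if (delta_min >= comp[donor])
    stop("reallocation would exhaust the donor behavior (",
         round(comp[donor], 1), " min available)", call. = FALSE)
  comp[donor] <- comp[donor] - delta_min
  comp[receiver] <- comp[receiver] + delta_min
  comp
}

# Shared design-matrix construction for covariate adjustment.  Parental
# education enters as two dummies against the "neither parent" reference.
covariate_frame <- function(cohort, covariates) {
  df <- data.frame(row.names = seq_len(nrow(cohort)))
  for (cv in covariates) {
    if (cv == "sex") {
      df$sex_female <- as.numeric(cohort$sex == "female")
    } else if (cv == "parental_education") {
      df$edu_one <- as.numeric(cohort$parental_education == "one")
      df$edu_both <- as.numeric(cohort$parental_education == "both")
    } else {
      df[[cv]] <- cohort[[cv]]
    }
  }
  df
}

#' Covariate-adjusted compositional regression
#'
#' Ordinary least squares of the outcome on all three pivot coordinates of
#' the daily composition (focal behavior rotated to first position) plus the
#' standard covariates.  The gamma coefficient is the coefficient of the
#' first coordinate: the association of the focal behavior relative to all
#' remaining behaviors.
#'
#' @param cohort a `movecomp_cohort`.
#' @param focal one of `"sleep"`, `"sed"`, `"lpa"`, `"mvpa"`.
#' @param outcome outcome column, e.g. `"gmv_right_hippocampus"`.
#' @param covariates covariate set, see [movecomp_covariates()].
#' @param conf_level confidence level for the gamma interval.
#' @return object of class `movecomp_coda_fit` with elements `focal`,
#'   `outcome`, `gamma`, `ci95`, `p_value`, `n`, `coefficients`, `vcov`,
#'   `ordering`, `covariate_means`, `base_composition`, `model`.
#' @export
fit_compositional <- function(cohort, focal, outcome,
                              covariates = movecomp_covariates(),
                              conf_level = 0.95) {
  stopifnot(focal %in% .behaviors)
  ordering <- c(focal, setdiff(.behaviors, focal))
  z <- ilr_pivot(as_comp_matrix(cohort), ordering = ordering)
  cf <- covariate_frame(cohort, covariates)
  dat <- cbind(data.frame(.y = cohort[[outcome]]), as.data.frame(z), cf)
  fit <- stats::lm(.y ~ ., data = dat)
  check_full_rank(fit)
  sm <- summary(fit)$coefficients
  est <- sm["ilr1", "Estimate"]
  se <- sm["ilr1", "Std. Error"]
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df = fit$df.residual)
  structure(list(
    focal = focal, outcome = outcome,
    gamma = est,
    ci95 = c(lower = est - tcrit * se, upper = est + tcrit * se),
    p_value = sm["ilr1", "Pr(>|t|)"],
    n = nrow(dat),
    coefficients = stats::coef(fit),
    vcov = stats::vcov(fit),
    ordering = ordering,
    covariate_means = colMeans(cf),
    base_composition = compositional_mean(cohort),
    model = fit), class = "movecomp_coda_fit")
}

#' @export
print.movecomp_coda_fit <- function(x, ...) {
  cat(sprintf(
    "Compositional fit: %s relative to remaining behaviors -> %s\n",
    x$focal, x$outcome))
  cat(sprintf("  gamma = %.2f  95%% CI [%.2f, %.2f]  p = %.4g  (n = %d)\n",
              x$gamma, x$ci95[1], x$ci95[2], x$p_value, x$n))
  invisible(x)
}

#' Fit the compositional model with each behavior rotated to focal position
#'
#' @inheritParams fit_compositional
#' @return data.frame with one row per behavior: gamma, CI bounds, p, n.
#' @export
fit_all_compositional <- function(cohort, outcome,
                                  covariates = movecomp_covariates()) {
  rows <- lapply(.behaviors, function(b) {
    f <- fit_compositional(cohort, b, outcome, covariates)
    data.frame(behavior = b, outcome = outcome, gamma = f$gamma,
               ci_lower = f$ci95[1], ci_upper = f$ci95[2],
               p_value = f$p_value, n = f$n, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Isotemporal-substitution reallocation curve
#'
#' Predicted outcome difference (vs. the base composition) when `delta`
#' minutes/day are moved from the donor to the receiver behavior, with
#' covariates held fixed (they cancel in the difference).  Confidence band by
#' the delta method: the difference is linear in the fitted ilr coefficients,
#' so its variance is `d' V d` with `d` the ilr difference vector.
#'
#' @param fit a `movecomp_coda_fit`.
#' @param base base composition; defaults to the fit's compositional mean.
#' @param donor,receiver behavior names.
#' @param deltas grid of minutes/day to reallocate (may include 0).
#' @param conf_level confidence level of the band.
#' @return data.frame of class `movecomp_realloc_curve` with columns `delta`,
#'   `estimate`, `ci_lower`, `ci_upper` (mm3 difference vs. base).
#' @export
substitution_curve <- function(fit, base = NULL, donor = "sed",
                               receiver = "mvpa", deltas = 0:30,
                               conf_level = 0.95) {
  stopifnot(inherits(fit, "movecomp_coda_fit"))
  base <- if (is.null(base)) fit$base_composition else
    drop(as_comp_matrix(base)[1, ])
  feasible <- deltas < base[donor] & (base[receiver] + deltas) > 0
  if (!all(feasible)) {
    warning("reallocation grid truncated to keep the donor positive")
    deltas <- deltas[feasible]
  }
  z0 <- ilr_pivot(base, ordering = fit$ordering)
  ilr_names <- colnames(z0)
  beta <- fit$coefficients[ilr_names]
  V <- fit$vcov[ilr_names, ilr_names]
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df = fit$model$df.residual)
  est <- se <- numeric(length(deltas))
  for (i in seq_along(deltas)) {
    comp_i <- if (deltas[i] == 0) base else
      reallocate(base, donor, receiver, deltas[i])
    d <- drop(ilr_pivot(comp_i, ordering = fit$ordering)) - drop(z0)
    est[i] <- sum(beta * d)
    se[i] <- sqrt(drop(t(d) %*% V %*% d))
  }
  out <- data.frame(delta = deltas, estimate = est,
                    ci_lower = est - tcrit * se, ci_upper = est + tcrit * se)
  attr(out, "donor") <- donor
  attr(out, "receiver") <- receiver
  class(out) <- c("movecomp_realloc_curve", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
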