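# Standard multiple linear regression of gray-matter volume on absolute
# behavior minutes with fixed covariates, a weight-status moderation screen
# (joint F-test at alpha = 0.15) and stratified fits.

#' Standard covariate set
#'
#' All analyses adjust for the same confounders: sex, peak-height-velocity
#' offset, parental university education (two dummies against "neither") and
#' total brain volume.
#'
#' @return character vector of covariate names.
#' @export
movecomp_covariates <- function() {
  c("sex", "phv_offset", "parental_education", "total_brain_volume")
}

behavior_column <- function(behavior) {
  stopifnot(behavior %in% c("sleep", "sed", "lpa", "mvpa"))
  paste0(behavior, "_min")
}

check_full_rank <- function(fit) {
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(fit)
}

#' Linear regression of an outcome on absolute behavior minutes
#'
#' Ordinary least squares of the outcome on one behavior's daily minutes
#' plus the standard covariates.  Separate models are fitted per behavior
#' (each behavior in isolation, not conditioning on the others).
#'
#' @param cohort a `movecomp_cohort`.
#' @param behavior one of `"sleep"`, `"sed"`, `"lpa"`, `"mvpa"`.
#' @param outcome outcome column name.
#' @param covariates covariate set, see [movecomp_covariates()].
#' @param conf_level confidence level.
#' @return object of class `movecomp_lm_fit`: `behavior`, `outcome`, `B`
#'   (non-standardized mm3 per min/day), `ci95`, `p_value`, `n`,
#'   `coefficients`, `model`.
#' @export
fit_absolute <- function(cohort, behavior, outcome,
                         covariates = movecomp_covariates(),
                         conf_level = 0.95) {
  col <- behavior_column(behavior)
  cf <- covariate_frame(cohort, covariates)
  dat <- cbind(data.frame(.y = cohort[[outcome]],
                          .behavior = cohort[[col]]), cf)
  if (nrow(dat) < ncol(dat) + 1)
    stop("need at least one more observation than parameters", call. = FALSE)
  if (stats::var(dat$.behavior) == 0)
    stop("rank-deficient design; collinear column(s): ", col, call. = FALSE)
  fit <- stats::lm(.y ~ ., data = dat)
  check_full_rank(fit)
  sm <- summary(fit)$coefficients
  est <- sm[".behavior", "Estimate"]
  se <- sm[".behavior", "Std. Error"]
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df = fit$df.residual)
  structure(list(
    behavior = behavior, outcome = outcome,
    B = est,
    ci95 = c(lower = est - tcrit * se, upper = est + tcrit * se),
    p_value = sm[".behavior", "Pr(>|t|)"],
    n = nrow(dat),
    coefficients = stats::coef(fit),
    model = fit), class = "movecomp_lm_fit")
}

#' @export
print.movecomp_lm_fit <- function(x, ...) {
  cat(sprintf("Absolute-minutes fit: %s -> %s\n", x$behavior, x$outcome))
  cat(sprintf("  B = %.3f  95%% CI [%.3f, %.3f]  p = %.4g  (n = %d)\n",
              x$B, x$ci95[1], x$ci95[2], x$p_value, x$n))
  invisible(x)
}

#' Weight-status moderation screen
#'
#' F-test comparing the covariate-adjusted model with and without
#' behavior-by-weight-status interaction terms (2 df with three groups).  A
#' liberal alpha of 0.15 flags moderation, triggering stratified analysis.
#'
#' @inheritParams fit_absolute
#' @param alpha moderation threshold (default 0.15).
#' @return object of class `movecomp_moderation`: `behavior`, `outcome`,
#'   `p_interaction`, `moderated`, `df_interaction`.
#' @export
test_moderation <- function(cohort, behavior, outcome,
                            covariates = movecomp_covariates(),
                            alpha = 0.15) {
  col <- behavior_column(behavior)
  groups <- droplevels(factor(cohort$weight_status))
  tab <- table(groups)
  if (any(tab == 0) || nlevels(groups) < 2)
    stop("moderation test needs at least two non-empty weight-status groups",
         call. = FALSE)
  if (any(tab < 3))
    warning("weight-status group(s) with fewer than 3 participants: ",
            paste(names(tab)[tab < 3], collapse = ", "))
  cf <- covariate_frame(cohort, covariates)
  dat <- cbind(data.frame(.y = cohort[[outcome]],
                          .behavior = cohort[[col]],
                          .group = groups), cf)
  f0 <- stats::lm(.y ~ ., data = dat)
  f1 <- stats::lm(.y ~ . + .behavior:.group, data = dat)
  an <- stats::anova(f0, f1)
  p <- an[["Pr(>F)"]][2]
  structure(list(
    behavior = behavior, outcome = outcome,
    p_interaction = p,
    moderated = is.finite(p) && p < alpha,
    df_interaction = an$Df[2]), class = "movecomp_moderation")
}

#' @export
print.movecomp_moderation <- function(x, ...) {
  cat(sprintf(
    "Moderation screen (%s -> %s): p = %.4g (%d df) -> %s\n",
    x$behavior, x$outcome, x$p_interaction, x$df_interaction,
    if (x$moderated) "stratify" else "no moderation"))
  invisible(x)
}

#' Fit the absolute-minutes model within each weight-status group
#'
#' @inheritParams fit_absolute
#' @return named list of `movecomp_lm_fit`, one per group; groups too small
#'   to fit are skipped with a warning.
#' @export
stratify_and_fit <- function(cohort, behavior, outcome,
                             covariates = movecomp_covariates()) {
  groups <- droplevels(factor(cohort$weight_status))
  out <- list()
  for (gl in levels(groups)) {
    sub <- cohort[groups == gl, , drop = FALSE]
    res <- tryCatch(fit_absolute(sub, behavior, outcome, covariates),
                    error = function(e) {
                      warning("group '", gl, "' skipped: ",
                              conditionMessage(e))
                      NULL
                    })
    if (!is.null(res)) out[[gl]] <- res
  }
  out
}
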