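# Orchestration: descriptive tables, behavior correlations, figure
# analogues and the configured end-to-end run.

#' Percent of the 24-hour day spent in a behavior
#'
#' @param minutes mean minutes/day (vectorized).
#' @param digits rounding digits (default 0: integer percent, as reported in
#'   descriptive tables).
#' @return percentage of 1440 minutes.
#' @export
percent_of_day <- function(minutes, digits = 0) {
  round(minutes / 1440 * 100, digits)
}

#' Express an outcome difference as a percentage of a baseline value
#'
#' Used to report reallocation effects (mm3) relative to a group's mean
#' gray-matter volume.
#'
#' @param effect difference on the outcome scale (e.g. mm3).
#' @param baseline baseline value on the same scale.
#' @param digits rounding digits (default 0).
#' @return percentage.
#' @export
percent_of_baseline <- function(effect, baseline, digits = 0) {
  if (any(baseline <= 0)) stop("baseline must be positive", call. = FALSE)
  round(effect / baseline * 100, digits)
}

mean_sd_row <- function(x) {
  s <- if (length(x) < 2) 0 else stats::sd(x)
  sprintf("%.2f (%.2f)", mean(x), s)
}

#' Descriptive characteristics table
#'
#' Mean (SD) of covariates, outcomes and behavior minutes, plus parental-
#' education percentages, per weight-status group and overall; behaviors are
#' additionally expressed as integer percent of the 24-h day.
#'
#' @param cohort a `movecomp_cohort`.
#' @return list with `table` (character data.frame in descriptive-table
#'   layout) and `percent_of_day` (named integer vector for sed, lpa, mvpa
#'   and in-bed time, overall).
#' @export
describe_cohort <- function(cohort) {
  if (!nrow(cohort)) stop("empty cohort", call. = FALSE)
  groups <- levels(droplevels(cohort$weight_status))
  empty <- setdiff(levels(cohort$weight_status), groups)
  if (length(empty))
    warning("empty weight-status group(s) omitted: ",
            paste(empty, collapse = ", "))
  cols <- c("All", groups)
  slices <- c(list(All = cohort),
              stats::setNames(lapply(groups, function(g)
                cohort[cohort$weight_status == g, , drop = FALSE]), groups))
  num_vars <- c("Age (years)" = "age", "PHV (years)" = "phv_offset",
                "Weight (kg)" = "weight", "Height (cm)" = "height",
                "BMI (kg/m2)" = "bmi",
                "Total brain volume" = "total_brain_volume",
                "L hippocampus (mm3)" = "gmv_left_hippocampus",
                "R hippocampus (mm3)" = "gmv_right_hippocampus",
                "Sleep (min/day)" = "sleep_min", "SED (min/day)" = "sed_min",
                "LPA (min/day)" = "lpa_min", "MVPA (min/day)" = "mvpa_min")
  rows <- lapply(names(num_vars), function(v)
    vapply(slices, function(s) mean_sd_row(s[[num_vars[[v]]]]), ""))
  edu <- lapply(c("neither", "one", "both"), function(lv)
    vapply(slices, function(s)
      sprintf("%.0f", 100 * mean(s$parental_education == lv)), ""))
  tab <- as.data.frame(do.call(rbind, c(rows, edu)))
  names(tab) <- vapply(slices, function(s)
    sprintf("%s (n = %d)", "", nrow(s)), "")
  names(tab) <- sprintf("%s (n = %d)", cols,
                        vapply(slices, nrow, 0L))
  tab <- cbind(Variable = c(names(num_vars),
                            paste0("Parental university: ",
                                   c("neither", "one", "both"), " (%)")),
               tab)
  pods <- c(sed = percent_of_day(mean(cohort$sed_min)),
            lpa = percent_of_day(mean(cohort$lpa_min)),
            mvpa = percent_of_day(mean(cohort$mvpa_min)),
            in_bed = percent_of_day(mean(cohort$sleep_min)))
  list(table = tab, percent_of_day = pods)
}

#' Pairwise Pearson correlations among behaviors and outcomes
#'
#' @param cohort a `movecomp_cohort`.
#' @return data.frame with variable pair, r and p-value.
#' @export
behavior_correlations <- function(cohort) {
  vars <- c("sed_min", "lpa_min", "mvpa_min",
            "gmv_left_hippocampus", "gmv_right_hippocampus")
  combs <- utils::combn(vars, 2)
  rows <- apply(combs, 2, function(pair) {
    ct <- stats::cor.test(cohort[[pair[1]]], cohort[[pair[2]]])
    data.frame(var1 = pair[1], var2 = pair[2],
               r = unname(ct$estimate), p_value = ct$p.value)
  })
  do.call(rbind, rows)
}

#' Build a pipeline run configuration
#'
#' @param generator a [generator_config()] (used when `participants_csv` is
#'   `NULL`).
#' @param participants_csv optional path to an existing participant table.
#' @param epochs_csv optional path to a long epoch CSV; when given, behavior
#'   minutes and spectra are re-derived from the epochs (accelerometer
#'   route) and invalid participants are excluded.
#' @param outcomes outcome columns to analyze.
#' @param analyses character subset of `c("absolute", "coda", "pls")`.
#' @param stratify run analyses within weight-status groups as well.
#' @param mc_reps,mc_holdout Monte-Carlo cross-validation settings.
#' @param reallocation_max largest reallocation (min/day) for curves.
#' @param seed master seed recorded in the manifest.
#' @param out_dir output directory.
#' @param figures write figure analogues (PNG when supported, else PDF).
#' @return object of class `movecomp_run_config`.
#' @export
run_config <- function(generator = generator_config(),
                       participants_csv = NULL,
                       epochs_csv = NULL,
                       outcomes = c("gmv_right_hippocampus",
                                    "gmv_left_hippocampus"),
                       analyses = c("absolute", "coda", "pls"),
                       stratify = TRUE,
                       mc_reps = 100, mc_holdout = 0.5,
                       reallocation_max = 30,
                       seed = 1L,
                       out_dir = "movecomp_run",
                       figures = TRUE) {
  if (!length(analyses))
    stop("at least one analysis must be enabled", call. = FALSE)
  analyses <- match.arg(analyses, c("absolute", "coda", "pls"),
                        several.ok = TRUE)
  structure(list(generator = generator, participants_csv = participants_csv,
                 epochs_csv = epochs_csv, outcomes = outcomes,
                 analyses = analyses, stratify = stratify,
                 mc_reps = mc_reps, mc_holdout = mc_holdout,
                 reallocation_max = reallocation_max,
                 seed = as.integer(seed), out_dir = out_dir,
                 figures = figures), class = "movecomp_run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Top-level keys mirror the [run_config()] arguments; a `generator` mapping
#' mirrors [generator_config()] (with `group_composition_means` as a 3x4
#' row-list).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `movecomp_run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.null(cfg$generator)) {
    g <- cfg$generator
    if (!is.null(g$group_composition_means))
      g$group_composition_means <- do.call(rbind, g$group_composition_means)
    if (!is.null(g$effect_spec))
      g$effect_spec <- as.data.frame(g$effect_spec)
    cfg$generator <- do.call(generator_config, g)
  }
  do.call(run_config, cfg)
}

write_csv_out <- function(x, dir, name) {
  utils::write.csv(x, file.path(dir, name), row.names = FALSE)
}

open_figure <- function(path_base, width = 7, height = 5) {
  if (capabilities("png")) {
    grDevices::png(paste0(path_base, ".png"), width = width, height = height,
                   units = "in", res = 150)
  } else {
    grDevices::pdf(paste0(path_base, ".pdf"), width = width, height = height)
  }
}

forest_plot <- function(tab, est_col, title) {
  ord <- seq_len(nrow(tab))
  graphics::plot(tab[[est_col]], ord, xlim = range(tab$ci_lower,
                                                   tab$ci_upper, 0),
                 pch = 16, yaxt = "n", ylab = "", xlab = est_col,
                 main = title)
  graphics::segments(tab$ci_lower, ord, tab$ci_upper, ord)
  graphics::abline(v = 0, lty = 2)
  lab <- paste(tab$behavior, tab$group %||% "", sep = " ")
  graphics::axis(2, at = ord, labels = lab, las = 1, cex.axis = 0.6)
}

#' Run the full analysis pipeline
#'
#' Generates (or reads) the participant table, optionally re-derives
#' behaviors from epoch data with validity filtering, writes the descriptive
#' table and correlation matrix, and runs the enabled analyses overall and
#' per weight-status group.  All outputs are CSV/JSON plus optional figure
#' analogues; the manifest records seeds and versions so a run can be
#' reproduced exactly.
#'
#' @param config a `movecomp_run_config` or path to a YAML/JSON file.
#' @return (invisibly) the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "movecomp_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  fig_dir <- file.path(config$out_dir, "figures")
  if (config$figures) dir.create(fig_dir, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("movecomp %s | R %s | seed %d",
       as.character(utils::packageVersion("movecomp")),
       paste(R.version$major, R.version$minor, sep = "."), config$seed)

  cohort <- if (!is.null(config$participants_csv)) {
    read_cohort(config$participants_csv)
  } else {
    gen <- config$generator
    gen$seed <- config$seed
    generate_cohort(gen)
  }
  n0 <- nrow(cohort)

  if (!is.null(config$epochs_csv)) {
    epochs <- read_epochs(config$epochs_csv)
    summ <- summarize_cohort_epochs(epochs)
    keep <- summ$id[summ$valid]
    logf("accelerometer validity filter: %d of %d participants valid",
         length(keep), n0)
    beh <- c("sleep_min", "sed_min", "lpa_min", "mvpa_min",
             spectrum_band_labels())
    cohort <- cohort[cohort$id %in% keep, , drop = FALSE]
    idx <- match(cohort$id, summ$id)
    cohort[, beh] <- summ[idx, beh]
  }
  if (!nrow(cohort)) stop("no valid participants remain", call. = FALSE)
  logf("cohort: %d participants, %d analyzed", n0, nrow(cohort))

  write_cohort(cohort, file.path(config$out_dir, "participants.csv"))
  desc <- describe_cohort(cohort)
  write_csv_out(desc$table, config$out_dir, "table1.csv")
  write_csv_out(behavior_correlations(cohort), config$out_dir,
                "correlations.csv")

  groups <- c(list(All = cohort),
              if (config$stratify)
                split(cohort, droplevels(cohort$weight_status)))
  behaviors <- c("sed", "lpa", "mvpa")

  if ("absolute" %in% config$analyses) {
    rows <- list()
    for (oc in config$outcomes) {
      for (b in behaviors) {
        mod <- tryCatch(suppressWarnings(test_moderation(cohort, b, oc)),
                        error = function(e)
                          list(p_interaction = NA_real_, moderated = NA))
        for (gname in names(groups)) {
          g <- groups[[gname]]
          f <- tryCatch(fit_absolute(g, b, oc), error = function(e) NULL)
          if (is.null(f)) next
          rows[[length(rows) + 1]] <- data.frame(
            outcome = oc, behavior = b, group = gname, n = f$n,
            B = f$B, ci_lower = f$ci95[1], ci_upper = f$ci95[2],
            p_value = f$p_value, p_interaction = mod$p_interaction,
            moderated = mod$moderated, row.names = NULL)
        }
      }
    }
    abs_tab <- do.call(rbind, rows)
    write_csv_out(abs_tab, config$out_dir, "absolute_models.csv")
    if (config$figures) {
      open_figure(file.path(fig_dir, "absolute_forest"))
      forest_plot(abs_tab[abs_tab$outcome == config$outcomes[1], ], "B",
                  "Absolute-minutes models (B, 95% CI)")
      grDevices::dev.off()
    }
  }

  if ("coda" %in% config$analyses) {
    rows <- list(); curves <- list()
    for (oc in config$outcomes) {
      for (gname in names(groups)) {
        g <- groups[[gname]]
        tab <- tryCatch(fit_all_compositional(g, oc),
                        error = function(e) NULL)
        if (is.null(tab)) next
        tab$group <- gname
        rows[[length(rows) + 1]] <- tab
        for (receiver in c("lpa", "mvpa")) {
          fit <- fit_compositional(g, receiver, oc)
          cv <- substitution_curve(fit, donor = "sed", receiver = receiver,
                                   deltas = 0:config$reallocation_max)
          cv$outcome <- oc; cv$group <- gname
          cv$donor <- "sed"; cv$receiver <- receiver
          curves[[length(curves) + 1]] <- as.data.frame(cv)
        }
      }
    }
    coda_tab <- do.call(rbind, rows)
    curve_tab <- do.call(rbind, curves)
    write_csv_out(coda_tab, config$out_dir, "coda_models.csv")
    write_csv_out(curve_tab, config$out_dir, "reallocation_curves.csv")
    if (config$figures) {
      open_figure(file.path(fig_dir, "coda_forest"))
      ct <- coda_tab[coda_tab$outcome == config$outcomes[1], ]
      names(ct)[names(ct) == "gamma"] <- "gamma"
      forest_plot(transform(ct, B = gamma), "gamma",
                  "Compositional models (gamma, 95% CI)")
      grDevices::dev.off()
      open_figure(file.path(fig_dir, "reallocation_curves"))
      sub <- curve_tab[curve_tab$outcome == config$outcomes[1] &
                         curve_tab$group == "All", ]
      graphics::plot(NULL, xlim = range(sub$delta),
                     ylim = range(sub$ci_lower, sub$ci_upper),
                     xlab = "minutes/day reallocated from SED",
                     ylab = "predicted GMV difference (mm3)",
                     main = "Isotemporal substitution")
      for (rc in split(sub, sub$receiver)) {
        graphics::lines(rc$delta, rc$estimate)
        graphics::lines(rc$delta, rc$ci_lower, lty = 3)
        graphics::lines(rc$delta, rc$ci_upper, lty = 3)
      }
      graphics::abline(h = 0, lty = 2)
      grDevices::dev.off()
    }
  }

  if ("pls" %in% config$analyses) {
    rows <- list()
    for (oc in config$outcomes) {
      for (gname in names(groups)) {
        g <- groups[[gname]]
        if (nrow(g) < 10) next
        plan <- mc_cv_plan(config$mc_reps, config$mc_holdout,
                           seed = config$seed)
        res <- pls_spectrum_analysis(g, oc, plan = plan)
        logf("pls %s / %s: selected k = %d", oc, gname, res$cv$selected_k)
        if (is.null(res$profile)) {
          rows[[length(rows) + 1]] <- data.frame(
            outcome = oc, group = gname, n = res$n, band = NA, sr = NA,
            ci_lower = NA, ci_upper = NA, n_components = 0)
        } else {
          pr <- as.data.frame(res$profile)
          pr$outcome <- oc; pr$group <- gname; pr$n <- res$n
          pr$n_components <- attr(res$profile, "n_components")
          rows[[length(rows) + 1]] <- pr[, c("outcome", "group", "n",
                                             "band", "sr", "ci_lower",
                                             "ci_upper", "n_components")]
          if (config$figures) {
            open_figure(file.path(
              fig_dir, paste0("sr_profile_", oc, "_", gsub("\\W", "_", gname))))
            graphics::barplot(pr$sr, names.arg = pr$band, las = 2,
                              cex.names = 0.5, ylim = c(-1, 1),
                              main = sprintf("Selectivity ratios: %s (%s)",
                                             oc, gname),
                              ylab = "selectivity ratio")
            grDevices::dev.off()
          }
        }
      }
    }
    write_csv_out(do.call(rbind, rows), config$out_dir, "sr_profiles.csv")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("movecomp")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    n_generated = n0, n_analyzed = nrow(cohort),
    analyses = config$analyses,
    outcomes = config$outcomes,
    stratify = config$stratify,
    mc_reps = config$mc_reps, mc_holdout = config$mc_holdout)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  logf("done")
  invisible(manifest)
}
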