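# Epoch-level accelerometer reduction: intensity classification on ENMO
# magnitudes (mg), non-wear imputation from the same clock time on other
# days, daily summaries with a 33-band awake intensity spectrum, and
# weekday/weekend weighted participant summaries with validity filtering.

#' Classify an epoch magnitude into an intensity class
#'
#' Non-dominant-wrist thresholds for children: sedentary below 35 mg, light
#' activity from 35 to 200 mg, moderate-to-vigorous above 200 mg.  Both
#' boundary values (35 and 200 mg) are assigned to LPA; the boundaries are
#' configurable.
#'
#' @param enmo_mg non-negative acceleration magnitude(s) in mg.
#' @param thresholds named vector `c(sed_max = 35, mvpa_min = 200)`.
#' @return factor with levels SED, LPA, MVPA.
#' @export
classify_epoch <- function(enmo_mg, thresholds = c(sed_max = 35, mvpa_min = 200)) {
  if (any(enmo_mg < 0, na.rm = TRUE))
    stop("acceleration magnitudes must be non-negative", call. = FALSE)
  cls <- ifelse(enmo_mg < thresholds[["sed_max"]], "SED",
                ifelse(enmo_mg > thresholds[["mvpa_min"]], "MVPA", "LPA"))
  factor(cls, levels = c("SED", "LPA", "MVPA"))
}

#' Intensity-spectrum band index for an epoch magnitude
#'
#' Bands are 25 mg wide (0-25, 25-50, ...); the 33rd band is open-ended
#' (>= 800 mg).  A value on a band edge belongs to the upper band, matching
#' half-open `[lo, hi)` bands.
#'
#' @param enmo_mg non-negative magnitude(s) in mg.
#' @param width band width in mg.
#' @param n_bands number of bands.
#' @return integer band index in 0..(n_bands-1).
#' @export
spectrum_bin <- function(enmo_mg, width = 25, n_bands = 33) {
  if (any(enmo_mg < 0, na.rm = TRUE))
    stop("acceleration magnitudes must be non-negative", call. = FALSE)
  pmin(floor(enmo_mg / width), n_bands - 1)
}

check_epochs <- function(epochs) {
  needed <- c("id", "timestamp", "enmo_mg", "wear", "sleep")
  if (!all(needed %in% names(epochs)))
    stop("epoch series must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  if (is.unsorted(epochs$timestamp, strictly = TRUE) &&
      length(unique(epochs$id)) == 1)
    stop("timestamps must be strictly increasing", call. = FALSE)
  invisible(epochs)
}

epoch_seconds <- function(epochs) {
  if (nrow(epochs) < 2) stop("cannot infer epoch length", call. = FALSE)
  d <- as.numeric(difftime(epochs$timestamp[2], epochs$timestamp[1],
                           units = "secs"))
  if (!isTRUE(d > 0)) stop("cannot infer epoch length", call. = FALSE)
  d
}

#' Impute non-wear epochs from the same clock time on other days
#'
#' Each non-wear epoch's magnitude is replaced by the mean magnitude at the
#' same time of day over all other days on which the device was worn at that
#' time.  Worn epochs are left untouched.  A clock slot that is non-wear on
#' every recorded day cannot be imputed and is flagged `unimputable`;
#' summaries exclude such epochs.  The `wear` flag is preserved (imputation
#' fills values, it does not create wear time), and an `imputed` flag marks
#' filled epochs.
#'
#' @param epochs single-participant epoch data.frame (see
#'   [generate_epoch_series()] for the schema).
#' @return the epoch data.frame with columns `imputed` and `unimputable`
#'   added and non-wear `enmo_mg` values filled where possible.
#' @export
impute_nonwear <- function(epochs) {
  check_epochs(epochs)
  out <- epochs
  out$imputed <- FALSE
  out$unimputable <- FALSE
  if (!any(!epochs$wear)) return(out)
  day <- as.Date(epochs$timestamp, tz = "UTC")
  if (length(unique(day)) < 2)
    stop("imputation requires at least 2 recorded days", call. = FALSE)
  tod <- as.integer(difftime(epochs$timestamp,
                             as.POSIXct(paste(day, "00:00:00"), tz = "UTC"),
                             units = "secs"))
  worn <- epochs$wear
  slot_sum <- tapply(ifelse(worn, epochs$enmo_mg, 0), tod, sum)
  slot_n <- tapply(as.integer(worn), tod, sum)
  key <- as.character(tod)
  nw <- which(!worn)
  n_at <- slot_n[key[nw]]
  fill <- slot_sum[key[nw]] / n_at
  ok <- n_at > 0
  out$enmo_mg[nw[ok]] <- fill[ok]
  out$imputed[nw[ok]] <- TRUE
  out$unimputable[nw[!ok]] <- TRUE
  out
}

#' Summarize one day of epochs
#'
#' Sleep minutes come from the sleep flags; awake worn (or imputed) epochs
#' are classified into SED/LPA/MVPA and binned into the 33-band intensity
#' spectrum (awake time only).  Wear hours count measured wear only, so
#' imputation does not make a day valid.
#'
#' @param epochs epoch data.frame for a single date, imputation already
#'   applied (columns `imputed`/`unimputable` optional).
#' @param epoch_s epoch length in seconds; inferred from timestamps when
#'   missing.
#' @return one-row data.frame: `date`, `is_weekend`, `wear_hours`,
#'   `sleep_min`, `sed_min`, `lpa_min`, `mvpa_min` and the 33 spectrum
#'   columns.
#' @export
summarize_day <- function(epochs, epoch_s = NULL) {
  if (!nrow(epochs)) stop("empty day of epochs", call. = FALSE)
  if (is.null(epochs$imputed)) epochs$imputed <- FALSE
  if (is.null(epochs$unimputable)) epochs$unimputable <- FALSE
  if (is.null(epoch_s)) epoch_s <- epoch_seconds(epochs)
  date <- as.Date(epochs$timestamp[1], tz = "UTC")
  usable <- (epochs$wear | epochs$imputed) & !epochs$unimputable
  min_per_epoch <- epoch_s / 60
  sleep_min <- sum(epochs$sleep & usable) * min_per_epoch
  awake <- usable & !epochs$sleep
  cls <- classify_epoch(epochs$enmo_mg[awake])
  mins <- as.numeric(table(cls)) * min_per_epoch
  spec <- numeric(33)
  if (any(awake)) {
    b <- spectrum_bin(epochs$enmo_mg[awake])
    tab <- table(factor(b, levels = 0:32))
    spec <- as.numeric(tab) * min_per_epoch
  }
  out <- data.frame(
    date = date,
    is_weekend = format(date, "%u") %in% c("6", "7"),
    wear_hours = sum(epochs$wear) * epoch_s / 3600,
    sleep_min = sleep_min,
    sed_min = mins[1], lpa_min = mins[2], mvpa_min = mins[3])
  spec <- as.data.frame(as.list(spec))
  names(spec) <- spectrum_band_labels()
  cbind(out, spec)
}

#' Combine daily summaries into a weighted participant summary
#'
#' Valid days require at least `min_wear_hours` of measured wear.  Behavior
#' minutes and spectrum bands are averaged within valid weekdays and valid
#' weekend days separately, then combined as
#' `(weekday_mean * 5 + weekend_mean * 2) / 7`.  A participant is valid when
#' at least `min_valid_days` valid days include at least
#' `min_weekend_days` weekend day(s); otherwise the weighted values fall
#' back to the available stratum and `valid` is `FALSE`.
#'
#' @param daily data.frame of [summarize_day()] rows for one participant.
#' @param min_wear_hours daily wear validity threshold (hours).
#' @param min_valid_days,min_weekend_days participant validity thresholds.
#' @return one-row data.frame with weighted `sleep_min`, `sed_min`,
#'   `lpa_min`, `mvpa_min`, spectrum columns, `n_valid_days`,
#'   `n_valid_weekend_days` and `valid`.
#' @export
weight_week <- function(daily, min_wear_hours = 16, min_valid_days = 4,
                        min_weekend_days = 1) {
  vars <- c("sleep_min", "sed_min", "lpa_min", "mvpa_min",
            spectrum_band_labels())
  ok <- daily$wear_hours >= min_wear_hours
  valid_days <- daily[ok, , drop = FALSE]
  n_valid <- nrow(valid_days)
  n_weekend <- sum(valid_days$is_weekend)
  wd <- valid_days[!valid_days$is_weekend, vars, drop = FALSE]
  we <- valid_days[valid_days$is_weekend, vars, drop = FALSE]
  if (nrow(wd) && nrow(we)) {
    w <- (colMeans(wd) * 5 + colMeans(we) * 2) / 7
  } else if (nrow(wd)) {
    w <- colMeans(wd)
  } else if (nrow(we)) {
    w <- colMeans(we)
  } else {
    w <- stats::setNames(rep(NA_real_, length(vars)), vars)
  }
  out <- as.data.frame(as.list(w))
  out$n_valid_days <- n_valid
  out$n_valid_weekend_days <- n_weekend
  out$valid <- n_valid >= min_valid_days && n_weekend >= min_weekend_days
  out
}

#' Reduce a participant's epoch series to a weighted behavior summary
#'
#' Runs non-wear imputation, per-day summaries and weekday/weekend
#' weighting.
#'
#' @param epochs single-participant epoch data.frame.
#' @param epoch_s epoch length in seconds (inferred when `NULL`).
#' @param ... passed to [weight_week()].
#' @return one-row data.frame with `id` prepended to the [weight_week()]
#'   columns.
#' @export
summarize_participant <- function(epochs, epoch_s = NULL, ...) {
  check_epochs(epochs)
  if (any(!epochs$wear)) epochs <- impute_nonwear(epochs)
  day <- as.Date(epochs$timestamp, tz = "UTC")
  daily <- do.call(rbind, lapply(split(epochs, day), summarize_day,
                                 epoch_s = epoch_s))
  out <- weight_week(daily, ...)
  cbind(data.frame(id = epochs$id[1], stringsAsFactors = FALSE), out)
}

#' Reduce a multi-participant epoch table to a summary table
#'
#' @param epochs long epoch data.frame with an `id` column covering several
#'   participants.
#' @param ... passed to [summarize_participant()].
#' @return data.frame, one row per participant.
#' @export
summarize_cohort_epochs <- function(epochs, ...) {
  parts <- split(epochs, epochs$id)
  do.call(rbind, c(lapply(parts, summarize_participant, ...),
                   make.row.names = FALSE))
}
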