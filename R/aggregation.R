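# Epoch classification and valid-day aggregation.
#
# Wrist-accelerometer output is summarised as average acceleration (ENMO, in
# milligravity) over 60-s epochs. Epochs during waking wear time are
# classified into SB / LIPA / MVPA by intensity cut-points, days are screened
# by a minimum-wear rule, and subjects are summarised by a weekday/weekend
# weighted mean.

#' Intensity cut-points for epoch classification
#'
#' @param sb_upper_mg Upper bound (exclusive) of sedentary behaviour, in
#'   milligravity. Default 40; a 45 mg alternative is the usual sensitivity
#'   setting.
#' @param mvpa_lower_mg Lower bound (inclusive) of MVPA, in milligravity
#'   (default 100). LIPA is the half-open band `[sb_upper_mg, mvpa_lower_mg)`.
#' @return A list with class `"cutpoint_set"`.
#' @export
#' @examples
#' cutpoints()          # 40 / 100 mg
#' cutpoints(45)        # sensitivity cut-off
cutpoints <- function(sb_upper_mg = 40, mvpa_lower_mg = 100) {
  if (!(sb_upper_mg > 0 && sb_upper_mg < mvpa_lower_mg))
    stop("cut-points must satisfy 0 < sb_upper_mg < mvpa_lower_mg", call. = FALSE)
  structure(list(sb_upper_mg = sb_upper_mg, mvpa_lower_mg = mvpa_lower_mg),
            class = "cutpoint_set")
}

#' Classify 60-s epochs into movement behaviours
#'
#' An epoch is SB when its average acceleration is below `sb_upper_mg`,
#' LIPA when in `[sb_upper_mg, mvpa_lower_mg)` and MVPA at or above
#' `mvpa_lower_mg`; the bands are exhaustive and disjoint.
#'
#' @param enmo_mg Numeric vector of epoch-average accelerations in
#'   milligravity; must be nonnegative.
#' @param cuts A [cutpoints()] object.
#' @return Factor with levels `SB`, `LIPA`, `MVPA`.
#' @export
#' @examples
#' classify_epoch(c(0, 39.9, 40, 99.9, 100, 250))
classify_epoch <- function(enmo_mg, cuts = cutpoints()) {
  if (!inherits(cuts, "cutpoint_set")) stop("`cuts` must come from cutpoints()", call. = FALSE)
  if (any(!is.finite(enmo_mg)) || any(enmo_mg < 0))
    stop("`enmo_mg` must be finite and nonnegative", call. = FALSE)
  cut(enmo_mg, breaks = c(-Inf, cuts$sb_upper_mg, cuts$mvpa_lower_mg, Inf),
      labels = c("SB", "LIPA", "MVPA"), right = FALSE)
}

#' Summarise one calendar day of epochs
#'
#' Counts minutes per behaviour over epochs that are both waking and worn,
#' and flags the day valid when wear time covers at least two thirds of the
#' waking period.
#'
#' @param epochs Data frame with columns `timestamp` (POSIXct or Date-time
#'   parseable), `enmo_mg`, `wear` (logical/0-1), `waking` (logical/0-1);
#'   all epochs must fall on one calendar day.
#' @param cuts A [cutpoints()] object.
#' @return One-row data frame: `date`, `is_weekend`, `sb_min`, `lipa_min`,
#'   `mvpa_min`, `wear_min`, `waking_min`, `valid`.
#' @export
summarize_day <- function(epochs, cuts = cutpoints()) {
  if (!is.data.frame(epochs) || nrow(epochs) == 0)
    stop("`epochs` must be a non-empty data frame", call. = FALSE)
  need <- c("timestamp", "enmo_mg", "wear", "waking")
  miss <- setdiff(need, names(epochs))
  if (length(miss)) stop("missing epoch columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  ts <- as.POSIXct(epochs$timestamp, tz = "UTC")
  day <- unique(as.Date(ts))
  if (length(day) != 1) stop("epochs span more than one calendar day", call. = FALSE)
  wear <- as.logical(epochs$wear)
  waking <- as.logical(epochs$waking)
  use <- wear & waking
  beh <- classify_epoch(epochs$enmo_mg[use], cuts)
  counts <- table(factor(beh, levels = c("SB", "LIPA", "MVPA")))
  waking_min <- sum(waking)
  wear_min <- sum(use)
  data.frame(
    date = day,
    is_weekend = format(day, "%u") %in% c("6", "7"),
    sb_min = as.numeric(counts["SB"]),
    lipa_min = as.numeric(counts["LIPA"]),
    mvpa_min = as.numeric(counts["MVPA"]),
    wear_min = wear_min,
    waking_min = waking_min,
    valid = wear_min >= (2 / 3) * waking_min
  )
}

#' Summarise an epoch table into daily rows
#'
#' Convenience wrapper applying [summarize_day()] to each subject-day of a
#' long epoch table.
#'
#' @param epochs Data frame as in [summarize_day()], with an additional
#'   `subject_id` column (a single implicit subject is assumed if absent).
#' @param cuts A [cutpoints()] object.
#' @return Data frame with one row per subject-day.
#' @export
summarize_days <- function(epochs, cuts = cutpoints()) {
  if (!"subject_id" %in% names(epochs)) epochs$subject_id <- 1L
  ts <- as.POSIXct(epochs$timestamp, tz = "UTC")
  key <- paste(epochs$subject_id, as.Date(ts))
  pieces <- lapply(split(seq_len(nrow(epochs)), key), function(i) {
    out <- summarize_day(epochs[i, , drop = FALSE], cuts)
    out$subject_id <- epochs$subject_id[i[1]]
    out
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$subject_id, out$date), c("subject_id", setdiff(names(out), "subject_id"))]
}

#' Aggregate a subject's valid days into a daily composition
#'
#' With 7 valid days, the subject's daily behaviour durations are the plain
#' mean over days. With fewer, a weighted average of valid weekday and
#' weekend means is used, with calendar weights 5/7 and 2/7. Subjects need
#' at least 2 valid weekdays and 2 valid weekend days; otherwise they are
#' excluded (returned as an exclusion record, not an error).
#'
#' @param days Data frame of daily summaries (see [summarize_day()]).
#' @return A list: `included` (logical), `reason` (character, `NA` when
#'   included), `composition` (named vector of pre-closure mean minutes, or
#'   `NULL`), `n_valid_days`, `waking_min` (mean waking duration over valid
#'   days).
#' @export
aggregate_subject <- function(days) {
  if (!is.data.frame(days) || nrow(days) == 0)
    stop("`days` must be a non-empty data frame of daily summaries", call. = FALSE)
  v <- days[as.logical(days$valid), , drop = FALSE]
  n_wd <- sum(!v$is_weekend)
  n_we <- sum(v$is_weekend)
  if (n_wd < 2 || n_we < 2) {
    return(list(included = FALSE,
                reason = sprintf("valid-day rule unmet (%d weekday, %d weekend valid days)",
                                 n_wd, n_we),
                composition = NULL, n_valid_days = nrow(v), waking_min = NA_real_))
  }
  cols <- c("sb_min", "lipa_min", "mvpa_min")
  comp <- if (nrow(v) == 7) {
    colMeans(v[, cols])
  } else {
    wd <- colMeans(v[!v$is_weekend, cols, drop = FALSE])
    we <- colMeans(v[v$is_weekend, cols, drop = FALSE])
    (5 * wd + 2 * we) / 7
  }
  names(comp) <- c("sb", "lipa", "mvpa")
  list(included = TRUE, reason = NA_character_, composition = comp,
       n_valid_days = nrow(v), waking_min = mean(v$waking_min))
}

#' Aggregate an epoch or daily table into a cohort composition table
#'
#' Runs [summarize_days()] (when given epochs) and [aggregate_subject()] per
#' subject, returning included subjects as cohort rows and excluded subjects
#' in an exclusion ledger.
#'
#' @param x Epoch data frame (with `enmo_mg`) or daily-summary data frame
#'   (with `valid`).
#' @param cuts A [cutpoints()] object, used only for epoch input.
#' @return A list with `cohort` (data frame: `subject_id`, `sb_min`,
#'   `lipa_min`, `mvpa_min`, `waking_min`, `n_valid_days`) and `excluded`
#'   (data frame: `subject_id`, `reason`).
#' @export
aggregate_cohort <- function(x, cuts = cutpoints()) {
  daily <- if ("valid" %in% names(x)) x else summarize_days(x, cuts)
  if (!"subject_id" %in% names(daily)) daily$subject_id <- 1L
  rows <- list(); excl <- list()
  for (sid in unique(daily$subject_id)) {
    res <- aggregate_subject(daily[daily$subject_id == sid, , drop = FALSE])
    if (res$included) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid,
        sb_min = res$composition[["sb"]],
        lipa_min = res$composition[["lipa"]],
        mvpa_min = res$composition[["mvpa"]],
        waking_min = res$waking_min,
        n_valid_days = res$n_valid_days)
    } else {
      excl[[length(excl) + 1L]] <- data.frame(subject_id = sid, reason = res$reason)
    }
  }
  list(
    cohort = if (length(rows)) do.call(rbind, rows) else
      data.frame(subject_id = character(0), sb_min = numeric(0),
                 lipa_min = numeric(0), mvpa_min = numeric(0),
                 waking_min = numeric(0), n_valid_days = integer(0)),
    excluded = if (length(excl)) do.call(rbind, excl) else
      data.frame(subject_id = character(0), reason = character(0))
  )
}
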