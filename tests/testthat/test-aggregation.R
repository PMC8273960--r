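day_of <- function(enmo, wear = TRUE, date = "2013-01-07") {
  n <- length(enmo)
  data.frame(
    timestamp = as.POSIXct(paste(date, "07:00:00"), tz = "UTC") + 60 * (seq_len(n) - 1),
    enmo_mg = enmo,
    wear = rep_len(wear, n),
    waking = rep_len(TRUE, n))
}

test_that("epoch classification follows the intensity bands", {
  expect_equal(as.character(classify_epoch(c(0, 39.9, 40, 99.9, 100, 250))),
               c("SB", "SB", "LIPA", "LIPA", "MVPA", "MVPA"))
  # 45 mg sensitivity cut-off moves the SB/LIPA boundary only
  expect_equal(as.character(classify_epoch(c(42, 45, 100), cutpoints(45))),
               c("SB", "LIPA", "MVPA"))
  expect_error(classify_epoch(-1), "nonnegative")
  # monotone in intensity
  codes <- as.integer(classify_epoch(sort(stats::runif(200, 0, 300))))
  expect_true(all(diff(codes) >= 0))
})

test_that("daily summaries count waking wear minutes and apply the 2/3 rule", {
  d <- summarize_day(day_of(rep(10, 960)))
  expect_equal(c(d$sb_min, d$lipa_min, d$mvpa_min), c(960, 0, 0))
  expect_true(d$valid)
  expect_false(d$is_weekend)   # a Monday

  # 639 worn minutes of a 960-min waking day miss the 2/3 threshold of 640
  d639 <- summarize_day(day_of(rep(10, 960), wear = c(rep(TRUE, 639), rep(FALSE, 321))))
  expect_false(d639$valid)
  d640 <- summarize_day(day_of(rep(10, 960), wear = c(rep(TRUE, 640), rep(FALSE, 320))))
  expect_true(d640$valid)

  # counting oracle on a mixed stream
  d <- summarize_day(day_of(c(rep(20, 300), rep(50, 100), rep(150, 40))))
  expect_equal(c(d$sb_min, d$lipa_min, d$mvpa_min), c(300, 100, 40))
  # conservation: behaviours partition waking wear time
  expect_equal(d$sb_min + d$lipa_min + d$mvpa_min, d$wear_min)

  expect_error(summarize_day(day_of(numeric(0))), "non-empty")
})

test_that("subject aggregation uses the 5/7-2/7 weighted mean", {
  mk_day <- function(date, sb, lipa, mvpa, valid = TRUE) {
    data.frame(date = as.Date(date),
               is_weekend = format(as.Date(date), "%u") %in% c("6", "7"),
               sb_min = sb, lipa_min = lipa, mvpa_min = mvpa,
               wear_min = 960, waking_min = 960, valid = valid)
  }
  # 7 identical valid days: plain mean
  days <- do.call(rbind, lapply(0:6, function(i)
    mk_day(as.Date("2013-01-07") + i, 700, 200, 60)))
  res <- aggregate_subject(days)
  expect_true(res$included)
  expect_equal(res$composition, c(sb = 700, lipa = 200, mvpa = 60))

  # 3 valid weekdays at SB 700, 2 valid weekend days at SB 630
  days <- rbind(
    do.call(rbind, lapply(0:2, function(i)
      mk_day(as.Date("2013-01-07") + i, 700, 200, 60))),
    mk_day("2013-01-12", 630, 260, 70), mk_day("2013-01-13", 630, 260, 70))
  res <- aggregate_subject(days)
  expect_equal(res$composition[["sb"]], (5 * 700 + 2 * 630) / 7)  # 680
  expect_equal(res$n_valid_days, 5)

  # all-valid week equals the weighted formula when means come from the week
  days <- do.call(rbind, lapply(0:6, function(i)
    mk_day(as.Date("2013-01-07") + i, 700 - 5 * i, 200 + 4 * i, 60 + i)))
  res <- aggregate_subject(days)
  wd <- colMeans(days[!days$is_weekend, c("sb_min", "lipa_min", "mvpa_min")])
  we <- colMeans(days[days$is_weekend, c("sb_min", "lipa_min", "mvpa_min")])
  expect_equal(unname(res$composition), unname((5 * wd + 2 * we) / 7))

  # a single valid weekend day: excluded, not an error
  res <- aggregate_subject(mk_day("2013-01-12", 700, 200, 60))
  expect_false(res$included)
  expect_match(res$reason, "valid-day rule")
})

test_that("noise-free epoch streams round-trip exactly through aggregation", {
  ep <- simulate_epochs(c(700, 200, 60), n_days = 7)
  agg <- aggregate_cohort(ep)
  expect_equal(nrow(agg$cohort), 1)
  expect_equal(unname(unlist(agg$cohort[1, c("sb_min", "lipa_min", "mvpa_min")])),
               c(700, 200, 60))
  expect_equal(agg$cohort$n_valid_days, 7)

  # forcing low wear invalidates those days; dropping enough days excludes
  ep <- simulate_epochs(c(700, 200, 60), n_days = 7, low_wear_days = c(6, 7))
  agg <- aggregate_cohort(ep)
  expect_equal(nrow(agg$cohort), 0)
  expect_match(agg$excluded$reason, "0 weekend")
})
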