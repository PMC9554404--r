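test_that("intensity bands have the stated boundaries", {
  cls <- classify_epoch_intensity(c(10, 24.999, 25, 99.9, 100, 400, 1000))
  expect_equal(as.character(cls),
               c("inactive", "inactive", "light", "light", "mvpa", "mvpa",
                 "mvpa"))
  expect_equal(attr(cls, "vigorous"),
               c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_error(classify_epoch_intensity(-1), "non-negative")
})

test_that("class-minute accrual matches brute-force counting", {
  set.seed(51)
  n <- 17280
  # 684 scattered MVPA epochs on a full-wear day -> 57 MVPA minutes
  enmo <- rep(10, n)
  enmo[sample(n, 684)] <- 150
  acc <- accrue_class_minutes(enmo, rep(TRUE, n))
  expect_equal(acc$mvpa_min, 57)

  expect_equal(accrue_class_minutes(enmo, rep(FALSE, n)),
               list(inactive_min = 0, lpa_min = 0, mvpa_min = 0, vpa_min = 0))

  # random labels against direct counts; partition property
  enmo <- sample(c(5, 50, 150, 500), n, replace = TRUE)
  wear <- stats::runif(n) > 0.3
  acc <- accrue_class_minutes(enmo, wear)
  expect_equal(acc$inactive_min, sum(wear & enmo < 25) / 12)
  expect_equal(acc$lpa_min, sum(wear & enmo >= 25 & enmo < 100) / 12)
  expect_equal(acc$mvpa_min, sum(wear & enmo >= 100) / 12)
  expect_equal(acc$vpa_min, sum(wear & enmo >= 400) / 12)
  expect_equal(acc$inactive_min + acc$lpa_min + acc$mvpa_min,
               sum(wear) / 12)

  # minute-level accrual: a minute is MVPA only at >= 80% qualifying epochs
  cfg <- wpa_config(); cfg$accrual$mode <- "minute80"
  enmo2 <- rep(10, 24)
  enmo2[1:10] <- 150            # minute 1: 10/12 epochs MVPA
  acc2 <- accrue_class_minutes(enmo2, rep(TRUE, 24), cfg)
  expect_equal(acc2$mvpa_min, 1)
  enmo2[10] <- 10               # 9/12: below the 80% criterion -> light
  acc2 <- accrue_class_minutes(enmo2, rep(TRUE, 24), cfg)
  expect_equal(acc2$mvpa_min, 0)
  expect_equal(acc2$lpa_min, 1)
})

test_that("bout detection honours the exact duration and fraction edges", {
  pad <- function(x) c(rep(0, 60), x, rep(0, 400 - length(x) - 60))
  above <- function(k) rep(150, k)

  b <- detect_mvpa_bouts(pad(above(120)))
  expect_equal(b$mvpa_bout10_min, 10)
  expect_equal(unname(b$intervals[1, ]), c(61, 180))

  expect_equal(detect_mvpa_bouts(pad(above(119)))$mvpa_bout10_min, 0)

  # repeating 9-above/1-below: fraction 0.9, qualifies; matches the oracle
  patt <- pad(rep(c(rep(150, 9), 0), 13))
  b <- detect_mvpa_bouts(patt)
  o <- bout_oracle(patt >= 100)
  expect_gt(b$mvpa_bout10_min, 10)
  expect_equal(b$mvpa_bout10_min, o$minutes)

  # 40 isolated 1-min bursts, 2-min rests: unbouted MVPA only
  day <- rep(c(rep(150, 12), rep(10, 24)), 40)
  day <- c(day, rep(10, 17280 - length(day)))
  expect_equal(detect_mvpa_bouts(day)$mvpa_bout10_min, 0)
  expect_equal(accrue_class_minutes(day, rep(TRUE, 17280))$mvpa_min, 40)
})

test_that("greedy bout scan agrees with exhaustive enumeration", {
  set.seed(52)
  for (k in 1:200) {
    n <- sample(150:360, 1)
    p <- stats::runif(1, 0.3, 0.95)
    above <- stats::runif(n) < p
    enmo <- ifelse(above, 150, 10)
    b <- detect_mvpa_bouts(enmo)
    o <- bout_oracle(above)
    expect_equal(b$mvpa_bout10_min, o$minutes)
    if (!is.null(b$intervals)) expect_equal(b$intervals, o$intervals)
  }
})

test_that("MX metrics are rank statistics over the day", {
  expect_equal(unname(mx_metrics(rep(50, 17280))), c(50, 50, 50))
  day <- c(rep(200, 24), rep(0, 17280 - 24))
  mx <- mx_metrics(day)
  expect_equal(unname(mx), c(200, 0, 0))

  set.seed(53)
  day <- stats::runif(17280, 0, 500)
  wear <- stats::runif(17280) > 0.2
  mx <- mx_metrics(day, wear)
  srt <- sort(ifelse(wear, day, 0), decreasing = TRUE)
  expect_equal(unname(mx), srt[c(24, 360, 720)])
  expect_true(mx[1] >= mx[2] && mx[2] >= mx[3])
})

test_that("24-h mean acceleration imputes non-wear from donor days", {
  n <- 17280
  expect_equal(mean_acceleration_24h(rep(20, n), rep(TRUE, n)), 20)

  # 1 h of non-wear; donors average 30 mg there
  wear <- rep(TRUE, n); wear[1:720] <- FALSE
  enmo <- rep(20, n)
  donor_e <- matrix(30, n, 2); donor_w <- matrix(TRUE, n, 2)
  got <- mean_acceleration_24h(enmo, wear, donor_e, donor_w)
  expect_equal(got, (30 * 720 + 20 * (n - 720)) / n)

  # no donors: the non-wear hour contributes zero
  expect_equal(mean_acceleration_24h(enmo, wear),
               20 * (n - 720) / n)
})

test_that("daily invariants hold on random days", {
  set.seed(54)
  for (k in 1:50) {
    enmo <- sample(c(0, 10, 50, 120, 200, 500), 17280, replace = TRUE,
                   prob = c(.3, .3, .2, .1, .07, .03))
    wear <- stats::runif(17280) > 0.2
    acc <- accrue_class_minutes(enmo, wear)
    b <- detect_mvpa_bouts(enmo, wear)
    mx <- mx_metrics(enmo, wear)
    expect_lte(b$mvpa_bout10_min, acc$mvpa_min / 0.8 + 1e-9)
    expect_equal(acc$inactive_min + acc$lpa_min + acc$mvpa_min,
                 sum(wear) / 12)
    # rank/threshold duality between M30 and 30 MVPA minutes
    expect_equal(mx[["m30_mg"]] >= 100, acc$mvpa_min >= 30)
  }
})
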