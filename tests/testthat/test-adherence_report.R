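test_that("valid-day selection applies wear and day-index rules", {
  days <- rbind(fake_day(1, wear_hours = 16), fake_day(2, wear_hours = 11.9),
                do.call(rbind, lapply(2:18, fake_day)))
  v <- select_valid_days(days)
  expect_false(any(v$wear_hours < 12))
  expect_false(any(v$day_index < 2))
  expect_equal(nrow(v), 17)     # days 2-18 with >= 12 h wear
})

test_that("participant summaries are means over valid days", {
  meta <- fake_meta()
  d6 <- do.call(rbind, lapply(2:7, fake_day, mvpa_min = 40))
  ps <- summarize_participant(d6, meta)
  expect_false(ps$included)     # 6 valid days
  expect_error(classify_adherence(ps), "included")

  d8 <- do.call(rbind, lapply(2:9, fake_day, mvpa_min = 40, steps = 9000))
  ps <- summarize_participant(d8, meta)
  expect_true(ps$included)
  expect_equal(ps$mvpa_min, 40)
  expect_equal(ps$steps, 9000)

  set.seed(71)
  dr <- do.call(rbind, lapply(2:11, function(d)
    fake_day(d, mvpa_min = stats::runif(1, 0, 90),
             steps = stats::runif(1, 2000, 15000))))
  ps <- summarize_participant(dr, meta)
  expect_equal(ps$mvpa_min, mean(dr$mvpa_min))
  expect_equal(ps$steps, mean(dr$steps))

  ps0 <- summarize_participant(dr[0, ], meta)
  expect_false(ps0$included)
  expect_true(is.na(ps0$mvpa_min))
})

test_that("adherence flags use inclusive boundaries", {
  meta <- fake_meta()
  mk <- function(mvpa, bout, steps) {
    d <- do.call(rbind, lapply(2:9, fake_day, mvpa_min = mvpa,
                               mvpa_bout10_min = bout, steps = steps))
    classify_adherence(summarize_participant(d, meta))
  }
  # the cohort's median participant: 2020 yes, 2010 no
  p <- mk(57, 7.1, 10463)
  expect_true(p$who2020); expect_false(p$who2010)
  expect_true(p$steps7500); expect_true(p$steps10000)

  p <- mk(29.9, 30, 7499.9)
  expect_false(p$who2020); expect_true(p$who2010)
  expect_false(p$steps7500); expect_false(p$steps10000)

  p <- mk(30, 0, 7500)
  expect_true(p$who2020); expect_true(p$steps7500)
  expect_false(p$steps10000)
})

test_that("flag monotonicity: reaching 10,000 steps implies 7,500", {
  meta <- fake_meta()
  set.seed(72)
  for (k in 1:20) {
    st <- stats::runif(1, 5000, 14000)
    d <- do.call(rbind, lapply(2:9, fake_day, steps = st))
    p <- classify_adherence(summarize_participant(d, meta))
    expect_true(!p$steps10000 || p$steps7500)
  }
})

test_that("daily adherence fractions match brute-force counts", {
  set.seed(73)
  days <- do.call(rbind, lapply(1:12, function(i)
    do.call(rbind, lapply(2:9, function(d)
      fake_day(d, wear_hours = sample(c(10, 16), 1, prob = c(.2, .8)),
               mvpa_min = stats::runif(1, 0, 80),
               mvpa_bout10_min = stats::runif(1, 0, 40),
               steps = stats::runif(1, 3000, 13000),
               participant_id = sprintf("P%02d", i))))))
  cur <- daily_adherence_curve(days)
  for (d in cur$day_index) {
    dd <- days[days$day_index == d & days$wear_hours >= 12, ]
    expect_equal(cur$n[cur$day_index == d], nrow(dd))
    expect_equal(cur$frac_who2020[cur$day_index == d],
                 mean(dd$mvpa_min >= 30))
    expect_equal(cur$frac_steps10000[cur$day_index == d],
                 mean(dd$steps >= 10000))
  }
  # a cohort that always walks 40 bouted minutes fulfils 2010 on every day
  days40 <- do.call(rbind, lapply(1:5, function(i)
    do.call(rbind, lapply(2:9, fake_day, mvpa_min = 40,
                          mvpa_bout10_min = 40,
                          participant_id = sprintf("P%02d", i)))))
  expect_true(all(daily_adherence_curve(days40)$frac_who2010 == 1))
})

make_participants <- function(n, flags_fn, seed = 74) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n), function(i) {
    meta <- participant_meta(sprintf("P%03d", i),
                             sample(47:77, 1),
                             sample(c("female", "male"), 1),
                             sample(c("ACS", "CCS"), 1, prob = c(.88, .12)),
                             as.Date("2021-03-01"))
    f <- flags_fn(i)
    d <- do.call(rbind, lapply(2:9, fake_day, mvpa_min = f$mvpa,
                               mvpa_bout10_min = f$bout, steps = f$steps,
                               peak30_cad = f$peak30))
    classify_adherence(summarize_participant(d, meta))
  }))
}

test_that("subgroup prevalence and tests behave on constructed cohorts", {
  p <- make_participants(90, function(i)
    list(mvpa = if (i %% 2) 50 else 10, bout = 0,
         steps = stats::runif(1, 4000, 12000), peak30 = 80))
  sp <- subgroup_prevalence(p, "sex")
  expect_equal(sp$criterion, c("who2020", "who2010", "steps7500", "steps10000"))
  row <- sp[sp$criterion == "who2020", ]
  expect_equal(row$adherent1 / row$n1 * 100, row$pct1)

  # identical group proportions -> chi-square p of 1
  p2 <- make_participants(80, function(i)
    list(mvpa = if (i %% 2) 50 else 10, bout = 0, steps = 8000, peak30 = 80))
  p2$sex <- rep(c("female", "male", "male", "female"), 20)  # balanced
  sp2 <- subgroup_prevalence(p2, "sex")
  expect_equal(sp2$p_value[sp2$criterion == "who2020"], 1)

  # chi-square p matches a label-permutation test within 0.01; permuting
  # labels with fixed margins makes the permuted cell count hypergeometric,
  # and the 2x2 Pearson statistic has the closed form n(ad-bc)^2/(r1 r2 c1 c2)
  chi2 <- function(a, m1, m2, k) {
    a <- as.numeric(a); m1 <- as.numeric(m1); m2 <- as.numeric(m2)
    k <- as.numeric(k)
    n <- m1 + m2
    n * (a * (m2 - k + a) - (m1 - a) * (k - a))^2 /
      (m1 * m2 * k * (n - k))
  }
  set.seed(75)
  for (rep_i in 1:3) {
    g <- sample(c(TRUE, FALSE), 1000, replace = TRUE)
    y <- stats::runif(1000) < ifelse(g, 0.53, 0.47)
    m1 <- sum(g); m2 <- sum(!g); k <- sum(y)
    obs <- chi2(sum(g & y), m1, m2, k)
    stat_perm <- chi2(stats::rhyper(1e5, m1, m2, k), m1, m2, k)
    # mid-p convention for the lattice ties of the 2x2 permutation law
    p_perm <- mean(stat_perm > obs + 1e-9) +
      0.5 * mean(abs(stat_perm - obs) < 1e-9)
    p_chi <- suppressWarnings(stats::chisq.test(table(g, y),
                                                correct = FALSE)$p.value)
    expect_lt(abs(p_perm - p_chi), 0.01)
  }
})

test_that("regressions recover closed forms and planted structure", {
  # exact line: mvpa = 0.004 * steps - 10
  p <- make_participants(50, function(i) {
    st <- 4000 + i * 150
    list(mvpa = 0.004 * st - 10, bout = 0.002 * st - 5, steps = st,
         peak30 = 60 + i / 2)
  })
  rg <- regress_metrics(p)
  row <- rg[rg$response == "mvpa_min" & rg$predictor == "steps", ]
  expect_equal(row$slope, 0.004, tolerance = 1e-9)
  expect_equal(row$r, 1, tolerance = 1e-9)
  expect_equal(row$x_at_30min, 10000, tolerance = 1e-6)

  # zero-variance predictor errors
  pz <- make_participants(10, function(i)
    list(mvpa = 30 + i, bout = 0, steps = 8000, peak30 = 80))
  expect_error(regress_metrics(pz), "variance")

  # noisy planted line recovered within 2 SE (n = 200)
  set.seed(76)
  pn <- make_participants(200, function(i) {
    st <- stats::runif(1, 3000, 15000)
    list(mvpa = 0.006 * st - 8 + stats::rnorm(1, 0, 8),
         bout = pmax(0.004 * st - 20 + stats::rnorm(1, 0, 10), 0),
         steps = st, peak30 = stats::runif(1, 50, 110))
  }, seed = 76)
  rg <- regress_metrics(pn)
  row <- rg[rg$response == "mvpa_min" & rg$predictor == "steps", ]
  expect_lt(abs(row$slope - 0.006), 2 * row$se_slope)
  expect_lt(abs(row$intercept - (-8)), 2 * row$se_intercept)
})

test_that("cohort report quartiles follow the interpolation convention", {
  p <- make_participants(11, function(i)
    list(mvpa = 10 * i, bout = 2 * i, steps = 1000 * i, peak30 = 50 + i),
    seed = 77)
  rep_ <- cohort_report(p, do.call(rbind, lapply(2:9, fake_day)))
  t1 <- rep_$table1
  expect_equal(t1$all_median[t1$metric == "mvpa_min"],
               stats::quantile(p$mvpa_min, 0.5, names = FALSE))
  expect_equal(t1$all_q1[t1$metric == "steps"],
               stats::quantile(p$steps, 0.25, names = FALSE))
  expect_equal(t1$all_q3[t1$metric == "steps"],
               stats::quantile(p$steps, 0.75, names = FALSE))
  expect_equal(rep_$fig4_sets$n_included, 11)
  expect_equal(rep_$prevalence$n[rep_$prevalence$criterion == "who2020"],
               sum(p$who2020))
})
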