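test_that("non-wear blocks are near-constant and step-free", {
  b <- activity_block("nonwear", as.POSIXct("2021-03-03", tz = "UTC"), 3600)
  set.seed(1)
  sim <- simulate_block(b, rate_hz = 50)
  expect_equal(nrow(sim$data), 180000L)
  expect_true(all(apply(sim$data, 2, stats::sd) * 1000 < 1))
  expect_equal(sim$truth$steps, 0L)
  expect_equal(sim$truth$wear_s, 0)
})

test_that("walk truth: one step per gait cycle, MVPA-band ENMO", {
  t0 <- as.POSIXct("2021-03-03", tz = "UTC")
  set.seed(2)
  sim <- simulate_block(activity_block("walk", t0, 60, cadence_spm = 120,
                                       peak_amp_g = 0.5), rate_hz = 50)
  expect_equal(sim$truth$steps, 120L)
  expect_equal(sim$truth$mvpa_s, 60)

  # 300 s at 110 steps/min, 0.5 g: every 5-s epoch lands at/above 100 mg
  sched <- build_schedule(data.frame(kind = "walk", minutes = 5,
                                     cadence = 110, amp = 0.5))
  gen <- generate_recording(sched, seed = 3)
  es <- aggregate_epochs(gen$recording)
  expect_equal(nrow(es), 60L)
  expect_true(all(es$enmo_mg >= 100))

  expect_error(simulate_block(data.frame(kind = "swim", duration_s = 10,
                                         jitter = 0)), "unsupported")
})

test_that("generated day truths follow the schedule arithmetic", {
  t0 <- as.POSIXct("2021-03-03", tz = "UTC")
  # one full non-wear day
  gen <- generate_recording(activity_block("nonwear", t0, 86400), seed = 5)
  expect_equal(gen$truth$true_wear_s, 0)
  expect_equal(gen$truth$true_steps, 0L)
  expect_equal(gen$truth$true_mvpa_s, 0)

  # 8 h sleep + 14 h sedentary + 2 h walk at 100 steps/min -> 12,000 steps
  sched <- build_schedule(data.frame(
    kind = c("sleep", "sedentary", "walk"), minutes = c(480, 840, 120),
    cadence = c(NA, NA, 100), amp = c(NA, NA, 0.4)))
  gen <- generate_recording(sched, seed = 6)
  expect_equal(gen$truth$true_steps, 12000L)
  expect_equal(gen$truth$true_sleep_s, 8 * 3600)
  expect_equal(gen$truth$true_wear_s, 86400)
  expect_equal(gen$truth$true_mvpa_s, 2 * 3600)
  expect_equal(gen$truth$true_bouted_mvpa_s, 2 * 3600)  # one continuous walk

  # day truth is additive over block truths
  set.seed(8)
  per_block <- lapply(seq_len(nrow(sched)), function(k)
    simulate_block(sched[k, ])$truth)
  expect_equal(gen$truth$true_mvpa_s, sum(vapply(per_block, `[[`, 1, "mvpa_s")))
  expect_equal(gen$truth$true_sleep_s, sum(vapply(per_block, `[[`, 1, "sleep_s")))
})

test_that("generation is deterministic under the seed", {
  sched <- build_schedule(data.frame(kind = c("light", "walk"),
                                     minutes = c(2, 2), cadence = c(NA, 110),
                                     amp = c(NA, 0.4)))
  a <- generate_recording(sched, seed = 11)
  b <- generate_recording(sched, seed = 11)
  c <- generate_recording(sched, seed = 12)
  expect_identical(a$recording$data, b$recording$data)
  expect_false(identical(a$recording$data, c$recording$data))
  expect_identical(a$truth, c$truth)   # truth is schedule-determined here

  bad <- sched; bad$start[2] <- bad$start[2] + 30
  expect_error(generate_recording(bad, seed = 1), "tile")
})

test_that("device distortion is the declared affine map", {
  n <- 500
  rec <- raw_recording(matrix(rep(c(0, 0, 1), each = n), n, 3),
                       as.POSIXct("2021-03-03", tz = "UTC"))
  id <- apply_device_distortion(rec, c(0, 0, 0), c(1, 1, 1))
  expect_identical(id$data, rec$data)
  d <- apply_device_distortion(rec, c(0.015, -0.010, 0.005), c(1, 1, 1))
  expect_equal(unname(d$data[1, ]), c(0.015, -0.010, 1.005))
  expect_error(apply_device_distortion(rec, c(0.2, 0, 0), c(1, 1, 1)), "offset")
  expect_error(apply_device_distortion(rec, c(0, 0, 0), c(1.2, 1, 1)), "gain")
})

test_that("cohort designed prevalence follows the archetype mixture", {
  ch <- generate_cohort(cohort_spec(n_participants = 10,
                                    fraction_bout_exercisers = 1, n_days = 1))
  expect_true(all(ch$designed$who2010) && all(ch$designed$who2020))
  expect_equal(unname(ch$designed_prevalence["who2010"]), 100)

  ch <- generate_cohort(cohort_spec(n_participants = 10,
                                    fraction_bout_exercisers = 0, n_days = 1))
  expect_true(all(ch$designed$who2020))
  expect_false(any(ch$designed$who2010))

  ch <- generate_cohort(cohort_spec())   # reference 20/80 mixture
  expect_equal(unname(ch$designed_prevalence["who2010"]), 20)
  expect_equal(unname(ch$designed_prevalence["who2020"]), 100)
  expect_equal(unname(ch$designed_prevalence["steps7500"]), 80)
  expect_equal(unname(ch$designed_prevalence["steps10000"]), 40)
  # schedules tile each day without gaps
  p <- ch$participants[[1]]
  st <- as.numeric(p$schedule$start)
  expect_equal(st[-1], (st + p$schedule$duration_s)[-nrow(p$schedule)])
})
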