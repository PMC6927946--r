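test_that("fraction correct counts hits and correct rejections", {
  expect_equal(fraction_correct(rep("HIT", 20)), 1)
  expect_equal(fraction_correct(c(rep("HIT", 10), rep("CORRECT_REJECTION", 9),
                                  "MISS")), 0.95)
  expect_equal(fraction_correct(c(rep("HIT", 16), rep("FALSE_ALARM", 4))), 0.8)
  expect_true(is.na(fraction_correct(character(0))))
  expect_error(fraction_correct(c("HIT", "ABORTED")), "completed")
})

test_that("d-prime agrees with a bisection inverse-normal oracle", {
  cases <- list(c(95, 5, 5, 95), c(80, 20, 30, 70), c(100, 0, 0, 100),
                c(50, 50, 50, 50), c(1, 9, 2, 8))
  for (cs in cases) {
    expect_lt(abs(dprime(cs[1], cs[2], cs[3], cs[4]) -
                    dprime_oracle(cs[1], cs[2], cs[3], cs[4])), 1e-9)
  }
})

test_that("d-prime is zero at equal rates and antisymmetric under rate swap", {
  expect_equal(dprime(50, 50, 50, 50), 0)
  expect_equal(dprime(30, 70, 30, 70), 0)
  expect_equal(dprime(95, 5, 5, 95), -dprime(5, 95, 95, 5))
  expect_true(is.na(dprime(0, 0, 5, 5)))
  expect_true(is.na(dprime(5, 5, 0, 0)))
})

test_that("perfect performance stays finite through extreme-rate clamping", {
  d <- dprime(100, 0, 0, 100)
  expect_true(is.finite(d))
  expect_equal(d, 2 * stats::qnorm(1 - 1 / 200))
})

make_records <- function(outcomes, labels = NULL, time_s = NULL,
                         animal_id = "m1") {
  n <- length(outcomes)
  if (is.null(labels))
    labels <- ifelse(outcomes %in% c("HIT", "MISS"), S_PLUS, S_MINUS)
  if (is.null(time_s)) time_s <- seq_len(n) * 10
  data.frame(time_s = time_s, animal_id = rep(animal_id, length.out = n),
             phase = rep("DISCRIMINATION", n), trial_label = labels,
             odor_id = rep("odorA", n), presampling_occupancy = rep(0.9, n),
             lick_blocks = rep(3L, n), head_retract_ms = rep(NA_real_, n),
             outcome = outcomes,
             reward_ul = ifelse(outcomes == "HIT", 15, 0),
             iti_s = ifelse(outcomes %in% c("MISS", "FALSE_ALARM"), 4, 1),
             odor_on_ms = rep(2000, n), block_id = rep(1L, n),
             block_index = seq_len(n), stringsAsFactors = FALSE)
}

test_that("performance series is defined only where the window is full", {
  rec <- make_records(rep(c("HIT", "CORRECT_REJECTION"), 30))
  s <- performance_series(rec, window = 20)
  expect_equal(s$trial, 20:60)
  expect_true(all(s$fraction_correct == 1))
  expect_equal(nrow(performance_series(rec, window = 100)), 0)
})

test_that("trials-to-criterion finds the first qualifying window", {
  rec <- make_records(rep(c("HIT", "CORRECT_REJECTION"), 30))
  s <- performance_series(rec, window = 20)
  expect_equal(trials_to_criterion(s, 0.95), 20L)
  expect_true(is.na(trials_to_criterion(s, 1.01)))
  # lenient thresholds are reached no later than strict ones
  rec2 <- make_records(c(rep(c("HIT", "FALSE_ALARM"), 25),
                         rep(c("HIT", "CORRECT_REJECTION"), 50)))
  s2 <- performance_series(rec2, window = 20)
  t_lenient <- trials_to_criterion(s2, 0.8)
  t_strict <- trials_to_criterion(s2, 0.95)
  expect_lte(t_lenient, t_strict)
})

test_that("circadian fractions average per-day distributions that sum to one", {
  t_h <- c(20.1, 20.5, 20.9, 44.2, 44.8, 45.5)  # day 1 hour 20, day 2 hours 20/21
  rec <- make_records(rep("HIT", 6), time_s = t_h * 3600)
  prof <- circadian_profile(rec, "m1")
  expect_equal(prof$day_count, 2L)
  expect_equal(sum(prof$hourly_fraction), 1, tolerance = 1e-9)
  expect_equal(prof$hourly_fraction[21], (1 + 2 / 3) / 2)  # hour 20 bin

  all20 <- make_records(rep("HIT", 5), time_s = (20 + seq(0.1, 0.9, 0.2)) * 3600)
  p <- circadian_profile(all20, "m1")
  expect_equal(p$hourly_fraction[21], 1)
  expect_equal(sum(p$hourly_fraction[-21]), 0)

  empty <- circadian_profile(all20, "ghost")
  expect_equal(empty$day_count, 0L)
  expect_true(all(is.na(empty$hourly_fraction)))
})

test_that("hourly performance shows no hour effect for hour-independent agents", {
  cfg <- run_config("m1",
                    agents = agent_params(h0 = 0.9, h_inf = 0.9, f0 = 0.2,
                                          f_inf = 0.2, p_rfid_fail = 0,
                                          p_presample_fail = 0,
                                          activity_rate = rep(15, 24)),
                    start_phase = "DISCRIMINATION", seed = 13)
  log <- simulate_cohort(cfg, duration_h = 96)
  rec <- log$records[log$records$outcome != "ABORTED", ]
  hour <- floor((rec$time_s / 3600) %% 24)
  correct <- rec$outcome %in% c("HIT", "CORRECT_REJECTION")
  p <- suppressWarnings(stats::chisq.test(table(hour, correct)))$p.value
  expect_gt(p, 0.001)
  hp <- hourly_performance(log$records)
  expect_length(hp, 24)
  expect_true(all(hp >= 0 & hp <= 1, na.rm = TRUE))
})

test_that("daily counts partition completed trials by animal and day", {
  rec <- rbind(make_records(rep("HIT", 10), time_s = seq(1, 10) * 100),
               make_records(rep("HIT", 10), time_s = 86400 + seq(1, 10) * 100),
               make_records(rep("HIT", 10), time_s = 2 * 86400 + seq(1, 10) * 100))
  dc <- daily_counts(rec)
  expect_equal(nrow(dc), 3)
  expect_true(all(dc$trials == 10))
  expect_equal(sum(dc$trials), 30)
  expect_equal(nrow(daily_counts(make_records(character(0)))), 0)
})

test_that("group-size correlation matches a hand-computed Pearson oracle", {
  size <- c(5, 8, 11, 14, 18)
  acc <- c(0.99, 0.985, 0.97, 0.955, 0.93)
  res <- groupsize_effect(size, acc)
  expect_equal(res$r, pearson_oracle(size, acc), tolerance = 1e-12)
  expect_lt(res$r, 0)
  fit <- sum((size - mean(size)) * (acc - mean(acc))) / sum((size - mean(size))^2)
  expect_equal(res$slope, fit, tolerance = 1e-12)

  exact <- groupsize_effect(c(1, 2, 3), c(6, 4, 2))
  expect_equal(exact$r, -1)
  expect_warning(res0 <- groupsize_effect(c(1, 2, 3), c(5, 5, 5)), "zero variance")
  expect_true(is.na(res0$r))
  expect_error(groupsize_effect(c(1, 1, 2), c(1, 2, 3)), "3 distinct")
})

test_that("pulse onset is the interpolated 10%-of-max crossing", {
  ramp <- list(time_ms = 0:100, concentration = 0:100 / 100)
  expect_equal(pulse_metrics(ramp)$onset_ms, 10)
  # a sampled step rises within one interval; the interpolated crossing
  # lands inside it, within one sample of the step time
  step <- list(time_ms = 0:50, concentration = c(rep(0, 30), rep(1, 21)))
  expect_lt(abs(pulse_metrics(step)$onset_ms - 30), 1)
  expect_equal(pulse_metrics(step)$peak_amplitude, 1)
  flat <- list(time_ms = 0:10, concentration = rep(0, 11))
  expect_true(all(is.na(unlist(pulse_metrics(flat)))))
  expect_error(pulse_metrics(list(time_ms = 1, concentration = 1)), "2 samples")
})
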