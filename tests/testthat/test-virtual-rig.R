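test_that("lick probabilities follow the exponential learning closed form", {
  p <- agent_params(h0 = 0.6, h_inf = 0.95, f0 = 0.7, f_inf = 0.05, tau = 80)
  expect_equal(lick_probability(p, 0, S_PLUS), 0.6)
  expect_equal(lick_probability(p, 0, S_MINUS), 0.7)
  expect_equal(lick_probability(p, 80, S_PLUS), 0.95 - (0.95 - 0.6) / exp(1))
  expect_equal(lick_probability(p, 1e6, S_PLUS), 0.95)
  expect_equal(lick_probability(p, 1e6, S_MINUS), 0.05)
  expect_error(agent_params(h0 = 1.2), "\\[0, 1\\]")
  expect_error(agent_params(tau = -3), "tau")
})

test_that("agent responses meet the lick criterion when licking, retract early otherwise", {
  p <- agent_params(h0 = 1, h_inf = 1, f0 = 0, f_inf = 0)
  set.seed(1)
  r <- agent_response(p, 10, S_PLUS, criterion = 3)
  expect_gte(r$lick_blocks, 3)
  expect_true(is.na(r$head_retract_ms))
  r <- agent_response(p, 10, S_MINUS, criterion = 3)
  expect_equal(r$lick_blocks, 0L)
  expect_true(r$head_retract_ms >= 250 && r$head_retract_ms <= 1200)
})

test_that("initiation process matches its hourly Poisson intensity", {
  p0 <- agent_params(activity_rate = rep(0, 24))
  expect_length(sample_initiations(p0, 24, seed = 1), 0)

  p12 <- agent_params(activity_rate = rep(12, 24))
  n <- length(sample_initiations(p12, 24, seed = 2))
  expect_lt(abs(n - 288), 3 * sqrt(288))

  noct <- agent_params(activity_rate = nocturnal_activity())
  t_h <- sample_initiations(noct, 24 * 4, seed = 3)
  hour <- floor(t_h %% 24)
  dark <- hour >= 18 | hour < 6
  expect_gte(mean(dark), 0.7)
})

test_that("initiations are reproducible under a fixed seed and time-sorted", {
  p <- agent_params()
  a <- sample_initiations(p, 48, seed = 9)
  expect_identical(a, sample_initiations(p, 48, seed = 9))
  expect_false(is.unsorted(a))
  expect_true(all(a >= 0 & a <= 48))
})

test_that("a flawless performer finishes pre-training in exactly 600 completed trials", {
  cfg <- run_config("m1", agents = flawless_agent(), seed = 3)
  log <- simulate_cohort(cfg, duration_h = 36)
  rec <- log$records
  pre <- rec[rec$phase != "DISCRIMINATION" & rec$outcome != "ABORTED", ]
  expect_equal(nrow(pre), 600)
  expect_equal(sum(pre$phase == "1"), 50)
  expect_equal(sum(pre$phase == "2"), 50)
  expect_equal(as.integer(table(pre$phase)[as.character(3:7)]), rep(100L, 5))
  expect_true("DISCRIMINATION" %in% rec$phase)
})

test_that("simulated logs satisfy the outcome partition and reward conservation", {
  cfg <- run_config(c("m1", "m2", "m3"),
                    agents = agent_params(p_rfid_fail = 0.08,
                                          p_presample_fail = 0.05,
                                          activity_rate = rep(15, 24)),
                    seed = 17)
  log <- simulate_cohort(cfg, duration_h = 48)
  rec <- log$records
  expect_true(isTRUE(validate_event_log(log)))
  expect_equal(sum(rec$outcome %in% OUTCOMES), nrow(rec))
  expect_equal(sum(rec$reward_ul), sum(rec$reward_ul[rec$outcome == "HIT"]))
  expect_true(all(rec$odor_on_ms <= 2000))
  completed <- rec[rec$outcome != "ABORTED", ]
  # completed-trial ITI is the phase base (ramped, at most 3.9 s) plus the
  # 3 s penalty exactly on Miss/False-Alarm outcomes
  penalized <- completed$outcome %in% c("MISS", "FALSE_ALARM")
  expect_true(all(completed$iti_s[penalized] >= 3))
  expect_true(all(completed$iti_s[!penalized] <= 3.9))
  # determinism: identical config + seed reproduces the record stream
  log2 <- simulate_cohort(cfg, duration_h = 48)
  expect_identical(log$records, log2$records)
})

test_that("single-port mutual exclusion: no two trials overlap in time", {
  cfg <- run_config(c("a", "b", "c", "d"),
                    agents = agent_params(activity_rate = rep(40, 24)),
                    seed = 5)
  log <- simulate_cohort(cfg, duration_h = 12)
  iv <- record_intervals(log$records)
  iv <- iv[order(iv$start), ]
  expect_true(all(diff(iv$start) >= 0))
  expect_true(all(iv$end[-nrow(iv)] <= iv$start[-1] + 1e-9))
})

test_that("aborted-RFID fraction converges to p_rfid_fail", {
  p_fail <- 0.1
  cfg <- run_config("m1",
                    agents = agent_params(p_rfid_fail = p_fail,
                                          p_presample_fail = 0,
                                          activity_rate = rep(40, 24)),
                    seed = 23)
  log <- simulate_cohort(cfg, duration_h = 72)
  rec <- log$records
  n <- nrow(rec)
  k <- sum(rec$outcome == "ABORTED" & rec$odor_id == "none")
  ci <- p_fail + c(-1, 1) * 3 * sqrt(p_fail * (1 - p_fail) / n)
  expect_gt(k / n, ci[1])
  expect_lt(k / n, ci[2])
})

test_that("learning agents cross and hold the 0.95 accuracy criterion", {
  cfg <- run_config("m1",
                    agents = agent_params(tau = 120, p_rfid_fail = 0,
                                          p_presample_fail = 0,
                                          activity_rate = rep(25, 24)),
                    start_phase = "DISCRIMINATION", seed = 31)
  log <- simulate_cohort(cfg, duration_h = 80)
  series <- performance_series(log$records, window = 100)
  ttc <- trials_to_criterion(series, 0.95, "fraction_correct")
  expect_false(is.na(ttc))
  after <- series$fraction_correct[series$trial >= ttc + 200]
  expect_gt(mean(after >= 0.95), 0.9)  # held, minor windowed dips allowed
})

test_that("smaller learning time constants reach criterion in fewer trials", {
  ttc <- sapply(c(60, 240), function(tau) {
    cfg <- run_config("m1",
                      agents = agent_params(tau = tau, p_rfid_fail = 0,
                                            p_presample_fail = 0,
                                            activity_rate = rep(25, 24)),
                      start_phase = "DISCRIMINATION", seed = 77)
    log <- simulate_cohort(cfg, duration_h = 60)
    trials_to_criterion(performance_series(log$records, 100), 0.95)
  })
  expect_lt(ttc[1], ttc[2])
})

test_that("noise-free pulses obey the configured onset, peak and linear gain", {
  m <- olfactometer_model(noise_sd = 0)
  tr <- synth_odor_trace(m, 2, 1)
  pm <- pulse_metrics(tr)
  expect_lt(abs(pm$onset_ms - m$onset_ms), tr$dt_ms)
  expect_lt(abs(pm$peak_ms - m$peak_ms[2]), tr$dt_ms)
  half <- pulse_metrics(synth_odor_trace(m, 2, 0.5))
  expect_equal(pm$peak_amplitude / half$peak_amplitude, 2)
  zero <- synth_odor_trace(olfactometer_model(), 1, 0, seed = 4)
  expect_lt(max(abs(zero$concentration)), 5 * olfactometer_model()$noise_sd)
  expect_error(synth_odor_trace(m, 99, 1), "valve_id")
  expect_error(synth_odor_trace(m, 1, 1.5), "dilution")
})

test_that("measured peaks track commanded dilutions tightly at default noise", {
  m <- olfactometer_model()
  dil <- rep(c(0.25, 0.4, 0.6, 1.0), each = 12)
  set.seed(7)
  peaks <- vapply(dil, function(d)
    pulse_metrics(synth_odor_trace(m, 3, d))$peak_amplitude, numeric(1))
  expect_gt(stats::cor(dil, peaks), 0.99)
})

test_that("the learning model is recoverable from a simulated log", {
  cfg <- run_config("m1",
                    agents = agent_params(tau = 120, p_rfid_fail = 0,
                                          p_presample_fail = 0,
                                          activity_rate = rep(20, 24)),
                    start_phase = "DISCRIMINATION", seed = 11)
  log <- simulate_cohort(cfg, duration_h = 110)
  rec <- log$records[log$records$outcome != "ABORTED", ]
  expect_gte(nrow(rec), 2000)
  fit <- fit_learning_model(log$records)
  expect_lt(abs(fit$tau - 120) / 120, 0.2)
  expect_lt(abs((fit$h_inf - fit$f_inf) - (0.99 - 0.02)), 0.05)
})
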