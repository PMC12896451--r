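test_that("generators are deterministic and leave the caller's RNG alone", {
  cfg <- sim_config(seed = 123L)
  s1 <- simulate_bout_schedule(cfg, "control", 3, "aggressive")
  set.seed(777); before <- runif(1)
  set.seed(777)
  s2 <- simulate_bout_schedule(cfg, "control", 3, "aggressive")
  expect_identical(s1, s2)
  expect_identical(runif(1), before)   # RNG state restored
  d1 <- render_detections(s1, cfg, 11L)
  d2 <- render_detections(s1, cfg, 11L)
  expect_identical(d1, d2)
  m1 <- render_manual(s1, cfg, 12L)
  expect_identical(m1, render_manual(s1, cfg, 12L))
  fx1 <- make_box_fixture(5, cfg, 13L)
  expect_identical(fx1, make_box_fixture(5, cfg, 13L))
  # different days draw different schedules
  expect_false(identical(s1, simulate_bout_schedule(cfg, "control", 4,
                                                    "aggressive")))
})

test_that("bout schedules respect rate structure and packing constraints", {
  cfg <- sim_config(base_bouts_per_day = c(aggressive = 0,
                                           ear_biting = 0,
                                           tail_biting = 0))
  expect_equal(nrow(simulate_bout_schedule(cfg, "control", 1,
                                           "aggressive")), 0L)
  crit <- bout_criteria()
  cfg <- sim_config(seed = 60L)
  s <- simulate_bout_schedule(cfg, "control", 1, "ear_biting")
  expect_true(all(s$duration_s >= crit$onset_min_s[["ear_biting"]]))
  expect_true(all(s$start_s >= 0L & s$end_s <= 86400L))
  if (nrow(s) > 1)   # same-class bouts separated by the termination gap
    expect_true(all(s$start_s[-1] - s$end_s[-nrow(s)] >=
                      crit$termination_gap_s))
  # infeasible expected packing is refused
  cfg_bad <- sim_config(base_bouts_per_day = c(aggressive = 4000,
                                               ear_biting = 1,
                                               tail_biting = 1))
  expect_error(simulate_bout_schedule(cfg_bad, "control", 1, "aggressive"),
               "infeasible")
})

test_that("daily bout counts recover the configured Poisson rate", {
  cfg <- sim_config(base_bouts_per_day = c(aggressive = 20,
                                           ear_biting = 20,
                                           tail_biting = 20),
                    day_trend = c(aggressive = 0, ear_biting = 0,
                                  tail_biting = 0),
                    seed = 202L)
  n_days <- 2000L
  counts <- vapply(seq_len(n_days), function(day)
    nrow(simulate_bout_schedule(cfg, "control", day, "aggressive")),
    numeric(1))
  se <- sqrt(20 / n_days)
  expect_lt(abs(mean(counts) - 20), 3 * se)
})

test_that("rendered detections realize the configured miss rate", {
  # noise-free: presence rebuilt from detections equals the schedule
  cfg0 <- noise_free_config(seed = 3L)
  s <- simulate_bout_schedule(cfg0, "control", 1, "aggressive")
  det <- render_detections(s, cfg0, 5L)
  pres <- to_presence_series(filter_by_confidence(det, 0.45), s$date[1],
                             "aggressive")
  expect_identical(pres, bouts_to_presence(s))
  # all confidences survive the operating threshold
  expect_true(all(det$confidence >= 0.45 & det$confidence <= 1))
  # miss_prob 1 is disallowed by validation; near-1 yields almost nothing
  cfg_m <- sim_config(miss_prob = 0.999, false_positive_rate = 0, seed = 3L)
  det_m <- render_detections(s, cfg_m, 5L)
  expect_lt(nrow(det_m[det_m$class == "aggressive", ]),
            0.05 * sum(s$duration_s))
  # binomial moment: detected fraction within 3 SE of 1 - miss_prob
  cfg1 <- sim_config(miss_prob = 0.1, false_positive_rate = 0, seed = 8L)
  long <- bout_table("aggressive", "2024-07-01", 0L, 20000L)
  det1 <- render_detections(long, cfg1, 21L)
  frac <- nrow(det1) / 20000
  expect_lt(abs(frac - 0.9), 3 * sqrt(0.9 * 0.1 / 20000))
  # false positives appear at the configured daily rate (Poisson moment)
  cfg2 <- sim_config(miss_prob = 0, false_positive_rate = 40, seed = 9L)
  n_fp <- vapply(1:100, function(i)
    nrow(render_detections(bout_table(), cfg2, i, date = "2024-07-01")),
    numeric(1))
  expect_lt(abs(mean(n_fp) - 120), 3 * sqrt(120 / 100))  # 3 classes x 40
})

test_that("manual rendering drops, jitters and preserves validity", {
  cfg0 <- noise_free_config(seed = 10L)
  s <- simulate_bout_schedule(cfg0, "control", 2, "tail_biting")
  expect_identical(render_manual(s, cfg0, 4L), s)
  cfg_all <- sim_config(manual_miss_prob = 0.999, seed = 10L)
  expect_lt(nrow(render_manual(s, cfg_all, 4L)), nrow(s))
  # half-normal moment of the start jitter
  cfg_j <- sim_config(manual_miss_prob = 0,
                      manual_boundary_jitter_sd_s = 2, seed = 10L)
  n <- 1000L
  starts <- seq(0L, by = 60L, length.out = n)
  big <- bout_table(rep("aggressive", n), rep("2024-07-01", n),
                    starts, starts + 20L)
  man <- render_manual(big, cfg_j, 6L)
  disp <- abs(man$start_s - big$start_s)
  # rounded-to-seconds gaussian jitter: compare to the discretized moment
  expected <- mean(abs(round(stats::qnorm((1:1e5 - 0.5) / 1e5, 0, 2))))
  expect_lt(abs(mean(disp) - expected), 3 * stats::sd(disp) / sqrt(n))
  expect_true(all(man$end_s > man$start_s))
  expect_true(all(man$start_s >= 0 & man$end_s <= 86400))
})

test_that("noise-free schedules survive the full pipeline unchanged", {
  crit <- bout_criteria()
  for (seed in 1:100) {
    cfg <- noise_free_config(seed = seed)
    day <- (seed %% 28L) + 1L
    group <- if (seed %% 2) "control" else "treatment"
    for (cl in behavior_classes()) {
      s <- simulate_bout_schedule(cfg, group, day, cl, crit)
      det <- render_detections(s, cfg, seed + 1000L,
                               date = cfg$start_date + day - 1)
      pres <- to_presence_series(filter_by_confidence(det, 0.45),
                                 cfg$start_date + day - 1, cl)
      got <- find_bouts(pres, cl, crit, date = cfg$start_date + day - 1)
      expect_same_bouts(got, s)
    }
  }
})

test_that("the treatment multiplier depresses simulated bout counts", {
  cfg <- sim_config(base_bouts_per_day = c(aggressive = 20, ear_biting = 20,
                                           tail_biting = 20),
                    treatment_multiplier = c(aggressive = 0.5,
                                             ear_biting = 0.5,
                                             tail_biting = 0.5),
                    day_trend = c(aggressive = 0, ear_biting = 0,
                                  tail_biting = 0))
  n_pos <- 0L; n_rep <- 200L
  for (r in seq_len(n_rep)) {
    cfg$seed <- 5000L + r
    ctrl <- mean(vapply(1:28, function(day)
      nrow(simulate_bout_schedule(cfg, "control", day, "aggressive")),
      numeric(1)))
    trt <- mean(vapply(1:28, function(day)
      nrow(simulate_bout_schedule(cfg, "treatment", day, "aggressive")),
      numeric(1)))
    n_pos <- n_pos + (ctrl > trt)
  }
  expect_gte(n_pos / n_rep, 0.99)
})

test_that("simulation configs round-trip through YAML", {
  cfg <- sim_config(seed = 99L, miss_prob = 0.02)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  cfg2 <- read_sim_config(path)
  expect_equal(cfg2, cfg)
  # and drive identical simulations
  expect_identical(simulate_bout_schedule(cfg, "control", 1, "aggressive"),
                   simulate_bout_schedule(cfg2, "control", 1, "aggressive"))
})

test_that("experiment assembly binds groups and days consistently", {
  cfg <- sim_config(base_bouts_per_day = c(aggressive = 5, ear_biting = 5,
                                           tail_biting = 5), seed = 77L)
  ex <- simulate_experiment(cfg, days = 3L)
  expect_setequal(unique(ex$true_bouts$group), c("control", "treatment"))
  expect_equal(length(unique(ex$true_bouts$date)), 3L)
  # detections carry the house channel of their group
  expect_true(all(ex$detections$channel[ex$detections$group ==
                                          "control"] == 11L))
  expect_true(all(ex$detections$channel[ex$detections$group ==
                                          "treatment"] == 10L))
})
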