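always_open_study <- function() minimal_study()

test_that("full adherence with an ample horizon completes every reachable module", {
  sim <- simulate_cohort(example_study(),
                         simulation_config(6, horizon = 30000,
                                           adherence_prob = 1, seed = 2))
  r <- sim$report
  # welcome and check-in open for everyone and are always completed
  pm <- r$per_module
  expect_equal(pm$completion_rate[pm$module_id == "m_welcome"], 1)
  expect_equal(pm$completion_rate[pm$module_id == "m_checkin"], 1)
  expect_equal(r$overall_completion_rate, 1)
})

test_that("zero adherence yields no answers while time rules still close modules", {
  sim <- simulate_cohort(example_study(),
                         simulation_config(4, horizon = 30000,
                                           adherence_prob = 0, seed = 2))
  expect_equal(sum(sim$events$kind == "answer"), 0)
  expect_equal(sim$report$overall_completion_rate, 0)
  # welcome modules opened; with nobody answering, the check-in never opens
  tr <- sim$transitions
  expect_equal(sum(tr$module_id == "m_welcome" & tr$to == "OPEN"), 4)
  expect_equal(sum(tr$to == "COMPLETED"), 0)
})

test_that("time-ruled modules close for non-adherent participants", {
  s <- study_definition("CL", "T", list(intervention("arm", "A", list(
    study_module("m1", "M", list(item("q1", "slider", "?", variable = "v")),
                 opening_rules = list(open_after_enrollment(0)),
                 closing_rules = list(close_after_open(100)))))))
  sim <- simulate_cohort(s, simulation_config(3, horizon = 1000,
                                              adherence_prob = 0, seed = 5))
  expect_equal(sum(sim$transitions$to == "CLOSED"), 3)
})

test_that("the simulated event log replays to the identical transition list", {
  for (seed in c(1, 8)) {
    sim <- simulate_cohort(example_study(),
                           simulation_config(5, horizon = 30000,
                                             enrollment_window = 2000,
                                             adherence_prob = 0.6, seed = seed))
    replay <- run_timeline(example_study(), sim$events)
    expect_identical(replay$transitions, sim$transitions)
  }
})

test_that("simulation is bit-identical under the same seed", {
  cfg <- simulation_config(5, horizon = 20000, enrollment_window = 1000,
                           adherence_prob = 0.5, seed = 7)
  a <- simulate_cohort(example_study(), cfg)
  b <- simulate_cohort(example_study(), cfg)
  expect_identical(a$events, b$events)
  expect_identical(a$transitions, b$transitions)
  expect_identical(a$plan, b$plan)
  expect_identical(a$report, b$report)
})

test_that("the simulator never answers a module that is not open at that minute", {
  sim <- simulate_cohort(example_study(),
                         simulation_config(6, horizon = 30000,
                                           adherence_prob = 0.7,
                                           response_latency = 400, seed = 13))
  ev <- sim$events
  # replay step by step; every logged answer must be accepted (module OPEN)
  timelines <- structure(list(), engine_time = -1L)
  for (i in seq_len(nrow(ev))) {
    res <- step(example_study(), timelines, ev[i, ])
    if (ev$kind[[i]] %in% c("answer", "module_completed"))
      expect_equal(attr(res$transitions, "rejected"), 0L)
    timelines <- res$timelines
  }
})

test_that("an empty cohort gives an all-zero report", {
  r <- adherence_report(emaflow:::empty_events(), emaflow:::empty_transitions())
  expect_equal(r$overall_completion_rate, 0)
  expect_equal(r$mean_response_latency, 0)
  expect_equal(sum(r$notification_counts), 0)
  expect_equal(nrow(r$per_module), 0)
})

test_that("a hand-built two-participant log reproduces hand-counted rates", {
  tr <- data.frame(
    time = c(0L, 10L, 0L, 500L, 20L, 30L),
    participant_id = c("p1", "p1", "p2", "p2", "p1", "p1"),
    module_id = c("m1", "m1", "m1", "m1", "m2", "m2"),
    from = c("LOCKED", "OPEN", "LOCKED", "OPEN", "LOCKED", "OPEN"),
    to = c("OPEN", "COMPLETED", "OPEN", "CLOSED", "OPEN", "COMPLETED"),
    stringsAsFactors = FALSE)
  r <- adherence_report(emaflow:::empty_events(), tr)
  # m1: 2 opened, 1 completed; m2: 1 opened, 1 completed; overall 2/3
  expect_equal(r$per_module$completion_rate, c(1 / 2, 1))
  expect_equal(r$overall_completion_rate, 2 / 3)
  # p1 completed 2/2, p2 0/1
  expect_equal(r$per_participant$completion_fraction, c(1, 0))
  # latencies: m1 for p1 10-0, m2 for p1 30-20
  expect_equal(r$mean_response_latency, 10)
})

test_that("per-participant fractions, opening-weighted, average to the overall rate", {
  sim <- simulate_cohort(example_study(),
                         simulation_config(8, horizon = 30000,
                                           adherence_prob = 0.5, seed = 21))
  r <- sim$report
  opened <- sim$transitions[sim$transitions$to == "OPEN", ]
  w <- vapply(r$per_participant$participant_id, function(p)
    sum(opened$participant_id == p), 0)
  expect_equal(sum(r$per_participant$completion_fraction * w) / sum(w),
               r$overall_completion_rate)
})

test_that("completion rates recover the configured adherence probability", {
  sim <- simulate_cohort(always_open_study(),
                         simulation_config(200, horizon = 5000,
                                           adherence_prob = 0.7, seed = 31))
  rate <- sim$report$overall_completion_rate
  expect_lt(abs(rate - 0.7), 3 * sqrt(0.7 * 0.3 / 200))
})

test_that("waitlist interventions receive no participants", {
  s <- study_definition("WL", "T", list(
    intervention("wl", "Waitlist", list(
      study_module("m1", "M", list(item("q1", "slider", "?", variable = "v")),
                   opening_rules = list(open_after_enrollment(0)))),
      assignment_policy = "waitlist")))
  sim <- simulate_cohort(s, simulation_config(5, horizon = 1000, seed = 1))
  expect_equal(sum(sim$events$kind != "clock_tick"), 0)
  expect_equal(nrow(sim$transitions), 0)
})

test_that("exported responses flag answers preserved from closed modules", {
  s <- study_definition("EXP", "T", list(intervention("arm", "A", list(
    study_module("m1", "M",
                 list(item("q1", "slider", "?", variable = "v1"),
                      item("q2", "slider", "?", variable = "v2")),
                 opening_rules = list(open_after_enrollment(0)),
                 closing_rules = list(close_after_open(100)))))))
  ev <- rbind(
    data.frame(time = 0L, participant_id = "p1", kind = "enroll",
               module_id = NA_character_, item_id = NA_character_,
               value = NA_character_),
    data.frame(time = 10L, participant_id = "p1", kind = "answer",
               module_id = NA_character_, item_id = "q1", value = "4"),
    data.frame(time = 500L, participant_id = "", kind = "clock_tick",
               module_id = NA_character_, item_id = NA_character_,
               value = NA_character_))
  r <- run_timeline(s, ev)
  long <- export_responses(s, r$timelines)
  expect_equal(nrow(long), 1)              # partial answers preserved
  expect_equal(long$module_state, "CLOSED")
  expect_equal(long$variable, "v1")
  expect_equal(long$study_code, "EXP")
})

test_that("event logs round-trip through CSV", {
  sim <- simulate_cohort(example_study(),
                         simulation_config(3, horizon = 20000,
                                           adherence_prob = 0.8, seed = 3))
  f <- withr::local_tempfile(fileext = ".csv")
  write_events(sim$events, f)
  back <- read_events(f)
  replay <- run_timeline(example_study(), back)
  expect_identical(replay$transitions, sim$transitions)
})
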