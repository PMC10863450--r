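# direct construction of a timeline fixture for rule-resolution tests
make_timeline <- function(study, enroll_time = 0L, pid = "p1") {
  iv <- study$interventions[[1]]
  emaflow:::new_timeline(pid, iv$id, as.integer(enroll_time), iv)
}

chain_study <- function(gap = 0) {
  study_definition("CHAIN", "Three-module chain", list(intervention("arm", "A", list(
    study_module("m1", "One", list(item("q1", "slider", "?", variable = "v1")),
                 opening_rules = list(open_after_enrollment(0)),
                 closing_rules = list(close_after_open(500))),
    study_module("m2", "Two", list(item("q2", "slider", "?", variable = "v2")),
                 opening_rules = list(open_after_completion("m1", gap)),
                 closing_rules = list(close_after_open(500))),
    study_module("m3", "Three", list(item("q3", "slider", "?", variable = "v3")),
                 opening_rules = list(open_after_completion("m2", gap)),
                 closing_rules = list(close_after_open(500)))))))
}

answer_ev <- function(time, item, value = "5", pid = "p1") {
  data.frame(time = as.integer(time), participant_id = pid, kind = "answer",
             module_id = NA_character_, item_id = item,
             value = as.character(value), stringsAsFactors = FALSE)
}
enroll_ev <- function(time = 0, pid = "p1") {
  data.frame(time = as.integer(time), participant_id = pid, kind = "enroll",
             module_id = NA_character_, item_id = NA_character_,
             value = NA_character_, stringsAsFactors = FALSE)
}
tick_ev <- function(time) {
  data.frame(time = as.integer(time), participant_id = "", kind = "clock_tick",
             module_id = NA_character_, item_id = NA_character_,
             value = NA_character_, stringsAsFactors = FALSE)
}

test_that("opening rules resolve to their firing times", {
  s <- chain_study()
  tl <- make_timeline(s, enroll_time = 0)
  expect_equal(resolve_open_time(open_after_enrollment(1440), tl, now = 0), 1440L)

  tl$instances$m1$finished_at <- 200L
  expect_equal(resolve_open_time(open_after_completion("m1", 60), tl, now = 200), 260L)

  tl$answers <- data.frame(time = 100L, item_id = "q3", value = "7")
  expect_equal(resolve_open_time(open_on_answer("q3", "ge", 7), tl, now = 100), 100L)
  tl$answers$value <- "5"
  expect_true(is.na(resolve_open_time(open_on_answer("q3", "ge", 7), tl, now = 100)))

  # fixed time before enrollment clamps to enrollment
  tl2 <- make_timeline(s, enroll_time = 300)
  expect_equal(resolve_open_time(open_at(50), tl2, now = 300), 300L)
})

test_that("open_if_not_finished stays undetermined until the check time", {
  s <- chain_study()
  tl <- make_timeline(s)
  r <- open_if_not_finished("m1", 2880)
  expect_true(is.na(resolve_open_time(r, tl, now = 100)))   # m1 never opened
  tl$instances$m1$opened_at <- 0L
  tl$instances$m1$state <- "OPEN"
  expect_true(is.na(resolve_open_time(r, tl, now = 1000)))  # outcome unknown
  expect_equal(resolve_open_time(r, tl, now = 2880), 2880L) # unfinished at check
  tl$instances$m1$finished_at <- 2000L
  expect_true(is.na(resolve_open_time(r, tl, now = 5000)))  # finished in time
  tl$instances$m1$finished_at <- 3000L
  expect_equal(resolve_open_time(r, tl, now = 2000), 2880L) # finished too late
})

test_that("closing rules resolve relative to the open instance", {
  s <- chain_study()
  tl <- make_timeline(s)
  inst <- tl$instances$m1
  inst$state <- "OPEN"; inst$opened_at <- 300L
  expect_equal(resolve_close_time(close_after_open(60), inst, tl), 360L)
  expect_equal(resolve_close_time(close_at(500), inst, tl), 500L)
  # fixed date before open degenerates to closing at the open instant
  expect_equal(resolve_close_time(close_at(100), inst, tl), 300L)
})

test_that("enroll opens zero-offset modules at the enrollment minute", {
  s <- minimal_study()
  r <- run_timeline(s, enroll_ev(42))
  expect_equal(r$transitions,
               data.frame(time = 42L, participant_id = "p1", module_id = "m1",
                          from = "LOCKED", to = "OPEN"))
})

test_that("answering the last unanswered item completes the module", {
  s <- minimal_study()
  r <- run_timeline(s, rbind(enroll_ev(0), answer_ev(10, "q1", "8")))
  expect_equal(r$transitions$to, c("OPEN", "COMPLETED"))
  expect_equal(r$timelines$p1$instances$m1$finished_at, 10L)
})

test_that("a module left unfinished branches its dependent open at the check time", {
  s <- study_definition("NF", "T", list(intervention("arm", "A", list(
    study_module("m1", "One", list(item("q1", "slider", "?", variable = "v1")),
                 opening_rules = list(open_after_enrollment(0))),
    study_module("m2", "Nudge", list(item("q2", "slider", "?", variable = "v2")),
                 opening_rules = list(open_if_not_finished("m1", 2880)))))))
  r <- run_timeline(s, rbind(enroll_ev(0), tick_ev(2880)))
  tr <- r$transitions
  expect_equal(tr[tr$module_id == "m2", ]$time, 2880L)
  expect_equal(tr[tr$module_id == "m2", ]$to, "OPEN")

  # completed in time: the nudge never opens
  r2 <- run_timeline(s, rbind(enroll_ev(0), answer_ev(100, "q1"), tick_ev(5000)))
  expect_false("m2" %in% r2$transitions$module_id)
})

test_that("a 3-module chain completes when answers are supplied and stalls when not", {
  s <- chain_study(gap = 0)
  ev <- rbind(enroll_ev(0), answer_ev(10, "q1"), answer_ev(20, "q2"),
              answer_ev(30, "q3"), tick_ev(2000))
  r <- run_timeline(s, ev)
  # hand-traced: m1 opens 0, completes 10; m2 opens 10, completes 20;
  # m3 opens 20, completes 30
  expected <- data.frame(
    time = c(0L, 10L, 10L, 20L, 20L, 30L),
    participant_id = "p1",
    module_id = c("m1", "m1", "m2", "m2", "m3", "m3"),
    from = c("LOCKED", "OPEN", "LOCKED", "OPEN", "LOCKED", "OPEN"),
    to = c("OPEN", "COMPLETED", "OPEN", "COMPLETED", "OPEN", "COMPLETED"))
  expect_equal(r$transitions, expected)

  # no answers: m1 opens at 0 and closes at 500, m2/m3 never open
  r2 <- run_timeline(s, rbind(enroll_ev(0), tick_ev(2000)))
  expect_equal(r2$transitions,
               data.frame(time = c(0L, 500L), participant_id = "p1",
                          module_id = "m1", from = c("LOCKED", "OPEN"),
                          to = c("OPEN", "CLOSED")))
  expect_equal(r2$timelines$p1$instances$m2$state, "LOCKED")
})

test_that("answers to non-OPEN modules are rejected without state change", {
  s <- chain_study()
  # q2 belongs to m2, which is LOCKED at t=5
  r <- run_timeline(s, rbind(enroll_ev(0), answer_ev(5, "q2"), tick_ev(600)))
  expect_equal(nrow(r$timelines$p1$answers), 0)
  # answer after m1 closed at 500
  r2 <- run_timeline(s, rbind(enroll_ev(0), answer_ev(600, "q1"), tick_ev(700)))
  expect_equal(nrow(r2$timelines$p1$answers), 0)
  expect_equal(r2$timelines$p1$instances$m1$state, "CLOSED")
})

test_that("out-of-order events are rejected with a monotonicity error", {
  s <- minimal_study()
  st <- step(s, structure(list(), engine_time = -1L), enroll_ev(100))
  expect_error(step(s, st$timelines, answer_ev(50, "q1")), "out-of-order")
  ev <- rbind(enroll_ev(100), answer_ev(50, "q1"))  # decreasing times
  expect_error(run_timeline(s, ev), "sorted")
})

test_that("empty event lists produce no transitions", {
  r <- run_timeline(minimal_study(), emaflow:::empty_events())
  expect_equal(nrow(r$transitions), 0)
  expect_length(r$timelines, 0)
})

test_that("no illegal transition is ever emitted over random studies and events", {
  legal <- c("LOCKED>OPEN", "OPEN>COMPLETED", "OPEN>CLOSED")
  for (seed in 1:30) {
    s <- random_study(seed)
    ev <- random_events(s, seed + 1000, horizon = 5000)
    tr <- run_timeline(s, ev)$transitions
    expect_true(all(paste0(tr$from, ">", tr$to) %in% legal),
                label = paste("seed", seed))
    # per instance: at most one open, one terminal, in time order
    key <- paste(tr$participant_id, tr$module_id)
    for (k in unique(key)) {
      sub <- tr[key == k, ]
      expect_lte(sum(sub$to == "OPEN"), 1)
      expect_lte(sum(sub$to %in% c("COMPLETED", "CLOSED")), 1)
      expect_true(!is.unsorted(sub$time))
    }
  }
})

test_that("replaying the same events is deterministic", {
  for (seed in c(3, 17)) {
    s <- random_study(seed)
    ev <- random_events(s, seed, horizon = 4000)
    expect_identical(run_timeline(s, ev)$transitions,
                     run_timeline(s, ev)$transitions)
  }
})

test_that("run_timeline matches the brute-force minute-by-minute oracle", {
  for (seed in 1:20) {
    s <- random_study(seed)
    ev <- random_events(s, seed + 500, n_participants = 2, horizon = 3000)
    expect_equal(run_timeline(s, ev)$transitions, oracle_run(s, ev),
                 label = paste("seed", seed))
  }
})
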