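# Random fixture generators used by the property-style tests. All draw from
# an explicit seed so every run exercises the same cases.

# A random valid study: <= n_max modules, slider/number items, a mix of all
# opening and closing rule kinds (references only to earlier modules, so
# every reference resolves), notifications on some modules.
random_study <- function(seed, n_max = 5) {
  set.seed(seed)
  n_mod <- sample.int(n_max, 1)
  modules <- vector("list", n_mod)
  for (i in seq_len(n_mod)) {
    its <- list(item(sprintf("q%da", i), "slider", "prompt",
                     variable = sprintf("v%da", i)))
    if (runif(1) < 0.4)
      its <- c(its, list(item(sprintf("q%db", i), "number_input", "prompt",
                              variable = sprintf("v%db", i))))

    r <- runif(1)
    ors <- if (i == 1 || r < 0.35) {
      list(open_after_enrollment(sample(0:2000, 1)))
    } else if (r < 0.55) {
      list(open_after_completion(sprintf("m%d", sample.int(i - 1, 1)),
                                 sample(0:1500, 1)))
    } else if (r < 0.70) {
      list(open_if_not_finished(sprintf("m%d", sample.int(i - 1, 1)),
                                sample(30:3000, 1)))
    } else if (r < 0.85) {
      list(open_on_answer(sprintf("q%da", sample.int(i - 1, 1)),
                          sample(COMPARATORS_TEST, 1), sample(1:10, 1)))
    } else {
      list(open_at(sample(0:6000, 1)))
    }
    if (runif(1) < 0.3)
      ors <- c(ors, list(open_after_enrollment(sample(0:4000, 1))))

    crs <- list()
    if (runif(1) < 0.5) crs <- c(crs, list(close_after_open(sample(30:2000, 1))))
    if (runif(1) < 0.25) crs <- c(crs, list(close_at(sample(500:8000, 1))))
    if (i > 1 && runif(1) < 0.2)
      crs <- c(crs, list(close_on_answer(sprintf("q%da", sample.int(i - 1, 1)),
                                         "ge", sample(5:10, 1))))

    nots <- list()
    if (runif(1) < 0.5)
      nots <- c(nots, list(notify_reminder(offset_minutes = sample(15:120, 1))))
    if (runif(1) < 0.4) {
      w <- sort(sample(0:60, 2, replace = TRUE))
      nots <- c(nots, list(notify_opening(window = w)))
    }
    closable <- any(vapply(crs, function(r)
      r$rule %in% c("fixed_date", "relative_to_module_start"), TRUE))
    if (closable && runif(1) < 0.4) nots <- c(nots, list(notify_closing()))

    modules[[i]] <- study_module(sprintf("m%d", i), sprintf("Module %d", i),
                                 its, ors, crs, nots)
  }
  study_definition(sprintf("RS%d", seed), "Random study",
                   list(intervention("iv", "Arm", modules)))
}

COMPARATORS_TEST <- c("eq", "ne", "lt", "le", "gt", "ge")

# A random sorted event log for a study: enrollments, answers at or after
# each participant's enrollment, occasional explicit completions and clock
# ticks, and a final tick at the horizon.
random_events <- function(study, seed, n_participants = 3, horizon = 10000) {
  set.seed(seed)
  iv <- study$interventions[[1]]
  item_ids <- unlist(lapply(iv$modules, function(m)
    vapply(m$items, function(it) it$id, "")))
  mod_ids <- vapply(iv$modules, function(m) m$id, "")
  rows <- list()
  enr <- integer(0)
  for (p in seq_len(n_participants)) {
    pid <- sprintf("p%d", p)
    enr[[pid]] <- sample(0:min(2000, horizon - 1), 1)
    rows[[length(rows) + 1]] <- data.frame(
      time = enr[[pid]], participant_id = pid, kind = "enroll",
      module_id = NA_character_, item_id = NA_character_,
      value = NA_character_, stringsAsFactors = FALSE)
  }
  n_ans <- sample(5:20, 1)
  for (k in seq_len(n_ans)) {
    pid <- sprintf("p%d", sample.int(n_participants, 1))
    rows[[length(rows) + 1]] <- data.frame(
      time = sample(enr[[pid]]:horizon, 1), participant_id = pid,
      kind = "answer", module_id = NA_character_,
      item_id = sample(item_ids, 1), value = as.character(sample(1:10, 1)),
      stringsAsFactors = FALSE)
  }
  if (runif(1) < 0.3) {
    pid <- sprintf("p%d", sample.int(n_participants, 1))
    rows[[length(rows) + 1]] <- data.frame(
      time = sample(enr[[pid]]:horizon, 1), participant_id = pid,
      kind = "module_completed", module_id = sample(mod_ids, 1),
      item_id = NA_character_, value = NA_character_, stringsAsFactors = FALSE)
  }
  rows[[length(rows) + 1]] <- data.frame(
    time = horizon, participant_id = "", kind = "clock_tick",
    module_id = NA_character_, item_id = NA_character_,
    value = NA_character_, stringsAsFactors = FALSE)
  ev <- do.call(rbind, rows)
  ev[order(ev$time, method = "radix"), , drop = FALSE]
}

# A random evaluation context for expression tests: a small cohort, three
# variables, mostly numeric answers with a sprinkling of non-numeric ones.
random_context <- function(seed, scope = "cohort") {
  set.seed(seed)
  n_ans <- sample(0:12, 1)
  vals <- as.character(sample(0:9, n_ans, replace = TRUE))
  if (n_ans > 0 && runif(1) < 0.2)
    vals[sample.int(n_ans, 1)] <- "not a number"
  answers <- data.frame(
    participant_id = sample(sprintf("p%d", 1:3), n_ans, replace = TRUE),
    time = sample.int(1000, n_ans, replace = TRUE),
    variable = sample(c("A", "B", "C"), n_ans, replace = TRUE),
    value = vals, stringsAsFactors = FALSE)
  # assignment counts always cover everyone who answered
  assigned <- length(unique(answers$participant_id)) + sample(0:2, 1)
  eval_context(assigned = assigned, answers = answers, scope = scope,
               participant = if (scope == "participant") "p1")
}

# Random expression AST over variables A, B, C. Exponents are small literals
# so magnitudes stay finite; division appears but may hit zero (both the
# implementation and the oracle must then raise).
random_ast <- function(depth = 3) {
  leaf <- function() {
    if (runif(1) < 0.6) list(kind = "num", value = as.numeric(sample(0:9, 1)))
    else list(kind = "var", name = sample(c("A", "B", "C"), 1))
  }
  build <- function(d) {
    if (d <= 0 || runif(1) < 0.25) return(structure(leaf(), class = "calc_expr"))
    r <- runif(1)
    node <- if (r < 0.12) {
      list(kind = "neg", operand = build(d - 1))
    } else if (r < 0.62) {
      op <- sample(c("+", "-", "*", "/"), 1, prob = c(0.35, 0.3, 0.25, 0.1))
      list(kind = "binop", op = op, lhs = build(d - 1), rhs = build(d - 1))
    } else if (r < 0.72) {
      list(kind = "binop", op = "^", lhs = build(d - 1),
           rhs = structure(list(kind = "num", value = as.numeric(sample(0:3, 1))),
                           class = "calc_expr"))
    } else {
      fn <- sample(c("SUM_ANS", "NUM_PS", "NUM_P_ANS", "MODE_ANS", "COUNT_ANS"), 1)
      args <- list(structure(list(kind = "var", name = sample(c("A", "B", "C"), 1)),
                             class = "calc_expr"))
      if (fn == "COUNT_ANS")
        args <- c(args, list(structure(list(kind = "num", value = as.numeric(sample(0:9, 1))),
                                       class = "calc_expr")))
      list(kind = "call", fn = fn, args = args)
    }
    structure(node, class = "calc_expr")
  }
  build(depth)
}
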