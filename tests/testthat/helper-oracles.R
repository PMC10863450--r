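# Independent oracles: a brute-force minute-by-minute lifecycle simulator
# (checks run_timeline) and a naive recursive expression evaluator (checks
# parse_expr/eval_expr). Deliberately written from the rule definitions,
# sharing no resolution code with the engine.

# --- minute-by-minute scheduler oracle ---------------------------------------

oracle_compare <- function(cmp, a, v) {
  an <- suppressWarnings(as.numeric(a))
  if (is.na(an)) {
    if (cmp == "eq") return(as.character(a) == as.character(v))
    if (cmp == "ne") return(as.character(a) != as.character(v))
    return(FALSE)
  }
  vn <- suppressWarnings(as.numeric(v))
  if (is.na(vn)) return(FALSE)
  switch(cmp, eq = an == vn, ne = an != vn, lt = an < vn, le = an <= vn,
         gt = an > vn, ge = an >= vn)
}

oracle_answer_match <- function(answers, item_id, cmp, value, from = 0, upto) {
  a <- answers[answers$item_id == item_id & answers$time <= upto &
                 answers$time >= from, , drop = FALSE]
  any(vapply(seq_len(nrow(a)), function(i)
    isTRUE(oracle_compare(cmp, a$value[[i]], value)), TRUE))
}

oracle_open_due <- function(rule, tl, t) {
  switch(rule$rule,
    relative_to_intervention_start = t >= tl$enroll + rule$offset_minutes,
    fixed_datetime = t >= max(rule$time, tl$enroll),
    relative_to_module_completion = {
      f <- tl$mods[[rule$ref_module_id]]$finished_at
      !is.na(f) && t >= f + rule$offset_minutes
    },
    on_module_not_finished = {
      ref <- tl$mods[[rule$ref_module_id]]
      if (is.na(ref$opened_at)) return(FALSE)
      check <- ref$opened_at + rule$check_offset_minutes
      t >= check && (is.na(ref$finished_at) || ref$finished_at > check)
    },
    answer_condition = oracle_answer_match(tl$ans, rule$ref_item_id,
                                           rule$comparator, rule$value, upto = t)
  )
}

oracle_close_due <- function(rule, inst, tl, t) {
  switch(rule$rule,
    fixed_date = t >= max(rule$time, inst$opened_at),
    relative_to_module_start = t >= inst$opened_at + rule$offset_minutes,
    answer_condition = oracle_answer_match(tl$ans, rule$ref_item_id,
                                           rule$comparator, rule$value,
                                           from = inst$opened_at, upto = t)
  )
}

# Replays events minute by minute from 0 to the last event time. Within a
# minute: due transitions from the pre-event state, then each event followed
# by the transitions it enabled. Due transitions are applied one at a time,
# scanning participants in sorted order and modules in study order.
oracle_run <- function(study, events) {
  iv <- study$interventions[[1]]
  mod_ids <- vapply(iv$modules, function(m) m$id, "")
  imap <- list()
  for (m in iv$modules) for (it in m$items) imap[[it$id]] <- m$id
  need <- lapply(iv$modules, function(m)
    vapply(Filter(function(it) it$item_type != "info_content", m$items),
           function(it) it$id, ""))
  names(need) <- mod_ids

  tls <- list()
  trans <- list()
  emit <- function(t, pid, mid, from, to)
    trans[[length(trans) + 1]] <<- data.frame(
      time = as.integer(t), participant_id = pid, module_id = mid,
      from = from, to = to, stringsAsFactors = FALSE)

  fixpoint <- function(t) {
    repeat {
      acted <- FALSE
      for (pid in sort(names(tls))) {
        tl <- tls[[pid]]
        for (mi in seq_along(iv$modules)) {
          m <- iv$modules[[mi]]
          inst <- tl$mods[[m$id]]
          if (inst$state == "LOCKED" && length(m$opening_rules) &&
              any(vapply(m$opening_rules, oracle_open_due, TRUE, tl = tl, t = t))) {
            tls[[pid]]$mods[[m$id]]$state <<- "OPEN"
            tls[[pid]]$mods[[m$id]]$opened_at <<- t
            emit(t, pid, m$id, "LOCKED", "OPEN")
            acted <- TRUE; break
          }
          if (inst$state == "OPEN" && length(m$closing_rules) &&
              any(vapply(m$closing_rules, oracle_close_due, TRUE,
                         inst = inst, tl = tl, t = t))) {
            tls[[pid]]$mods[[m$id]]$state <<- "CLOSED"
            tls[[pid]]$mods[[m$id]]$closed_at <<- t
            emit(t, pid, m$id, "OPEN", "CLOSED")
            acted <- TRUE; break
          }
        }
        if (acted) break
      }
      if (!acted) return(invisible())
    }
  }

  apply_event <- function(ev, t) {
    kind <- ev$kind; pid <- ev$participant_id
    if (kind == "enroll") {
      mods <- lapply(mod_ids, function(mid)
        list(state = "LOCKED", opened_at = NA_integer_, finished_at = NA_integer_,
             closed_at = NA_integer_))
      names(mods) <- mod_ids
      tls[[pid]] <<- list(enroll = t, mods = mods,
                          ans = data.frame(time = integer(0), item_id = character(0),
                                           value = character(0), stringsAsFactors = FALSE))
    } else if (kind == "answer") {
      mid <- imap[[ev$item_id]]
      tl <- tls[[pid]]
      if (tl$mods[[mid]]$state == "OPEN") {
        tls[[pid]]$ans <<- rbind(tl$ans, data.frame(
          time = t, item_id = ev$item_id, value = ev$value, stringsAsFactors = FALSE))
        if (all(need[[mid]] %in% tls[[pid]]$ans$item_id)) {
          tls[[pid]]$mods[[mid]]$state <<- "COMPLETED"
          tls[[pid]]$mods[[mid]]$finished_at <<- t
          emit(t, pid, mid, "OPEN", "COMPLETED")
        }
      }
    } else if (kind == "module_completed") {
      mid <- ev$module_id
      tl <- tls[[pid]]
      if (tl$mods[[mid]]$state == "OPEN" && all(need[[mid]] %in% tl$ans$item_id)) {
        tls[[pid]]$mods[[mid]]$state <<- "COMPLETED"
        tls[[pid]]$mods[[mid]]$finished_at <<- t
        emit(t, pid, mid, "OPEN", "COMPLETED")
      }
    }
  }

  pri <- c(enroll = 0L, answer = 1L, module_completed = 2L, clock_tick = 3L)
  events <- events[order(events$time, pri[as.character(events$kind)],
                         method = "radix"), , drop = FALSE]
  t_max <- if (nrow(events)) max(events$time) else -1L
  for (t in seq_len(t_max + 1L) - 1L) {
    fixpoint(t)
    evs <- events[events$time == t, , drop = FALSE]
    for (i in seq_len(nrow(evs))) {
      apply_event(as.list(evs[i, ]), t)
      fixpoint(t)
    }
  }
  out <- if (length(trans)) do.call(rbind, trans) else
    data.frame(time = integer(0), participant_id = character(0),
               module_id = character(0), from = character(0),
               to = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# --- naive expression oracle -------------------------------------------------

# Fully independent recursive evaluator. Returns list(status, value) where
# status is "ok", "undefined" or "error".
oracle_eval <- function(ast, ctx) {
  undef <- list(status = "undefined", value = NA_real_)
  num_rows <- function(variable, pid = NULL) {
    a <- ctx$answers[ctx$answers$variable == variable, , drop = FALSE]
    if (!is.null(pid)) a <- a[a$participant_id == pid, , drop = FALSE]
    v <- suppressWarnings(as.numeric(a$value))
    list(values = v[!is.na(v)], pids = a$participant_id[!is.na(v)],
         times = a$time[!is.na(v)])
  }
  go <- function(n) {
    if (n$kind == "num") return(list(status = "ok", value = n$value))
    if (n$kind == "var") {
      if (ctx$scope != "participant") return(undef)
      r <- num_rows(n$name, ctx$participant)
      if (!length(r$values)) return(undef)
      # most recent answer; ties broken by input order (later row wins)
      latest <- which(r$times == max(r$times))
      return(list(status = "ok", value = r$values[[latest[length(latest)]]]))
    }
    if (n$kind == "neg") {
      v <- go(n$operand)
      if (v$status != "ok") return(v)
      return(list(status = "ok", value = -v$value))
    }
    if (n$kind == "binop") {
      l <- go(n$lhs); if (l$status != "ok") return(l)
      r <- go(n$rhs); if (r$status != "ok") return(r)
      if (n$op == "/" && r$value == 0) return(list(status = "error", value = NA_real_))
      v <- switch(n$op, "+" = l$value + r$value, "-" = l$value - r$value,
                  "*" = l$value * r$value, "/" = l$value / r$value,
                  "^" = l$value ^ r$value)
      return(list(status = "ok", value = v))
    }
    if (n$kind == "call") {
      variable <- n$args[[1]]$name
      r <- num_rows(variable)
      if (n$fn == "SUM_ANS") return(list(status = "ok", value = sum(r$values)))
      if (n$fn == "NUM_PS") return(list(status = "ok", value = ctx$assigned))
      if (n$fn == "NUM_P_ANS")
        return(list(status = "ok", value = length(unique(r$pids))))
      if (n$fn == "MODE_ANS") {
        if (!length(r$values)) return(undef)
        freq <- sapply(split(r$values, r$values), length)
        winners <- names(freq)[freq == max(freq)]
        v <- if (length(winners) == 1) as.numeric(winners) else mean(r$values)
        return(list(status = "ok", value = v))
      }
      if (n$fn == "COUNT_ANS") {
        tv <- go(n$args[[2]])
        if (tv$status != "ok") return(tv)
        return(list(status = "ok", value = sum(r$values == tv$value)))
      }
    }
    stop("oracle: unknown node")
  }
  go(ast)
}

# run eval_expr and classify its outcome the same way
impl_eval_outcome <- function(ast, ctx) {
  out <- tryCatch(eval_expr(ast, ctx), error = function(e) e)
  if (inherits(out, "error")) list(status = "error", value = NA_real_)
  else if (is.na(out)) list(status = "undefined", value = NA_real_)
  else list(status = "ok", value = out)
}

# latest-answer helper used by several tests as a direct mean oracle
oracle_mean_answers <- function(ctx, variable, pid) {
  a <- ctx$answers[ctx$answers$variable == variable &
                     ctx$answers$participant_id == pid, , drop = FALSE]
  v <- suppressWarnings(as.numeric(a$value))
  v <- v[!is.na(v)]
  if (!length(v)) NA_real_ else mean(v)
}
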