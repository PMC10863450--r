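# Per-participant module lifecycle state machine.
#
# States: LOCKED -> OPEN -> {COMPLETED, CLOSED}; COMPLETED and CLOSED are
# terminal. The engine is event-driven but transition times are the times at
# which rules actually fire (not the times of the events that reveal them),
# so a replay is indistinguishable from a minute-by-minute simulation.
# Multiple opening rules on a module combine as OR (earliest firing wins);
# likewise for closing rules.
#
# Within one minute the engine applies, in order: (1) rule-driven transitions
# already due from the pre-event state, (2) the events of that minute, and
# (3) rule-driven transitions the events enabled (including cascades). Hence
# a close due at minute t beats an answer arriving at minute t.

MODULE_STATES <- c("LOCKED", "OPEN", "COMPLETED", "CLOSED")

new_instance <- function(participant_id, module_id) {
  list(participant_id = participant_id, module_id = module_id,
       state = "LOCKED", opened_at = NA_integer_, finished_at = NA_integer_,
       closed_at = NA_integer_)
}

new_timeline <- function(participant_id, intervention_id, enrollment_time, iv) {
  instances <- lapply(iv$modules, function(m) new_instance(participant_id, m$id))
  names(instances) <- vapply(iv$modules, function(m) m$id, "")
  list(participant_id = participant_id, intervention_id = intervention_id,
       enrollment_time = enrollment_time, instances = instances,
       answers = data.frame(time = integer(0), item_id = character(0),
                            value = character(0), stringsAsFactors = FALSE))
}

empty_transitions <- function() {
  data.frame(time = integer(0), participant_id = character(0),
             module_id = character(0), from = character(0), to = character(0),
             stringsAsFactors = FALSE)
}

#' Resolve the firing time of an opening rule
#'
#' Returns the earliest time (at or after enrollment) at which the rule fires
#' for this participant, or `NA` if it cannot yet be determined from the
#' timeline. `open_if_not_finished` needs the current clock: before the check
#' time has been reached the outcome is still open.
#'
#' @param rule An opening rule (see [opening_rules]).
#' @param timeline A participant timeline (from [run_timeline()] internals).
#' @param now Current engine time in minutes.
#' @return Firing time in minutes, or `NA`.
#' @export
resolve_open_time <- function(rule, timeline, now) {
  enr <- timeline$enrollment_time
  t <- switch(rule$rule,
    relative_to_intervention_start = enr + rule$offset_minutes,
    fixed_datetime = rule$time,
    relative_to_module_completion = {
      ref <- timeline$instances[[rule$ref_module_id]]
      if (is.null(ref)) stop("dangling module reference: ", rule$ref_module_id, call. = FALSE)
      if (is.na(ref$finished_at)) NA_integer_ else ref$finished_at + rule$offset_minutes
    },
    on_module_not_finished = {
      ref <- timeline$instances[[rule$ref_module_id]]
      if (is.null(ref)) stop("dangling module reference: ", rule$ref_module_id, call. = FALSE)
      if (is.na(ref$opened_at)) NA_integer_
      else {
        f <- ref$opened_at + rule$check_offset_minutes
        finished_by_f <- !is.na(ref$finished_at) && ref$finished_at <= f
        if (finished_by_f) NA_integer_           # completed in time: never fires
        else if (!is.na(ref$finished_at) || now >= f) f
        else NA_integer_                          # outcome unknown until f
      }
    },
    answer_condition = {
      a <- timeline$answers[timeline$answers$item_id == rule$ref_item_id, , drop = FALSE]
      hit <- NA_integer_
      for (i in seq_len(nrow(a))) {
        ok <- tryCatch(compare_values(rule$comparator, coerce_answer(a$value[[i]]), rule$value),
                       error = function(e) FALSE)
        if (isTRUE(ok)) { hit <- a$time[[i]]; break }
      }
      hit
    },
    stop("unknown opening rule: ", rule$rule, call. = FALSE)
  )
  if (is.na(t)) NA_integer_ else max(as.integer(t), enr)
}

#' Resolve the closing time of a closing rule
#'
#' Returns the time at which the rule closes an open module instance, or
#' `NA` if undetermined. A fixed close date earlier than the open time
#' degenerates to closing at the instant the module opened.
#'
#' @param rule A closing rule (see [closing_rules]).
#' @param instance The module instance (must be OPEN).
#' @param timeline The participant timeline.
#' @return Closing time in minutes, or `NA`.
#' @export
resolve_close_time <- function(rule, instance, timeline) {
  stopifnot(instance$state == "OPEN")
  op <- instance$opened_at
  t <- switch(rule$rule,
    fixed_date = rule$time,
    relative_to_module_start = op + rule$offset_minutes,
    answer_condition = {
      a <- timeline$answers[timeline$answers$item_id == rule$ref_item_id &
                              timeline$answers$time >= op, , drop = FALSE]
      hit <- NA_integer_
      for (i in seq_len(nrow(a))) {
        ok <- tryCatch(compare_values(rule$comparator, coerce_answer(a$value[[i]]), rule$value),
                       error = function(e) FALSE)
        if (isTRUE(ok)) { hit <- a$time[[i]]; break }
      }
      hit
    },
    stop("unknown closing rule: ", rule$rule, call. = FALSE)
  )
  if (is.na(t)) NA_integer_ else max(as.integer(t), op)
}

coerce_answer <- function(v) {
  num <- suppressWarnings(as.numeric(v))
  if (is.na(num)) as.character(v) else num
}

# earliest pending rule-driven transition for one participant, or NULL
pending_for <- function(tl, iv, now) {
  best <- NULL
  for (mi in seq_along(iv$modules)) {
    m <- iv$modules[[mi]]
    inst <- tl$instances[[m$id]]
    if (inst$state == "LOCKED" && length(m$opening_rules)) {
      ts <- vapply(m$opening_rules, resolve_open_time, 0L, timeline = tl, now = now)
      ts <- ts[!is.na(ts)]
      if (length(ts) && min(ts) <= now) {
        cand <- list(time = min(ts), module_index = mi, module_id = m$id, kind = 0L)
        if (is.null(best) || cand$time < best$time ||
            (cand$time == best$time && cand$module_index < best$module_index))
          best <- cand
      }
    } else if (inst$state == "OPEN" && length(m$closing_rules)) {
      ts <- vapply(m$closing_rules, resolve_close_time, 0L, instance = inst, timeline = tl)
      ts <- ts[!is.na(ts)]
      if (length(ts) && min(ts) <= now) {
        cand <- list(time = min(ts), module_index = mi, module_id = m$id, kind = 1L)
        if (is.null(best) || cand$time < best$time ||
            (cand$time == best$time && cand$module_index < best$module_index))
          best <- cand
      }
    }
  }
  best
}

# earliest rule-driven transition that would fire at or before `upto`, given
# current knowledge, or NA; used by the simulator to advance its clock to the
# next opening/closing instead of jumping straight to the next event
next_pending_time <- function(study, timelines, upto) {
  best <- NA_integer_
  for (pid in names(timelines) %||% character(0)) {
    tl <- timelines[[pid]]
    iv <- find_intervention(study, tl$intervention_id)
    cand <- pending_for(tl, iv, upto)
    if (!is.null(cand) && (is.na(best) || cand$time < best)) best <- cand$time
  }
  best
}

# apply all rule-driven transitions due at or before `now`, chronologically;
# ties broken by participant id, then module order in the study, opens before
# closes of the same module at the same minute (the close only becomes
# pending once the open is applied)
advance_timelines <- function(study, timelines, now, emit) {
  repeat {
    best <- NULL; best_pid <- NULL
    for (pid in sort(names(timelines) %||% character(0), method = "radix")) {
      tl <- timelines[[pid]]
      iv <- find_intervention(study, tl$intervention_id)
      cand <- pending_for(tl, iv, now)
      if (!is.null(cand) &&
          (is.null(best) || cand$time < best$time ||
           (cand$time == best$time && best_pid > pid) ||
           (cand$time == best$time && best_pid == pid &&
              cand$module_index < best$module_index))) {
        best <- cand; best_pid <- pid
      }
    }
    if (is.null(best)) return(timelines)
    inst <- timelines[[best_pid]]$instances[[best$module_id]]
    if (best$kind == 0L) {
      inst$state <- "OPEN"; inst$opened_at <- best$time
      emit(best$time, best_pid, best$module_id, "LOCKED", "OPEN")
    } else {
      inst$state <- "CLOSED"; inst$closed_at <- best$time
      emit(best$time, best_pid, best$module_id, "OPEN", "CLOSED")
    }
    timelines[[best_pid]]$instances[[best$module_id]] <- inst
  }
}

module_complete <- function(module, tl) {
  need <- vapply(answerable_items(module), function(it) it$id, "")
  all(need %in% tl$answers$item_id)
}

#' Apply one event to the cohort state
#'
#' Folds one event into the per-participant timelines: first applies every
#' rule-driven transition already due at the event time, then the event
#' itself, then any transitions the event enabled. Answers addressed to a
#' module that is not OPEN at that minute are rejected without state change
#' (the count is returned as attribute `rejected` on the transitions).
#'
#' @param study A validated [study_definition()].
#' @param timelines Named list of participant timelines (may be empty).
#' @param event One-row data frame or list with fields `time`,
#'   `participant_id`, `kind` (`enroll`, `answer`, `module_completed`,
#'   `clock_tick`), `module_id`, `item_id`, `value`. For `enroll`, `value`
#'   optionally names the intervention (default: first intervention).
#' @return List with `timelines` (updated) and `transitions` (data frame of
#'   the transitions this event produced, in deterministic order).
#' @export
step <- function(study, timelines, event) {
  time <- as.integer(event$time)
  last <- attr(timelines, "engine_time") %||% -1L
  if (time < last)
    stop("out-of-order event: time ", time, " after engine time ", last, call. = FALSE)

  trans <- list()
  emit <- function(time, pid, mid, from, to)
    trans[[length(trans) + 1]] <<- data.frame(
      time = as.integer(time), participant_id = pid, module_id = mid,
      from = from, to = to, stringsAsFactors = FALSE)
  rejected <- 0L

  timelines <- advance_timelines(study, timelines, time, emit)

  kind <- as.character(event$kind)
  pid <- as.character(event$participant_id)
  if (kind == "enroll") {
    if (!is.null(timelines[[pid]]))
      stop("participant ", pid, " already enrolled", call. = FALSE)
    iv_id <- event$value
    if (is.null(iv_id) || is.na(iv_id) || !nzchar(iv_id))
      iv_id <- study$interventions[[1]]$id
    iv <- find_intervention(study, as.character(iv_id))
    timelines[[pid]] <- new_timeline(pid, iv$id, time, iv)
  } else if (kind == "answer") {
    tl <- timelines[[pid]]
    if (is.null(tl)) stop("answer from unenrolled participant ", pid, call. = FALSE)
    iv <- find_intervention(study, tl$intervention_id)
    imap <- item_module_map(iv)
    mid <- imap[[as.character(event$item_id)]]
    if (is.null(mid)) stop("unknown item: ", event$item_id, call. = FALSE)
    inst <- tl$instances[[mid]]
    if (inst$state == "OPEN") {
      tl$answers <- rbind(tl$answers, data.frame(
        time = time, item_id = as.character(event$item_id),
        value = as.character(event$value), stringsAsFactors = FALSE))
      timelines[[pid]] <- tl
      mod <- iv$modules[[which(vapply(iv$modules, function(m) m$id, "") == mid)]]
      if (module_complete(mod, tl)) {
        inst$state <- "COMPLETED"; inst$finished_at <- time
        timelines[[pid]]$instances[[mid]] <- inst
        emit(time, pid, mid, "OPEN", "COMPLETED")
      }
    } else {
      rejected <- rejected + 1L
    }
  } else if (kind == "module_completed") {
    tl <- timelines[[pid]]
    if (is.null(tl)) stop("event for unenrolled participant ", pid, call. = FALSE)
    mid <- as.character(event$module_id)
    inst <- tl$instances[[mid]]
    if (is.null(inst)) stop("unknown module: ", mid, call. = FALSE)
    iv <- find_intervention(study, tl$intervention_id)
    mod <- iv$modules[[which(vapply(iv$modules, function(m) m$id, "") == mid)]]
    if (inst$state == "OPEN" && module_complete(mod, tl)) {
      inst$state <- "COMPLETED"; inst$finished_at <- time
      timelines[[pid]]$instances[[mid]] <- inst
      emit(time, pid, mid, "OPEN", "COMPLETED")
    } else {
      rejected <- rejected + 1L
    }
  } else if (kind != "clock_tick") {
    stop("unknown event kind: ", kind, call. = FALSE)
  }

  timelines <- advance_timelines(study, timelines, time, emit)
  attr(timelines, "engine_time") <- time

  transitions <- if (length(trans)) do.call(rbind, trans) else empty_transitions()
  attr(transitions, "rejected") <- rejected
  list(timelines = timelines, transitions = transitions)
}

EVENT_KIND_PRIORITY <- c(enroll = 0L, answer = 1L, module_completed = 2L,
                         clock_tick = 3L)

#' Replay an event timeline through the state machine
#'
#' Folds [step()] over a sorted event log and returns the final per-participant
#' timelines together with the ordered list of all module transitions.
#' Replaying the same events always yields the identical transition list.
#' Events must be non-decreasing in time; ties within a minute are applied
#' in kind order `enroll < answer < module_completed < clock_tick`, then
#' input order.
#'
#' @param study A validated [study_definition()].
#' @param events Data frame with columns `time`, `participant_id`, `kind`,
#'   `module_id`, `item_id`, `value` (see [read_events()]).
#' @return List with `timelines` and `transitions`.
#' @export
#' @examples
#' s <- example_study()
#' ev <- data.frame(time = 0, participant_id = "p1", kind = "enroll",
#'                  module_id = NA, item_id = NA, value = NA)
#' run_timeline(s, ev)$transitions
run_timeline <- function(study, events) {
  timelines <- structure(list(), engine_time = -1L)
  all_trans <- list()
  if (nrow(events)) {
    if (is.unsorted(events$time)) stop("events must be sorted by time", call. = FALSE)
    pri <- EVENT_KIND_PRIORITY[as.character(events$kind)]
    events <- events[order(events$time, pri, method = "radix"), , drop = FALSE]
    for (i in seq_len(nrow(events))) {
      res <- step(study, timelines, events[i, , drop = FALSE])
      timelines <- res$timelines
      if (nrow(res$transitions)) all_trans[[length(all_trans) + 1]] <- res$transitions
    }
  }
  transitions <- if (length(all_trans)) do.call(rbind, all_trans) else empty_transitions()
  rownames(transitions) <- NULL
  attr(transitions, "rejected") <- NULL
  list(timelines = timelines, transitions = transitions)
}
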