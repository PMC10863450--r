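# Notification dispatch planning. The planner turns module notification
# specs plus a simulated/replayed cohort into a dispatch plan (a data frame),
# decoupled from any push transport. Timing semantics:
#   * opening:  at open + interval (fixed or uniform random window), or at a
#     fixed date (clamped to the open time);
#   * reminder: at open + offset, offset >= 15 min (default 15);
#   * closing:  exactly 15 min before the predicted close time, which must be
#     predictable (fixed-date or relative-after-start closing rule).
# No notification is dispatched for an instance that completed or closed
# strictly before the dispatch time.

empty_plan <- function() {
  data.frame(dispatch_time = integer(0), participant_id = character(0),
             module_id = character(0), kind = character(0), text = character(0),
             stringsAsFactors = FALSE)
}

planning_violation <- function(pid, mid, code, message) {
  data.frame(participant_id = pid, module_id = mid, code = code,
             message = message, stringsAsFactors = FALSE)
}

#' Plan notification dispatch times for a cohort
#'
#' Computes every notification dispatch implied by the study's notification
#' specs and the cohort's module instances, then suppresses those whose
#' module instance had already completed or closed. Uniform-window opening
#' notifications are drawn with a stream derived from `(seed, participant,
#' module)`, so the plan is reproducible and independent of participant
#' iteration order.
#'
#' Closing notifications need a predictable close time; if the module's
#' closing rules cannot provide one, or the module stays open for less than
#' the 15-minute lead, the notification is dropped and recorded in the
#' `violations` attribute of the returned plan.
#'
#' @param study A validated [study_definition()].
#' @param timelines Participant timelines from [run_timeline()].
#' @param transitions Transition log from [run_timeline()].
#' @param seed Integer seed for random-interval triggers.
#' @return Data frame `dispatch_time, participant_id, module_id, kind, text`,
#'   sorted by dispatch time, with attribute `violations`.
#' @export
plan_notifications <- function(study, timelines, transitions, seed = 1L) {
  rows <- list(); viols <- list()
  for (pid in sort(names(timelines) %||% character(0), method = "radix")) {
    tl <- timelines[[pid]]
    iv <- find_intervention(study, tl$intervention_id)
    for (m in iv$modules) {
      inst <- tl$instances[[m$id]]
      if (is.na(inst$opened_at) || !length(m$notifications)) next
      open <- inst$opened_at
      close_pred <- predicted_close_time(m, inst)
      for (spec in m$notifications) {
        dt <- switch(spec$kind,
          opening = {
            trig <- spec$trigger
            if (trig$type == "fixed_datetime") max(trig$time, open)
            else if (!is.null(trig$window)) {
              rs <- derive_seed(seed, pid, m$id, "opening")
              open + local_draw(rs, trig$window[[1]], trig$window[[2]])
            } else open + trig$offset_minutes
          },
          reminder = open + spec$trigger$offset_minutes,
          closing = {
            if (is.na(close_pred)) {
              viols[[length(viols) + 1]] <- planning_violation(
                pid, m$id, "CLOSE_TIME_UNRESOLVABLE",
                "closing notification requested but no predictable close time")
              next
            }
            if (close_pred - open < CLOSING_LEAD_MINUTES) {
              viols[[length(viols) + 1]] <- planning_violation(
                pid, m$id, "CLOSING_LEAD_UNSATISFIABLE",
                sprintf("module open for %d min; cannot dispatch %d min before close",
                        close_pred - open, CLOSING_LEAD_MINUTES))
              next
            }
            close_pred - CLOSING_LEAD_MINUTES
          })
        rows[[length(rows) + 1]] <- data.frame(
          dispatch_time = as.integer(dt), participant_id = pid,
          module_id = m$id, kind = spec$kind, text = spec$text,
          stringsAsFactors = FALSE)
      }
    }
  }
  plan <- if (length(rows)) do.call(rbind, rows) else empty_plan()
  plan <- suppress_on_terminal(plan, transitions)
  plan <- plan[order(plan$dispatch_time, plan$participant_id, plan$module_id,
                     plan$kind, method = "radix"), , drop = FALSE]
  rownames(plan) <- NULL
  attr(plan, "violations") <- if (length(viols)) do.call(rbind, viols)
  else planning_violation(character(0), character(0), character(0), character(0))
  plan
}

# earliest close time computable without knowing future answers
predicted_close_time <- function(module, inst) {
  ts <- vapply(module$closing_rules, function(r) {
    switch(r$rule,
      fixed_date = max(as.integer(r$time), inst$opened_at),
      relative_to_module_start = inst$opened_at + as.integer(r$offset_minutes),
      NA_integer_)
  }, 0L)
  ts <- ts[!is.na(ts)]
  if (length(ts)) min(ts) else NA_integer_
}

# one uniform integer draw on [lo, hi] under a local seed, leaving the
# global RNG state untouched
local_draw <- function(seed, lo, hi) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  as.integer(lo + sample.int(hi - lo + 1L, 1L) - 1L)
}

#' Suppress notifications for terminated module instances
#'
#' Removes every planned notification whose module instance reached
#' COMPLETED or CLOSED strictly before the dispatch time: a participant who
#' already finished (or lost) a module is not nagged about it.
#'
#' @param plan A notification plan data frame.
#' @param transitions Transition log the plan was built against.
#' @return The filtered plan.
#' @export
suppress_on_terminal <- function(plan, transitions) {
  if (!nrow(plan)) return(plan)
  term <- transitions[transitions$to %in% c("COMPLETED", "CLOSED"), , drop = FALSE]
  keep <- vapply(seq_len(nrow(plan)), function(i) {
    hit <- term$participant_id == plan$participant_id[[i]] &
      term$module_id == plan$module_id[[i]] &
      term$time < plan$dispatch_time[[i]]
    !any(hit)
  }, TRUE)
  plan[keep, , drop = FALSE]
}
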