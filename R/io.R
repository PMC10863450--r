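# Plain-CSV interchange for event logs, transition logs, notification plans
# and biomarker sample streams, plus the long-format response export.

EVENT_COLS <- c("time", "participant_id", "kind", "module_id", "item_id", "value")

#' Read / write an event log CSV
#'
#' Event logs use the columns
#' `time,participant_id,kind,module_id,item_id,value`; unused fields are
#' empty. `read_events` restores the column types [run_timeline()] expects.
#'
#' @param path File path.
#' @param events Event log data frame.
#' @return `read_events`: the event data frame.
#' @name event_io
#' @export
read_events <- function(path) {
  ev <- utils::read.csv(path, colClasses = c(
    time = "integer", participant_id = "character", kind = "character",
    module_id = "character", item_id = "character", value = "character"))
  stopifnot(identical(names(ev), EVENT_COLS))
  ev
}

#' @rdname event_io
#' @export
write_events <- function(events, path) {
  utils::write.csv(events[, EVENT_COLS], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write biomarker sample CSVs
#'
#' Samples use the columns `participant_id,kind,value,start,end,source`.
#'
#' @param path File path.
#' @param samples Sample data frame.
#' @name sample_io
#' @export
read_biomarker_samples <- function(path) {
  utils::read.csv(path, colClasses = c(
    participant_id = "character", kind = "character", value = "numeric",
    start = "integer", end = "integer", source = "character"))
}

#' @rdname sample_io
#' @export
write_biomarker_samples <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Export responses in long format
#'
#' One row per recorded answer:
#' `study_code,intervention_id,participant_id,module_id,item_id,variable,value,answered_at,module_state`.
#' `module_state` is the instance's final state, so answers preserved from a
#' module that closed before completion are visibly flagged by
#' `module_state == "CLOSED"`.
#'
#' @param study The [study_definition()] the cohort ran against.
#' @param timelines Participant timelines from [run_timeline()] or
#'   [simulate_cohort()].
#' @return Long-format data frame, ordered by participant, time, item.
#' @export
export_responses <- function(study, timelines) {
  rows <- list()
  for (pid in sort(names(timelines) %||% character(0), method = "radix")) {
    tl <- timelines[[pid]]
    iv <- find_intervention(study, tl$intervention_id)
    imap <- item_module_map(iv)
    vmap <- list()
    for (m in iv$modules) for (it in m$items)
      vmap[[it$id]] <- it$variable %||% NA_character_
    a <- tl$answers
    for (i in seq_len(nrow(a))) {
      mid <- imap[[a$item_id[[i]]]]
      rows[[length(rows) + 1]] <- data.frame(
        study_code = study$study_code, intervention_id = iv$id,
        participant_id = pid, module_id = mid, item_id = a$item_id[[i]],
        variable = vmap[[a$item_id[[i]]]], value = a$value[[i]],
        answered_at = a$time[[i]],
        module_state = tl$instances[[mid]]$state,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(study_code = character(0), intervention_id = character(0),
               participant_id = character(0), module_id = character(0),
               item_id = character(0), variable = character(0),
               value = character(0), answered_at = integer(0),
               module_state = character(0), stringsAsFactors = FALSE)
}

#' Answer history from simulated timelines, for the expression evaluator
#'
#' Flattens recorded answers into the long `participant_id,time,variable,value`
#' format [eval_context()] consumes, keeping only answers to items that bind
#' a variable.
#'
#' @inheritParams export_responses
#' @return Answer data frame.
#' @export
answers_from_timelines <- function(study, timelines) {
  long <- export_responses(study, timelines)
  long <- long[!is.na(long$variable), , drop = FALSE]
  data.frame(participant_id = long$participant_id, time = long$answered_at,
             variable = long$variable, value = long$value,
             stringsAsFactors = FALSE)
}
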