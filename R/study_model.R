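# Study definition data model: a study holds one or more interventions
# (versions of a coaching programme); each intervention holds ordered modules
# (chapters); each module holds items plus its opening/closing timing rules
# and notification specs. All clock quantities are integer minutes from a
# study-local epoch (timezone-naive).

new_node <- function(x, class) structure(x, class = c(class, "emaflow_node"))

as_minutes <- function(x, what) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x != trunc(x))
    stop(what, " must be a single integer number of minutes", call. = FALSE)
  as.integer(x)
}

check_token <- function(x, what) {
  if (length(x) != 1 || !is.character(x) || is.na(x) || !nzchar(x))
    stop(what, " must be a non-empty string", call. = FALSE)
  x
}

#' Construct a study definition
#'
#' The root of the declarative study tree. Participants join a study using its
#' short `study_code`; each intervention is a version of the programme and is
#' either auto-assigned to enrolling participants or used as a waitlist.
#'
#' @param study_code Short alphanumeric token identifying the study.
#' @param title Human-readable study title.
#' @param interventions List of [intervention()] objects (at least one).
#' @return An object of class `study_definition`.
#' @seealso [load_study()], [save_study()], [validate_study()]
#' @export
#' @examples
#' s <- study_definition("DEMO1", "Demo study", list(
#'   intervention("arm_a", "Arm A", list(
#'     study_module("m1", "Check-in",
#'       items = list(item("q1", "slider", "How do you feel?", variable = "mood")),
#'       opening_rules = list(open_after_enrollment(0)))
#'   ))
#' ))
#' validate_study(s)
study_definition <- function(study_code, title, interventions) {
  new_node(list(
    schema_version = 1L,
    study_code = check_token(study_code, "study_code"),
    title = check_token(title, "title"),
    interventions = interventions
  ), "study_definition")
}

#' Construct an intervention (one version of the programme)
#'
#' @param id Token unique within the study.
#' @param name Display name.
#' @param modules Ordered list of [study_module()] objects.
#' @param assignment_policy `"auto_assign"` (enrolling participants are placed
#'   into the intervention) or `"waitlist"` (participants are parked and see no
#'   modules).
#' @param calc_variables List of [calc_variable()] definitions available to
#'   feedback text and timing rules.
#' @export
intervention <- function(id, name, modules, assignment_policy = "auto_assign",
                         calc_variables = list()) {
  assignment_policy <- match.arg(assignment_policy, c("auto_assign", "waitlist"))
  new_node(list(
    id = check_token(id, "intervention id"),
    name = check_token(name, "intervention name"),
    assignment_policy = assignment_policy,
    calc_variables = calc_variables,
    modules = modules
  ), "intervention")
}

#' Construct a module (the unit of scheduling, notification and completion)
#'
#' @param id Token unique within its intervention.
#' @param title Display title.
#' @param items Ordered list of [item()] objects.
#' @param opening_rules List of opening rules; several rules combine as OR and
#'   the earliest firing rule wins. A module with no opening rules stays locked.
#' @param closing_rules List of closing rules (OR, earliest wins). A module
#'   with no closing rules stays open until completed.
#' @param notifications List of notification specs; at most one `opening` and
#'   one `closing` notification are allowed per module.
#' @export
study_module <- function(id, title, items, opening_rules = list(),
                         closing_rules = list(), notifications = list()) {
  new_node(list(
    id = check_token(id, "module id"),
    title = check_token(title, "module title"),
    items = items,
    opening_rules = opening_rules,
    closing_rules = closing_rules,
    notifications = notifications
  ), "study_module")
}

#' Construct a module item
#'
#' @param id Token unique within its intervention.
#' @param item_type One of [ITEM_TYPES]. `info_content` items take no answer
#'   and may not carry a variable.
#' @param prompt Question or content text.
#' @param variable Optional variable name the answer is bound to; must be
#'   unique within the intervention. Required if expressions are to reference
#'   the answer.
#' @param options Optional list of `list(label =, code =)` pairs for coded
#'   choice items; answers are the numeric codes.
#' @param media_ref Optional opaque media reference.
#' @export
item <- function(id, item_type, prompt, variable = NULL, options = NULL,
                 media_ref = NULL) {
  if (!item_type %in% ITEM_TYPES)
    stop("unknown item_type: '", item_type, "'", call. = FALSE)
  if (!is.null(options)) {
    options <- lapply(options, function(o) {
      if (is.null(o$label) || is.null(o$code) || !is.numeric(o$code))
        stop("each option needs a label and a numeric code", call. = FALSE)
      list(label = as.character(o$label), code = as.numeric(o$code))
    })
  }
  new_node(list(
    id = check_token(id, "item id"),
    item_type = item_type,
    prompt = check_token(prompt, "prompt"),
    variable = if (is.null(variable)) NULL else check_token(variable, "variable"),
    options = options,
    media_ref = media_ref
  ), "item")
}

#' @export
print.study_definition <- function(x, ...) {
  n_mod <- sum(vapply(x$interventions, function(iv) length(iv$modules), 0L))
  n_item <- sum(vapply(x$interventions, function(iv)
    sum(vapply(iv$modules, function(m) length(m$items), 0L)), 0L))
  cat(sprintf("<study_definition> %s: \"%s\"\n", x$study_code, x$title))
  cat(sprintf("  %d intervention(s), %d module(s), %d item(s)\n",
              length(x$interventions), n_mod, n_item))
  invisible(x)
}

# Opening rules ----------------------------------------------------------------

#' Opening rules: when a locked module becomes available
#'
#' Five rule kinds control module opening. All fire relative to a
#' participant's own timeline; several rules on one module combine as OR and
#' the earliest firing rule determines the open time.
#'
#' * `open_after_enrollment(offset)` — a relative time after the participant
#'   started the intervention.
#' * `open_after_completion(ref, offset)` — a relative time after the
#'   participant completed module `ref`.
#' * `open_if_not_finished(ref, check_offset)` — fires at `ref`'s open time
#'   plus `check_offset` if `ref` has not been completed by then (e.g. to
#'   branch non-responders into a nudge module). If `ref` never opens, the
#'   rule never fires.
#' * `open_on_answer(ref_item, comparator, value)` — fires at the timestamp of
#'   the first answer to `ref_item` satisfying the condition.
#' * `open_at(time)` — a fixed date and time; clamped to the participant's
#'   enrollment if earlier.
#'
#' @param offset_minutes,check_offset_minutes Non-negative integer minutes.
#' @param ref_module_id,ref_item_id Referenced module/item id in the same
#'   intervention.
#' @param comparator One of `eq, ne, lt, le, gt, ge` (text answers: `eq, ne`).
#' @param value Numeric or text value to compare the answer against.
#' @param time Absolute study time in minutes.
#' @return A tagged opening-rule object.
#' @name opening_rules
NULL

#' @rdname opening_rules
#' @export
open_after_enrollment <- function(offset_minutes) {
  off <- as_minutes(offset_minutes, "offset_minutes")
  if (off < 0) stop("offset_minutes must be >= 0", call. = FALSE)
  new_node(list(rule = "relative_to_intervention_start", offset_minutes = off),
           "opening_rule")
}

#' @rdname opening_rules
#' @export
open_after_completion <- function(ref_module_id, offset_minutes) {
  off <- as_minutes(offset_minutes, "offset_minutes")
  if (off < 0) stop("offset_minutes must be >= 0", call. = FALSE)
  new_node(list(rule = "relative_to_module_completion",
                ref_module_id = check_token(ref_module_id, "ref_module_id"),
                offset_minutes = off), "opening_rule")
}

#' @rdname opening_rules
#' @export
open_if_not_finished <- function(ref_module_id, check_offset_minutes) {
  off <- as_minutes(check_offset_minutes, "check_offset_minutes")
  if (off < 0) stop("check_offset_minutes must be >= 0", call. = FALSE)
  new_node(list(rule = "on_module_not_finished",
                ref_module_id = check_token(ref_module_id, "ref_module_id"),
                check_offset_minutes = off), "opening_rule")
}

#' @rdname opening_rules
#' @export
open_on_answer <- function(ref_item_id, comparator, value) {
  comparator <- match.arg(comparator, COMPARATORS)
  if (is.numeric(value)) value <- as.numeric(value)
  new_node(list(rule = "answer_condition",
                ref_item_id = check_token(ref_item_id, "ref_item_id"),
                comparator = comparator, value = value), "opening_rule")
}

#' @rdname opening_rules
#' @export
open_at <- function(time) {
  new_node(list(rule = "fixed_datetime", time = as_minutes(time, "time")),
           "opening_rule")
}

# Closing rules ----------------------------------------------------------------

#' Closing rules: when an open module is withdrawn
#'
#' Three rule kinds close a module that a participant has not completed:
#' on a satisfying answer to an item, on a fixed date, or a relative time
#' after the module opened. Several rules combine as OR (earliest wins).
#' A fixed close date earlier than the open time closes the module the
#' instant it opens.
#'
#' @inheritParams opening_rules
#' @return A tagged closing-rule object.
#' @name closing_rules
NULL

#' @rdname closing_rules
#' @export
close_on_answer <- function(ref_item_id, comparator, value) {
  comparator <- match.arg(comparator, COMPARATORS)
  if (is.numeric(value)) value <- as.numeric(value)
  new_node(list(rule = "answer_condition",
                ref_item_id = check_token(ref_item_id, "ref_item_id"),
                comparator = comparator, value = value), "closing_rule")
}

#' @rdname closing_rules
#' @export
close_at <- function(time) {
  new_node(list(rule = "fixed_date", time = as_minutes(time, "time")),
           "closing_rule")
}

#' @rdname closing_rules
#' @export
close_after_open <- function(offset_minutes) {
  off <- as_minutes(offset_minutes, "offset_minutes")
  if (off <= 0) stop("offset_minutes must be > 0", call. = FALSE)
  new_node(list(rule = "relative_to_module_start", offset_minutes = off),
           "closing_rule")
}

# Notifications ----------------------------------------------------------------

#' Notification specifications
#'
#' Modules may announce themselves by push-style notifications. Three kinds
#' exist:
#'
#' * `notify_opening()` — sent when the module becomes available, either a
#'   fixed interval after open (`offset_minutes`), a uniform random interval
#'   (`window = c(lo, hi)` minutes after open), or at a fixed time (`at`).
#' * `notify_reminder()` — sent once the module has been available for at
#'   least 15 minutes (`offset_minutes >= 15`, default 15).
#' * `notify_closing()` — sent exactly 15 minutes before the module closes;
#'   only allowed on modules whose closing rules make the close time
#'   predictable (fixed date, or relative time after open).
#'
#' Notifications for module instances already completed or closed are never
#' dispatched.
#'
#' @param text Custom notification text.
#' @param offset_minutes Minutes after module open.
#' @param window Integer vector `c(lo, hi)`: uniform random dispatch window
#'   in minutes after open (mutually exclusive with `offset_minutes`/`at`).
#' @param at Fixed dispatch time in absolute minutes.
#' @return A notification spec object.
#' @name notifications_spec
NULL

#' @rdname notifications_spec
#' @export
notify_opening <- function(text = "Module available", offset_minutes = 0,
                           window = NULL, at = NULL) {
  trigger <- if (!is.null(at)) {
    list(type = "fixed_datetime", time = as_minutes(at, "at"))
  } else if (!is.null(window)) {
    lo <- as_minutes(window[[1]], "window lo"); hi <- as_minutes(window[[2]], "window hi")
    if (lo < 0 || hi < lo) stop("window must satisfy 0 <= lo <= hi", call. = FALSE)
    list(type = "interval_after_open", window = c(lo, hi))
  } else {
    off <- as_minutes(offset_minutes, "offset_minutes")
    if (off < 0) stop("offset_minutes must be >= 0", call. = FALSE)
    list(type = "interval_after_open", offset_minutes = off)
  }
  new_node(list(kind = "opening", trigger = trigger,
                text = check_token(text, "text")), "notification_spec")
}

#' @rdname notifications_spec
#' @export
notify_reminder <- function(text = "Reminder: module waiting",
                            offset_minutes = REMINDER_MIN_OFFSET) {
  off <- as_minutes(offset_minutes, "offset_minutes")
  new_node(list(kind = "reminder",
                trigger = list(type = "interval_after_open", offset_minutes = off),
                text = check_token(text, "text")), "notification_spec")
}

#' @rdname notifications_spec
#' @export
notify_closing <- function(text = "Module closing soon") {
  new_node(list(kind = "closing", trigger = list(type = "closing_lead"),
                text = check_token(text, "text")), "notification_spec")
}

#' Define a calculated variable
#'
#' A named expression over item variables and cohort aggregates, usable for
#' interactive feedback and timing rules. See [parse_expr()] for the language.
#'
#' @param name Variable name (unique within the intervention).
#' @param expression Expression source text.
#' @export
calc_variable <- function(name, expression) {
  new_node(list(name = check_token(name, "name"),
                expression = check_token(expression, "expression")),
           "calc_variable")
}

# Lookup helpers ---------------------------------------------------------------

find_intervention <- function(study, intervention_id) {
  for (iv in study$interventions) if (iv$id == intervention_id) return(iv)
  stop("unknown intervention: ", intervention_id, call. = FALSE)
}

# map item id -> module id within one intervention
item_module_map <- function(iv) {
  out <- character(0)
  for (m in iv$modules)
    for (it in m$items) out[[it$id]] <- m$id
  out
}

# items that require an answer for module completion
answerable_items <- function(module) {
  Filter(function(it) it$item_type != "info_content", module$items)
}

# TRUE if answers to this item are numeric (sliders, number inputs, coded
# choices); used to gate aggregation legality
item_is_numeric <- function(it) {
  it$item_type %in% NUMERIC_ITEM_TYPES ||
    (it$item_type %in% CODED_ITEM_TYPES && !is.null(it$options))
}
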