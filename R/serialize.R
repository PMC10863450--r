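# Canonical serialization of study definitions. One JSON schema
# (schema_version 1); YAML is accepted as an alternate surface syntax of the
# same schema, so a single strict loader validates both. Unknown fields are
# hard errors with the offending path, because study authors are typically
# not programmers and silent tolerance hides typos.

schema_err <- function(path, msg) {
  stop(sprintf("study schema error at %s: %s", path, msg), call. = FALSE)
}

check_fields <- function(x, path, required, optional = character(0)) {
  if (!is.list(x)) schema_err(path, "expected a mapping/object")
  nm <- names(x)
  if (is.null(nm) || any(!nzchar(nm))) schema_err(path, "expected named fields")
  unknown <- setdiff(nm, c(required, optional))
  if (length(unknown))
    schema_err(paste0(path, ".", unknown[[1]]), "unknown field")
  missing <- setdiff(required, nm)
  if (length(missing))
    schema_err(paste0(path, ".", missing[[1]]), "missing required field")
  invisible(x)
}

scalar_at <- function(x, path) {
  if (is.list(x) || length(x) != 1) schema_err(path, "expected a scalar")
  x
}

plain_to_opening_rule <- function(x, path) {
  if (is.null(x$rule)) schema_err(paste0(path, ".rule"), "missing required field")
  switch(as.character(x$rule),
    relative_to_intervention_start = {
      check_fields(x, path, c("rule", "offset_minutes"))
      open_after_enrollment(scalar_at(x$offset_minutes, paste0(path, ".offset_minutes")))
    },
    relative_to_module_completion = {
      check_fields(x, path, c("rule", "ref_module_id", "offset_minutes"))
      open_after_completion(x$ref_module_id, x$offset_minutes)
    },
    on_module_not_finished = {
      check_fields(x, path, c("rule", "ref_module_id", "check_offset_minutes"))
      open_if_not_finished(x$ref_module_id, x$check_offset_minutes)
    },
    answer_condition = {
      check_fields(x, path, c("rule", "ref_item_id", "comparator", "value"))
      if (!x$comparator %in% COMPARATORS)
        schema_err(paste0(path, ".comparator"), paste0("unknown comparator '", x$comparator, "'"))
      open_on_answer(x$ref_item_id, x$comparator, x$value)
    },
    fixed_datetime = {
      check_fields(x, path, c("rule", "time"))
      open_at(x$time)
    },
    schema_err(paste0(path, ".rule"), paste0("unknown opening rule '", x$rule, "'"))
  )
}

plain_to_closing_rule <- function(x, path) {
  if (is.null(x$rule)) schema_err(paste0(path, ".rule"), "missing required field")
  switch(as.character(x$rule),
    answer_condition = {
      check_fields(x, path, c("rule", "ref_item_id", "comparator", "value"))
      if (!x$comparator %in% COMPARATORS)
        schema_err(paste0(path, ".comparator"), paste0("unknown comparator '", x$comparator, "'"))
      close_on_answer(x$ref_item_id, x$comparator, x$value)
    },
    fixed_date = {
      check_fields(x, path, c("rule", "time"))
      close_at(x$time)
    },
    relative_to_module_start = {
      check_fields(x, path, c("rule", "offset_minutes"))
      close_after_open(x$offset_minutes)
    },
    schema_err(paste0(path, ".rule"), paste0("unknown closing rule '", x$rule, "'"))
  )
}

plain_to_notification <- function(x, path) {
  check_fields(x, path, c("kind", "trigger"), "text")
  kind <- as.character(scalar_at(x$kind, paste0(path, ".kind")))
  if (!kind %in% c("opening", "reminder", "closing"))
    schema_err(paste0(path, ".kind"), paste0("unknown notification kind '", kind, "'"))
  trig <- x$trigger
  tpath <- paste0(path, ".trigger")
  text <- x$text %||% switch(kind, opening = "Module available",
                             reminder = "Reminder: module waiting",
                             closing = "Module closing soon")
  if (kind == "closing") {
    check_fields(trig, tpath, "type")
    if (trig$type != "closing_lead")
      schema_err(paste0(tpath, ".type"), "closing notifications use trigger type 'closing_lead'")
    return(notify_closing(text))
  }
  check_fields(trig, tpath, "type", c("offset_minutes", "window", "time"))
  type <- as.character(trig$type)
  if (type == "fixed_datetime") {
    if (kind != "opening")
      schema_err(tpath, "fixed_datetime triggers are only valid for opening notifications")
    return(notify_opening(text, at = trig$time))
  }
  if (type != "interval_after_open")
    schema_err(paste0(tpath, ".type"), paste0("unknown trigger type '", type, "'"))
  if (kind == "reminder")
    return(notify_reminder(text, offset_minutes = trig$offset_minutes %||% REMINDER_MIN_OFFSET))
  if (!is.null(trig$window))
    notify_opening(text, window = unlist(trig$window))
  else
    notify_opening(text, offset_minutes = trig$offset_minutes %||% 0)
}

plain_to_item <- function(x, path) {
  check_fields(x, path, c("id", "item_type", "prompt"),
               c("variable", "options", "media_ref"))
  if (!x$item_type %in% ITEM_TYPES)
    schema_err(paste0(path, ".item_type"),
               paste0("unknown item_type '", x$item_type, "'"))
  opts <- if (is.null(x$options)) NULL else lapply(seq_along(x$options), function(i) {
    o <- check_fields(x$options[[i]], sprintf("%s.options[%d]", path, i),
                      c("label", "code"))
    list(label = o$label, code = o$code)
  })
  item(x$id, x$item_type, x$prompt, variable = x$variable, options = opts,
       media_ref = x$media_ref)
}

plain_to_module <- function(x, path) {
  check_fields(x, path, c("id", "title", "items"),
               c("opening_rules", "closing_rules", "notifications"))
  idx <- function(field, f) {
    xs <- x[[field]] %||% list()
    lapply(seq_along(xs), function(i) f(xs[[i]], sprintf("%s.%s[%d]", path, field, i)))
  }
  study_module(x$id, x$title,
               items = idx("items", plain_to_item),
               opening_rules = idx("opening_rules", plain_to_opening_rule),
               closing_rules = idx("closing_rules", plain_to_closing_rule),
               notifications = idx("notifications", plain_to_notification))
}

plain_to_intervention <- function(x, path) {
  check_fields(x, path, c("id", "name", "modules"),
               c("assignment_policy", "calc_variables"))
  pol <- x$assignment_policy %||% "auto_assign"
  if (!pol %in% c("auto_assign", "waitlist"))
    schema_err(paste0(path, ".assignment_policy"),
               paste0("unknown assignment_policy '", pol, "'"))
  cvs <- x$calc_variables %||% list()
  cvs <- lapply(seq_along(cvs), function(i) {
    cv <- check_fields(cvs[[i]], sprintf("%s.calc_variables[%d]", path, i),
                       c("name", "expression"))
    calc_variable(cv$name, cv$expression)
  })
  mods <- lapply(seq_along(x$modules), function(i)
    plain_to_module(x$modules[[i]], sprintf("%s.modules[%d]", path, i)))
  intervention(x$id, x$name, mods, assignment_policy = pol, calc_variables = cvs)
}

plain_to_study <- function(x) {
  check_fields(x, "$", c("study_code", "title", "interventions"), "schema_version")
  sv <- x$schema_version %||% 1L
  if (!identical(as.integer(sv), 1L))
    schema_err("$.schema_version", paste0("unsupported schema_version ", sv))
  ivs <- lapply(seq_along(x$interventions), function(i)
    plain_to_intervention(x$interventions[[i]], sprintf("interventions[%d]", i)))
  study_definition(x$study_code, x$title, ivs)
}

# strip classes down to plain lists in canonical key order (the constructors
# already build fields in canonical order, so unclass suffices)
to_plain <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, to_plain)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' Load a study definition from JSON or YAML
#'
#' Reads a study document, validates it strictly against the schema
#' (`schema_version: 1`) and returns a fully typed [study_definition()] with
#' all defaults filled. Unknown fields, unknown item types and malformed
#' rules raise errors naming the offending field path. Loading then saving
#' is a structural identity.
#'
#' @param path Path to a `.study.json` / `.study.yaml` file, or a literal
#'   JSON/YAML string.
#' @param format `"auto"` (by file extension, else sniffed), `"json"` or
#'   `"yaml"`.
#' @return A `study_definition` object.
#' @export
load_study <- function(path, format = c("auto", "json", "yaml")) {
  format <- match.arg(format)
  is_file <- length(path) == 1 && !grepl("[\n{]", path) && file.exists(path)
  text <- if (is_file) paste(readLines(path, warn = FALSE), collapse = "\n") else path
  if (format == "auto") {
    format <- if (is_file && grepl("\\.ya?ml$", path, ignore.case = TRUE)) "yaml"
    else if (is_file && grepl("\\.json$", path, ignore.case = TRUE)) "json"
    else if (grepl("^\\s*\\{", text)) "json" else "yaml"
  }
  plain <- if (format == "json") {
    jsonlite::fromJSON(text, simplifyVector = FALSE)
  } else {
    yaml::yaml.load(text)
  }
  plain_to_study(plain)
}

#' Serialize a study definition to canonical JSON
#'
#' Writes the canonical JSON form (fixed key order, schema_version 1). The
#' output is byte-stable: serializing the same study twice yields identical
#' text, and `load_study(save_study(s))` is structurally equal to `s`.
#'
#' @param study A [study_definition()].
#' @param path Optional file path; if `NULL` the JSON text is returned.
#' @return The JSON string, invisibly if written to a file.
#' @export
save_study <- function(study, path = NULL) {
  stopifnot(inherits(study, "study_definition"))
  json <- jsonlite::toJSON(to_plain(study), auto_unbox = TRUE, pretty = TRUE,
                           digits = NA, null = "null")
  json <- paste0(as.character(json), "\n")
  if (is.null(path)) return(json)
  writeLines(sub("\n$", "", json), path)
  invisible(json)
}
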