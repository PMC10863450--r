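# Structural validator. Violations are data, not exceptions: the scheduler
# and evaluator may assume a study with zero violations never produces
# dangling-reference errors downstream.

violation <- function(code, path, message) {
  data.frame(code = code, path = path, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a study definition
#'
#' Checks every structural invariant of the study tree and returns the
#' violations as a data frame (empty when the study is clean), stable-ordered
#' by path. Checks include: unique intervention/module/item ids and variable
#' names, resolvable rule references, offset sign constraints, comparator
#' legality for text items, notification cardinality (at most one opening and
#' one closing notification per module), closing-notification compatibility
#' (only with a fixed-date or relative-after-start closing rule), reminder
#' offsets of at least 15 minutes, no variables on `info_content` items,
#' parseable calculated-variable expressions, and numeric aggregation applied
#' only to variables of numeric items.
#'
#' @param study A [study_definition()].
#' @return Data frame with columns `code`, `path`, `message`; zero rows iff
#'   the study is valid.
#' @export
validate_study <- function(study) {
  v <- list()
  add <- function(code, path, message) v[[length(v) + 1]] <<- violation(code, path, message)

  if (!nzchar(study$study_code %||% ""))
    add("EMPTY_STUDY_CODE", "study_code", "study_code must be non-empty")
  if (length(study$interventions) == 0)
    add("NO_INTERVENTIONS", "interventions", "study must contain at least one intervention")

  iv_ids <- vapply(study$interventions, function(iv) iv$id, "")
  for (d in unique(iv_ids[duplicated(iv_ids)]))
    add("DUP_INTERVENTION_ID", "interventions",
        sprintf("intervention id '%s' is not unique", d))

  for (i in seq_along(study$interventions)) {
    iv <- study$interventions[[i]]
    ipath <- sprintf("interventions[%d]", i)
    mod_ids <- vapply(iv$modules, function(m) m$id, "")
    for (d in unique(mod_ids[duplicated(mod_ids)]))
      add("DUP_MODULE_ID", paste0(ipath, ".modules"),
          sprintf("module id '%s' is not unique within intervention '%s'", d, iv$id))

    items <- unlist(lapply(iv$modules, function(m) m$items), recursive = FALSE)
    item_ids <- vapply(items, function(it) it$id, "")
    for (d in unique(item_ids[duplicated(item_ids)]))
      add("DUP_ITEM_ID", paste0(ipath, ".modules"),
          sprintf("item id '%s' is not unique within intervention '%s'", d, iv$id))

    vars <- vapply(items, function(it) it$variable %||% NA_character_, "")
    vars <- vars[!is.na(vars)]
    for (d in unique(vars[duplicated(vars)]))
      add("DUP_VARIABLE", paste0(ipath, ".modules"),
          sprintf("variable '%s' bound by more than one item", d))

    item_by_id <- stats::setNames(items, item_ids)
    numeric_vars <- vapply(items, function(it)
      if (!is.null(it$variable) && item_is_numeric(it)) it$variable else NA_character_, "")
    numeric_vars <- numeric_vars[!is.na(numeric_vars)]

    check_answer_cond <- function(rule, rpath) {
      it <- item_by_id[[rule$ref_item_id]]
      if (is.null(it)) {
        add("DANGLING_REF", rpath,
            sprintf("item '%s' not found in intervention '%s'", rule$ref_item_id, iv$id))
        return(invisible())
      }
      if (it$item_type == "info_content")
        add("DANGLING_REF", rpath,
            sprintf("item '%s' is info_content and takes no answers", rule$ref_item_id))
      if (!item_is_numeric(it) && !rule$comparator %in% c("eq", "ne"))
        add("BAD_COMPARATOR", rpath,
            sprintf("comparator '%s' requires a numeric item; '%s' yields text answers",
                    rule$comparator, rule$ref_item_id))
    }

    for (j in seq_along(iv$modules)) {
      m <- iv$modules[[j]]
      mpath <- sprintf("%s.modules[%d]", ipath, j)

      for (k in seq_along(m$items)) {
        it <- m$items[[k]]
        if (it$item_type == "info_content" && !is.null(it$variable))
          add("INFO_ITEM_VARIABLE", sprintf("%s.items[%d]", mpath, k),
              sprintf("info_content item '%s' cannot bind a variable", it$id))
      }

      for (k in seq_along(m$opening_rules)) {
        r <- m$opening_rules[[k]]
        rpath <- sprintf("%s.opening_rules[%d]", mpath, k)
        if (r$rule %in% c("relative_to_module_completion", "on_module_not_finished")) {
          if (!r$ref_module_id %in% mod_ids)
            add("DANGLING_REF", rpath,
                sprintf("module '%s' not found in intervention '%s'", r$ref_module_id, iv$id))
        } else if (r$rule == "answer_condition") {
          check_answer_cond(r, rpath)
        }
      }

      for (k in seq_along(m$closing_rules)) {
        r <- m$closing_rules[[k]]
        if (r$rule == "answer_condition")
          check_answer_cond(r, sprintf("%s.closing_rules[%d]", mpath, k))
      }

      kinds <- vapply(m$notifications, function(n) n$kind, "")
      npath <- paste0(mpath, ".notifications")
      if (sum(kinds == "opening") > 1)
        add("NOTIF_CARDINALITY", npath,
            "only one opening notification can be created per module")
      if (sum(kinds == "closing") > 1)
        add("NOTIF_CARDINALITY", npath,
            "only one closing notification can be created per module")
      if (any(kinds == "closing")) {
        compat <- any(vapply(m$closing_rules, function(r)
          r$rule %in% c("fixed_date", "relative_to_module_start"), TRUE))
        if (!compat)
          add("CLOSING_NOTIF_INCOMPATIBLE", npath,
              paste("a closing notification requires a fixed-date or",
                    "relative-after-start closing rule"))
      }
      for (k in seq_along(m$notifications)) {
        n <- m$notifications[[k]]
        if (n$kind == "reminder" &&
            (n$trigger$offset_minutes %||% 0) < REMINDER_MIN_OFFSET)
          add("REMINDER_OFFSET", sprintf("%s[%d]", npath, k),
              sprintf("reminders are sent after the module is available for at least %d min",
                      REMINDER_MIN_OFFSET))
      }
    }

    cv_names <- vapply(iv$calc_variables, function(cv) cv$name, "")
    for (d in unique(cv_names[duplicated(cv_names)]))
      add("DUP_CALC_VARIABLE", paste0(ipath, ".calc_variables"),
          sprintf("calculated variable '%s' defined more than once", d))
    for (k in seq_along(iv$calc_variables)) {
      cv <- iv$calc_variables[[k]]
      cpath <- sprintf("%s.calc_variables[%d]", ipath, k)
      ast <- tryCatch(parse_expr(cv$expression), error = function(e) e)
      if (inherits(ast, "error")) {
        add("EXPR_SYNTAX", cpath,
            sprintf("expression for '%s' does not parse: %s", cv$name, conditionMessage(ast)))
      } else {
        for (vn in expr_agg_variables(ast)) {
          if (!vn %in% c(vars, cv_names)) {
            add("DANGLING_REF", cpath,
                sprintf("aggregated variable '%s' is not bound by any item", vn))
          } else if (vn %in% vars && !vn %in% c(numeric_vars, cv_names)) {
            add("AGG_NON_NUMERIC", cpath,
                sprintf("variable '%s' is bound by a non-numeric item; aggregation requires numeric answers", vn))
          }
        }
      }
    }
  }

  out <- if (length(v)) do.call(rbind, v)
  else violation(character(0), character(0), character(0))
  out[order(out$path, out$code, method = "radix"), , drop = FALSE]
}
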