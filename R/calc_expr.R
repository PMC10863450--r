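# Calculated-variables expression language. A small arithmetic DSL over item
# variables, extended with five cohort aggregation functions:
#
#   SUM_ANS(N)        sum of all recorded responses to variable N
#   NUM_PS(N)         number of participants assigned to the intervention
#   NUM_P_ANS(N)      number of participants who answered N
#   MODE_ANS(N)       most frequent response; mean of all responses if no
#                     unique mode exists
#   COUNT_ANS(N, v)   number of responses to N equal to v
#
# Implemented as a hand-written tokenizer + recursive-descent parser because
# the language's semantics (undefined propagation, cohort scope, the
# aggregation functions) are the point, not an embedding of R's own parser.

AGG_FUNCTIONS <- c(SUM_ANS = 1L, NUM_PS = 1L, NUM_P_ANS = 1L, MODE_ANS = 1L,
                   COUNT_ANS = 2L)

# --- tokenizer ---------------------------------------------------------------

tokenize_expr <- function(source) {
  chars <- strsplit(source, "")[[1]]
  n <- length(chars)
  toks <- list(); i <- 1
  push <- function(type, value, pos) toks[[length(toks) + 1]] <<- list(type = type, value = value, pos = pos)
  while (i <= n) {
    c0 <- chars[[i]]
    if (grepl("^\\s$", c0)) { i <- i + 1; next }
    if (c0 %in% c("+", "-", "*", "/", "^", "(", ")", ",")) {
      push(c0, c0, i); i <- i + 1; next
    }
    if (grepl("[0-9.]", c0)) {
      j <- i
      while (j <= n && grepl("[0-9.]", chars[[j]])) j <- j + 1
      num <- paste(chars[i:(j - 1)], collapse = "")
      val <- suppressWarnings(as.numeric(num))
      if (is.na(val)) stop("invalid number '", num, "' at position ", i, call. = FALSE)
      push("num", val, i); i <- j; next
    }
    if (grepl("[A-Za-z_]", c0)) {
      j <- i
      while (j <= n && grepl("[A-Za-z0-9_]", chars[[j]])) j <- j + 1
      push("ident", paste(chars[i:(j - 1)], collapse = ""), i); i <- j; next
    }
    stop("unexpected character '", c0, "' at position ", i, call. = FALSE)
  }
  push("eof", "", n + 1)
  toks
}

# --- parser ------------------------------------------------------------------

#' Parse a calculated-variable expression
#'
#' Grammar: binary `+ - * / ^` with standard precedence (`*`/`/` bind tighter
#' than `+`/`-`; `^` binds tightest and is right-associative), unary minus,
#' parentheses, numeric literals, variable references, and the five
#' aggregation functions `SUM_ANS(N)`, `NUM_PS(N)`, `NUM_P_ANS(N)`,
#' `MODE_ANS(N)`, `COUNT_ANS(N, v)` (the second argument of `COUNT_ANS` is a
#' literal or a variable reference). Arity is fixed and checked at parse time.
#'
#' @param source Expression source text.
#' @return An AST of class `calc_expr`.
#' @seealso [eval_expr()]
#' @export
#' @examples
#' ast <- parse_expr("1 + 2 * 3")
#' eval_expr(ast, eval_context(assigned = 0))
parse_expr <- function(source) {
  if (!is.character(source) || length(source) != 1 || !nzchar(trimws(source)))
    stop("expression source must be a non-empty string", call. = FALSE)
  toks <- tokenize_expr(source)
  pos <- 1L
  peek <- function() toks[[pos]]
  advance <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }
  expect <- function(type) {
    t <- peek()
    if (t$type != type)
      stop("syntax error at position ", t$pos, ": expected '", type,
           "', found '", if (t$type == "eof") "end of input" else t$value, "'",
           call. = FALSE)
    advance()
  }

  node <- function(kind, ...) structure(list(kind = kind, ...), class = "calc_expr")

  parse_sum <- function() {
    lhs <- parse_product()
    while (peek()$type %in% c("+", "-")) {
      op <- advance()$type
      lhs <- node("binop", op = op, lhs = lhs, rhs = parse_product())
    }
    lhs
  }
  parse_product <- function() {
    lhs <- parse_unary()
    while (peek()$type %in% c("*", "/")) {
      op <- advance()$type
      lhs <- node("binop", op = op, lhs = lhs, rhs = parse_unary())
    }
    lhs
  }
  parse_unary <- function() {
    if (peek()$type == "-") { advance(); return(node("neg", operand = parse_unary())) }
    parse_power()
  }
  parse_power <- function() {
    base <- parse_primary()
    if (peek()$type == "^") {
      advance()
      # right-associative; exponent may carry its own unary minus
      return(node("binop", op = "^", lhs = base, rhs = parse_unary()))
    }
    base
  }
  parse_primary <- function() {
    t <- peek()
    if (t$type == "num") { advance(); return(node("num", value = t$value)) }
    if (t$type == "(") {
      advance(); e <- parse_sum(); expect(")"); return(e)
    }
    if (t$type == "ident") {
      advance()
      if (peek()$type == "(") {
        if (!t$value %in% names(AGG_FUNCTIONS))
          stop("unknown function '", t$value, "' at position ", t$pos, call. = FALSE)
        advance()
        args <- list(parse_arg())
        while (peek()$type == ",") { advance(); args[[length(args) + 1]] <- parse_arg() }
        expect(")")
        arity <- AGG_FUNCTIONS[[t$value]]
        if (length(args) != arity)
          stop(t$value, " takes ", arity, " argument", if (arity > 1) "s",
               ", got ", length(args), call. = FALSE)
        if (args[[1]]$kind != "var")
          stop("first argument of ", t$value, " must be a variable name", call. = FALSE)
        return(node("call", fn = t$value, args = args))
      }
      return(node("var", name = t$value))
    }
    stop("syntax error at position ", t$pos, ": unexpected '",
         if (t$type == "eof") "end of input" else t$value, "'", call. = FALSE)
  }
  # function arguments: a variable name, a (possibly negated) literal, or for
  # generality a parenthesised expression
  parse_arg <- function() parse_sum()

  ast <- parse_sum()
  expect("eof")
  ast
}

#' @export
print.calc_expr <- function(x, ...) {
  cat("<calc_expr> ", deparse_expr(x), "\n", sep = "")
  invisible(x)
}

#' Render an AST back to source text
#'
#' Produces a fully parenthesized rendering, so that
#' `parse_expr(deparse_expr(ast))` reproduces `ast` regardless of precedence.
#'
#' @param ast A `calc_expr` AST.
#' @return Source string.
#' @export
deparse_expr <- function(ast) {
  switch(ast$kind,
    num = format(ast$value, scientific = FALSE),
    var = ast$name,
    neg = paste0("(-", deparse_expr(ast$operand), ")"),
    binop = paste0("(", deparse_expr(ast$lhs), " ", ast$op, " ",
                   deparse_expr(ast$rhs), ")"),
    call = paste0(ast$fn, "(", paste(vapply(ast$args, deparse_expr, ""),
                                     collapse = ", "), ")"),
    stop("unknown node kind: ", ast$kind)
  )
}

# variable names referenced inside aggregation-function calls (for the
# validator's numeric-aggregation check)
expr_agg_variables <- function(ast) {
  switch(ast$kind,
    num = character(0),
    var = character(0),
    neg = expr_agg_variables(ast$operand),
    binop = c(expr_agg_variables(ast$lhs), expr_agg_variables(ast$rhs)),
    call = unique(c(ast$args[[1]]$name,
                    unlist(lapply(ast$args[-1], expr_agg_variables)))),
    character(0)
  )
}

# --- evaluation context ------------------------------------------------------

#' Build an evaluation context
#'
#' The data the expression evaluator consumes: the number of participants
#' assigned to the intervention (the cohort denominator used by `NUM_PS`),
#' the per-variable answer histories, and the evaluation scope. Plain
#' variable references resolve to the scoped participant's most recent
#' answer; aggregation functions always evaluate over the whole cohort.
#'
#' @param assigned Number of participants assigned to the intervention.
#' @param answers Data frame with columns `participant_id`, `time`,
#'   `variable`, `value` (long format; `value` may be character, non-numeric
#'   values are excluded from aggregation and the exclusion counted).
#' @param scope `"cohort"` or `"participant"`.
#' @param participant Participant id, required when `scope = "participant"`.
#' @return An object of class `eval_context`.
#' @export
eval_context <- function(assigned, answers = NULL,
                         scope = c("cohort", "participant"),
                         participant = NULL) {
  scope <- match.arg(scope)
  if (is.null(answers))
    answers <- data.frame(participant_id = character(0), time = integer(0),
                          variable = character(0), value = character(0),
                          stringsAsFactors = FALSE)
  stopifnot(all(c("participant_id", "time", "variable", "value") %in% names(answers)))
  if (scope == "participant" && is.null(participant))
    stop("participant scope requires a participant id", call. = FALSE)
  if (length(assigned) != 1 || is.na(assigned) || assigned < 0)
    stop("assigned must be a single count >= 0", call. = FALSE)
  structure(list(assigned = as.numeric(assigned), answers = answers,
                 scope = scope, participant = participant),
            class = "eval_context")
}

# numeric answers for one variable, in time order; non-numeric values dropped
# (dropped count attached as an attribute)
numeric_answers <- function(ctx, variable, participant = NULL) {
  a <- ctx$answers[ctx$answers$variable == variable, , drop = FALSE]
  if (!is.null(participant))
    a <- a[a$participant_id == participant, , drop = FALSE]
  a <- a[order(a$time, method = "radix"), , drop = FALSE]
  vals <- suppressWarnings(as.numeric(a$value))
  keep <- !is.na(vals)
  structure(list(values = vals[keep], participants = a$participant_id[keep]),
            excluded = sum(!keep))
}

# --- evaluator ---------------------------------------------------------------

UNDEFINED <- structure(NA_real_, class = "emaflow_undefined")

is_undefined <- function(x) inherits(x, "emaflow_undefined") || is.na(x)

#' Evaluate a calculated-variable expression
#'
#' Deterministic evaluation of a parsed expression against a context.
#' Aggregation functions evaluate in cohort scope over all recorded numeric
#' answers; a plain variable reference resolves to the scoped participant's
#' most recent answer. An expression whose value cannot be determined (a
#' referenced variable with no answer, `MODE_ANS` over zero answers) is
#' *undefined*, returned as `NA`; undefinedness propagates through every
#' operator and function, so scheduling rules gated on an undefined
#' expression simply do not fire. Division by zero with defined operands is
#' an error, not `NaN`.
#'
#' @param ast A `calc_expr` from [parse_expr()], or source text (parsed on
#'   the fly).
#' @param ctx An [eval_context()].
#' @return A number, or `NA` when the expression is undefined.
#' @export
#' @examples
#' ans <- data.frame(participant_id = c("p1", "p2"), time = c(10, 20),
#'                   variable = "N", value = c("4", "6"))
#' ctx <- eval_context(assigned = 3, answers = ans)
#' eval_expr("NUM_PS(N)", ctx)     # 3 participants assigned
#' eval_expr("NUM_P_ANS(N)", ctx)  # 2 answered
#' eval_expr("SUM_ANS(N)", ctx)    # 10
eval_expr <- function(ast, ctx) {
  if (is.character(ast)) ast <- parse_expr(ast)
  stopifnot(inherits(ast, "calc_expr"), inherits(ctx, "eval_context"))
  v <- eval_node(ast, ctx)
  if (is_undefined(v)) NA_real_ else v
}

eval_node <- function(ast, ctx) {
  switch(ast$kind,
    num = ast$value,
    var = {
      if (ctx$scope != "participant") return(UNDEFINED)
      na <- numeric_answers(ctx, ast$name, ctx$participant)
      if (length(na$values) == 0) UNDEFINED else na$values[[length(na$values)]]
    },
    neg = {
      v <- eval_node(ast$operand, ctx)
      if (is_undefined(v)) UNDEFINED else -v
    },
    binop = {
      # left-to-right with short-circuit: an undefined operand makes the
      # whole expression undefined before the other side is evaluated, so a
      # division-by-zero error is only raised when actually reached
      l <- eval_node(ast$lhs, ctx)
      if (is_undefined(l)) return(UNDEFINED)
      r <- eval_node(ast$rhs, ctx)
      if (is_undefined(r)) return(UNDEFINED)
      switch(ast$op,
        "+" = l + r, "-" = l - r, "*" = l * r,
        "/" = if (r == 0) stop("division by zero", call. = FALSE) else l / r,
        "^" = l ^ r)
    },
    call = eval_call(ast, ctx),
    stop("unknown node kind: ", ast$kind)
  )
}

eval_call <- function(ast, ctx) {
  variable <- ast$args[[1]]$name
  na <- numeric_answers(ctx, variable)
  switch(ast$fn,
    SUM_ANS = sum(na$values),
    NUM_PS = ctx$assigned,
    NUM_P_ANS = as.numeric(length(unique(na$participants))),
    MODE_ANS = {
      if (length(na$values) == 0) return(UNDEFINED)
      mode_or_mean(na$values)
    },
    COUNT_ANS = {
      v <- eval_node(ast$args[[2]], ctx)
      if (is_undefined(v)) return(UNDEFINED)
      as.numeric(sum(values_equal(na$values, v)))
    },
    stop("unknown function: ", ast$fn)
  )
}

# the most responded value; when the maximal frequency is shared by two or
# more distinct values there is no mode and the mean of all answers is
# returned instead
mode_or_mean <- function(values) {
  tab <- table(values)
  top <- max(tab)
  modes <- names(tab)[tab == top]
  if (length(modes) == 1) as.numeric(modes[[1]]) else mean(values)
}

# exact equality on integers; 1e-9 relative tolerance otherwise
values_equal <- function(values, target) {
  if (target == trunc(target) && all(values == trunc(values)))
    return(values == target)
  abs(values - target) <= 1e-9 * pmax(abs(values), abs(target), 1)
}

#' Mean of a participant's answers across daily module instances
#'
#' Convenience wrapper for the common "ask the same question for several
#' days, then feed back the average" pattern (e.g. a 3-day mood average).
#' Returns the arithmetic mean over the answers the participant actually
#' gave; days with no answer are skipped, and the result is undefined (`NA`)
#' when no answer exists at all.
#'
#' @param variable Variable name bound by the daily item.
#' @param ctx An [eval_context()] containing the answer history.
#' @param participant Participant id.
#' @return Mean of the available answers, or `NA`.
#' @export
three_day_average <- function(variable, ctx, participant) {
  na <- numeric_answers(ctx, variable, participant)
  if (length(na$values) == 0) return(NA_real_)
  mean(na$values)
}
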