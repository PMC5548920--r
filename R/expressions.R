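# Minimal arithmetic expression grammar for model definitions.
#
# Right-hand sides, output functions and initial-state expressions are plain
# arithmetic over declared state/parameter identifiers: + - * / ^ and
# parentheses.  Expressions are parsed with base R and the parse tree is
# walked to reject anything outside the grammar, so a model file cannot
# smuggle arbitrary code into the solver.

.ALLOWED_OPS <- c("+", "-", "*", "/", "^", "(")

#' Parse a model arithmetic expression
#'
#' Parses an arithmetic expression over declared identifiers, restricted to
#' the operators `+ - * / ^` and parentheses.
#'
#' @param text character scalar, the expression source.
#' @param allowed character vector of identifiers that may appear (state,
#'   parameter and time names).
#' @return an unevaluated R expression (language object).
#' @keywords internal
parse_model_expr <- function(text, allowed) {
  stopifnot(is.character(text), length(text) == 1L)
  ex <- tryCatch(str2lang(text), error = function(e) {
    stop("cannot parse expression '", text, "': ", conditionMessage(e),
         call. = FALSE)
  })
  check_expr_tree(ex, allowed, text)
  ex
}

check_expr_tree <- function(ex, allowed, text) {
  if (is.numeric(ex)) return(invisible(TRUE))
  if (is.name(ex)) {
    nm <- as.character(ex)
    if (!nm %in% allowed) {
      stop("unknown identifier '", nm, "' in expression '", text,
           "'; declared identifiers: ", paste(allowed, collapse = ", "),
           call. = FALSE)
    }
    return(invisible(TRUE))
  }
  if (is.call(ex)) {
    op <- as.character(ex[[1L]])
    if (!op %in% .ALLOWED_OPS) {
      stop("operator or function '", op, "' not allowed in expression '",
           text, "' (grammar: + - * / ^ and parentheses)", call. = FALSE)
    }
    for (i in seq_along(ex)[-1L]) check_expr_tree(ex[[i]], allowed, text)
    return(invisible(TRUE))
  }
  stop("unsupported token in expression '", text, "'", call. = FALSE)
}

# Symbolic partial derivative of a parsed expression; returns a language
# object (possibly the constant 0).
expr_deriv <- function(ex, name) stats::D(ex, name)
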