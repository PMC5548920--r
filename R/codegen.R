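# Build-time code generation for the ODE right-hand sides.
#
# Evaluating each rhs expression in a freshly built environment at every
# solver step dominates runtime for interpreted models.  Instead, each
# model is compiled once into a single R function that binds states and
# parameters by position and returns the derivative vector; the
# augmented sensitivity system likewise becomes one function in which
# only the structurally nonzero entries of df/dx and df/dtheta are
# assigned.  The symbolic derivative expressions themselves come from
# `stats::D` on the declared rhs.

dep1 <- function(ex) paste(deparse(ex), collapse = " ")

is_zero_expr <- function(ex) is.numeric(ex) && length(ex) == 1L && ex == 0

# function(t, y, p) -> derivative vector
compile_rhs_function <- function(state_names, param_names, rhs_exprs) {
  n <- length(state_names)
  lines <- c(
    sprintf("%s <- y[[%dL]]", state_names, seq_len(n)),
    sprintf("%s <- p[[%dL]]", param_names, seq_along(param_names)),
    sprintf("c(%s)", paste(vapply(rhs_exprs, dep1, character(1L)),
                           collapse = ", ")))
  f <- function(t, y, p) NULL
  body(f) <- str2lang(paste0("{", paste(lines, collapse = "\n"), "}"))
  compiler::cmpfun(f)
}

# function(t, y, p) for the augmented system: y = c(x, vec(S)),
# dS/dt = (df/dx) S + df/dtheta.
compile_aug_function <- function(state_names, param_names, rhs_exprs,
                                 dfdx, free) {
  n <- length(state_names)
  p <- length(free)
  lines <- c(
    sprintf("%s <- y[[%dL]]", state_names, seq_len(n)),
    sprintf("%s <- p[[%dL]]", param_names, seq_along(param_names)),
    sprintf("S <- matrix(y[-seq_len(%dL)], %dL, %dL)", n, n, p),
    sprintf("Jx <- matrix(0, %dL, %dL)", n, n),
    sprintf("Jp <- matrix(0, %dL, %dL)", n, p))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (!is_zero_expr(dfdx[[i, j]]))
      lines <- c(lines, sprintf("Jx[%dL, %dL] <- %s", i, j,
                                dep1(dfdx[[i, j]])))
  }
  for (i in seq_len(n)) for (k in seq_len(p)) {
    dd <- expr_deriv(rhs_exprs[[i]], free[k])
    if (!is_zero_expr(dd))
      lines <- c(lines, sprintf("Jp[%dL, %dL] <- %s", i, k, dep1(dd)))
  }
  lines <- c(lines,
             sprintf("dx <- c(%s)",
                     paste(vapply(rhs_exprs, dep1, character(1L)),
                           collapse = ", ")),
             "c(dx, Jx %*% S + Jp)")
  f <- function(t, y, p) NULL
  body(f) <- str2lang(paste0("{", paste(lines, collapse = "\n"), "}"))
  compiler::cmpfun(f)
}
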