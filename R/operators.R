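#' Operator vocabulary for expression trees
#'
#' The function-node vocabulary of the genetic-programming search:
#' four binary arithmetic operators and five unary transforms. Each
#' operator carries a domain guard; rows of data that violate a guard
#' (zero divisor, non-positive log argument, negative square-root
#' argument) or overflow past \code{1e300} are flagged invalid rather
#' than raising an error, so that domain filters and fitness penalties
#' can act on them.
#'
#' @format A named list; each element has fields \code{name},
#'   \code{arity} (1 or 2) and \code{fn}, the guarded vectorized
#'   implementation.
#' @examples
#' names(op_table())
#' op_table()[["ln"]]$arity
#' @export
op_table <- function() .OP_TABLE

# magnitude cap: anything beyond is treated as an invalid evaluation
.OVERFLOW_LIMIT <- 1e300

# clamp non-finite / overflowed values to NaN so invalidity propagates
# through later operations (exp(log(0)) must stay invalid, not become 0)
.guard <- function(v) {
  bad <- !is.finite(v) | abs(v) > .OVERFLOW_LIMIT
  if (any(bad)) v[bad] <- NaN
  v
}

s_add  <- function(a, b) .guard(a + b)
s_sub  <- function(a, b) .guard(a - b)
s_mul  <- function(a, b) .guard(a * b)
s_div  <- function(a, b) { r <- a / b; r[b == 0] <- NaN; .guard(r) }
s_sqrt <- function(a) { r <- suppressWarnings(sqrt(a)); r[a < 0] <- NaN; .guard(r) }
s_square <- function(a) .guard(a * a)
s_cube   <- function(a) .guard(a * a * a)
s_exp    <- function(a) .guard(exp(a))
s_ln     <- function(a) { r <- suppressWarnings(log(a)); r[a <= 0] <- NaN; .guard(r) }

.OP_TABLE <- list(
  "+"      = list(name = "+",      arity = 2L, fn = s_add),
  "-"      = list(name = "-",      arity = 2L, fn = s_sub),
  "*"      = list(name = "*",      arity = 2L, fn = s_mul),
  "/"      = list(name = "/",      arity = 2L, fn = s_div),
  "sqrt"   = list(name = "sqrt",   arity = 1L, fn = s_sqrt),
  "square" = list(name = "square", arity = 1L, fn = s_square),
  "cube"   = list(name = "cube",   arity = 1L, fn = s_cube),
  "exp"    = list(name = "exp",    arity = 1L, fn = s_exp),
  "ln"     = list(name = "ln",     arity = 1L, fn = s_ln)
)

#' Default operator-group sets for the nesting filter
#'
#' Groups of operators that must not be nested within one another on a
#' root-to-leaf path: \code{{sqrt}}, \code{{square, cube}},
#' \code{{ln, exp}}.
#'
#' @return A list of character vectors.
#' @export
default_f_groups <- function() {
  list(c("sqrt"), c("square", "cube"), c("ln", "exp"))
}
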