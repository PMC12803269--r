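#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a temporary RNG seed
#'
#' Seeds the random number generator, evaluates `expr`, and restores the
#' caller's RNG state afterwards.  All stochastic entry points in the package
#' funnel their draws through the current RNG stream, so wrapping a call in
#' `with_seed()` makes it reproducible without disturbing the session.
#'
#' @param seed Integer seed (NULL leaves the RNG untouched).
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Round-half-up (0.5 always rounds away from zero for non-negative x), unlike
# base round()'s round-half-even.  Used for masking budgets.
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_smiclm <- function(msg, class) {
  stop(structure(class = c(class, "smiclm_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
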