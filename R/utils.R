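#' Signal a classed tremorloop error
#'
#' All package errors carry a machine-readable condition class (e.g.
#' "role-missing", "rate-mismatch") so callers and tests can dispatch on the
#' failure mode rather than matching message text.
#'
#' @param class character scalar, the condition class.
#' @param msg human-readable message.
#' @param call. logical, include the call.
#' @keywords internal
tl_stop <- function(class, msg, call. = FALSE) {
  cond <- structure(
    class = c(class, "tremorloop_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  )
  stop(cond)
}

tl_warn <- function(class, msg) {
  cond <- structure(
    class = c(class, "tremorloop_warning", "warning", "condition"),
    list(message = msg, call = NULL)
  )
  warning(cond)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded generators do not
#' perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
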