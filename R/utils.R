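# Internal helpers: argument checking, seeded RNG scoping, logging.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals do not disturb the
#' caller's RNG stream. All stochastic stages of the pipeline derive their
#' seeds from one user-facing seed through this helper.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stage-specific 31-bit sub-seed from a master seed, so stages are
# decoupled: changing epochs in one stage never shifts another stage's stream.
derive_seed <- function(seed, tag) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

log_msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(format(Sys.time(), "[%H:%M:%S] "), ...)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Numerically stable mean binary cross-entropy from logits.
bce_with_logits <- function(logits, targets) {
  mean(pmax(logits, 0) - logits * targets + log1p(exp(-abs(logits))))
}
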