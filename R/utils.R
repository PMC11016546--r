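# Shared internal helpers: typed conditions, seeded evaluation.

#' @keywords internal
ssvepr_error <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(paste0("ssvepr_", class), "ssvepr_error")))
}

abort_format <- function(msg, ...) ssvepr_error("format_error", msg, ...)
abort_lead <- function(msg, ...) ssvepr_error("lead_error", msg, ...)
abort_bounds <- function(msg, ...) ssvepr_error("bounds_error", msg, ...)
abort_shape <- function(msg, ...) ssvepr_error("shape_error", msg, ...)
abort_valid <- function(msg, ...) ssvepr_error("validation_error", msg, ...)

#' Evaluate an expression under a fixed RNG seed, restoring the caller's RNG state
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of child seeds from a base seed, stable across R versions.
derive_seeds <- function(base_seed, n) {
  with_seed(base_seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sigmoid <- function(x) 1 / (1 + exp(-x))

elu <- function(x, alpha = 1) {
  neg <- which(x < 0)  # which() drops NAs so non-finite inputs pass through
  x[neg] <- alpha * expm1(x[neg])
  x
}

# y must be elu(x); derivative is 1 for x > 0 and y + alpha below.
elu_grad <- function(x, y, alpha = 1) {
  g <- x
  g[] <- 1
  neg <- which(x < 0)
  g[neg] <- y[neg] + alpha
  g
}
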