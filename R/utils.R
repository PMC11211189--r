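# Internal helpers: error conditions and seeded randomness.

# All package errors carry a subclass ("eproximetry_<what>") plus the
# umbrella class "eproximetry_error", so callers can catch either level.
abort <- function(message, class, ...) {
  stop(errorCondition(message, ..., class = c(class, "eproximetry_error")))
}

warn <- function(message, class) {
  warning(warningCondition(message, class = c(class, "eproximetry_warning")))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded simulations do not
#' perturb the global random stream. A `NULL` seed evaluates the expression
#' under the current stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    env <- globalenv()
    if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      old <- get(".Random.seed", envir = env)
      on.exit(assign(".Random.seed", old, envir = env), add = TRUE)
    } else {
      on.exit(
        if (exists(".Random.seed", envir = env, inherits = FALSE)) {
          rm(".Random.seed", envir = env)
        },
        add = TRUE
      )
    }
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic sub-seed for a named random substream. Keeps all randomness
# tied to one master seed while making the draws for one data type (growth,
# po2, spectra, ...) independent of whether another type is generated.
substream_seed <- function(seed, stream) {
  if (is.null(seed)) {
    return(NULL)
  }
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes)) %% 99991L
  (as.integer(seed) %% 1000003L) * 2011L + h * 31L
}

stopifnot_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name),
          "eproximetry_invalid_parameter")
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0", name), "eproximetry_invalid_parameter")
  }
  invisible(x)
}
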