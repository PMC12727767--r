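# Internal helpers shared across modules.

# canonical state order used everywhere (index 0, 1, 2)
.STATES <- c("FS", "NS", "HS")

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: `%s` %s", field, msg), call. = FALSE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so seeded helpers do not perturb an enclosing simulation.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Fold a coordinate into [0, w] by reflection at both walls; handles
# displacements of arbitrary magnitude (multiple bounces).
reflect_into <- function(x, w) {
  x <- x %% (2 * w)
  ifelse(x > w, 2 * w - x, x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
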