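# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the RNG seeded at `seed` and restores the caller's RNG
#' state afterwards, so seeded package operations never perturb user code.
#' A `NULL` seed evaluates `expr` under the current RNG state.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env) else
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

#' Derive a per-component seed from a single master seed
#'
#' A single user-facing seed fans out to independent component seeds
#' (data shuffling, noise draws, dropout, weight init) through a fixed
#' integer mixing function, keeping every stream reproducible while
#' decoupled. Results stay below 2^31 - 1.
#' @noRd
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  # multiplicative mixing in double precision, exact below 2^53
  v <- (as.numeric(seed) * 2654435761 + h * 40503 + 97) %% 2147483629
  as.integer(v + 1)
}

softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_gexmol <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "gexmol_error")))
}
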