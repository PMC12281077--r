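# Internal helpers: argument checking, deterministic sub-seeding, tiny hashing.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_painmod <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "painmod_error")))
}

check_finite_numeric <- function(x, name, len = NULL) {
  if (!is.numeric(x) || anyNA(x) || !all(is.finite(x))) {
    stop_painmod(sprintf("`%s` must be finite numeric", name), "painmod_invalid_input")
  }
  if (!is.null(len) && length(x) != len) {
    stop_painmod(sprintf("`%s` must have length %d, got %d", name, len, length(x)),
                 "painmod_invalid_input")
  }
  invisible(x)
}

#' @noRd
#' Deterministic polynomial string hash modulo the Mersenne prime 2^31 - 1
#' (all arithmetic stays exact in doubles). Used to derive stable
#' per-subject RNG sub-seeds and config fingerprints.
string_hash <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  h
}

#' Derive a reproducible sub-seed for one subject
#'
#' Combines a master seed with a subject identifier so that every subject owns
#' an independent, order-invariant RNG stream: adding or reordering subjects
#' never perturbs the draws of the others.
#'
#' @param seed master integer seed.
#' @param subject_id character or integer identifier.
#' @return an integer in `[0, 2^31 - 1)`.
#' @keywords internal
subject_seed <- function(seed, subject_id) {
  as.integer(string_hash(paste0(format(seed, scientific = FALSE), "::", subject_id)))
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# global RNG state is untouched.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

clamp01_100 <- function(x) pmin(100, pmax(0, x))
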