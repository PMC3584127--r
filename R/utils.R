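#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's
#' `.Random.seed` afterwards, so seeded package functions never disturb the
#' global random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
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
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a master seed
#'
#' Deterministic FNV-1a style hash of `(master, stage, id)` folded into the
#' 31-bit positive integer range. Adding observers or stages never perturbs
#' the stream of an existing `(stage, id)` pair.
#'
#' @param master integer master seed.
#' @param stage character stage name (e.g. `"design"`, `"observer"`).
#' @param id optional identifier (observer id, replicate index, ...).
#' @return A positive integer seed below 2^31.
#' @export
#' @examples
#' derive_seed(1, "design")
#' derive_seed(1, "observer", "f03")
derive_seed <- function(master, stage, id = "") {
  key <- paste(format(master, scientific = FALSE), stage, id, sep = ":")
  bytes <- utf8ToInt(key)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    # 32-bit multiply by the FNV prime, done in double precision modulo 2^31-1
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h %% 2147483646L) + 1L
}

# shared argument checks ------------------------------------------------

check_scalar <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be TRUE or FALSE", name), call. = FALSE)
  }
  invisible(x)
}
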