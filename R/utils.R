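# Internal helpers: seeded RNG streams and small numeric utilities.

#' Derive a deterministic sub-seed for a named RNG stream
#'
#' Each generator operation draws from its own named stream seeded from the
#' user-facing seed, so adding draws to one stream cannot shift another.
#' The result is always in `[1, 2^31 - 2]`.
#'
#' @param seed Integer user seed.
#' @param stream Character stream name.
#' @return A single integer seed.
#' @keywords internal
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.double(seed %% m)
  for (k in utf8ToInt(stream)) {
    h <- (h * 131 + k) %% m
  }
  as.integer(h %% (m - 1L) + 1L)
}

# Evaluate `expr` with the RNG seeded from (seed, stream), restoring the
# caller's RNG state afterwards so generators are pure functions of their
# parameters.
with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, stream))
  expr
}

# Trapezoid integral of y over x (baseline 0).
trapz <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 2L)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

# Round half away from zero to an integer (base round() is banker's rounding).
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Parse a Newick string strictly: warnings count as parse failures.
parse_newick <- function(text) {
  tree <- tryCatch(
    withCallingHandlers(
      ape::read.tree(text = text),
      warning = function(w) stop(conditionMessage(w), call. = FALSE)),
    error = function(e) NULL)
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop("malformed Newick tree", call. = FALSE)
  }
  tree
}
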