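# Internal helpers shared across modules.

#' Derive a child RNG seed from a master seed
#'
#' Deterministically maps a (seed, stream label) pair to a new 31-bit integer
#' seed so that independent simulation stages draw from non-overlapping
#' streams while remaining reproducible from one master seed.
#'
#' @param seed Master integer seed.
#' @param stream Character label of the consuming stage.
#' @return A single integer in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  # simple polynomial string hash folded into 31 bits
  h <- as.double(seed %% 2147483647)
  for (ch in utf8ToInt(as.character(stream))) {
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer(h)
}

#' Evaluate an expression with a local, restored RNG state
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# symmetry check used by matrix-consuming operations
check_symmetric <- function(M, tol = 1e-8, what = "matrix") {
  if (!is.matrix(M) || nrow(M) != ncol(M)) {
    stop(what, " must be a square matrix", call. = FALSE)
  }
  if (max(abs(M - t(M))) > tol * max(1, max(abs(M)))) {
    stop(what, " is not symmetric within tolerance", call. = FALSE)
  }
  invisible(TRUE)
}

# population variance (divide by n), the convention used for relationship
# summaries
pop_var <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  mean((x - mean(x))^2)
}
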