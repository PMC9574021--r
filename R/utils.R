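#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's random number
#' generator state afterwards, so seeded helpers do not perturb the global
#' random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
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
  set.seed(as.integer(seed))
  code
}

#' Derive a stable child seed from a master seed
#'
#' Deterministic integer hash used to give each participant (or each replicate)
#' its own reproducible random stream. Kept below 2^31 - 1 so the result is a
#' valid R integer seed.
#'
#' @param master Integer master seed.
#' @param index Integer index (participant number, replicate number, ...).
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(1, 1:3)
derive_seed <- function(master, index) {
  master <- as.numeric(master)
  index <- as.numeric(index)
  stopifnot(all(is.finite(master)), all(is.finite(index)))
  # mixed congruential hash, all intermediates < 2^53 so doubles stay exact
  h <- (abs(master) %% 94906249) * 10007 + index * 7919 + 12345
  as.integer(h %% 2147483629 + 1)
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid("`%s` must be a single finite number", name)
  }
  if (positive && x <= 0) {
    stop_invalid("`%s` must be positive (got %g)", name, x)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
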