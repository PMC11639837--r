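# Internal helpers shared across modules.

#' @keywords internal
abort_hsd <- function(msg, class) {
  stop(structure(class = c(class, "hsdefect_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic 32-bit-safe integer hash of an integer vector, used to
# derive per-evaluation seeds from (global seed, band combination).
hash_ints <- function(x, init = 17L) {
  h <- as.double(init)
  for (v in as.double(x)) h <- (h * 31 + v + 1) %% 2147483647
  as.integer(h)
}

#' Round half away from zero at a given number of decimals
#'
#' Base R's `round()` rounds half to even; report tables use the
#' conventional half-up rule (0.9915 -> 0.992 at 3 decimals).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x == floor(x)
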