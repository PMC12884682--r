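# Internal helpers: seeding and RNG hygiene.

#' Derive a stream seed from a master seed
#'
#' Deterministically maps (master seed, index, salt) to a 31-bit seed so that
#' per-cell / per-mouse / per-stage random streams never collide or reorder.
#' All arithmetic is done in doubles below 2^53, reduced mod 2^31 - 19.
#'
#' @param master integer master seed.
#' @param index non-negative integer stream index.
#' @param salt optional character label folded into the stream.
#' @return a single integer in \[1, 2^31 - 19\].
#' @export
derive_seed <- function(master, index = 0L, salt = "") {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  m <- 2^31 - 19  # prime below 2^31
  h <- abs(as.numeric(master)) %% m
  h <- (h * 48271 + 11) %% m
  h <- (h + (abs(as.numeric(index)) %% m) * 69621) %% m
  if (nzchar(salt)) {
    for (code in utf8ToInt(salt)) h <- (h * 131 + code) %% m
  }
  as.integer(h %% m + 1)
}

# Evaluate `expr` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
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
  set.seed(seed)
  expr
}

# stop() with a consistent error class so callers can test for package errors
abort <- function(msg, class = "miniepoch_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
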