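#' @keywords internal
"_PACKAGE"

# Internal validation helpers. All user-facing errors route through these so
# the error classes referenced in the tests stay consistent.

ct_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "coraltex_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

assert_that <- function(cond, msg, class = "coraltex_validation_error") {
  if (!isTRUE(cond)) ct_stop(msg, class)
  invisible(TRUE)
}

#' Derive a child seed from a master seed
#'
#' Deterministic fan-out of one master seed into per-stage, per-replicate
#' seeds, so any single replicate can be replayed without rerunning the whole
#' experiment. The scheme is a fixed integer hash of the master seed and a
#' counter path; results stay inside the positive 32-bit integer range.
#'
#' @param seed master seed (single integer).
#' @param ... integer counters identifying the stage/replicate/colony, hashed
#'   in order.
#' @return a single integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' seed_stream(42, 1, 3) # replicate 3 of stage 1
seed_stream <- function(seed, ...) {
  parts <- c(seed, ...)
  assert_that(length(parts) >= 1 && all(is.finite(parts)),
              "seed_stream() needs finite integer arguments")
  h <- 0
  m <- 2147483629 # largest prime < 2^31
  for (p in as.double(parts)) {
    h <- (h * 69069 + (p %% m) + 1) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
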