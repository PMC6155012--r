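# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators do not perturb the
#' caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
  }
  expr
}

# Derive a per-stage seed from a global seed. Stage offsets are fixed so a
# stage re-run in isolation reproduces its in-pipeline stream. Kept below
# 2^31 - 1 by modular reduction.
stage_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  offsets <- c(
    sim_cyto = 101L, sim_imc = 211L, sim_rep = 307L, sim_reads = 401L,
    cyto = 503L, distinct = 601L, imc = 701L, repqc = 809L,
    clone = 907L, overlap = 1009L
  )
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
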