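# Internal helpers shared across modules: seeded RNG scoping and
# deterministic child-seed derivation.

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards. All seeded entry points go
# through this so they do not disturb the session RNG.
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
  force(expr)
}

#' Derive reproducible child seeds from a master seed
#'
#' A single master seed spawns one child seed per randomized unit of work
#' (one per random network, one per trial, one per pipeline stage). Children
#' are drawn from a generator seeded with the master seed, so one integer
#' reproduces an entire multi-stage, multi-trial run. All seeds stay below
#' 2^31 (valid R integers).
#'
#' @param master integer master seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(master, n) {
  stopifnot(length(master) == 1L, is.finite(master), n >= 0L)
  if (n == 0L) return(integer(0))
  with_seed(as.integer(master), sample.int(.Machine$integer.max - 1L, n))
}

stop_rptraj <- function(msg, class) {
  stop(structure(
    class = c(class, "rptraj_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
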