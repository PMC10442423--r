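# Internal helpers shared across modules.

#' @import stats
#' @importFrom utils read.delim write.table
#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All generators route their randomness
# through this so that every one is a pure function of (config, seed).
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite number")
  }
  env <- globalenv()
  has_old <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-stage seed derived from one experiment seed; kept inside
# the 32-bit signed range R requires of set.seed().
stage_seed <- function(seed, stage) {
  (as.numeric(seed) * 7919 + as.numeric(stage) * 104729) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Smallest positive p-value we ever report; guards against a literal 0 from
# pnorm/pt underflow so that -log10(p) stays finite.
P_FLOOR <- .Machine$double.xmin

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
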