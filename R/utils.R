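# Internal helpers shared across modules.

#' @importFrom methods as is new
#' @importFrom stats median plogis pnorm psignrank quantile rbinom rpois runif setNames
#' @importFrom utils head read.delim write.table
#' @importFrom tools md5sum
NULL

# Canonical set of annotation entry types. Order is irrelevant here; the
# precedence used for boundary building lives in region_builder.
ENTRY_TYPES <- c(
  "Domain", "Family", "HomologousSuperfamily", "UnintegratedSignature",
  "SignalPeptide", "Transmembrane", "NonTransmembrane", "Disorder",
  "Repeat", "Site", "Other"
)

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}

.is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)

# Quantile (type 7) of the implicit sorted vector made of `n_zero` zeros
# followed by the values in `nz` (any order).  Avoids materialising the
# all-pairs similarity vector when most entries are structural zeros.
.quantile_with_zeros <- function(nz, n_zero, p) {
  nz <- sort(nz)
  n <- length(nz) + n_zero
  .assert(n >= 1, "quantile of an empty vector")
  at <- function(i) if (i <= n_zero) 0 else nz[i - n_zero]
  h <- (n - 1) * p
  lo <- floor(h)
  v_lo <- at(lo + 1)
  if (lo + 2 > n) return(v_lo)
  v_lo + (h - lo) * (at(lo + 2) - v_lo)
}

# Derive a stream-specific 32-bit seed from a master seed.
.derive_seed <- function(seed, offset) {
  (as.integer(seed) + 7919L * as.integer(offset)) %% 2147483587L
}

# Evaluate `expr` under `seed` and restore the caller's RNG state after.
.with_seed <- function(seed, expr) {
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
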