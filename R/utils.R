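#' @keywords internal
#' @importFrom graphics plot segments points text
#' @importFrom stats setNames
"_PACKAGE"

## Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global random-number state set from `seed`, then
#' restores whatever state existed before the call, so package functions are
#' deterministic given their `seed` argument without clobbering the caller's
#' random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

## Exact 32-bit FNV-1a over a string; used to derive per-stage seeds and to
## stamp outputs with a short config fingerprint.  The 32-bit multiply is done
## in two 16-bit halves so intermediate products stay below 2^53.
fnv1a <- function(x) {
  bytes <- utf8ToInt(enc2utf8(as.character(x)))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    ## h may exceed the signed-integer range, but b < 256, so the xor only
    ## touches the low byte
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(lo8, b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- ((hi * prime) %% 65536) * 65536 + lo * prime
    h <- h %% 4294967296
  }
  h
}

#' Derive a stage-specific seed from a run seed
#'
#' Each randomised stage of a pipeline consumes a seed derived
#' deterministically from the run seed and the stage name, so stages can be
#' re-run in isolation and still reproduce.
#'
#' @param seed integer run seed.
#' @param stage character stage name.
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  as.integer((as.double(seed) + fnv1a(stage)) %% 2147483647)
}

## Short hexadecimal fingerprint of an R object (via its canonical JSON).
## The hash exceeds the signed-integer range, so format it in two halves.
config_fingerprint <- function(x) {
  h <- fnv1a(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

## All ordered pairs (i, j), i != j, over node labels, in row-major order.
ordered_pairs <- function(nodes) {
  n <- length(nodes)
  idx <- expand.grid(obj = seq_len(n), pred = seq_len(n))
  idx <- idx[idx$pred != idx$obj, c("pred", "obj")]
  data.frame(pred = nodes[idx$pred], obj = nodes[idx$obj],
             stringsAsFactors = FALSE)
}

## Upper-triangle (i < j) values of a square matrix, in combn(n, 2) order
## (row index varying slowest), matching the edge ordering used by the
## null-graph ensemble.
upper_pairs <- function(m) t(m)[lower.tri(t(m))]
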