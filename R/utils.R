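# Internal helpers: seeded evaluation, stable id hashing, assertions.

#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, restoring the caller's
#' RNG state afterwards so library code never clobbers user randomness.
#'
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic 31-bit hash of a character id (polynomial rolling hash).
# Used to derive per-subject RNG substreams that survive cohort reordering.
stable_hash <- function(x) {
  vapply(as.character(x), function(s) {
    h <- 0
    for (cc in utf8ToInt(s)) h <- (h * 31 + cc) %% 2147483647L
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

# Combine a base seed with a per-subject hash, staying inside 31 bits.
derive_seed <- function(seed, id) {
  as.integer((as.double(seed) + as.double(stable_hash(id))) %% 2147483647)
}

stop_remed <- function(fmt, ..., class = "remedbp_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

assert_numeric_col <- function(df, col, file = "table") {
  v <- df[[col]]
  if (is.character(v)) {
    conv <- suppressWarnings(as.numeric(ifelse(trimws(v) == "", NA, v)))
    bad <- which(!is.na(v) & trimws(v) != "" & is.na(conv))
    if (length(bad)) {
      stop_remed("non-numeric value '%s' in column '%s', row %d of %s",
                 v[bad[1]], col, bad[1], file, class = "remedbp_parse_error")
    }
    return(conv)
  }
  as.numeric(v)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
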