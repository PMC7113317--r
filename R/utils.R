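# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded simulators do not disturb the
#' caller's RNG stream.  With `seed = NULL` the expression runs on the current
#' stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic substream seed derived from a master seed and a label.
# Polynomial rolling hash modulo a Mersenne prime keeps results < 2^31,
# valid R integer seeds.
derive_seed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  h <- 17
  for (b in utf8ToInt(label)) h <- (h * 131 + b) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Rolling hash of an R object, for config provenance headers.
config_hash <- function(x) {
  txt <- paste(deparse(x), collapse = "\n")
  h <- 17
  for (b in utf8ToInt(txt)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Checks that a count matrix is numeric, non-negative and named.
check_count_matrix <- function(x, what = "counts") {
  if (!is.matrix(x) || !is.numeric(x))
    stopf("'%s' must be a numeric matrix", what)
  if (any(!is.finite(x)) || any(x < 0))
    stopf("'%s' must contain finite, non-negative values", what)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stopf("'%s' must have gene rownames and sample colnames", what)
  invisible(x)
}
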