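## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_config <- function(msg) stop(structure(
  class = c("radfuse_config_error", "error", "condition"),
  list(message = msg, call = NULL)
))

abort_io <- function(msg) stop(structure(
  class = c("radfuse_io_error", "error", "condition"),
  list(message = msg, call = NULL)
))

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    abort_config(sprintf("`%s` must be TRUE or FALSE", name))
  invisible(x)
}

assert_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max)
    abort_config(sprintf("`%s` must be a finite number in [%s, %s]", name, min, max))
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  assert_number(x, name, min = min)
  if (x != as.integer(x)) abort_config(sprintf("`%s` must be an integer", name))
  invisible(as.integer(x))
}

## Run `expr` under a temporary RNG state seeded with `seed`, restoring the
## caller's stream afterwards. All package randomness funnels through this.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

## Derive a per-item substream seed from a base seed and a counter, kept
## inside 32-bit integer range so set.seed() accepts it.
substream_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(counter) * 16807) %% 2147483647)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

is_pixel_matrix <- function(x) {
  is.matrix(x) && is.numeric(x) && all(is.finite(x)) &&
    min(x) >= 0 && max(x) <= 1
}
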