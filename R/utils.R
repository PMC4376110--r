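# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so library calls never perturb user code.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Lowercase, non-alphanumeric runs collapsed to single underscores.
slugify <- function(x) {
  s <- tolower(x)
  s <- gsub("[^a-z0-9]+", "_", s)
  gsub("^_+|_+$", "", s)
}

# Render a probability annotation with 12 significant digits, no scientific
# notation drift across platforms.
format_annotation <- function(p) {
  vapply(p, function(v) trimws(formatC(v, digits = 12L, format = "g")), character(1))
}

is_probability <- function(x, open_left = FALSE, open_right = FALSE) {
  ok <- is.numeric(x) & is.finite(x)
  lo <- if (open_left) x > 0 else x >= 0
  hi <- if (open_right) x < 1 else x <= 1
  ok & lo & hi
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c("fallrisk_error", "fallrisk_input_error")))
}

stop_numeric <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c("fallrisk_error", "fallrisk_numeric_error")))
}
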