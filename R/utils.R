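# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG state, then restore it
#'
#' All stochastic operations in the package route their draws through this
#' helper so that a single integer seed makes a whole run bit-reproducible
#' without clobbering the caller's RNG stream.
#'
#' @param seed integer scalar seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed != trunc(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Canonical key for gene-symbol matching: trim whitespace, fold case.
# Original spellings are preserved everywhere for output; only the
# comparison is case-insensitive (microarray annotation tables are
# notoriously inconsistent about symbol capitalization).
symbol_key <- function(x) tolower(trimws(as.character(x)))

# Stop with a classed condition so callers/tests can distinguish
# configuration, format and input errors.
abort <- function(msg, class) {
  stop(structure(
    class = c(class, "rslgn_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

config_error <- function(msg) abort(msg, "rslgn_config_error")
format_error <- function(msg) abort(msg, "rslgn_format_error")
input_error  <- function(msg) abort(msg, "rslgn_input_error")

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != trunc(x) || x < min) {
    config_error(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_fraction <- function(x, name, lower_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
  if (ok && lower_open && x == 0) ok <- FALSE
  if (!ok) {
    config_error(sprintf(
      "`%s` must be a single number in %s0, 1]", name, if (lower_open) "(" else "["
    ))
  }
  as.numeric(x)
}

# FNV-1a 32-bit hash of a character scalar; used for config fingerprints in
# run manifests (stable across sessions, no external dependency).
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  # 32-bit arithmetic carried in doubles, split into 16-bit halves so every
  # intermediate stays well inside the exact-integer range of a double
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    lo <- bitwXor(h %% 65536, b)
    hi <- h %/% 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
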