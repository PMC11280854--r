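# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generators never disturb
#' the caller's RNG stream. All randomness in the package flows through this.
#'
#' @param seed single integer-like seed
#' @param code expression to evaluate
#' @return the value of `code`
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Draw n sub-seeds (< 2^31) from the master seed, for per-item generators.
draw_subseeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

#' FNV-1a hash of a character vector
#'
#' 32-bit Fowler-Noll-Vo hash used to fingerprint the feature-name registry
#' embedded in model files. Implemented with split-word arithmetic so the
#' modular multiply stays exact in doubles.
#'
#' @param x character vector (joined with a unit separator before hashing)
#' @return an 8-character lowercase hex string
#' @export
#' @examples
#' fnv1a_hash(c("left.emg1.mav", "left.emg1.rms"))
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(enc2utf8(as.character(x)), collapse = "\x1f")))
  h <- 2166136261
  for (b in bytes) {
    h <- (h %/% 256) * 256 + bitwXor(as.integer(h %% 256), b)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

stop_invalid <- function(...) stop(..., call. = FALSE)

check_scalar_num <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    stop_invalid(sprintf("`%s` must be a single finite number", name))
  as.numeric(x)
}
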