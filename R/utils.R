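# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stable string hash
#'
#' Deterministic, platform-independent polynomial hash of a character scalar,
#' reduced modulo a prime below 2^31. Used to derive per-sample / per-stage
#' random seeds from a single global seed so that adding samples never
#' reshuffles the random stream of existing ones.
#'
#' @param x Character scalar.
#' @return A non-negative integer below 1000003.
#' @keywords internal
stable_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  h <- 0
  for (code in utf8ToInt(x)) h <- (h * 31 + code) %% 1000003
  as.integer(h)
}

# Combine a user seed with a label into a derived seed < 2^31.
derive_seed <- function(seed, ...) {
  h <- stable_hash(paste(c(...), collapse = "/"))
  as.integer((abs(as.numeric(seed)) %% 44483 * 48271 + h) %% 2147483587)
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Strip allele suffixes ("*01") and MiXCR score annotations ("*00(1234.5)")
# from a V/J call, leaving the plain segment name.
strip_allele <- function(call) {
  sub("\\*.*$", "", sub("\\(.*$", "", call))
}

# Case-insensitive, whitespace-free segment name ("Trbv12-1" == "TRBV12-1").
normalize_segment <- function(segment) {
  toupper(gsub("[[:space:]]", "", segment))
}

is_count_scalar <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}
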