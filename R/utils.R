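#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-subject RNG seed from a master seed
#'
#' Stable integer hash of (master seed, subject index) so that every subject
#' is reproducible in isolation and cohorts generated from the same master
#' seed are bit-identical across runs and platforms. Kept strictly below
#' 2^31 so the result is always a valid R integer seed.
#'
#' @param master integer master seed.
#' @param index integer subject index (1-based).
#' @return a single integer seed.
#' @export
derive_seed <- function(master, index) {
  stopifnot(is.numeric(master), length(master) == 1L,
            is.numeric(index), length(index) == 1L)
  # Lehmer-style mixing in double precision; every intermediate stays below
  # 2^52 so the arithmetic is exact on all platforms.
  h <- (abs(master) %% 2147483647) + 1
  h <- (h * 48271) %% 2147483647
  h <- (h + (index %% 2147483647) * 69621) %% 2147483647
  h <- (h * 16807) %% 2147483647
  as.integer(h)
}

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores \code{.Random.seed} so library code never perturbs the
#' caller's RNG stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @keywords internal
stop_data <- function(...) stop(..., call. = FALSE)

#' @keywords internal
is_binary_mask <- function(x) {
  is.array(x) && length(dim(x)) == 3L && all(x %in% c(0, 1))
}

#' @keywords internal
check_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b)))
    stop_data(sprintf("%s must share the same array dimensions", what))
  invisible(TRUE)
}

#' Stable hash of an R object (provenance stamping)
#'
#' FNV-1a (32 bit) over the serialized representation, implemented in exact
#' double arithmetic; used to stamp pipeline outputs with a configuration
#' fingerprint that changes iff the configuration changes.
#'
#' @param x any R object.
#' @return an 8-character hexadecimal string.
#' @export
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 2166136261
  for (b in bytes) {
    lo <- bitwXor(h %% 65536, b)          # byte only touches the low half
    hi <- h %/% 65536
    h <- hi * 65536 + lo
    # multiply by the FNV prime 16777619 modulo 2^32, split to stay exact
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}
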