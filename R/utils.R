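#' @useDynLib audcm, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats contr.poly cov dgamma pf pt rnorm runif sd t.test var
#' @importFrom utils modifyList read.delim write.table
NULL

# Evaluate `code` under a given RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Derive a reproducible sequence of sub-seeds from one master seed
#'
#' A single master seed fans out to independent per-stage / per-subject seeds
#' so every stage of a pipeline can be regenerated in isolation.
#'
#' @param master_seed Integer master seed.
#' @param n Number of sub-seeds.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
seed_sequence <- function(master_seed, n) {
  with_seed(master_seed, sample.int(2147483646L, n))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# Small deterministic fingerprint (hex string) for stamping artifacts.
fingerprint <- function(x) {
  txt <- paste(deparse(x), collapse = "\n")
  bytes <- as.integer(charToRaw(txt))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
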