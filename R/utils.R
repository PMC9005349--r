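# Internal helpers shared across modules.

#' Derive a named substream seed from a root seed
#'
#' All stochastic stages draw their seed from a single root seed plus a stage
#' name, so any stage can be reproduced in isolation.
#'
#' @param seed integer root seed.
#' @param name character stream name.
#' @return An integer seed in [0, 2^31 - 1).
#' @keywords internal
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(seed) + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# standardize a vector; errors on zero variance unless allow_constant
std <- function(x, allow_constant = FALSE) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    if (allow_constant) return(rep(0, length(x)))
    stop("cannot standardize a constant vector")
  }
  (x - mean(x)) / s
}

# two-sided normal p-value from a z score
z_to_p <- function(z) 2 * stats::pnorm(-abs(z))

# md5 fingerprint of an arbitrary R object (used by run manifests)
fingerprint <- function(x) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
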