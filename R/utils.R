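#' @importFrom stats rnorm runif rpois rgamma setNames sd var dnorm pnorm cor
#' @importFrom utils head tail read.table write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a base seed and stream labels
#'
#' Combines a base integer seed with one or more integer or character labels
#' (epoch numbers, replicate indices, window ids, ...) into a new seed in
#' `[1, 2^31 - 2]`. The same inputs always give the same seed, and distinct
#' label streams give (with overwhelming probability) distinct seeds, so
#' independent random streams can be carved out of one user-facing seed.
#'
#' @param seed integer base seed.
#' @param ... integers or strings identifying the stream.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483629 # large prime < 2^31
  h <- as.numeric(seed) %% m
  for (x in list(...)) {
    if (is.character(x)) {
      for (cc in utf8ToInt(paste(x, collapse = "\r"))) h <- (h * 131 + cc) %% m
    } else {
      for (v in as.numeric(x)) h <- (h * 69069 + (v %% m) + 17) %% m
    }
  }
  as.integer(h %% (m - 2) + 1)
}

stop_s2t <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x) && x >= min
}

#' Numerically stable softplus and its derivative
#'
#' `softplus(x) = log(1 + exp(x))`, evaluated without overflow; used as the
#' output nonlinearity that maps head activations to strictly positive
#' Poisson rates.
#'
#' @param x numeric vector or matrix.
#' @return object of the same shape as `x`.
#' @export
softplus <- function(x) {
  out <- pmax(x, 0) + log1p(exp(-abs(x)))
  if (is.matrix(x)) dim(out) <- dim(x)
  out
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# md5 of an R object's binary serialization (version 3, deterministic)
object_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 3L, xdr = TRUE)
  close(con)
  unname(tools::md5sum(f))
}

# total number of values across a list of numeric arrays
param_count <- function(params) {
  if (length(params) == 0L) return(0L)
  sum(vapply(params, length, integer(1)))
}
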