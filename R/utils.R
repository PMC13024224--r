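# Internal helpers: seeded evaluation, clip-tensor checks, small numerics.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. `seed = NULL` runs code unseeded.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic fan-out of one user seed into independent sub-seeds
# (kept below 2^31 - 1 so they remain valid R integer seeds).
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 7907 * as.double(k)) %% 2147483647)
}

#' Validate a clip tensor
#'
#' A clip tensor is a 5-axis numeric array with dimensions
#' (batch, channel, time, height, width) and values in \[0, 1\]. This layout
#' is the universal unit of model input throughout the package.
#'
#' @param x object to check.
#' @param check_range also verify values lie in \[0, 1\].
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
as_clip_tensor <- function(x, check_range = TRUE) {
  if (!is.array(x) || length(dim(x)) != 5L)
    stop("a clip tensor must be a 5-axis (B, C, T, H, W) array")
  if (!is.numeric(x)) stop("clip tensor must be numeric")
  if (check_range) {
    r <- range(x)
    if (r[1] < -1e-8 || r[2] > 1 + 1e-8)
      stop("clip tensor values must lie in [0, 1]")
  }
  invisible(x)
}

clip_dims <- function(x) {
  d <- dim(x)
  list(B = d[1], C = d[2], T = d[3], H = d[4], W = d[5])
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# round-half-away-from-zero (base round() is round-half-even)
round_half_away <- function(x) floor(x + 0.5)

# elementwise combination of two identically-structured parameter lists
param_map2 <- function(a, b, f) {
  stopifnot(identical(names(a), names(b)))
  out <- a
  for (nm in names(a)) out[[nm]] <- f(a[[nm]], b[[nm]])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
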