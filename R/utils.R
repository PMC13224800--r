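# Small numerical helpers shared across modules.

#' Finite-difference weights on arbitrarily spaced nodes
#'
#' Computes the weights of the interpolatory finite-difference approximation
#' to the `k`-th derivative at `x0` using all nodes in `x`, by solving the
#' (scaled) Vandermonde moment conditions.  With three nodes this yields the
#' usual second-order centred or one-sided stencils, and remains exact on
#' non-uniform spacings such as the junctions between the piecewise-uniform
#' radial grid regions.
#'
#' @param x0 evaluation point.
#' @param x node locations (length >= k + 1).
#' @param k derivative order (0 = interpolation).
#' @return numeric vector of weights, one per node.
#' @keywords internal
fd_weights <- function(x0, x, k) {
  n <- length(x)
  stopifnot(n >= k + 1L)
  h <- max(abs(x - x0), na.rm = TRUE)
  if (h == 0) h <- 1
  d <- (x - x0) / h
  A <- t(vapply(0:(n - 1L), function(p) d^p, numeric(n)))
  rhs <- numeric(n)
  rhs[k + 1L] <- factorial(k)
  solve(A, rhs) / h^k
}

# Stable content hash (FNV-1a, 32 bit) of an R object; used to stamp output
# files with the configuration they were produced from.  No cryptographic
# strength required, only reproducibility.  32-bit modular arithmetic is done
# in 16-bit halves to stay within exact double precision.
content_hash <- function(x) {
  raw <- serialize(x, connection = NULL, version = 2L)
  h <- 2166136261
  for (b in as.integer(raw)) {
    low <- h %% 256
    h <- h - low + bitwXor(low, b)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Deterministic key for memoisation: exact decimal rendering of all numeric
# leaves, so distinct inputs can never collide.
num_key <- function(...) {
  parts <- rapply(list(...), function(v) {
    if (is.complex(v)) paste(format(Re(v), digits = 17), format(Im(v), digits = 17))
    else if (is.numeric(v)) paste(format(v, digits = 17), collapse = ",")
    else paste(as.character(v), collapse = ",")
  }, how = "unlist")
  paste(parts, collapse = "|")
}

# Wrap phase into (-pi, pi]
wrap_phase <- function(phi) {
  out <- (phi + pi) %% (2 * pi) - pi
  out[out <= -pi] <- out[out <= -pi] + 2 * pi
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
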