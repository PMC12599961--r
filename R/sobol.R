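# Sobol low-discrepancy sequence, direction numbers from the published
# Joe & Kuo D(6) table (dimensions 1-32; dimension 1 is the van der
# Corput sequence). Enough for the 14-dimensional design box and the
# 28-dimensional Saltelli base used here.
.sobol_poly <- c(1L, 3L, 7L, 11L, 13L, 19L, 25L, 37L, 41L, 47L, 55L, 59L,
                 61L, 67L, 91L, 97L, 103L, 109L, 115L, 131L, 137L, 143L,
                 145L, 157L, 167L, 171L, 185L, 191L, 193L, 203L, 211L, 213L)
.sobol_minit <- list(
  c(1), c(1), c(1, 3), c(1, 3, 1), c(1, 1, 1), c(1, 1, 3, 3),
  c(1, 3, 5, 13), c(1, 1, 5, 5, 17), c(1, 1, 5, 5, 5), c(1, 1, 7, 11, 19),
  c(1, 1, 5, 1, 1), c(1, 1, 1, 3, 11), c(1, 3, 5, 5, 31),
  c(1, 3, 3, 9, 7, 49), c(1, 1, 1, 15, 21, 21), c(1, 3, 1, 13, 27, 49),
  c(1, 1, 1, 15, 7, 5), c(1, 3, 1, 15, 13, 25), c(1, 1, 5, 5, 19, 61),
  c(1, 3, 7, 11, 23, 15, 103), c(1, 3, 7, 13, 13, 15, 69),
  c(1, 1, 3, 13, 7, 35, 63), c(1, 3, 5, 9, 1, 25, 53),
  c(1, 3, 1, 13, 9, 35, 107), c(1, 3, 1, 5, 27, 61, 31),
  c(1, 1, 5, 11, 19, 41, 61), c(1, 3, 5, 3, 3, 13, 69),
  c(1, 1, 7, 13, 1, 19, 1), c(1, 3, 7, 5, 13, 19, 59),
  c(1, 1, 3, 9, 25, 29, 41), c(1, 3, 5, 13, 23, 1, 55),
  c(1, 3, 7, 3, 13, 59, 17))

# Direction integers for one dimension, L bits.
.sobol_directions <- function(dim, L) {
  if (dim == 1) return(bitwShiftL(1L, L - seq_len(L)))
  p <- .sobol_poly[dim]
  s <- floor(log2(p))
  # a_1..a_{s-1}: bits of p between the leading and trailing 1
  a <- if (s > 1) bitwAnd(bitwShiftR(p, s - seq_len(s - 1)), 1L) else integer(0)
  m <- .sobol_minit[[dim]]
  v <- integer(L)
  for (k in seq_len(min(s, L))) v[k] <- bitwShiftL(m[k], L - k)
  if (L > s) {
    for (k in (s + 1):L) {
      vk <- bitwXor(v[k - s], bitwShiftR(v[k - s], s))
      if (s > 1) for (i in seq_len(s - 1)) {
        if (a[i] == 1L) vk <- bitwXor(vk, v[k - i])
      }
      v[k] <- vk
    }
  }
  v
}

#' Sobol quasi-random sequence
#'
#' First `n` points of the d-dimensional Sobol sequence on the unit
#' hypercube (Gray-code order, including the initial origin point).
#' Deterministic for fixed `n` and `d`.
#'
#' @param n number of points (n < 2^30)
#' @param d dimension (1 to 32)
#' @return n x d matrix in \[0, 1)
#' @export
sobol_sequence <- function(n, d) {
  stopifnot(n >= 1, n < 2^30, d >= 1, d <= 32)
  L <- max(ceiling(log2(n + 1)), 1)
  V <- vapply(seq_len(d), .sobol_directions, integer(L), L = L)  # L x d
  X <- matrix(0, n, d)
  state <- integer(d)
  if (n > 1) {
    for (i in 2:n) {
      cbit <- 1L
      im1 <- i - 2L  # index of previous point, 0-based
      while (bitwAnd(im1, 1L) == 1L) { im1 <- bitwShiftR(im1, 1L); cbit <- cbit + 1L }
      state <- bitwXor(state, V[cbit, ])
      X[i, ] <- state
    }
  }
  X / 2^L
}

#' Scale unit-cube points to physical ranges
#'
#' @param U matrix of points in \[0,1\]^d
#' @param ranges data.frame with `name`, `lower`, `upper` (see
#'   [param_ranges()])
#' @return matrix in physical units with named columns
#' @export
scale_to_ranges <- function(U, ranges) {
  U <- as.matrix(U)
  stopifnot(ncol(U) == nrow(ranges))
  X <- sweep(sweep(U, 2, ranges$upper - ranges$lower, "*"),
             2, ranges$lower, "+")
  colnames(X) <- ranges$name
  X
}

#' Normalise physical points to the unit cube
#'
#' @param X matrix in physical units
#' @inheritParams scale_to_ranges
#' @return matrix in \[0,1\]^d
#' @export
normalize_to_ranges <- function(X, ranges) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == nrow(ranges))
  n <- nrow(X)
  lo <- matrix(ranges$lower, n, ncol(X), byrow = TRUE)
  span <- matrix(ranges$upper - ranges$lower, n, ncol(X), byrow = TRUE)
  U <- (X - lo) / span
  colnames(U) <- ranges$name
  U
}

#' Sobol design over parameter ranges
#'
#' The first `n` Sobol points scaled to the physical box, used for
#' emulator training designs (n of at least 10 times the input
#' dimension). Following standard quasi-Monte-Carlo practice for
#' unscrambled sequences, the initial origin point — which maps to the
#' degenerate all-lower-bounds corner of the box — is dropped, so the
#' design consists of sequence points 2 to n + 1.
#'
#' @param ranges a [param_ranges()]-style data.frame
#' @param n number of design points
#' @return n x d matrix with named columns, every row inside its range
#' @export
sobol_design <- function(ranges, n) {
  U <- sobol_sequence(n + 1, nrow(ranges))[-1, , drop = FALSE]
  scale_to_ranges(U, ranges)
}

#' Latin-hypercube design over parameter ranges
#'
#' Random LHS (via the lhs package) scaled to the physical box; used for
#' the large history-matching test clouds.
#'
#' @inheritParams sobol_design
#' @param seed integer seed controlling the draw
#' @return n x d matrix with named columns
#' @export
lhs_design <- function(ranges, n, seed = 1L) {
  U <- with_seed(seed, lhs::randomLHS(n, nrow(ranges)))
  scale_to_ranges(U, ranges)
}

# Evaluate fn under a local RNG seed, restoring the caller's RNG state.
# The seed promise is forced before the state is saved, so arguments
# like sample.int(...) are not rolled back.
with_seed <- function(seed, expr) {
  force(seed)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
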