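#' Discretization of the latent domain [-1, 1]
#'
#' Builds the discrete basis in which all model functions and operators live:
#' Chebyshev--Gauss--Lobatto nodes (so that both domain boundaries are grid
#' nodes, as required by the absorbing boundary conditions), a spectral
#' differentiation matrix, a cumulative integration matrix that integrates the
#' polynomial interpolant exactly from -1 to each node, and quadrature weights
#' taken from the full-domain row of that matrix (Clenshaw--Curtis weights).
#' Using one integration rule for both cumulative integrals and normalization
#' keeps the change-of-variables reconstructions internally consistent.
#'
#' @param n_nodes Number of grid nodes (>= 8). Both endpoints are included.
#' @return An object of class `sd_grid` with elements `nodes` (strictly
#'   increasing, from -1 to 1), `weights` (positive, summing to 2), `D1`
#'   (first-derivative matrix), `D2` (second-derivative matrix), `cumint`
#'   (matrix mapping function values to values of the cumulative integral
#'   from -1), `n`, and `interior` (indices of non-boundary nodes).
#' @examples
#' g <- build_grid(64)
#' sum(g$weights)                      # domain length: 2
#' sum(g$weights * g$nodes^2)          # 2/3
#' @export
build_grid <- function(n_nodes = 256L) {
  n_nodes <- as.integer(n_nodes)
  if (is.na(n_nodes) || n_nodes < 8L) {
    stop("n_nodes must be at least 8: the discrete second-derivative operator ",
         "and absorbing boundary treatment are meaningless on coarser grids.",
         call. = FALSE)
  }
  N <- n_nodes - 1L
  j <- 0:N
  # Trefethen's Chebyshev differentiation matrix (nodes descending), then
  # reindexed to ascending order.
  x_desc <- cos(pi * j / N)
  cc <- c(2, rep(1, N - 1L), 2) * (-1)^j
  X <- matrix(x_desc, n_nodes, n_nodes)
  dX <- X - t(X)
  D <- (cc %o% (1 / cc)) / (dX + diag(n_nodes))
  D <- D - diag(rowSums(D))
  rev_idx <- n_nodes:1
  D1 <- D[rev_idx, rev_idx]
  nodes <- x_desc[rev_idx]
  nodes[1] <- -1; nodes[n_nodes] <- 1

  # Value-to-Chebyshev-coefficient matrix (descending node convention).
  cj <- c(2, rep(1, N - 1L), 2)
  K <- outer(j, j)                       # k * j
  Cmat <- (2 / N) * cos(pi * K / N) / (cj %o% cj)
  # Antiderivative in coefficient space: b_k = (c_{k-1} a_{k-1} - a_{k+1}) / (2k)
  # with c_0 = 2 (integral of T_0 is T_1), c_k = 1 otherwise.
  A <- matrix(0, n_nodes + 1L, n_nodes)
  for (k in 1:(n_nodes)) {               # k = 1 .. N+1 (coefficient index)
    A[k + 1L, k] <- A[k + 1L, k] + (if (k == 1L) 1 else 1 / (2 * k))
    if (k + 2L <= n_nodes) A[k + 1L, k + 2L] <- A[k + 1L, k + 2L] - 1 / (2 * k)
  }
  # Evaluate antiderivative at descending nodes and at x = -1.
  kk <- 0:n_nodes
  Tnodes <- cos(outer(pi * j / N, kk))   # T_k(x_j), descending nodes
  Tm1 <- cos(pi * kk)                    # T_k(-1) = (-1)^k
  Qdesc <- (Tnodes - matrix(Tm1, n_nodes, n_nodes + 1L, byrow = TRUE)) %*% A %*% Cmat
  cumint <- Qdesc[rev_idx, rev_idx]
  cumint[1, ] <- 0
  weights <- cumint[n_nodes, ]
  if (any(weights <= 0)) stop("internal error: non-positive quadrature weights")

  # value <-> Chebyshev-coefficient maps in ascending-node convention
  vals2coefs <- Cmat[, rev_idx]
  coefs2vals <- Tnodes[rev_idx, 1:n_nodes]

  structure(
    list(nodes = nodes, weights = weights, D1 = D1, D2 = D1 %*% D1,
         cumint = cumint, n = n_nodes, interior = 2:(n_nodes - 1L),
         vals2coefs = vals2coefs, coefs2vals = coefs2vals),
    class = "sd_grid")
}

#' Low-pass projection onto the leading Chebyshev modes
#'
#' Returns the matrix projecting grid-sampled functions onto the first
#' `n_modes` Chebyshev polynomials. Used to keep optimized functions in a
#' smooth subspace of the grid: functional gradients have almost no curvature
#' along node-scale oscillations, so unfiltered normalized updates accumulate
#' discretization-scale noise there.
#'
#' @param grid An `sd_grid`.
#' @param n_modes Number of retained modes (>= 2).
#' @return A `grid$n` x `grid$n` projection matrix.
#' @export
lowpass_projector <- function(grid, n_modes) {
  stopifnot_grid(grid)
  n_modes <- min(as.integer(n_modes), grid$n)
  if (n_modes < 2L) stop("n_modes must be at least 2", call. = FALSE)
  grid$coefs2vals[, 1:n_modes, drop = FALSE] %*%
    grid$vals2coefs[1:n_modes, , drop = FALSE]
}

#' @export
print.sd_grid <- function(x, ...) {
  cat("Latent-domain grid on [-1, 1]:", x$n,
      "Chebyshev-Gauss-Lobatto nodes\n")
  invisible(x)
}

is_grid <- function(g) inherits(g, "sd_grid")

stopifnot_grid <- function(g) {
  if (!is_grid(g)) stop("expected an object created by build_grid()", call. = FALSE)
  invisible(g)
}

#' Integrate a function sampled on the grid
#'
#' @param values Function values at `grid$nodes`.
#' @param grid An `sd_grid`.
#' @return The quadrature approximation of the integral over [-1, 1].
#' @keywords internal
grid_integral <- function(values, grid) sum(grid$weights * values)
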