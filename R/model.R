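#' Reconstruct the potential from a force function
#'
#' The latent dynamics are driven by the force F(x) = -dPhi/dx, so the
#' potential is the negative cumulative integral of the force,
#' Phi(x) = -int_{-1}^{x} F(s) ds + C. The integration constant C is fixed so
#' that int exp(-Phi) dx = 1, which makes potentials comparable across models;
#' absolute offsets carry no meaning beyond this convention.
#'
#' @param F Force values at `grid$nodes` (units 1/x).
#' @param grid An `sd_grid`.
#' @return Potential values Phi at the grid nodes.
#' @export
force_to_potential <- function(F, grid) {
  stopifnot_grid(grid)
  F <- as.numeric(F)
  if (length(F) != grid$n || any(!is.finite(F)))
    stop("F must be finite and of length grid$n", call. = FALSE)
  phi0 <- -as.numeric(grid$cumint %*% F)
  m <- max(-phi0)
  C <- log(sum(grid$weights * exp(-phi0 - m))) + m
  phi0 + C
}

#' Reconstruct the initial-state density from its auxiliary log-derivative
#'
#' The initial density is optimized through the unconstrained auxiliary
#' function F0(x) = p0'(x)/p0(x). This reconstruction exponentiates the
#' cumulative integral of F0 and normalizes, which guarantees p0 > 0 and
#' int p0 dx = 1. The exponent is re-centred internally, so the result is
#' invariant to adding a constant to the cumulative integral.
#'
#' @param F0 Auxiliary function values at `grid$nodes`.
#' @param grid An `sd_grid`.
#' @return Density values p0 at the grid nodes.
#' @export
aux_to_density <- function(F0, grid) {
  stopifnot_grid(grid)
  F0 <- as.numeric(F0)
  if (length(F0) != grid$n || any(!is.finite(F0)))
    stop("F0 must be finite and of length grid$n", call. = FALSE)
  g <- as.numeric(grid$cumint %*% F0)
  g <- g - max(g)
  e <- exp(g)
  e / sum(grid$weights * e)
}

#' Reconstruct a tuning function from its auxiliary parametrization
#'
#' A tuning function is represented by its firing rate at the left boundary,
#' Ci = f(-1), and the auxiliary log-derivative Fi(x) = f'(x)/f(x), giving
#' f(x) = Ci exp(int_{-1}^{x} Fi ds). This guarantees f >= 0 everywhere for
#' any unconstrained Fi.
#'
#' @param Fi Auxiliary function values at `grid$nodes`.
#' @param Ci Firing rate at x = -1 (Hz, >= 0).
#' @param grid An `sd_grid`.
#' @return Tuning-function values (Hz) at the grid nodes.
#' @export
aux_to_tuning <- function(Fi, Ci, grid) {
  stopifnot_grid(grid)
  Fi <- as.numeric(Fi)
  if (length(Fi) != grid$n || any(!is.finite(Fi)))
    stop("Fi must be finite and of length grid$n", call. = FALSE)
  if (!is.finite(Ci) || Ci < 0) stop("Ci must be non-negative", call. = FALSE)
  Ci * exp(as.numeric(grid$cumint %*% Fi))
}

#' Latent Langevin model with neuronal tuning
#'
#' Container for all inferred model components: a per-condition force (the
#' negative potential derivative), a shared noise magnitude D, the initial
#' density (through its auxiliary function F0), and per-neuron tuning
#' functions (through boundary rates Ci and auxiliary functions Fi). The
#' optimized quantities are the unconstrained auxiliary functions; potentials,
#' densities and rates are reconstructed on demand.
#'
#' @param grid An `sd_grid`.
#' @param forces Matrix (`grid$n` x n_conditions) of force values per
#'   condition, or a vector for a single condition.
#' @param D Noise magnitude (> 0, units x^2/s).
#' @param F0 Auxiliary values for the initial density (default 0: uniform p0).
#' @param C Numeric vector of boundary rates f_i(-1), one per neuron (Hz).
#' @param Fi Matrix (`grid$n` x n_neurons) of tuning auxiliary values
#'   (default 0: constant tuning at rate C).
#' @return An object of class `sd_model`.
#' @export
latent_model <- function(grid, forces, D, F0 = NULL, C = numeric(0), Fi = NULL) {
  stopifnot_grid(grid)
  forces <- as.matrix(forces)
  dimnames(forces) <- NULL
  if (nrow(forces) != grid$n) stop("forces must have grid$n rows", call. = FALSE)
  if (!is.finite(D) || D <= 0) stop("D must be positive", call. = FALSE)
  if (is.null(F0)) F0 <- numeric(grid$n)
  C <- as.numeric(C)
  if (any(!is.finite(C)) || any(C < 0)) stop("all C must be >= 0", call. = FALSE)
  M <- length(C)
  if (is.null(Fi)) Fi <- matrix(0, grid$n, M)
  Fi <- as.matrix(Fi)
  dimnames(Fi) <- NULL
  if (M > 0L && (nrow(Fi) != grid$n || ncol(Fi) != M))
    stop("Fi must be grid$n x length(C)", call. = FALSE)
  structure(
    list(grid = grid, forces = forces, D = D, F0 = as.numeric(F0),
         C = C, Fi = Fi,
         n_conditions = ncol(forces), n_neurons = M),
    class = "sd_model")
}

is_model <- function(m) inherits(m, "sd_model")

#' @export
print.sd_model <- function(x, ...) {
  cat("Latent Langevin model:", x$n_conditions, "condition(s),",
      x$n_neurons, "neuron(s), D =", signif(x$D, 4),
      "on", x$grid$n, "nodes\n")
  invisible(x)
}

#' Reconstructed potential of one condition
#' @param model An `sd_model`.
#' @param condition Condition index.
#' @return Potential values at the grid nodes.
#' @export
model_potential <- function(model, condition = 1L) {
  force_to_potential(model$forces[, condition], model$grid)
}

#' Reconstructed initial-state density
#' @param model An `sd_model`.
#' @return Density values at the grid nodes.
#' @export
model_p0 <- function(model) aux_to_density(model$F0, model$grid)

#' Reconstructed tuning functions
#' @param model An `sd_model`.
#' @return Matrix (`grid$n` x n_neurons) of firing rates (Hz).
#' @export
model_tuning <- function(model) {
  M <- model$n_neurons
  out <- matrix(0, model$grid$n, max(M, 0L))
  for (i in seq_len(M)) out[, i] <- aux_to_tuning(model$Fi[, i], model$C[i], model$grid)
  out
}

#' Mirror a model across the latent midline
#'
#' The likelihood is exactly invariant under the reflection x -> -x of the
#' latent space (absorption collects both boundaries), so the orientation of
#' a fitted model is a gauge. This returns the reflected model: forces and
#' auxiliary functions reversed and negated, boundary rates moved to the
#' other end. Used to fix the gauge by the behavioural convention that the
#' right boundary (+1) is the right choice.
#'
#' @param model An `sd_model`.
#' @return The reflected `sd_model`.
#' @export
mirror_model <- function(model) {
  n <- model$grid$n
  rev_idx <- n:1
  tun <- model_tuning(model)
  model$forces <- -model$forces[rev_idx, , drop = FALSE]
  model$F0 <- -model$F0[rev_idx]
  model$Fi <- -model$Fi[rev_idx, , drop = FALSE]
  model$C <- tun[n, ]
  model
}

#' Count potential barriers from two data-split force estimates
#'
#' A barrier is a sign change of the force (a potential extremum). A change is
#' counted only where the force estimates from both data splits hold the
#' pre-change sign over a run of consecutive nodes on one side and the
#' post-change sign over an equally long run on the other side, and only at
#' interfaces far enough from the domain boundaries. The run length and
#' boundary margin are node counts (10 and 30 at the reference 256-node grid)
#' and scale proportionally with grid size.
#'
#' @param F_split1,F_split2 Force values on the same grid from the two splits.
#' @param grid An `sd_grid`.
#' @param run Consecutive-node run length required on each side
#'   (default `round(10 * n/256)`, at least 2).
#' @param margin Nodes next to each boundary where changes are ignored. The
#'   default covers the nodes within 30/255 of the domain length of each
#'   boundary (the extent of a 30-point strip on a 256-point uniform grid);
#'   on boundary-clustered grids a fixed node count would exclude a much
#'   narrower slice of the domain than intended.
#' @return Number of counted sign changes (non-negative integer).
#' @export
count_barriers <- function(F_split1, F_split2, grid, run = NULL, margin = NULL) {
  stopifnot_grid(grid)
  n <- grid$n
  if (is.null(run)) run <- max(2L, as.integer(round(10 * n / 256)))
  if (is.null(margin)) {
    x_cut <- 1 - 2 * 30 / 255
    margin <- max(run, sum(grid$nodes > x_cut))
  }
  if (n < 2L * (margin + run))
    stop("grid too short for the requested run/margin barrier-counting rule",
         call. = FALSE)
  if (length(F_split1) != n || length(F_split2) != n)
    stop("force arrays must live on the same grid", call. = FALSE)
  # Nodes where both split estimates agree on the sign, compressed into
  # maximal same-sign runs of sufficient length; a sign change is a pair of
  # adjacent opposite-sign runs whose separating region lies inside the
  # boundary margins.
  agree <- integer(n)
  agree[F_split1 > 0 & F_split2 > 0] <- 1L
  agree[F_split1 < 0 & F_split2 < 0] <- -1L
  r <- rle(agree)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L & r$lengths >= run
  sgn <- r$values[keep]; starts <- starts[keep]; ends <- ends[keep]
  count <- 0L
  if (length(sgn) >= 2L) {
    for (k in seq_len(length(sgn) - 1L)) {
      if (sgn[k + 1L] == sgn[k]) next
      if (ends[k] <= margin || starts[k + 1L] > n - margin) next
      count <- count + 1L
    }
  }
  count
}
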