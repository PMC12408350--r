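#' Assemble the modified Fokker--Planck generator for one condition
#'
#' Builds the linear operator H such that the latent density between spike
#' observations obeys dp/dt = -H p, with
#' H = D d/dx(F .) - D d^2/dx^2 + sum_i f_i(x). The drift and diffusion terms
#' describe the Langevin dynamics; the decay term sum_i f_i(x) removes
#' probability at the population firing rate, so the propagated density
#' includes only trajectories consistent with no spikes during the interval.
#' Densities are pinned to zero at both boundary nodes (absorbing boundary
#' conditions), and the absorption flux is read from the one-sided density
#' derivative at each boundary times D.
#'
#' @param model An `sd_model`.
#' @param condition Condition index (<= `model$n_conditions`).
#' @param include_decay If `FALSE`, the spike-decay term is omitted; this is
#'   the plain Fokker--Planck operator used for the reaction-time marginal
#'   likelihood that normalizes the full likelihood.
#' @return An object of class `sd_generator` holding the full-domain operator,
#'   its interior restriction, the eigendecomposition used for exact
#'   exp(-H dt) propagation, and the boundary-flux functionals.
#' @export
assemble_generator <- function(model, condition = 1L, include_decay = TRUE) {
  if (!is_model(model)) stop("expected sd_model", call. = FALSE)
  if (condition < 1L || condition > model$n_conditions)
    stop("condition out of range", call. = FALSE)
  g <- model$grid
  F <- model$forces[, condition]
  decay <- if (include_decay && model$n_neurons > 0) rowSums(model_tuning(model)) else numeric(g$n)
  Hfull <- model$D * (g$D1 %*% diag(F)) - model$D * g$D2 + diag(decay)
  int <- g$interior
  Hint <- Hfull[int, int]
  ed <- eigen(Hint)
  V <- ed$vectors
  structure(
    list(grid = g, D = model$D, F = F, decay = decay,
         Hfull = Hfull, Hint = Hint,
         V = V, Vinv = solve(V), mu = ed$values,
         aL = model$D * g$D1[1, int],
         aR = -model$D * g$D1[g$n, int],
         wint = g$weights[int], interior = int,
         include_decay = include_decay),
    class = "sd_generator")
}

is_generator <- function(x) inherits(x, "sd_generator")

#' Apply the generator to a density (full domain, no boundary conditions)
#'
#' Mainly a diagnostic: with the decay term off, H applied to exp(-Phi)
#' vanishes in the interior (the zero-flux solution of drift--diffusion).
#'
#' @param gen An `sd_generator`.
#' @param p Density values on the full grid.
#' @return H p on the full grid.
#' @export
generator_apply <- function(gen, p) {
  as.numeric(gen$Hfull %*% p)
}

#' Propagate a latent density over a time interval
#'
#' Solves dp/dt = -H p exactly via the eigendecomposition of the interior
#' generator: p(dt) = exp(-H dt) p(0). Boundary values are held at zero
#' (absorbing). Numerical negatives below -1e-12 times the density scale are
#' left untouched; tiny sign noise above that is clipped to zero without
#' rescaling the mass.
#'
#' @param p Density values on the full grid (or interior nodes).
#' @param dt Time interval in seconds (>= 0).
#' @param gen An `sd_generator`.
#' @return Propagated density on the full grid (boundary nodes zero).
#' @export
propagate <- function(p, dt, gen) {
  if (!is_generator(gen)) stop("expected sd_generator", call. = FALSE)
  if (!is.finite(dt) || dt < 0) stop("dt must be >= 0", call. = FALSE)
  g <- gen$grid
  full <- length(p) == g$n
  pin <- if (full) p[gen$interior] else p
  if (length(pin) != length(gen$interior)) stop("density has wrong length", call. = FALSE)
  if (dt == 0) return(p)
  q <- Re(gen$V %*% (exp(-gen$mu * dt) * (gen$Vinv %*% pin)))
  q <- as.numeric(q)
  tiny <- -1e-12 * max(abs(q), 1e-300)
  q[q < 0 & q > tiny] <- 0
  out <- numeric(g$n)
  out[gen$interior] <- q
  out
}

#' Boundary absorption weights
#'
#' Instantaneous probability flux into each absorbing boundary, the final
#' likelihood factor restricting trajectories to those terminating on a
#' boundary at the trial end.
#'
#' @param p Density values on the full grid (or interior nodes).
#' @param gen An `sd_generator`.
#' @return Named vector `c(left = , right = )` of non-negative flux weights.
#' @export
absorb <- function(p, gen) {
  if (!is_generator(gen)) stop("expected sd_generator", call. = FALSE)
  pin <- if (length(p) == gen$grid$n) p[gen$interior] else p
  c(left = max(sum(gen$aL * pin), 0), right = max(sum(gen$aR * pin), 0))
}
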