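#' Stationary ground state of the summed population
#'
#' In the equal-diffusion long-time regime the summed density
#' `w = n + a` solves the eigenproblem
#' `-eps^2 w'' = w (r_inf - N)`, i.e. `w` is the positive ground state of
#' the Schroedinger-type operator `-eps^2 Lap - r_inf` and `N` its principal
#' eigenvalue. Discretely, the function returns the largest-eigenvalue
#' eigenpair of `eps^2 Lap_h + diag(r_profile)` with the Neumann closure of
#' [neumann_laplacian()]. The boundary-weighted similarity transform makes
#' the operator symmetric, so a dense symmetric eigensolve applies and the
#' Perron eigenvector is strictly positive.
#'
#' The eigenvector is scaled so that its trapezoid integral equals the
#' eigenvalue `N_inf`: in the stationary problem the competition level is
#' simultaneously the eigenvalue and the total mass of `w`.
#'
#' @param r_profile Fitness values over the grid nodes (e.g. `r_inf` from a
#'   [fitness_profile()]).
#' @param epsilon Scaling parameter (`> 0`).
#' @param grid A [trait_grid()] with at least 3 nodes.
#' @param tol Maximal admissible relative operator residual.
#' @return An object of class `ground_state`: positive profile `w`,
#'   eigenvalue `N_inf`, achieved `residual`, and the inputs.
#' @examples
#' g <- trait_grid(4, M = 81)
#' gs <- ground_state(rep(0.8, g$M), 0.05, g)  # constant fitness: N_inf = 0.8
#' gs$N_inf
#' @export
ground_state <- function(r_profile, epsilon, grid, tol = 1e-8) {
  stopifnot(inherits(grid, "trait_grid"), length(r_profile) == grid$M)
  if (any(!is.finite(r_profile))) stop("r_profile must be finite")
  if (epsilon <= 0) stop("epsilon must be positive")
  M <- grid$M
  L <- as.matrix(neumann_laplacian(grid))
  A <- epsilon^2 * L + diag(r_profile)
  # trapezoid-weight similarity: S = W^{1/2} A W^{-1/2} is symmetric
  sw <- rep(1, M); sw[c(1, M)] <- sqrt(0.5)
  S <- sweep(sweep(A, 1, sw, `*`), 2, sw, `/`)
  S <- (S + t(S)) / 2  # scrub round-off asymmetry
  es <- eigen(S, symmetric = TRUE)
  lam <- es$values[1]
  v <- es$vectors[, 1] / sw
  if (sum(v) < 0) v <- -v
  if (any(v <= 0)) {
    # Perron vector of an irreducible operator; tiny negative round-off only
    if (min(v) < -1e-10 * max(v)) {
      stop(sprintf("ground-state eigenvector not positive (min relative %.3g)",
                   min(v) / max(v)))
    }
    v <- pmax(v, .Machine$double.xmin)
  }
  residual <- max(abs(A %*% v - lam * v)) / max(abs(v))
  if (residual > tol) {
    stop(sprintf("eigensolve residual %.3g exceeds tolerance %.3g", residual, tol))
  }
  mass <- trapz_mass(v, grid)
  if (lam > 0) {
    w <- v * (lam / mass)
  } else {
    warning("principal eigenvalue not positive; normalising to unit mass")
    w <- v / mass
  }
  structure(list(w = w, N_inf = lam, residual = residual,
                 epsilon = epsilon, grid = grid, r_profile = r_profile),
            class = "ground_state")
}

#' @export
print.ground_state <- function(x, ...) {
  pk <- argmax_fitness(x$w, x$grid)
  cat(sprintf("Ground state: N_inf = %.8f, peak at %.4f, residual %.2g (eps = %g)\n",
              x$N_inf, pk$trait, x$residual, x$epsilon))
  invisible(x)
}

#' Consistency of a long-time trajectory with the stationary ground state
#'
#' The time-dependent system is expected to relax, for equal diffusions and
#' long times, to the stationary profile `w` with total mass `N_inf`. This
#' reports the normalised `L1` distance between the terminal summed density
#' and `w`, and the gap between the terminal mass and `N_inf`. Both are
#' asymptotic statements, so no hard threshold is imposed; along a doubling
#' sequence of horizons both discrepancies should shrink.
#'
#' @param trajectory A [simulate_system()] result (run with `d1 = d2`).
#' @param gs A [ground_state()] on the same grid.
#' @return A list: `l1_distance` (`||(n+a)(t_end) - w||_L1 / N_inf`),
#'   `mass_gap` (`|N(t_end) - N_inf|`), `t_end`.
#' @export
stationary_consistency <- function(trajectory, gs) {
  stopifnot(inherits(trajectory, "trajectory"), inherits(gs, "ground_state"))
  grid <- trajectory$config$grid
  if (grid$M != gs$grid$M || grid$x_max != gs$grid$x_max) {
    stop("trajectory and ground state live on different grids")
  }
  summed <- trajectory$state$n + trajectory$state$a
  l1 <- trapz_mass(abs(summed - gs$w), grid) / abs(gs$N_inf)
  list(l1_distance = l1,
       mass_gap = abs(trajectory$N[length(trajectory$N)] - gs$N_inf),
       t_end = trajectory$state$t)
}
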