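#' Diffusion (mutation) coefficients of the two populations
#'
#' @param d1 Trait diffusion of the healthy population (trait^2/time).
#' @param d2 Trait diffusion of the adapted population. Adapted cells carry
#'   higher genomic instability, so `d2 > d1` is the biologically motivated
#'   regime, but any non-negative pair with `d1 + d2 > 0` is admissible.
#' @return An object of class `diffusion_pair`.
#' @export
diffusion_pair <- function(d1 = 1, d2 = 1) {
  if (d1 < 0 || d2 < 0) stop("diffusion coefficients must be non-negative")
  if (d1 == 0 && d2 == 0) stop("at least one diffusion coefficient must be positive")
  structure(list(d1 = d1, d2 = d2), class = "diffusion_pair")
}

# Discriminant-safe positive root of delta_j X^2 - b X - delta_i = 0,
# i.e. X = (b + sqrt(b^2 + 4 delta_i delta_j)) / (2 delta_j), computed with
# the conjugate form when b < 0 so the root stays positive and accurate
# when delta_i * delta_j << b^2.
pos_root <- function(b, delta_i, delta_j) {
  disc <- sqrt(b^2 + 4 * delta_i * delta_j)
  ifelse(b >= 0, (b + disc) / (2 * delta_j), 2 * delta_i / (disc - b))
}

#' Asymptotic population ratio root q
#'
#' The ratio of the two population densities equilibrates, trait by trait,
#' at the unique positive root of the quadratic
#' `P(X) = ((d_i - d_j) rho^2 + r_i - r_j) X + delta_i - delta_j X^2`.
#' For `which = 1` the root is the limiting healthy/adapted ratio `n1/n2`.
#'
#' @param field A `coefficient_field` (vectorised over its nodes), or `NULL`
#'   if the coefficient vectors are passed directly.
#' @param diff A [diffusion_pair()].
#' @param rho Trait-gradient value of the phase of the *other* population
#'   entering the quadratic (default 0; irrelevant when `d1 = d2`).
#' @param which Index `i` of the numerator population (1 or 2).
#' @param r1,r2,delta1,delta2 Optional explicit coefficient vectors
#'   overriding `field`.
#' @return Positive root(s) `q_i`, one per node.
#' @examples
#' g <- trait_grid(1, M = 5)
#' q_root(coefficient_field(g, 1, 1, 0.2, 0.05))  # sqrt(delta1/delta2) = 2
#' @export
q_root <- function(field = NULL, diff = diffusion_pair(), rho = 0, which = 1,
                   r1 = field$r1, r2 = field$r2,
                   delta1 = field$delta1, delta2 = field$delta2) {
  stopifnot(which %in% c(1, 2))
  if (which == 1) {
    ri <- r1; rj <- r2; di <- diff$d1; dj <- diff$d2
    delta_i <- delta1; delta_j <- delta2
  } else {
    ri <- r2; rj <- r1; di <- diff$d2; dj <- diff$d1
    delta_i <- delta2; delta_j <- delta1
  }
  if (any(delta_j <= 0)) stop("the denominator conversion coefficient must be strictly positive")
  b <- (di - dj) * rho^2 + (ri - rj)
  pos_root(b, delta_i, delta_j)
}

#' Hamiltonian fitness of the coupled pair
#'
#' Effective growth rate of the cooperating healthy/adapted pair at a trait:
#' the dominant eigenvalue contribution
#' `r_H = (r1 + r2 + sqrt(((d1 - d2) rho^2 + (r1 - r2))^2 + 4 delta1 delta2)) / 2`.
#' With equal diffusions the gradient term drops out and `r_H` is a pure
#' function of the trait; its maximiser is the trait that selection is
#' predicted to retain.
#'
#' @inheritParams q_root
#' @return `r_H` value(s), one per node.
#' @export
hamiltonian_fitness <- function(field = NULL, diff = diffusion_pair(), rho = 0,
                                r1 = field$r1, r2 = field$r2,
                                delta1 = field$delta1, delta2 = field$delta2) {
  b <- (diff$d1 - diff$d2) * rho^2 + (r1 - r2)
  (r1 + r2 + sqrt(b^2 + 4 * delta1 * delta2)) / 2
}

#' Effective Hamiltonian
#'
#' The principal eigenvalue of `rho^2 D + R(x, N)`, decomposed as
#' `H = (d1 + d2)/2 * rho^2 + r_H(x, rho) - N`.
#'
#' @inheritParams q_root
#' @param N Total-mass (competition) level.
#' @return Eigenvalue(s) `H`.
#' @export
hamiltonian <- function(field = NULL, diff = diffusion_pair(), rho = 0, N = 0,
                        r1 = field$r1, r2 = field$r2,
                        delta1 = field$delta1, delta2 = field$delta2) {
  (diff$d1 + diff$d2) / 2 * rho^2 +
    hamiltonian_fitness(diff = diff, rho = rho, r1 = r1, r2 = r2,
                        delta1 = delta1, delta2 = delta2) - N
}

#' Principal eigenpair of the coupled growth matrix
#'
#' Returns the dominant eigenvalue of
#' `rho^2 D + R(x, N)` together with its strictly positive eigenvector,
#' normalised so the first (healthy) component is 1. The second component is
#' the conjugate root `(-b + sqrt(b^2 + 4 delta1 delta2)) / (2 delta1)`
#' (with `b = (d1 - d2) rho^2 + r1 - r2`), i.e. the adapted/healthy ratio;
#' it is computed in a cancellation-safe form.
#'
#' @param x Trait value (scalar), used only when scalar coefficients are
#'   taken from `field` at the nearest node; otherwise pass coefficients
#'   directly.
#' @inheritParams hamiltonian
#' @return An object of class `spectral_point`: `H` (eigenvalue), `psi`
#'   (length-2 positive vector, first entry 1), `residual` (max-norm
#'   eigen-residual), and the inputs.
#' @export
principal_eigenvector <- function(field = NULL, diff = diffusion_pair(),
                                  rho = 0, N = 0, x = NULL,
                                  r1 = NULL, r2 = NULL,
                                  delta1 = NULL, delta2 = NULL) {
  if (is.null(r1)) {
    stopifnot(inherits(field, "coefficient_field"), !is.null(x))
    i <- which.min(abs(field$grid$nodes - x))
    r1 <- field$r1[i]; r2 <- field$r2[i]
    delta1 <- field$delta1[i]; delta2 <- field$delta2[i]
  }
  if (delta2 <= 0 || delta1 <= 0) {
    stop("conversion coefficients must be strictly positive for a positive eigenvector")
  }
  b <- (diff$d1 - diff$d2) * rho^2 + (r1 - r2)
  disc <- sqrt(b^2 + 4 * delta1 * delta2)
  psi2 <- if (b <= 0) (disc - b) / (2 * delta1) else 2 * delta2 / (disc + b)
  H <- (diff$d1 + diff$d2) / 2 * rho^2 + (r1 + r2 + disc) / 2 - N
  A <- rho^2 * diag(c(diff$d1, diff$d2)) +
    matrix(c(r1 - N, delta2, delta1, r2 - N), 2, 2)
  psi <- c(1, psi2)
  residual <- max(abs(A %*% psi - H * psi))
  structure(list(H = H, psi = psi, residual = residual,
                 rho = rho, N = N, diff = diff,
                 coefs = c(r1 = r1, r2 = r2, delta1 = delta1, delta2 = delta2)),
            class = "spectral_point")
}

#' @export
print.spectral_point <- function(x, ...) {
  cat(sprintf("Spectral point: H = %.8g, psi = (1, %.8g), residual = %.2g\n",
              x$H, x$psi[2], x$residual))
  invisible(x)
}

#' Stationary effective fitness
#'
#' Fitness of the summed population in the equal-diffusion long-time regime:
#' the `q`-weighted average
#' `r_inf = q/(1+q) (r1 + delta2) + 1/(1+q) (r2 + delta1)`,
#' which coincides nodewise with the Hamiltonian fitness at equal diffusions.
#'
#' @param field A `coefficient_field`.
#' @return Vector `r_inf` over the grid nodes.
#' @export
effective_fitness_r_inf <- function(field) {
  q <- q_root(field, diff = diffusion_pair(1, 1), rho = 0, which = 1)
  q / (1 + q) * (field$r1 + field$delta2) +
    1 / (1 + q) * (field$r2 + field$delta1)
}

#' Fitness profile over the trait grid
#'
#' Bundles, on the grid of a coefficient field, the ratio root `q`, the
#' Hamiltonian fitness `r_H`, and the stationary effective fitness `r_inf`.
#' With `d1 = d2` the gradient value `rho` is irrelevant and
#' `r_inf == r_H` nodewise.
#'
#' @param field A `coefficient_field`.
#' @param diff A [diffusion_pair()].
#' @param rho Gradient value assumed for the `rho`-dependent quantities
#'   (default 0).
#' @return An object of class `fitness_profile` with elements `grid`, `q`,
#'   `r_H`, `r_inf`, `rho_used`, `diff`.
#' @export
fitness_profile <- function(field, diff = diffusion_pair(1, 1), rho = 0) {
  stopifnot(inherits(field, "coefficient_field"))
  q <- q_root(field, diff = diff, rho = rho, which = 1)
  if (any(q <= 0)) stop("ratio root must be strictly positive")
  structure(
    list(grid = field$grid, q = q,
         r_H = hamiltonian_fitness(field, diff = diff, rho = rho),
         r_inf = effective_fitness_r_inf(field),
         rho_used = rho, diff = diff),
    class = "fitness_profile")
}

#' @export
print.fitness_profile <- function(x, ...) {
  pk <- argmax_fitness(x)
  cat(sprintf("Fitness profile on [0, %g] (M = %d): r_H in [%.4f, %.4f]\n",
              x$grid$x_max, x$grid$M, min(x$r_H), max(x$r_H)))
  cat(sprintf("  argmax r_H = %.4f%s\n", pk$trait,
              if (pk$boundary) " (boundary)" else ""))
  invisible(x)
}

# Three-point quadratic refinement of a discrete interior maximum.
quad_refine <- function(xm1, x0, xp1, fm1, f0, fp1) {
  denom <- fm1 - 2 * f0 + fp1
  if (denom >= 0) return(x0)  # not locally concave; keep the node
  x0 + 0.5 * (x0 - xm1) * (fm1 - fp1) / denom
}

#' Predicted selected trait: maximiser of the fitness profile
#'
#' Locates the maximiser of `r_H` on the grid, refined by fitting a parabola
#' through the three nodes around the discrete maximum. Ties are broken
#' towards the smallest trait value; a maximum attained at a domain end is
#' reported with a boundary flag (an increasing profile on a bounded grid
#' signals selection pushing the trait towards the right end), and an
#' essentially flat profile with a flatness flag.
#'
#' @param profile A `fitness_profile`, or a numeric vector of fitness values
#'   (then `grid` must be given).
#' @param grid A [trait_grid()] when `profile` is a bare vector.
#' @param flat_tol Relative range below which the profile is declared flat.
#' @return A list: `trait` (refined maximiser), `value`, `index` (discrete
#'   argmax node), `boundary`, `flat`.
#' @export
argmax_fitness <- function(profile, grid = NULL, flat_tol = 1e-12) {
  if (inherits(profile, "fitness_profile")) {
    vals <- profile$r_H
    grid <- profile$grid
  } else {
    vals <- profile
    stopifnot(inherits(grid, "trait_grid"), length(vals) == grid$M)
  }
  rng <- max(vals) - min(vals)
  flat <- rng <= flat_tol * max(abs(vals), 1)
  i <- which.max(vals)          # leftmost maximum on ties
  x <- grid$nodes
  if (flat || i == 1 || i == grid$M) {
    return(list(trait = x[i], value = vals[i], index = i,
                boundary = (i == 1 || i == grid$M) && !flat, flat = flat))
  }
  xr <- quad_refine(x[i - 1], x[i], x[i + 1],
                    vals[i - 1], vals[i], vals[i + 1])
  xr <- min(max(xr, x[i - 1]), x[i + 1])
  list(trait = xr, value = vals[i], index = i, boundary = FALSE, flat = flat)
}
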