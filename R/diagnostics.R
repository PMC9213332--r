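#' Hopf-Cole (logarithmic phase) field of a density
#'
#' Transforms a trait density into the order-one phase `u = eps * log(n)`.
#' Exponentially concentrated densities become smooth phase functions whose
#' zero set carries the surviving traits in the small-`eps` limit. Densities
#' below `floor` are floored before the logarithm so the field stays finite
#' at numerical zero.
#'
#' @param density Non-negative density values over the grid.
#' @param epsilon Scaling parameter.
#' @param floor Density floor applied before the logarithm.
#' @return An object of class `hopf_cole_field`: `u`, `epsilon`, `floor`.
#' @examples
#' x <- seq(0, 1, 0.01)
#' hc <- hopf_cole(exp(-(x - 0.5)^2 / 0.01), 0.01)
#' max(hc$u)  # ~ 0 at the peak
#' @export
hopf_cole <- function(density, epsilon, floor = 1e-300) {
  if (any(density < 0)) stop("density must be non-negative")
  structure(list(u = epsilon * log(pmax(density, floor)),
                 epsilon = epsilon, floor = floor),
            class = "hopf_cole_field")
}

# Active-region mask: nodes where a density is meaningfully above numerical
# zero (relative threshold; Hopf-Cole phases are meaningless below it).
active_region <- function(density, rel = 1e-30) {
  density > rel * max(density)
}

#' Sup-distance between the population ratio and its predicted limit
#'
#' For equal diffusions the ratio `n/a` converges, trait by trait, to the
#' root `q(x)`; this measures `sup |n/a - q|` over a trait window
#' (default `[0, 10]`). The sup is taken over the mass-carrying region:
#' nodes whose adapted density exceeds `active_rel` times its maximum,
#' with `active_rel` defaulting to square-root machine precision (about
#' 1.5e-8) so that the compared ratios retain at least half the double
#' mantissa. Far below that threshold the ratio measures a slowly
#' equilibrating O(epsilon) phase-transport layer rather than the local
#' equilibrium, and the sup saturates near `2 * epsilon`; pass a smaller
#' `active_rel` to probe that layer deliberately. Window nodes below the
#' threshold are excluded and reported.
#'
#' @param state A [population_state()].
#' @param profile A [fitness_profile()] providing `q` on the same grid.
#' @param window Length-2 trait interval over which the sup is taken.
#' @param active_rel Relative density threshold defining the active region.
#' @return The sup-distance, with attributes `n_excluded` (number of window
#'   nodes dropped) and `excluded_range` (trait range of the dropped nodes,
#'   `NULL` if none).
#' @export
ratio_distance <- function(state, profile, window = c(0, 10),
                           active_rel = sqrt(.Machine$double.eps)) {
  grid <- profile$grid
  if (length(state$n) != grid$M) stop("state and profile grids differ")
  in_win <- grid$nodes >= window[1] & grid$nodes <= window[2]
  alive <- active_region(state$a, active_rel)
  use <- in_win & alive
  if (!any(use)) stop("adapted density numerically zero on the whole window")
  d <- max(abs(state$n[use] / state$a[use] - profile$q[use]))
  dropped <- in_win & !alive
  attr(d, "n_excluded") <- sum(dropped)
  attr(d, "excluded_range") <- if (any(dropped)) range(grid$nodes[dropped]) else NULL
  d
}

#' Check the phase gap against the theoretical ratio band
#'
#' For any positive time the difference of the two Hopf-Cole phases is
#' predicted to lie in the band `eps * (log q +/- eps^4 / t)`. The bound is
#' asymptotic, so this is a diagnostic: it reports the worst excess of
#' `|u1 - u2 - eps log q|` over the half band width `eps^5 / t`, measured on
#' the active region of both densities.
#'
#' @param u1,u2 [hopf_cole()] fields of the two densities (same `epsilon`).
#' @param profile A [fitness_profile()] providing `q`.
#' @param t Positive time of the snapshot.
#' @param active_rel Relative threshold defining the active region (applied
#'   to `exp(u/eps)` implicitly through the phases: nodes within
#'   `eps * log(active_rel)` of the phase maximum).
#' @return A list: `excess` (worst excess beyond the band, 0 if inside),
#'   `band_half_width` (`eps^5 / t`), `n_active`.
#' @export
ratio_band_check <- function(u1, u2, profile, t, active_rel = 1e-30) {
  if (t <= 0) stop("the ratio band is defined for positive times only")
  if (u1$epsilon != u2$epsilon) stop("phase fields have different epsilon")
  eps <- u1$epsilon
  cutoff <- eps * log(active_rel)
  act <- (u1$u - max(u1$u) > cutoff) & (u2$u - max(u2$u) > cutoff)
  if (!any(act)) stop("no active nodes shared by the two phase fields")
  gap <- u1$u[act] - u2$u[act] - eps * log(profile$q[act])
  half <- eps^5 / t
  list(excess = max(0, max(abs(gap)) - half),
       band_half_width = half, n_active = sum(act))
}

#' Concentration summary of a trait density
#'
#' Location and width statistics used to monitor Dirac concentration: the
#' interpolated peak (three-point quadratic refinement at the discrete
#' maximum, leftmost on ties), the mass-weighted mean and standard
#' deviation, and the mass fraction in the terminal 5% of the domain (a
#' right-boundary contamination monitor).
#'
#' @param state A [population_state()] (the summed density `n + a` is
#'   used), or a bare non-negative density vector.
#' @param grid The [trait_grid()].
#' @return A list: `peak`, `mean`, `spread`, `mass_tail`.
#' @export
concentration <- function(state, grid) {
  v <- if (inherits(state, "population_state")) state$n + state$a else state
  stopifnot(length(v) == grid$M)
  mass <- trapz_mass(v, grid)
  if (mass <= 0) stop("zero total mass")
  pk <- argmax_fitness(v, grid)
  x <- grid$nodes
  wts <- rep(grid$h, grid$M); wts[c(1, grid$M)] <- grid$h / 2
  m1 <- sum(wts * x * v) / mass
  m2 <- sum(wts * (x - m1)^2 * v) / mass
  tail_idx <- x >= grid$x_max * 0.95
  list(peak = pk$trait, mean = m1, spread = sqrt(max(m2, 0)),
       mass_tail = sum(wts[tail_idx] * v[tail_idx]) / mass)
}

#' Check a recorded mass series against the structural bounds
#'
#' Flags every recorded total mass lying outside `[c_N - tol, C_N + tol]`
#' and reports the worst excursion and its time. Initial data whose mass
#' starts outside the bracket (admissible data start inside it) can be
#' accommodated by excluding a declared transient.
#'
#' @param trajectory A [simulate_system()] result.
#' @param report An `assumption_report` (from [validate_assumptions()]).
#' @param tol Tolerance added on both sides of the bracket.
#' @param transient Initial time span excluded from the check (default 0).
#' @return A list: `c_N`, `C_N`, `tol`, `n_violations`, `worst_excess`
#'   (0 when the series stays inside), `worst_time`, `transient`.
#' @export
mass_bounds_check <- function(trajectory, report, tol = 0.05, transient = 0) {
  stopifnot(inherits(report, "assumption_report"))
  keep <- trajectory$times >= transient
  tt <- trajectory$times[keep]
  NN <- trajectory$N[keep]
  excess <- pmax(report$c_N - tol - NN, NN - report$C_N - tol, 0)
  worst <- which.max(excess)
  list(c_N = report$c_N, C_N = report$C_N, tol = tol,
       n_violations = sum(excess > 0),
       worst_excess = excess[worst],
       worst_time = if (excess[worst] > 0) tt[worst] else NA_real_,
       transient = transient)
}
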