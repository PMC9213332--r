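#' Uniform trait grid
#'
#' Uniform partition of `[0, x_max]` including both endpoints. The default
#' domain length 12 is large enough that, for fast-decaying initial data,
#' the right boundary is never felt by the solution.
#'
#' @param x_max Domain length (trait units).
#' @param M Number of nodes (including both ends); alternatively give `h`.
#' @param h Grid spacing; ignored when `M` is supplied.
#' @return An object of class `trait_grid` with fields `x_max`, `M`,
#'   `nodes`, `h`.
#' @examples
#' g <- trait_grid(12, h = 0.01)
#' g$M
#' @export
trait_grid <- function(x_max = 12, M = NULL, h = 0.01) {
  if (x_max <= 0) stop("x_max must be positive")
  if (is.null(M)) {
    M <- round(x_max / h) + 1
    if (!isTRUE(all.equal(x_max / (M - 1), h))) {
      # keep the exact domain; adjust h to fit
      h <- x_max / (M - 1)
    }
  }
  if (M < 2) stop("grid needs at least 2 nodes")
  structure(list(x_max = x_max, M = as.integer(M),
                 nodes = seq(0, x_max, length.out = M),
                 h = x_max / (M - 1)),
            class = "trait_grid")
}

#' @export
print.trait_grid <- function(x, ...) {
  cat(sprintf("Trait grid [0, %g], M = %d, h = %g\n", x$x_max, x$M, x$h))
  invisible(x)
}

#' Discrete Laplacian with homogeneous Neumann closure
#'
#' Standard second-difference operator on the grid with reflecting
#' (mirror ghost-node) closure at both ends, so a zero-flux boundary is
#' enforced and constants are annihilated exactly. The operator is
#' symmetric with respect to the trapezoid inner product (boundary nodes
#' weighted 1/2), which preserves discrete integration by parts.
#'
#' @param grid A [trait_grid()] with at least 3 nodes.
#' @return A sparse `M x M` matrix (class `dgCMatrix`).
#' @export
neumann_laplacian <- function(grid) {
  stopifnot(inherits(grid, "trait_grid"))
  M <- grid$M
  if (M < 3) stop("need at least 3 nodes for a second-difference operator")
  h2 <- grid$h^2
  i <- c(seq_len(M), 2:M, 1:(M - 1))
  j <- c(seq_len(M), 1:(M - 1), 2:M)
  v <- c(rep(-2, M), rep(1, M - 1), rep(1, M - 1))
  L <- Matrix::sparseMatrix(i = i, j = j, x = v, dims = c(M, M))
  # mirror ghosts: L[1,2] and L[M,M-1] double
  L[1, 2] <- 2
  L[M, M - 1] <- 2
  L / h2
}

#' Population state on the trait grid
#'
#' @param n Healthy-cell density over the nodes.
#' @param a Adapted-cell density over the nodes.
#' @param t Time stamp.
#' @return An object of class `population_state`.
#' @export
population_state <- function(n, a, t = 0) {
  if (length(n) != length(a)) stop("n and a must have the same length")
  if (any(!is.finite(n)) || any(!is.finite(a))) stop("densities must be finite")
  structure(list(n = n, a = a, t = t), class = "population_state")
}

#' Total mass of a population state
#'
#' Trapezoid quadrature of `n + a` over the trait domain; this is the
#' non-local competition level `N(t)` penalising growth equally across
#' traits.
#'
#' @param state A [population_state()].
#' @param grid The [trait_grid()] the state lives on.
#' @return Positive total mass.
#' @export
total_mass <- function(state, grid) {
  trapz_mass(state$n + state$a, grid)
}

trapz_mass <- function(v, grid) {
  h <- grid$h
  h * (sum(v) - 0.5 * (v[1] + v[length(v)]))
}

#' Solver configuration for the scaled two-population system
#'
#' @param epsilon Scaling parameter of the rare-mutation regime (`> 0`).
#' @param diff A [diffusion_pair()].
#' @param grid A [trait_grid()].
#' @param dt Time step; defaults to `epsilon` (the explicit reaction terms
#'   require `dt` of the order of `epsilon`).
#' @param t_end Simulation horizon (rescaled time).
#' @param env An [env_spec()] (used in `coefficient_mode = "time_varying_r1"`).
#' @param coefficient_mode `"static"` for frozen coefficients, or
#'   `"time_varying_r1"` to modulate the repair inflow of `r1` by
#'   `abar(t) / alpha_m` each step (the numerically tractable periodic-
#'   environment variant).
#' @param snapshot_times Times at which full `(n, a)` snapshots are stored.
#' @param thin Record `N(t)` and diagnostics every `thin`-th step.
#' @param dt_band Allowed band for `dt / epsilon`; outside it the solver
#'   refuses to run (override by widening the band).
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(epsilon, diff = diffusion_pair(), grid = trait_grid(),
                          dt = NULL, t_end = 1, env = env_spec(),
                          coefficient_mode = c("static", "time_varying_r1"),
                          snapshot_times = numeric(0), thin = 1L,
                          dt_band = c(0.05, 20)) {
  coefficient_mode <- match.arg(coefficient_mode)
  if (epsilon <= 0) stop("epsilon must be positive")
  if (is.null(dt)) dt <- epsilon
  if (dt <= 0) stop("dt must be positive")
  ratio <- dt / epsilon
  if (ratio < dt_band[1] || ratio > dt_band[2]) {
    stop(sprintf(
      "dt/epsilon = %.3g outside the stability band [%g, %g]; pick dt of the order of epsilon or widen dt_band",
      ratio, dt_band[1], dt_band[2]))
  }
  if (t_end < 0) stop("t_end must be non-negative")
  structure(list(epsilon = epsilon, diff = diff, grid = grid, dt = dt,
                 t_end = t_end, env = env,
                 coefficient_mode = coefficient_mode,
                 snapshot_times = sort(snapshot_times), thin = as.integer(thin),
                 dt_band = dt_band),
            class = "solver_config")
}

# Pre-factorised Crank-Nicolson operators for both populations.
cn_operators <- function(config) {
  grid <- config$grid
  L <- neumann_laplacian(grid)
  I <- Matrix::Diagonal(grid$M)
  mk <- function(d) {
    c0 <- config$epsilon * d * config$dt / 2
    list(expl = I + c0 * L,
         impl = Matrix::lu(I - c0 * L))
  }
  list(p1 = mk(config$diff$d1), p2 = mk(config$diff$d2))
}

# r1 vector at time t under the active coefficient mode. In the
# time-varying variant the static repair-probability integral is scaled by
# abar(t) / alpha_m, so a hostile environment (abar = 0) suppresses the
# repair inflow entirely.
r1_at_time <- function(field, config, t) {
  if (config$coefficient_mode == "static") return(field$r1)
  if (is.null(field$repair_prob) || is.null(field$bio)) {
    stop("time_varying_r1 mode needs a field built by effective_coefficients()")
  }
  modulation <- alpha_bar(config$env, t) / field$bio$alpha_m
  1 - field$bio$damage + modulation * field$bio$damage * field$repair_prob
}

#' One Crank-Nicolson / explicit-reaction step
#'
#' Advances the pair `(n, a)` by one time step of the scheme: the trait
#' Laplacians are treated by Crank-Nicolson, all reaction terms (growth,
#' competition through the pre-step total mass `N`, and the conversion
#' coupling) explicitly:
#' `(n' - n)/dt = eps*d1*(Lap n' + Lap n)/2 + (1/eps)(n (r1 - N) + delta1 a)`
#' and symmetrically for `a`.
#'
#' @param state A [population_state()].
#' @param field A `coefficient_field` on the same grid.
#' @param config A [solver_config()].
#' @param ops Pre-factorised operators from an internal cache; built on the
#'   fly when omitted (convenient for single-step use, wasteful in loops —
#'   use [simulate_system()] for full runs).
#' @return The advanced [population_state()].
#' @export
pde_step <- function(state, field, config, ops = NULL) {
  if (is.null(ops)) ops <- cn_operators(config)
  eps <- config$epsilon
  dt <- config$dt
  N <- total_mass(state, config$grid)
  r1 <- r1_at_time(field, config, state$t)
  rn <- state$n * (r1 - N) + field$delta1 * state$a
  ra <- state$a * (field$r2 - N) + field$delta2 * state$n
  n_new <- as.numeric(Matrix::solve(
    ops$p1$impl, ops$p1$expl %*% state$n + (dt / eps) * rn))
  a_new <- as.numeric(Matrix::solve(
    ops$p2$impl, ops$p2$expl %*% state$a + (dt / eps) * ra))
  if (any(!is.finite(n_new)) || any(!is.finite(a_new))) {
    stop(sprintf("non-finite density produced at t = %g; reduce dt or epsilon ratio",
                 state$t + dt))
  }
  population_state(n_new, a_new, state$t + dt)
}

#' Integrate the scaled two-population system
#'
#' Runs the Crank-Nicolson / explicit-reaction scheme from an initial state
#' to `t_end`, recording the total mass and concentration diagnostics along
#' the run and full snapshots at the requested times. On completion the
#' recorded mass series is checked against the structural bounds
#' `[c_N, C_N]` from [validate_assumptions()] (fields built by hand, where
#' the closed bracket is unavailable, still use the numeric constants).
#'
#' @param config A [solver_config()].
#' @param field A `coefficient_field` on `config$grid`.
#' @param init A [population_state()]; defaults to [default_initial()] on
#'   the grid.
#' @param validate Run [validate_assumptions()] before integrating
#'   (default `TRUE`); set `FALSE` to integrate fields that violate the
#'   structural hypotheses deliberately.
#' @param neg_tol Tolerated negative undershoot relative to the state
#'   maximum before a warning is emitted.
#' @return An object of class `trajectory`: recorded `times`, `N`, `peak`,
#'   `spread`, `mass_tail`, `snapshots` (list of states), terminal `state`,
#'   the `config`, the assumption `report`, and `bounds` (from
#'   [mass_bounds_check()]).
#' @export
simulate_system <- function(config, field, init = NULL, validate = TRUE,
                            neg_tol = 1e-12) {
  stopifnot(inherits(config, "solver_config"),
            inherits(field, "coefficient_field"))
  grid <- config$grid
  if (field$grid$M != grid$M || field$grid$x_max != grid$x_max) {
    stop("coefficient field and solver grid differ")
  }
  if (is.null(init)) init <- default_initial(grid)
  if (length(init$n) != grid$M) stop("initial state not on the solver grid")
  report <- if (validate) validate_assumptions(field) else NULL

  n_steps <- if (config$t_end == 0) 0L else ceiling(config$t_end / config$dt - 1e-9)
  ops <- if (n_steps > 0) cn_operators(config) else NULL

  rec_idx <- if (n_steps == 0) integer(0) else seq(0L, n_steps, by = config$thin)
  if (n_steps > 0 && rec_idx[length(rec_idx)] != n_steps) {
    rec_idx <- c(rec_idx, n_steps)
  }
  if (n_steps == 0) rec_idx <- 0L
  n_rec <- length(rec_idx)
  times <- Ns <- peaks <- spreads <- tails <- numeric(n_rec)

  snaps <- list()
  snap_left <- config$snapshot_times
  state <- init
  worst_neg <- 0
  k_rec <- 1L
  record <- function(state, k_rec) {
    conc <- concentration(state, grid)
    times[k_rec] <<- state$t
    Ns[k_rec] <<- total_mass(state, grid)
    peaks[k_rec] <<- conc$peak
    spreads[k_rec] <<- conc$spread
    tails[k_rec] <<- conc$mass_tail
  }
  record(state, k_rec)
  if (length(snap_left) && snap_left[1] <= state$t + 1e-12) {
    snaps[[length(snaps) + 1L]] <- state
    snap_left <- snap_left[-1]
  }
  if (n_steps > 0) {
    ptr <- 2L  # rec_idx[1] == 0 is the initial record
    for (k in seq_len(n_steps)) {
      state <- pde_step(state, field, config, ops)
      worst_neg <- min(worst_neg, min(state$n), min(state$a))
      if (ptr <= n_rec && k == rec_idx[ptr]) {
        k_rec <- k_rec + 1L
        record(state, k_rec)
        ptr <- ptr + 1L
      }
      while (length(snap_left) && snap_left[1] <= state$t + 1e-12) {
        snaps[[length(snaps) + 1L]] <- state
        snap_left <- snap_left[-1]
      }
    }
  }
  scale <- max(max(state$n), max(state$a), 1e-300)
  if (worst_neg < -neg_tol * scale) {
    warning(sprintf("negative density undershoot %.3g (relative %.3g)",
                    worst_neg, worst_neg / scale))
  }
  tail_mass <- tails[n_rec]
  if (is.finite(tail_mass) && tail_mass > 1e-8) {
    warning(sprintf(
      "terminal 5%% of the domain holds %.3g of the mass; enlarge x_max",
      tail_mass))
  }
  traj <- structure(
    list(times = times, N = Ns, peak = peaks, spread = spreads,
         mass_tail = tails, snapshots = snaps, state = state,
         config = config, report = report, worst_negative = worst_neg,
         bounds = NULL),
    class = "trajectory")
  if (!is.null(report)) {
    traj$bounds <- mass_bounds_check(traj, report)
  }
  traj
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: t in [0, %g], eps = %g, d = (%g, %g), %d records\n",
              x$times[length(x$times)], x$config$epsilon,
              x$config$diff$d1, x$config$diff$d2, length(x$times)))
  cat(sprintf("  terminal N = %.6f, peak = %.4f, spread = %.4f\n",
              x$N[length(x$N)], x$peak[length(x$peak)],
              x$spread[length(x$spread)]))
  if (!is.null(x$bounds)) {
    cat(sprintf("  mass bounds [%.4f, %.4f]: worst excursion %.3g\n",
                x$bounds$c_N, x$bounds$C_N, x$bounds$worst_excess))
  }
  invisible(x)
}
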