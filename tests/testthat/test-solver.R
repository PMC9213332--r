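test_that("Neumann Laplacian annihilates constants and has cosine eigenpairs", {
  g <- trait_grid(2, M = 41)
  L <- neumann_laplacian(g)
  expect_equal(as.numeric(L %*% rep(3, g$M)), rep(0, g$M))
  # cosine modes are exact discrete eigenvectors of the mirror closure
  for (k in c(1, 3, 7)) {
    v <- cos(pi * k * g$nodes / g$x_max)
    lam <- -(2 / g$h^2) * (1 - cos(pi * k * g$h / g$x_max))
    expect_equal(as.numeric(L %*% v), lam * v, tolerance = 1e-10)
  }
  # interior second difference of a quadratic is exactly 2
  w <- as.numeric(L %*% g$nodes^2)
  expect_equal(w[2:(g$M - 1)], rep(2, g$M - 2), tolerance = 1e-9)
  expect_error(neumann_laplacian(trait_grid(1, M = 2)), "at least 3")
})

test_that("stepping preserves the zero state and exchange symmetry", {
  g <- trait_grid(12, M = 121)
  fld <- flat_field(g, r1 = 0.8, r2 = 0.8, d1 = 0.1, d2 = 0.1)
  cfg <- solver_config(0.05, diffusion_pair(1, 1), g, t_end = 1)
  z <- population_state(rep(0, g$M), rep(0, g$M))
  z1 <- pde_step(z, fld, cfg)
  expect_equal(z1$n, rep(0, g$M))
  expect_equal(z1$a, rep(0, g$M))
  # symmetric system + identical initial data: n and a stay equal
  st <- default_initial(g)
  for (k in 1:10) st <- pde_step(st, fld, cfg)
  expect_equal(st$n, st$a, tolerance = 1e-14)
})

test_that("uniform states follow the reduced two-ODE dynamics", {
  skip_if_not_installed("deSolve")
  g <- trait_grid(12, M = 121)
  r1 <- 0.9; r2 <- 0.6; de1 <- 0.05; de2 <- 0.07; eps <- 0.01
  fld <- flat_field(g, r1, r2, de1, de2)
  cfg <- solver_config(eps, diffusion_pair(1, 1), g, dt = eps / 5, t_end = 1)
  st <- population_state(rep(0.02, g$M), rep(0.01, g$M))
  # (the boundary-tail monitor fires for a uniform state; that is expected)
  traj <- suppressWarnings(simulate_system(cfg, fld, st, validate = FALSE))
  # uniformity is preserved (x-independent coefficients, Neumann walls)
  expect_lt(diff(range(traj$state$n)), 1e-12 * max(traj$state$n))
  # adaptive stiff oracle for eps u' = u (r - N) + delta v coupling
  ode_rhs <- function(t, y, parms) {
    N <- (y[1] + y[2]) * g$x_max
    list(c((y[1] * (r1 - N) + de1 * y[2]) / eps,
           (y[2] * (r2 - N) + de2 * y[1]) / eps))
  }
  sol <- deSolve::ode(c(0.02, 0.01), c(0, 1), ode_rhs, NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  expect_equal(traj$state$n[1], unname(sol[2, 2]), tolerance = 1e-6)
  expect_equal(traj$state$a[1], unname(sol[2, 3]), tolerance = 1e-6)
})

test_that("total mass is the trapezoid integral of the summed densities", {
  g <- trait_grid(12, h = 0.01)
  expect_equal(total_mass(population_state(rep(0.3, g$M), rep(0.2, g$M)), g),
               0.5 * 12)
  # unit hat supported away from the walls
  hat <- pmax(0, 1 - abs(g$nodes - 6)) / 1  # integral 1
  expect_equal(total_mass(population_state(hat, 0 * hat), g), 1,
               tolerance = 1e-12)
  # reference Gaussian pair: closed-form integral 2 * 0.2 * sqrt(pi/10)
  expect_equal(total_mass(default_initial(g), g), 0.4 * sqrt(pi / 10),
               tolerance = 1e-6)
})

test_that("simulate records series, snapshots, and the mass-bound report", {
  g <- medium_grid()
  fld <- medium_field()
  cfg0 <- solver_config(0.05, diffusion_pair(1, 1), g, t_end = 0)
  tr0 <- simulate_system(cfg0, fld)
  expect_length(tr0$times, 1)
  expect_equal(tr0$times, 0)
  cfg <- solver_config(0.05, diffusion_pair(1, 1), g, t_end = 1,
                       snapshot_times = c(0.5, 1))
  rep <- validate_assumptions(fld)
  init <- initial_state(g, total_mass = rep$c_N)  # admissible starting mass
  tr <- simulate_system(cfg, fld, init)
  expect_length(tr$snapshots, 2)
  expect_equal(tr$snapshots[[1]]$t, 0.5, tolerance = 1e-9)
  expect_true(all(diff(tr$times) > 0))
  expect_equal(tr$bounds$worst_excess, 0)
  expect_true(all(tr$N >= rep$c_N - 0.05 & tr$N <= rep$C_N + 0.05))
})

test_that("dt ratio guard and grid mismatch are rejected", {
  g <- trait_grid(12, M = 61)
  expect_error(solver_config(0.01, grid = g, dt = 1), "stability band")
  fld <- small_field()
  cfg <- solver_config(0.05, diffusion_pair(1, 1), trait_grid(12, M = 31),
                       t_end = 0.1)
  expect_error(simulate_system(cfg, fld), "grid")
})

test_that("self-convergence: order one overall, order two for pure diffusion", {
  g <- trait_grid(12, M = 241)
  fld <- effective_coefficients(g, bio_params(), ds = 0.05)
  eps <- 0.05
  run_dt <- function(dt, field = fld, validate = TRUE) {
    cfg <- solver_config(eps, diffusion_pair(1, 1), g, dt = dt, t_end = 0.5,
                         dt_band = c(1e-3, 20))
    simulate_system(cfg, field, default_initial(g), validate = validate)$state
  }
  s1 <- run_dt(eps);      s2 <- run_dt(eps / 2)
  s3 <- run_dt(eps / 4)
  e12 <- max(abs(s1$n - s2$n), abs(s1$a - s2$a))
  e23 <- max(abs(s2$n - s3$n), abs(s2$a - s3$a))
  expect_gt(e12 / e23, 1.6)   # ~2 for first order
  expect_lt(e12 / e23, 2.6)
  # reaction-free subproblem: with zero coefficients and zero total mass
  # (antisymmetric pair) every reaction term vanishes identically and the
  # update is pure Crank-Nicolson, which is second order in dt
  zf <- coefficient_field(g, 0, 0, 0, 0)
  v <- 0.2 * exp(-10 * (g$nodes - 5)^2)
  diffuse <- function(dt) {
    cfg <- solver_config(eps, diffusion_pair(1, 1), g, dt = dt, t_end = 0.5,
                         dt_band = c(1e-3, 20))
    st <- population_state(v, -v)
    for (k in seq_len(ceiling(0.5 / dt))) st <- pde_step(st, zf, cfg)
    st
  }
  z1 <- diffuse(eps); z2 <- diffuse(eps / 2); z3 <- diffuse(eps / 4)
  f12 <- max(abs(z1$n - z2$n))
  f23 <- max(abs(z2$n - z3$n))
  expect_gt(f12 / f23, 3)     # ~4 for second order
  expect_lt(f12 / f23, 5)
})

test_that("enlarging the domain does not move the solution", {
  bio <- bio_params()
  fld12 <- effective_coefficients(trait_grid(12, h = 0.05), bio, ds = 0.05)
  fld16 <- effective_coefficients(trait_grid(16, h = 0.05), bio, ds = 0.05)
  run <- function(fld) {
    g <- fld$grid
    cfg <- solver_config(0.05, diffusion_pair(1, 1), g, t_end = 0.5)
    simulate_system(cfg, fld, default_initial(g))
  }
  t12 <- run(fld12); t16 <- run(fld16)
  expect_lt(max(abs(t12$N - t16$N)), 1e-8)
  M12 <- fld12$grid$M
  expect_lt(max(abs(t12$state$n - t16$state$n[seq_len(M12)])), 1e-8)
})

test_that("time-varying repair inflow follows the environment", {
  g <- trait_grid(12, M = 61)
  bio <- bio_params(trait_mode = "heterogeneity_p", fixed_trait = 4)
  fld <- effective_coefficients(g, bio, ds = 0.05)
  # hostile environment suppresses the repair inflow entirely: r1 = 1 - D
  cfg_h <- solver_config(0.05, diffusion_pair(1, 1), g, t_end = 1,
                         env = env_spec("constant", level = 0),
                         coefficient_mode = "time_varying_r1")
  st <- default_initial(g)
  st1 <- pde_step(st, fld, cfg_h)
  # compare against a static field with r1 frozen at 1 - D
  fld_frozen <- fld
  fld_frozen$r1 <- rep(1 - bio$damage, g$M)
  cfg_s <- solver_config(0.05, diffusion_pair(1, 1), g, t_end = 1)
  st1s <- pde_step(st, fld_frozen, cfg_s)
  expect_equal(st1$n, st1s$n, tolerance = 1e-14)
  # favourable environment at full level reproduces the static run
  cfg_f <- solver_config(0.05, diffusion_pair(1, 1), g, t_end = 1,
                         env = env_spec("constant", level = 0.5),
                         coefficient_mode = "time_varying_r1")
  expect_equal(pde_step(st, fld, cfg_f)$n, pde_step(st, fld, cfg_s)$n,
               tolerance = 1e-14)
  # hand-built fields cannot run the time-varying mode
  cf <- coefficient_field(g, 1, 0.6, 0.05, 0.07)
  expect_error(pde_step(st, cf, cfg_f), "effective_coefficients")
})
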