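# Bisection oracle for the positive root of
# P(X) = b X + delta_i - delta_j X^2 on [0, upper].
bisect_q <- function(b, delta_i, delta_j, upper = 1e8, tol = 1e-14) {
  P <- function(X) b * X + delta_i - delta_j * X^2
  lo <- 0; hi <- upper
  stopifnot(P(lo) > 0, P(hi) < 0)
  for (k in 1:200) {
    mid <- (lo + hi) / 2
    if (P(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol * max(1, mid)) break
  }
  (lo + hi) / 2
}

test_that("ratio root solves its quadratic and matches a bisection oracle", {
  g <- trait_grid(1, M = 5)
  # symmetric quadratic: q = sqrt(delta1/delta2)
  expect_equal(q_root(coefficient_field(g, 1, 1, 0.2, 0.05)), rep(2, 5))
  expect_equal(q_root(coefficient_field(g, 1, 1, 0.3, 0.3)), rep(1, 5))
  set.seed(42)
  smp <- draw_spectral_inputs(200)
  for (i in seq_len(nrow(smp))) {
    s <- smp[i, ]
    q <- q_root(diff = diffusion_pair(s$d1, s$d2), rho = s$rho, which = 1,
                r1 = s$r1, r2 = s$r2, delta1 = s$delta1, delta2 = s$delta2)
    b <- (s$d1 - s$d2) * s$rho^2 + (s$r1 - s$r2)
    expect_gt(q, 0)
    # root property to round-off
    expect_lt(abs(b * q + s$delta1 - s$delta2 * q^2), 1e-11 * max(1, q^2))
    expect_equal(q, bisect_q(b, s$delta1, s$delta2), tolerance = 1e-10)
  }
  # cancellation-safe branch: huge negative linear term, tiny product
  q <- q_root(diff = diffusion_pair(1, 1), which = 1,
              r1 = 0, r2 = 50, delta1 = 1e-8, delta2 = 1e-8)
  expect_gt(q, 0)
  expect_equal(q, 1e-8 / 50, tolerance = 1e-6)
  expect_error(q_root(coefficient_field(g, 1, 1, 0.1, 0)), "strictly positive")
})

test_that("Hamiltonian fitness equals the dominant eigenvalue of the growth matrix", {
  # rho drops out at equal diffusions
  r1 <- 0.9; r2 <- 0.6; d1 <- 0.07; d2 <- 0.04
  vals <- sapply(c(0, 1, 3), function(rho)
    hamiltonian_fitness(diff = diffusion_pair(1, 1), rho = rho,
                        r1 = r1, r2 = r2, delta1 = d1, delta2 = d2))
  expect_equal(max(vals) - min(vals), 0)
  # vanishing conversion product: r_H -> max(r1, r2)
  expect_equal(hamiltonian_fitness(diff = diffusion_pair(1, 1),
                                   r1 = 0.9, r2 = 0.6, delta1 = 0, delta2 = 0),
               0.9)
  set.seed(7)
  smp <- draw_spectral_inputs(300)
  for (i in seq_len(nrow(smp))) {
    s <- smp[i, ]
    A <- s$rho^2 * diag(c(s$d1, s$d2)) +
      rbind(c(s$r1 - s$N, s$delta1), c(s$delta2, s$r2 - s$N))
    lam_max <- max(eigen(A, only.values = TRUE)$values)
    H <- hamiltonian(diff = diffusion_pair(s$d1, s$d2), rho = s$rho, N = s$N,
                     r1 = s$r1, r2 = s$r2, delta1 = s$delta1, delta2 = s$delta2)
    rH <- hamiltonian_fitness(diff = diffusion_pair(s$d1, s$d2), rho = s$rho,
                              r1 = s$r1, r2 = s$r2,
                              delta1 = s$delta1, delta2 = s$delta2)
    expect_equal(H, lam_max, tolerance = 1e-10)
    # decomposition H = (d1 + d2)/2 rho^2 + r_H - N to round-off
    expect_lt(abs(H - ((s$d1 + s$d2) / 2 * s$rho^2 + rH - s$N)), 1e-12)
  }
  # H vanishes when the mass equals the zero-gradient fitness
  rH0 <- hamiltonian_fitness(diff = diffusion_pair(1, 1), rho = 0,
                             r1 = r1, r2 = r2, delta1 = d1, delta2 = d2)
  expect_equal(hamiltonian(diff = diffusion_pair(1, 1), rho = 0, N = rH0,
                           r1 = r1, r2 = r2, delta1 = d1, delta2 = d2), 0)
})

test_that("principal eigenvector is strictly positive with tiny residual", {
  # full symmetry: psi = (1, 1)
  sp <- principal_eigenvector(diff = diffusion_pair(1, 1), rho = 2, N = 0.3,
                              r1 = 1, r2 = 1, delta1 = 0.2, delta2 = 0.2)
  expect_equal(sp$psi, c(1, 1))
  set.seed(11)
  smp <- draw_spectral_inputs(1000)
  worst <- 0
  for (i in seq_len(nrow(smp))) {
    s <- smp[i, ]
    sp <- principal_eigenvector(diff = diffusion_pair(s$d1, s$d2),
                                rho = s$rho, N = s$N, r1 = s$r1, r2 = s$r2,
                                delta1 = s$delta1, delta2 = s$delta2)
    expect_true(all(sp$psi > 0))
    scale <- max(abs(s$r1), abs(s$r2), s$delta1, s$delta2,
                 (s$d1 + s$d2) * s$rho^2, 1)
    worst <- max(worst, sp$residual / (scale * max(sp$psi)))
  }
  expect_lt(worst, 1e-10)
  # collinearity with a generic dense eigensolver
  s <- list(r1 = 1.2, r2 = 0.4, delta1 = 0.3, delta2 = 0.05,
            d1 = 0.5, d2 = 1.5, rho = 1.7, N = 0.8)
  A <- s$rho^2 * diag(c(s$d1, s$d2)) +
    rbind(c(s$r1 - s$N, s$delta1), c(s$delta2, s$r2 - s$N))
  es <- eigen(A)
  v <- es$vectors[, which.max(es$values)]
  sp <- principal_eigenvector(diff = diffusion_pair(s$d1, s$d2), rho = s$rho,
                              N = s$N, r1 = s$r1, r2 = s$r2,
                              delta1 = s$delta1, delta2 = s$delta2)
  expect_equal(sp$psi[2] / sp$psi[1], v[2] / v[1], tolerance = 1e-10)
  expect_error(
    principal_eigenvector(diff = diffusion_pair(1, 1), r1 = 1, r2 = 1,
                          delta1 = 0.1, delta2 = 0),
    "strictly positive")
})

test_that("ratio identities tie q to the Hamiltonian fitness", {
  # at equal diffusions: r2 + delta2 q1 = r_H and r1 + delta1 / q1 = r_H
  set.seed(23)
  eqd <- draw_spectral_inputs(300, equal_diffusion = TRUE)
  for (i in seq_len(nrow(eqd))) {
    s <- eqd[i, ]
    dp <- diffusion_pair(s$d1, s$d2)
    q1 <- q_root(diff = dp, rho = s$rho, which = 1, r1 = s$r1, r2 = s$r2,
                 delta1 = s$delta1, delta2 = s$delta2)
    rH <- hamiltonian_fitness(diff = dp, rho = s$rho, r1 = s$r1, r2 = s$r2,
                              delta1 = s$delta1, delta2 = s$delta2)
    expect_equal(s$r2 + s$delta2 * q1, rH, tolerance = 1e-10)
    expect_equal(s$r1 + s$delta1 / q1, rH, tolerance = 1e-10)
    # the two roots are reciprocal at equal diffusions
    q2 <- q_root(diff = dp, rho = s$rho, which = 2, r1 = s$r1, r2 = s$r2,
                 delta1 = s$delta1, delta2 = s$delta2)
    expect_equal(q1 * q2, 1, tolerance = 1e-12)
  }
  # general diffusions: the identities carry an explicit (d1-d2) rho^2 / 2
  # diffusion-asymmetry term on either side
  gen <- draw_spectral_inputs(300)
  for (i in seq_len(nrow(gen))) {
    s <- gen[i, ]
    dp <- diffusion_pair(s$d1, s$d2)
    shift <- (s$d1 - s$d2) * s$rho^2 / 2
    q1 <- q_root(diff = dp, rho = s$rho, which = 1, r1 = s$r1, r2 = s$r2,
                 delta1 = s$delta1, delta2 = s$delta2)
    rH <- hamiltonian_fitness(diff = dp, rho = s$rho, r1 = s$r1, r2 = s$r2,
                              delta1 = s$delta1, delta2 = s$delta2)
    expect_equal(s$r2 + s$delta2 * q1, rH + shift, tolerance = 1e-10)
    expect_equal(s$r1 + s$delta1 / q1, rH - shift, tolerance = 1e-10)
  }
})

test_that("stationary effective fitness is the equal-diffusion Hamiltonian fitness", {
  fld <- small_field()
  prof <- fitness_profile(fld, diffusion_pair(1, 1))
  expect_lt(max(abs(prof$r_inf - prof$r_H)), 1e-12)
  # rho arbitrary at equal diffusions: same r_H array
  prof3 <- fitness_profile(fld, diffusion_pair(1, 1), rho = 3)
  expect_equal(prof3$r_H, prof$r_H)
  # constant symmetric field: r_inf = r + delta (the q = 1 average)
  g <- trait_grid(2, M = 9)
  cf <- coefficient_field(g, 0.8, 0.8, 0.12, 0.12)
  expect_equal(effective_fitness_r_inf(cf), rep(0.92, 9))
  # the weighted-average form evaluated independently
  q <- q_root(fld)
  byhand <- q / (1 + q) * (fld$r1 + fld$delta2) +
    1 / (1 + q) * (fld$r2 + fld$delta1)
  expect_equal(effective_fitness_r_inf(fld), byhand)
})

test_that("fitness maximiser: quadratic refinement, boundaries, ties, stability", {
  g <- trait_grid(6, M = 121)
  # parabola: refinement recovers the vertex to sub-grid accuracy
  pk <- argmax_fitness(1 - (g$nodes - 3.013)^2, g)
  expect_equal(pk$trait, 3.013, tolerance = 1e-10)
  expect_false(pk$boundary)
  # monotone profile: right boundary with the boundary flag
  pk2 <- argmax_fitness(g$nodes * 0.1, g)
  expect_equal(pk2$trait, 6)
  expect_true(pk2$boundary)
  # two equal bumps: leftmost wins
  two <- exp(-(g$nodes - 2)^2) + exp(-(g$nodes - 4)^2)
  pk3 <- argmax_fitness(two, g)
  expect_lt(pk3$trait, 3)
  # flat profile flagged, leftmost node returned
  pk4 <- argmax_fitness(rep(1, g$M), g)
  expect_true(pk4$flat)
  expect_equal(pk4$trait, 0)
  # default landscape: interior maximum stable under grid doubling
  fld <- small_field()
  pk_c <- argmax_fitness(fitness_profile(fld))
  fld2 <- effective_coefficients(trait_grid(12, M = 121), bio_params(),
                                 ds = 0.05)
  pk_f <- argmax_fitness(fitness_profile(fld2))
  expect_false(pk_c$boundary || pk_f$boundary)
  expect_lt(abs(pk_c$trait - pk_f$trait), 2 * fld$grid$h)
})

test_that("diffusion pair guards enforce admissibility", {
  expect_error(diffusion_pair(-1, 1), "non-negative")
  expect_error(diffusion_pair(0, 0), "positive")
  expect_silent(diffusion_pair(0, 2))
})
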