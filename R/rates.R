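#' Biological parameters of the damage/repair/adaptation model
#'
#' Bundles the rates describing the fate of a DNA-damaged cell and the
#' conversion of adapted cells back to the healthy compartment. Defaults
#' follow the calibration used throughout the numerical studies:
#' `gamma_d = 0.1`, `gamma_a = 0.35`, `alpha_m = beta_m = 0.5`,
#' `sigma = 0.5`, `mu_a = 1`; the late-repair rate `delta` and the damage
#' fraction `damage` are not pinned down by data and default to `0.05` and
#' `0.3`.
#'
#' @param gamma_d Death rate of damaged cells (1/time).
#' @param gamma_a Death rate of adapted cells (1/time); must be `< 1`.
#' @param delta Repair rate of adapted cells (1/time), the constant low rate
#'   at which adapted lineages eventually fix their damage.
#' @param damage Fraction `D` of healthy cells damaged per unit time,
#'   dimensionless, in `(0, 1)`.
#' @param alpha_m Maximal repair rate (1/time), the peak of the Gaussian
#'   repair-rate curve.
#' @param beta_m Maximal adaptation rate (1/time), the plateau of the
#'   logistic adaptation-rate curve.
#' @param sigma Spread parameter of the Gaussian repair rate; enters the
#'   exponent verbatim as `(s - mu_a)^2 / (2 * sigma)`.
#' @param mu_a Time since damage at which the repair rate peaks.
#' @param fixed_trait Value of the trait that is *not* varying: the
#'   heterogeneity `p` when `trait_mode = "timing_x"` (default 3), or the
#'   timing `x` when `trait_mode = "heterogeneity_p"` (default 4).
#' @param trait_mode Which trait the grid axis represents: `"timing_x"`
#'   (mean adaptation time `x`, logistic steepness fixed at `p = fixed_trait`)
#'   or `"heterogeneity_p"` (steepness `p`, timing fixed at
#'   `x = fixed_trait`).
#'
#' @return An object of class `bio_params`.
#' @examples
#' bio <- bio_params()
#' bio$gamma_a
#' @export
bio_params <- function(gamma_d = 0.1, gamma_a = 0.35, delta = 0.05,
                       damage = 0.3, alpha_m = 0.5, beta_m = 0.5,
                       sigma = 0.5, mu_a = 1, fixed_trait = NULL,
                       trait_mode = c("timing_x", "heterogeneity_p")) {
  trait_mode <- match.arg(trait_mode)
  if (is.null(fixed_trait)) {
    fixed_trait <- if (trait_mode == "timing_x") 3 else 4
  }
  rates <- c(gamma_d = gamma_d, gamma_a = gamma_a, delta = delta,
             alpha_m = alpha_m, beta_m = beta_m, mu_a = mu_a)
  if (any(rates < 0)) {
    stop("all rates must be non-negative; offending: ",
         paste(names(rates)[rates < 0], collapse = ", "))
  }
  if (!is.numeric(damage) || damage < 0 || damage >= 1) {
    stop("damage fraction D must lie in [0, 1)")
  }
  if (gamma_a >= 1) stop("gamma_a must be < 1 for the effective growth rates to be admissible")
  if (sigma <= 0) stop("sigma must be > 0")
  if (fixed_trait < 0) stop("fixed_trait must be non-negative")
  structure(
    list(gamma_d = gamma_d, gamma_a = gamma_a, delta = delta, damage = damage,
         alpha_m = alpha_m, beta_m = beta_m, sigma = sigma, mu_a = mu_a,
         fixed_trait = fixed_trait, trait_mode = trait_mode),
    class = "bio_params")
}

#' @export
print.bio_params <- function(x, ...) {
  cat("Biological parameters (", x$trait_mode, ")\n", sep = "")
  cat(sprintf("  gamma_d = %g, gamma_a = %g, delta = %g, D = %g\n",
              x$gamma_d, x$gamma_a, x$delta, x$damage))
  cat(sprintf("  alpha_m = %g, beta_m = %g, sigma = %g, mu_a = %g\n",
              x$alpha_m, x$beta_m, x$sigma, x$mu_a))
  cat(sprintf("  fixed trait (%s) = %g\n",
              if (x$trait_mode == "timing_x") "p" else "x", x$fixed_trait))
  invisible(x)
}

#' Environmental forcing of the repair rate
#'
#' The amplitude `abar(t)` of the Gaussian repair rate models environmental
#' windows in which DNA repair is possible. Two modes are supported: a
#' constant level, and a periodic even power of a cosine,
#' `abar(t) = level * cos(pi * t / period)^exponent`, which alternates
#' favourable and hostile phases.
#'
#' @param mode `"constant"` or `"cosine_power"`.
#' @param level Peak value of `abar` (1/time); must satisfy
#'   `0 <= level <= alpha_m` of the accompanying [bio_params()]. Defaults to
#'   0.5 (the default `alpha_m`).
#' @param period Period of the cosine (time units); default 5.
#' @param exponent Even integer power; default 8.
#' @return An object of class `env_spec`.
#' @examples
#' ev <- env_spec("cosine_power")
#' alpha_bar(ev, c(0, 2.5, 5))
#' @export
env_spec <- function(mode = c("constant", "cosine_power"), level = 0.5,
                     period = 5, exponent = 8) {
  mode <- match.arg(mode)
  if (level < 0) stop("environment level must be non-negative")
  if (mode == "cosine_power") {
    if (period <= 0) stop("period must be positive")
    if (exponent <= 0 || exponent %% 2 != 0) stop("exponent must be a positive even integer")
  }
  structure(list(mode = mode, level = level, period = period,
                 exponent = exponent), class = "env_spec")
}

#' Evaluate the environmental repair amplitude
#'
#' @param env An [env_spec()] object.
#' @param t Absolute time(s), non-negative.
#' @return `abar(t)`, in `[0, level]`.
#' @export
alpha_bar <- function(env, t) {
  if (any(t < 0)) stop("absolute time t must be non-negative")
  switch(env$mode,
         constant = rep_len(env$level, length(t)),
         cosine_power = env$level * cos(pi * t / env$period)^env$exponent)
}

#' Repair rate of damaged cells
#'
#' Rate at which a cell damaged since time `s` repairs its DNA at absolute
#' time `t`: a Gaussian bump in `s` centred at `mu_a`, modulated by the
#' environmental amplitude `abar(t)`,
#' `alpha(s, t) = abar(t) * exp(-(s - mu_a)^2 / (2 * sigma))`.
#'
#' @param s Time since damage, non-negative (vectorised).
#' @param t Absolute time, non-negative.
#' @param env An [env_spec()]; its `level` may not exceed `bio$alpha_m`.
#' @param bio A [bio_params()] object.
#' @return Non-negative rate(s), bounded by `alpha_m`.
#' @examples
#' bio <- bio_params()
#' repair_rate(1, 0, env_spec(), bio)   # peak value 0.5
#' @export
repair_rate <- function(s, t = 0, env = env_spec(), bio = bio_params()) {
  if (any(s < 0)) stop("time since damage s must be non-negative")
  if (env$level > bio$alpha_m + 1e-12) {
    stop("environment level exceeds alpha_m")
  }
  alpha_bar(env, t) * exp(-(s - bio$mu_a)^2 / (2 * bio$sigma))
}

# Resolve (x, p) for a given trait value under the active trait mode.
resolve_trait <- function(trait, bio) {
  if (bio$trait_mode == "timing_x") {
    list(x = trait, p = bio$fixed_trait)
  } else {
    list(x = bio$fixed_trait, p = trait)
  }
}

#' Adaptation rate of damaged cells
#'
#' Logistic rate at which a damaged lineage overrides the checkpoint and
#' resumes division: `beta(s) = beta_m / (1 + exp(-p * (s - x)))`, centred at
#' the timing trait `x` with steepness `p`. Which of `x`, `p` the `trait`
#' argument supplies is governed by `bio$trait_mode`.
#'
#' @param trait Trait value (timing `x` or heterogeneity `p`).
#' @param s Time since damage, non-negative (vectorised).
#' @param bio A [bio_params()] object.
#' @return Rate(s) in `(0, beta_m)` (for `p = 0` the curve is flat at
#'   `beta_m / 2`).
#' @examples
#' adaptation_rate(4, 4, bio_params())  # logistic midpoint: beta_m / 2
#' @export
adaptation_rate <- function(trait, s, bio = bio_params()) {
  if (any(s < 0)) stop("time since damage s must be non-negative")
  tp <- resolve_trait(trait, bio)
  bio$beta_m / (1 + exp(-tp$p * (s - tp$x)))
}

# Stable log(1 + exp(y)).
softplus <- function(y) {
  out <- numeric(length(y))
  big <- y > 35
  out[big] <- y[big]
  out[!big] <- log1p(exp(y[!big]))
  out
}

# Cumulative repair exposure int_0^s alpha(z) dz at constant amplitude
# abar = alpha_m, from the Gaussian antiderivative (error function).
cum_repair <- function(s, bio) {
  sc <- sqrt(2 * bio$sigma)
  bio$alpha_m * sqrt(pi * bio$sigma / 2) *
    (pracma::erf((s - bio$mu_a) / sc) + pracma::erf(bio$mu_a / sc))
}

# Cumulative adaptation exposure int_0^s beta(z) dz from the logistic
# antiderivative (softplus); p = 0 degenerates to the flat rate beta_m / 2.
cum_adapt <- function(trait, s, bio) {
  tp <- resolve_trait(trait, bio)
  if (tp$p == 0) return(bio$beta_m * s / 2)
  (bio$beta_m / tp$p) * (softplus(tp$p * (s - tp$x)) - softplus(-tp$p * tp$x))
}

#' Survival kernel of damaged cells
#'
#' Probability that a cell damaged at time 0 is still damaged (neither
#' repaired, adapted, nor dead) after time `s`:
#' `K(trait, s) = exp(-gamma_d * s - int_0^s alpha - int_0^s beta)`,
#' with the repair amplitude held at its maximum `alpha_m`. The cumulative
#' exposures are evaluated from closed-form antiderivatives (error function
#' and softplus), so no quadrature error enters here.
#'
#' @param trait Trait value (interpreted per `bio$trait_mode`).
#' @param s Time(s) since damage, non-negative (vectorised).
#' @param bio A [bio_params()] object.
#' @return Value(s) in `[0, 1]`, non-increasing in `s` and dominated by
#'   `exp(-gamma_d * s)`.
#' @examples
#' survival_kernel(4, c(0, 1, 3), bio_params())
#' @export
survival_kernel <- function(trait, s, bio = bio_params()) {
  if (any(s < 0)) stop("time since damage s must be non-negative")
  exp(-bio$gamma_d * s - cum_repair(s, bio) - cum_adapt(trait, s, bio))
}

#' Quasi-static damaged-cell density
#'
#' Closed-form density of cells with a given trait damaged since time `s`,
#' under the quasi-static approximation in which the damaged compartment
#' equilibrates instantaneously: `d = D * n * K(trait, s)` where `n` is the
#' healthy density at that trait and `K` the [survival_kernel()].
#'
#' @param trait Trait value.
#' @param s Time since damage, non-negative.
#' @param n_value Healthy-cell density at the trait (non-negative).
#' @param bio A [bio_params()] object.
#' @return Damaged density value(s).
#' @export
damaged_density <- function(trait, s, n_value, bio = bio_params()) {
  if (any(n_value < 0)) stop("n_value must be non-negative")
  bio$damage * n_value * survival_kernel(trait, s, bio)
}

# Composite Simpson weights for a uniform grid with an odd number of nodes.
simpson_weights <- function(n, ds) {
  stopifnot(n >= 3, n %% 2 == 1)
  w <- rep(c(2, 4), length.out = n)
  w[1] <- 1
  w[n] <- 1
  w * ds / 3
}

#' Effective coefficients of the two-population system
#'
#' Integrates the damaged-cell fates over the time-since-damage axis to
#' obtain the effective growth and conversion coefficients of the reduced
#' healthy/adapted system at every grid node:
#' \describe{
#'   \item{`r1(x)`}{`1 - D + D * int_0^Inf alpha(s) K(x, s) ds` — healthy
#'     growth corrected for damage outflow and repair inflow.}
#'   \item{`r2`}{`1 - gamma_a - delta` — adapted growth (constant).}
#'   \item{`delta1`}{`delta` — adapted-to-healthy late repair (constant).}
#'   \item{`delta2(x)`}{`D * int_0^Inf beta(x, s) K(x, s) ds` — healthy-to-
#'     adapted conversion via the damaged compartment.}
#' }
#' The three splitting probabilities of a damaged cell (repair, adaptation,
#' death) are returned as well; they sum to one up to the quadrature and
#' truncation tolerance, which the function reports.
#'
#' The outer `s`-integrals use composite Simpson quadrature on
#' `[0, s_max]` with step `ds`; the truncation point satisfies
#' `exp(-gamma_d * s_max) < tail_tol` so the discarded tail is negligible.
#'
#' @param grid A [trait_grid()].
#' @param bio A [bio_params()] object.
#' @param s_max Truncation of the time-since-damage axis; default chosen
#'   from `tail_tol`.
#' @param ds Quadrature step on the `s` axis (default 0.02).
#' @param tail_tol Bound required of the truncated tail mass
#'   `exp(-gamma_d * s_max)` (default 1e-10).
#' @param refine If `TRUE`, recompute with `ds / 2` and attach the maximal
#'   change in `r1` and `delta2` as the achieved quadrature tolerance.
#' @return An object of class `coefficient_field`: the grid, vectors `r1`,
#'   `r2`, `delta1`, `delta2`, the splitting probabilities `repair_prob`,
#'   `adapt_prob`, `death_prob`, the worst probability-conservation defect
#'   `prob_defect`, and the parameters used.
#' @examples
#' fld <- effective_coefficients(trait_grid(12, M = 61), bio_params(), ds = 0.05)
#' max(abs(fld$repair_prob + fld$adapt_prob + fld$death_prob - 1))
#' @export
effective_coefficients <- function(grid, bio = bio_params(), s_max = NULL,
                                   ds = 0.02, tail_tol = 1e-10,
                                   refine = FALSE) {
  stopifnot(inherits(grid, "trait_grid"))
  if (bio$gamma_d <= 0) stop("gamma_d must be positive so the s-integrals converge")
  if (is.null(s_max)) s_max <- ceiling(-log(tail_tol) / bio$gamma_d)
  if (exp(-bio$gamma_d * s_max) > tail_tol) {
    stop(sprintf(
      "s_max = %g too small: tail bound exp(-gamma_d*s_max) = %.3g > %.3g; need s_max >= %g",
      s_max, exp(-bio$gamma_d * s_max), tail_tol, -log(tail_tol) / bio$gamma_d))
  }
  one_pass <- function(ds) {
    n_s <- ceiling(s_max / ds)
    if (n_s %% 2 == 1) n_s <- n_s + 1        # even panel count, odd node count
    s <- seq(0, s_max, length.out = n_s + 1)
    w <- simpson_weights(n_s + 1, s[2] - s[1])
    alpha_s <- bio$alpha_m * exp(-(s - bio$mu_a)^2 / (2 * bio$sigma))
    core <- exp(-bio$gamma_d * s - cum_repair(s, bio))  # trait-independent part
    M <- grid$M
    rep_p <- ada_p <- dea_p <- numeric(M)
    for (i in seq_len(M)) {
      tr <- grid$nodes[i]
      K <- core * exp(-cum_adapt(tr, s, bio))
      beta_s <- adaptation_rate(tr, s, bio)
      rep_p[i] <- sum(w * alpha_s * K)
      ada_p[i] <- sum(w * beta_s * K)
      dea_p[i] <- bio$gamma_d * sum(w * K)
    }
    list(rep_p = rep_p, ada_p = ada_p, dea_p = dea_p)
  }
  pr <- one_pass(ds)
  quad_tol <- NA_real_
  if (refine) {
    pr2 <- one_pass(ds / 2)
    quad_tol <- max(abs(bio$damage * (pr$rep_p - pr2$rep_p)),
                    abs(bio$damage * (pr$ada_p - pr2$ada_p)))
    pr <- pr2
  }
  structure(
    list(grid = grid,
         r1 = 1 - bio$damage + bio$damage * pr$rep_p,
         r2 = rep_len(1 - bio$gamma_a - bio$delta, grid$M),
         delta1 = rep_len(bio$delta, grid$M),
         delta2 = bio$damage * pr$ada_p,
         repair_prob = pr$rep_p,
         adapt_prob = pr$ada_p,
         death_prob = pr$dea_p,
         prob_defect = max(abs(pr$rep_p + pr$ada_p + pr$dea_p - 1)),
         bio = bio, s_max = s_max, ds = ds, tail_tol = tail_tol,
         quad_tol = quad_tol),
    class = "coefficient_field")
}

#' Construct a coefficient field from explicit arrays
#'
#' Assembles a `coefficient_field` directly from user-supplied coefficient
#' vectors, bypassing the biological-rate construction. Useful for analytic
#' test cases and for the stationary closed-form benchmarks.
#'
#' @param grid A [trait_grid()].
#' @param r1,r2,delta1,delta2 Numeric vectors over grid nodes (scalars are
#'   recycled).
#' @return A `coefficient_field` (without splitting probabilities).
#' @export
coefficient_field <- function(grid, r1, r2, delta1, delta2) {
  stopifnot(inherits(grid, "trait_grid"))
  M <- grid$M
  structure(
    list(grid = grid,
         r1 = rep_len(r1, M), r2 = rep_len(r2, M),
         delta1 = rep_len(delta1, M), delta2 = rep_len(delta2, M),
         repair_prob = NULL, adapt_prob = NULL, death_prob = NULL,
         prob_defect = NA_real_, bio = NULL, s_max = NA_real_,
         ds = NA_real_, tail_tol = NA_real_, quad_tol = NA_real_),
    class = "coefficient_field")
}

#' @export
print.coefficient_field <- function(x, ...) {
  cat(sprintf("Coefficient field on [0, %g], M = %d nodes\n",
              x$grid$x_max, x$grid$M))
  cat(sprintf("  r1 in [%.4f, %.4f], r2 = %.4f, delta1 = %.4f, delta2 in [%.4g, %.4g]\n",
              min(x$r1), max(x$r1), x$r2[1], x$delta1[1],
              min(x$delta2), max(x$delta2)))
  if (is.finite(x$prob_defect)) {
    cat(sprintf("  worst probability-conservation defect: %.3g\n", x$prob_defect))
  }
  invisible(x)
}

#' Validate the structural hypotheses on a coefficient field
#'
#' Checks the standing assumptions the well-posedness and mass-bound theory
#' requires of the coefficients: strict positivity of both conversion terms,
#' and the existence of constants `c_N <= r_i + delta_j <= C_N` uniformly in
#' the trait. Returns the numeric constants realised on the grid together
#' with the closed-form bracket `c_N = min(1 - gamma_a, 1 - D)`,
#' `C_N = 2 + D` available when the field comes from the biological rates.
#'
#' @param field A `coefficient_field`.
#' @return An object of class `assumption_report` with elements `c_N`, `C_N`
#'   (numeric, realised on the grid), `c_N_closed`, `C_N_closed` (closed-form
#'   bracket, `NA` for hand-built fields), `delta_positive` (logical), and
#'   `n_bad_delta`.
#' @examples
#' fld <- coefficient_field(trait_grid(1, M = 11), 1, 1, 0.1, 0.1)
#' validate_assumptions(fld)$c_N  # 1.1
#' @export
validate_assumptions <- function(field) {
  stopifnot(inherits(field, "coefficient_field"))
  bad <- (field$delta1 <= 0) | (field$delta2 <= 0)
  if (any(bad)) {
    stop(sprintf(
      "conversion coefficients must be strictly positive; %d node(s) violate this",
      sum(bad)))
  }
  lo <- pmin(field$r1 + field$delta2, field$r2 + field$delta1)
  hi <- pmax(field$r1 + field$delta2, field$r2 + field$delta1)
  cN_closed <- CN_closed <- NA_real_
  if (!is.null(field$bio)) {
    cN_closed <- min(1 - field$bio$gamma_a, 1 - field$bio$damage)
    CN_closed <- 2 + field$bio$damage
  }
  structure(
    list(c_N = min(lo), C_N = max(hi),
         c_N_closed = cN_closed, C_N_closed = CN_closed,
         delta_positive = !any(bad), n_bad_delta = sum(bad)),
    class = "assumption_report")
}

#' @export
print.assumption_report <- function(x, ...) {
  cat(sprintf("Assumption report: c_N = %.6f, C_N = %.6f\n", x$c_N, x$C_N))
  if (is.finite(x$c_N_closed)) {
    cat(sprintf("  closed-form bracket: [%.4f, %.4f]\n",
                x$c_N_closed, x$C_N_closed))
  }
  cat(sprintf("  conversion terms strictly positive: %s\n", x$delta_positive))
  invisible(x)
}
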