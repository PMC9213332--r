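# Shared fixtures, cached across test files to avoid recomputing the
# coefficient quadrature.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# coarse default-parameter field (timing mode, p = 3)
small_field <- function() {
  cached("small_field",
         effective_coefficients(trait_grid(12, M = 61), bio_params(),
                                ds = 0.05))
}

# medium-resolution field used by the solver/diagnostics checks
medium_field <- function() {
  cached("medium_field",
         effective_coefficients(trait_grid(12, h = 0.02), bio_params(),
                                ds = 0.02))
}

medium_grid <- function() medium_field()$grid

# spatially flat analytic field on a given grid (no biology attached)
flat_field <- function(grid, r1 = 0.9, r2 = 0.6, d1 = 0.05, d2 = 0.08) {
  coefficient_field(grid, r1, r2, d1, d2)
}

# random admissible spectral inputs; equal-diffusion rows for the verbatim
# identity checks, general rows for the corrected ones
draw_spectral_inputs <- function(n, equal_diffusion = FALSE) {
  d1 <- runif(n, 0, 2)
  d2 <- if (equal_diffusion) d1 else runif(n, 0, 2)
  data.frame(
    r1 = runif(n, 0, 2), r2 = runif(n, 0, 2),
    delta1 = runif(n, 1e-3, 1), delta2 = runif(n, 1e-3, 1),
    d1 = d1, d2 = d2,
    rho = runif(n, -3, 3), N = runif(n, 0, 2))
}
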