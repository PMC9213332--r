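# adaptdyn

Simulation and analysis toolkit for the evolutionary dynamics of
**adaptation to DNA damage** in trait-structured cell populations.

Damaged cells normally arrest at the DNA-damage checkpoint until repair
succeeds; some lineages instead *adapt* — override the checkpoint after a
heritable waiting time and divide with the damage unrepaired. `adaptdyn`
models a population of healthy cells `n(x, t)` and adapted cells
`a(x, t)` structured by such a trait (the mean adaptation timing `x`, or
the heterogeneity `p` of the timing), competing for a common resource and
exchanging individuals through damage, repair and adaptation. The
audience is mathematical biologists and modellers studying selection of
adaptation strategies, bet-hedging in fluctuating environments, and
phenotype-structured non-local PDEs generally.

## The model

The scaled cooperative system on the trait interval, with zero-flux
boundaries, is

```
eps n_t - eps^2 d1 n_xx = n (r1(x) - N(t)) + delta1 a
eps a_t - eps^2 d2 a_xx = a (r2    - N(t)) + delta2(x) n,   N(t) = ∫ (n + a) dx
```

where `eps` makes mutations rare and time long; as `eps -> 0` the
densities concentrate into moving Dirac masses at the selected traits.
The coefficients are derived from cell biology by a quasi-static
treatment of the damaged compartment: a cell damaged since time `s`
repairs at a Gaussian rate, adapts at a logistic rate, dies at rate
`gamma_d`, giving a survival kernel `K(x, s)` whose fate integrals yield
`r1(x) = 1 - D + D ∫ alpha K ds`, `delta2(x) = D ∫ beta K ds`,
`r2 = 1 - gamma_a - delta`, `delta1 = delta` (repair + adaptation +
death probabilities sum to 1, which the package verifies).

The central analysis object is the **Hamiltonian fitness**

```
r_H(x) = ( r1 + r2 + sqrt((r1 - r2)^2 + 4 delta1 delta2) ) / 2,
```

the dominant eigenvalue of the coupled growth matrix: its maximiser
`x* = argmax r_H` is the trait selection retains, the positive root
`q(x)` of the associated quadratic is the limiting ratio `n/a`, and the
stationary profile of `n + a` is the ground state of
`-eps^2 d²/dx² - r_H` with the principal eigenvalue equal to the
limiting total mass.

## Worked example

```r
library(adaptdyn)

grid  <- trait_grid(12, h = 0.02)
bio   <- bio_params()                      # timing mode, p fixed at 3
field <- effective_coefficients(grid, bio)
(rep  <- validate_assumptions(field))
#> Assumption report: c_N = 0.650000, C_N = 0.963499
#>   closed-form bracket: [0.6500, 2.3000]
#>   conversion terms strictly positive: TRUE

(profile <- fitness_profile(field))
#> Fitness profile on [0, 12] (M = 601): r_H in [0.8402, 0.8675]
#>   argmax r_H = 2.6285

cfg <- solver_config(epsilon = 0.01, diff = diffusion_pair(1, 1),
                     grid = grid, t_end = 4)
run <- simulate_system(cfg, field, initial_state(grid, total_mass = rep$c_N))
run
#> Trajectory: t in [0, 4], eps = 0.01, d = (1, 1), 401 records
#>   terminal N = 0.864970, peak = 4.9542, spread = 0.3610
#>   mass bounds [0.6500, 0.9635]: worst excursion 0

ground_state(profile$r_inf, epsilon = 0.01, grid)
#> Ground state: N_inf = 0.86712892, peak at 2.7113, residual 7.5e-16 (eps = 0.01)
```

Reading the numbers: the structural competition constants bracket the
total mass in `[0.65, 0.96]`, and the recorded mass never leaves that
bracket (worst excursion 0). The fitness landscape peaks at
`x* = 2.63` — the predicted optimal adaptation timing. At `eps = 0.01`
over a short horizon the density peak (4.95) has only begun its drift
from the initial position 5 towards `x*`; longer runs at smaller `eps`
(see `preset("fig5")`) concentrate tightly onto it, and the stationary
ground state already peaks at 2.71 with limiting mass
`N_inf = 0.867 ~ max r_H`. The initial state is rescaled to total mass
`c_N` because the mass-bound theory assumes the starting mass inside the
bracket.

Preset studies (`preset()`, `run_suite()`) reproduce the standard
numerical experiments — ratio convergence to `q`, Dirac concentration
across `eps`, diffusion-asymmetry robustness, and the stable-versus-
periodic environment contrast — and write deterministic TSV/JSON outputs.
A thin command-line front end is installed at `exec/adaptdyn`
(subcommands `coefficients`, `fitness`, `simulate`, `stationary`,
`check`, `suite`).

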