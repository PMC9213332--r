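#' Reference initial condition
#'
#' Both populations initialised to the same centred Gaussian,
#' `n0 = a0 = (1/5) exp(-10 (x - 5)^2)`: fast-decaying, interior, and of
#' comparable scale in both compartments so the ratio `n/a` is well-behaved
#' from the start.
#'
#' @param grid A [trait_grid()].
#' @return A [population_state()] at `t = 0`.
#' @examples
#' st <- default_initial(trait_grid(12, M = 121))
#' max(st$n)  # 0.2 at x = 5
#' @export
default_initial <- function(grid) {
  v <- 0.2 * exp(-10 * (grid$nodes - 5)^2)
  population_state(v, v, t = 0)
}

#' Parametric initial conditions
#'
#' Generates initial trait profiles of two kinds:
#' \describe{
#'   \item{`gaussian`}{`amplitude * exp(-width * (x - center)^2)`.}
#'   \item{`h4_envelope`}{the same Gaussian clipped nodewise into the
#'     admissible corridor `c * exp((-a x^2 - c)/eps) <= n0(x) <=
#'     C * exp((-A x + C)/eps)` required of well-prepared data (quadratic
#'     lower envelope, linear upper envelope, both on the `eps`-scale).}
#' }
#' Optionally the profile pair is rescaled to a prescribed total mass, e.g.
#' to start inside the structural mass bracket `[c_N, C_N]`.
#'
#' @param grid A [trait_grid()].
#' @param kind `"gaussian"` or `"h4_envelope"`.
#' @param amplitude,center,width Gaussian parameters.
#' @param epsilon Scaling parameter (needed for `h4_envelope`).
#' @param envelope Constants `a`, `A`, `c`, `C` of the corridor (named
#'   list), all positive.
#' @param total_mass If non-`NULL`, rescale both densities so the summed
#'   trapezoid mass equals this value.
#' @return A [population_state()] with `n = a`.
#' @export
initial_state <- function(grid, kind = c("gaussian", "h4_envelope"),
                          amplitude = 0.2, center = 5, width = 10,
                          epsilon = 0.01,
                          envelope = list(a = 1, A = 1, c = 0.1, C = 1),
                          total_mass = NULL) {
  kind <- match.arg(kind)
  x <- grid$nodes
  v <- amplitude * exp(-width * (x - center)^2)
  if (kind == "h4_envelope") {
    if (any(unlist(envelope) <= 0)) stop("envelope constants must be positive")
    lower <- envelope$c * exp((-envelope$a * x^2 - envelope$c) / epsilon)
    upper <- envelope$C * exp((-envelope$A * x + envelope$C) / epsilon)
    if (any(lower > upper)) stop("empty envelope corridor; adjust the constants")
    v <- pmin(pmax(v, lower), upper)
  }
  st <- population_state(v, v, t = 0)
  if (!is.null(total_mass)) {
    st <- rescale_mass(st, grid, total_mass)
  }
  st
}

#' Rescale a state to a prescribed total mass
#'
#' @param state A [population_state()].
#' @param grid The [trait_grid()].
#' @param total_mass Target trapezoid mass of `n + a` (positive).
#' @return The rescaled state.
#' @export
rescale_mass <- function(state, grid, total_mass) {
  if (total_mass <= 0) stop("total_mass must be positive")
  f <- total_mass / total_mass(state, grid)
  population_state(state$n * f, state$a * f, state$t)
}

#' Preset configurations of the reference numerical studies
#'
#' Fully populated run specifications for the package's standard numerical
#' experiments:
#' \describe{
#'   \item{`fig4`}{timing mode, `d1 = d2 = 1`, `eps = 0.01`, horizon 1;
#'     tracks the sup-distance between `n/a` and `q`.}
#'   \item{`fig5`}{timing mode, `d1 = d2 = 1`,
#'     `eps` in 0.05, 0.01, 0.001, 1e-4; Dirac concentration onto the
#'     fitness maximiser.}
#'   \item{`fig6`}{timing mode, `eps = 0.001`, diffusion pairs
#'     (1,1), (0.5,1.5), (0.05,1.95), (0,2) — constant sum `d1 + d2 = 2`.}
#'   \item{`fig7`}{heterogeneity mode, `x = 4`, `eps` in 0.01, 0.001;
#'     monotone drift towards large `p`.}
#'   \item{`fig8`}{heterogeneity mode, `x = 4`, `d1 = d2 = 1`,
#'     `eps = 0.001`, horizon 300; constant versus periodic environment
#'     `abar(t) = alpha_m * cos(pi t / 5)^8` through the time-varying
#'     repair-inflow coefficient.}
#' }
#' Horizons for `fig5`--`fig7` are the package's own choices: 40 rescaled
#' time units, long enough for the concentrating peak to settle near the
#' fitness maximiser at the smallest `epsilon`. `t_scale` shortens the
#' horizons and `h` coarsens the grid for desk-scale reruns.
#'
#' @param name One of `"fig4"`, `"fig5"`, `"fig6"`, `"fig7"`, `"fig8"`.
#' @param t_scale Positive factor multiplying the horizons (default 1).
#' @param h Grid spacing (default 0.01).
#' @return A list of class `experiment_preset`: `name`, `bio`, `env`(s),
#'   `grid`, `runs` (list of [solver_config()]-ready parameter sets), and
#'   `track` (diagnostics to record).
#' @export
preset <- function(name = c("fig4", "fig5", "fig6", "fig7", "fig8"),
                   t_scale = 1, h = 0.01) {
  name <- match.arg(name)
  if (t_scale <= 0) stop("t_scale must be positive")
  grid <- trait_grid(12, h = h)
  mk_run <- function(eps, d1, d2, t_end, env = env_spec(),
                     mode = "static") {
    list(epsilon = eps, d1 = d1, d2 = d2, t_end = t_end * t_scale,
         env = env, coefficient_mode = mode)
  }
  spec <- switch(
    name,
    fig4 = list(bio = bio_params(trait_mode = "timing_x", fixed_trait = 3),
                runs = list(mk_run(0.01, 1, 1, 1)),
                track = "ratio_distance"),
    fig5 = list(bio = bio_params(trait_mode = "timing_x", fixed_trait = 3),
                runs = lapply(c(0.05, 0.01, 0.001, 1e-4),
                              function(e) mk_run(e, 1, 1, 40)),
                track = "concentration"),
    fig6 = list(bio = bio_params(trait_mode = "timing_x", fixed_trait = 3),
                runs = lapply(list(c(1, 1), c(0.5, 1.5), c(0.05, 1.95), c(0, 2)),
                              function(d) mk_run(0.001, d[1], d[2], 40)),
                track = "concentration"),
    fig7 = list(bio = bio_params(trait_mode = "heterogeneity_p", fixed_trait = 4),
                runs = lapply(c(0.01, 0.001),
                              function(e) mk_run(e, 1, 1, 40)),
                track = "concentration"),
    fig8 = list(bio = bio_params(trait_mode = "heterogeneity_p", fixed_trait = 4),
                runs = list(
                  mk_run(0.001, 1, 1, 300, env_spec("constant", level = 0.5),
                         mode = "time_varying_r1"),
                  mk_run(0.001, 1, 1, 300,
                         env_spec("cosine_power", level = 0.5,
                                  period = 5, exponent = 8),
                         mode = "time_varying_r1")),
                track = "concentration"))
  structure(c(list(name = name, grid = grid, t_scale = t_scale), spec),
            class = "experiment_preset")
}

#' @export
print.experiment_preset <- function(x, ...) {
  cat(sprintf("Preset %s: %d run(s) on [0, %g] (h = %g), mode %s\n",
              x$name, length(x$runs), x$grid$x_max, x$grid$h,
              x$bio$trait_mode))
  invisible(x)
}

# Deterministic numeric formatting for byte-stable text output.
fmt_num <- function(v) formatC(v, format = "g", digits = 12)

write_table_with_meta <- function(df, meta, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)),
             con)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  body <- apply(vapply(df, fmt_num, character(nrow(df))), 1, paste,
                collapse = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Export a coefficient field as a delimited table
#'
#' Tab-separated columns `trait, r1, r2, delta1, delta2` preceded by a
#' JSON metadata header line (`# {...}`) recording the parameters,
#' truncation and tolerances.
#'
#' @param field A `coefficient_field`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_field <- function(field, path) {
  meta <- list(type = "coefficient_field",
               s_max = field$s_max, ds = field$ds,
               tail_tol = field$tail_tol, prob_defect = field$prob_defect)
  if (!is.null(field$bio)) meta$bio <- unclass(field$bio)
  df <- data.frame(trait = field$grid$nodes, r1 = field$r1, r2 = field$r2,
                   delta1 = field$delta1, delta2 = field$delta2)
  write_table_with_meta(df, meta, path)
}

#' Export a fitness profile as a delimited table
#'
#' Columns `trait, q, r_H, r_inf` plus a JSON metadata header.
#'
#' @param profile A `fitness_profile`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_profile <- function(profile, path) {
  meta <- list(type = "fitness_profile", rho = profile$rho_used,
               d1 = profile$diff$d1, d2 = profile$diff$d2)
  df <- data.frame(trait = profile$grid$nodes, q = profile$q,
                   r_H = profile$r_H, r_inf = profile$r_inf)
  write_table_with_meta(df, meta, path)
}

#' Export a trajectory's time series and snapshots
#'
#' Writes `<stem>_series.tsv` (columns `t, N, peak, spread, mass_tail`) and
#' one `<stem>_snapshot_<k>.tsv` per stored snapshot (columns
#' `x, n, a, u1, u2` with the Hopf-Cole phases at the run's `epsilon`).
#'
#' @param traj A [simulate_system()] result.
#' @param stem Output path stem.
#' @return Character vector of the files written, invisibly.
#' @export
write_trajectory <- function(traj, stem) {
  eps <- traj$config$epsilon
  meta <- list(type = "trajectory_series", epsilon = eps,
               d1 = traj$config$diff$d1, d2 = traj$config$diff$d2,
               dt = traj$config$dt, t_end = traj$config$t_end,
               coefficient_mode = traj$config$coefficient_mode)
  if (!is.null(traj$bounds)) {
    meta$c_N <- traj$bounds$c_N
    meta$C_N <- traj$bounds$C_N
    meta$worst_mass_excess <- traj$bounds$worst_excess
  }
  files <- paste0(stem, "_series.tsv")
  write_table_with_meta(
    data.frame(t = traj$times, N = traj$N, peak = traj$peak,
               spread = traj$spread, mass_tail = traj$mass_tail),
    meta, files[1])
  for (k in seq_along(traj$snapshots)) {
    st <- traj$snapshots[[k]]
    f <- sprintf("%s_snapshot_%d.tsv", stem, k)
    write_table_with_meta(
      data.frame(x = traj$config$grid$nodes, n = st$n, a = st$a,
                 u1 = hopf_cole(st$n, eps)$u, u2 = hopf_cole(st$a, eps)$u),
      list(type = "trajectory_snapshot", t = st$t, epsilon = eps), f)
    files <- c(files, f)
  }
  invisible(files)
}

#' Export a ground state as a delimited table
#'
#' Columns `x, w`; the eigenvalue and residual go in the metadata header.
#'
#' @param gs A [ground_state()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_ground_state <- function(gs, path) {
  write_table_with_meta(
    data.frame(x = gs$grid$nodes, w = gs$w),
    list(type = "ground_state", N_inf = gs$N_inf,
         residual = gs$residual, epsilon = gs$epsilon),
    path)
}

#' Run preset experiments and write their outputs
#'
#' Executes each named preset (validating the coefficient field first),
#' writes the time-series and snapshot tables plus a JSON metadata file per
#' run, and returns a manifest of the files produced with their MD5
#' checksums. The whole pipeline is deterministic: rerunning with the same
#' configuration reproduces identical files.
#'
#' @param names Character vector of preset names (may be empty).
#' @param outdir Output directory (created if missing).
#' @param t_scale,h Passed to [preset()]; shrink/coarsen for desk-scale
#'   reruns.
#' @param ds Quadrature step for [effective_coefficients()].
#' @return A data frame manifest (`file`, `md5`), with zero rows when
#'   `names` is empty.
#' @export
run_suite <- function(names, outdir, t_scale = 1, h = 0.01, ds = 0.02) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  files <- character(0)
  for (nm in names) {
    ps <- preset(nm, t_scale = t_scale, h = h)
    field <- effective_coefficients(ps$grid, ps$bio, ds = ds)
    validate_assumptions(field)
    prof <- fitness_profile(field)
    pf <- file.path(outdir, paste0(nm, "_profile.tsv"))
    write_profile(prof, pf)
    files <- c(files, pf)
    for (k in seq_along(ps$runs)) {
      run <- ps$runs[[k]]
      cfg <- solver_config(
        epsilon = run$epsilon,
        diff = diffusion_pair(run$d1, run$d2),
        grid = ps$grid, t_end = run$t_end, env = run$env,
        coefficient_mode = run$coefficient_mode,
        snapshot_times = run$t_end,
        thin = max(1L, ceiling(run$t_end / run$epsilon / 2000)))
      traj <- simulate_system(cfg, field)
      stem <- file.path(outdir, sprintf("%s_run%d", nm, k))
      out <- write_trajectory(traj, stem)
      meta_file <- paste0(stem, "_meta.json")
      meta <- list(preset = nm, run = k, epsilon = run$epsilon,
                   d1 = run$d1, d2 = run$d2, t_end = run$t_end,
                   coefficient_mode = run$coefficient_mode,
                   env = unclass(run$env),
                   terminal_N = traj$N[length(traj$N)],
                   terminal_peak = traj$peak[length(traj$peak)],
                   terminal_spread = traj$spread[length(traj$spread)])
      if (identical(ps$track, "ratio_distance")) {
        meta$terminal_ratio_distance <-
          as.numeric(ratio_distance(traj$state, prof))
      }
      jsonlite::write_json(meta, meta_file, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      files <- c(files, out, meta_file)
    }
  }
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(files)),
                         row.names = NULL)
  manifest
}

#' Read a structured run configuration file
#'
#' Parses a YAML configuration with sections `bio`, `environment`, `solver`
#' and optional `output`, returning ready-to-use parameter objects. Every
#' field mirrors an argument of [bio_params()], [env_spec()] or
#' [solver_config()]; omitted fields take the package defaults.
#'
#' @param path Path to the YAML file.
#' @return A list: `bio`, `env`, `grid`, `config` ([solver_config()]),
#'   `output` (raw list or `NULL`).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  bio <- do.call(bio_params, raw$bio %||% list())
  env <- do.call(env_spec, raw$environment %||% list())
  sv <- raw$solver %||% list()
  grid_args <- sv[intersect(names(sv), c("x_max", "M", "h"))]
  grid <- do.call(trait_grid, grid_args)
  cfg_args <- sv[intersect(names(sv),
                           c("epsilon", "dt", "t_end", "coefficient_mode",
                             "snapshot_times", "thin"))]
  cfg_args$diff <- diffusion_pair(sv$d1 %||% 1, sv$d2 %||% 1)
  cfg_args$grid <- grid
  cfg_args$env <- env
  config <- do.call(solver_config, cfg_args)
  list(bio = bio, env = env, grid = grid, config = config,
       output = raw$output)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
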