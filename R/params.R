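#' The eighteen swept model parameters
#'
#' A `hdc_params` object is a named numeric vector of the eighteen tunable
#' model parameters, `p1` ... `p18`. All simulation behavior that is subject
#' to sensitivity analysis flows through these values; engine settings that
#' are never swept (domain size, time step, decay rates, ...) live in the
#' [make_engine_config()] object instead.
#'
#' Parameter meanings and units (LS = lattice site, au = arbitrary units):
#'
#' | id  | meaning | unit |
#' |-----|---------|------|
#' | p1  | diffusion coefficient shared by all diffusible signals | LS^2/day |
#' | p2  | M2S secretion rate by tumor cells | pg/LS/day |
#' | p3  | Activator secretion rate by tumor cells | pg/LS/day |
#' | p4  | M2S secretion rate by M2 macrophages | pg/LS/day |
#' | p5  | TLS secretion rate by M1 macrophages | pg/LS/day |
#' | p6  | TLS concentration lethal to tumor cells | pg/LS |
#' | p7  | Activator threshold licensing naive-macrophage polarization | pg/LS |
#' | p8  | oxygen delivery rate per unit vasculature | pg/LS/day/au |
#' | p9  | oxygen uptake rate per live cell | pg/LS/day |
#' | p10 | anoxia death threshold (oxygen) | pg/LS |
#' | p11 | mean of the initial M2S distribution | pg/LS |
#' | p12 | tumor division rate | 1/day |
#' | p13 | M2 polarization threshold (M2S at half-maximal M2 probability) | pg/LS |
#' | p14 | vasculature growth rate per unit M2S | au/day/(pg/LS) |
#' | p15 | naive macrophage recruitment rate per unit vasculature | cells/LS/day/au |
#' | p16 | polarization stochasticity (logistic dose-response width) | pg/LS |
#' | p17 | spatial heterogeneity of initial M2S (standard deviation) | pg/LS |
#' | p18 | initial tumor cell count | cells |
#'
#' The shipped base values were calibrated so that, at base settings, a
#' 200-run ensemble produces both tumor survival and tumor death, a necrotic
#' core forms early, and the macrophage compartment eventually becomes
#' M2-dominated; see the methods vignette for the calibration rationale.
#'
#' @return A named numeric vector of class `hdc_params`, all entries positive.
#' @examples
#' ps <- make_base_parameters()
#' ps[["p12"]]   # tumor division rate, 1/day
#' @export
make_base_parameters <- function() {
  ps <- c(
    p1  = 50,       # signal diffusion coefficient [LS^2/day]
    p2  = 1e-5,     # M2S secretion by tumor [pg/LS/day]
    p3  = 1e-3,     # Activator secretion by tumor [pg/LS/day]
    p4  = 8e-5,     # M2S secretion by M2 cells [pg/LS/day]
    p5  = 1e-2,     # TLS secretion by M1 cells [pg/LS/day]
    p6  = 2.1e-4,     # tumor TLS lethality threshold [pg/LS]
    p7  = 5e-5,     # Activator activation threshold [pg/LS]
    p8  = 0.5,      # oxygen delivery per unit vasculature [pg/LS/day/au]
    p9  = 30,       # oxygen uptake per live cell [pg/LS/day]
    p10 = 0.05,     # anoxia threshold [pg/LS]
    p11 = 5e-7,     # mean initial M2S [pg/LS]
    p12 = 1,        # tumor division rate [1/day]
    p13 = 1.1e-6,   # M2 polarization threshold [pg/LS]
    p14 = 3e6,      # vasculature growth per unit M2S [au/day/(pg/LS)]
    p15 = 2e-3,     # naive recruitment per unit vasculature [cells/LS/day/au]
    p16 = 2e-7,     # polarization stochasticity [pg/LS]
    p17 = 2.5e-7,   # initial M2S spatial heterogeneity (sd) [pg/LS]
    p18 = 50        # initial tumor cell count [cells]
  )
  class(ps) <- c("hdc_params", "numeric")
  ps
}

param_names <- function() paste0("p", 1:18)

#' @export
print.hdc_params <- function(x, ...) {
  cat("<hdc_params> 18 model parameters\n")
  print(format(unclass(x), digits = 6), quote = FALSE)
  invisible(x)
}

#' Scale selected parameters by multipliers
#'
#' Returns a copy of `base` with the listed parameters multiplied; this is the
#' elementary operation of the multiparametric sensitivity designs, where each
#' design point is a map from parameter index to fold-change.
#'
#' @param base A [make_base_parameters()] object (or any `hdc_params`).
#' @param assignments Named list or vector of multipliers; names are parameter
#'   ids (`"p4"`) or bare indices (`4`). All multipliers must be positive.
#' @return A `hdc_params` equal to `base` except at the listed indices.
#' @examples
#' low_feedback <- scale_parameters(make_base_parameters(), list(p4 = 0.25))
#' @export
scale_parameters <- function(base, assignments) {
  stopifnot(inherits(base, "hdc_params"))
  out <- base
  if (length(assignments) == 0) return(out)
  mult <- unlist(assignments)
  nm <- names(mult)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("assignments must be named by parameter id (e.g. p4 = 0.25)")
  }
  nm <- ifelse(grepl("^[0-9]+$", nm), paste0("p", nm), nm)
  unknown <- setdiff(nm, param_names())
  if (length(unknown) > 0) {
    stop("unknown parameter index: ", paste(unknown, collapse = ", "),
         " (valid: p1..p18)")
  }
  if (any(!is.finite(mult)) || any(mult <= 0)) {
    stop("multipliers must be positive and finite")
  }
  out[nm] <- out[nm] * mult
  out
}

#' Fixed engine configuration
#'
#' Collects all quantities that define the simulation engine but are never
#' varied by sensitivity analysis: domain geometry, time stepping, initial
#' densities, signal decay rates and behavioral conventions.
#'
#' @param nx,ny Domain size in lattice sites.
#' @param dx Lattice spacing (LS); the model's unit of length.
#' @param dt Macro time step in days. Must divide `t_end` and `t_mpi` exactly.
#' @param t_end Simulation horizon (days); outcome is classified here.
#' @param t_mpi Time at which the macrophage polarization index is evaluated.
#' @param out_dt Output sampling interval for the cell-count time series.
#' @param n_substeps Diffusion sub-steps per macro step, or `NA` to choose
#'   automatically from the explicit-scheme stability bound
#'   `sub_dt <= dx^2 / (4 D)` with a safety factor of 0.8.
#' @param rho0 Initial naive-macrophage density, cells per lattice site.
#' @param v0 Baseline vasculature (au).
#' @param v_max Vasculature cap (au).
#' @param o2_init Initial oxygen level (pg/LS); the normoxic tissue value at
#'   which delivery and resident-cell uptake are taken as balanced.
#' @param lambda_tls,lambda_m2s,lambda_act,lambda_blocker First-order decay
#'   rates (1/day) of the corresponding signals. Oxygen has cellular uptake
#'   instead of decay.
#' @param necro_window Duration (days) for which a newly dead tumor cell keeps
#'   releasing Activator (necrosis-mediated macrophage activation).
#' @param chemotaxis_mode `"deterministic"` (move to the unoccupied neighbor
#'   with maximal M2S, ties at random) or `"stochastic"` (destination drawn
#'   with probability proportional to M2S plus `chemotaxis_floor`).
#' @param chemotaxis_floor Uniform weight floor (pg/LS) in stochastic mode.
#' @param chemotax_classes `"all"` macrophage classes chemotax (default), or
#'   `"naive_m1"` for the variant where M2 cells are sessile.
#' @param neighborhood `"moore"` (8 neighbors) or `"vonneumann"` (4).
#' @return A list of class `hdc_config`.
#' @export
make_engine_config <- function(nx = 100, ny = 100, dx = 1,
                               dt = 0.005, t_end = 5, t_mpi = 0.5, out_dt = 0.05,
                               n_substeps = NA,
                               rho0 = 0.01, v0 = 1, v_max = 40, o2_init = 1,
                               lambda_tls = 0.3, lambda_m2s = 0.5, lambda_act = 1,
                               lambda_blocker = 0.5,
                               necro_window = 0.5,
                               chemotaxis_mode = c("deterministic", "stochastic"),
                               chemotaxis_floor = 1e-7,
                               chemotax_classes = c("all", "naive_m1"),
                               neighborhood = c("moore", "vonneumann")) {
  chemotaxis_mode <- match.arg(chemotaxis_mode)
  chemotax_classes <- match.arg(chemotax_classes)
  neighborhood <- match.arg(neighborhood)
  stopifnot(nx >= 3, ny >= 3, dx > 0, dt > 0, t_end > 0, t_mpi > 0, out_dt > 0)
  if (t_mpi >= t_end) stop("t_mpi must be smaller than t_end")
  if (!divides(dt, t_end) || !divides(dt, t_mpi)) {
    stop("dt must divide t_end and t_mpi exactly")
  }
  if (!divides(out_dt, t_end) || !divides(dt, out_dt)) {
    stop("out_dt must be a multiple of dt and divide t_end")
  }
  cfg <- list(nx = as.integer(nx), ny = as.integer(ny), dx = dx,
              dt = dt, t_end = t_end, t_mpi = t_mpi, out_dt = out_dt,
              n_substeps = n_substeps,
              rho0 = rho0, v0 = v0, v_max = v_max, o2_init = o2_init,
              lambda_tls = lambda_tls, lambda_m2s = lambda_m2s,
              lambda_act = lambda_act, lambda_blocker = lambda_blocker,
              necro_window = necro_window,
              chemotaxis_mode = chemotaxis_mode,
              chemotaxis_floor = chemotaxis_floor,
              chemotax_classes = chemotax_classes,
              neighborhood = neighborhood)
  class(cfg) <- "hdc_config"
  cfg
}

divides <- function(small, big, tol = 1e-9) {
  ratio <- big / small
  abs(ratio - round(ratio)) < tol
}

#' @export
print.hdc_config <- function(x, ...) {
  cat(sprintf("<hdc_config> %dx%d lattice, dt = %g d, horizon %g d (MPI at %g d)\n",
              x$nx, x$ny, x$dt, x$t_end, x$t_mpi))
  cat(sprintf("  chemotaxis: %s (%s classes), neighborhood: %s\n",
              x$chemotaxis_mode, x$chemotax_classes, x$neighborhood))
  invisible(x)
}

#' Number of diffusion sub-steps actually used
#'
#' Resolves the configured `n_substeps` against the explicit-scheme stability
#' bound `sub_dt <= dx^2 / (4 D)` for the given diffusion coefficient. When
#' `n_substeps` is `NA`, enough sub-steps are taken that the diffusion number
#' `D sub_dt / dx^2` stays at or below 0.2 (bound 0.25, safety factor 0.8).
#'
#' @param cfg A [make_engine_config()] object.
#' @param D Diffusion coefficient (LS^2/day), typically `p1`.
#' @return Integer sub-step count, at least 1.
#' @export
resolve_substeps <- function(cfg, D) {
  if (D <= 0) return(1L)
  bound <- cfg$dx^2 / (4 * D)
  if (is.na(cfg$n_substeps)) {
    max(1L, as.integer(ceiling(cfg$dt / (0.8 * bound))))
  } else {
    as.integer(cfg$n_substeps)
  }
}

# cfg list as consumed by the C++ core (codes instead of strings, nsub resolved)
cfg_for_cpp <- function(cfg, ps) {
  c(cfg,
    list(n_substeps_resolved = resolve_substeps(cfg, ps[["p1"]]),
         chemo_mode_code = if (cfg$chemotaxis_mode == "stochastic") 1L else 0L,
         chemo_classes_code = if (cfg$chemotax_classes == "naive_m1") 1L else 0L,
         neighborhood_code = if (cfg$neighborhood == "vonneumann") 1L else 0L)) ->
    out
  out$n_substeps <- out$n_substeps_resolved
  out
}

#' Validate a parameter set against its invariants
#'
#' Checks every parameter-set invariant (strict positivity, integer initial
#' tumor count) plus the diffusion-stability bound implied by the engine
#' configuration. Validation always returns; it never throws.
#'
#' @param ps A `hdc_params` vector.
#' @param cfg A [make_engine_config()] object.
#' @return A list of class `hdc_validation` with elements `valid` (logical)
#'   and `violations` (character vector, empty when valid).
#' @export
validate_parameters <- function(ps, cfg = make_engine_config()) {
  v <- character(0)
  x <- unclass(ps)
  if (length(x) != 18 || !identical(names(x), param_names())) {
    v <- c(v, "parameter set must contain exactly p1..p18 in order")
  } else {
    bad <- names(x)[!is.finite(x) | x <= 0]
    if (length(bad) > 0) {
      v <- c(v, paste0(bad, " must be strictly positive"))
    }
    if (is.finite(x[["p18"]]) &&
        (x[["p18"]] < 1 || abs(x[["p18"]] - round(x[["p18"]])) > 1e-9)) {
      v <- c(v, "p18 must be a positive integer")
    }
    if (is.finite(x[["p1"]]) && x[["p1"]] > 0) {
      nsub <- resolve_substeps(cfg, x[["p1"]])
      sub_dt <- cfg$dt / nsub
      bound <- cfg$dx^2 / (4 * x[["p1"]])
      if (sub_dt > bound * (1 + 1e-12)) {
        v <- c(v, sprintf(
          "diffusion sub-step %.3g day violates stability bound dx^2/(4 p1) = %.3g day (need >= %d sub-steps)",
          sub_dt, bound, ceiling(cfg$dt / bound)))
      }
    }
  }
  structure(list(valid = length(v) == 0, violations = v),
            class = "hdc_validation")
}

#' @export
print.hdc_validation <- function(x, ...) {
  if (x$valid) cat("<hdc_validation> OK: all invariants satisfied\n")
  else cat("<hdc_validation>", length(x$violations), "violation(s):\n ",
           paste(x$violations, collapse = "\n  "), "\n")
  invisible(x)
}

#' Counter-based per-run seed derivation
#'
#' Maps (master seed, design-point index, replicate index) to a stream seed
#' deterministically and injectively (for fixed master seed, distinct
#' (point, replicate) pairs give distinct seeds as long as
#' `point * 10^5 + replicate` stays below 2^31 - 1). This makes sweeps
#' reproducible and order-independent under parallel execution.
#'
#' @param master Master seed, a non-negative integer.
#' @param point Design-point index (1-based) or 0 for standalone ensembles.
#' @param replicate Replicate index (1-based), below `1e5`.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_run_seed <- function(master, point, replicate) {
  stopifnot(master >= 0, point >= 0, replicate >= 1, replicate < 1e5)
  m <- 2147483647  # 2^31 - 1, prime
  idx <- point * 1e5 + replicate
  as.integer((((master %% m) * 69621) %% m + idx) %% m) + 1L
}
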