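#' Explicit diffusion step with zero-flux boundaries
#'
#' Advances a concentration grid by one macro time step of diffusion using the
#' explicit forward-time central-space 5-point stencil, sub-stepped so that the
#' stability bound `sub_dt <= dx^2 / (4 D)` holds. Boundaries are reflecting
#' (zero flux): the simulated patch is embedded in like tissue, so no mass
#' leaves the domain and the grid total is conserved to rounding error.
#'
#' @param field Numeric matrix of concentrations (pg/LS), all non-negative.
#' @param D Diffusion coefficient (LS^2/day).
#' @param dt Macro time step (day).
#' @param n_substeps Number of sub-steps, or `NA` to choose automatically.
#' @param dx Lattice spacing (LS).
#' @return The diffused matrix, same shape, non-negative, same total mass.
#' @examples
#' f <- matrix(0, 9, 9); f[5, 5] <- 1
#' g <- diffuse_field(f, D = 10, dt = 0.005)
#' all.equal(sum(g), 1)
#' @export
diffuse_field <- function(field, D, dt, n_substeps = NA, dx = 1) {
  stopifnot(is.matrix(field), D >= 0, dt > 0, dx > 0)
  if (D == 0) return(field)
  bound <- dx^2 / (4 * D)
  if (is.na(n_substeps)) {
    n_substeps <- max(1L, as.integer(ceiling(dt / (0.8 * bound))))
  }
  n_substeps <- as.integer(n_substeps)
  if (dt / n_substeps > bound * (1 + 1e-12)) {
    stop(sprintf(
      "diffusion sub-step %.4g day unstable for D = %g; need sub_dt <= %.4g day (>= %d sub-steps)",
      dt / n_substeps, D, bound, ceiling(dt / bound)))
  }
  cpp_diffuse(field, D, dt, n_substeps, dx)
}

#' Secretion, oxygen delivery/uptake and signal decay
#'
#' Applies one macro step of the local (non-diffusive) field dynamics to a
#' simulation state: M1 cells deposit TLS (`p5`; EMP-M1 at `tls_multiplier *
#' p5` under the enhanced-lethality therapy), tumor cells deposit M2S (`p2`)
#' and Activator (`p3`), recently dead tumor cells keep releasing Activator
#' for `necro_window` days, M2 cells deposit M2S (`p4`), vasculature delivers
#' oxygen (`p8` per au) and every live cell takes up oxygen (`p9`, floored at
#' zero), and TLS/M2S/Activator (and blocker) decay exponentially at their
#' configured rates.
#'
#' @param state A [initialize_state()] object.
#' @param ps A `hdc_params` vector.
#' @param cfg A [make_engine_config()] object.
#' @param therapy Optional [make_therapy_config()] object.
#' @return The state with updated `tls`, `m2s`, `activator`, `oxygen`,
#'   `blocker` grids.
#' @export
react_fields <- function(state, ps, cfg, therapy = NULL) {
  check_state(state)
  upd <- cpp_react(state, as.numeric(ps), cfg_for_cpp(cfg, ps),
                   therapy_for_cpp(therapy))
  state[names(upd)] <- upd
  state
}

#' M2S-driven vasculature growth
#'
#' Vasculature density grows in proportion to local M2S (`v += p14 * m2s *
#' dt`), is capped at `v_max` and never decreases: no vessel regression occurs
#' on the simulated 5-day horizon.
#'
#' @inheritParams react_fields
#' @return The state with an updated `vasculature` grid.
#' @export
grow_vasculature <- function(state, ps, cfg) {
  check_state(state)
  state$vasculature <- cpp_grow_vasc(state$vasculature, state$m2s,
                                     ps[["p14"]], cfg$v_max, cfg$dt)
  state
}
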