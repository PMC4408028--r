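#' Integer codes of the two occupancy layers
#'
#' The tumor layer and macrophage layer overlay the same lattice; each layer
#' holds at most one entry per site, and dead entries persist forever,
#' blocking their layer (retained dead cells, e.g. the necrotic core).
#'
#' @return A list with named integer code tables for the `tumor` and `mac`
#'   layers.
#' @export
occupancy_codes <- function() {
  list(
    tumor = c(EMPTY = 0L, TUMOR = 1L, DEAD = 2L),
    mac = c(EMPTY = 0L, NAIVE = 1L, M1 = 2L, M2 = 3L,
            EMP_NAIVE = 4L, EMP_M1 = 5L, EMP_M2 = 6L, MP_DEAD = 7L)
  )
}

#' Vasculature-proportional recruitment of naive macrophages
#'
#' Each macrophage-layer-empty site independently gains a naive macrophage
#' with probability `min(1, p15 * vasculature * dt)`; occupied sites are
#' unchanged. With a therapy configuration, recruits arriving at or after
#' `t_intro` are engineered (EMP) with probability `emp_fraction` (see
#' [recruit_with_emp()]).
#'
#' @inheritParams react_fields
#' @return The state with an updated macrophage layer.
#' @export
recruit_naive <- function(state, ps, cfg, therapy = NULL) {
  check_state(state)
  state$mac <- cpp_recruit(state$mac, state$vasculature, ps[["p15"]],
                           therapy_for_cpp(therapy), state$time, cfg$dt)
  state
}

#' M2 polarization probability
#'
#' The probability that an activated naive macrophage adopts the M2 state is
#' a logistic function of local M2S: `P(M2) = logistic((m2s - p13) / p16)`.
#' `p13` is the half-maximal threshold; `p16` sets the width of the
#' dose-response and is the model's functional-heterogeneity dial — larger
#' `p16` flattens the curve, making the decision more stochastic, while
#' `p16 -> 0` recovers a deterministic threshold rule.
#'
#' @param m2s_local Local M2S concentration(s), pg/LS, non-negative.
#' @param ps A `hdc_params` vector (uses `p13`, `p16`).
#' @return Probabilities in (0, 1), strictly increasing in `m2s_local`.
#' @examples
#' ps <- make_base_parameters()
#' polarization_probability(ps[["p13"]], ps)  # exactly 0.5 at the threshold
#' @export
polarization_probability <- function(m2s_local, ps) {
  stopifnot(all(m2s_local >= 0))
  stats::plogis((m2s_local - ps[["p13"]]) / ps[["p16"]])
}

#' Polarization of activated naive macrophages
#'
#' Naive macrophages at sites where Activator is at or above `p7` polarize
#' irreversibly: each draws a uniform variate and becomes M2 with probability
#' [polarization_probability()], otherwise M1. Sites below the Activator
#' threshold leave the cell naive. There is no M1/M2 interconversion. Under a
#' therapy configuration, EMP follow their strategy's rule (see
#' [emp_polarize()]).
#'
#' @inheritParams react_fields
#' @return The state with an updated macrophage layer.
#' @export
polarize_macrophages <- function(state, ps, cfg = NULL, therapy = NULL) {
  check_state(state)
  state$mac <- cpp_polarize(state$mac, state$activator, state$m2s,
                            state$blocker, as.numeric(ps),
                            therapy_for_cpp(therapy))
  state
}

#' Chemotaxis along M2S gradients
#'
#' Live macrophages are visited in a random order each step. In deterministic
#' mode each cell moves to the candidate site (its own site plus unoccupied
#' neighbors) with maximal M2S, ties broken uniformly at random; in stochastic
#' mode the destination is drawn with probability proportional to candidate
#' M2S plus a uniform floor. A fully surrounded cell stays put; the one-cell-
#' per-site-per-layer invariant is preserved.
#'
#' @inheritParams react_fields
#' @return The state with an updated macrophage layer.
#' @export
move_macrophages <- function(state, cfg, ps = NULL) {
  check_state(state)
  pvec <- if (is.null(ps)) make_base_parameters() else ps
  state$mac <- cpp_move(state$mac, state$m2s, cfg_for_cpp(cfg, pvec))
  state
}

#' Tumor division into empty neighboring sites
#'
#' Each live tumor cell with at least one tumor-layer-empty neighbor divides
#' with probability `min(1, p12 * dt)`, placing a daughter in a uniformly
#' chosen empty neighbor. Cells fully enclosed by tumor or dead cells cannot
#' divide, so growth is surface-limited.
#'
#' @inheritParams react_fields
#' @return The state with an updated tumor layer.
#' @export
divide_tumor <- function(state, ps, cfg) {
  check_state(state)
  state$tumor <- cpp_divide(state$tumor, ps[["p12"]], cfg_for_cpp(cfg, ps),
                            cfg$dt)
  state
}

#' Death by tumor lethality signal and by anoxia
#'
#' Live tumor cells at sites where TLS is at or above `p6` die; any live cell
#' (tumor or macrophage, engineered or not) at a site where oxygen is below
#' `p10` dies. Both thresholds are inclusive on the lethal side. Dead entries
#' persist and block their layer.
#'
#' @inheritParams react_fields
#' @return The state with updated tumor and macrophage layers and tumor
#'   death-time grid.
#' @export
apply_death <- function(state, ps, cfg = NULL) {
  check_state(state)
  upd <- cpp_death(state$tumor, state$mac, state$tls, state$oxygen,
                   state$tdeath, ps[["p6"]], ps[["p10"]], state$time)
  state$tumor <- upd$tumor
  state$mac <- upd$mac
  state$tdeath <- upd$tdeath
  state
}

check_state <- function(state) {
  if (!inherits(state, "hdc_state")) stop("not a hdc_state object")
  invisible(state)
}
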