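#' Initialize a simulation state
#'
#' Seeds the tumor layer with a compact disc of `p18` live tumor cells at the
#' domain center (sites ordered by distance, ties by angle), scatters naive
#' macrophages uniformly at random at density `rho0`, sets vasculature to
#' `v0` everywhere, draws the initial M2S field per site from
#' `Normal(p11, p17)` truncated at zero, initializes oxygen at the normoxic
#' level `o2_init`, and zeroes TLS, Activator and blocker. Deterministic
#' given the seed.
#'
#' @param ps A `hdc_params` vector.
#' @param cfg A [make_engine_config()] object.
#' @param seed Integer RNG seed. The same seed reproduces the state bitwise.
#' @return A list of class `hdc_state` with elements `time`, the field grids
#'   (`tls`, `m2s`, `activator`, `oxygen`, `blocker`, `vasculature`), the
#'   occupancy layers (`tumor`, `mac`) and the tumor death-time grid
#'   (`tdeath`, -1 where no death has occurred).
#' @export
initialize_state <- function(ps, cfg = make_engine_config(), seed = 1L) {
  val <- validate_parameters(ps, cfg)
  if (!val$valid) {
    stop("invalid parameters: ", paste(val$violations, collapse = "; "))
  }
  nx <- cfg$nx; ny <- cfg$ny
  n <- nx * ny
  p18 <- as.integer(round(ps[["p18"]]))
  if (p18 > n) stop("p18 = ", p18, " exceeds domain capacity of ", n, " sites")
  set.seed(seed)

  tumor <- matrix(0L, nx, ny)
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  ii <- rep(seq_len(nx), times = ny)
  jj <- rep(seq_len(ny), each = nx)
  d2 <- (ii - cx)^2 + (jj - cy)^2
  ang <- atan2(jj - cy, ii - cx)
  ord <- order(d2, ang)
  tumor[ord[seq_len(p18)]] <- 1L

  mac <- matrix(0L, nx, ny)
  n_mac <- round(cfg$rho0 * n)
  if (n_mac > 0) mac[sample.int(n, n_mac)] <- 1L

  m2s <- matrix(pmax(0, stats::rnorm(n, ps[["p11"]], ps[["p17"]])), nx, ny)

  state <- list(
    time = 0,
    tls = matrix(0, nx, ny),
    m2s = m2s,
    activator = matrix(0, nx, ny),
    oxygen = matrix(cfg$o2_init, nx, ny),
    blocker = matrix(0, nx, ny),
    vasculature = matrix(cfg$v0, nx, ny),
    tumor = tumor,
    mac = mac,
    tdeath = matrix(-1, nx, ny)
  )
  class(state) <- "hdc_state"
  state
}

#' @export
print.hdc_state <- function(x, ...) {
  ct <- state_counts(x)
  cat(sprintf("<hdc_state> t = %g d on a %dx%d lattice\n",
              x$time, nrow(x$tumor), ncol(x$tumor)))
  cat(sprintf("  tumor: %d live, %d dead; macrophages: %d naive, %d M1, %d M2 (+%d EMP, %d dead)\n",
              ct[["tumor_live"]], ct[["tumor_dead"]], ct[["naive"]],
              ct[["m1"]], ct[["m2"]],
              ct[["emp_naive"]] + ct[["emp_m1"]] + ct[["emp_m2"]],
              ct[["mac_dead"]]))
  invisible(x)
}

#' Cell counts of a state
#'
#' @param state A `hdc_state`.
#' @return Named integer vector of per-class cell counts.
#' @export
state_counts <- function(state) {
  check_state(state)
  mc <- tabulate(state$mac + 1L, nbins = 8)
  c(tumor_live = sum(state$tumor == 1L), tumor_dead = sum(state$tumor == 2L),
    naive = mc[2], m1 = mc[3], m2 = mc[4],
    emp_naive = mc[5], emp_m1 = mc[6], emp_m2 = mc[7], mac_dead = mc[8])
}

#' Advance the state by one macro time step
#'
#' Applies the eight update stages in their canonical order: (1) secretion,
#' oxygen delivery/uptake and decay; (2) diffusion of all diffusible signals
#' (sub-stepped); (3) vasculature growth; (4) recruitment; (5) polarization;
#' (6) chemotaxis; (7) tumor division; (8) death checks. Decisions therefore
#' read post-transport concentrations and deaths settle the step; a cell
#' recruited in stage 4 may polarize in stage 5 of the same step.
#'
#' @inheritParams react_fields
#' @return The advanced state; the clock has moved by exactly `dt`.
#' @export
step_state <- function(state, ps, cfg, therapy = NULL) {
  check_state(state)
  out <- cpp_step(state, as.numeric(ps), cfg_for_cpp(cfg, ps),
                  therapy_for_cpp(therapy))
  class(out) <- "hdc_state"
  out
}

#' Run one simulation to the horizon
#'
#' Initializes from the seed and advances the state to `t_end`, recording the
#' cell-count/field-summary time series every `out_dt`. When the tumor goes
#' extinct the run may exit early (the outcome can no longer change: dead
#' cells are never removed and tumor cells do not re-enter); the series is
#' padded to the horizon with its last values. Fully deterministic given
#' `(ps, cfg, seed, therapy)`.
#'
#' @inheritParams react_fields
#' @param seed Integer RNG seed for the run's stream.
#' @param early_exit Stop stepping once the tumor is extinct (default TRUE).
#' @param params_id Optional label stored with the result.
#' @return A list of class `hdc_run`: `ts` (data.frame time series), `mpi`
#'   (macrophage polarization index at `t_mpi`), `outcome` (`"SURVIVAL"` or
#'   `"DEATH"`), `first_core_time` (first appearance of a dead tumor cell,
#'   NA if none), `seed`, `params_id`, and `final_state`.
#' @examples
#' \donttest{
#' cfg <- make_engine_config(nx = 30, ny = 30, t_end = 1, t_mpi = 0.5)
#' ps <- scale_parameters(make_base_parameters(), list(p18 = 10 / 50))
#' r <- run_simulation(ps, cfg, seed = 1)
#' r$outcome
#' }
#' @export
run_simulation <- function(ps, cfg = make_engine_config(), seed = 1L,
                           therapy = NULL, early_exit = TRUE,
                           params_id = "base") {
  state <- initialize_state(ps, cfg, seed)  # validates and seeds the stream
  res <- cpp_run(state, as.numeric(ps), cfg_for_cpp(cfg, ps),
                 therapy_for_cpp(therapy), cfg$t_end, cfg$out_dt, early_exit)
  ts <- as.data.frame(res$ts)
  names(ts) <- c("time", "tumor_live", "tumor_dead", "naive", "m1", "m2",
                 "emp_naive", "emp_m1", "emp_m2", "mac_dead",
                 "m2s_mean", "m2s_max", "oxy_mean", "oxy_min",
                 "tls_mean", "tls_max", "act_mean", "vasc_mean", "vasc_max")
  row_mpi <- which.min(abs(ts$time - cfg$t_mpi))
  mpi_val <- mpi(ts[row_mpi, ])
  final_live <- ts$tumor_live[nrow(ts)]
  out <- list(
    params_id = params_id,
    seed = as.integer(seed),
    ts = ts,
    mpi = mpi_val,
    tumor_live_tmpi = ts$tumor_live[row_mpi],
    outcome = classify_outcome(final_live),
    first_core_time = res$first_core_time,
    early_exit = res$early_exit,
    final_state = structure(res$state, class = "hdc_state")
  )
  class(out) <- "hdc_run"
  out
}

#' @export
print.hdc_run <- function(x, ...) {
  cat(sprintf("<hdc_run> seed %d (%s): outcome %s, MPI(t_mpi) = %.3g\n",
              x$seed, x$params_id, x$outcome, x$mpi))
  invisible(x)
}

#' Classify the terminal outcome of a run
#'
#' A run counts as tumor survival when more than zero live tumor cells remain
#' at the horizon, and as tumor death when none do. If the evaluation time is
#' supplied and lies before the horizon, classification is refused unless the
#' tumor is already extinct (extinction is irreversible, so it certifies the
#' outcome early).
#'
#' @param tumor_live Final live tumor cell count (non-negative integer).
#' @param t Optional time at which the count was taken (days).
#' @param t_end Optional horizon (days).
#' @return `"SURVIVAL"` or `"DEATH"`.
#' @export
classify_outcome <- function(tumor_live, t = NULL, t_end = NULL) {
  if (length(tumor_live) != 1 || is.na(tumor_live) || tumor_live < 0) {
    stop("tumor_live must be a single non-negative count")
  }
  if (!is.null(t) && !is.null(t_end) && t < t_end && tumor_live > 0) {
    stop("cannot classify before the horizon: a live tumor at t < t_end is not a certificate")
  }
  if (tumor_live > 0) "SURVIVAL" else "DEATH"
}

#' Run an ensemble of replicates at one parameter set
#'
#' Convenience wrapper running `n` seeded replicates (seeds derived from the
#' master seed with [derive_run_seed()]) and returning the list of
#' [run_simulation()] results.
#'
#' @inheritParams run_simulation
#' @param n Number of replicates.
#' @param master_seed Master seed for the counter-based seed stream.
#' @param jobs Number of worker processes (forked; results are identical for
#'   any value because every replicate owns a derived seed).
#' @return List of `hdc_run` objects, length `n`, in replicate order.
#' @details By default ensembles run to the horizon without the
#'   extinction early exit, so outcome-stratified mean trajectories reflect
#'   the full macrophage dynamics; pass `early_exit = TRUE` when only
#'   outcomes and early-time metrics are needed.
#' @export
run_ensemble <- function(ps, cfg = make_engine_config(), n = 200,
                         master_seed = 1L, therapy = NULL, jobs = 1L,
                         params_id = "base", early_exit = FALSE) {
  seeds <- vapply(seq_len(n), function(r) derive_run_seed(master_seed, 0, r),
                  integer(1))
  worker <- function(r) {
    run_simulation(ps, cfg, seed = seeds[r], therapy = therapy,
                   params_id = params_id, early_exit = early_exit)
  }
  if (jobs > 1L) {
    parallel::mclapply(seq_len(n), worker, mc.cores = jobs)
  } else {
    lapply(seq_len(n), worker)
  }
}
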