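#' Engineered-macrophage (EMP) therapy configuration
#'
#' Three "Trojan horse" strategies modify how recruited engineered
#' macrophages behave while leaving their chemotaxis, oxygen uptake and
#' anoxia death identical to native cells:
#'
#' * `ENHANCED_TLS` — EMP polarize by the normal stochastic rule, but
#'   EMP-M1 cells secrete the tumor lethality signal at `tls_multiplier`
#'   times the native rate (enhanced immunostimulation).
#' * `NO_M2` — activated EMP always polarize to M1; the M2 branch is
#'   forbidden (decreased immunosuppression).
#' * `ACTIVE_CONVERSION` — as `NO_M2`, and every live EMP constitutively
#'   secretes a diffusible blocker; native naive macrophages then polarize
#'   using the competitively attenuated signal
#'   `M2S_eff = M2S / (1 + blocker / k_blocker)`.
#'
#' From `t_intro` onward, each newly recruited macrophage is an EMP with
#' probability `emp_fraction`; before `t_intro` no EMP enter, and the
#' resident population is never modified (only the recruit mix changes).
#'
#' @param strategy One of `"ENHANCED_TLS"`, `"NO_M2"`, `"ACTIVE_CONVERSION"`.
#' @param t_intro Introduction time of the first EMP, days, >= 0.
#' @param emp_fraction Fraction of incoming macrophages that are EMP after
#'   `t_intro`, in `[0, 1]`.
#' @param tls_multiplier Fold-increase of TLS secretion by EMP-M1 cells
#'   (`ENHANCED_TLS` only), >= 1.
#' @param blocker_rate Constitutive blocker secretion rate per live EMP,
#'   pg/LS/day (`ACTIVE_CONVERSION` only).
#' @param k_blocker Blocker inhibition constant, pg/LS: the blocker level at
#'   which effective M2S is halved.
#' @return A list of class `hdc_therapy`.
#' @export
make_therapy_config <- function(strategy = c("ENHANCED_TLS", "NO_M2",
                                             "ACTIVE_CONVERSION"),
                                t_intro = 0, emp_fraction = 0.5,
                                tls_multiplier = 4,
                                blocker_rate = 2e-6, k_blocker = 2e-7) {
  strategy <- match.arg(strategy)
  stopifnot(t_intro >= 0, emp_fraction >= 0, emp_fraction <= 1,
            tls_multiplier >= 1, blocker_rate >= 0, k_blocker > 0)
  tc <- list(strategy = strategy,
             strategy_code = match(strategy, c("ENHANCED_TLS", "NO_M2",
                                               "ACTIVE_CONVERSION")),
             t_intro = t_intro, emp_fraction = emp_fraction,
             tls_multiplier = tls_multiplier,
             blocker_rate = blocker_rate, k_blocker = k_blocker)
  class(tc) <- "hdc_therapy"
  tc
}

#' @export
print.hdc_therapy <- function(x, ...) {
  cat(sprintf("<hdc_therapy> %s: t_intro = %g d, EMP fraction = %g\n",
              x$strategy, x$t_intro, x$emp_fraction))
  invisible(x)
}

therapy_for_cpp <- function(therapy) {
  if (is.null(therapy)) return(NULL)
  stopifnot(inherits(therapy, "hdc_therapy"))
  list(strategy_code = as.integer(therapy$strategy_code),
       t_intro = therapy$t_intro, emp_fraction = therapy$emp_fraction,
       tls_multiplier = therapy$tls_multiplier,
       blocker_rate = therapy$blocker_rate, k_blocker = therapy$k_blocker)
}

#' Recruitment with an engineered-macrophage mix
#'
#' Identical to [recruit_naive()] except that, at or after `t_intro`, each
#' recruited cell enters as `EMP_NAIVE` with probability `emp_fraction` and
#' as native `NAIVE` otherwise. Before `t_intro` no EMP enter.
#'
#' @inheritParams react_fields
#' @param tc A [make_therapy_config()] object.
#' @return The state with an updated macrophage layer.
#' @export
recruit_with_emp <- function(state, ps, cfg, tc) {
  recruit_naive(state, ps, cfg, therapy = tc)
}

#' Polarization under an EMP strategy
#'
#' Applies the strategy-specific polarization rules described in
#' [make_therapy_config()] to all activated naive cells (native and EMP).
#'
#' @inheritParams react_fields
#' @param tc A [make_therapy_config()] object.
#' @return The state with an updated macrophage layer.
#' @export
emp_polarize <- function(state, ps, tc) {
  polarize_macrophages(state, ps, therapy = tc)
}

#' Introduction-time by EMP-fraction efficacy sweep
#'
#' For each combination of introduction time and EMP fraction, runs `reps`
#' therapy-enabled simulations and records the tumor survival probability.
#' Seeds derive from the master seed by grid-cell index and replicate, so the
#' grid is reproducible and order-independent.
#'
#' @inheritParams run_simulation
#' @param strategy Strategy name, passed to [make_therapy_config()].
#' @param t_intro_values Numeric vector of introduction times (days).
#' @param fraction_values Numeric vector of EMP fractions in `[0, 1]`.
#' @param reps Replicates per grid cell.
#' @param master_seed Master seed of the sweep.
#' @param jobs Worker processes (forked).
#' @param ... Further arguments to [make_therapy_config()].
#' @return Object of class `hdc_survival_grid`: a matrix of survival
#'   probabilities (rows = introduction times, columns = fractions) with
#'   attributes `reps`, `strategy`, `n_failed`.
#' @export
therapy_sweep <- function(ps, cfg = make_engine_config(), strategy = "NO_M2",
                          t_intro_values = c(0, 2.5), fraction_values = c(0.1, 0.5),
                          reps = 50, master_seed = 1L, jobs = 1L, ...) {
  stopifnot(reps >= 1)
  grid <- expand.grid(t_intro = t_intro_values, frac = fraction_values,
                      KEEP.OUT.ATTRS = FALSE)
  one_cell <- function(k) {
    tc <- make_therapy_config(strategy = strategy, t_intro = grid$t_intro[k],
                              emp_fraction = grid$frac[k], ...)
    n_surv <- 0L; n_fail <- 0L
    for (r in seq_len(reps)) {
      seed <- derive_run_seed(master_seed, k, r)
      res <- tryCatch(run_simulation(ps, cfg, seed = seed, therapy = tc),
                      error = function(e) e)
      if (inherits(res, "error")) { n_fail <- n_fail + 1L; next }
      if (res$outcome == "SURVIVAL") n_surv <- n_surv + 1L
    }
    c(surv = n_surv, fail = n_fail)
  }
  res <- if (jobs > 1L) {
    parallel::mclapply(seq_len(nrow(grid)), one_cell, mc.cores = jobs)
  } else {
    lapply(seq_len(nrow(grid)), one_cell)
  }
  surv <- vapply(res, `[[`, numeric(1), "surv")
  fail <- vapply(res, `[[`, numeric(1), "fail")
  prob <- surv / pmax(1, reps - fail)
  g <- matrix(prob, nrow = length(t_intro_values),
              dimnames = list(t_intro = t_intro_values,
                              emp_fraction = fraction_values))
  structure(g, class = c("hdc_survival_grid", "matrix"),
            reps = reps, strategy = strategy, master_seed = master_seed,
            n_failed = matrix(fail, nrow = length(t_intro_values)))
}

#' @export
print.hdc_survival_grid <- function(x, ...) {
  cat(sprintf("<hdc_survival_grid> %s, %d reps/cell (rows t_intro, cols EMP fraction)\n",
              attr(x, "strategy"), attr(x, "reps")))
  m <- x
  attributes(m) <- attributes(x)[c("dim", "dimnames")]
  print(round(m, 3))
  invisible(x)
}
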