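#' Macrophage polarization index (MPI)
#'
#' `MPI = M2 / (1 + M1 + naive)`: the bias of the macrophage population
#' toward the tumor-promoting M2 phenotype. The +1 keeps the ratio finite for
#' empty populations; MPI is zero exactly when no M2 cells are present and
#' strictly decreases in the M1 and naive counts. Engineered macrophages are
#' counted with their phenotypic class by default so therapy ensembles remain
#' comparable; `native_only = TRUE` restricts to unmodified cells.
#'
#' @param counts Named vector, list or one-row data.frame with components
#'   `m2`, `m1`, `naive` (and optionally `emp_m2`, `emp_m1`, `emp_naive`).
#' @param native_only Count only unmodified macrophages.
#' @return A single non-negative finite number.
#' @examples
#' mpi(c(m2 = 9, m1 = 3, naive = 5))  # 9 / (1 + 3 + 5) = 1
#' @export
mpi <- function(counts, native_only = FALSE) {
  g <- function(nm) {
    if (!nm %in% names(counts)) return(0)
    v <- counts[[nm]]
    if (is.null(v) || length(v) == 0) 0 else as.numeric(v)
  }
  if (any(c(g("m2"), g("m1"), g("naive"),
            g("emp_m2"), g("emp_m1"), g("emp_naive")) < 0)) {
    stop("cell counts must be non-negative")
  }
  if (native_only) {
    g("m2") / (1 + g("m1") + g("naive"))
  } else {
    (g("m2") + g("emp_m2")) /
      (1 + g("m1") + g("emp_m1") + g("naive") + g("emp_naive"))
  }
}

#' Mean local coefficient of variation of a field
#'
#' Partitions the grid into non-overlapping `tile x tile` arrays, computes the
#' coefficient of variation (sd/mean) of the field within each array, and
#' returns the mean over all arrays. On the default 100x100 domain with
#' `tile = 10` this averages exactly 100 array values. The CV of an array
#' whose mean is zero is defined as zero. The statistic is invariant to
#' multiplying the field by a positive constant, making it a pure measure of
#' spatial heterogeneity.
#'
#' @param field Numeric matrix.
#' @param tile Tile edge length in lattice sites; must divide both dimensions.
#' @param population_sd Use the population standard deviation (divisor `n`,
#'   the default) rather than the sample sd (divisor `n - 1`).
#' @return Mean of the per-array CVs.
#' @export
mean_local_cv <- function(field, tile = 10, population_sd = TRUE) {
  stopifnot(is.matrix(field))
  nx <- nrow(field); ny <- ncol(field)
  if (nx %% tile != 0 || ny %% tile != 0) {
    adm <- Filter(function(t) nx %% t == 0 && ny %% t == 0, seq_len(min(nx, ny)))
    stop(sprintf("tile %d does not divide the %dx%d domain; admissible tiles: %s",
                 tile, nx, ny, paste(adm, collapse = ", ")))
  }
  bi <- (seq_len(nx) - 1L) %/% tile
  bj <- (seq_len(ny) - 1L) %/% tile
  block <- outer(bi, bj * (nx %/% tile), "+")
  mu <- tapply(field, block, mean)
  if (population_sd) {
    m2 <- tapply(field^2, block, mean)
    sdv <- sqrt(pmax(0, m2 - mu^2))
  } else {
    sdv <- tapply(field, block, stats::sd)
  }
  cv <- ifelse(mu == 0, 0, sdv / mu)
  mean(cv)
}

#' Domain-wide mean and maximum of a field
#'
#' @param field Numeric matrix.
#' @return Named numeric vector `c(mean = , max = )`.
#' @export
field_summary <- function(field) {
  c(mean = mean(field), max = max(field))
}

#' Tumor survival probability of an ensemble
#'
#' Fraction of runs classified `"SURVIVAL"`, with an exact (Clopper-Pearson)
#' binomial confidence interval.
#'
#' @param outcomes Character vector of outcomes, or a list of `hdc_run`
#'   objects.
#' @param conf_level Confidence level for the interval.
#' @return List with `prob`, `n`, `lower`, `upper`.
#' @export
survival_probability <- function(outcomes, conf_level = 0.95) {
  if (is.list(outcomes) && length(outcomes) > 0 &&
      inherits(outcomes[[1]], "hdc_run")) {
    outcomes <- vapply(outcomes, `[[`, character(1), "outcome")
  }
  if (length(outcomes) == 0) stop("empty outcome sequence")
  if (!all(outcomes %in% c("SURVIVAL", "DEATH"))) {
    stop("outcomes must be SURVIVAL or DEATH")
  }
  k <- sum(outcomes == "SURVIVAL"); n <- length(outcomes)
  ci <- stats::binom.test(k, n, conf.level = conf_level)$conf.int
  list(prob = k / n, n = n, lower = ci[1], upper = ci[2])
}

#' Regress tumor survival probability on an early-time metric
#'
#' Ordinary least squares of survival probability on a per-design-point
#' metric (for instance mean MPI or mean tumor count at `t_mpi`), restricted
#' to design points whose survival probability is below one — points where
#' the tumor always survives carry no information about the boundary. The
#' metric may be min-max normalized across points first; the R-squared is
#' invariant to that (or any affine) transformation.
#'
#' @param points A data.frame with a `survival_prob` column and the metric
#'   column, e.g. the table from [run_design()].
#' @param metric Name of the metric column (default `"mean_mpi"`).
#' @param normalize Min-max normalize the metric before fitting.
#' @return A list of class `hdc_regression` with `slope`, `intercept`, `r2`,
#'   `n`, `filter` and `degenerate` (TRUE when the metric was constant, in
#'   which case `r2` is reported as 0).
#' @export
regress_metric_vs_survival <- function(points, metric = "mean_mpi",
                                       normalize = TRUE) {
  stopifnot(is.data.frame(points), "survival_prob" %in% names(points),
            metric %in% names(points))
  keep <- points$survival_prob < 1
  d <- points[keep, , drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 design points with survival probability < 1")
  x <- d[[metric]]
  degenerate <- (max(x) - min(x)) == 0 ||
    (max(d$survival_prob) - min(d$survival_prob)) == 0
  if (normalize && !degenerate) x <- (x - min(x)) / (max(x) - min(x))
  if (degenerate) {
    out <- list(slope = 0, intercept = mean(d$survival_prob), r2 = 0,
                n = nrow(d), filter = "survival_prob < 1", degenerate = TRUE)
  } else {
    fit <- stats::lm(d$survival_prob ~ x)
    # exactly collinear synthetic inputs trigger summary.lm's perfect-fit
    # warning; the R^2 itself is what we report
    r2 <- suppressWarnings(summary(fit)$r.squared)
    out <- list(slope = unname(stats::coef(fit)[2]),
                intercept = unname(stats::coef(fit)[1]),
                r2 = r2,
                n = nrow(d), filter = "survival_prob < 1", degenerate = FALSE)
  }
  class(out) <- "hdc_regression"
  out
}

#' @export
print.hdc_regression <- function(x, ...) {
  cat(sprintf("<hdc_regression> slope %.4g, intercept %.4g, R^2 = %.3f (n = %d, %s)\n",
              x$slope, x$intercept, x$r2, x$n, x$filter))
  invisible(x)
}

#' Outcome-stratified ensemble aggregates
#'
#' Groups the runs of an ensemble by terminal outcome and returns, per group,
#' the mean and standard-error trajectory of every cell class, plus the MPI
#' values at `t_mpi` for histogramming. All runs must share the output time
#' grid.
#'
#' @param results List of `hdc_run` objects.
#' @return List of class `hdc_outcome_groups`: `trajectories` (data.frame with
#'   outcome, time, class, mean, se), `mpi` (data.frame with outcome, mpi),
#'   `n` (named group sizes).
#' @export
aggregate_by_outcome <- function(results) {
  stopifnot(length(results) > 0)
  times <- results[[1]]$ts$time
  for (r in results) {
    if (!isTRUE(all.equal(r$ts$time, times))) {
      stop("all results must share the output time grid")
    }
  }
  outcomes <- vapply(results, `[[`, character(1), "outcome")
  if (length(unique(outcomes)) == 1) {
    warning("single-outcome ensemble: only one group formed")
  }
  classes <- c("tumor_live", "tumor_dead", "naive", "m1", "m2",
               "emp_naive", "emp_m1", "emp_m2", "mac_dead")
  traj <- do.call(rbind, lapply(unique(outcomes), function(oc) {
    sub <- results[outcomes == oc]
    do.call(rbind, lapply(classes, function(cl) {
      m <- vapply(sub, function(r) r$ts[[cl]], numeric(length(times)))
      m <- matrix(m, nrow = length(times))
      data.frame(outcome = oc, time = times, class = cl,
                 mean = rowMeans(m),
                 se = apply(m, 1, stats::sd) / sqrt(ncol(m)))
    }))
  }))
  mpis <- data.frame(outcome = outcomes,
                     mpi = vapply(results, `[[`, numeric(1), "mpi"))
  out <- list(trajectories = traj, mpi = mpis, n = table(outcomes))
  class(out) <- "hdc_outcome_groups"
  out
}

#' @export
print.hdc_outcome_groups <- function(x, ...) {
  cat("<hdc_outcome_groups>", paste(names(x$n), as.integer(x$n),
                                    sep = ": ", collapse = ", "), "\n")
  agg <- stats::aggregate(mpi ~ outcome, data = x$mpi, FUN = mean)
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  mean MPI(t_mpi) | %s = %.4g\n", agg$outcome[i], agg$mpi[i]))
  }
  invisible(x)
}
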