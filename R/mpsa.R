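#' Multiplier grids of the two sensitivity designs
#'
#' The linear design samples one order of magnitude around the base value,
#' `{0.25, 0.75, 1.25, 1.75, 2.25} * p_i`; the log design spans two orders of
#' magnitude, `{0.1, 0.3, 1.0, 3.0, 10.0} * p_i`.
#'
#' @param mode `"LINEAR"` or `"LOG"`.
#' @return Numeric vector of the five multipliers.
#' @export
design_multipliers <- function(mode = c("LINEAR", "LOG")) {
  mode <- match.arg(mode)
  if (mode == "LINEAR") c(0.25, 0.75, 1.25, 1.75, 2.25)
  else c(0.1, 0.3, 1.0, 3.0, 10.0)
}

#' Build a one- and two-parameter sensitivity design
#'
#' Enumerates the design points of the multiparametric sensitivity analysis:
#' for every parameter a SINGLE case sweeping the five multipliers, and for
#' every unordered pair of distinct parameters a PAIR case sweeping the 5x5
#' multiplier grid. With all 18 parameters this gives 18 single cases and 153
#' proper pair cases (171 pair cases when the degenerate self-pairs, which
#' coincide with the single cases, are counted), for 18*5 + 153*25 = 3915
#' unique design points; see [design_cardinality()].
#'
#' @param base A `hdc_params` vector.
#' @param mode `"LINEAR"` or `"LOG"` multiplier grid.
#' @param reps Replicate simulations per design point.
#' @param params Integer vector of parameter indices to sweep (default all 18).
#' @param pairs Include the pairwise design points.
#' @return An object of class `hdc_design`: a data.frame with columns `id`,
#'   `type` (`"SINGLE"`/`"PAIR"`), `i`, `j`, `mi`, `mj`, plus attributes
#'   `base`, `mode`, `reps`, `multipliers`. Point ids are stable and sorted.
#' @export
build_design <- function(base, mode = c("LINEAR", "LOG"), reps = 50,
                         params = 1:18, pairs = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(base, "hdc_params"), reps >= 1,
            all(params %in% 1:18), !anyDuplicated(params))
  params <- sort(as.integer(params))
  mult <- design_multipliers(mode)
  singles <- expand.grid(mi = mult, i = params)[, c("i", "mi")]
  singles <- data.frame(type = "SINGLE", i = singles$i, j = NA_integer_,
                        mi = singles$mi, mj = NA_real_)
  rows <- singles[order(singles$i, singles$mi), ]
  if (pairs && length(params) >= 2) {
    pr <- utils::combn(params, 2)
    pair_rows <- do.call(rbind, lapply(seq_len(ncol(pr)), function(k) {
      g <- expand.grid(mj = mult, mi = mult)
      data.frame(type = "PAIR", i = pr[1, k], j = pr[2, k],
                 mi = g$mi, mj = g$mj)
    }))
    pair_rows <- pair_rows[order(pair_rows$i, pair_rows$j,
                                 pair_rows$mi, pair_rows$mj), ]
    rows <- rbind(rows, pair_rows)
  }
  rows$id <- ifelse(rows$type == "SINGLE",
                    sprintf("S_p%02d_m%.2f", rows$i, rows$mi),
                    sprintf("P_p%02dxp%02d_m%.2fx%.2f",
                            rows$i, rows$j, rows$mi, rows$mj))
  rownames(rows) <- NULL
  rows <- rows[, c("id", "type", "i", "j", "mi", "mj")]
  structure(rows, class = c("hdc_design", "data.frame"),
            base = base, mode = mode, reps = as.integer(reps),
            multipliers = mult, params = params)
}

#' Cardinalities of a sensitivity design
#'
#' Reports both enumeration conventions for the pairwise design: proper
#' unordered pairs (i < j) and pair cases including the degenerate self-pairs
#' (i <= j), whose grids collapse onto the single-parameter cases. With the
#' full 18-parameter design these are 153 and 171 respectively, and the
#' design holds 3915 unique points.
#'
#' @param design A [build_design()] object.
#' @return List with `singles`, `proper_pairs`, `pair_cases`,
#'   `unique_points`, `evaluations` (points times replicates).
#' @export
design_cardinality <- function(design) {
  stopifnot(inherits(design, "hdc_design"))
  np <- length(attr(design, "params"))
  has_pairs <- any(design$type == "PAIR")
  proper <- if (has_pairs) choose(np, 2) else 0
  list(singles = np,
       proper_pairs = proper,
       pair_cases = if (has_pairs) proper + np else 0,
       unique_points = nrow(design),
       evaluations = nrow(design) * attr(design, "reps"))
}

#' @export
print.hdc_design <- function(x, ...) {
  card <- design_cardinality(x)
  cat(sprintf("<hdc_design> %s mode: %d single + %d proper-pair cases, %d unique points x %d reps\n",
              attr(x, "mode"), card$singles, card$proper_pairs,
              card$unique_points, attr(x, "reps")))
  invisible(x)
}

design_assignments <- function(row) {
  a <- list()
  a[[paste0("p", row$i)]] <- row$mi
  if (!is.na(row$j)) a[[paste0("p", row$j)]] <- row$mj
  a
}

#' Execute a sensitivity design
#'
#' Runs `reps` seeded simulations per design point and tallies outcomes and
#' early-time metrics. Seeds are derived from the master seed by design-point
#' index and replicate ([derive_run_seed()]), so results are identical
#' regardless of execution order or parallelism. Per-point checkpoint files
#' allow interrupted sweeps to resume.
#'
#' @param design A [build_design()] object.
#' @param cfg A [make_engine_config()] object.
#' @param master_seed Master seed of the sweep.
#' @param jobs Worker processes (forked).
#' @param checkpoint_dir Optional directory for one CSV per design point;
#'   existing files are reused instead of re-simulated.
#' @param therapy Optional therapy configuration applied to every run.
#' @return An object of class `hdc_mpsa`: the design columns plus
#'   `n_survival`, `n_death`, `n_failed`, `reps`, `survival_prob`,
#'   `mean_mpi`, `mean_tumor` (the latter two at `t_mpi`), with provenance
#'   attributes (`master_seed`, `cfg`).
#' @export
run_design <- function(design, cfg = make_engine_config(), master_seed = 1L,
                       jobs = 1L, checkpoint_dir = NULL, therapy = NULL) {
  stopifnot(inherits(design, "hdc_design"))
  base <- attr(design, "base")
  reps <- attr(design, "reps")
  if (!is.null(checkpoint_dir) && !dir.exists(checkpoint_dir)) {
    dir.create(checkpoint_dir, recursive = TRUE)
  }
  one_point <- function(k) {
    row <- design[k, ]
    ckpt <- if (!is.null(checkpoint_dir)) {
      file.path(checkpoint_dir, paste0(row$id, ".csv"))
    } else NULL
    if (!is.null(ckpt) && file.exists(ckpt)) {
      return(utils::read.csv(ckpt))
    }
    ps <- scale_parameters(base, design_assignments(row))
    n_surv <- 0L; n_fail <- 0L
    mpis <- numeric(0); tums <- numeric(0)
    for (r in seq_len(reps)) {
      seed <- derive_run_seed(master_seed, k, r)
      res <- tryCatch(
        run_simulation(ps, cfg, seed = seed, therapy = therapy,
                       params_id = row$id),
        error = function(e) e)
      if (inherits(res, "error")) {
        n_fail <- n_fail + 1L
        next
      }
      if (res$outcome == "SURVIVAL") n_surv <- n_surv + 1L
      mpis <- c(mpis, res$mpi)
      tums <- c(tums, res$tumor_live_tmpi)
    }
    ok <- reps - n_fail
    out <- data.frame(id = row$id, n_survival = n_surv,
                      n_death = ok - n_surv, n_failed = n_fail, reps = reps,
                      survival_prob = if (ok > 0) n_surv / ok else NA_real_,
                      mean_mpi = if (ok > 0) mean(mpis) else NA_real_,
                      mean_tumor = if (ok > 0) mean(tums) else NA_real_)
    if (!is.null(ckpt)) utils::write.csv(out, ckpt, row.names = FALSE)
    out
  }
  res <- if (jobs > 1L) {
    parallel::mclapply(seq_len(nrow(design)), one_point, mc.cores = jobs)
  } else {
    lapply(seq_len(nrow(design)), one_point)
  }
  tab <- do.call(rbind, res)
  out <- cbind(design[, c("id", "type", "i", "j", "mi", "mj")],
               tab[, setdiff(names(tab), "id")])
  structure(out, class = c("hdc_mpsa", "data.frame"),
            base = base, mode = attr(design, "mode"),
            multipliers = attr(design, "multipliers"),
            params = attr(design, "params"),
            reps = reps, master_seed = master_seed)
}

#' @export
print.hdc_mpsa <- function(x, ...) {
  cat(sprintf("<hdc_mpsa> %d design points x %d reps (master seed %d)\n",
              nrow(x), attr(x, "reps"), attr(x, "master_seed")))
  cat(sprintf("  survival probability: min %.2f, median %.2f, max %.2f\n",
              min(x$survival_prob, na.rm = TRUE),
              stats::median(x$survival_prob, na.rm = TRUE),
              max(x$survival_prob, na.rm = TRUE)))
  invisible(x)
}

# Quadratic response-surface model matrix in the multipliers.
# x_i = multiplier of parameter i (1.0 when unvaried at a point).
quad_model_matrix <- function(tab, params) {
  n <- nrow(tab)
  X <- matrix(1, n, length(params))
  colnames(X) <- paste0("x", params)
  for (r in seq_len(n)) {
    X[r, paste0("x", tab$i[r])] <- tab$mi[r]
    if (!is.na(tab$j[r])) X[r, paste0("x", tab$j[r])] <- tab$mj[r]
  }
  terms <- list()
  for (ix in seq_along(params)) {
    terms[[paste0("b", params[ix])]] <- X[, ix]
    terms[[paste0("b", params[ix], "_", params[ix])]] <- X[, ix]^2
  }
  if (length(params) >= 2) {
    cmb <- utils::combn(params, 2)
    for (k in seq_len(ncol(cmb))) {
      i <- cmb[1, k]; j <- cmb[2, k]
      terms[[paste0("b", i, "_", j)]] <-
        X[, paste0("x", i)] * X[, paste0("x", j)]
    }
  }
  do.call(cbind, terms)
}

#' Quadratic-regression sensitivities of a behavior metric
#'
#' Fits the response surface
#' `metric ~ b0 + sum_i b_i x_i + sum_i b_ii x_i^2 + sum_{i<j} b_ij x_i x_j`
#' by least squares over the design points, where `x_i` is the multiplier of
#' parameter i (1 when unvaried), and defines the sensitivity of the metric
#' to parameter i as the partial derivative of the fitted surface at the base
#' point `x = 1`: `s_i = b_i + 2 b_ii + sum_{j != i} b_ij`. Sensitivities are
#' normalized so the largest magnitude is one, and ranked by signed value.
#' Because the covariates are dimensionless fold-changes, sensitivities are
#' comparable across parameters.
#'
#' @param result A [run_design()] table (or any data.frame with columns
#'   `i`, `j`, `mi`, `mj` and the metric).
#' @param metric Metric column to model (default `"survival_prob"`).
#' @param base_point Multiplier value at which the derivative is evaluated
#'   (default 1, the base case).
#' @param interactions Include the pairwise interaction terms.
#' @return Object of class `hdc_sensitivity`: data.frame with `param`,
#'   `sensitivity`, `normalized`, `rank`, plus attributes `metric`, `r2`
#'   (goodness of fit) and `dropped` (terms removed by rank deficiency, whose
#'   coefficients are treated as zero).
#' @export
quadratic_sensitivities <- function(result, metric = "survival_prob",
                                    base_point = 1.0, interactions = TRUE) {
  stopifnot(is.data.frame(result), metric %in% names(result),
            all(c("i", "j", "mi", "mj") %in% names(result)))
  keep <- !is.na(result[[metric]])
  tab <- result[keep, , drop = FALSE]
  params <- sort(unique(c(tab$i, tab$j[!is.na(tab$j)])))
  M <- quad_model_matrix(tab, params)
  if (!interactions) {
    is_cross <- vapply(strsplit(sub("^b", "", colnames(M)), "_"),
                       function(s) length(s) == 2 && s[1] != s[2], logical(1))
    M <- M[, !is_cross, drop = FALSE]
  }
  y <- tab[[metric]]
  fit <- stats::lm(y ~ M)
  cf <- stats::coef(fit)
  names(cf) <- sub("^M", "", names(cf))
  dropped <- names(cf)[is.na(cf)]
  cf[is.na(cf)] <- 0
  coef_of <- function(nm) if (nm %in% names(cf)) cf[[nm]] else 0
  sens <- vapply(params, function(i) {
    s <- coef_of(paste0("b", i)) + 2 * coef_of(paste0("b", i, "_", i)) * base_point
    for (j in params) {
      if (j == i) next
      nm <- paste0("b", min(i, j), "_", max(i, j))
      s <- s + coef_of(nm) * base_point
    }
    s
  }, numeric(1))
  scale <- max(abs(sens))
  normalized <- if (scale > 0) sens / scale else sens
  tabout <- data.frame(param = paste0("p", params),
                       sensitivity = sens,
                       normalized = normalized,
                       rank = rank(-sens, ties.method = "first"))
  # noiseless synthetic surfaces fit exactly; the perfect-fit warning from
  # summary.lm is expected there
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(tabout, class = c("hdc_sensitivity", "data.frame"),
            metric = metric, r2 = r2,
            scale = scale, dropped = dropped, base_point = base_point)
}

#' @export
print.hdc_sensitivity <- function(x, ...) {
  cat(sprintf("<hdc_sensitivity> metric '%s', fit R^2 = %.3f\n",
              attr(x, "metric"), attr(x, "r2")))
  ord <- order(x$rank)
  print(data.frame(x)[ord, ], row.names = FALSE)
  invisible(x)
}

#' Change in sensitivities between two base cases
#'
#' Elementwise difference (`alt - base`) of the raw sensitivities of two
#' reports for the same metric, expressed on a shared normalization scale
#' (the larger of the two reports' maximal sensitivity magnitudes), so that
#' deltas are comparable to the normalized sensitivities themselves.
#'
#' @param report_alt,report_base Two [quadratic_sensitivities()] reports for
#'   the same metric and parameter set.
#' @return data.frame with `param` and `delta`.
#' @export
sensitivity_delta <- function(report_alt, report_base) {
  stopifnot(inherits(report_alt, "hdc_sensitivity"),
            inherits(report_base, "hdc_sensitivity"))
  if (!identical(attr(report_alt, "metric"), attr(report_base, "metric"))) {
    stop("sensitivity reports are for different metrics: ",
         attr(report_alt, "metric"), " vs ", attr(report_base, "metric"))
  }
  if (!identical(report_alt$param, report_base$param)) {
    stop("sensitivity reports cover different parameters")
  }
  scale <- max(attr(report_alt, "scale"), attr(report_base, "scale"))
  if (scale <= 0) scale <- 1
  data.frame(param = report_alt$param,
             delta = (report_alt$sensitivity - report_base$sensitivity) / scale)
}

#' Extract a pairwise metric surface
#'
#' Returns the 5x5 grid of a metric over the multiplier combinations of one
#' parameter pair, rows indexed by the multiplier of `i` and columns by the
#' multiplier of `j` (so the grid for `(j, i)` is the transpose).
#'
#' @param result A [run_design()] table containing the pair.
#' @param i,j Distinct parameter indices present as a PAIR case.
#' @param metric Metric column (default `"survival_prob"`).
#' @return Numeric matrix with multiplier dimnames.
#' @export
pairwise_surface <- function(result, i, j, metric = "survival_prob") {
  stopifnot(is.data.frame(result), i != j)
  lo <- min(i, j); hi <- max(i, j)
  sub <- result[result$type == "PAIR" & result$i == lo & result$j == hi, ]
  if (nrow(sub) == 0) {
    stop(sprintf("pair (p%d, p%d) is not present in the design", i, j))
  }
  mult <- sort(unique(c(sub$mi, sub$mj)))
  g <- matrix(NA_real_, length(mult), length(mult),
              dimnames = list(mult, mult))
  for (r in seq_len(nrow(sub))) {
    g[as.character(sub$mi[r]), as.character(sub$mj[r])] <- sub[[metric]][r]
  }
  if (i <= j) g else t(g)
}
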