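#' Write a parameter/engine/therapy configuration file
#'
#' Serializes the model configuration as a flat key-value YAML file with unit
#' annotations in comments. Decimal values are written at full double
#' precision so a write-read round trip is lossless.
#'
#' @param ps A `hdc_params` vector.
#' @param cfg A [make_engine_config()] object.
#' @param path Output file path.
#' @param therapy Optional [make_therapy_config()] object.
#' @return `path`, invisibly.
#' @export
save_config <- function(ps, cfg, path, therapy = NULL) {
  fmt <- function(v) {
    if (is.character(v)) v
    else if (is.na(v)) "~"
    else if (is.integer(v) || (is.numeric(v) && v == round(v) && abs(v) < 1e15)) {
      format(v, scientific = FALSE)
    } else format(v, digits = 17)
  }
  units <- c(p1 = "LS^2/day", p2 = "pg/LS/day", p3 = "pg/LS/day",
             p4 = "pg/LS/day", p5 = "pg/LS/day", p6 = "pg/LS", p7 = "pg/LS",
             p8 = "pg/LS/day/au", p9 = "pg/LS/day", p10 = "pg/LS",
             p11 = "pg/LS", p12 = "1/day", p13 = "pg/LS",
             p14 = "au/day/(pg/LS)", p15 = "cells/LS/day/au", p16 = "pg/LS",
             p17 = "pg/LS", p18 = "cells")
  lines <- c("# hdctme configuration", "params:")
  for (nm in names(ps)) {
    lines <- c(lines, sprintf("  %s: %s  # [%s]", nm, fmt(ps[[nm]]), units[[nm]]))
  }
  lines <- c(lines, "engine:")
  for (nm in names(cfg)) {
    lines <- c(lines, sprintf("  %s: %s", nm, fmt(cfg[[nm]])))
  }
  if (!is.null(therapy)) {
    lines <- c(lines, "therapy:")
    for (nm in setdiff(names(therapy), "strategy_code")) {
      lines <- c(lines, sprintf("  %s: %s", nm, fmt(therapy[[nm]])))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

suggest_key <- function(key, valid) {
  d <- utils::adist(key, valid)
  valid[which.min(d)]
}

#' Load and validate a configuration file
#'
#' Reads a [save_config()] file back into validated parameter, engine and
#' (optionally) therapy objects. Unknown keys are rejected with a
#' nearest-key suggestion.
#'
#' @param path Configuration file path.
#' @return List with elements `params` (`hdc_params`), `cfg` (`hdc_config`)
#'   and `therapy` (`hdc_therapy` or `NULL`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  bad_top <- setdiff(names(raw), c("params", "engine", "therapy"))
  if (length(bad_top) > 0) {
    stop("unknown section '", bad_top[1], "'; expected params/engine/therapy")
  }
  pn <- param_names()
  unknown <- setdiff(names(raw$params), pn)
  if (length(unknown) > 0) {
    stop(sprintf("unknown parameter key '%s'; did you mean '%s'?",
                 unknown[1], suggest_key(unknown[1], pn)))
  }
  missing <- setdiff(pn, names(raw$params))
  if (length(missing) > 0) {
    stop("missing parameter keys: ", paste(missing, collapse = ", "))
  }
  ps <- structure(as.numeric(unlist(raw$params[pn])), names = pn,
                  class = c("hdc_params", "numeric"))
  cfg_args <- raw$engine
  valid_cfg <- names(formals(make_engine_config))
  unknown <- setdiff(names(cfg_args), valid_cfg)
  if (length(unknown) > 0) {
    stop(sprintf("unknown engine key '%s'; did you mean '%s'?",
                 unknown[1], suggest_key(unknown[1], valid_cfg)))
  }
  cfg_args <- lapply(cfg_args, function(v) if (is.null(v)) NA else v)
  cfg <- do.call(make_engine_config, cfg_args[intersect(names(cfg_args), valid_cfg)])
  therapy <- NULL
  if (!is.null(raw$therapy)) {
    valid_tc <- names(formals(make_therapy_config))
    unknown <- setdiff(names(raw$therapy), valid_tc)
    if (length(unknown) > 0) {
      stop(sprintf("unknown therapy key '%s'; did you mean '%s'?",
                   unknown[1], suggest_key(unknown[1], valid_tc)))
    }
    therapy <- do.call(make_therapy_config, raw$therapy)
  }
  val <- validate_parameters(ps, cfg)
  if (!val$valid) {
    stop("configuration failed validation: ",
         paste(val$violations, collapse = "; "))
  }
  list(params = ps, cfg = cfg, therapy = therapy)
}

run_filename <- function(result) {
  sprintf("run_%s_seed%d.csv", result$params_id, result$seed)
}

#' Archive a run's time series
#'
#' Appends the run's time-series table to an archive directory, keyed by
#' (parameter-set id, seed). Writing the same run twice is a no-op; writing a
#' different result under an existing key is an integrity error.
#'
#' @param result A [run_simulation()] result.
#' @param dir Archive directory (created if needed).
#' @return The written file path, invisibly.
#' @export
write_run <- function(result, dir) {
  stopifnot(inherits(result, "hdc_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, run_filename(result))
  if (file.exists(path)) {
    prev <- utils::read.csv(path)
    if (!isTRUE(all.equal(prev, result$ts, tolerance = 1e-12))) {
      stop("integrity error: archive already holds a different time series for (",
           result$params_id, ", seed ", result$seed, ")")
    }
    return(invisible(path))
  }
  utils::write.csv(result$ts, path, row.names = FALSE)
  manifest <- file.path(dir, "manifest.csv")
  row <- data.frame(params_id = result$params_id, seed = result$seed,
                    outcome = result$outcome, mpi = result$mpi,
                    file = basename(path))
  if (file.exists(manifest)) {
    utils::write.table(row, manifest, sep = ",", append = TRUE,
                       col.names = FALSE, row.names = FALSE)
  } else {
    utils::write.csv(row, manifest, row.names = FALSE)
  }
  invisible(path)
}

#' Read an archived run time series
#'
#' @param dir Archive directory.
#' @param params_id Parameter-set id of the run.
#' @param seed Seed of the run.
#' @return The time-series data.frame.
#' @export
read_run <- function(dir, params_id, seed) {
  path <- file.path(dir, sprintf("run_%s_seed%d.csv", params_id, seed))
  if (!file.exists(path)) stop("no archived run at ", path)
  utils::read.csv(path)
}

#' Write an occupancy snapshot as an integer-coded text matrix
#'
#' Header comment lines record the layer, time stamp and code table (see
#' [occupancy_codes()]); the body is a whitespace-delimited integer matrix.
#'
#' @param state A `hdc_state`.
#' @param layer `"tumor"` or `"mac"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_occupancy_snapshot <- function(state, layer = c("tumor", "mac"), path) {
  layer <- match.arg(layer)
  check_state(state)
  codes <- occupancy_codes()[[layer]]
  hdr <- c(sprintf("# occupancy layer: %s", layer),
           sprintf("# time: %g day", state$time),
           sprintf("# codes: %s", paste(names(codes), codes, sep = "=",
                                        collapse = " ")))
  writeLines(hdr, path)
  utils::write.table(state[[layer]], path, append = TRUE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a field snapshot as a plain-text matrix
#'
#' @param state A `hdc_state`.
#' @param field Field name (`"m2s"`, `"oxygen"`, ...).
#' @param path Output path.
#' @param units Unit string recorded in the header.
#' @return `path`, invisibly.
#' @export
write_field_snapshot <- function(state, field, path, units = "pg/LS") {
  check_state(state)
  if (!field %in% c("tls", "m2s", "activator", "oxygen", "blocker",
                    "vasculature")) {
    stop("unknown field: ", field)
  }
  hdr <- c(sprintf("# field: %s [%s]", field, units),
           sprintf("# time: %g day", state$time))
  writeLines(hdr, path)
  utils::write.table(state[[field]], path, append = TRUE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export a state frame as PNG panels
#'
#' Renders the two occupancy layers and the M2S, oxygen and vasculature
#' fields side by side into one PNG frame, keyed by simulation time.
#'
#' @param state A `hdc_state`.
#' @param path PNG output path.
#' @param width,height Device size in pixels.
#' @return `path`, invisibly.
#' @export
export_frame <- function(state, path, width = 1200, height = 300) {
  check_state(state)
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mfrow = c(1, 5), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  panels <- list(tumor = state$tumor, macrophages = state$mac,
                 M2S = state$m2s, oxygen = state$oxygen,
                 vasculature = state$vasculature)
  for (nm in names(panels)) {
    graphics::image(panels[[nm]], axes = FALSE,
                    main = sprintf("%s (t = %g d)", nm, state$time))
  }
  invisible(path)
}

#' Deterministic test fixtures
#'
#' Generates the small synthetic objects used by the test suite:
#'
#' * `tiny_lattice` — a 20x20 state with a 5-cell tumor and 10 naive
#'   macrophages (with matching `params`/`cfg` attributes) for fast rule
#'   tests;
#' * `quadratic_surface` — a noiseless design table whose metric is an
#'   exactly known quadratic in the multipliers, for sensitivity-oracle
#'   tests (true coefficients in attributes);
#' * `metric_points` — synthetic design-point metrics with a prescribed
#'   linear survival-MPI relation for regression tests.
#'
#' @param kind Fixture kind.
#' @param seed RNG seed; the same seed reproduces the fixture exactly.
#' @return The fixture object; see details above.
#' @export
make_fixture <- function(kind = c("tiny_lattice", "quadratic_surface",
                                  "metric_points"), seed = 1L) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (kind == "tiny_lattice") {
    cfg <- make_engine_config(nx = 20, ny = 20, t_end = 1, t_mpi = 0.5,
                              rho0 = 10 / 400)
    ps <- make_base_parameters()
    ps["p18"] <- 5
    st <- initialize_state(ps, cfg, seed = seed)
    attr(st, "params") <- ps
    attr(st, "cfg") <- cfg
    return(st)
  }
  if (kind == "quadratic_surface") {
    base <- make_base_parameters()
    des <- build_design(base, mode = "LINEAR", reps = 1, params = c(1, 2, 3))
    beta <- list(b0 = 0.3, lin = c(2, 0, -1), quad = c(0.5, 0, 0),
                 cross = c("1_2" = 0.25, "1_3" = 0, "2_3" = 0))
    x <- function(row, p) {
      if (row$i == p) row$mi else if (!is.na(row$j) && row$j == p) row$mj else 1
    }
    metric <- vapply(seq_len(nrow(des)), function(k) {
      r <- des[k, ]
      x1 <- x(r, 1); x2 <- x(r, 2); x3 <- x(r, 3)
      beta$b0 + beta$lin[1] * x1 + beta$lin[2] * x2 + beta$lin[3] * x3 +
        beta$quad[1] * x1^2 + beta$cross[["1_2"]] * x1 * x2
    }, numeric(1))
    tab <- cbind(as.data.frame(des), metric = metric)
    attr(tab, "beta") <- beta
    # analytic sensitivities at the base point x = 1
    attr(tab, "true_sensitivity") <- c(
      p1 = beta$lin[1] + 2 * beta$quad[1] + beta$cross[["1_2"]],
      p2 = beta$lin[2] + beta$cross[["1_2"]],
      p3 = beta$lin[3])
    return(tab)
  }
  # metric_points: survival = 0.1 + 0.8 * mpi exactly, capped at 1
  mpi_vals <- seq(0, 1.2, length.out = 15)
  surv <- pmin(1, 0.1 + 0.8 * mpi_vals)
  data.frame(id = sprintf("pt%02d", seq_along(mpi_vals)),
             survival_prob = surv, mean_mpi = mpi_vals,
             mean_tumor = rep(50, length(mpi_vals)))
}
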