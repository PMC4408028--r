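# Small, fast study systems used across the unit tests. The full 100x100 /
# 5-day configuration is exercised only by the acceptance suite.

small_cfg <- function(...) {
  args <- utils::modifyList(
    list(nx = 20, ny = 20, t_end = 0.5, t_mpi = 0.25,
         out_dt = 0.05, rho0 = 10 / 400),
    list(...))
  do.call(make_engine_config, args)
}

small_ps <- function(...) {
  ps <- make_base_parameters()
  ps["p18"] <- 5
  tweaks <- list(...)
  for (nm in names(tweaks)) ps[nm] <- tweaks[[nm]]
  ps
}

# A bare state with empty layers and constant fields, for single-rule tests.
blank_state <- function(nx = 5, ny = 5, vasc = 1, oxygen = 1) {
  st <- list(
    time = 0,
    tls = matrix(0, nx, ny),
    m2s = matrix(0, nx, ny),
    activator = matrix(0, nx, ny),
    oxygen = matrix(oxygen, nx, ny),
    blocker = matrix(0, nx, ny),
    vasculature = matrix(vasc, nx, ny),
    tumor = matrix(0L, nx, ny),
    mac = matrix(0L, nx, ny),
    tdeath = matrix(-1, nx, ny)
  )
  class(st) <- "hdc_state"
  st
}

# Independent 5-point zero-flux diffusion oracle (direct stencil arithmetic,
# mirror boundary), used to cross-check the engine's diffusion kernel.
diffuse_oracle <- function(f, D, dt, dx = 1) {
  nx <- nrow(f); ny <- ncol(f)
  out <- f
  r <- D * dt / dx^2
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      im <- max(i - 1, 1); ip <- min(i + 1, nx)
      jm <- max(j - 1, 1); jp <- min(j + 1, ny)
      lap <- f[im, j] + f[ip, j] + f[i, jm] + f[i, jp] - 4 * f[i, j]
      out[i, j] <- f[i, j] + r * lap
    }
  }
  out
}
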