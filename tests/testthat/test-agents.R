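codes <- occupancy_codes()

test_that("recruitment is vasculature-proportional and spares occupied sites", {
  cfg <- make_engine_config(nx = 20, ny = 20)
  ps <- small_ps()

  ps0 <- ps; ps0["p15"] <- 1e-300
  st <- blank_state(20, 20, vasc = 5)
  set.seed(1)
  expect_equal(recruit_naive(st, ps0, cfg)$mac, st$mac)

  st0 <- blank_state(20, 20, vasc = 0)
  set.seed(1)
  expect_equal(recruit_naive(st, ps0, cfg)$mac, st0$mac)

  # occupied sites never change class
  st$mac[1, 1] <- codes$mac[["M1"]]
  psbig <- ps; psbig["p15"] <- 1e6  # probability clipped at 1
  set.seed(1)
  out <- recruit_naive(st, psbig, cfg)
  expect_equal(out$mac[1, 1], codes$mac[["M1"]])
  expect_true(all(out$mac[-1] == codes$mac[["NAIVE"]]))
})

test_that("recruit counts match the binomial expectation within 4 sigma", {
  cfg <- make_engine_config(nx = 20, ny = 20, dt = 0.05, t_end = 1, t_mpi = 0.5)
  ps <- small_ps()
  v <- 2
  p_site <- min(1, ps[["p15"]] * v * cfg$dt) # 2e-4
  nrep <- 200
  set.seed(33)
  total <- 0
  for (k in seq_len(nrep)) {
    st <- blank_state(20, 20, vasc = v)
    total <- total + sum(recruit_naive(st, ps, cfg)$mac == 1L)
  }
  n_draws <- nrep * 400
  expect_lt(abs(total - n_draws * p_site),
            4 * sqrt(n_draws * p_site * (1 - p_site)) + 1)
})

test_that("polarization probability is a logistic dose-response in M2S", {
  ps <- small_ps()
  expect_equal(polarization_probability(ps[["p13"]], ps), 0.5)
  # strictly increasing
  x <- seq(0, 4 * ps[["p13"]], length.out = 50)
  p <- polarization_probability(x, ps)
  expect_true(all(diff(p) > 0))
  # step limit as p16 -> 0+
  sharp <- ps; sharp["p16"] <- 1e-12
  expect_equal(polarization_probability(ps[["p13"]] * 1.01, sharp), 1)
  expect_equal(polarization_probability(ps[["p13"]] * 0.99, sharp), 0)
  # larger p16 flattens the curve
  flat <- ps; flat["p16"] <- ps[["p16"]] * 10
  hi <- ps[["p13"]] * 1.2
  expect_lt(polarization_probability(hi, flat),
            polarization_probability(hi, ps))
})

test_that("polarization requires the Activator license and is irreversible", {
  ps <- small_ps()
  st <- blank_state(6, 6)
  st$mac[] <- codes$mac[["NAIVE"]]
  # no Activator anywhere: nobody polarizes
  set.seed(5)
  expect_equal(polarize_macrophages(st, ps)$mac, st$mac)

  # at or above threshold with M2S = 0 and tight dose-response: all become M1
  st$activator[] <- ps[["p7"]]  # threshold inclusive
  sharp <- ps; sharp["p16"] <- 1e-12
  set.seed(5)
  out <- polarize_macrophages(st, sharp)
  expect_true(all(out$mac == codes$mac[["M1"]]))

  # with M2S far above threshold: all become M2
  st$m2s[] <- ps[["p13"]] * 10
  set.seed(5)
  out2 <- polarize_macrophages(st, sharp)
  expect_true(all(out2$mac == codes$mac[["M2"]]))

  # polarized cells never change state again
  set.seed(6)
  expect_equal(polarize_macrophages(out, sharp)$mac, out$mac)
  expect_equal(polarize_macrophages(out2, sharp)$mac, out2$mac)
})

test_that("M1/M2 split follows the Bernoulli probability over replicates", {
  ps <- small_ps()
  ps["p16"] <- 2e-7
  m2s_val <- ps[["p13"]]  # P(M2) = 0.5 exactly
  nrep <- 40
  set.seed(77)
  n_m2 <- 0
  for (k in seq_len(nrep)) {
    st <- blank_state(5, 5)
    st$mac[] <- codes$mac[["NAIVE"]]
    st$activator[] <- ps[["p7"]] * 2
    st$m2s[] <- m2s_val
    n_m2 <- n_m2 + sum(polarize_macrophages(st, ps)$mac == codes$mac[["M2"]])
  }
  n <- nrep * 25
  expect_lt(abs(n_m2 - 0.5 * n), 4 * sqrt(n * 0.25))
})

test_that("deterministic chemotaxis climbs the M2S gradient", {
  cfg <- make_engine_config(nx = 3, ny = 3)
  ps <- small_ps()
  st <- blank_state(3, 3)
  st$mac[2, 2] <- codes$mac[["NAIVE"]]
  st$m2s <- matrix(runif(9, 0, 1e-7), 3, 3)
  st$m2s[1, 3] <- 1e-6  # strict maximum
  set.seed(8)
  out <- move_macrophages(st, cfg, ps)
  expect_equal(out$mac[1, 3], codes$mac[["NAIVE"]])
  expect_equal(sum(out$mac != 0), 1)
})

test_that("ties on a flat field break uniformly among candidates", {
  cfg <- make_engine_config(nx = 3, ny = 3)
  ps <- small_ps()
  dest <- integer(0)
  set.seed(9)
  for (k in 1:300) {
    st <- blank_state(3, 3)
    st$mac[2, 2] <- codes$mac[["NAIVE"]]
    out <- move_macrophages(st, cfg, ps)
    dest <- c(dest, which(out$mac != 0))
  }
  # all nine candidate sites (self + 8 Moore neighbors) are reachable
  expect_setequal(sort(unique(dest)), 1:9)
})

test_that("a fully surrounded macrophage stays put", {
  cfg <- make_engine_config(nx = 3, ny = 3)
  ps <- small_ps()
  st <- blank_state(3, 3)
  st$mac[] <- codes$mac[["NAIVE"]]
  st$m2s[1, 1] <- 1e-5
  set.seed(10)
  out <- move_macrophages(st, cfg, ps)
  expect_equal(out$mac, st$mac)
})

test_that("stochastic chemotaxis prefers high-M2S destinations", {
  cfg <- make_engine_config(nx = 3, ny = 3, chemotaxis_mode = "stochastic",
                            chemotaxis_floor = 1e-12)
  ps <- small_ps()
  hits <- 0
  set.seed(11)
  for (k in 1:100) {
    st <- blank_state(3, 3)
    st$mac[2, 2] <- codes$mac[["NAIVE"]]
    st$m2s[3, 3] <- 1  # overwhelming weight
    out <- move_macrophages(st, cfg, ps)
    hits <- hits + (out$mac[3, 3] != 0)
  }
  expect_gte(hits, 99)
})

test_that("tumor division fills empty neighbors at the configured rate", {
  cfg <- make_engine_config(nx = 7, ny = 7, dt = 0.3, t_end = 0.6, t_mpi = 0.3, out_dt = 0.3)
  ps <- small_ps()

  ps0 <- ps; ps0["p12"] <- 1e-300
  st <- blank_state(7, 7)
  st$tumor[4, 4] <- 1L
  set.seed(12)
  expect_equal(divide_tumor(st, ps0, cfg)$tumor, st$tumor)

  # enclosed cell cannot divide even at probability one
  ps1 <- ps; ps1["p12"] <- 10
  enc <- blank_state(3, 3)
  enc$tumor[] <- 2L
  enc$tumor[2, 2] <- 1L
  set.seed(13)
  out <- divide_tumor(enc, ps1, cfg)
  expect_equal(out$tumor, enc$tumor)

  # division count across replicates matches Binomial(n, p12*dt)
  p_div <- ps[["p12"]] * cfg$dt  # 0.3
  nrep <- 300
  set.seed(14)
  divisions <- 0
  for (k in seq_len(nrep)) {
    st <- blank_state(7, 7)
    st$tumor[4, 4] <- 1L
    out <- divide_tumor(st, ps, cfg)
    divisions <- divisions + (sum(out$tumor == 1L) - 1)
  }
  expect_lt(abs(divisions - nrep * p_div),
            4 * sqrt(nrep * p_div * (1 - p_div)))
})

test_that("death thresholds are inclusive and dead cells persist", {
  ps <- small_ps()
  st <- blank_state(4, 4)
  st$tumor[1, 1] <- 1L
  st$tumor[2, 2] <- 1L
  st$mac[3, 3] <- codes$mac[["M2"]]

  # TLS exactly at p6 kills (threshold inclusive); below does not
  st$tls[1, 1] <- ps[["p6"]]
  st$tls[2, 2] <- ps[["p6"]] * 0.999
  out <- apply_death(st, ps)
  expect_equal(out$tumor[1, 1], codes$tumor[["DEAD"]])
  expect_equal(out$tumor[2, 2], codes$tumor[["TUMOR"]])
  expect_equal(out$mac[3, 3], codes$mac[["M2"]])  # oxygen fine, macrophage lives
  expect_equal(out$tdeath[1, 1], st$time)

  # oxygen below p10 kills every live cell; dead entries stay dead
  st2 <- out
  st2$oxygen[] <- 0
  out2 <- apply_death(st2, ps)
  expect_equal(out2$tumor[2, 2], codes$tumor[["DEAD"]])
  expect_equal(out2$mac[3, 3], codes$mac[["MP_DEAD"]])
  expect_equal(out2$tumor[1, 1], codes$tumor[["DEAD"]])
  out3 <- apply_death(out2, ps)
  expect_equal(out3$tumor, out2$tumor)
  expect_equal(out3$mac, out2$mac)

  # oxygen exactly at p10 is survivable
  st3 <- blank_state(3, 3, oxygen = ps[["p10"]])
  st3$tumor[2, 2] <- 1L
  expect_equal(apply_death(st3, ps)$tumor[2, 2], codes$tumor[["TUMOR"]])
})
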