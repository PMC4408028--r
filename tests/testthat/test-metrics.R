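test_that("MPI follows its defining ratio and monotonicities", {
  expect_equal(mpi(c(m2 = 0, m1 = 7, naive = 2)), 0)
  expect_equal(mpi(c(m2 = 9, m1 = 3, naive = 5)), 1.0)
  expect_equal(mpi(c(m2 = 4, m1 = 0, naive = 0)), 4)
  # strictly decreasing in M1 at fixed M2
  vals <- vapply(0:10, function(m1) mpi(c(m2 = 5, m1 = m1, naive = 2)),
                 numeric(1))
  expect_true(all(diff(vals) < 0))
  # EMP counted with their phenotype class unless native_only
  ct <- c(m2 = 2, m1 = 1, naive = 1, emp_m2 = 3, emp_m1 = 1, emp_naive = 0)
  expect_equal(mpi(ct), 5 / (1 + 2 + 1))
  expect_equal(mpi(ct, native_only = TRUE), 2 / (1 + 1 + 1))
  # tumor counts are irrelevant
  expect_equal(mpi(c(m2 = 1, m1 = 1, naive = 1, tumor_live = 99)),
               mpi(c(m2 = 1, m1 = 1, naive = 1)))
  expect_error(mpi(c(m2 = -1, m1 = 0, naive = 0)), "non-negative")
})

test_that("mean local CV averages per-tile CVs and is scale invariant", {
  expect_equal(mean_local_cv(matrix(3, 20, 20), tile = 10), 0)

  # one 2x2 tile with half value a, half zero has population CV exactly 1
  f <- matrix(c(2, 2, 0, 0), 2, 2)
  expect_equal(mean_local_cv(f, tile = 2), 1)

  # a 100x100 domain with tile 10 averages exactly 100 tile values:
  # give one tile CV 1 and the rest CV 0, the mean must be 1/100
  g <- matrix(5, 100, 100)
  g[1:10, 1:5] <- 10; g[1:10, 6:10] <- 0  # tile mean 5, population sd 5
  expect_equal(mean_local_cv(g, tile = 10), 1 / 100)

  set.seed(31)
  h <- matrix(rexp(400), 20, 20)
  expect_equal(mean_local_cv(h * 7.3, tile = 10), mean_local_cv(h, tile = 10))

  expect_error(mean_local_cv(h, tile = 7), "admissible")
  # sample-sd variant stays finite and close for big tiles
  expect_gt(mean_local_cv(h, tile = 10, population_sd = FALSE),
            mean_local_cv(h, tile = 10))
})

test_that("field summaries report mean and maximum", {
  expect_equal(field_summary(matrix(2.5, 4, 4)), c(mean = 2.5, max = 2.5))
  f <- matrix(0, 5, 5); f[2, 3] <- 10
  expect_equal(field_summary(f), c(mean = 10 / 25, max = 10))
  set.seed(32)
  g <- matrix(runif(100), 10, 10)
  s <- field_summary(g)
  expect_gte(s[["max"]], s[["mean"]])
})

test_that("survival probability is the ordered-invariant survival fraction", {
  expect_equal(survival_probability(rep("DEATH", 8))$prob, 0)
  oc <- c(rep("SURVIVAL", 25), rep("DEATH", 25))
  expect_equal(survival_probability(oc)$prob, 0.5)
  set.seed(33)
  expect_equal(survival_probability(sample(oc))$prob, 0.5)
  sp <- survival_probability(oc)
  expect_true(sp$lower < 0.5 && sp$upper > 0.5)
  expect_error(survival_probability(character(0)), "empty")
  expect_error(survival_probability(c("ALIVE")), "SURVIVAL")
})

test_that("survival regression filters saturated points and reports R^2", {
  pts <- make_fixture("metric_points", seed = 1)
  fit <- regress_metric_vs_survival(pts, metric = "mean_mpi")
  # the sub-saturation points lie exactly on a line
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(fit$n, sum(pts$survival_prob < 1))

  # R^2 is invariant to affine transformation of the metric and to
  # the normalization switch
  pts2 <- pts; pts2$mean_mpi <- 3 * pts2$mean_mpi - 0.2
  expect_equal(regress_metric_vs_survival(pts2, "mean_mpi")$r2, fit$r2,
               tolerance = 1e-12)
  expect_equal(regress_metric_vs_survival(pts, "mean_mpi", normalize = FALSE)$r2,
               fit$r2, tolerance = 1e-12)

  # an uninformative metric has near-zero R^2 on average over permutations
  set.seed(34)
  r2s <- replicate(30, {
    shuffled <- pts
    shuffled$mean_mpi <- sample(shuffled$mean_mpi)
    regress_metric_vs_survival(shuffled, "mean_mpi")$r2
  })
  expect_lt(mean(r2s), 0.25)

  # degenerate constant metric is flagged with R^2 = 0
  pts3 <- pts; pts3$mean_mpi <- 1
  fit3 <- regress_metric_vs_survival(pts3, "mean_mpi")
  expect_true(fit3$degenerate)
  expect_equal(fit3$r2, 0)

  expect_error(regress_metric_vs_survival(pts[pts$survival_prob >= 1, ],
                                          "mean_mpi"), "at least 3")
})

fake_run <- function(outcome, mpi_val, m1 = c(0, 4, 4), m2 = c(0, 1, 6)) {
  ts <- data.frame(time = c(0, 0.25, 0.5),
                   tumor_live = c(5, 4, 3), tumor_dead = c(0, 1, 2),
                   naive = c(10, 8, 7), m1 = m1, m2 = m2,
                   emp_naive = 0, emp_m1 = 0, emp_m2 = 0, mac_dead = 0)
  structure(list(ts = ts, outcome = outcome, mpi = mpi_val, seed = 1L,
                 params_id = "fake"), class = "hdc_run")
}

test_that("outcome aggregation groups runs and reports mean/SE trajectories", {
  runs <- list(fake_run("SURVIVAL", 0.4), fake_run("SURVIVAL", 0.4),
               fake_run("DEATH", 0.1, m1 = c(0, 6, 8), m2 = c(0, 0, 1)),
               fake_run("DEATH", 0.2, m1 = c(0, 8, 10), m2 = c(0, 0, 1)))
  agg <- aggregate_by_outcome(runs)
  expect_equal(sum(agg$n), 4)
  expect_setequal(names(agg$n), c("SURVIVAL", "DEATH"))
  # identical runs: SE zero, mean equals any member
  s_m2 <- subset(agg$trajectories, outcome == "SURVIVAL" & class == "m2")
  expect_equal(s_m2$mean, c(0, 1, 6))
  expect_equal(s_m2$se, c(0, 0, 0))
  d_m1 <- subset(agg$trajectories, outcome == "DEATH" & class == "m1")
  expect_equal(d_m1$mean, c(0, 7, 9))
  expect_equal(mean(agg$mpi$mpi[agg$mpi$outcome == "SURVIVAL"]), 0.4)

  # a single-outcome ensemble yields one group with a warning
  expect_warning(one <- aggregate_by_outcome(runs[1:2]), "single-outcome")
  expect_equal(sum(one$n), 2)

  # runs must share the time grid
  bad <- fake_run("DEATH", 0)
  bad$ts$time <- c(0, 0.3, 0.6)
  expect_error(aggregate_by_outcome(c(runs, list(bad))), "time grid")
})
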