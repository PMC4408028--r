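test_that("the full linear design has the canonical cardinalities", {
  des <- build_design(make_base_parameters(), mode = "LINEAR", reps = 50)
  card <- design_cardinality(des)
  expect_equal(card$singles, 18)
  expect_equal(card$proper_pairs, 153)
  expect_equal(card$pair_cases, 171)
  expect_equal(card$unique_points, 18 * 5 + 153 * 25)
  expect_equal(card$unique_points, 3915)
  expect_equal(card$evaluations, 3915 * 50)
  expect_equal(sum(des$type == "SINGLE"), 90)
  expect_equal(sum(des$type == "PAIR"), 153 * 25)
  expect_false(anyDuplicated(des$id) > 0)
})

test_that("design multipliers match the linear and log grids exactly", {
  expect_identical(design_multipliers("LINEAR"), c(0.25, 0.75, 1.25, 1.75, 2.25))
  expect_identical(design_multipliers("LOG"), c(0.1, 0.3, 1.0, 3.0, 10.0))
  des <- build_design(make_base_parameters(), "LINEAR", reps = 1)
  expect_setequal(unique(des$mi), c(0.25, 0.75, 1.25, 1.75, 2.25))
  expect_false(any(des$mi == 1))   # no varied index carries multiplier 1.0
  expect_false(any(des$mj == 1, na.rm = TRUE))
  # a single-parameter case scales only that parameter
  p11_rows <- des[des$type == "SINGLE" & des$i == 11, ]
  expect_equal(nrow(p11_rows), 5)
  expect_true(all(is.na(p11_rows$j)))
  deslog <- build_design(make_base_parameters(), "LOG", reps = 1,
                         params = c(2, 9), pairs = FALSE)
  expect_setequal(deslog$mi, c(0.1, 0.3, 1.0, 3.0, 10.0))
})

toy_mpsa <- function(master_seed = 1, jobs = 1, checkpoint_dir = NULL) {
  des <- build_design(small_ps(), "LINEAR", reps = 2, params = c(11, 13))
  run_design(des, small_cfg(), master_seed = master_seed, jobs = jobs,
             checkpoint_dir = checkpoint_dir)
}

test_that("run_design tallies replicates and is reproducible", {
  res <- toy_mpsa()
  expect_equal(nrow(res), 2 * 5 + 1 * 25)
  expect_true(all(res$n_survival + res$n_death + res$n_failed == 2))
  expect_true(all(res$survival_prob >= 0 & res$survival_prob <= 1))
  res2 <- toy_mpsa()
  expect_identical(as.data.frame(res), as.data.frame(res2))
})

test_that("parallel and serial sweeps agree; checkpoints resume losslessly", {
  serial <- toy_mpsa(master_seed = 3)
  parallel <- toy_mpsa(master_seed = 3, jobs = 2)
  expect_equal(as.data.frame(serial), as.data.frame(parallel))

  dir <- tempfile("ckpt")
  first <- toy_mpsa(master_seed = 3, checkpoint_dir = dir)
  expect_gt(length(list.files(dir)), 0)
  resumed <- toy_mpsa(master_seed = 3, checkpoint_dir = dir)
  expect_equal(as.data.frame(first), as.data.frame(resumed))
})

# helper: multiplier of parameter p at a design row
x_of <- function(row, p) {
  if (row$i == p) row$mi
  else if (!is.na(row$j) && row$j == p) row$mj
  else 1
}

synthetic_metric <- function(des, f) {
  vapply(seq_len(nrow(des)), function(k) {
    r <- des[k, ]
    f(x_of(r, 1), x_of(r, 2), x_of(r, 3))
  }, numeric(1))
}

test_that("quadratic sensitivities recover analytic derivatives exactly", {
  des <- build_design(make_base_parameters(), "LINEAR", reps = 1,
                      params = c(1, 2, 3))
  tab <- as.data.frame(des)

  # metric = 2 x1: sensitivity 2 for p1, zero elsewhere
  tab$metric <- synthetic_metric(des, function(x1, x2, x3) 2 * x1)
  s <- quadratic_sensitivities(tab, "metric")
  expect_equal(s$sensitivity[s$param == "p1"], 2, tolerance = 1e-8)
  expect_equal(s$sensitivity[s$param != "p1"], c(0, 0), tolerance = 1e-8)
  expect_equal(s$normalized[s$param == "p1"], 1)
  expect_equal(s$rank[s$param == "p1"], 1)

  # metric = x1^2: d/dx1 at x=1 is 2
  tab$metric <- synthetic_metric(des, function(x1, x2, x3) x1^2)
  s2 <- quadratic_sensitivities(tab, "metric")
  expect_equal(s2$sensitivity[s2$param == "p1"], 2, tolerance = 1e-8)

  # constant metric: all sensitivities zero
  tab$metric <- 1.25
  s3 <- quadratic_sensitivities(tab, "metric")
  expect_equal(s3$sensitivity, rep(0, 3), tolerance = 1e-8)

  # a full random quadratic surface is recovered coefficient-for-coefficient
  set.seed(41)
  b <- list(lin = rnorm(3), quad = rnorm(3), cross = rnorm(3))
  tab$metric <- synthetic_metric(des, function(x1, x2, x3) {
    sum(b$lin * c(x1, x2, x3)) + sum(b$quad * c(x1, x2, x3)^2) +
      b$cross[1] * x1 * x2 + b$cross[2] * x1 * x3 + b$cross[3] * x2 * x3
  })
  s4 <- quadratic_sensitivities(tab, "metric")
  truth <- c(b$lin[1] + 2 * b$quad[1] + b$cross[1] + b$cross[2],
             b$lin[2] + 2 * b$quad[2] + b$cross[1] + b$cross[3],
             b$lin[3] + 2 * b$quad[3] + b$cross[2] + b$cross[3])
  expect_equal(s4$sensitivity, truth, tolerance = 1e-8)
  expect_equal(attr(s4, "r2"), 1, tolerance = 1e-10)
  expect_true(all(sort(s4$rank) == 1:3))
})

test_that("the packaged quadratic-surface fixture matches its oracle", {
  tab <- make_fixture("quadratic_surface", seed = 1)
  s <- quadratic_sensitivities(tab, "metric")
  truth <- attr(tab, "true_sensitivity")
  expect_equal(s$sensitivity, unname(truth[s$param]), tolerance = 1e-8)
})

test_that("sensitivity deltas are antisymmetric on a shared scale", {
  tab <- make_fixture("quadratic_surface", seed = 1)
  a <- quadratic_sensitivities(tab, "metric")
  tab2 <- tab
  tab2$metric <- tab2$metric * 0.5
  b <- quadratic_sensitivities(tab2, "metric")

  expect_equal(sensitivity_delta(a, a)$delta, rep(0, 3))
  d_ab <- sensitivity_delta(a, b)
  d_ba <- sensitivity_delta(b, a)
  expect_equal(d_ab$delta, -d_ba$delta)
  expect_false(all(d_ab$delta == 0))

  tab3 <- tab; names(tab3)[names(tab3) == "metric"] <- "other"
  cc <- quadratic_sensitivities(tab3, "other")
  expect_error(sensitivity_delta(a, cc), "different metrics")
})

test_that("pairwise surfaces extract the 5x5 grid with transpose symmetry", {
  tab <- make_fixture("quadratic_surface", seed = 1)
  g12 <- pairwise_surface(tab, 1, 2, "metric")
  expect_equal(dim(g12), c(5, 5))
  expect_false(any(is.na(g12)))
  # lookup: the cell is the metric at that multiplier pair
  row <- tab[tab$type == "PAIR" & tab$i == 1 & tab$j == 2 &
               tab$mi == 0.25 & tab$mj == 2.25, ]
  expect_equal(g12["0.25", "2.25"], row$metric)
  expect_equal(pairwise_surface(tab, 2, 1, "metric"), t(g12))
  expect_error(pairwise_surface(tab, 1, 7, "metric"), "not present")
})
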