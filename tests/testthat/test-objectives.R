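test_that("objective values match hand-computed cases", {
  expect_equal(objective_value("sq_deviation", c(59, 60, 61), dose_gy = 60), 2 / 3)
  expect_equal(objective_value("sq_overdose", c(10, 25, 30), dose_gy = 20), 125 / 3)
  expect_equal(objective_value("sq_underdose", c(10, 25, 30), dose_gy = 20), 100 / 3)
  expect_equal(objective_value("mean_dose", c(0, 0, 0)), 0)
  expect_equal(objective_value("sq_deviation", rep(45, 8), dose_gy = 45), 0)
  # serialized aliases resolve to the same kinds
  expect_equal(objective_value("f_sqdev+", c(10, 25, 30), dose_gy = 20), 125 / 3)
  expect_error(objective_value("sq_deviation", numeric(0), dose_gy = 1), "empty")
  expect_error(objective_value("nope", 1), "unknown objective kind")
})

test_that("objectives are homogeneous / nonnegative where claimed", {
  set.seed(1)
  for (rep in 1:20) {
    d <- runif(17, 0, 80)
    c_ <- runif(1, 0.1, 3)
    expect_equal(objective_value("mean_dose", c_ * d),
                 c_ * objective_value("mean_dose", d))
    for (kind in c("sq_deviation", "sq_overdose", "sq_underdose")) {
      expect_gte(objective_value(kind, d, dose_gy = 40), 0)
    }
  }
})

test_that("analytic gradients agree with central finite differences", {
  set.seed(7)
  kinds <- c("sq_deviation", "sq_overdose", "sq_underdose", "mean_dose",
             "max_dvh", "min_dvh")
  for (kind in kinds) {
    for (rep in 1:50) {
      ns <- sample(4:25, 1)
      d <- runif(ns, 0, 80)
      ref <- runif(1, 10, 70)
      vol <- runif(1, 0.1, 0.9)
      g <- objective_gradient(kind, d, dose_gy = ref, volume = vol)
      fn <- function(z) objective_value(kind, z, dose_gy = ref, volume = vol)
      g_fd <- fd_gradient(fn, d)
      denom <- max(1, sqrt(sum(g_fd^2)))
      expect_lt(sqrt(sum((g - g_fd)^2)) / denom, 1e-5)
    }
  }
})

test_that("mean-dose gradient is the uniform averaging vector", {
  expect_equal(objective_gradient("mean_dose", rep(5, 4)), rep(0.25, 4))
  expect_equal(objective_gradient("sq_deviation", rep(60, 6), dose_gy = 60),
               rep(0, 6))
})

test_that("inverse DVH quantile follows the nearest-rank convention", {
  expect_equal(inverse_dvh_quantile(c(10, 20, 30, 40), 0.25), 40)
  expect_equal(inverse_dvh_quantile(c(10, 20, 30, 40), 0.6), 30)
  for (v in c(0.05, 0.3, 0.51, 0.95))
    expect_equal(inverse_dvh_quantile(rep(7, 13), v), 7)
  expect_error(inverse_dvh_quantile(numeric(0), 0.5), "empty")
  expect_error(inverse_dvh_quantile(1:4, 1), "volume")
})

test_that("quantile agrees with a brute-force threshold scan", {
  set.seed(3)
  for (rep in 1:100) {
    ns <- sample(3:40, 1)
    d <- runif(ns, 0, 100) # continuous: ties have probability zero
    v <- runif(1, 0.05, 0.95)
    got <- inverse_dvh_quantile(d, v)
    # scan all candidate thresholds for the closest achievable fraction
    devs <- vapply(d, function(t) abs(mean(d >= t) - v), numeric(1))
    best <- d[devs <= min(devs) + 1e-15]
    expect_true(any(abs(best - got) < 1e-12))
  }
})

test_that("DVH objective selects exactly the stated voxel band", {
  # all doses below the reference: no violators, flat zero
  r <- dvh_objective("max_dvh", c(10, 20, 30), dose_gy = 50, volume = 0.5)
  expect_equal(r$value, 0)
  expect_equal(r$gradient, rep(0, 3))
  # d_V = 70 at V = 1/3; penalized voxels {55, 70}
  r <- dvh_objective("max_dvh", c(40, 55, 70), dose_gy = 50, volume = 1 / 3)
  expect_equal(r$d_v, 70)
  expect_equal(r$value, (25 + 400) / 3)
  expect_equal(which(r$gradient != 0), c(2L, 3L))
})

test_that("min_dvh equals max_dvh under dose reflection", {
  set.seed(9)
  for (rep in 1:25) {
    ns <- sample(5:30, 1)
    d <- runif(ns, 0, 80)
    ref <- runif(1, 20, 60)
    k <- sample(2:(ns - 1), 1) # keep both quantile fractions inside (0, 1)
    v_min <- k / ns
    got <- dvh_objective("min_dvh", d, dose_gy = ref, volume = v_min)
    # reflect d -> -d: the k-th largest of d is the (ns-k+1)-th largest of -d
    shift <- 100 # keep reflected doses positive so conventions are untouched
    v_ref <- (ns - k + 1) / ns
    mirrored <- dvh_objective("max_dvh", shift - d, dose_gy = shift - ref,
                              volume = v_ref)
    expect_equal(got$value, mirrored$value, tolerance = 1e-12)
  }
})

test_that("composite chains the gradient through the dose matrix", {
  # A = identity, one mean_dose spec over all voxels -> gradient = 1/n
  n <- 6
  di <- dose_influence(Matrix::Diagonal(n, 1))
  ss <- structure_set(list(list(name = "All", voxels = 1:n, priority = 1L)), n)
  obj <- composite_objective(list(objective_spec("f_mean", "All")), ss, di)
  res <- composite_value_and_gradient(obj, rep(2, n))
  expect_equal(res$f, 2)
  expect_equal(res$gradient, rep(1 / n, n))
  # all weights zero -> identically zero
  obj0 <- composite_objective(list(objective_spec("f_mean", "All", weight = 0)),
                              ss, di)
  res0 <- composite_value_and_gradient(obj0, runif(n))
  expect_equal(res0$f, 0)
  expect_equal(res0$gradient, rep(0, n))
  expect_error(composite_value_and_gradient(obj, rep(1, n + 1)), "length")
})

test_that("composite gradient matches finite differences in intensity space", {
  set.seed(21)
  for (rep in 1:10) {
    tp <- make_toy_problem(25, 6, 0.5, slack = 1, seed = rep)
    ss <- structure_set(list(
      list(name = "Hot", voxels = 1:10, priority = 1L),
      list(name = "Cold", voxels = 11:25, priority = 2L)
    ), 25)
    obj <- composite_objective(list(
      objective_spec("f_sqdev", "Hot", weight = 10, dose_gy = 5),
      objective_spec("f_sqdev+", "Cold", weight = 2, dose_gy = 1),
      objective_spec("f_maxDVH", "Cold", weight = 1, dose_gy = 2, volume = 0.2),
      objective_spec("f_mean", "Cold", weight = 0.5)
    ), ss, tp$matrix)
    x <- runif(6, 0.5, 2)
    res <- composite_value_and_gradient(obj, x)
    g_fd <- fd_gradient(function(z) composite_value_and_gradient(obj, z)$f, x)
    expect_lt(sqrt(sum((res$gradient - g_fd)^2)) / max(1, sqrt(sum(g_fd^2))),
              1e-5)
  }
})

test_that("composite is additive in its spec list", {
  tp <- make_toy_problem(20, 5, 0.5, slack = 1, seed = 2)
  ss <- structure_set(list(list(name = "All", voxels = 1:20, priority = 1L)), 20)
  s1 <- objective_spec("f_sqdev", "All", weight = 3, dose_gy = 4)
  s2 <- objective_spec("f_mean", "All", weight = 2)
  x <- runif(5)
  f_joint <- composite_value_and_gradient(
    composite_objective(list(s1, s2), ss, tp$matrix), x)$f
  f_parts <- composite_value_and_gradient(
    composite_objective(list(s1), ss, tp$matrix), x)$f +
    composite_value_and_gradient(composite_objective(list(s2), ss, tp$matrix), x)$f
  expect_equal(f_joint, f_parts, tolerance = 1e-12)
})

test_that("objective specs validate their parameters", {
  expect_error(objective_spec("f_sqdev", "T", weight = -1, dose_gy = 60), "nonnegative")
  expect_error(objective_spec("f_sqdev", "T"), "reference dose")
  expect_error(objective_spec("f_maxDVH", "T", dose_gy = 50), "volume")
  expect_error(objective_spec("f_maxDVH", "T", dose_gy = 50, volume = 1.2), "volume")
  ss <- structure_set(list(list(name = "T", voxels = 1:2, priority = 1L)), 4)
  di <- dose_influence(Matrix::Diagonal(4, 1))
  expect_error(
    composite_objective(list(objective_spec("f_mean", "Absent")), ss, di),
    "no structure")
})
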