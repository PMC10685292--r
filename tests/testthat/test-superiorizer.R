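test_that("descent direction normalizes the negative gradient", {
  expect_equal(descent_direction(c(3, 4)), c(-0.6, -0.8))
  expect_equal(descent_direction(c(0, 0)), c(0, 0))
  set.seed(2)
  for (rep in 1:20) {
    g <- rnorm(7)
    expect_equal(sqrt(sum(descent_direction(g)^2)), 1, tolerance = 1e-12)
  }
  expect_error(descent_direction(c(1, NaN)), "finite")
})

# f(x) = x^2 through a 1x1 identity system: sq_deviation to 0 on one voxel
quadratic_objective <- function() {
  di <- dose_influence(Matrix::Matrix(1, 1, 1, sparse = TRUE))
  ss <- structure_set(list(list(name = "All", voxels = 1L, priority = 1L)), 1)
  composite_objective(list(objective_spec("f_sqdev", "All", dose_gy = 0)),
                      ss, di)
}

test_that("perturbation accepts the first proposal reaching f(z) <= f_start", {
  obj <- quadratic_objective()
  # x = 1, alpha = 0.5, s = 0: first proposal z = 1 - 1 = 0, f = 0 <= 1
  res <- perturbation_phase(1, obj, alpha = 0.5, s_in = 0,
                            n_perturbations = 1, s_increment_first = 1)
  expect_equal(res$x, 0)
  expect_equal(res$s, 1)
})

test_that("rejected proposals shrink the step until acceptance", {
  obj <- quadratic_objective()
  # x = 0.1: proposals z = -0.9, -0.4, -0.15 rejected; z = -0.025 accepted
  res <- perturbation_phase(0.1, obj, alpha = 0.5, s_in = 0,
                            n_perturbations = 1, s_increment_first = 1)
  expect_equal(res$x, -0.025, tolerance = 1e-12)
  expect_equal(res$s, 4)
  expect_equal(res$beta_sum, 1 + 0.5 + 0.25 + 0.125)
})

test_that("a stationary objective leaves the iterate untouched", {
  # constant f: mean dose of an all-zero matrix row
  di <- dose_influence(Matrix::Matrix(0, 1, 1, sparse = TRUE))
  ss <- structure_set(list(list(name = "All", voxels = 1L, priority = 1L)), 1)
  obj <- composite_objective(list(objective_spec("f_mean", "All")), ss, di)
  res <- perturbation_phase(2, obj, alpha = 0.9, s_in = 5, n_perturbations = 3)
  expect_equal(res$x, 2)
  expect_equal(res$s, 5) # no proposals: gradient is zero
})

test_that("weight decay follows the kernel powers", {
  expect_equal(decay_weights(0.5, eta = 0.9, k = 2), 0.405)
  expect_equal(decay_weights(c(0.2, 1), eta = 0.7, k = 0), c(0.2, 1))
  expect_equal(decay_weights(c(0.2, 1), eta = 1, k = 50), c(0.2, 1))
  expect_error(decay_weights(1, eta = 1.1, k = 1), "eta")
})

test_that("stopping rule evaluates the documented examples", {
  h <- data.frame(f = rep(2, 4), V = rep(0.5, 4))
  expect_true(stopping_met(h, 1e-4, 1e-3, 3))
  # 1% decrease per iteration with f > 1 exceeds tol_f
  h2 <- data.frame(f = 10 * 0.99^(0:4), V = rep(0.5, 5))
  expect_false(stopping_met(h2, 1e-4, 1e-3, 3))
  # the max{1, .} denominator: f 0.5 -> 0.50004 gives 4e-5 < 1e-4
  h3 <- data.frame(f = c(0.5, 0.50004, 0.50008, 0.50012),
                   V = rep(0.2, 4))
  expect_true(stopping_met(h3, 1e-4, 1e-3, 3))
  # too short a history never stops
  expect_false(stopping_met(h3[1:3, ], 1e-4, 1e-3, 3))
  # negative tolerance disables a part
  expect_true(stopping_met(h2, -1, 1e-3, 3))
})

test_that("stopping rule agrees with a literal transcription on random histories", {
  set.seed(31)
  for (rep in 1:1000) {
    nh <- sample(2:8, 1)
    f <- abs(cumsum(rnorm(nh, sd = 10^runif(1, -6, 0))))
    V <- abs(cumsum(rnorm(nh, sd = 10^runif(1, -6, 0))))
    tol_f <- sample(c(-1, 0, 1e-4, 1e-2), 1)
    tol_V <- sample(c(-1, 0, 1e-3, 1e-1), 1)
    consec <- sample(1:4, 1)
    expect_identical(
      stopping_met(data.frame(f = f, V = V), tol_f, tol_V, consec),
      literal_stopping(f, V, tol_f, tol_V, consec)
    )
  }
})

test_that("solver defaults match the documented stopping parameters", {
  cfg <- superiorization_config()
  expect_equal(cfg$tol_f, 1e-4)
  expect_equal(cfg$tol_V, 1e-3)
  expect_equal(cfg$consecutive, 3L)
  expect_equal(cfg$max_iterations, 500L)
  expect_equal(cfg$warm_start_increment, 25L)
  expect_error(superiorization_config(alpha = 1), "alpha")
  expect_error(superiorization_config(lambda = 2.5), "lambda")
})

test_that("superiorization reaches feasibility with a reduced objective", {
  wins <- 0L
  for (s in 0:9) {
    tp <- make_toy_problem(200, 30, 0.3, TRUE, slack = 0.5, seed = s)
    cs <- amsplan:::toy_constraints(tp)
    obj <- toy_objective(tp)
    sm <- superiorize(matrix = tp$matrix, constraints = cs, objective = obj,
                      config = superiorization_config(seed = s))
    bare <- feasibility_solve(matrix = tp$matrix, constraints = cs, seed = s)
    f_sm <- sm$history$f[nrow(sm$history)]
    f_bare <- amsplan:::composite_value(obj, bare$x_final)
    if (max_violation(sm$x_final, tp$matrix, cs) < 0.01 && f_sm <= f_bare)
      wins <- wins + 1L
  }
  # the early-stopping rule may cut an occasional run short of feasibility
  expect_gte(wins, 9L)
})

test_that("zero objective weights reduce superiorization to bare AMS bitwise", {
  tp <- make_toy_problem(100, 15, 0.4, slack = 0.5, seed = 3)
  cs <- amsplan:::toy_constraints(tp, nu = runif(100, 0.2, 1))
  obj0 <- toy_objective(tp, list(objective_spec("f_mean", "All", weight = 0)))
  for (ctrl in c("cyclic", "random", "weight_descending")) {
    sm <- superiorize(matrix = tp$matrix, constraints = cs, objective = obj0,
                      config = superiorization_config(control = ctrl, seed = 8,
                                                      max_iterations = 40,
                                                      tol_f = 0, tol_V = 0))
    bare <- feasibility_solve(matrix = tp$matrix, constraints = cs,
                              control = ctrl, max_sweeps = 40, tol_V = 0,
                              seed = 8)
    expect_identical(sm$x_final, bare$x_final)
    expect_identical(sm$history$V, bare$history$V)
    expect_identical(sm$history$max_violation, bare$history$max_violation)
  }
})

test_that("step sizes are summable and the exponent never decreases", {
  tp <- make_toy_problem(80, 12, 0.4, slack = 0.5, seed = 5)
  cs <- amsplan:::toy_constraints(tp)
  obj <- toy_objective(tp)
  cfg <- superiorization_config(alpha = 0.95, max_iterations = 60)
  sm <- superiorize(matrix = tp$matrix, constraints = cs, objective = obj,
                    config = cfg)
  h <- sm$history
  expect_true(all(diff(h$s) >= 0))
  s0 <- attr(h, "s0")
  expect_lte(attr(h, "beta_sum"), cfg$alpha^s0 / (1 - cfg$alpha))
})

test_that("superiorized phantom run shows the typical trajectory shape", {
  pp <- suppressMessages(phantom_problem(nx = 48, spacing_mm = 4))
  sm <- superiorize(matrix = pp$matrix, constraints = pp$constraints,
                    objective = pp$objective,
                    config = superiorization_config(max_iterations = 200))
  h <- sm$history
  expect_lt(h$f[2], h$f[1]) # strong first-iteration decrease
  expect_true(all(diff(h$V[1:11]) <= 1e-12)) # proximity falls monotonically
  expect_true(all(sm$x_final >= 0))
  expect_equal(sm$d_final, compute_dose(pp$matrix, sm$x_final))
})
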