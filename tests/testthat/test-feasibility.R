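test_that("prescription expansion assigns bounds by priority with rescaled weights", {
  g <- voxel_grid(c(48, 48, 1), spacing = 3.5)
  ss <- build_phantom(g, body_radii_mm = 80)
  rx <- data.frame(structure = c("Target", "Core", "Body"),
                   lower = c(59, 0, 0), upper = c(61, 20, 30),
                   weight = c(1000, 100, 30))
  cs <- suppressMessages(prescription_to_constraints(ss, rx))
  target <- structure_voxels(ss, "Target")
  core <- structure_voxels(ss, "Core")
  body_only <- setdiff(structure_voxels(ss, "Body"), c(target, core))
  expect_true(all(cs$lower[target] == 59 & cs$upper[target] == 61))
  expect_true(all(cs$lower[core] == 0 & cs$upper[core] == 20))
  expect_true(all(cs$upper[body_only] == 30))
  expect_equal(unique(cs$nu[target]), 1.0)
  expect_equal(unique(cs$nu[core]), 0.1)
  expect_equal(unique(cs$nu[body_only]), 0.03)
  # no Body bound leaks into the higher-priority Target
  expect_false(any(cs$upper[target] == 30))
  # voxels outside every structure are not active
  outside <- setdiff(seq_len(g$n), structure_voxels(ss, "Body"))
  expect_length(intersect(cs$active, outside), 0)
})

test_that("a trivial all-voxel [0, Inf) prescription yields an empty active set", {
  ss <- structure_set(list(list(name = "All", voxels = 1:10, priority = 1L)), 10)
  rx <- data.frame(structure = "All", lower = 0, upper = Inf, weight = 1)
  cs <- prescription_to_constraints(ss, rx)
  expect_length(cs$active, 0)
  expect_error(prescription_to_constraints(
    ss, data.frame(structure = "All", lower = 5, upper = 2, weight = 1)),
    "All")
})

test_that("half-space step closes the residual in proportion to its weight", {
  # <a, x> = 7 > u = 2; exact projection lands on the boundary
  x1 <- halfspace_step(c(1, 1), c(3, 4), 2, "upper", step_weight = 1)
  expect_equal(x1, c(0.4, 0.2))
  expect_equal(sum(c(3, 4) * x1), 2, tolerance = 1e-12)
  # half weight closes half the residual
  x_half <- halfspace_step(c(1, 1), c(3, 4), 2, "upper", step_weight = 0.5)
  expect_equal(sum(c(3, 4) * x_half), 4.5, tolerance = 1e-12)
  # non-violated constraints are no-ops
  expect_identical(halfspace_step(c(1, 1), c(3, 4), 10, "upper"), c(1, 1))
  expect_identical(halfspace_step(c(1, 1), c(3, 4), 2, "lower"), c(1, 1))
  expect_warning(halfspace_step(c(1, 1), c(0, 0), 2, "upper"), "zero row")
  expect_error(halfspace_step(c(1, 1), c(3, 4), 2, "upper", step_weight = 3),
               "step weight")
})

test_that("sweep on decoupled coordinates solves both slabs at once", {
  di <- dose_influence(Matrix::Diagonal(2, 1))
  cs <- constraint_system(lower = c(1, 0), upper = c(2, 1))
  x <- ams_sweep(c(0, 3), di, cs)
  expect_equal(x, c(1, 1))
  expect_equal(max_violation(x, di, cs), 0)
})

test_that("sweep clamps negative intensities onto the orthant", {
  # row [2, 1] with slab [0, 0]: projecting x = (0, 1) onto the boundary
  # lands at (-0.4, 0.8), which the orthant projection clips to (0, 0.8)
  di <- dose_influence(Matrix::Matrix(c(2, 1), 1, 2, sparse = TRUE))
  cs <- constraint_system(lower = 0, upper = 0)
  x <- ams_sweep(c(0, 1), di, cs)
  expect_equal(x, c(0, 0.8))
})

test_that("sweep agrees with a straight-line dense re-implementation", {
  set.seed(13)
  for (rep in 1:25) {
    tp <- make_toy_problem(10, 4, 0.6, slack = 0.2, seed = rep)
    cs <- amsplan:::toy_constraints(tp, nu = runif(10, 0.2, 1))
    lambda <- sample(c(0.5, 1, 1.5), 1)
    ord <- sample(cs$active)
    x0 <- runif(4, 0, 3)
    got <- ams_sweep(x0, tp$matrix, cs, lambda = lambda, order = ord)
    want <- r_sweep_oracle(x0, as.matrix(tp$matrix$A), cs$lower, cs$upper,
                           cs$nu, lambda, ord)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("control sequences order the active set as documented", {
  cs <- constraint_system(lower = c(1, 1, 1), upper = c(2, 2, 2),
                          nu = c(0.1, 0.9, 0.5))
  expect_identical(make_control_sequence("cyclic", cs), 1:3)
  expect_identical(make_control_sequence("weight_ascending", cs), c(1L, 3L, 2L))
  expect_identical(make_control_sequence("weight_descending", cs), c(2L, 3L, 1L))
  r1 <- make_control_sequence("random", cs, seed = 4)
  r2 <- make_control_sequence("random", cs, seed = 4)
  r3 <- make_control_sequence("random", cs, seed = 5)
  expect_identical(r1, r2)
  expect_setequal(r3, 1:3)
  expect_error(make_control_sequence("zigzag", cs), "unknown control sequence")
})

test_that("proximity and max violation match hand computation and brute force", {
  # single voxel, a = [2], x = [3] -> dose 6, slab [0, 4]
  di <- dose_influence(Matrix::Matrix(2, 1, 1, sparse = TRUE))
  cs <- constraint_system(lower = 0, upper = 4)
  expect_equal(proximity_V(3, di, cs), 1) # (6-4)^2 / 4 / 1
  expect_equal(max_violation(3, di, cs), 2)
  set.seed(17)
  for (rep in 1:100) {
    tp <- make_toy_problem(sample(5:25, 1), sample(3:8, 1), 0.5,
                           slack = 0.3, seed = rep)
    cs <- amsplan:::toy_constraints(tp)
    x <- runif(tp$matrix$m, 0, 3)
    A_dense <- as.matrix(tp$matrix$A)
    expect_equal(proximity_V(x, tp$matrix, cs),
                 brute_proximity(x, A_dense, cs$lower, cs$upper, cs$active),
                 tolerance = 1e-12)
    expect_equal(max_violation(x, tp$matrix, cs),
                 brute_max_violation(x, A_dense, cs$lower, cs$upper, cs$active),
                 tolerance = 1e-12)
    expect_equal(proximity_V(tp$witness, tp$matrix, cs), 0)
    expect_equal(max_violation(tp$witness, tp$matrix, cs), 0)
  }
})

test_that("starting at a feasible witness stops by stagnation with V = 0", {
  tp <- make_toy_problem(40, 8, 0.4, slack = 0.5, seed = 6)
  cs <- amsplan:::toy_constraints(tp)
  res <- feasibility_solve(x0 = tp$witness, matrix = tp$matrix,
                           constraints = cs)
  expect_identical(res$status, "stopped_criterion")
  expect_equal(res$history$V[nrow(res$history)], 0)
  expect_identical(res$x_final, tp$witness) # nothing to project
})

test_that("bare AMS converges on feasible toys and stalls positive on infeasible ones", {
  tp <- make_toy_problem(200, 30, 0.3, TRUE, slack = 0.5, seed = 4)
  cs <- amsplan:::toy_constraints(tp)
  res <- feasibility_solve(matrix = tp$matrix, constraints = cs,
                           max_sweeps = 500)
  expect_lt(max_violation(res$x_final, tp$matrix, cs), 0.01)
  # infeasible: stagnation fires at strictly positive proximity
  tpi <- make_toy_problem(50, 10, 0.4, feasible = FALSE, slack = 0.5, seed = 4)
  csi <- amsplan:::toy_constraints(tpi)
  resi <- feasibility_solve(matrix = tpi$matrix, constraints = csi,
                            max_sweeps = 500)
  expect_identical(resi$status, "stopped_criterion")
  expect_gt(resi$history$V[nrow(resi$history)], 0)
})

test_that("each sweep is Fejer monotone with respect to the witness", {
  for (s in 0:2) {
    tp <- make_toy_problem(60, 12, 0.4, slack = 0.5, seed = s)
    cs <- amsplan:::toy_constraints(tp, nu = runif(60, 0.1, 1))
    for (lambda in c(0.5, 1.0, 1.5)) {
      x <- runif(12, 0, 4)
      dist <- sqrt(sum((x - tp$witness)^2))
      for (t in 1:30) {
        ord <- make_control_sequence("random", cs, seed = 100 * s + t)
        x <- ams_sweep(x, tp$matrix, cs, lambda = lambda, order = ord)
        dist_new <- sqrt(sum((x - tp$witness)^2))
        expect_lte(dist_new, dist + 1e-10)
        dist <- dist_new
      }
    }
  }
})
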