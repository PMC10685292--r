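# Independent straight-line oracles the implementation is checked against.
# These deliberately share no code with the package's hot paths: dense
# arithmetic, explicit loops, naive accumulation.

# dense per-voxel re-implementation of one AMS sweep (upper side first,
# then lower against the updated iterate; clamp after the full pass)
r_sweep_oracle <- function(x, A_dense, lower, upper, nu, lambda, order,
                           weight_scale = 1) {
  for (i in order) {
    a <- A_dense[i, ]
    nrm2 <- sum(a^2)
    if (nrm2 <= 0) next
    w <- lambda * nu[i] * weight_scale
    dot <- sum(a * x)
    if (is.finite(upper[i]) && dot > upper[i]) {
      x <- x - w * (dot - upper[i]) / nrm2 * a
      dot <- sum(a * x)
    }
    if (dot < lower[i]) {
      x <- x + w * (lower[i] - dot) / nrm2 * a
    }
  }
  pmax(x, 0)
}

# naive proximity: mean over active voxels of squared normalized violations
brute_proximity <- function(x, A_dense, lower, upper, active) {
  total <- 0
  used <- 0L
  for (i in active) {
    nrm2 <- sum(A_dense[i, ]^2)
    if (nrm2 <= 0) next
    d <- sum(A_dense[i, ] * x)
    lo <- max(lower[i] - d, 0)
    hi <- if (is.finite(upper[i])) max(d - upper[i], 0) else 0
    total <- total + (lo^2 + hi^2) / nrm2
    used <- used + 1L
  }
  total / used
}

brute_max_violation <- function(x, A_dense, lower, upper, active) {
  worst <- 0
  for (i in active) {
    if (sum(A_dense[i, ]^2) <= 0) next
    d <- sum(A_dense[i, ] * x)
    hi <- if (is.finite(upper[i])) d - upper[i] else -Inf
    worst <- max(worst, lower[i] - d, hi, 0)
  }
  worst
}

# central finite differences of a scalar function of a vector
fd_gradient <- function(fn, x, h_scale = 1e-4) {
  g <- numeric(length(x))
  for (j in seq_along(x)) {
    h <- h_scale * max(1, abs(x[j]))
    e <- numeric(length(x)); e[j] <- h
    g[j] <- (fn(x + e) - fn(x - e)) / (2 * h)
  }
  g
}

# literal transcription of the two-part relative-change stopping rule
literal_stopping <- function(f, V, tol_f, tol_V, consecutive) {
  n <- length(f)
  if (n < consecutive + 1) return(FALSE)
  for (k in (n - consecutive):(n - 1)) {
    ok_f <- tol_f < 0 || abs(f[k + 1] - f[k]) / max(1, f[k]) < tol_f
    ok_V <- tol_V < 0 || abs(V[k + 1] - V[k]) / max(1, V[k]) < tol_V
    if (!(ok_f && ok_V)) return(FALSE)
  }
  TRUE
}

# minimal achievable summed squared slab violation over x >= 0, via a
# generic bound-constrained quasi-Newton solver (independent of the
# projection code path); returns ~0 iff the system is feasible
min_violation_oracle <- function(A_dense, lower, upper, restarts = 5) {
  fn <- function(x) {
    d <- as.numeric(A_dense %*% x)
    sum(pmax(lower - d, 0)^2 + pmax(d - upper, 0)^2)
  }
  gr <- function(x) {
    d <- as.numeric(A_dense %*% x)
    r <- -2 * pmax(lower - d, 0) + 2 * pmax(d - upper, 0)
    as.numeric(crossprod(A_dense, r))
  }
  best <- Inf
  for (r in seq_len(restarts)) {
    x0 <- if (r == 1) rep(1, ncol(A_dense)) else runif(ncol(A_dense), 0, 3)
    fit <- optim(x0, fn, gr, method = "L-BFGS-B", lower = 0,
                 control = list(maxit = 500, factr = 1e4))
    best <- min(best, fit$value)
  }
  best
}

# ray-casting point-in-polygon (polygon as two-column matrix of vertices)
point_in_polygon <- function(pt, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((poly[i, 2] > pt[2]) != (poly[j, 2] > pt[2]) &&
        pt[1] < (poly[j, 1] - poly[i, 1]) * (pt[2] - poly[i, 2]) /
          (poly[j, 2] - poly[i, 2]) + poly[i, 1])
      inside <- !inside
    j <- i
  }
  inside
}

# small composite objective on a toy problem's single "All" structure
toy_objective <- function(tp, specs = NULL) {
  n <- tp$matrix$n
  ss <- structure_set(list(list(name = "All", voxels = seq_len(n),
                                priority = 1L)), n)
  specs <- specs %||% list(objective_spec("f_mean", "All", weight = 1))
  composite_objective(specs, ss, tp$matrix)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
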