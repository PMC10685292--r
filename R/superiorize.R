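#' Tunables of the superiorized AMS algorithm
#'
#' Collects every knob of the interlaced perturbation/feasibility iteration
#' with validation and the documented defaults.
#'
#' @param alpha perturbation kernel in (0, 1): step sizes are
#'   \eqn{\beta = \alpha^s} with a globally nondecreasing exponent `s`, so
#'   the step-size series is summable.
#' @param n_perturbations number of objective-reducing perturbations `N`
#'   executed before each feasibility sweep (>= 1; 0 disables perturbation
#'   and reduces the method to bare feasibility-seeking).
#' @param lambda AMS relaxation parameter in (0, 2].
#' @param eta weight-decay kernel in (0, 1]: sweep `k` (0-based) uses
#'   projection weights \eqn{\eta^k \nu}; `eta = 1` keeps them constant.
#' @param warm_start_increment exponent jump applied after the run's very
#'   first proposal (default 25), taming the initial step sizes.
#' @param max_iterations iteration budget (default 500).
#' @param max_time_s wall-clock budget in seconds (default 3000, i.e. 50
#'   minutes).
#' @param tol_f,tol_V relative-change stopping tolerances for the objective
#'   (default `1e-4`) and the proximity (default `1e-3`); a negative value
#'   disables that part of the criterion.
#' @param consecutive both parts must hold for this many consecutive
#'   iteration pairs (default 3).
#' @param control control-sequence kind, see [make_control_sequence()].
#' @param seed integer seed (drives the random control sequence).
#' @return An object of class `superiorization_config`.
#' @export
superiorization_config <- function(alpha = 0.99, n_perturbations = 5,
                                   lambda = 1, eta = 1,
                                   warm_start_increment = 25,
                                   max_iterations = 500, max_time_s = 3000,
                                   tol_f = 1e-4, tol_V = 1e-3,
                                   consecutive = 3, control = "cyclic",
                                   seed = 1) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (n_perturbations < 0) stop("n_perturbations must be >= 0")
  if (lambda <= 0 || lambda > 2) stop("lambda must lie in (0, 2]")
  if (eta <= 0 || eta > 1) stop("eta must lie in (0, 1]")
  if (warm_start_increment < 1) stop("warm_start_increment must be >= 1")
  if (max_iterations < 1) stop("max_iterations must be >= 1")
  if (consecutive < 1) stop("consecutive must be >= 1")
  if (!control %in% c("cyclic", "random", "weight_ascending", "weight_descending"))
    stop(sprintf("unknown control sequence kind '%s'", control))
  structure(list(
    alpha = alpha, n_perturbations = as.integer(n_perturbations),
    lambda = lambda, eta = eta,
    warm_start_increment = as.integer(warm_start_increment),
    max_iterations = as.integer(max_iterations), max_time_s = max_time_s,
    tol_f = tol_f, tol_V = tol_V, consecutive = as.integer(consecutive),
    control = control, seed = as.integer(seed)
  ), class = "superiorization_config")
}

#' Normalized negative-gradient direction
#'
#' Returns \eqn{-g / \|g\|_2}, or the zero vector when the gradient
#' vanishes (the perturbation then becomes a no-op). Normalizing makes the
#' kernel power \eqn{\alpha^s} the actual step length.
#'
#' @param g gradient vector; must be finite.
#' @return Unit-norm descent direction, or zeros.
#' @export
descent_direction <- function(g) {
  if (!all(is.finite(g))) stop("gradient must be finite")
  nrm <- sqrt(sum(g^2))
  if (nrm > 0) -g / nrm else numeric(length(g))
}

#' Objective-reducing perturbation phase
#'
#' Executes `N` perturbations. Each perturbation records the phase-start
#' value `f_start = f(x)`, then proposes \eqn{z = x + \beta v} with
#' \eqn{\beta = \alpha^s} and `v` the normalized negative gradient at `x`;
#' after every proposal `s` is incremented (by `s_increment_first` on the
#' phase's first proposal — the warm start when this is the run's first
#' phase — and by 1 afterwards). The proposal is accepted as soon as
#' \eqn{f(z) \le f_{start}}; rejected proposals retry with the next (smaller)
#' step size. A zero gradient skips the perturbation. `s` never decreases,
#' and the accepted point never exceeds the phase-start objective value
#' (asserted).
#'
#' @param x current intensity vector.
#' @param objective a [composite_objective()].
#' @param alpha kernel in (0, 1).
#' @param s_in current (global) exponent, >= 0.
#' @param n_perturbations number of perturbations `N`.
#' @param s_increment_first increment applied after the first proposal of
#'   this phase (warm-start value or 1).
#' @return List with the updated `x`, the final exponent `s`, the number of
#'   objective evaluations `evals`, the summed proposed step sizes
#'   `beta_sum` (accepted and rejected) and the final objective value `f`.
#' @export
perturbation_phase <- function(x, objective, alpha, s_in, n_perturbations,
                               s_increment_first = 1) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (s_in < 0) stop("s must be nonnegative")
  s <- s_in
  evals <- 0L
  beta_sum <- 0
  first_proposal <- TRUE
  f_x <- NULL
  for (p in seq_len(n_perturbations)) {
    vg <- composite_value_and_gradient(objective, x)
    evals <- evals + 1L
    f_start <- vg$f
    v <- descent_direction(vg$gradient)
    if (all(v == 0)) { f_x <- f_start; next } # stationary: skip perturbation
    repeat {
      beta <- alpha^s
      z <- x + beta * v
      beta_sum <- beta_sum + beta
      s <- s + if (first_proposal) s_increment_first else 1L
      first_proposal <- FALSE
      f_z <- composite_value(objective, z)
      evals <- evals + 1L
      if (f_z <= f_start) {
        x <- z
        f_x <- f_z
        break
      }
      if (beta < .Machine$double.eps^2) { # step underflow: give up this perturbation
        f_x <- f_start
        break
      }
    }
    stopifnot(f_x <= f_start) # within-perturbation monotonicity, asserted live
  }
  if (is.null(f_x)) {
    f_x <- composite_value(objective, x)
    evals <- evals + 1L
  }
  list(x = x, s = s, evals = evals, beta_sum = beta_sum, f = f_x)
}

#' Geometric decay of the projection weights
#'
#' Effective weights after `k` feasibility sweeps: \eqn{\eta^k \nu}.
#' `eta = 1` reproduces constant weights.
#'
#' @param nu base per-voxel weights.
#' @param eta decay kernel in (0, 1].
#' @param k sweep counter, >= 0.
#' @return `eta^k * nu`, elementwise.
#' @export
decay_weights <- function(nu, eta, k) {
  if (eta <= 0 || eta > 1) stop("eta must lie in (0, 1]")
  if (k < 0) stop("k must be nonnegative")
  eta^k * nu
}

#' Two-part relative-change stopping criterion
#'
#' Stops when, for the last `consecutive` iteration pairs, both
#' \eqn{|f_{k+1} - f_k| / \max(1, f_k) <} `tol_f` and
#' \eqn{|V_{k+1} - V_k| / \max(1, V_k) <} `tol_V`. A negative tolerance
#' disables that part (it is then always considered satisfied).
#'
#' @param history data frame with columns `f` and `V` (one row per
#'   iteration, oldest first).
#' @param tol_f,tol_V tolerances on the relative changes.
#' @param consecutive required number of consecutive satisfied pairs.
#' @return `TRUE` when the criterion is met; `FALSE` otherwise (including
#'   when fewer than `consecutive + 1` iterations are available).
#' @export
stopping_met <- function(history, tol_f = 1e-4, tol_V = 1e-3,
                         consecutive = 3) {
  nh <- nrow(history)
  if (nh < consecutive + 1L) return(FALSE)
  idx <- (nh - consecutive):(nh - 1L)
  ok_part <- function(vals, tol) {
    if (tol < 0) return(TRUE)
    prev <- vals[idx]; nxt <- vals[idx + 1L]
    all(abs(nxt - prev) / pmax(1, prev) < tol)
  }
  ok_part(history$f, tol_f) && ok_part(history$V, tol_V)
}

#' Superiorized AMS planning
#'
#' The superiorized version of the feasibility-seeking basic algorithm:
#' iteration `k = 0, 1, ...` runs the [perturbation_phase()] (`N`
#' objective-reducing steps with summable step sizes), then one
#' [ams_sweep()] with projection weights decayed to \eqn{\eta^k \nu}, then
#' increments `k`. One history record is appended per full iteration.
#' Terminates via [stopping_met()], the iteration budget or the wall-time
#' budget. With `N = 0` or all objective weights zero the iterate sequence
#' is identical to [feasibility_solve()] under the same seed and control
#' sequence (given `eta = 1`).
#'
#' @param x0 nonnegative starting intensities (default: zero vector, an
#'   objective-neutral cold start).
#' @param matrix a [dose_influence()].
#' @param constraints a [constraint_system()].
#' @param objective a [composite_objective()].
#' @param config a [superiorization_config()].
#' @param verbose emit a structured log line per iteration.
#' @return A `plan_result` (see [feasibility_solve()]); its history also
#'   carries the objective value `f`, the exponent `s` and the sweep
#'   counter `k` per iteration, plus attributes `beta_sum` (total proposed
#'   step length) and `s0` (exponent of the run's first proposal).
#' @export
superiorize <- function(x0 = NULL, matrix, constraints, objective, config,
                        verbose = FALSE) {
  stopifnot(inherits(matrix, "dose_influence"),
            inherits(constraints, "constraint_system"),
            inherits(objective, "composite_objective"),
            inherits(config, "superiorization_config"))
  if (objective$matrix$m != matrix$m || objective$matrix$n != matrix$n)
    stop("objective and constraint system refer to different problems")
  x <- x0 %||% numeric(matrix$m)
  if (length(x) != matrix$m) stop("x0 length must equal the beamlet count")
  if (any(x < 0)) stop("x0 must be nonnegative")
  csr <- as_csr(matrix)
  csr$row_sq <- matrix$row_sq_norms

  t0 <- proc.time()[["elapsed"]]
  s <- 0L
  beta_sum <- 0
  vm <- violation_metrics(x, matrix, constraints)
  f0 <- composite_value(objective, x)
  hist <- history_frame(config$max_iterations + 1L)
  hist[1L, ] <- list(0L, f0, vm$V, vm$max_violation, 0L, 0L, 0)
  nrec <- 1L
  status <- "max_iterations"
  for (k in 0:(config$max_iterations - 1L)) {
    if (config$n_perturbations > 0L) {
      ph <- perturbation_phase(
        x, objective, config$alpha, s, config$n_perturbations,
        s_increment_first = if (k == 0L) config$warm_start_increment else 1L
      )
      x <- ph$x
      s <- ph$s
      beta_sum <- beta_sum + ph$beta_sum
    }
    ord <- if (config$control == "random")
      make_control_sequence("random", constraints, seed = config$seed + k + 1L)
    else make_control_sequence(config$control, constraints)
    x <- ams_sweep_kernel(x, csr, constraints, config$lambda, ord,
                          config$eta^k)
    vm <- violation_metrics(x, matrix, constraints, quiet = TRUE)
    f_now <- composite_value(objective, x)
    el <- proc.time()[["elapsed"]] - t0
    nrec <- nrec + 1L
    hist[nrec, ] <- list(k + 1L, f_now, vm$V, vm$max_violation, s, k + 1L, el)
    if (verbose)
      message(sprintf("iter=%d f=%.6g V=%.6g max_violation=%.6g s=%d",
                      k + 1L, f_now, vm$V, vm$max_violation, s))
    if (stopping_met(hist[seq_len(nrec), ], config$tol_f, config$tol_V,
                     config$consecutive)) {
      status <- "stopped_criterion"
      break
    }
    if (el > config$max_time_s) {
      status <- "max_time"
      break
    }
  }
  res <- plan_result(x, matrix, hist[seq_len(nrec), ], status,
                     config = c(list(mode = "superiorize"), unclass(config)))
  attr(res$history, "beta_sum") <- beta_sum
  attr(res$history, "s0") <- 0L
  res
}
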