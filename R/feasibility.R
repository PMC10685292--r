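#' Per-voxel hyperslab constraint system
#'
#' Holds the lower/upper dose bounds \eqn{[\ell_i, u_i]} (Gy) and the
#' projection weights \eqn{\nu_i \in (0, 1]} for every voxel. The *active
#' set* contains the voxels carrying a nontrivial slab (a positive lower
#' bound or a finite upper bound); only those are visited by the sweeps and
#' enter the proximity metrics.
#'
#' @param lower,upper numeric vectors (one entry per voxel); `upper` may be
#'   `Inf` for absent upper bounds, `lower >= 0` and `lower <= upper`.
#' @param nu per-voxel weights in (0, 1].
#' @return An object of class `constraint_system` with fields `lower`,
#'   `upper`, `nu` and `active` (1-based voxel indices).
#' @export
constraint_system <- function(lower, upper, nu = rep(1, length(lower))) {
  n <- length(lower)
  if (length(upper) != n || length(nu) != n)
    stop("lower, upper and nu must have one entry per voxel")
  if (any(lower < 0)) stop("lower bounds must be nonnegative")
  if (any(lower > upper)) stop("lower bounds must not exceed upper bounds")
  if (any(nu <= 0 | nu > 1)) stop("weights nu must lie in (0, 1]")
  active <- which(lower > 0 | is.finite(upper))
  structure(list(lower = as.numeric(lower), upper = as.numeric(upper),
                 nu = as.numeric(nu), active = active),
            class = "constraint_system")
}

#' @export
print.constraint_system <- function(x, ...) {
  cat(sprintf("<constraint_system> %d voxels, %d active slabs\n",
              length(x$lower), length(x$active)))
  invisible(x)
}

#' Expand a per-VOI prescription into per-voxel constraints
#'
#' Each voxel is assigned the bounds of its highest-priority containing
#' structure that appears in the prescription (exclusive partition by
#' priority rank). Projection weights are the prescription's relative
#' weights rescaled into (0, 1] by dividing by the maximum. Voxels covered
#' by no prescribed structure get the trivial slab `[0, Inf)` and are
#' excluded from the active set.
#'
#' @param structures a [structure_set()].
#' @param prescription a data frame with columns `structure`, `lower`,
#'   `upper` (Gy; `upper` may be `Inf` or `NA` for "no upper bound") and
#'   `weight` (relative importance, positive) — the shape of a clinical
#'   tolerance table.
#' @return A [constraint_system()] over all `structures$n` voxels.
#' @examples
#' ss <- build_phantom(voxel_grid(c(32, 32, 1), 5))
#' rx <- data.frame(structure = c("Target", "Core", "Body"),
#'                  lower = c(59, 0, 0), upper = c(61, 20, 30),
#'                  weight = c(1000, 100, 30))
#' cs <- prescription_to_constraints(ss, rx)
#' @export
prescription_to_constraints <- function(structures, prescription) {
  stopifnot(inherits(structures, "structure_set"))
  req <- c("structure", "lower", "upper", "weight")
  if (!all(req %in% names(prescription)))
    stop("prescription needs columns: ", paste(req, collapse = ", "))
  prescription$upper[is.na(prescription$upper)] <- Inf
  if (any(prescription$lower > prescription$upper)) {
    bad <- prescription$structure[prescription$lower > prescription$upper]
    stop(sprintf("inconsistent bounds (lower > upper) for: %s",
                 paste(bad, collapse = ", ")))
  }
  if (any(prescription$weight <= 0)) stop("prescription weights must be positive")
  unknown <- setdiff(prescription$structure, structure_names(structures))
  if (length(unknown))
    stop(sprintf("prescription references unknown structures: %s",
                 paste(unknown, collapse = ", ")))

  n <- structures$n
  lower <- numeric(n)
  upper <- rep(Inf, n)
  nu <- rep(1, n)
  assigned <- logical(n)
  numax <- max(prescription$weight)
  # structures come ordered by priority rank; first containing wins
  for (s in structures$structures) {
    row <- which(prescription$structure == s$name)
    if (!length(row)) next
    v <- s$voxels[!assigned[s$voxels]]
    assigned[v] <- TRUE
    lower[v] <- prescription$lower[row[1]]
    upper[v] <- prescription$upper[row[1]]
    nu[v] <- prescription$weight[row[1]] / numax
  }
  n_out <- sum(!assigned)
  if (n_out)
    message(sprintf("%d voxels belong to no prescribed structure; excluded from the active set", n_out))
  constraint_system(lower, upper, nu)
}

#' Relaxed projection onto one violated half-space
#'
#' The elementary AMS step: if the voxel's inequality on the given side is
#' violated, move `x` along the row direction by the relaxed residual,
#' \eqn{x' = x \mp \omega \frac{\langle a_i, x\rangle - b}{\|a_i\|_2^2} a_i}
#' with step weight \eqn{\omega = \lambda \nu_i}. With \eqn{\omega = 1} the
#' residual is closed exactly; \eqn{\omega \in (0, 2)} interpolates /
#' over-relaxes. Non-violated constraints leave `x` unchanged.
#'
#' @param x current intensity vector.
#' @param a the voxel's dose-influence row (dense numeric).
#' @param bound the bound on this side (Gy).
#' @param side `"upper"` or `"lower"`.
#' @param step_weight effective relaxation \eqn{\lambda \nu_i}, in (0, 2].
#' @return The updated vector `x'`.
#' @export
halfspace_step <- function(x, a, bound, side = c("upper", "lower"),
                           step_weight = 1) {
  side <- match.arg(side)
  nrm2 <- sum(a^2)
  if (nrm2 <= 0) {
    warning("zero row: half-space undefined, step skipped")
    return(x)
  }
  if (step_weight <= 0 || step_weight > 2)
    stop("step weight must lie in (0, 2]")
  dot <- sum(a * x)
  if (side == "upper" && is.finite(bound) && dot > bound) {
    x - step_weight * (dot - bound) / nrm2 * a
  } else if (side == "lower" && dot < bound) {
    x + step_weight * (bound - dot) / nrm2 * a
  } else x
}

#' Control sequence: row visiting order for one sweep
#'
#' @param kind one of `"cyclic"` (ascending voxel index), `"random"`
#'   (seeded shuffle, redrawn every sweep by the solvers), or
#'   `"weight_ascending"` / `"weight_descending"` (stable sort by
#'   \eqn{\nu_i}).
#' @param constraints a [constraint_system()].
#' @param seed integer seed (random kind only).
#' @return An integer permutation of the active voxel indices.
#' @export
make_control_sequence <- function(kind, constraints, seed = NULL) {
  stopifnot(inherits(constraints, "constraint_system"))
  act <- constraints$active
  switch(kind,
    cyclic = sort(act),
    random = with_seed(seed %||% 0L, sample(act)),
    weight_ascending = act[order(constraints$nu[act], method = "radix")],
    weight_descending = act[order(-constraints$nu[act], method = "radix")],
    stop(sprintf("unknown control sequence kind '%s'", kind))
  )
}

#' One full AMS relaxation sweep
#'
#' Visits every active voxel once in the given order; for each, applies the
#' upper-bound half-space step and then the lower-bound step (against the
#' already-updated inner product) with effective weight
#' \eqn{\lambda \cdot \nu_i \cdot} `weight_scale`. After the full pass the
#' iterate is clamped onto the nonnegative orthant. The heavy lifting runs
#' in compiled code; [feasibility_solve()] and [superiorize()] call the same
#' kernel with a cached sparse-row layout.
#'
#' @param x intensity vector (length `m`), finite.
#' @param matrix a [dose_influence()].
#' @param constraints a [constraint_system()] over the matrix's rows.
#' @param lambda relaxation parameter in (0, 2].
#' @param order visiting order, an integer vector of (active) voxel
#'   indices; defaults to the cyclic sequence.
#' @param weight_scale extra multiplier in (0, 1] applied to all weights
#'   (used for the decay \eqn{\eta^k} during superiorization).
#' @return The swept (and clamped) intensity vector.
#' @export
ams_sweep <- function(x, matrix, constraints, lambda = 1, order = NULL,
                      weight_scale = 1) {
  stopifnot(inherits(matrix, "dose_influence"),
            inherits(constraints, "constraint_system"))
  if (lambda <= 0 || lambda > 2) stop("lambda must lie in (0, 2]")
  if (weight_scale <= 0 || weight_scale > 1)
    stop("weight scale must lie in (0, 1]")
  if (!all(is.finite(x))) stop("x must be finite")
  if (is.null(order)) order <- make_control_sequence("cyclic", constraints)
  csr <- as_csr(matrix)
  csr$row_sq <- matrix$row_sq_norms
  ams_sweep_kernel(x, csr, constraints, lambda, order, weight_scale)
}

ams_sweep_kernel <- function(x, csr, constraints, lambda, order, weight_scale) {
  .ams_sweep_csr(
    as.numeric(x), csr$p, csr$j, csr$x,
    constraints$lower, constraints$upper,
    csr$row_sq, lambda * weight_scale * constraints$nu,
    as.integer(order) - 1L
  )
}

#' Proximity function: weighted mean squared slab violation
#'
#' \deqn{V(x) = \frac{1}{n_{act}} \sum_{i \in act}
#'   \frac{(\ell_i - \langle a_i, x\rangle)_+^2 +
#'         (\langle a_i, x\rangle - u_i)_+^2}{\|a_i\|_2^2}}
#' The sum runs over the active voxels; all-zero rows are excluded (their
#' half-spaces are undefined) with a message. `V(x) = 0` exactly when `x`
#' satisfies every active slab.
#'
#' @inheritParams ams_sweep
#' @return Scalar `V >= 0`.
#' @export
proximity_V <- function(x, matrix, constraints) {
  vm <- violation_metrics(x, matrix, constraints)
  vm$V
}

#' Maximum constraint violation in Gy
#'
#' The infinity norm over all active inequality residuals:
#' \eqn{\max_i \max(\ell_i - \langle a_i, x\rangle,
#' \langle a_i, x\rangle - u_i, 0)}.
#'
#' @inheritParams ams_sweep
#' @return Scalar violation in Gy (0 when feasible).
#' @export
max_violation <- function(x, matrix, constraints) {
  vm <- violation_metrics(x, matrix, constraints)
  vm$max_violation
}

# shared computation of V and the max residual (one matvec)
violation_metrics <- function(x, matrix, constraints, d = NULL, quiet = FALSE) {
  stopifnot(inherits(matrix, "dose_influence"),
            inherits(constraints, "constraint_system"))
  act <- constraints$active
  if (!length(act)) stop("constraint system has an empty active set")
  zero <- act[matrix$row_sq_norms[act] == 0]
  if (length(zero)) {
    if (!quiet)
      message(sprintf("%d active voxels have all-zero rows; excluded from proximity", length(zero)))
    act <- setdiff(act, zero)
  }
  if (is.null(d)) d <- as.numeric(matrix$A %*% x)
  lo <- pmax(constraints$lower[act] - d[act], 0)
  hi <- pmax(d[act] - constraints$upper[act], 0)
  hi[!is.finite(constraints$upper[act])] <- 0
  list(
    V = mean((lo^2 + hi^2) / matrix$row_sq_norms[act]),
    max_violation = if (length(act)) max(lo, hi, 0) else 0
  )
}

#' Bare AMS feasibility-seeking
#'
#' Iterates [ams_sweep()] (weight scale fixed at 1) from `x0` until the
#' proximity stagnates, a sweep budget is exhausted, or a wall-time limit
#' is hit. Stagnation uses the relative-change rule
#' \eqn{|V_{k+1} - V_k| / \max(1, V_k) <} `tol_V` for `consecutive`
#' consecutive sweep pairs (set `tol_V < 0` to disable).
#'
#' @param x0 nonnegative starting intensities (default: zero vector).
#' @param matrix a [dose_influence()].
#' @param constraints a [constraint_system()].
#' @param lambda relaxation parameter in (0, 2].
#' @param control control-sequence kind, see [make_control_sequence()].
#' @param max_sweeps sweep budget.
#' @param max_time_s wall-time budget in seconds.
#' @param tol_V stagnation tolerance on the relative change of V.
#' @param consecutive number of consecutive stagnant pairs required.
#' @param seed base seed for the random control sequence (sweep `t` draws
#'   with `seed + t`).
#' @param verbose emit a structured log line per sweep.
#' @return A list of class `plan_result` with `x_final`, `d_final`,
#'   `history` (per-sweep `sweep`, `f` (`NA` here), `V`, `max_violation`,
#'   `s`, `k`, `elapsed_s`) and `status`.
#' @export
feasibility_solve <- function(x0 = NULL, matrix, constraints, lambda = 1,
                              control = "cyclic", max_sweeps = 500,
                              max_time_s = 3000, tol_V = 1e-3,
                              consecutive = 3, seed = 1, verbose = FALSE) {
  stopifnot(inherits(matrix, "dose_influence"))
  x <- x0 %||% numeric(matrix$m)
  if (length(x) != matrix$m) stop("x0 length must equal the beamlet count")
  if (any(x < 0)) stop("x0 must be nonnegative")
  csr <- as_csr(matrix)
  csr$row_sq <- matrix$row_sq_norms
  t0 <- proc.time()[["elapsed"]]
  vm <- violation_metrics(x, matrix, constraints)
  hist <- history_frame(max_sweeps + 1L)
  hist[1L, ] <- list(0L, NA_real_, vm$V, vm$max_violation, 0L, 0L, 0)
  nrec <- 1L
  status <- "max_iterations"
  for (t in seq_len(max_sweeps)) {
    ord <- if (control == "random")
      make_control_sequence("random", constraints, seed = seed + t)
    else make_control_sequence(control, constraints)
    x <- ams_sweep_kernel(x, csr, constraints, lambda, ord, 1)
    vm <- violation_metrics(x, matrix, constraints, quiet = TRUE)
    el <- proc.time()[["elapsed"]] - t0
    nrec <- nrec + 1L
    hist[nrec, ] <- list(t, NA_real_, vm$V, vm$max_violation, 0L, t, el)
    if (verbose)
      message(sprintf("sweep=%d V=%.6g max_violation=%.6g", t, vm$V, vm$max_violation))
    if (stopping_met(hist[seq_len(nrec), ], tol_f = -1, tol_V = tol_V,
                     consecutive = consecutive)) {
      status <- "stopped_criterion"
      break
    }
    if (el > max_time_s) {
      status <- "max_time"
      break
    }
  }
  plan_result(x, matrix, hist[seq_len(nrec), ], status,
              config = list(mode = "feasibility", lambda = lambda,
                            control = control, seed = seed))
}

history_frame <- function(nrow) {
  data.frame(sweep = integer(nrow), f = NA_real_, V = NA_real_,
             max_violation = NA_real_, s = integer(nrow), k = integer(nrow),
             elapsed_s = NA_real_)
}

plan_result <- function(x, matrix, history, status, config = list()) {
  structure(list(
    x_final = x,
    d_final = as.numeric(matrix$A %*% x),
    history = history,
    status = status,
    config = config
  ), class = "plan_result")
}

#' @export
print.plan_result <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf("<plan_result> %s after %d sweeps: f=%s V=%.4g max_violation=%.4g Gy\n",
              x$status, last$sweep,
              if (is.na(last$f)) "-" else sprintf("%.6g", last$f),
              last$V, last$max_violation))
  invisible(x)
}
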