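#' Random small feasibility problems with known status
#'
#' Draws a sparse nonnegative system of voxel hyperslabs for oracle testing.
#' Feasible instances carry a certified nonnegative witness `x_star`: bounds
#' are built as `[<a_i, x*> - slack, <a_i, x*> + slack]` (lower bound clipped
#' at 0), so the witness satisfies every slab by construction. Infeasible
#' instances duplicate one matrix row into another and give the two copies
#' disjoint intervals — no x can satisfy both, which certifies infeasibility
#' without an external solver.
#'
#' @param n number of voxels (rows); `n >= 2` required when
#'   `feasible = FALSE`.
#' @param m number of beamlets (columns).
#' @param density expected fraction of nonzero entries, in (0, 1].
#' @param feasible construct a feasible (default) or provably infeasible
#'   instance.
#' @param slack half-width of each slab around the witness dose, in Gy;
#'   must be positive for feasible instances.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @return A list of class `toy_problem` with fields `matrix`
#'   (a [dose_influence()]), `lower`, `upper`, `witness` (NULL when
#'   infeasible), `feasible` and `seed`.
#' @examples
#' tp <- make_toy_problem(n = 20, m = 5, density = 0.5, slack = 0.5, seed = 1)
#' d <- as.numeric(tp$matrix$A %*% tp$witness)
#' all(d >= tp$lower - 1e-12 & d <= tp$upper + 1e-12)
#' @export
make_toy_problem <- function(n, m, density = 0.3, feasible = TRUE,
                             slack = 0.5, seed = 1) {
  if (n < 1 || m < 1) stop("n and m must be >= 1")
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  if (feasible && slack <= 0) stop("slack must be positive for feasible problems")
  if (!feasible && n < 2) stop("infeasible construction needs n >= 2")
  if (!feasible && slack <= 0) stop("slack must be positive (it separates the duplicated slabs)")
  with_seed(seed, {
    nz <- matrix(runif(n * m) < density, n, m)
    # every row needs at least one entry so each voxel defines a half-space
    empty <- which(rowSums(nz) == 0)
    if (length(empty)) nz[cbind(empty, sample.int(m, length(empty), replace = TRUE))] <- TRUE
    vals <- matrix(0, n, m)
    vals[nz] <- runif(sum(nz), 0.1, 1)
    x_star <- runif(m, 0.5, 1.5)
    if (!feasible) {
      # duplicated rows with disjoint slabs
      vals[2, ] <- vals[1, ]
    }
    t_dose <- as.numeric(vals %*% x_star)
    lower <- pmax(t_dose - slack, 0)
    upper <- t_dose + slack
    if (!feasible) {
      lower[1] <- t_dose[1]; upper[1] <- t_dose[1] + slack
      lower[2] <- t_dose[2] + 3 * slack; upper[2] <- t_dose[2] + 4 * slack
    }
    structure(list(
      matrix = dose_influence(Matrix::Matrix(vals, sparse = TRUE)),
      lower = lower,
      upper = upper,
      witness = if (feasible) x_star else NULL,
      feasible = feasible,
      seed = as.integer(seed)
    ), class = "toy_problem")
  })
}

#' @export
print.toy_problem <- function(x, ...) {
  cat(sprintf("<toy_problem> %d x %d, %s (seed %d)\n",
              x$matrix$n, x$matrix$m,
              if (x$feasible) "feasible by witness" else "infeasible by construction",
              x$seed))
  invisible(x)
}

# ConstraintSystem view of a toy problem: every voxel active, unit weights.
toy_constraints <- function(tp, nu = NULL) {
  constraint_system(lower = tp$lower, upper = tp$upper,
                    nu = nu %||% rep(1, tp$matrix$n))
}
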