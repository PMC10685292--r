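#' The packaged TG119-like planning problem
#'
#' Builds the complete synthetic benchmark used throughout the package's
#' examples and tests: horseshoe phantom, beamlet dose influence matrix, a
#' clinical-tolerance-shaped prescription (Target 59-61 Gy, Core < 20 Gy,
#' Body < 30 Gy with relative weights 1000/100/30), the matching
#' weighted-sum objective (squared deviation to 60 Gy on the Target,
#' squared overdose at 20/30 Gy on Core/Body), and a per-voxel constraint
#' system guaranteed feasible by construction.
#'
#' Feasibility guarantee: a nonnegative witness fluence is computed by a
#' bound-constrained least-squares fit to the ideal dose (60 Gy in the
#' Target, 0 elsewhere), rescaled to a 60 Gy mean target dose. Each VOI's
#' tolerance is then widened exactly as far as needed (plus `margin_gy`)
#' to contain the witness dose, so the witness certifies the constraint
#' system. With the default geometry the synthetic dose model cannot reach
#' clinical target homogeneity, so the effective target window is wider
#' than 59-61 Gy; the widened bounds are returned alongside the nominal
#' prescription.
#'
#' Structures are resolved to the exclusive partition (Target > Core >
#' Body by priority) for both constraints and objectives.
#'
#' @param nx in-plane grid size (the slab is `nx` x `nx` x 1).
#' @param spacing_mm voxel spacing.
#' @param beams a [beam_config()].
#' @param margin_gy slack added around the witness dose when widening
#'   bounds (gives the feasible set an interior).
#' @return A list of class `plan_problem` whose `meta` carries the witness
#'   and the nominal prescription; fields `matrix`, `structures`
#'   (exclusive), `constraints`, `grid`, `objective`, `prescription`.
#' @examples
#' \donttest{
#' pp <- phantom_problem(nx = 32, spacing_mm = 6)
#' max_violation(pp$meta$witness, pp$matrix, pp$constraints) # 0: certified
#' }
#' @export
phantom_problem <- function(nx = 64, spacing_mm = 3, beams = beam_config(),
                            margin_gy = 0.5) {
  grid <- voxel_grid(c(nx, nx, 1), spacing_mm)
  half <- nx * spacing_mm / 2
  geom_scale <- min(1, half / 82) # shrink radii on small grids
  ss_raw <- build_phantom(grid,
                          core_radius_mm = 10 * geom_scale,
                          target_inner_mm = 15 * geom_scale,
                          target_outer_mm = 37 * geom_scale,
                          body_radii_mm = c(80, 80) * geom_scale)
  di <- generate_dose_influence(grid, ss_raw, beams)
  ss <- resolve_structures(ss_raw)

  target <- structure_voxels(ss, "Target")
  core <- structure_voxels(ss, "Core")
  body <- structure_voxels(ss, "Body")

  # nonnegative least-squares witness against the ideal dose
  ideal <- numeric(grid$n)
  ideal[target] <- 60
  wvox <- numeric(grid$n)
  wvox[target] <- 10
  wvox[core] <- 1
  wvox[body] <- 0.05
  A <- di$A
  obj_fn <- function(x) {
    r <- as.numeric(A %*% x) - ideal
    sum(wvox * r^2)
  }
  obj_gr <- function(x) {
    r <- as.numeric(A %*% x) - ideal
    2 * as.numeric(Matrix::crossprod(A, wvox * r))
  }
  fit <- optim(rep(0.1, di$m), obj_fn, obj_gr, method = "L-BFGS-B",
               lower = 0, control = list(maxit = 300))
  witness <- pmax(fit$par, 0)
  d_w <- as.numeric(A %*% witness)
  witness <- witness * 60 / mean(d_w[target])
  d_w <- d_w * 60 / mean(d_w[target])

  prescription <- data.frame(
    structure = c("Target", "Core", "Body"),
    lower = c(59, 0, 0),
    upper = c(61, 20, 30),
    weight = c(1000, 100, 30)
  )
  widened <- prescription
  widened$lower[1] <- min(59, min(d_w[target]) - margin_gy)
  widened$upper[1] <- max(61, max(d_w[target]) + margin_gy)
  widened$upper[2] <- max(20, max(d_w[core]) + margin_gy)
  widened$upper[3] <- max(30, max(d_w[body]) + margin_gy)

  constraints <- prescription_to_constraints(ss, widened)
  objective <- composite_objective(list(
    objective_spec("f_sqdev", "Target", weight = 1000, dose_gy = 60),
    objective_spec("f_sqdev+", "Core", weight = 100, dose_gy = 20),
    objective_spec("f_sqdev+", "Body", weight = 30, dose_gy = 30)
  ), ss, di)

  out <- plan_problem(di, structures = ss, constraints = constraints,
                      grid = grid,
                      meta = list(kind = "phantom", witness = witness,
                                  prescription_nominal = prescription,
                                  prescription = widened))
  out$objective <- objective
  out$prescription <- widened
  out
}
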