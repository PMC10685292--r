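OBJECTIVE_KINDS <- c("sq_deviation", "sq_overdose", "sq_underdose",
                     "mean_dose", "max_dvh", "min_dvh")

# serialized names used in prescriptions/configs -> canonical kinds
OBJECTIVE_ALIASES <- c(
  f_sqdev = "sq_deviation", "f_sqdev+" = "sq_overdose",
  "f_sqdev-" = "sq_underdose", f_mean = "mean_dose",
  f_maxDVH = "max_dvh", f_minDVH = "min_dvh"
)

normalize_objective_kind <- function(kind) {
  if (kind %in% OBJECTIVE_KINDS) return(kind)
  if (kind %in% names(OBJECTIVE_ALIASES)) return(unname(OBJECTIVE_ALIASES[[kind]]))
  stop(sprintf("unknown objective kind '%s' (use one of: %s)", kind,
               paste(c(OBJECTIVE_KINDS, names(OBJECTIVE_ALIASES)), collapse = ", ")))
}

#' Per-VOI dose objective specification
#'
#' One term of the weighted-sum planning objective
#' \eqn{f(x) = \sum_p w_p f_p(d(x))}. Supported kinds (per-structure mean
#' convention, doses `d_i` restricted to the structure `S`):
#' \describe{
#'   \item{`sq_deviation` (`f_sqdev`)}{\eqn{\frac{1}{|S|}\sum_i (d_i - \hat d)^2}}
#'   \item{`sq_overdose` (`f_sqdev+`)}{\eqn{\frac{1}{|S|}\sum_i \max(d_i - \hat d, 0)^2}}
#'   \item{`sq_underdose` (`f_sqdev-`)}{\eqn{\frac{1}{|S|}\sum_i \min(d_i - \hat d, 0)^2}}
#'   \item{`mean_dose` (`f_mean`)}{\eqn{\frac{1}{|S|}\sum_i d_i}}
#'   \item{`max_dvh` (`f_maxDVH`)}{squared overdose restricted to the
#'     hottest `volume`-fraction above `dose_gy`, see [dvh_objective()]}
#'   \item{`min_dvh` (`f_minDVH`)}{squared underdose restricted to the
#'     coldest voxels below `dose_gy` down to the `volume`-quantile}
#' }
#'
#' @param kind canonical kind or serialized alias (e.g. `"f_sqdev+"`).
#' @param structure name of the structure the term operates on.
#' @param weight nonnegative importance weight \eqn{w_p}.
#' @param dose_gy reference dose \eqn{\hat d} in Gy (all kinds except
#'   `mean_dose`).
#' @param volume volume fraction in (0, 1) (DVH kinds only).
#' @return An object of class `objective_spec`.
#' @export
objective_spec <- function(kind, structure, weight = 1,
                           dose_gy = NULL, volume = NULL) {
  kind <- normalize_objective_kind(kind)
  if (weight < 0) stop("objective weight must be nonnegative")
  needs_ref <- kind != "mean_dose"
  if (needs_ref) {
    if (is.null(dose_gy) || dose_gy < 0)
      stop(sprintf("objective '%s' needs a reference dose >= 0 Gy", kind))
  }
  if (kind %in% c("max_dvh", "min_dvh")) {
    if (is.null(volume) || volume <= 0 || volume >= 1)
      stop("DVH objectives need a volume fraction in (0, 1)")
  } else volume <- NULL
  structure(list(kind = kind, structure = structure, weight = weight,
                 dose_gy = if (needs_ref) dose_gy else NULL, volume = volume),
            class = "objective_spec")
}

#' @export
print.objective_spec <- function(x, ...) {
  params <- c(if (!is.null(x$dose_gy)) sprintf("%g Gy", x$dose_gy),
              if (!is.null(x$volume)) sprintf("%g%%", 100 * x$volume))
  cat(sprintf("<objective_spec> %s on %s, w = %g%s\n", x$kind, x$structure,
              x$weight,
              if (length(params)) paste0(" (", paste(params, collapse = ", "), ")") else ""))
  invisible(x)
}

#' Evaluate one dose objective on a structure's dose vector
#'
#' @param kind objective kind (canonical or alias, see [objective_spec()]).
#' @param doses per-voxel doses (Gy) restricted to the structure.
#' @param dose_gy reference dose in Gy.
#' @param volume volume fraction for DVH kinds.
#' @return Scalar objective value (>= 0 for all kinds on nonnegative doses).
#' @examples
#' objective_value("sq_deviation", c(59, 60, 61), dose_gy = 60) # 2/3
#' @export
objective_value <- function(kind, doses, dose_gy = NULL, volume = NULL) {
  kind <- normalize_objective_kind(kind)
  if (!length(doses)) stop("empty structure: objective undefined")
  switch(kind,
    sq_deviation = mean((doses - dose_gy)^2),
    sq_overdose = mean(pmax(doses - dose_gy, 0)^2),
    sq_underdose = mean(pmin(doses - dose_gy, 0)^2),
    mean_dose = mean(doses),
    max_dvh = ,
    min_dvh = dvh_objective(kind, doses, dose_gy, volume)$value
  )
}

#' Analytic gradient of one dose objective
#'
#' Returns \eqn{\partial f / \partial d_i} for every voxel of the structure;
#' matches central finite differences of [objective_value()]. For the DVH
#' kinds the selection quantile is treated as locally constant (subgradient
#' convention), so the gradient is nonzero only on the penalized voxel set.
#'
#' @inheritParams objective_value
#' @return Numeric vector, same length as `doses`.
#' @export
objective_gradient <- function(kind, doses, dose_gy = NULL, volume = NULL) {
  kind <- normalize_objective_kind(kind)
  if (!length(doses)) stop("empty structure: objective undefined")
  ns <- length(doses)
  switch(kind,
    sq_deviation = 2 * (doses - dose_gy) / ns,
    sq_overdose = 2 * pmax(doses - dose_gy, 0) / ns,
    sq_underdose = 2 * pmin(doses - dose_gy, 0) / ns,
    mean_dose = rep(1 / ns, ns),
    max_dvh = ,
    min_dvh = dvh_objective(kind, doses, dose_gy, volume)$gradient
  )
}

#' Dose at the hottest V-fraction (inverse DVH quantile)
#'
#' Nearest-rank convention on the descending sort: the returned dose is the
#' `max(1, round(V * |S|))`-th largest entry, i.e. the dose received by
#' (at least) the hottest `V`-fraction of the structure.
#'
#' @param doses per-voxel doses (Gy), nonempty.
#' @param volume fraction in (0, 1).
#' @return A dose in Gy (always one of the input values).
#' @examples
#' inverse_dvh_quantile(c(10, 20, 30, 40), 0.25) # 40
#' @export
inverse_dvh_quantile <- function(doses, volume) {
  if (!length(doses)) stop("empty dose vector")
  if (volume <= 0 || volume >= 1) stop("volume fraction must be in (0, 1)")
  sorted <- sort(doses, decreasing = TRUE)
  sorted[max(1L, round(volume * length(doses)))]
}

#' DVH objective value and gradient
#'
#' Penalizes the voxels between the reference dose and the `volume`-quantile
#' dose \eqn{d_V} = [inverse_dvh_quantile()]: `max_dvh` penalizes
#' \eqn{(d_i - \hat d)^2 / |S|} over voxels with \eqn{\hat d < d_i \le d_V}
#' (hot voxels that should be pushed below \eqn{\hat d}, sparing the allowed
#' hottest fraction), `min_dvh` over voxels with \eqn{d_V \le d_i < \hat d}.
#' \eqn{d_V} is held constant during differentiation.
#'
#' @param kind `"max_dvh"` or `"min_dvh"`.
#' @inheritParams objective_value
#' @return List with `value`, `gradient` (length `|S|`) and the quantile
#'   dose `d_v`.
#' @export
dvh_objective <- function(kind, doses, dose_gy, volume) {
  kind <- normalize_objective_kind(kind)
  if (!kind %in% c("max_dvh", "min_dvh")) stop("kind must be a DVH objective")
  if (!length(doses)) stop("empty structure: objective undefined")
  d_v <- inverse_dvh_quantile(doses, volume)
  sel <- if (kind == "max_dvh") doses > dose_gy & doses <= d_v
         else doses >= d_v & doses < dose_gy
  ns <- length(doses)
  grad <- numeric(ns)
  grad[sel] <- 2 * (doses[sel] - dose_gy) / ns
  list(value = sum((doses[sel] - dose_gy)^2) / ns, gradient = grad, d_v = d_v)
}

#' Weighted-sum composite objective
#'
#' Chains a list of per-VOI objective terms to beamlet-intensity space
#' through the dose influence matrix: \eqn{f(x) = \sum_p w_p f_p(d(x)|S_p)}
#' with \eqn{d = Ax}.
#'
#' @param specs list of [objective_spec()]s.
#' @param structures a [structure_set()]; every referenced structure must
#'   exist and be nonempty.
#' @param matrix a [dose_influence()].
#' @return An object of class `composite_objective`.
#' @export
composite_objective <- function(specs, structures, matrix) {
  stopifnot(inherits(structures, "structure_set"),
            inherits(matrix, "dose_influence"))
  if (inherits(specs, "objective_spec")) specs <- list(specs)
  for (sp in specs) {
    stopifnot(inherits(sp, "objective_spec"))
    v <- structure_voxels(structures, sp$structure) # errors if absent
    if (!length(v))
      stop(sprintf("objective on empty structure '%s'", sp$structure))
  }
  structure(list(specs = specs, structures = structures, matrix = matrix),
            class = "composite_objective")
}

#' @export
print.composite_objective <- function(x, ...) {
  cat(sprintf("<composite_objective> %d terms on %d x %d system\n",
              length(x$specs), x$matrix$n, x$matrix$m))
  for (sp in x$specs)
    cat(sprintf("  w=%-7g %s(%s%s) on %s\n", sp$weight, sp$kind,
                if (!is.null(sp$dose_gy)) sprintf("%g Gy", sp$dose_gy) else "",
                if (!is.null(sp$volume)) sprintf(", %g%%", 100 * sp$volume) else "",
                sp$structure))
  invisible(x)
}

#' Composite objective value and intensity-space gradient
#'
#' Computes \eqn{f(x)} and \eqn{\nabla_x f = A^T \sum_p w_p \nabla_d f_p}
#' with a single dose computation `d = A x` per call. `x` need not be
#' nonnegative (perturbation candidates may be anywhere in \eqn{R^m}).
#'
#' @param objective a [composite_objective()].
#' @param x beamlet intensity vector of length `m`.
#' @return List with scalar `f` and length-`m` numeric `gradient`.
#' @export
composite_value_and_gradient <- function(objective, x) {
  stopifnot(inherits(objective, "composite_objective"))
  A <- objective$matrix$A
  if (length(x) != ncol(A))
    stop(sprintf("x has length %d but the matrix has %d beamlets",
                 length(x), ncol(A)))
  d <- as.numeric(A %*% x)
  f <- 0
  gvox <- numeric(length(d))
  for (sp in objective$specs) {
    if (sp$weight == 0) next
    S <- structure_voxels(objective$structures, sp$structure)
    dS <- d[S]
    f <- f + sp$weight * objective_value(sp$kind, dS, sp$dose_gy, sp$volume)
    gvox[S] <- gvox[S] +
      sp$weight * objective_gradient(sp$kind, dS, sp$dose_gy, sp$volume)
  }
  g <- if (any(gvox != 0)) as.numeric(Matrix::crossprod(A, gvox)) else numeric(ncol(A))
  list(f = f, gradient = g)
}

# value-only evaluation (skips the adjoint product); used by the
# perturbation phase where proposals only need f
composite_value <- function(objective, x) {
  d <- as.numeric(objective$matrix$A %*% x)
  f <- 0
  for (sp in objective$specs) {
    if (sp$weight == 0) next
    S <- structure_voxels(objective$structures, sp$structure)
    f <- f + sp$weight * objective_value(sp$kind, d[S], sp$dose_gy, sp$volume)
  }
  f
}
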