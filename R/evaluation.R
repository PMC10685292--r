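#' Compute the voxel dose vector
#'
#' The sparse product `d = A x`.
#'
#' @param matrix a [dose_influence()] (or a plain matrix).
#' @param x intensity vector of length `m`.
#' @return Numeric dose vector of length `n` (Gy).
#' @export
compute_dose <- function(matrix, x) {
  A <- if (inherits(matrix, "dose_influence")) matrix$A else matrix
  if (length(x) != ncol(A))
    stop(sprintf("x has length %d but the matrix has %d columns",
                 length(x), ncol(A)))
  as.numeric(A %*% x)
}

#' Cumulative dose-volume histogram
#'
#' For each dose level `t` of the grid, the fraction of the structure's
#' voxels receiving at least `t` Gy (the `>=` convention at bin edges).
#' The curve is non-increasing and equals 1 at dose 0 for nonnegative
#' doses.
#'
#' @param d full dose vector (Gy).
#' @param voxels the structure's voxel indices (nonempty).
#' @param dose_grid ascending dose levels; default 200 levels from 0 to
#'   `1.1 * max(d)`.
#' @return A data frame of class `dvh_curve` with columns `dose_gy` and
#'   `volume_fraction`.
#' @examples
#' compute_dvh(c(0, 50, 100), 1:3, dose_grid = c(0, 50))
#' @export
compute_dvh <- function(d, voxels, dose_grid = NULL) {
  if (!length(voxels)) stop("empty structure: DVH undefined")
  dS <- d[voxels]
  if (is.null(dose_grid))
    dose_grid <- seq(0, 1.1 * max(d, 0), length.out = 200)
  if (is.unsorted(dose_grid)) stop("dose grid must be ascending")
  vf <- vapply(dose_grid, function(t) mean(dS >= t), numeric(1))
  structure(data.frame(dose_gy = dose_grid, volume_fraction = vf),
            class = c("dvh_curve", "data.frame"))
}

#' Dose statistics for one structure
#'
#' Mean/min/max dose plus `D_x` (dose to the hottest `x`-fraction, via
#' [inverse_dvh_quantile()]) and `V_t` (fraction receiving at least `t` Gy,
#' via the DVH counting rule).
#'
#' @param d full dose vector (Gy).
#' @param voxels the structure's voxel indices (nonempty).
#' @param d_fractions volume fractions for the `D_x` report.
#' @param v_levels_gy dose levels for the `V_t` report.
#' @return A list of class `dose_stats` with `mean`, `min`, `max`,
#'   `d_at` (named by fraction) and `v_at` (named by Gy).
#' @export
dose_statistics <- function(d, voxels, d_fractions = c(0.02, 0.5, 0.95),
                            v_levels_gy = numeric(0)) {
  if (!length(voxels)) stop("empty structure: statistics undefined")
  dS <- d[voxels]
  d_at <- vapply(d_fractions, function(v) inverse_dvh_quantile(dS, v), numeric(1))
  names(d_at) <- sprintf("D%g", 100 * d_fractions)
  v_at <- vapply(v_levels_gy, function(t) mean(dS >= t), numeric(1))
  names(v_at) <- sprintf("V%gGy", v_levels_gy)
  structure(list(mean = mean(dS), min = min(dS), max = max(dS),
                 d_at = d_at, v_at = v_at),
            class = "dose_stats")
}

#' @export
print.dose_stats <- function(x, ...) {
  cat(sprintf("<dose_stats> mean %.2f / min %.2f / max %.2f Gy\n",
              x$mean, x$min, x$max))
  if (length(x$d_at))
    cat("  ", paste(sprintf("%s=%.2f", names(x$d_at), x$d_at), collapse = "  "), "\n")
  if (length(x$v_at))
    cat("  ", paste(sprintf("%s=%.1f%%", names(x$v_at), 100 * x$v_at), collapse = "  "), "\n")
  invisible(x)
}

#' Side-by-side comparison of plan results
#'
#' Aggregates several [feasibility_solve()] / [superiorize()] results on the
#' *same* problem into a per-run summary (final objective, proximity, max
#' violation, status), a per-run-per-structure dose-statistics table, and
#' the long-format trajectory series for plotting. Pure aggregation of the
#' stored histories and final vectors.
#'
#' @param results named list of `plan_result`s (names label the runs).
#' @param structures a [structure_set()].
#' @param d_fractions passed to [dose_statistics()].
#' @return A list of class `run_comparison` with data frames `summary`,
#'   `per_structure` and `trajectories`.
#' @export
compare_runs <- function(results, structures, d_fractions = c(0.02, 0.5, 0.95)) {
  stopifnot(length(results) >= 1, inherits(structures, "structure_set"))
  if (is.null(names(results)) || any(names(results) == ""))
    names(results) <- sprintf("run%d", seq_along(results))
  m <- length(results[[1]]$x_final)
  n <- length(results[[1]]$d_final)
  for (r in results) {
    stopifnot(inherits(r, "plan_result"))
    if (length(r$x_final) != m || length(r$d_final) != n)
      stop("results refer to different problems (dimension mismatch)")
  }
  if (structures$n != n)
    stop("structure set does not match the results' voxel count")

  summary <- do.call(rbind, lapply(names(results), function(nm) {
    h <- results[[nm]]$history
    last <- h[nrow(h), ]
    data.frame(run = nm, iterations = last$sweep, f = last$f, V = last$V,
               max_violation = last$max_violation,
               status = results[[nm]]$status)
  }))

  per_structure <- do.call(rbind, lapply(names(results), function(nm) {
    d <- results[[nm]]$d_final
    do.call(rbind, lapply(structures$structures, function(s) {
      if (!length(s$voxels)) return(NULL)
      st <- dose_statistics(d, s$voxels, d_fractions)
      cbind(data.frame(run = nm, structure = s$name, mean = st$mean,
                       min = st$min, max = st$max),
            as.data.frame(as.list(st$d_at)))
    }))
  }))

  trajectories <- do.call(rbind, lapply(names(results), function(nm) {
    h <- results[[nm]]$history
    cbind(data.frame(run = nm), h)
  }))

  structure(list(summary = summary, per_structure = per_structure,
                 trajectories = trajectories),
            class = "run_comparison")
}

#' @export
print.run_comparison <- function(x, ...) {
  cat("<run_comparison>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
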