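#' Voxelized planning grid
#'
#' Defines the regular voxel grid the patient (or phantom) is discretized
#' on. Voxels are addressed by a linear index running x-fastest, then y,
#' then z; all in-memory indices are 1-based (files written by
#' [write_problem()] use 0-based indices, see its documentation).
#'
#' @param shape integer triple `(nx, ny, nz)`, each >= 1.
#' @param spacing voxel spacing in mm per axis; a scalar is recycled.
#' @return An object of class `voxel_grid` with fields `shape`, `spacing`
#'   and the total voxel count `n`.
#' @examples
#' g <- voxel_grid(c(4, 4, 1), spacing = 3)
#' g$n
#' @export
voxel_grid <- function(shape, spacing = 3) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("`shape` must be three integers >= 1")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be positive (mm)")
  structure(
    list(shape = shape, spacing = spacing, n = prod(shape)),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, %g x %g x %g mm (n = %d)\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3], x$n))
  invisible(x)
}

# (ix, iy, iz) -> linear index, x-fastest. All arguments 1-based.
voxel_index <- function(grid, ix, iy, iz = 1L) {
  ix + (iy - 1L) * grid$shape[1] + (iz - 1L) * grid$shape[1] * grid$shape[2]
}

# linear index -> matrix with columns ix, iy, iz (1-based)
voxel_subscripts <- function(grid, idx) {
  nx <- grid$shape[1]; ny <- grid$shape[2]
  idx0 <- idx - 1L
  ix <- idx0 %% nx
  iy <- (idx0 %/% nx) %% ny
  iz <- idx0 %/% (nx * ny)
  cbind(ix = ix + 1L, iy = iy + 1L, iz = iz + 1L)
}

# physical voxel-center coordinates (mm), origin at the grid center
voxel_centers_mm <- function(grid) {
  sub <- voxel_subscripts(grid, seq_len(grid$n))
  cbind(
    x = (sub[, "ix"] - (grid$shape[1] + 1) / 2) * grid$spacing[1],
    y = (sub[, "iy"] - (grid$shape[2] + 1) / 2) * grid$spacing[2],
    z = (sub[, "iz"] - (grid$shape[3] + 1) / 2) * grid$spacing[3]
  )
}

#' Set of segmented structures (volumes of interest)
#'
#' An ordered collection of named voxel-index sets with unique priority
#' ranks (1 = highest). Structures may overlap as stored;
#' [resolve_structures()] produces the exclusive partition used when
#' assigning per-voxel dose bounds.
#'
#' @param structures a list of lists with fields `name`, `voxels`
#'   (1-based linear indices) and `priority` (unique positive integers).
#' @param n total number of voxels the indices refer to.
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(structures, n) {
  stopifnot(is.list(structures), length(n) == 1L, n >= 0)
  names_ <- vapply(structures, function(s) s$name, character(1))
  if (anyDuplicated(names_)) stop("structure names must be unique")
  prio <- vapply(structures, function(s) as.integer(s$priority), integer(1))
  if (anyDuplicated(prio)) stop("priority ranks must be unique")
  for (s in structures) {
    v <- s$voxels
    if (length(v) && (min(v) < 1L || max(v) > n))
      stop(sprintf("structure '%s' has voxel indices outside [1, %d]", s$name, n))
  }
  structures <- structures[order(prio)]
  structure(list(structures = structures, n = n), class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> %d structures over %d voxels\n",
              length(x$structures), x$n))
  for (s in x$structures)
    cat(sprintf("  [%d] %-10s %d voxels\n", s$priority, s$name, length(s$voxels)))
  invisible(x)
}

#' @rdname structure_set
#' @param ss a `structure_set`.
#' @param name structure name to look up.
#' @export
structure_voxels <- function(ss, name) {
  for (s in ss$structures) if (identical(s$name, name)) return(s$voxels)
  stop(sprintf("no structure named '%s'", name))
}

structure_names <- function(ss) vapply(ss$structures, `[[`, character(1), "name")

#' Resolve overlapping structures into an exclusive partition
#'
#' Each voxel is assigned to its highest-priority containing structure
#' (rank 1 wins). The returned set has pairwise disjoint voxel sets; names
#' and priorities are preserved.
#'
#' @param ss a [structure_set()].
#' @return A `structure_set` with disjoint voxel sets.
#' @export
resolve_structures <- function(ss) {
  taken <- logical(ss$n)
  out <- lapply(ss$structures, function(s) {
    keep <- s$voxels[!taken[s$voxels]]
    taken[keep] <<- TRUE
    list(name = s$name, voxels = keep, priority = s$priority)
  })
  structure_set(out, ss$n)
}

#' Build the TG119-like horseshoe phantom
#'
#' Generates the classic planning benchmark geometry on a 2D slab (or
#' extruded 3D) grid: a C-shaped target annulus wrapping a central circular
#' core (the organ at risk), both inside an elliptical body contour. The
#' C opening faces the +x direction. Target and Core are disjoint by
#' construction; Body contains both (overlaps are resolved downstream by
#' priority).
#'
#' @param grid a [voxel_grid()].
#' @param core_radius_mm radius of the central core disc.
#' @param target_inner_mm,target_outer_mm inner/outer radii of the C-shaped
#'   target annulus; `core_radius_mm < target_inner_mm` is required.
#' @param target_gap_deg angular width (degrees) of the C opening.
#' @param body_radii_mm semi-axes of the elliptical body contour (a scalar
#'   gives a circle).
#' @return A [structure_set()] with structures `Target` (priority 1),
#'   `Core` (2), `Body` (3).
#' @examples
#' ss <- build_phantom(voxel_grid(c(64, 64, 1)))
#' lengths <- vapply(ss$structures, function(s) length(s$voxels), integer(1))
#' @export
build_phantom <- function(grid,
                          core_radius_mm = 10,
                          target_inner_mm = 15,
                          target_outer_mm = 37,
                          target_gap_deg = 90,
                          body_radii_mm = c(80, 80)) {
  stopifnot(inherits(grid, "voxel_grid"))
  body_radii_mm <- rep_len(as.numeric(body_radii_mm), 2L)
  if (any(c(core_radius_mm, target_inner_mm, target_outer_mm,
            target_gap_deg, body_radii_mm) < 0))
    stop("geometry parameters must be nonnegative")
  if (core_radius_mm >= target_inner_mm && core_radius_mm > 0)
    stop("core radius must be smaller than the target inner radius")
  half_extent <- (grid$shape[1:2] * grid$spacing[1:2]) / 2
  if (max(body_radii_mm[1], target_outer_mm) > half_extent[1] ||
      max(body_radii_mm[2], target_outer_mm) > half_extent[2])
    stop("geometry exceeds the grid extent")

  xy <- voxel_centers_mm(grid)[, c("x", "y"), drop = FALSE]
  r <- sqrt(xy[, 1]^2 + xy[, 2]^2)
  ang <- atan2(xy[, 2], xy[, 1]) * 180 / pi # (-180, 180], opening at 0

  in_gap <- abs(ang) <= target_gap_deg / 2
  target <- which(r >= target_inner_mm & r <= target_outer_mm & !in_gap)
  core <- which(r <= core_radius_mm)
  if (core_radius_mm == 0) core <- integer(0)
  if (target_outer_mm == 0 || target_inner_mm > target_outer_mm)
    target <- integer(0)
  body <- if (all(body_radii_mm > 0)) {
    which((xy[, 1] / body_radii_mm[1])^2 + (xy[, 2] / body_radii_mm[2])^2 <= 1)
  } else {
    which(xy[, 1] == 0 & xy[, 2] == 0)
  }

  structure_set(list(
    list(name = "Target", voxels = target, priority = 1L),
    list(name = "Core", voxels = core, priority = 2L),
    list(name = "Body", voxels = body, priority = 3L)
  ), grid$n)
}

#' Beam arrangement for the synthetic dose engine
#'
#' Describes an equidistant coplanar photon-like beam arrangement and the
#' parameters of the depth-attenuation / lateral-Gaussian dose deposition
#' model used by [generate_dose_influence()].
#'
#' @param gantry_angles_deg beam angles in `[0, 360)` degrees; default five
#'   equidistant fields.
#' @param beamlet_width_mm lateral spacing between adjacent beamlet rays.
#' @param mu_per_mm linear attenuation coefficient (per mm) applied to the
#'   depth below the body surface; the default is in the range of
#'   megavoltage photons in water.
#' @param sigma_mm lateral Gaussian spread of a beamlet (mm).
#' @param scale_gy_per_unit dose at zero depth on the beamlet axis for unit
#'   intensity (Gy).
#' @return An object of class `beam_config`.
#' @export
beam_config <- function(gantry_angles_deg = c(0, 72, 144, 216, 288),
                        beamlet_width_mm = 5,
                        mu_per_mm = 0.005,
                        sigma_mm = 3,
                        scale_gy_per_unit = 1) {
  ang <- as.numeric(gantry_angles_deg)
  if (!length(ang) || any(ang < 0 | ang >= 360))
    stop("gantry angles must lie in [0, 360)")
  if (beamlet_width_mm <= 0 || sigma_mm <= 0 || scale_gy_per_unit <= 0)
    stop("beamlet width, sigma and dose scale must be positive")
  if (mu_per_mm < 0) stop("mu must be nonnegative (0 = attenuation-free)")
  structure(list(
    gantry_angles_deg = ang,
    beamlet_width_mm = beamlet_width_mm,
    mu_per_mm = mu_per_mm,
    sigma_mm = sigma_mm,
    scale_gy_per_unit = scale_gy_per_unit
  ), class = "beam_config")
}

#' Sparse dose influence matrix container
#'
#' Wraps the nonnegative sparse n-by-m matrix mapping beamlet intensities to
#' voxel doses, caching the squared Euclidean row norms the projection steps
#' divide by and flagging all-zero rows (voxels no beamlet reaches).
#'
#' @param A a nonnegative sparse (or dense) numeric matrix, n voxels by m
#'   beamlets, in Gy per unit intensity.
#' @return An object of class `dose_influence` with fields `A` (a
#'   `dgCMatrix`), `row_sq_norms`, `n`, `m` and `zero_rows`.
#' @export
dose_influence <- function(A) {
  A <- as(as(as(A, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (any(A@x < 0)) stop("dose influence entries must be nonnegative")
  rsq <- Matrix::rowSums(A^2)
  structure(list(
    A = A,
    row_sq_norms = as.numeric(rsq),
    n = nrow(A),
    m = ncol(A),
    zero_rows = which(rsq == 0)
  ), class = "dose_influence")
}

#' @export
print.dose_influence <- function(x, ...) {
  cat(sprintf("<dose_influence> %d voxels x %d beamlets, %d nonzeros (%d zero rows)\n",
              x$n, x$m, length(x$A@x), length(x$zero_rows)))
  invisible(x)
}

# CSR view used by the sweep kernel; cached computation, 0-based indices.
as_csr <- function(di) {
  R <- as(di$A, "RsparseMatrix")
  list(p = R@p, j = R@j, x = R@x)
}

#' Generate a beamlet dose influence matrix
#'
#' A deterministic, physically plausible stand-in for a pencil-beam dose
#' engine: each beamlet deposits dose along its ray proportional to
#' `exp(-mu * depth) * exp(-lateral^2 / (2 sigma^2))`, where depth is
#' measured from the beamlet ray's entry into the Body contour. Dose is only
#' deposited inside Body; entries below `cutoff_rel` times the beamlet's
#' maximum are dropped to control sparsity. Beamlets are laid out per field
#' across the body's lateral extent at `beamlet_width_mm` spacing; beamlets
#' whose ray misses the body are discarded.
#'
#' The model is 2D in the axial plane and applied identically to every z
#' slice (cylindrical symmetry along the gantry rotation axis).
#'
#' @param grid a [voxel_grid()].
#' @param structures a [structure_set()] containing a structure named
#'   `"Body"` (dose is deposited in its voxels).
#' @param beams a [beam_config()].
#' @param cutoff_rel relative sparsity cutoff per beamlet.
#' @return A [dose_influence()] object.
#' @export
generate_dose_influence <- function(grid, structures, beams,
                                    cutoff_rel = 1e-4) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(structures, "structure_set"),
            inherits(beams, "beam_config"))
  body <- structure_voxels(structures, "Body")
  if (!length(body)) stop("Body structure is empty; no beamlets can be formed")
  xy <- voxel_centers_mm(grid)[, c("x", "y"), drop = FALSE]
  sub <- voxel_subscripts(grid, seq_len(grid$n))
  # in-plane (ix, iy) pattern is shared by all z slices
  body_plane <- body[sub[body, "iz"] == 1L]
  if (!length(body_plane)) body_plane <- body
  bx <- xy[body_plane, 1]; by <- xy[body_plane, 2]
  nz <- grid$shape[3]
  plane_size <- grid$shape[1] * grid$shape[2]

  trip_i <- list(); trip_j <- list(); trip_x <- list()
  jcol <- 0L
  for (theta in beams$gantry_angles_deg) {
    th <- theta * pi / 180
    dirv <- c(-sin(th), -cos(th))     # beam travel direction (source at angle theta)
    latv <- c(cos(th), -sin(th))      # lateral unit vector
    t_long <- bx * dirv[1] + by * dirv[2]
    l_all <- bx * latv[1] + by * latv[2]
    lat_range <- range(l_all)
    ctr <- mean(lat_range)
    k <- floor((lat_range[2] - ctr) / beams$beamlet_width_mm)
    offsets <- ctr + (-k:k) * beams$beamlet_width_mm
    for (o in offsets) {
      lat <- l_all - o
      reach <- abs(lat) <= beams$beamlet_width_mm / 2 + 3 * beams$sigma_mm
      if (!any(reach)) next
      t_entry <- min(t_long[abs(lat) <= beams$beamlet_width_mm / 2 + 1e-9],
                     t_long[reach])
      depth <- pmax(t_long - t_entry, 0)
      dose <- beams$scale_gy_per_unit *
        exp(-beams$mu_per_mm * depth) *
        exp(-lat^2 / (2 * beams$sigma_mm^2))
      keep <- dose >= cutoff_rel * max(dose)
      if (!any(keep)) next
      jcol <- jcol + 1L
      rows <- body_plane[keep]
      vals <- dose[keep]
      if (nz > 1L) {
        rows <- rep(rows, nz) + rep((seq_len(nz) - 1L) * plane_size, each = length(rows))
        vals <- rep(vals, nz)
      }
      trip_i[[jcol]] <- rows
      trip_j[[jcol]] <- rep.int(jcol, length(rows))
      trip_x[[jcol]] <- vals
    }
  }
  if (jcol == 0L) stop("beam configuration produced zero beamlets")
  A <- Matrix::sparseMatrix(
    i = unlist(trip_i), j = unlist(trip_j), x = unlist(trip_x),
    dims = c(grid$n, jcol)
  )
  dose_influence(A)
}
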