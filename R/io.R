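#' Write a sparse matrix in MatrixMarket coordinate format
#'
#' Writes 1-based coordinate triplets with 17 significant digits so that
#' [read_matrix_market()] reproduces every entry bit-for-bit.
#'
#' @param A a sparse (or dense) numeric matrix.
#' @param path output file path (conventionally `.mtx`).
#' @return `path`, invisibly.
#' @export
write_matrix_market <- function(A, path) {
  A <- as(as(as(A, "dMatrix"), "generalMatrix"), "TsparseMatrix")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "%%MatrixMarket matrix coordinate real general",
    "% written by amsplan; 1-based indices, full double precision",
    sprintf("%d %d %d", nrow(A), ncol(A), length(A@x))
  ), con)
  if (length(A@x))
    writeLines(sprintf("%d %d %.17g", A@i + 1L, A@j + 1L, A@x), con)
  invisible(path)
}

#' Read a MatrixMarket coordinate file
#'
#' Thin validating wrapper around [Matrix::readMM()]: checks the banner,
#' rejects indices outside the declared dimensions, and raises explicit
#' parse errors instead of cryptic ones.
#'
#' @param path file to read.
#' @return A `dgCMatrix`.
#' @export
read_matrix_market <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  first <- readLines(path, n = 1L)
  if (!length(first) || !startsWith(first, "%%MatrixMarket"))
    stop(sprintf("malformed MatrixMarket header in %s: %s", path,
                 if (length(first)) first else "<empty file>"))
  M <- tryCatch(Matrix::readMM(path), error = function(e)
    stop(sprintf("failed to parse %s: %s", path, conditionMessage(e)), call. = FALSE))
  as(as(as(M, "dMatrix"), "generalMatrix"), "CsparseMatrix")
}

#' Planning problem container
#'
#' Bundles everything a solver needs: the dose influence matrix, the
#' structures, optional per-voxel constraint system and free-form metadata
#' (grid, beams, seed). Built by [phantom_problem()], [make_toy_problem()]
#' conversion or [read_problem()].
#'
#' @param matrix a [dose_influence()].
#' @param structures a [structure_set()] or `NULL`.
#' @param constraints a [constraint_system()] or `NULL`.
#' @param grid a [voxel_grid()] or `NULL`.
#' @param meta named list of metadata serialized to JSON on write.
#' @return An object of class `plan_problem`.
#' @export
plan_problem <- function(matrix, structures = NULL, constraints = NULL,
                         grid = NULL, meta = list()) {
  stopifnot(inherits(matrix, "dose_influence"))
  if (!is.null(structures)) stopifnot(inherits(structures, "structure_set"))
  if (!is.null(constraints)) {
    stopifnot(inherits(constraints, "constraint_system"))
    if (length(constraints$lower) != matrix$n)
      stop("constraint system size does not match the matrix row count")
  }
  structure(list(matrix = matrix, structures = structures,
                 constraints = constraints, grid = grid, meta = meta),
            class = "plan_problem")
}

#' Write / read a planning problem directory
#'
#' On-disk layout (all plain text): `matrix.mtx` (MatrixMarket coordinate,
#' 1-based), `structures.csv` with header `voxel_index,structure`
#' (0-based linear voxel indices, x-fastest), `bounds.csv` with header
#' `voxel_index,lower,upper,weight` (0-based; `Inf` for absent upper
#' bounds), and `meta.json` (grid shape/spacing, seed, beam parameters,
#' witness, ...). `read_problem(write_problem(P, dir))` reproduces every
#' matrix entry, index and bound exactly.
#'
#' @param problem a [plan_problem()].
#' @param dir directory to create/fill.
#' @return `write_problem` returns `dir` invisibly; `read_problem` returns
#'   a `plan_problem`.
#' @export
write_problem <- function(problem, dir) {
  stopifnot(inherits(problem, "plan_problem"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_market(problem$matrix$A, file.path(dir, "matrix.mtx"))
  if (!is.null(problem$structures)) {
    rows <- do.call(rbind, lapply(problem$structures$structures, function(s)
      if (length(s$voxels))
        data.frame(voxel_index = s$voxels - 1L, structure = s$name)
      else NULL))
    if (is.null(rows))
      rows <- data.frame(voxel_index = integer(0), structure = character(0))
    write.csv(rows, file.path(dir, "structures.csv"), row.names = FALSE)
  }
  if (!is.null(problem$constraints)) {
    cs <- problem$constraints
    write.csv(data.frame(voxel_index = seq_along(cs$lower) - 1L,
                         lower = format_dbl(cs$lower),
                         upper = format_dbl(cs$upper),
                         weight = format_dbl(cs$nu)),
              file.path(dir, "bounds.csv"), row.names = FALSE, quote = FALSE)
  }
  meta <- problem$meta
  if (!is.null(problem$grid))
    meta$grid <- list(shape = problem$grid$shape, spacing = problem$grid$spacing)
  if (!is.null(problem$structures))
    meta$structure_priorities <- lapply(problem$structures$structures,
                                        function(s) list(name = s$name, priority = s$priority))
  meta$n <- problem$matrix$n
  meta$m <- problem$matrix$m
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(dir)
}

#' @rdname write_problem
#' @export
read_problem <- function(dir) {
  if (!dir.exists(dir)) stop(sprintf("no such directory: %s", dir))
  A <- read_matrix_market(file.path(dir, "matrix.mtx"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  di <- dose_influence(A)
  grid <- NULL
  if (!is.null(meta$grid))
    grid <- voxel_grid(meta$grid$shape, meta$grid$spacing)
  structures <- NULL
  spath <- file.path(dir, "structures.csv")
  if (file.exists(spath)) {
    sdf <- read.csv(spath, stringsAsFactors = FALSE)
    if (nrow(sdf) && (min(sdf$voxel_index) < 0 || max(sdf$voxel_index) >= di$n))
      stop("structures.csv has voxel indices outside [0, n)")
    prio <- meta$structure_priorities
    ordered_names <- if (!is.null(prio)) {
      if (is.data.frame(prio)) prio$name[order(prio$priority)]
      else vapply(prio, `[[`, character(1), "name")
    } else unique(sdf$structure)
    structures <- structure_set(lapply(seq_along(ordered_names), function(k) {
      nm <- ordered_names[k]
      list(name = nm, voxels = sdf$voxel_index[sdf$structure == nm] + 1L,
           priority = k)
    }), di$n)
  }
  constraints <- NULL
  bpath <- file.path(dir, "bounds.csv")
  if (file.exists(bpath)) {
    bdf <- read.csv(bpath, stringsAsFactors = FALSE)
    bdf <- bdf[order(bdf$voxel_index), ]
    if (nrow(bdf) != di$n)
      stop("bounds.csv must carry one row per voxel")
    constraints <- constraint_system(lower = bdf$lower, upper = bdf$upper,
                                     nu = bdf$weight)
  }
  keep <- setdiff(names(meta), c("grid", "structure_priorities", "n", "m"))
  plan_problem(di, structures = structures, constraints = constraints,
               grid = grid, meta = meta[keep])
}

# full-precision decimal rendering (17 significant digits round-trips
# any double exactly through read.csv)
format_dbl <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.infinite(x)] <- ifelse(x[is.infinite(x)] > 0, "Inf", "-Inf")
  out
}

# history <-> CSV (columns: sweep, f, V, max_violation, elapsed_s)
write_history <- function(history, path) {
  cols <- intersect(c("sweep", "f", "V", "max_violation", "elapsed_s"),
                    names(history))
  write.csv(history[, cols], path, row.names = FALSE)
  invisible(path)
}

read_history <- function(path) read.csv(path, stringsAsFactors = FALSE)
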