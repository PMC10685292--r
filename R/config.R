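#' Parse and validate a run configuration file
#'
#' Reads a YAML or JSON plan configuration, validates it against the
#' schema below, fills documented defaults, and returns the resolved
#' configuration. Unknown keys anywhere in the schema are rejected so
#' typos fail loudly rather than silently falling back to defaults.
#'
#' Schema (top level): \describe{
#'   \item{`problem`}{either `generate: {kind: phantom|toy, ...params}` or
#'     `load: <directory written by write_problem()>`.}
#'   \item{`prescription`}{list of rows `{structure, lower, upper, weight}`
#'     — the shape of a clinical tolerance table. `upper` may be omitted
#'     (no upper bound).}
#'   \item{`objectives`}{optional list of
#'     `{name, structure, weight, dose_gy, volume}` where `name` is one of
#'     `f_sqdev`, `f_sqdev+`, `f_sqdev-`, `f_mean`, `f_maxDVH`, `f_minDVH`
#'     (or a canonical kind). Each referenced structure must appear in the
#'     prescription or the problem's structure set.}
#'   \item{`solver`}{`mode: feasibility|superiorize` plus any
#'     [superiorization_config()] field.}
#'   \item{`output_dir`}{artifact directory (default `"."`).}
#'   \item{`seed`}{integer (default 1).}
#' }
#'
#' @param path configuration file (`.yaml`/`.yml` or `.json`).
#' @return A validated list of class `plan_spec_config` with defaults
#'   filled in.
#' @export
parse_plan_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such config file: %s", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a mapping")

  known_top <- c("problem", "prescription", "objectives", "solver",
                 "output_dir", "seed")
  unknown <- setdiff(names(cfg), known_top)
  if (length(unknown))
    stop(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")))
  for (req in c("problem", "solver"))
    if (is.null(cfg[[req]])) stop(sprintf("config is missing '%s'", req))
  # prescription may be omitted when the problem ships its own per-voxel
  # bounds (toy problems, re-loaded problem directories)

  # --- problem -------------------------------------------------------
  pb <- cfg$problem
  if (length(setdiff(names(pb), c("generate", "load"))) ||
      (is.null(pb$generate) == is.null(pb$load)))
    stop("problem must have exactly one of 'generate' or 'load'")
  if (!is.null(pb$generate)) {
    gen <- pb$generate
    kind <- gen$kind %||% stop("problem.generate needs a 'kind'")
    if (!kind %in% c("phantom", "toy"))
      stop(sprintf("unknown problem kind '%s' (phantom or toy)", kind))
    known_gen <- if (kind == "phantom")
      c("kind", "nx", "spacing_mm", "margin_gy")
    else c("kind", "n", "m", "density", "feasible", "slack")
    unknown <- setdiff(names(gen), known_gen)
    if (length(unknown))
      stop(sprintf("unknown problem.generate keys for kind '%s': %s",
                   kind, paste(unknown, collapse = ", ")))
  }

  # --- prescription --------------------------------------------------
  rx <- cfg$prescription
  rx_df <- if (!length(rx)) NULL else do.call(rbind, lapply(rx, function(row) {
    unknown <- setdiff(names(row), c("structure", "lower", "upper", "weight"))
    if (length(unknown))
      stop(sprintf("unknown prescription keys: %s", paste(unknown, collapse = ", ")))
    if (is.null(row$structure)) stop("prescription row without 'structure'")
    data.frame(structure = row$structure,
               lower = as.numeric(row$lower %||% 0),
               upper = as.numeric(row$upper %||% Inf),
               weight = as.numeric(row$weight %||% 1))
  }))
  if (!is.null(rx_df)) {
    bad <- rx_df$structure[rx_df$lower > rx_df$upper]
    if (length(bad))
      stop(sprintf("prescription has lower > upper for: %s",
                   paste(bad, collapse = ", ")))
    if (any(rx_df$weight <= 0)) stop("prescription weights must be positive")
  }

  # --- objectives ----------------------------------------------------
  obj_specs <- list()
  if (!is.null(cfg$objectives)) {
    obj_specs <- lapply(cfg$objectives, function(o) {
      unknown <- setdiff(names(o), c("name", "structure", "weight",
                                     "dose_gy", "volume"))
      if (length(unknown))
        stop(sprintf("unknown objective keys: %s", paste(unknown, collapse = ", ")))
      if (is.null(o$name) || is.null(o$structure))
        stop("each objective needs 'name' and 'structure'")
      if (!is.null(rx_df) && !o$structure %in% rx_df$structure)
        stop(sprintf("objective references VOI '%s' absent from the prescription",
                     o$structure))
      objective_spec(o$name, o$structure, weight = o$weight %||% 1,
                     dose_gy = o$dose_gy, volume = o$volume)
    })
  }

  # --- solver --------------------------------------------------------
  sv <- cfg$solver
  mode <- sv$mode %||% stop("solver needs a 'mode'")
  if (!mode %in% c("feasibility", "superiorize"))
    stop(sprintf("unknown solver mode '%s'", mode))
  sv_fields <- setdiff(names(sv), "mode")
  cfg_defaults <- formals(superiorization_config)
  unknown <- setdiff(sv_fields, names(cfg_defaults))
  if (length(unknown))
    stop(sprintf("unknown solver keys: %s", paste(unknown, collapse = ", ")))
  sup_cfg <- do.call(superiorization_config, sv[sv_fields])

  structure(list(
    problem = pb,
    prescription = rx_df,
    objectives = obj_specs,
    mode = mode,
    solver = sup_cfg,
    output_dir = cfg$output_dir %||% ".",
    seed = as.integer(cfg$seed %||% 1L)
  ), class = "plan_spec_config")
}

# materialize the problem a config refers to
config_problem <- function(cfg) {
  pb <- cfg$problem
  if (!is.null(pb$load)) return(read_problem(pb$load))
  gen <- pb$generate
  if (gen$kind == "phantom") {
    phantom_problem(nx = gen$nx %||% 64, spacing_mm = gen$spacing_mm %||% 3,
                    margin_gy = gen$margin_gy %||% 0.5)
  } else {
    tp <- make_toy_problem(n = gen$n %||% 200, m = gen$m %||% 30,
                           density = gen$density %||% 0.3,
                           feasible = gen$feasible %||% TRUE,
                           slack = gen$slack %||% 0.5, seed = cfg$seed)
    # a toy problem carries its own per-voxel bounds; expose them as a
    # single structure so prescriptions/objectives can refer to "All"
    ss <- structure_set(list(list(name = "All", voxels = seq_len(tp$matrix$n),
                                  priority = 1L)), tp$matrix$n)
    plan_problem(tp$matrix, structures = ss,
                 constraints = toy_constraints(tp),
                 meta = list(kind = "toy", witness = tp$witness,
                             feasible = tp$feasible, seed = tp$seed))
  }
}

#' Run a planning command
#'
#' Reproducible end-to-end entry points over the package's functions; the
#' same verbs are exposed by the `exec/amsplan` command-line script.
#' \describe{
#'   \item{`phantom`}{generate the packaged phantom problem and write it to
#'     `args$out` (`nx`, `spacing_mm` optional).}
#'   \item{`toy`}{generate a toy feasibility problem (`n`, `m`, `density`,
#'     `feasible`, `slack`, `seed`) and write it to `args$out`.}
#'   \item{`plan`}{run the solver described by `args$config` (a file parsed
#'     with [parse_plan_config()]); writes `x.csv`, `dose.csv`,
#'     `history.csv`, `summary.json` and the resolved `config.yaml` into
#'     the output directory.}
#'   \item{`evaluate`}{compute DVHs (`dvh.csv`) and per-structure dose
#'     statistics (`stats.csv`) for a finished `plan` directory
#'     (`args$result`).}
#'   \item{`compare`}{aggregate several `plan` directories
#'     (`args$results`, a character vector) into `comparison.csv` /
#'     `comparison.json` under `args$out`.}
#' }
#'
#' All verbs are deterministic given their arguments and seed; every `plan`
#' artifact directory contains the resolved configuration for provenance.
#'
#' @param verb one of `"phantom"`, `"toy"`, `"plan"`, `"evaluate"`,
#'   `"compare"`.
#' @param args named list of verb arguments.
#' @param verbose print structured per-iteration log lines during `plan`.
#' @return Invisibly, a named list of the artifact paths written.
#' @export
run_command <- function(verb, args = list(), verbose = FALSE) {
  switch(verb,
    phantom = {
      out <- args$out %||% stop("phantom needs 'out'")
      pp <- phantom_problem(nx = args$nx %||% 64,
                            spacing_mm = args$spacing_mm %||% 3)
      write_problem(pp, out)
      invisible(list(problem = out))
    },
    toy = {
      out <- args$out %||% stop("toy needs 'out'")
      tp <- make_toy_problem(n = args$n %||% 200, m = args$m %||% 30,
                             density = args$density %||% 0.3,
                             feasible = args$feasible %||% TRUE,
                             slack = args$slack %||% 0.5,
                             seed = args$seed %||% 1)
      ss <- structure_set(list(list(name = "All", voxels = seq_len(tp$matrix$n),
                                    priority = 1L)), tp$matrix$n)
      write_problem(plan_problem(tp$matrix, structures = ss,
                                 constraints = toy_constraints(tp),
                                 meta = list(kind = "toy", witness = tp$witness,
                                             feasible = tp$feasible,
                                             seed = tp$seed)),
                    out)
      invisible(list(problem = out))
    },
    plan = {
      cfg <- if (inherits(args$config, "plan_spec_config")) args$config
             else parse_plan_config(args$config %||% stop("plan needs 'config'"))
      run_plan(cfg, verbose = verbose)
    },
    evaluate = {
      dir <- args$result %||% stop("evaluate needs 'result'")
      evaluate_result_dir(dir)
    },
    compare = {
      dirs <- args$results %||% stop("compare needs 'results'")
      out <- args$out %||% stop("compare needs 'out'")
      compare_result_dirs(dirs, out)
    },
    stop(sprintf("unknown verb '%s'", verb))
  )
}

run_plan <- function(cfg, verbose = FALSE) {
  problem <- config_problem(cfg)
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  # the config's prescription is expanded over the problem's structures;
  # with no prescription the problem must ship its own per-voxel bounds
  # (toy problems, re-loaded directories, the witness-widened phantom)
  constraints <- if (is.null(cfg$prescription)) {
    if (is.null(problem$constraints))
      stop("config has no prescription and the problem carries no bounds")
    problem$constraints
  } else {
    missing_ <- setdiff(cfg$prescription$structure, structure_names(problem$structures))
    if (length(missing_))
      stop(sprintf("prescription references structures absent from the problem: %s",
                   paste(missing_, collapse = ", ")))
    prescription_to_constraints(problem$structures, cfg$prescription)
  }

  solver_cfg <- cfg$solver
  solver_cfg$seed <- cfg$seed
  result <- if (cfg$mode == "superiorize") {
    if (!length(cfg$objectives))
      stop("superiorize mode needs at least one objective")
    objective <- composite_objective(cfg$objectives, problem$structures,
                                     problem$matrix)
    superiorize(matrix = problem$matrix, constraints = constraints,
                objective = objective, config = solver_cfg,
                verbose = verbose)
  } else {
    feasibility_solve(matrix = problem$matrix, constraints = constraints,
                      lambda = solver_cfg$lambda,
                      control = solver_cfg$control,
                      max_sweeps = solver_cfg$max_iterations,
                      max_time_s = solver_cfg$max_time_s,
                      tol_V = solver_cfg$tol_V,
                      consecutive = solver_cfg$consecutive,
                      seed = cfg$seed, verbose = verbose)
  }

  paths <- list(
    x = file.path(out, "x.csv"),
    dose = file.path(out, "dose.csv"),
    history = file.path(out, "history.csv"),
    summary = file.path(out, "summary.json"),
    config = file.path(out, "config.yaml"),
    problem = file.path(out, "problem")
  )
  write.csv(data.frame(beamlet = seq_along(result$x_final) - 1L,
                       intensity = format_dbl(result$x_final)),
            paths$x, row.names = FALSE, quote = FALSE)
  write.csv(data.frame(voxel_index = seq_along(result$d_final) - 1L,
                       dose_gy = format_dbl(result$d_final)),
            paths$dose, row.names = FALSE, quote = FALSE)
  write_history(result$history, paths$history)
  last <- result$history[nrow(result$history), ]
  jsonlite::write_json(list(
    mode = cfg$mode, status = result$status, iterations = last$sweep,
    f = if (is.na(last$f)) NULL else last$f, V = last$V,
    max_violation = last$max_violation, seed = cfg$seed
  ), paths$summary, auto_unbox = TRUE, digits = NA, null = "null")
  yaml::write_yaml(config_to_list(cfg), paths$config)
  write_problem(problem, paths$problem)
  invisible(c(paths, list(result = result)))
}

config_to_list <- function(cfg) {
  list(
    problem = cfg$problem,
    prescription = if (is.null(cfg$prescription)) NULL
      else lapply(seq_len(nrow(cfg$prescription)), function(i)
        as.list(cfg$prescription[i, ])),
    objectives = lapply(cfg$objectives, function(o)
      Filter(Negate(is.null), list(name = o$kind, structure = o$structure,
                                   weight = o$weight, dose_gy = o$dose_gy,
                                   volume = o$volume))),
    solver = c(list(mode = cfg$mode), unclass(cfg$solver)),
    output_dir = cfg$output_dir,
    seed = cfg$seed
  )
}

evaluate_result_dir <- function(dir) {
  problem <- read_problem(file.path(dir, "problem"))
  dose <- read.csv(file.path(dir, "dose.csv"))
  d <- dose$dose_gy[order(dose$voxel_index)]
  if (is.null(problem$structures)) stop("result problem has no structures")
  dvh <- do.call(rbind, lapply(problem$structures$structures, function(s) {
    if (!length(s$voxels)) return(NULL)
    curve <- compute_dvh(d, s$voxels)
    data.frame(structure = s$name, dose_gy = curve$dose_gy,
               volume_fraction = curve$volume_fraction)
  }))
  stats <- do.call(rbind, lapply(problem$structures$structures, function(s) {
    if (!length(s$voxels)) return(NULL)
    st <- dose_statistics(d, s$voxels)
    cbind(data.frame(structure = s$name, mean = st$mean, min = st$min,
                     max = st$max), as.data.frame(as.list(st$d_at)))
  }))
  paths <- list(dvh = file.path(dir, "dvh.csv"),
                stats = file.path(dir, "stats.csv"))
  write.csv(dvh, paths$dvh, row.names = FALSE)
  write.csv(stats, paths$stats, row.names = FALSE)
  invisible(paths)
}

compare_result_dirs <- function(dirs, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  rows <- do.call(rbind, lapply(dirs, function(d) {
    s <- jsonlite::read_json(file.path(d, "summary.json"), simplifyVector = TRUE)
    data.frame(run = basename(d), mode = s$mode, status = s$status,
               iterations = s$iterations,
               f = if (is.null(s$f)) NA_real_ else s$f,
               V = s$V, max_violation = s$max_violation)
  }))
  paths <- list(csv = file.path(out, "comparison.csv"),
                json = file.path(out, "comparison.json"))
  write.csv(rows, paths$csv, row.names = FALSE)
  jsonlite::write_json(rows, paths$json, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
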