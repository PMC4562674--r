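## Configuration loading, result serialization and fixture scenarios.

.config_keys <- c("grid", "damage", "duration_days", "params_file", "params",
                  "lambda_E0", "drug", "method", "dt", "output",
                  "inflammation", "chemotaxis_scheme")
.drug_keys <- c("drug", "B1", "B2", "B3", "A", "B", "start_day", "ramp_days")

config_drug <- function(block) {
  if (is.null(block) || length(block) == 0) return(NULL)
  if (!is.null(block$combination)) {
    regs <- lapply(block$combination, config_drug)
    return(combine_regimens(regs))
  }
  unknown <- setdiff(names(block), .drug_keys)
  if (length(unknown))
    stop("unknown drug config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(block$drug)) stop("drug block needs a 'drug' entry")
  args <- block[setdiff(names(block), "drug")]
  do.call(drug_regimen, c(list(drug = block$drug), args))
}

#' Load a scenario configuration file
#'
#' Reads a YAML scenario description and returns a validated [scenario()].
#' Unknown keys (anywhere in the file) are rejected, naming the offender.
#'
#' Recognised top-level keys: `grid` (`{K1, K2, K3}` or a single integer),
#' `damage` (`{center, edges}`, or empty/absent for a control run),
#' `duration_days`, `params_file` (flat parameter YAML overriding the
#' calibrated defaults), `params` (inline overrides), `lambda_E0`, `drug`
#' (`{drug, B1|B2|B3|A,B, start_day, ramp_days}`, or
#' `{combination: [ ... ]}`), `method`, `dt`, `inflammation`,
#' `chemotaxis_scheme` and `output` (`{sample_every_days, snapshot_days}`).
#'
#' @param path Path to the YAML file.
#' @return An `ipf_scenario`.
#' @export
load_config <- function(path) {
  cfg <- yaml::yaml.load_file(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping: ", path)
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  K <- if (is.null(cfg$grid)) 20 else if (is.list(cfg$grid)) {
    unknown <- setdiff(names(cfg$grid), c("K1", "K2", "K3"))
    if (length(unknown))
      stop("unknown grid key(s): ", paste(unknown, collapse = ", "))
    c(cfg$grid$K1, cfg$grid$K2, cfg$grid$K3)
  } else cfg$grid
  damage <- if (is.null(cfg$damage) || length(cfg$damage) == 0) NULL else {
    unknown <- setdiff(names(cfg$damage), c("center", "edges"))
    if (length(unknown))
      stop("unknown damage key(s): ", paste(unknown, collapse = ", "))
    damage_box(center = if (is.null(cfg$damage$center)) c(0.5, 0.5, 0.5)
                        else unlist(cfg$damage$center),
               edge = unlist(cfg$damage$edges))
  }
  params <- if (!is.null(cfg$params_file))
    load_parameters(cfg$params_file) else default_parameters(calibrated = TRUE)
  if (!is.null(cfg$params)) {
    unknown <- setdiff(names(cfg$params), parameter_table()$name)
    if (length(unknown))
      stop("unknown parameter key(s): ", paste(unknown, collapse = ", "))
    for (nm in names(cfg$params))
      params <- set_param(params, nm, as.numeric(cfg$params[[nm]]))
  }
  out <- cfg$output
  if (!is.null(out)) {
    unknown <- setdiff(names(out), c("sample_every_days", "snapshot_days"))
    if (length(unknown))
      stop("unknown output key(s): ", paste(unknown, collapse = ", "))
  }
  args <- list(grid = K, damage = damage,
               duration = if (is.null(cfg$duration_days)) 30 else cfg$duration_days,
               params = params, drug = config_drug(cfg$drug),
               lambda_E0 = cfg$lambda_E0)
  if (!is.null(cfg$method)) args$method <- cfg$method
  if (!is.null(cfg$dt)) args$dt <- cfg$dt
  if (!is.null(cfg$inflammation)) args$inflammation <- cfg$inflammation
  if (!is.null(cfg$chemotaxis_scheme)) args$chemotaxis_scheme <- cfg$chemotaxis_scheme
  if (!is.null(out$sample_every_days)) args$sample_every <- out$sample_every_days
  if (!is.null(out$snapshot_days)) args$snapshot_days <- unlist(out$snapshot_days)
  do.call(scenario, args)
}

#' Tidy per-day averages of a simulation
#'
#' @param result An `ipf_sim`.
#' @return `data.frame` with columns `day`, `species`,
#'   `average_g_per_cm3`.
#' @export
result_table <- function(result) {
  stopifnot(inherits(result, "ipf_sim"))
  sp <- colnames(result$averages)
  data.frame(day = rep(result$times, times = length(sp)),
             species = rep(sp, each = length(result$times)),
             average_g_per_cm3 = as.vector(result$averages),
             stringsAsFactors = FALSE)
}

#' Write simulation averages as CSV
#'
#' @param result An `ipf_sim`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(result, path) {
  utils::write.csv(result_table(result), path, row.names = FALSE)
  invisible(path)
}

#' Fold-change report vs the healthy control
#'
#' Tabulates the disease / control ratio of every species at a given day.
#' The scar is reported absolutely (its baseline is zero); the activated AEC
#' (also absent in health) likewise.  A zero baseline in any other species
#' is an error.  Optionally rescales concentrations by `1/gamma` to the
#' per-tissue-volume convention used when comparing cytokine levels with
#' bronchial measurements.
#'
#' @param result An `ipf_sim`.
#' @param day Day at which to report (default: the horizon).
#' @param per_tissue_volume If `TRUE`, divide reported concentrations (not
#'   ratios) by the tissue fraction `gamma`.
#' @return `data.frame` with columns `species`, `average`, `baseline`,
#'   `ratio` (`NA` where the baseline is legitimately zero).
#' @export
fold_change_report <- function(result, day = NULL, per_tissue_volume = FALSE) {
  fc <- fold_change(result, day)
  base <- fc$baseline
  zero_ok <- c("S", "E")
  bad <- names(base)[base <= 0 & !names(base) %in% zero_ok]
  if (length(bad))
    stop("baseline is zero for species ", paste(bad, collapse = ", "),
         "; fold-change undefined")
  scale <- if (per_tissue_volume) 1 / result$scenario$tensor$gamma else 1
  data.frame(species = names(fc$value),
             average = as.numeric(fc$value) * scale,
             baseline = as.numeric(base) * scale,
             ratio = as.numeric(fc$ratio),
             stringsAsFactors = FALSE)
}

#' Built-in fixture scenarios
#'
#' Small deterministic scenarios used by the test-suite and for quick
#' experimentation:
#' \describe{
#'   \item{"tiny-disease"}{8^3 grid, centered damage cube of edge 0.25 cm,
#'     3 days.}
#'   \item{"uniform-ode"}{4^3 grid with the damage indicator equal to 1
#'     everywhere; spatially uniform, so the trajectory must coincide with
#'     the homogeneous ODE system.}
#'   \item{"no-damage"}{8^3 grid, no damage: homeostasis persistence.}
#' }
#'
#' @param name Fixture name.
#' @param ... Overrides forwarded to [scenario()].
#' @return An `ipf_scenario`.
#' @export
make_fixture <- function(name = c("tiny-disease", "uniform-ode", "no-damage"),
                         ...) {
  name <- match.arg(name)
  base <- switch(name,
    "tiny-disease" = list(grid = 8, damage = damage_box(edge = 0.25),
                          duration = 3),
    "uniform-ode" = list(grid = 4, damage = damage_box(edge = 1),
                         duration = 3),
    "no-damage" = list(grid = 8, damage = NULL, duration = 3))
  do.call(scenario, utils::modifyList(base, list(...)))
}

#' Run manifest
#'
#' A serializable record of a run: scenario echo, full parameter table with
#' provenance, solver settings and environment stamps.  Round-trips through
#' JSON losslessly at full double precision.
#'
#' @param result An `ipf_sim`.
#' @return A list (class `ipf_manifest`).
#' @export
run_manifest <- function(result) {
  stopifnot(inherits(result, "ipf_sim"))
  sc <- result$scenario
  structure(list(
    package_version = as.character(utils::packageVersion("fibrosim")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    grid = sc$grid$K,
    damage = if (is.null(sc$damage)) NULL
             else list(center = sc$damage$center, edge = sc$damage$edge),
    duration_days = sc$duration,
    method = result$method, dt = result$dt,
    inflammation = sc$inflammation,
    tensor = list(a11 = sc$tensor$a[1, 1], gamma = sc$tensor$gamma),
    parameters = attr(sc$params, "info")), class = "ipf_manifest")
}

#' Write / read a run manifest
#'
#' @param manifest An `ipf_manifest` (for writing).
#' @param path JSON file path.
#' @return `read_manifest` returns the manifest list.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$parameters <- as.data.frame(m$parameters, stringsAsFactors = FALSE)
  structure(m, class = "ipf_manifest")
}
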