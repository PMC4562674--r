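#' Parameter table of the IPF model
#'
#' Returns the full set of kinetic, transport and saturation constants of the
#' fibrosis network, one row per named constant, with its value, unit,
#' provenance tag and a short description.  Provenance is one of
#' `"table"` (literature-sourced), `"estimated"` (order-of-magnitude
#' estimate), `"unvalued"` (used by the model equations but with no published
#' value; the shipped default is a modelling choice), `"calibrated"`
#' (re-solved against the homeostatic baseline, see
#' [calibrate_parameters()]) or `"user"` (overridden via a parameter file).
#'
#' @return A `data.frame` with columns `name`, `value`, `unit`, `provenance`
#'   and `description`.
#' @seealso [default_parameters()], [load_parameters()]
#' @export
parameter_table <- function() {
  tab <- function(name, value, unit, provenance, description)
    data.frame(name = name, value = value, unit = unit,
               provenance = provenance, description = description,
               stringsAsFactors = FALSE)
  rows <- list(
    ## transport -------------------------------------------------------------
    tab("D_M",      8.64e-7, "cm^2/day", "table", "dispersion of macrophages"),
    tab("D_P",      1.728e-1, "cm^2/day", "table", "diffusion of MCP-1"),
    tab("D_G",      8.64e-2, "cm^2/day", "table", "diffusion of PDGF"),
    tab("D_Q",      4.32e-2, "cm^2/day", "table", "diffusion of MMP"),
    tab("D_Qr",     4.32e-2, "cm^2/day", "table", "diffusion of TIMP"),
    tab("D_Tbeta",  4.32e-2, "cm^2/day", "table", "diffusion of TGF-beta"),
    tab("D_Talpha", 1.29e-2, "cm^2/day", "table", "diffusion of TNF-alpha"),
    tab("D_f",      1.47e-6, "cm^2/day", "table", "dispersion of fibroblasts"),
    tab("D_m",      1.47e-5, "cm^2/day", "table", "dispersion of myofibroblasts"),
    tab("D_I13",    1.08e-2, "cm^2/day", "table", "diffusion of IL-13"),
    tab("chi_P",    10,      "cm^5/(g day)", "table", "chemotactic sensitivity of M1 to MCP-1"),
    ## production / transition rates ------------------------------------------
    tab("lambda_MT",     5e-3,    "1/day", "table", "M2 -> M1 repolarization by TNF-alpha"),
    tab("lambda_M1",     9.02e-6, "1/day", "estimated", "M1 -> M2 polarization"),
    tab("lambda_E0",     0.25,    "1/day", "estimated", "AEC activation rate in the damaged region"),
    tab("lambda_1",      1e-3,    "g/(cm^3 day)", "estimated", "fibrocyte-mediated AEC repair amplitude"),
    tab("lambda_EM",     1.65e-3, "1/day", "estimated", "EMT rate of activated AEC"),
    tab("lambda_TbetaM", 1.5e-2,  "1/day", "table", "TGF-beta production by M2 macrophages"),
    tab("lambda_Tbetaf", 7.5e-3,  "1/day", "estimated", "TGF-beta production by fibroblasts"),
    tab("lambda_GM",     2.4e-5,  "1/day", "table", "PDGF production by M2 macrophages"),
    tab("lambda_QM",     3e-4,    "1/day", "table", "MMP production by M2 macrophages"),
    tab("lambda_QrM",    6e-5,    "1/day", "table", "TIMP production by M2 macrophages"),
    tab("lambda_PE",     1e-8,    "1/day", "table", "MCP-1 production by activated AEC"),
    tab("lambda_rhof",   3e-3,    "1/day", "table", "ECM production by fibroblasts"),
    tab("lambda_rhom",   6e-3,    "1/day", "table", "ECM production by myofibroblasts"),
    tab("lambda_rhoTbeta", 2,     "",      "table", "TGF-beta enhancement of ECM production"),
    tab("lambda_Ef",     2.5e-1,  "1/day", "estimated", "fibroblast source from resting AEC (bFGF proxy)"),
    tab("lambda_fE",     5e-4,    "1/day", "estimated", "fibroblast proliferation by TGF-beta/IL-13 + AEC"),
    tab("lambda_mfT",    0.12,    "1/day", "table", "fibroblast -> myofibroblast by TGF-beta"),
    tab("lambda_mfG",    0.12,    "1/day", "table", "fibroblast -> myofibroblast by PDGF"),
    tab("lambda_TalphaM", 1.39e-5, "1/day", "table", "TNF-alpha production by M1 macrophages"),
    tab("lambda_TalphaE", 6.9e-6, "1/day", "estimated", "TNF-alpha production by epithelium"),
    tab("lambda_I13",    2.12e-7, "g/(cm^3 day)", "table", "IL-13 source (Th2 cells, lumped)"),
    tab("lambda_I13M",   3.98e-4, "1/day", "table", "IL-13 production by M2 macrophages"),
    ## death / degradation -----------------------------------------------------
    tab("d_M1",   0.02,    "1/day", "table", "M1 macrophage death"),
    tab("d_M2",   0.015,   "1/day", "table", "M2 macrophage death"),
    tab("d_E",    1.65e-2, "1/day", "table", "activated AEC death"),
    tab("d_E0",   1.65e-2, "1/day", "table", "resting AEC death"),
    tab("d_E0T",  1.65e-3, "",      "table", "TGF-beta enhancement of AEC apoptosis"),
    tab("delta",  1e-3,    "",      "estimated", "oxidative-stress apoptosis excess in the injury"),
    tab("d_rho",  0.37,    "1/day", "table", "ECM degradation"),
    tab("d_P",    1.73,    "1/day", "table", "MCP-1 degradation"),
    tab("d_PM",   2.08e-4, "1/day", "table", "MCP-1 internalization by M1 macrophages"),
    tab("d_G",    3.84,    "1/day", "table", "PDGF degradation"),
    tab("d_QQr",  4.98e8,  "cm^3/(g day)", "table", "MMP loss by binding to TIMP"),
    tab("d_QrQ",  1.04e9,  "cm^3/(g day)", "table", "TIMP loss by binding to MMP"),
    tab("d_Q",    4.32,    "1/day", "table", "MMP degradation"),
    tab("d_Qr",   21.6,    "1/day", "table", "TIMP degradation"),
    tab("d_rhoQ", 2.59e7,  "cm^3/(g day)", "table", "ECM degradation by MMP"),
    tab("d_Tbeta", 3.33e2, "1/day", "table", "TGF-beta degradation"),
    tab("d_f",    1.66e-2, "1/day", "table", "fibroblast death"),
    tab("d_m",    1.66e-2, "1/day", "table", "myofibroblast death"),
    tab("d_Talpha", 55.45, "1/day", "table", "TNF-alpha degradation"),
    tab("d_I13",  12.47,   "1/day", "table", "IL-13 degradation"),
    ## saturation / carrying constants ----------------------------------------
    tab("A_E0",    8.27e-3, "g/(cm^3 day)", "table", "intrinsic AEC proliferation"),
    tab("K_G",     1.5e-8,  "g/cm^3", "table", "PDGF saturation"),
    tab("K_Tbeta", 1e-10,   "g/cm^3", "table", "TGF-beta saturation"),
    tab("K_P",     5e-9,    "g/cm^3", "table", "MCP-1 saturation"),
    tab("K_Talpha", 5e-7,   "g/cm^3", "table", "TNF-alpha saturation"),
    tab("K_I13",   2e-7,    "g/cm^3", "table", "IL-13 saturation"),
    tab("K_E",     0.1,     "g/cm^3", "estimated", "AEC saturation"),
    tab("rho_0",   1e-2,    "g/cm^3", "table", "ECM carrying density"),
    tab("rho_star", 3.26e-3, "g/cm^3", "estimated", "ECM density in health"),
    tab("E_star",  0.799,   "g/cm^3", "estimated", "AEC density in health"),
    tab("f_star",  4.75e-3, "g/cm^3", "estimated", "fibroblast density in health"),
    tab("M_0",     5e-5,    "g/cm^3", "table", "blood monocyte density (M1 source)"),
    tab("beta",    0.2,     "1/day",  "table", "M1 influx rate (post-homogenization volumetric form)"),
    ## constants used by the equations but never published ----------------------
    tab("K_D",    1e-2, "g/cm^3", "unvalued", "saturation of the fibrocyte repair term"),
    tab("lambda_MTalpha", 5e-3, "1/day", "unvalued", "TNF-alpha consumption during M2 -> M1 switching"),
    tab("lambda_TbetaI13", 1, "", "unvalued", "IL-13 enhancement amplitude of TGF-beta production"),
    tab("lambda_S", 1, "", "unvalued", "scar density coefficient")
  )
  do.call(rbind, rows)
}

.param_provenances <- c("table", "estimated", "unvalued", "calibrated", "user")

#' Build a parameter set
#'
#' Assembles an `ipf_params` object from the default [parameter_table()],
#' optionally calibrated so that the homeostatic anchors are an exact steady
#' state (see [calibrate_parameters()]).
#'
#' @param calibrated If `TRUE` (default), the estimated-tagged parameters that
#'   close the homeostatic balances are re-solved against the printed healthy
#'   baseline.  If `FALSE`, the raw table values are returned; note that the
#'   raw table is not self-consistent at the healthy baseline.
#' @param options Model interpretation switches, see Details.
#'
#' @details `options` is a list with entries:
#' \describe{
#'   \item{tnfa_epithelial_total}{logical; attribute the epithelial TNF-alpha
#'     source to the total epithelium `E + E0` (default `TRUE`).  With the
#'     source restricted to activated AEC alone the healthy TNF-alpha balance
#'     cannot close, since activated AEC vanish at rest.}
#'   \item{tgfb_apoptosis_treated}{logical; whether the anti-TGF-beta blocking
#'     substitution also weakens TGF-beta-driven AEC apoptosis
#'     (default `TRUE`).}
#'   \item{delta_with_damage}{logical; oxidative-stress apoptosis excess
#'     `delta` acts only inside the damaged region (default `TRUE`).}
#' }
#'
#' @return An object of class `ipf_params`: a named list of numeric values
#'   with an `info` attribute (the provenance table) and an `options`
#'   attribute.
#' @export
default_parameters <- function(calibrated = TRUE, options = list()) {
  p <- as_ipf_params(parameter_table(), options = options)
  if (calibrated) p <- calibrate_parameters(homeostasis_anchors(), p)
  p
}

default_param_options <- function() {
  list(tnfa_epithelial_total = TRUE,
       tgfb_apoptosis_treated = TRUE,
       delta_with_damage = TRUE)
}

as_ipf_params <- function(info, options = list()) {
  stopifnot(is.data.frame(info),
            all(c("name", "value", "provenance") %in% names(info)))
  if (anyDuplicated(info$name))
    stop("duplicated parameter name: ",
         paste(info$name[duplicated(info$name)], collapse = ", "))
  opts <- utils::modifyList(default_param_options(), options)
  p <- as.list(stats::setNames(info$value, info$name))
  attr(p, "info") <- info
  attr(p, "options") <- opts
  class(p) <- "ipf_params"
  validate_parameters(p)
  p
}

#' @export
print.ipf_params <- function(x, ...) {
  info <- attr(x, "info")
  cat("<ipf_params> ", nrow(info), " constants (",
      paste(sprintf("%s: %d", names(table(info$provenance)),
                    as.integer(table(info$provenance))), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.ipf_params <- function(x, ...) attr(x, "info")

param_options <- function(params) attr(params, "options")

#' Validate a parameter set
#'
#' Checks the structural invariants of an `ipf_params` object: all values are
#' finite and non-negative, the healthy ECM density lies below the carrying
#' density (`rho_star < rho_0`), every constant referenced by the model
#' equations is present, and provenance tags are recognised.
#'
#' @param params An `ipf_params` object.
#' @return `params`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_parameters <- function(params) {
  info <- attr(params, "info")
  vals <- unlist(params)
  required <- parameter_table()$name
  missing <- setdiff(required, names(vals))
  if (length(missing))
    stop("missing model constant(s): ", paste(missing, collapse = ", "))
  if (any(!is.finite(vals)))
    stop("non-finite parameter value: ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "))
  if (any(vals < 0))
    stop("negative parameter value: ",
         paste(names(vals)[vals < 0], collapse = ", "))
  if (params$rho_star >= params$rho_0)
    stop("rho_star must be below the ECM carrying density rho_0")
  bad <- setdiff(unique(info$provenance), .param_provenances)
  if (length(bad))
    stop("unknown provenance tag: ", paste(bad, collapse = ", "))
  invisible(params)
}

set_param <- function(params, name, value, provenance = "user") {
  info <- attr(params, "info")
  if (!name %in% info$name) stop("unknown parameter: ", name)
  params[[name]] <- value
  info$value[info$name == name] <- value
  info$provenance[info$name == name] <- provenance
  attr(params, "info") <- info
  validate_parameters(params)
  params
}

#' Read a parameter file
#'
#' Reads a flat key--value YAML file of model constants.  Keys must be ASCII
#' parameter names from [parameter_table()]; unknown keys are rejected.
#' Values present in the file override the defaults and are provenance-tagged
#' `"user"`; omitted constants keep their default value.
#'
#' @param path Path to a YAML file mapping parameter names to numbers.
#' @param base Parameter set supplying defaults for omitted keys
#'   (default: uncalibrated table values).
#' @return An `ipf_params` object.
#' @seealso [write_parameters()]
#' @export
load_parameters <- function(path, base = default_parameters(calibrated = FALSE)) {
  raw <- yaml::yaml.load_file(path)
  if (!is.list(raw)) stop("parameter file must be a key-value mapping: ", path)
  unknown <- setdiff(names(raw), parameter_table()$name)
  if (length(unknown))
    stop("unknown parameter key(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  p <- base
  for (nm in names(raw)) {
    v <- raw[[nm]]
    ## YAML 1.1 scans exponents like 1e-08 as strings; accept them
    if (is.character(v) && length(v) == 1L)
      v <- suppressWarnings(as.numeric(v))
    if (!is.numeric(v) || length(v) != 1L || is.na(v))
      stop("parameter ", nm, " must be a single number")
    p <- set_param(p, nm, as.numeric(v))
  }
  p
}

#' Write a parameter file
#'
#' Serializes a parameter set to flat YAML with unit and provenance comments,
#' full double precision.  The file round-trips through [load_parameters()].
#'
#' @param params An `ipf_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  info <- attr(params, "info")
  lines <- c("# fibrosim parameter set (g, cm, day units)",
             sprintf("%s: %.17g  # [%s] %s; %s", info$name, info$value,
                     info$unit, info$provenance, info$description))
  writeLines(lines, path)
  invisible(path)
}
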