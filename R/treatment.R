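## In-silico anti-fibrotic drug regimens.
##
## Each drug acts as a multiplicative inhibition of specific kinetic terms,
## switched on gradually (a linear 20-day ramp starting at day 100 by
## default):
##   anti-TNF-alpha : lambda_MT      -> lambda_MT / (1 + B1)
##   anti-PDGF      : lambda_mfG     -> lambda_mfG / (1 + B2)
##   anti-IL-13     : lambda_TbetaI13 -> lambda_TbetaI13 / (1 + B3)
##   anti-TGF-beta  : lambda_TbetaM, lambda_Tbetaf -> /(1 + A), and the
##                    TGF-beta concentration seen by every fibrosis-promoting
##                    saturating term -> Tb / (1 + B)
## Combinations apply all listed modifications simultaneously.

.drug_kinds <- c("anti_TNFa", "anti_PDGF", "anti_IL13", "anti_TGFb")

#' Drug regimen
#'
#' @param drug One of `"anti_TNFa"`, `"anti_PDGF"`, `"anti_IL13"`,
#'   `"anti_TGFb"`.
#' @param B1,B2,B3 Blocking amplitudes of anti-TNF-alpha, anti-PDGF and
#'   anti-IL-13 (the published trials use 1).
#' @param A,B Anti-TGF-beta amplitudes: `A` inhibits TGF-beta production,
#'   `B` its fibrosis-promoting action (the published trials use
#'   `A = B = 0.1`).
#' @param start_day Day treatment begins (default 100, counted from disease
#'   onset).
#' @param ramp_days Days over which the effective amplitude ramps linearly
#'   from 0 to its full value (default 20).
#' @return An object of class `drug_regimen`.
#' @seealso [combine_regimens()], [ramp_fraction()], [drug_modifier()]
#' @export
drug_regimen <- function(drug, B1 = 1, B2 = 1, B3 = 1, A = 0.1, B = 0.1,
                         start_day = 100, ramp_days = 20) {
  if (!drug %in% .drug_kinds)
    stop("unknown drug '", drug, "'; known: ",
         paste(.drug_kinds, collapse = ", "))
  amps <- c(B1 = B1, B2 = B2, B3 = B3, A = A, B = B)
  if (any(amps < 0) || start_day < 0 || ramp_days < 0)
    stop("amplitudes, start_day and ramp_days must be non-negative")
  structure(list(drug = drug, B1 = B1, B2 = B2, B3 = B3, A = A, B = B,
                 start_day = start_day, ramp_days = ramp_days),
            class = "drug_regimen")
}

#' Combine several drug regimens
#'
#' @param ... `drug_regimen` objects to administer simultaneously.
#' @return An object of class `drug_combination`.
#' @export
combine_regimens <- function(...) {
  regs <- list(...)
  if (length(regs) == 1L && is.list(regs[[1]]) &&
      !inherits(regs[[1]], "drug_regimen")) regs <- regs[[1]]
  if (!all(vapply(regs, inherits, logical(1), "drug_regimen")))
    stop("all arguments must be drug_regimen objects")
  structure(regs, class = "drug_combination")
}

#' Treatment ramp fraction
#'
#' The effective fraction of the drug amplitude at time `t`: 0 before the
#' start day, rising linearly to 1 over the ramp, then 1.
#'
#' @param t Time (day), vectorized.
#' @param regimen A [drug_regimen()].
#' @return Values in `[0, 1]`.
#' @export
ramp_fraction <- function(t, regimen) {
  if (any(t < 0)) stop("time must be non-negative")
  if (regimen$ramp_days == 0) return(as.numeric(t >= regimen$start_day))
  pmin(pmax((t - regimen$start_day) / regimen$ramp_days, 0), 1)
}

#' Kinetic modifier of a drug regimen at a given time
#'
#' Translates a regimen (or combination) into the divisors applied to the
#' affected kinetic terms at time `t`, using the ramped effective
#' amplitudes.  `NULL` (untreated) yields all divisors 1.
#'
#' @param regimen A [drug_regimen()], [combine_regimens()] result, or
#'   `NULL`.
#' @param t Time (day).
#' @return List of divisors `MT`, `mfG`, `TbI13`, `A`, `B` (each `>= 1`)
#'   consumed by [reaction_rates()].
#' @export
drug_modifier <- function(regimen, t) {
  mod <- no_drug_modifier()
  if (is.null(regimen)) return(mod)
  regs <- if (inherits(regimen, "drug_combination")) regimen else list(regimen)
  for (r in regs) {
    th <- ramp_fraction(t, r)
    switch(r$drug,
           anti_TNFa = { mod$MT <- mod$MT * (1 + th * r$B1) },
           anti_PDGF = { mod$mfG <- mod$mfG * (1 + th * r$B2) },
           anti_IL13 = { mod$TbI13 <- mod$TbI13 * (1 + th * r$B3) },
           anti_TGFb = {
             mod$A <- mod$A * (1 + th * r$A)
             mod$B <- mod$B * (1 + th * r$B)
           })
  }
  mod
}

#' Presets of the published treatment scenarios
#'
#' Mild: centered damage cube of edge 0.3 cm with AEC activation rate
#' `lambda_E0 = 2.5e-3`/day; severe: edge 0.5 cm with
#' `lambda_E0 = 3e-3`/day.
#'
#' @param severity `"mild"` or `"severe"`.
#' @return List with `damage` (a [damage_box()]) and `lambda_E0`.
#' @export
treatment_preset <- function(severity = c("mild", "severe")) {
  severity <- match.arg(severity)
  if (severity == "mild")
    list(damage = damage_box(edge = 0.3), lambda_E0 = 2.5e-3)
  else
    list(damage = damage_box(edge = 0.5), lambda_E0 = 3e-3)
}

#' Run comparative treatment arms
#'
#' Simulates a common disease scenario under several drug regimens (plus the
#' untreated control) and collects the domain-averaged ECM and scar
#' endpoints at the horizon.
#'
#' @param base A [scenario()] describing the untreated disease (its `drug`
#'   field is ignored).
#' @param regimens Named list of regimens (`drug_regimen`,
#'   `drug_combination` or `NULL` for control arms).
#' @return An object of class `ipf_trial`: list with `arms` (per-arm
#'   [simulate()] results), and `endpoints` (data.frame: arm, ECM and scar
#'   averages at the horizon, relative ECM change vs the `untreated` arm if
#'   present), ordered by increasing ECM endpoint.
#' @export
compare_scenarios <- function(base, regimens) {
  stopifnot(inherits(base, "ipf_scenario"))
  if (is.null(names(regimens)) || any(!nzchar(names(regimens))))
    stop("regimens must be a named list")
  arms <- lapply(regimens, function(reg) {
    sc <- base
    sc$drug <- reg
    simulate(sc)
  })
  ecm <- vapply(arms, function(a) final_average(a, "rho"), numeric(1))
  scar <- vapply(arms, function(a) final_average(a, "S"), numeric(1))
  endpoints <- data.frame(arm = names(regimens), ecm = ecm, scar = scar,
                          row.names = NULL, stringsAsFactors = FALSE)
  if ("untreated" %in% names(regimens)) {
    ref <- ecm[["untreated"]]
    endpoints$ecm_vs_untreated <- ecm / ref - 1
  }
  endpoints <- endpoints[order(endpoints$ecm), ]
  structure(list(arms = arms, endpoints = endpoints, horizon = base$duration),
            class = "ipf_trial")
}

#' @export
print.ipf_trial <- function(x, ...) {
  cat(sprintf("<ipf_trial> %d arms, horizon %g days\n",
              nrow(x$endpoints), x$horizon))
  print(x$endpoints, row.names = FALSE)
  invisible(x)
}
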