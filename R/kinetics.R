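## Pointwise reaction kinetics of the 15-species fibrosis network.
## All concentrations are in g/cm^3 and all rates in g/(cm^3 day).

#' Species of the fibrosis model
#'
#' The model tracks 14 dynamic species plus the diagnostic scar density `S`.
#' All are measured in g/cm^3.  The two epithelial populations (`E0`, `E`)
#' obey pointwise ODEs and do not diffuse; only M1 macrophages are
#' chemotactic (toward MCP-1).
#'
#' @return A `data.frame` with columns `name`, `label`, `diffusing`,
#'   `chemotactic` and `dynamic`.
#' @export
species_table <- function() {
  nm <- c("M1", "M2", "E0", "E", "f", "m", "rho",
          "P", "G", "Tb", "Q", "Qr", "Ta", "I13", "S")
  lb <- c("M1 macrophages", "M2 macrophages", "AEC (resting)",
          "AEC (activated)", "fibroblasts", "myofibroblasts", "ECM",
          "MCP-1", "PDGF", "TGF-beta", "MMP", "TIMP", "TNF-alpha", "IL-13",
          "scar")
  data.frame(name = nm, label = lb,
             diffusing = !nm %in% c("E0", "E", "rho", "S"),
             chemotactic = nm == "M1",
             dynamic = nm != "S",
             stringsAsFactors = FALSE)
}

## canonical ordering of the dynamic species
.species <- c("M1", "M2", "E0", "E", "f", "m", "rho",
              "P", "G", "Tb", "Q", "Qr", "Ta", "I13")

species_names <- function(dynamic_only = TRUE)
  if (dynamic_only) .species else c(.species, "S")

#' Saturating (Michaelis--Menten) factor
#'
#' The dimensionless factor `x / (K + x)` used by every saturating
#' interaction in the model.
#'
#' @param x Concentration(s), must be non-negative.
#' @param K Saturation constant, must be positive.
#' @return Values in `[0, 1)`, strictly increasing in `x`.
#' @examples
#' hill(0, 5e-9)      # 0
#' hill(5e-9, 5e-9)   # half-saturation
#' @export
hill <- function(x, K) {
  if (length(K) != 1L || !is.finite(K) || K <= 0)
    stop("saturation constant K must be a single positive number")
  if (any(x < 0)) stop("hill(): negative concentration")
  x / (K + x)
}

## default modifier = untreated kinetics (all divisors 1)
no_drug_modifier <- function()
  list(MT = 1, mfG = 1, TbI13 = 1, A = 1, B = 1)

#' Pointwise reaction rates of the fibrosis network
#'
#' Evaluates the non-transport (reaction) right-hand sides of the 14 dynamic
#' species at one state, or elementwise over fields.  Diffusion and
#' chemotaxis are handled separately by the spatial integrator.
#'
#' The M1 influx from the blood uses the volumetric form
#' `beta(P) (M0 - M1)` with `beta(P) = beta P / (K_P + P)`, obtained by
#' folding the monocyte boundary influx into a source term on the homogenized
#' domain.  The fibroblast ECM production carries the logistic clamp
#' `(1 - rho/rho_0)_+`.
#'
#' @param state Named numeric vector (one value per dynamic species) or a
#'   named list of equal-shaped arrays; names must cover
#'   `species_names()`.
#' @param params An `ipf_params` parameter set.
#' @param damage Damage indicator `I_D`: scalar 0/1 or an array shaped like
#'   the state fields.
#' @param drug Optional drug modifier (list of divisors, see
#'   [drug_modifier()]); `NULL` means untreated.
#' @param inflammation Optional constant overriding the MCP-1 production term
#'   `lambda_PE * E` (g/(cm^3 day)); used for the homeostasis computation
#'   where this residual inflammation term is held at `1e-10`.
#' @param split If `TRUE`, return `list(production, loss)` with
#'   `rate = production - loss`, both componentwise non-negative.
#' @param check Validate non-negativity of the state (default `TRUE`).
#' @return Named rates in g/(cm^3 day), same shape as `state`; or the
#'   production/loss split if `split = TRUE`.
#' @export
reaction_rates <- function(state, params, damage = 0, drug = NULL,
                           inflammation = NULL, split = FALSE, check = TRUE) {
  vec_in <- is.numeric(state)
  s <- if (vec_in) as.list(state) else state
  missing <- setdiff(.species, names(s))
  if (length(missing))
    stop("state is missing species: ", paste(missing, collapse = ", "))
  if (check) {
    for (nm in .species) {
      v <- s[[nm]]
      if (any(!is.finite(v))) stop("non-finite state entry in ", nm)
      if (any(v < 0)) stop("negative state entry in ", nm)
    }
    if (any(damage < 0 | damage > 1)) stop("damage indicator must lie in [0, 1]")
  }
  p <- params
  opt <- attr(params, "options")
  dm <- if (is.null(drug)) no_drug_modifier() else drug

  M1 <- s$M1; M2 <- s$M2; E0 <- s$E0; E <- s$E; f <- s$f; m <- s$m
  rho <- s$rho; P <- s$P; G <- s$G; Tb <- s$Tb; Q <- s$Q; Qr <- s$Qr
  Ta <- s$Ta; I13 <- s$I13

  ## saturating factors.  Tb_prom is the TGF-beta concentration seen by the
  ## fibrosis-promoting interactions; anti-TGF-beta blockade replaces Tb by
  ## Tb/(1+B) there (but not in TGF-beta's own turnover).
  Tb_prom <- Tb / dm$B
  hTa  <- Ta / (p$K_Talpha + Ta)
  hTbP <- Tb_prom / (p$K_Tbeta + Tb_prom)
  hTb_apop <- if (isTRUE(opt$tgfb_apoptosis_treated)) hTbP else Tb / (p$K_Tbeta + Tb)
  hG   <- G / (p$K_G + G)
  hI13 <- I13 / (p$K_I13 + I13)
  hP   <- P / (p$K_P + P)
  hE   <- E / (p$K_E + E)

  betaP   <- p$beta * hP
  m2_to_m1 <- (p$lambda_MT / dm$MT) * hTa * M2
  f_to_m   <- ((p$lambda_mfT) * hTbP + (p$lambda_mfG / dm$mfG) * hG) * f
  delta_eff <- if (isTRUE(opt$delta_with_damage)) p$delta * damage else p$delta

  prod <- list(); loss <- list()
  prod$M1 <- betaP * p$M_0 + m2_to_m1
  loss$M1 <- betaP * M1 + p$d_M1 * M1 + p$lambda_M1 * M1
  prod$M2 <- p$lambda_M1 * M1
  loss$M2 <- p$d_M2 * M2 + m2_to_m1
  prod$E0 <- p$A_E0 * (1 + p$lambda_1 * E0 * damage / (p$K_D + E0 * damage))
  loss$E0 <- p$d_E0 * E0 * (1 + delta_eff + p$d_E0T * hTb_apop) +
    p$lambda_E0 * E0 * damage
  prod$E <- p$lambda_E0 * E0 * damage
  loss$E <- p$lambda_EM * E * damage + p$d_E * E
  prod$f <- p$lambda_Ef * E0 + p$lambda_fE * (hTbP + hI13) * hE * f
  loss$f <- p$d_f * f + f_to_m
  prod$m <- f_to_m
  loss$m <- p$d_m * m
  prod$rho <- p$lambda_rhof * f * pmax(1 - rho / p$rho_0, 0) +
    p$lambda_rhom * (1 + p$lambda_rhoTbeta * hTbP) * m
  loss$rho <- p$d_rho * rho + p$d_rhoQ * Q * rho
  ## the standing residual-inflammation source (when given) maintains the
  ## healthy baseline; activated AEC add to it during disease
  prod$P <- if (is.null(inflammation)) p$lambda_PE * E else
    inflammation + p$lambda_PE * E
  loss$P <- p$d_P * P + p$d_PM * hP * M1
  prod$G <- p$lambda_GM * M2
  loss$G <- p$d_G * G
  prod$Tb <- (p$lambda_TbetaM / dm$A) * M2 *
    (1 + (p$lambda_TbetaI13 / dm$TbI13) * hI13) +
    (p$lambda_Tbetaf / dm$A) * f * hE
  loss$Tb <- p$d_Tbeta * Tb
  prod$Q <- p$lambda_QM * M2
  loss$Q <- p$d_QQr * Qr * Q + p$d_Q * Q
  prod$Qr <- p$lambda_QrM * M2
  loss$Qr <- p$d_QrQ * Q * Qr + p$d_Qr * Qr
  prod$Ta <- p$lambda_TalphaM * M1 +
    p$lambda_TalphaE * (if (isTRUE(opt$tnfa_epithelial_total)) E + E0 else E)
  loss$Ta <- p$d_Talpha * Ta + p$lambda_MTalpha * hTa * M2
  prod$I13 <- p$lambda_I13 + p$lambda_I13M * M2
  loss$I13 <- p$d_I13 * I13

  if (split) {
    if (vec_in) {
      prod <- unlist(prod)[.species]; loss <- unlist(loss)[.species]
    }
    return(list(production = prod, loss = loss))
  }
  rates <- lapply(.species, function(nm) prod[[nm]] - loss[[nm]])
  names(rates) <- .species
  if (vec_in) unlist(rates) else rates
}

## Coefficients of the constant linear decay folded into the stiff linear
## part of the time integrator; the remaining (nonlinear) reaction terms are
## rate + lin * state.
linear_decay_rates <- function(params) {
  c(M1 = params$d_M1 + params$lambda_M1, M2 = params$d_M2,
    E0 = params$d_E0, E = params$d_E, f = params$d_f, m = params$d_m,
    rho = params$d_rho, P = params$d_P, G = params$d_G,
    Tb = params$d_Tbeta, Q = params$d_Q, Qr = params$d_Qr,
    Ta = params$d_Talpha, I13 = params$d_I13)
}

#' Scar density
#'
#' The scar is the ECM excess over its homeostatic density:
#' `S = lambda_S * (rho - rho_star)_+`.
#'
#' @param rho ECM density (g/cm^3), scalar or array.
#' @param params An `ipf_params` parameter set.
#' @return Scar density, same shape as `rho`.
#' @export
scar_density <- function(rho, params) {
  if (any(rho < 0)) stop("negative ECM density")
  params$lambda_S * pmax(rho - params$rho_star, 0)
}
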