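## Healthy-baseline (homeostasis) computation.
##
## The healthy lung is modelled as a spatially homogeneous steady state of
## the reaction network with no damage and a small residual inflammation:
## the MCP-1 production term lambda_PE * E is held at the fixed value 1e-10
## g/(cm^3 day).  The published baseline (anchors below) is not consistent
## with the raw parameter table, so the estimated-tagged parameters that
## appear linearly in the anchored balances are re-solved (calibrated) so
## that the anchors become an exact root.

#' Homeostatic anchor values
#'
#' The printed healthy-baseline concentrations used to calibrate the
#' estimated parameters, plus the fixed residual-inflammation value of the
#' MCP-1 production term.
#'
#' @return A list with entries `E0`, `f`, `rho`, `Ta`, `Tb` (g/cm^3),
#'   `I13_candidates` (the two printed IL-13 values; diagnostic only, IL-13
#'   is not anchored) and `inflammation` (g/(cm^3 day)).
#' @export
homeostasis_anchors <- function() {
  list(E0 = 0.79, f = 4.75e-3, rho = 3.26e-3,
       Ta = 2.5e-8, Tb = 2.51e-12,
       I13_candidates = c(3.2e-8, 1.76e-8),
       inflammation = 1e-10)
}

## --- internal: anchored rest-state completion -------------------------------

## Solve the coupled MCP-1 / M1 rest balance:
##   s = d_P P + d_PM hill(P) M1
##   beta hill(P) (M0 - M1) = d_M1 M1 + d_M2 M2   (M1 balance with the
##   M2-exchange terms eliminated through the M2 balance)
rest_M1_P <- function(p, s, M2) {
  P <- s / p$d_P
  M1 <- 0
  for (it in 1:200) {
    hP <- P / (p$K_P + P)
    M1_new <- (p$beta * hP * p$M_0 - p$d_M2 * M2) / (p$beta * hP + p$d_M1)
    if (M1_new < 0) M1_new <- 0
    ## scalar root for P given M1 (monotone in P)
    g <- function(Pv) p$d_P * Pv + p$d_PM * Pv / (p$K_P + Pv) * M1_new - s
    P_new <- stats::uniroot(g, c(0, s / p$d_P * (1 + 1e-9)),
                            tol = 1e-25)$root
    if (abs(M1_new - M1) <= 1e-14 * max(M1, 1e-30) &&
        abs(P_new - P) <= 1e-14 * max(P, 1e-30)) {
      M1 <- M1_new; P <- P_new; break
    }
    M1 <- M1_new; P <- P_new
  }
  list(M1 = M1, P = P)
}

## M2 implied by the TGF-beta anchor, coupled with the IL-13 balance
rest_M2_from_Tb <- function(p, Tb) {
  M2 <- 0
  for (it in 1:200) {
    I13 <- (p$lambda_I13 + p$lambda_I13M * M2) / p$d_I13
    hI <- I13 / (p$K_I13 + I13)
    M2_new <- p$d_Tbeta * Tb /
      (p$lambda_TbetaM * (1 + p$lambda_TbetaI13 * hI))
    if (abs(M2_new - M2) <= 1e-15 * max(M2, 1e-30)) { M2 <- M2_new; break }
    M2 <- M2_new
  }
  M2
}

## MMP/TIMP rest pair for a given M2 (mutual-binding fixed point)
rest_Q_Qr <- function(p, M2) {
  Q <- p$lambda_QM * M2 / p$d_Q
  Qr <- p$lambda_QrM * M2 / p$d_Qr
  for (it in 1:200) {
    Qn <- p$lambda_QM * M2 / (p$d_QQr * Qr + p$d_Q)
    Qrn <- p$lambda_QrM * M2 / (p$d_QrQ * Qn + p$d_Qr)
    if (abs(Qn - Q) <= 1e-15 * max(Q, 1e-300) &&
        abs(Qrn - Qr) <= 1e-15 * max(Qr, 1e-300)) { Q <- Qn; Qr <- Qrn; break }
    Q <- Qn; Qr <- Qrn
  }
  list(Q = Q, Qr = Qr)
}

## Completion of the rest state from the anchors under the current
## parameters.  If use_Tb_anchor, M2 is implied by the TGF-beta anchor
## (appropriate when lambda_M1 is being calibrated); otherwise M2 follows
## from the M1 -> M2 polarization chain.
anchored_rest_state <- function(p, anchors, use_Tb_anchor = TRUE) {
  hTa <- anchors$Ta / (p$K_Talpha + anchors$Ta)
  if (use_Tb_anchor) {
    M2 <- rest_M2_from_Tb(p, anchors$Tb)
    mp <- rest_M1_P(p, anchors$inflammation, M2)
    M1 <- mp$M1; P <- mp$P
  } else {
    ## joint M1/M2/P fixed point under the current lambda_M1
    M2 <- 0
    for (it in 1:200) {
      mp <- rest_M1_P(p, anchors$inflammation, M2)
      M2_new <- p$lambda_M1 * mp$M1 / (p$d_M2 + p$lambda_MT * hTa)
      if (abs(M2_new - M2) <= 1e-15 * max(M2, 1e-30)) { M2 <- M2_new; break }
      M2 <- M2_new
    }
    mp <- rest_M1_P(p, anchors$inflammation, M2)
    M1 <- mp$M1; P <- mp$P
  }
  I13 <- (p$lambda_I13 + p$lambda_I13M * M2) / p$d_I13
  G <- p$lambda_GM * M2 / p$d_G
  qq <- rest_Q_Qr(p, M2)
  hTb <- anchors$Tb / (p$K_Tbeta + anchors$Tb)
  hG <- G / (p$K_G + G)
  tau <- p$lambda_mfT * hTb + p$lambda_mfG * hG   # f -> m transition rate
  m <- tau * anchors$f / p$d_m
  st <- c(M1 = M1, M2 = M2, E0 = anchors$E0, E = 0,
          f = anchors$f, m = m, rho = anchors$rho,
          P = P, G = G, Tb = anchors$Tb, Q = qq$Q, Qr = qq$Qr,
          Ta = anchors$Ta, I13 = I13)
  st[.species]
}

## Registry of calibratable parameters: each maps to exactly one anchored
## steady-state balance with the parameter appearing linearly.
.calibration_registry <- c(
  lambda_M1      = "M2 balance (TGF-beta anchor fixes the M2 level)",
  lambda_TalphaE = "TNF-alpha balance",
  A_E0           = "resting-AEC balance",
  lambda_Ef      = "fibroblast balance",
  d_rho          = "ECM balance"
)

#' Calibrate estimated parameters against the homeostatic anchors
#'
#' Re-solves a set of free parameters so that the printed healthy baseline
#' (the anchors) is an exact steady state of the reaction network with the
#' MCP-1 production term held at the residual-inflammation value.  Each free
#' parameter appears linearly in exactly one anchored balance and is
#' recovered in closed form; calibrated entries are provenance-tagged
#' `"calibrated"`.
#'
#' The default free set is `lambda_M1` (closes the TGF-beta anchor through
#' the M2 level), `lambda_TalphaE` (TNF-alpha balance, with the epithelial
#' source attributed to total epithelium at rest), `A_E0` (resting-AEC
#' balance), `lambda_Ef` (fibroblast balance) and `d_rho` (ECM balance).
#'
#' @param anchors Anchor list from [homeostasis_anchors()].
#' @param params An `ipf_params` parameter set.
#' @param free Character vector of parameter names to re-solve.  Only the
#'   registered closed-form balances are supported; an empty set is a no-op.
#' @return The calibrated `ipf_params`, with the anchored rest state attached
#'   as attribute `"rest_state"` (used to seed [solve_homeostasis()]).
#' @export
calibrate_parameters <- function(anchors = homeostasis_anchors(),
                                 params = default_parameters(calibrated = FALSE),
                                 free = names(.calibration_registry)) {
  if (length(free) == 0) return(params)
  free <- unique(free)
  unsupported <- setdiff(free, names(.calibration_registry))
  if (length(unsupported)) {
    extra <- if ("lambda_fE" %in% unsupported)
      " (lambda_fE multiplies the activated-AEC factor, which vanishes at rest: its balance is degenerate there)"
    else ""
    stop("no closed-form homeostatic balance registered for: ",
         paste(unsupported, collapse = ", "), extra)
  }
  p <- params
  opt <- param_options(p)
  st <- anchored_rest_state(p, anchors,
                            use_Tb_anchor = "lambda_M1" %in% free)
  hTa <- st[["Ta"]] / (p$K_Talpha + st[["Ta"]])
  hTb <- st[["Tb"]] / (p$K_Tbeta + st[["Tb"]])
  hG  <- st[["G"]] / (p$K_G + st[["G"]])

  solved <- list()
  if ("lambda_M1" %in% free)
    solved$lambda_M1 <- (p$d_M2 + p$lambda_MT * hTa) * st[["M2"]] / st[["M1"]]
  if ("lambda_TalphaE" %in% free) {
    esrc <- if (isTRUE(opt$tnfa_epithelial_total)) st[["E"]] + st[["E0"]]
            else st[["E"]]
    if (esrc <= 0)
      stop("TNF-alpha balance is degenerate: no epithelial source at rest ",
           "(set option tnfa_epithelial_total = TRUE)")
    solved$lambda_TalphaE <-
      (p$d_Talpha * st[["Ta"]] + p$lambda_MTalpha * hTa * st[["M2"]] -
         p$lambda_TalphaM * st[["M1"]]) / esrc
  }
  if ("A_E0" %in% free)
    solved$A_E0 <- p$d_E0 * st[["E0"]] * (1 + p$d_E0T * hTb)
  if ("lambda_Ef" %in% free) {
    tau <- p$lambda_mfT * hTb + p$lambda_mfG * hG
    solved$lambda_Ef <- (p$d_f + tau) * st[["f"]] / st[["E0"]]
  }
  if ("d_rho" %in% free) {
    production <- p$lambda_rhof * st[["f"]] * max(1 - st[["rho"]] / p$rho_0, 0) +
      p$lambda_rhom * (1 + p$lambda_rhoTbeta * hTb) * st[["m"]]
    solved$d_rho <- production / st[["rho"]] - p$d_rhoQ * st[["Q"]]
  }
  for (nm in names(solved)) {
    if (!is.finite(solved[[nm]]) || solved[[nm]] < 0)
      stop("calibration of ", nm, " from the ", .calibration_registry[[nm]],
           " produced an invalid value: ", solved[[nm]])
    p <- set_param(p, nm, solved[[nm]], provenance = "calibrated")
  }
  ## recompute the rest state under the calibrated parameters
  attr(p, "rest_state") <- anchored_rest_state(p, anchors,
                                               use_Tb_anchor = FALSE)
  p
}

## typical magnitudes, used for Jacobian steps and residual scaling
.state_typical <- c(M1 = 1e-5, M2 = 1e-7, E0 = 1, E = 1e-2, f = 1e-2,
                    m = 1e-3, rho = 1e-2, P = 1e-10, G = 1e-12, Tb = 1e-11,
                    Q = 1e-11, Qr = 1e-12, Ta = 1e-8, I13 = 1e-8)

## scaled reaction residual: |rate| relative to the species' gross turnover
scaled_residual <- function(state, params, inflammation) {
  pl <- reaction_rates(state, params, damage = 0,
                       inflammation = inflammation, split = TRUE,
                       check = FALSE)
  rate <- pl$production - pl$loss
  turnover <- pmax(pl$production + pl$loss,
                   linear_decay_rates(params) * .state_typical * 1e-6)
  abs(rate) / turnover
}

#' Solve the homeostatic steady state
#'
#' Finds the spatially homogeneous root of the 14-species reaction system at
#' rest (damage off, MCP-1 production held at the residual-inflammation
#' value) by a damped Newton iteration with finite-difference Jacobian,
#' falling back to long-time ODE relaxation if Newton stalls.
#'
#' @param params An `ipf_params` set (usually calibrated).
#' @param inflammation Fixed value of the MCP-1 production term
#'   (g/(cm^3 day)); default `1e-10`.
#' @param start Optional starting state (named vector); defaults to the
#'   calibrated rest state attached to `params`, or to typical magnitudes.
#' @param tol Convergence tolerance on the maximum scaled residual
#'   (reaction rate relative to gross turnover); default `1e-12`.
#' @param max_iter Maximum Newton iterations.
#' @return An object of class `ipf_steady_state`: list with `state` (named
#'   vector, g/cm^3), `residual` (max scaled residual), `iterations` and
#'   `converged`.
#' @export
solve_homeostasis <- function(params, inflammation = homeostasis_anchors()$inflammation,
                              start = NULL, tol = 1e-12, max_iter = 60) {
  x <- if (!is.null(start)) start[.species]
       else if (!is.null(attr(params, "rest_state"))) attr(params, "rest_state")
       else .state_typical
  if (any(!is.finite(x)) || any(x < 0)) stop("invalid starting state")
  rate_fn <- function(s) reaction_rates(s, params, damage = 0,
                                        inflammation = inflammation,
                                        check = FALSE)
  obj <- function(s) max(scaled_residual(s, params, inflammation))
  n <- length(.species)
  best <- obj(x)
  it <- 0
  relaxed <- FALSE
  while (best > tol && it < max_iter) {
    it <- it + 1
    r <- rate_fn(x)
    J <- matrix(0, n, n, dimnames = list(.species, .species))
    for (j in seq_len(n)) {
      h <- 1e-7 * max(abs(x[j]), .state_typical[j] * 1e-3)
      xp <- x; xp[j] <- x[j] + h
      xm <- x; xm[j] <- x[j] - h
      J[, j] <- (rate_fn(xp) - rate_fn(xm)) / (2 * h)
    }
    dx <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(dx)) dx <- -as.numeric(MASS_ginv(J) %*% r)
    alpha <- 1
    improved <- FALSE
    for (k in 1:40) {
      xn <- x + alpha * dx
      xn[xn < 0 & xn > -1e-12 * .state_typical] <- 0
      if (all(xn >= 0)) {
        val <- obj(xn)
        if (val < best) {
          x <- xn; best <- val; improved <- TRUE; break
        }
      }
      alpha <- alpha / 2
    }
    if (!improved) {
      if (relaxed) break
      ## fall back to ODE relaxation toward the attracting root
      relaxed <- TRUE
      x <- relax_to_steady(x, params, inflammation, days = 500)
      best <- obj(x)
    }
  }
  structure(list(state = x, residual = best, iterations = it,
                 converged = best <= tol, inflammation = inflammation),
            class = "ipf_steady_state")
}

## minimal pseudo-inverse (avoids importing MASS for one corner case)
MASS_ginv <- function(X, tol = 1e-12) {
  s <- svd(X)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

relax_to_steady <- function(x, params, inflammation, days = 500) {
  f <- function(t, y, parms) {
    y[y < 0] <- 0
    list(reaction_rates(stats::setNames(y, .species), params, damage = 0,
                        inflammation = inflammation, check = FALSE))
  }
  out <- deSolve::ode(y = as.numeric(x), times = c(0, days), func = f,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = .state_typical * 1e-12)
  st <- pmax(out[nrow(out), -1], 0)
  stats::setNames(st, .species)
}

#' @export
print.ipf_steady_state <- function(x, ...) {
  cat(sprintf("<ipf_steady_state> converged = %s, scaled residual = %.3g (%d iterations)\n",
              x$converged, x$residual, x$iterations))
  print(signif(x$state, 6))
  invisible(x)
}

#' Verify a steady state by forward integration
#'
#' Integrates the homogeneous reaction ODE system from a putative steady
#' state and reports the worst relative drift over the horizon -- a
#' regression guard on the fixed point.
#'
#' @param steady An `ipf_steady_state` (or a named state vector).
#' @param params The parameter set used to produce it.
#' @param horizon Days to integrate (default 30).
#' @param inflammation The fixed MCP-1 production term used for the steady
#'   state.
#' @return A list with `max_drift` (relative, over the horizon), the
#'   `worst_species`, and the drift per species.
#' @export
verify_fixed_point <- function(steady, params, horizon = 30,
                               inflammation = homeostasis_anchors()$inflammation) {
  x0 <- if (inherits(steady, "ipf_steady_state")) steady$state else steady[.species]
  f <- function(t, y, parms)
    list(reaction_rates(stats::setNames(pmax(y, 0), .species), params,
                        damage = 0, inflammation = inflammation,
                        check = FALSE))
  out <- deSolve::ode(y = as.numeric(x0), times = c(0, horizon), func = f,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = .state_typical * 1e-12)
  xT <- stats::setNames(out[nrow(out), -1], .species)
  drift <- abs(xT - x0) / pmax(abs(x0), .state_typical * 1e-9)
  list(max_drift = max(drift),
       worst_species = .species[which.max(drift)],
       drift = drift)
}
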