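## Time integration of the homogenized reaction-diffusion-chemotaxis system.
##
## Two interchangeable schemes advance the method-of-lines system
##   dX/dt = (D_X a_11 / gamma) lap_h X + chemotaxis + F_X(X):
##
## * "rk4": the classical explicit 4-stage Runge-Kutta applied to the full
##   semi-discretized right-hand side; the step size is bounded by the
##   stiffest linear decay (TGF-beta, 333/day) and the diffusion CFL.
## * "etd": a two-stage exponential time-differencing Runge-Kutta (ETD2RK)
##   in the cosine eigenbasis of the mirror-ghost Laplacian.  Diffusion and
##   the constant linear decay of each species are integrated exactly, so
##   the scheme is steady-state preserving and stable at steps an order of
##   magnitude larger than the explicit bound; the remaining nonlinear
##   reaction and chemotaxis terms enter through the phi-function weights.

## phi functions of the exponential integrator, elementwise, z <= 0
phi1 <- function(z) ifelse(z == 0, 1, expm1(z) / z)
phi2 <- function(z) {
  small <- abs(z) < 1e-4
  out <- numeric(length(z))
  zs <- z[small]
  out[small] <- 0.5 + zs / 6 + zs^2 / 24 + zs^3 / 120
  zb <- z[!small]
  out[!small] <- (expm1(zb) - zb) / zb^2
  if (!is.null(dim(z))) dim(out) <- dim(z)
  out
}

## Precomputed stepping context for a scenario
make_stepper <- function(params, grid, damage, tensor, method = c("etd", "rk4"),
                         dt = NULL, inflammation = NULL,
                         chemotaxis_scheme = "upwind") {
  method <- match.arg(method)
  sp <- species_table()
  dyn <- sp$name[sp$dynamic]
  D_named <- c(M1 = params$D_M, M2 = params$D_M, E0 = 0, E = 0,
               f = params$D_f, m = params$D_m, rho = 0,
               P = params$D_P, G = params$D_G, Tb = params$D_Tbeta,
               Q = params$D_Q, Qr = params$D_Qr, Ta = params$D_Talpha,
               I13 = params$D_I13)
  D_eff <- vapply(D_named, effective_diffusion, numeric(1), tensor = tensor)
  chi_eff <- effective_diffusion(params$chi_P, tensor)
  lin <- linear_decay_rates(params)
  if (is.null(dt)) {
    dt_decay <- 1.5 / max(lin)
    dt_cfl <- 2.78 / max(4 * max(D_eff) * sum(grid$K^2), 1e-12)
    dt <- if (method == "rk4") min(dt_decay, dt_cfl) / 2 else 0.02
  }
  ctx <- list(params = params, grid = grid, damage = damage, method = method,
              dt = dt, D_eff = D_eff, chi_eff = chi_eff, lin = lin,
              inflammation = inflammation, dyn = dyn,
              chemotaxis_scheme = chemotaxis_scheme)
  if (method == "etd") {
    basis <- dct_basis(grid$K)
    lam <- basis$lambda
    lap_eig <- outer(outer(lam[[1]], lam[[2]], "+"), lam[[3]], "+")
    dspec <- dyn[D_eff[dyn] > 0]
    pspec <- setdiff(dyn, dspec)
    Lam <- vapply(dspec, function(s) -lin[[s]] + D_eff[[s]] * lap_eig,
                  lap_eig)
    dim(Lam) <- c(grid$K, length(dspec))
    ctx$basis <- basis
    ctx$dspec <- dspec
    ctx$pspec <- pspec
    ctx$Lam <- Lam
    ctx <- etd_set_dt(ctx, dt)
  }
  ctx
}

## (re)build the exponential-integrator weights for a step size
etd_set_dt <- function(ctx, dt) {
  z <- ctx$Lam * dt
  ctx$dt <- dt
  ctx$E1s <- exp(z)
  ctx$P1s <- dt * phi1(z)
  ctx$P2s <- dt * phi2(z)
  coefp <- lapply(ctx$pspec, function(s) {
    zp <- -ctx$lin[[s]] * dt
    list(E1 = exp(zp), P1 = dt * phi1(zp), P2 = dt * phi2(zp))
  })
  names(coefp) <- ctx$pspec
  ctx$coefp <- coefp
  ctx
}

## stack a list of fields into a 4-D array / split it back
stack_fields <- function(state, spec, K) {
  u <- unlist(state[spec], use.names = FALSE)
  dim(u) <- c(K, length(spec))
  u
}
unstack_fields <- function(u, spec, K) {
  n <- prod(K)
  out <- vector("list", length(spec))
  names(out) <- spec
  for (i in seq_along(spec))
    out[[i]] <- array(u[((i - 1) * n + 1):(i * n)], dim = K)
  out
}

## nonlinear part N(X) = reactions + linear decay added back + chemotaxis
stepper_nonlinear <- function(ctx, state, drug) {
  rates <- reaction_rates(state, ctx$params, damage = ctx$damage, drug = drug,
                          inflammation = ctx$inflammation, check = FALSE)
  for (s in ctx$dyn) rates[[s]] <- rates[[s]] + ctx$lin[[s]] * state[[s]]
  if (ctx$chi_eff > 0)
    rates$M1 <- rates$M1 +
      chemotaxis_term(state$M1, state$P, ctx$grid, ctx$chi_eff,
                      scheme = ctx$chemotaxis_scheme)
  rates
}

## full right-hand side (for the explicit scheme)
stepper_rhs <- function(ctx, state, drug) {
  rates <- reaction_rates(state, ctx$params, damage = ctx$damage, drug = drug,
                          inflammation = ctx$inflammation, check = FALSE)
  for (s in ctx$dyn) {
    if (ctx$D_eff[[s]] > 0)
      rates[[s]] <- rates[[s]] +
        homogenized_laplacian(state[[s]], ctx$grid, ctx$D_eff[[s]])
  }
  if (ctx$chi_eff > 0)
    rates$M1 <- rates$M1 +
      chemotaxis_term(state$M1, state$P, ctx$grid, ctx$chi_eff,
                      scheme = ctx$chemotaxis_scheme)
  rates
}

clamp_state <- function(state, dyn) {
  for (s in dyn) {
    v <- state[[s]]
    if (any(v < 0)) state[[s]] <- pmax(v, 0)
  }
  state
}

#' Advance the state fields by one time step
#'
#' One step of the configured scheme (`"etd"` or `"rk4"`); used internally by
#' [simulate()] and exposed for step-level testing.
#'
#' @param state Named list of fields (one per dynamic species).
#' @param t Current time (day); enters through the drug ramp.
#' @param ctx Stepping context from the scenario (see [simulate()]).
#' @param regimen Optional [drug_regimen()].
#' @return The state fields at `t + ctx$dt`.
#' @keywords internal
#' @export
step_fields <- function(state, t, ctx, regimen = NULL) {
  if (ctx$method == "rk4") step_rk4(state, t, ctx, regimen)
  else step_etd(state, t, ctx, regimen)
}

step_rk4 <- function(state, t, ctx, regimen) {
  dt <- ctx$dt
  drug1 <- drug_modifier(regimen, t)
  drug2 <- drug_modifier(regimen, t + dt / 2)
  drug3 <- drug_modifier(regimen, t + dt)
  k1 <- stepper_rhs(ctx, state, drug1)
  s2 <- state; for (s in ctx$dyn) s2[[s]] <- state[[s]] + dt / 2 * k1[[s]]
  k2 <- stepper_rhs(ctx, s2, drug2)
  s3 <- state; for (s in ctx$dyn) s3[[s]] <- state[[s]] + dt / 2 * k2[[s]]
  k3 <- stepper_rhs(ctx, s3, drug2)
  s4 <- state; for (s in ctx$dyn) s4[[s]] <- state[[s]] + dt * k3[[s]]
  k4 <- stepper_rhs(ctx, s4, drug3)
  out <- state
  for (s in ctx$dyn)
    out[[s]] <- state[[s]] +
      dt / 6 * (k1[[s]] + 2 * k2[[s]] + 2 * k3[[s]] + k4[[s]])
  bad <- vapply(out[ctx$dyn], function(v) any(!is.finite(v)), logical(1))
  if (any(bad))
    stop("rk4 step produced non-finite values (dt = ", dt, ") in: ",
         paste(ctx$dyn[bad], collapse = ", "))
  clamp_state(out, ctx$dyn)
}

step_etd <- function(state, t, ctx, regimen) {
  dt <- ctx$dt
  K <- ctx$grid$K
  drug1 <- drug_modifier(regimen, t)
  drug2 <- drug_modifier(regimen, t + dt)
  N1 <- stepper_nonlinear(ctx, state, drug1)
  ## diffusing species: one stacked transform covers the whole set
  xhat <- dct4(stack_fields(state, ctx$dspec, K), ctx$basis)
  n1hat <- dct4(stack_fields(N1, ctx$dspec, K), ctx$basis)
  ahat <- ctx$E1s * xhat + ctx$P1s * n1hat
  a <- unstack_fields(idct4(ahat, ctx$basis), ctx$dspec, K)
  ## pointwise species: uniform linear part, no transform needed
  for (s in ctx$pspec) {
    cf <- ctx$coefp[[s]]
    a[[s]] <- cf$E1 * state[[s]] + cf$P1 * N1[[s]]
  }
  a <- clamp_state(a[ctx$dyn], ctx$dyn)
  N2 <- stepper_nonlinear(ctx, a, drug2)
  n2hat <- dct4(stack_fields(N2, ctx$dspec, K), ctx$basis)
  out <- unstack_fields(idct4(ahat + ctx$P2s * (n2hat - n1hat), ctx$basis),
                        ctx$dspec, K)
  for (s in ctx$pspec) {
    cf <- ctx$coefp[[s]]
    out[[s]] <- a[[s]] + cf$P2 * (N2[[s]] - N1[[s]])
  }
  out <- out[ctx$dyn]
  bad <- vapply(out, function(v) any(!is.finite(v)), logical(1))
  if (any(bad))
    stop("etd step produced non-finite values (dt = ", dt, ") in: ",
         paste(ctx$dyn[bad], collapse = ", "))
  clamp_state(out, ctx$dyn)
}
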