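# Independent oracles used to cross-check the implementation.  These are
# deliberately written as plain, literal transcriptions (scalar arithmetic,
# explicit loops) and share no code with the package internals.

# literal one-term-at-a-time transcription of the reaction network
oracle_rates <- function(st, p, ID = 0, inflammation = NULL) {
  H <- function(x, K) x / (K + x)
  with(as.list(st), {
    hTa <- H(Ta, p$K_Talpha); hTb <- H(Tb, p$K_Tbeta); hG <- H(G, p$K_G)
    hI <- H(I13, p$K_I13); hP <- H(P, p$K_P); hE <- H(E, p$K_E)
    r <- numeric(0)
    r["M1"] <- p$beta * hP * (p$M_0 - M1) - p$d_M1 * M1 +
      p$lambda_MT * hTa * M2 - p$lambda_M1 * M1
    r["M2"] <- p$lambda_M1 * M1 - p$d_M2 * M2 - p$lambda_MT * hTa * M2
    r["E0"] <- p$A_E0 * (1 + p$lambda_1 * E0 * ID / (p$K_D + E0 * ID)) -
      p$d_E0 * E0 * (1 + p$delta * ID + p$d_E0T * hTb) -
      p$lambda_E0 * E0 * ID
    r["E"] <- p$lambda_E0 * E0 * ID - p$lambda_EM * E * ID - p$d_E * E
    trans <- p$lambda_mfT * hTb + p$lambda_mfG * hG
    r["f"] <- p$lambda_Ef * E0 + p$lambda_fE * (hTb + hI) * hE * f -
      p$d_f * f - trans * f
    r["m"] <- trans * f - p$d_m * m
    r["rho"] <- p$lambda_rhof * f * max(1 - rho / p$rho_0, 0) +
      p$lambda_rhom * (1 + p$lambda_rhoTbeta * hTb) * m -
      p$d_rho * rho - p$d_rhoQ * Q * rho
    src_P <- if (is.null(inflammation)) p$lambda_PE * E else
      inflammation + p$lambda_PE * E
    r["P"] <- src_P - p$d_P * P - p$d_PM * hP * M1
    r["G"] <- p$lambda_GM * M2 - p$d_G * G
    r["Tb"] <- p$lambda_TbetaM * M2 * (1 + p$lambda_TbetaI13 * hI) +
      p$lambda_Tbetaf * f * hE - p$d_Tbeta * Tb
    r["Q"] <- p$lambda_QM * M2 - p$d_QQr * Qr * Q - p$d_Q * Q
    r["Qr"] <- p$lambda_QrM * M2 - p$d_QrQ * Q * Qr - p$d_Qr * Qr
    r["Ta"] <- p$lambda_TalphaM * M1 + p$lambda_TalphaE * (E + E0) -
      p$d_Talpha * Ta - p$lambda_MTalpha * hTa * M2
    r["I13"] <- p$lambda_I13 + p$lambda_I13M * M2 - p$d_I13 * I13
    r
  })
}

# random physically plausible state (positive, near typical magnitudes)
random_state <- function() {
  typ <- c(M1 = 1e-5, M2 = 1e-7, E0 = 0.8, E = 1e-2, f = 5e-3, m = 1e-3,
           rho = 3e-3, P = 1e-9, G = 1e-12, Tb = 1e-11, Q = 1e-11,
           Qr = 1e-12, Ta = 1e-8, I13 = 1e-8)
  typ * exp(stats::runif(length(typ), -1, 1))
}

# brute-force mirror-ghost Laplacian (triple loop)
oracle_laplacian <- function(u, K, coef) {
  out <- array(0, dim = K)
  at <- function(i, j, k) {
    i <- min(max(i, 1), K[1]); j <- min(max(j, 1), K[2])
    k <- min(max(k, 1), K[3])
    u[i, j, k]
  }
  for (i in 1:K[1]) for (j in 1:K[2]) for (k in 1:K[3]) {
    out[i, j, k] <- coef * (
      K[1]^2 * (at(i + 1, j, k) + at(i - 1, j, k) - 2 * u[i, j, k]) +
      K[2]^2 * (at(i, j + 1, k) + at(i, j - 1, k) - 2 * u[i, j, k]) +
      K[3]^2 * (at(i, j, k + 1) + at(i, j, k - 1) - 2 * u[i, j, k]))
  }
  out
}

# brute-force face-by-face upwind/central chemotaxis flux divergence
oracle_chemotaxis <- function(M1, P, K, chi, upwind = TRUE) {
  out <- array(0, dim = K)
  for (ax in 1:3) {
    for (i in 1:K[1]) for (j in 1:K[2]) for (k in 1:K[3]) {
      idx <- c(i, j, k)
      if (idx[ax] >= K[ax]) next
      nb <- idx; nb[ax] <- nb[ax] + 1
      vel <- chi * (P[nb[1], nb[2], nb[3]] - P[i, j, k]) * K[ax]
      mf <- if (upwind) {
        if (vel > 0) M1[i, j, k] else M1[nb[1], nb[2], nb[3]]
      } else (M1[i, j, k] + M1[nb[1], nb[2], nb[3]]) / 2
      flux <- vel * mf
      out[i, j, k] <- out[i, j, k] - flux * K[ax]
      out[nb[1], nb[2], nb[3]] <- out[nb[1], nb[2], nb[3]] + flux * K[ax]
    }
  }
  out
}

# plain scalar classical RK4 on the homogeneous reaction system
oracle_ode_rk4 <- function(x0, p, ID, dt, n_steps, inflammation = NULL) {
  x <- x0
  f <- function(s) oracle_rates(s, p, ID, inflammation)
  for (i in seq_len(n_steps)) {
    k1 <- f(x); k2 <- f(x + dt / 2 * k1)
    k3 <- f(x + dt / 2 * k2); k4 <- f(x + dt * k3)
    x <- pmax(x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0)
  }
  x
}

params_raw <- function() default_parameters(calibrated = FALSE)
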