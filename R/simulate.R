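## Disease-progression simulation on the homogenized unit cube.

#' Simulation scenario
#'
#' Bundles everything one run needs: grid, damaged region, duration,
#' parameters, effective tensor, drug regimen and integrator settings.
#'
#' @param grid A [sim_grid()] or the per-axis subdivisions (default 20).
#' @param damage A [damage_box()], or `NULL` for a healthy-control run.
#' @param duration Simulated days (default 30).
#' @param params Parameter set; default the calibrated set.
#' @param tensor Effective diffusion tensor; default [reference_tensor()],
#'   the published value used by the original disease simulations.
#' @param drug A [drug_regimen()]/[combine_regimens()] or `NULL`.
#' @param lambda_E0 Optional override of the AEC activation rate (the
#'   treatment presets use 2.5e-3 or 3e-3 per day; the baseline disease runs
#'   keep the table value).
#' @param method `"etd"` (exponential integrator, default) or `"rk4"`
#'   (explicit).
#' @param dt Time step (day); `NULL` selects the scheme default (0.02 for
#'   `"etd"`; half the stability bound for `"rk4"`).
#' @param dt_slow Optional coarser step (day) used by the `"etd"` scheme
#'   outside the fast-transient windows (the disease onset up to
#'   `slow_after` days and a margin around each drug ramp); `NULL` (default)
#'   keeps a single rate.
#' @param slow_after Day after which the slow phase may begin (default 40).
#' @param sample_every Days between recorded samples of the domain averages
#'   (default 1).
#' @param snapshot_days Times (days) at which full field snapshots are kept.
#' @param inflammation Standing residual MCP-1 production (g/(cm^3 day)),
#'   default the homeostatic value `1e-10`; the activated-AEC production
#'   `lambda_PE * E` adds to it during disease.
#' @param chemotaxis_scheme `"upwind"` (default) or `"central"`.
#' @return An object of class `ipf_scenario`.
#' @export
scenario <- function(grid = 20, damage = damage_box(edge = 0.3),
                     duration = 30, params = NULL,
                     tensor = reference_tensor(), drug = NULL,
                     lambda_E0 = NULL, method = c("etd", "rk4"), dt = NULL,
                     dt_slow = NULL, slow_after = 40,
                     sample_every = 1, snapshot_days = numeric(),
                     inflammation = homeostasis_anchors()$inflammation,
                     chemotaxis_scheme = "upwind") {
  method <- match.arg(method)
  if (!inherits(grid, "sim_grid")) grid <- sim_grid(grid)
  if (!is.null(damage) && !inherits(damage, "damage_box"))
    stop("damage must be a damage_box or NULL")
  if (is.null(params)) params <- default_parameters(calibrated = TRUE)
  if (!is.null(lambda_E0)) params <- set_param(params, "lambda_E0", lambda_E0)
  stopifnot(duration > 0, sample_every > 0)
  structure(list(grid = grid, damage = damage, duration = duration,
                 params = params, tensor = tensor, drug = drug,
                 method = method, dt = dt, dt_slow = dt_slow,
                 slow_after = slow_after, sample_every = sample_every,
                 snapshot_days = snapshot_days, inflammation = inflammation,
                 chemotaxis_scheme = chemotaxis_scheme),
            class = "ipf_scenario")
}

## fast-stepping windows: the disease onset transient and each drug ramp
fast_windows <- function(sc) {
  win <- list(c(0, sc$slow_after))
  regs <- if (is.null(sc$drug)) list()
          else if (inherits(sc$drug, "drug_combination")) sc$drug
          else list(sc$drug)
  for (r in regs)
    win <- c(win, list(c(r$start_day - 1, r$start_day + r$ramp_days + 20)))
  win
}

#' @export
print.ipf_scenario <- function(x, ...) {
  cat(sprintf("<ipf_scenario> %d x %d x %d grid, %g days, %s%s, method %s\n",
              x$grid$K[1], x$grid$K[2], x$grid$K[3], x$duration,
              if (is.null(x$damage)) "no damage"
              else sprintf("damage %.2g x %.2g x %.2g cm",
                           x$damage$edge[1], x$damage$edge[2], x$damage$edge[3]),
              if (is.null(x$drug)) "" else ", treated", x$method))
  invisible(x)
}

#' Simulate disease progression
#'
#' Integrates the homogenized reaction-diffusion-chemotaxis system from the
#' calibrated homeostatic state, with the damage indicator (and the
#' injury-associated apoptosis excess) switched on at day 0, recording the
#' domain-averaged trajectory of every species plus the scar density.
#'
#' @param sc An [scenario()].
#' @param baseline Optional precomputed `ipf_steady_state` for the scenario
#'   parameters (saves re-solving in multi-arm studies).
#' @return An object of class `ipf_sim`: list with `times` (days),
#'   `averages` (matrix, one column per species plus `"S"`), `baseline`
#'   (named homeostatic state including `S = 0`), `snapshots`, and run
#'   metadata (`method`, `dt`, `scenario`).
#' @export
simulate <- function(sc, baseline = NULL) {
  stopifnot(inherits(sc, "ipf_scenario"))
  params <- sc$params
  if (is.null(baseline)) baseline <- solve_homeostasis(params)
  if (!baseline$converged)
    stop("homeostasis solve did not converge (residual ",
         signif(baseline$residual, 3), "); calibrate the parameters first")
  grid <- sc$grid
  damage <- rasterize_damage(sc$damage, grid)
  ctx <- make_stepper(params, grid, damage, sc$tensor, method = sc$method,
                      dt = sc$dt, inflammation = sc$inflammation,
                      chemotaxis_scheme = sc$chemotaxis_scheme)
  ## an integer number of steps per sample interval
  n_per <- max(1L, ceiling(sc$sample_every / ctx$dt))
  dt_fast <- sc$sample_every / n_per
  ctx <- if (ctx$method == "etd") etd_set_dt(ctx, dt_fast) else
    within_list(ctx, dt = dt_fast)
  ## optional coarser stepping in the slow fibrotic phase (etd only)
  two_rate <- ctx$method == "etd" && !is.null(sc$dt_slow)
  if (two_rate) {
    n_per_slow <- max(1L, ceiling(sc$sample_every / sc$dt_slow))
    ctx_slow <- etd_set_dt(ctx, sc$sample_every / n_per_slow)
    windows <- fast_windows(sc)
  }
  n_samples <- ceiling(sc$duration / sc$sample_every)
  times <- seq(0, by = sc$sample_every, length.out = n_samples + 1)

  state <- lapply(baseline$state, function(v) array(v, dim = grid$K))
  names(state) <- names(baseline$state)
  avg <- matrix(NA_real_, nrow = n_samples + 1, ncol = length(.species) + 1,
                dimnames = list(NULL, c(.species, "S")))
  take_avg <- function(st) {
    a <- vapply(.species, function(s) average_concentration(st[[s]], grid),
                numeric(1))
    c(a, S = average_concentration(scar_density(st$rho, params), grid))
  }
  avg[1, ] <- take_avg(state)
  ## blow-up guard.  Some cytokines legitimately rise orders of magnitude
  ## above their (tiny) healthy baselines -- activated TGF-beta most of all,
  ## since its homeostatic level is ~2.5e-12 g/cm^3 -- so the abort
  ## threshold leaves generous headroom above both baseline and typical
  ## disease magnitudes.
  guard <- 1e6 * pmax(baseline$state, .state_typical * 1e-3)
  snapshots <- list()
  want_snap <- sc$snapshot_days
  t <- 0
  for (i in seq_len(n_samples)) {
    use_slow <- two_rate &&
      !any(vapply(windows, function(w)
        t < w[2] - 1e-9 && t + sc$sample_every > w[1] + 1e-9, logical(1)))
    ctx_i <- if (use_slow) ctx_slow else ctx
    n_i <- if (use_slow) n_per_slow else n_per
    for (k in seq_len(n_i)) {
      state <- step_fields(state, t, ctx_i, sc$drug)
      t <- t + ctx_i$dt
    }
    avg[i + 1, ] <- take_avg(state)
    if (any(avg[i + 1, .species] > guard))
      stop("instability: averaged ", paste(
        .species[avg[i + 1, .species] > guard], collapse = ", "),
        " exceeded 1000x homeostasis at day ", signif(t, 4),
        " (dt = ", ctx$dt, ")")
    if (length(want_snap) && any(abs(want_snap - t) < sc$sample_every / 2)) {
      snapshots[[sprintf("day_%g", round(t, 6))]] <- state
      want_snap <- want_snap[abs(want_snap - t) >= sc$sample_every / 2]
    }
  }
  structure(list(times = times, averages = avg,
                 baseline = c(baseline$state, S = 0),
                 snapshots = snapshots,
                 method = ctx$method, dt = ctx$dt, scenario = sc),
            class = "ipf_sim")
}

#' @export
print.ipf_sim <- function(x, ...) {
  cat(sprintf("<ipf_sim> %g days (%s, dt = %.4g), %d samples\n",
              max(x$times), x$method, x$dt, length(x$times)))
  fc <- fold_change(x)
  show <- c("M1", "M2", "E", "f", "m", "rho", "Tb", "Qr", "S")
  cat("fold-change vs homeostasis at day", max(x$times), "\n")
  print(signif(fc$ratio[show], 4))
  invisible(x)
}

within_list <- function(x, ...) utils::modifyList(x, list(...))

## averaged value of one species at the horizon (or a given day)
final_average <- function(result, species, day = NULL) {
  stopifnot(inherits(result, "ipf_sim"))
  row <- if (is.null(day)) nrow(result$averages)
         else which.min(abs(result$times - day))
  result$averages[row, species]
}

#' Fold-change of the averaged concentrations vs homeostasis
#'
#' Ratios of the domain-averaged concentrations at a given day to the
#' homeostatic baseline.  The scar (absent at baseline) and the activated
#' AEC (zero at baseline) are reported absolutely, with ratio `NA`.
#'
#' @param result An `ipf_sim` from [simulate()].
#' @param day Day at which to evaluate (default: the horizon).
#' @return List with `day`, `value` (averages), `baseline` and `ratio`
#'   (named vectors over species plus `"S"`).
#' @export
fold_change <- function(result, day = NULL) {
  stopifnot(inherits(result, "ipf_sim"))
  row <- if (is.null(day)) nrow(result$averages)
         else which.min(abs(result$times - day))
  value <- result$averages[row, ]
  base <- result$baseline[colnames(result$averages)]
  ratio <- ifelse(base > 0, value / base, NA_real_)
  names(ratio) <- colnames(result$averages)
  list(day = result$times[row], value = value, baseline = base, ratio = ratio)
}
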