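## Spatial discretization on the unit tissue cube R = [0,1]^3 (cm).
##
## Fields live at cell centers x_i = (i - 1/2)/K; zero-flux boundaries are
## realized by mirror ghost cells, which makes the discrete diffusion and
## chemotaxis operators exactly conservative (their cell sums telescope to
## zero) and is diagonalized exactly by the type-II discrete cosine basis.

#' Simulation grid on the unit cube
#'
#' @param K Subdivisions per axis: a single integer or a length-3 vector
#'   `(K1, K2, K3)`; at least 4 per axis.
#' @return An object of class `sim_grid` with the per-axis subdivisions,
#'   spacings and cell-center coordinates.
#' @export
sim_grid <- function(K = 20) {
  K <- as.integer(K)
  if (length(K) == 1L) K <- rep(K, 3L)
  if (length(K) != 3L || any(K < 4L)) stop("grid needs K >= 4 per axis")
  structure(list(K = K, h = 1 / K,
                 coords = lapply(K, function(k) (seq_len(k) - 0.5) / k)),
            class = "sim_grid")
}

#' @export
print.sim_grid <- function(x, ...) {
  cat(sprintf("<sim_grid> %d x %d x %d cells on [0,1]^3 cm\n",
              x$K[1], x$K[2], x$K[3]))
  invisible(x)
}

#' Damaged-region specification
#'
#' An axis-aligned box of damaged epithelium inside the unit cube; the
#' published scenarios use centered cubes of edge 0.3 cm (baseline, mild) or
#' 0.5 cm (severe).
#'
#' @param center Box center (cm), length 3; default the cube center.
#' @param edge Edge lengths (cm), scalar or length 3.
#' @return An object of class `damage_box`.
#' @export
damage_box <- function(center = c(0.5, 0.5, 0.5), edge = 0.3) {
  if (length(edge) == 1L) edge <- rep(edge, 3L)
  stopifnot(length(center) == 3L, length(edge) == 3L, all(edge >= 0))
  lo <- center - edge / 2; hi <- center + edge / 2
  if (any(lo < -1e-12) || any(hi > 1 + 1e-12))
    stop("damage box must lie inside the unit cube")
  structure(list(center = center, edge = edge, lo = lo, hi = hi),
            class = "damage_box")
}

#' Rasterize a damage box to a 0/1 indicator field
#'
#' Cells whose centers lie in the closed box are marked 1.
#'
#' @param box A [damage_box()], or `NULL` for no damage.
#' @param grid A [sim_grid()].
#' @return A 0/1 array of the grid dimensions.
#' @export
rasterize_damage <- function(box, grid) {
  if (is.null(box)) return(array(0, dim = grid$K))
  stopifnot(inherits(box, "damage_box"), inherits(grid, "sim_grid"))
  tol <- 1e-12
  inside <- lapply(1:3, function(ax)
    grid$coords[[ax]] >= box$lo[ax] - tol & grid$coords[[ax]] <= box$hi[ax] + tol)
  ind <- outer(outer(inside[[1]], inside[[2]], "&"), inside[[3]], "&")
  array(as.numeric(ind), dim = grid$K)
}

#' Domain average of a field
#'
#' Cell-volume-weighted mean over the unit cube (the midpoint rule, exact for
#' the cell-centered layout).
#'
#' @param field Array of grid dimensions, or a scalar.
#' @param grid A [sim_grid()].
#' @return The average (same units as `field`).
#' @export
average_concentration <- function(field, grid) {
  if (length(field) == 1L) return(as.numeric(field))
  stopifnot(all(dim(field) == grid$K))
  mean(field)
}

## mirror-shifted index vectors (ghost cell = first interior cell)
.shift_up <- function(K) c(2:K, K)
.shift_dn <- function(K) c(1, 1:(K - 1))

#' Homogenized diffusion operator
#'
#' Second-difference sum `coefficient * sum_axis K_axis^2 (u_+ + u_- - 2u)`
#' with mirror ghost cells (zero flux).  The cell sum of the output is zero
#' to rounding for any field (discrete conservation).
#'
#' @param field Array of grid dimensions.
#' @param grid A [sim_grid()].
#' @param coefficient Effective diffusion coefficient (cm^2/day), see
#'   [effective_diffusion()].
#' @return Array of the same dimensions.
#' @export
homogenized_laplacian <- function(field, grid, coefficient) {
  K <- grid$K
  if (!all(dim(field) == K)) stop("field shape does not match the grid")
  laplacian_kernel(field, K, coefficient)
}

#' Chemotaxis operator
#'
#' The discrete `-div(M1 chi_P grad P)` in conservative flux form: the face
#' flux is `chi_P * M1_face * dP/dx`, with the face density `M1_face` taken
#' from the donor (upwind) cell of the drift direction, or as the face
#' average for the central variant.  Boundary faces carry no flux, so the
#' cell sum of the output vanishes exactly (mass is moved, not created).
#'
#' @param M1 Chemotactic cell density field.
#' @param P Chemoattractant (MCP-1) field.
#' @param grid A [sim_grid()].
#' @param chi_P Effective chemotactic coefficient (cm^5/(g day)).
#' @param scheme `"upwind"` (default) or `"central"`.
#' @return Array: rate of change of `M1` due to chemotaxis (g/(cm^3 day)).
#' @export
chemotaxis_term <- function(M1, P, grid, chi_P, scheme = c("upwind", "central")) {
  scheme <- match.arg(scheme)
  K <- grid$K
  if (!all(dim(M1) == K) || !all(dim(P) == K)) stop("field shape mismatch")
  if (chi_P == 0) return(array(0, dim = K))
  chemotaxis_kernel(M1, P, K, chi_P, scheme == "upwind")
}

## --- discrete cosine basis ---------------------------------------------------
## Orthonormal DCT-II matrix whose rows are the eigenvectors of the
## mirror-ghost second-difference operator; eigenvalue of mode l (0-based)
## along an axis with K cells is -4 K^2 sin^2(pi l / (2K)).
dct_matrix <- function(K) {
  l <- seq_len(K) - 1
  i <- seq_len(K) - 0.5
  C <- sqrt(2 / K) * cos(pi * outer(l, i) / K)
  C[1, ] <- sqrt(1 / K)
  C
}

dct_eigenvalues <- function(K) -4 * K^2 * sin(pi * (seq_len(K) - 1) / (2 * K))^2

## apply M along each axis of a 3-D array (forward: M = C, inverse: M = t(C))
apply_axes <- function(u, Ms) {
  for (ax in 1:3) {
    d <- dim(u)
    u <- array(Ms[[ax]] %*% matrix(u, d[1]), c(nrow(Ms[[ax]]), d[2], d[3]))
    u <- aperm(u, c(2, 3, 1))
  }
  u
}

dct3 <- function(u, basis) apply_axes(u, basis$fwd)
idct3 <- function(u, basis) apply_axes(u, basis$inv)

## same transform applied to a stack of fields (dim (K1, K2, K3, n)),
## delegated to BLAS products along each spatial axis
apply_axes4 <- function(u, Ms) axes_transform(u, Ms[[1]], Ms[[2]], Ms[[3]])

dct4 <- function(u, basis) apply_axes4(u, basis$fwd)
idct4 <- function(u, basis) apply_axes4(u, basis$inv)

dct_basis <- function(K) {
  fwd <- lapply(K, dct_matrix)
  list(fwd = fwd, inv = lapply(fwd, t),
       lambda = lapply(K, dct_eigenvalues))
}
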