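# 1D vertex-centered grid spanning the fabric layers and the air gap.
# Nodes run from the outer-shell surface (x = 0) to the skin surface (last
# node, Dirichlet). Layer interfaces fall exactly on nodes; each interval is
# single-material, so a steady two-material slab reproduces the
# series-resistance solution exactly.

# volumetric heat capacity of the gap air, J/(m^3 K); the temperature
# dependence of rho*cp over the simulated range is ~1% and is neglected
RHO_CP_AIR <- 1.1614 * 1007

#' Build the clothing/air-gap finite-difference grid
#'
#' Discretizes the fabric layers (default spacing 5e-6 m) and the air gap
#' (default 1e-4 m; the gap field is near-linear so the fabric's 5 um step
#' would be wasteful there). Interval counts are the layer thickness over the
#' requested spacing, rounded to the nearest integer, and the actual spacing
#' is adjusted so interfaces land exactly on nodes.
#'
#' @param layers list of [fabric_layer()] objects, outermost first.
#' @param gap an [air_gap()]; size 0 omits gap nodes (liner inner surface in
#'   perfect contact with the skin).
#' @param dx_fabric_m fabric node spacing, m.
#' @param dx_gap_m gap node spacing, m.
#' @return object of class `grid1d`: node positions `x_m`, per-interval
#'   material index `mat` (1..n layers, 0 = gap), spacing `dx_m`, volumetric
#'   capacity `rho_cp`, conductivity scale `k_scale`, extinction `kappa_m1`,
#'   per-node control-volume capacities `cv_J_m2K`, radiative deposition
#'   fractions `frac_src` / `frac_gap` (+ `_skin` remainders), and the index
#'   of the liner inner-surface node `idx_liner`.
#' @export
build_grid <- function(layers, gap, dx_fabric_m = 5e-6, dx_gap_m = 1e-4) {
  stopifnot(length(layers) >= 1, inherits(gap, "air_gap"),
            dx_fabric_m > 0, dx_gap_m > 0)
  x <- 0
  mat <- integer(0); dx <- numeric(0)
  rho_cp <- numeric(0); k_scale <- numeric(0); kappa <- numeric(0)
  mix300 <- .mixture_conductivity(300)
  for (j in seq_along(layers)) {
    l <- layers[[j]]
    if (dx_fabric_m > l$thickness_m) {
      stop(sprintf("dx_fabric (%g m) exceeds the thickness of layer '%s'",
                   dx_fabric_m, l$name), call. = FALSE)
    }
    n <- max(1L, as.integer(round(l$thickness_m / dx_fabric_m)))
    h <- l$thickness_m / n
    x <- c(x, x[length(x)] + cumsum(rep(h, n)))
    mat <- c(mat, rep(j, n)); dx <- c(dx, rep(h, n))
    rho_cp <- c(rho_cp, rep(l$density_kg_m3 * l$specific_heat_J_kgK, n))
    k_scale <- c(k_scale, rep(l$conductivity_ref_W_mK / mix300, n))
    kappa <- c(kappa, rep(l$extinction_m1, n))
  }
  idx_liner <- length(x) # 1-based node index of the liner inner surface
  if (gap$size_m > 0) {
    n <- max(1L, as.integer(round(gap$size_m / dx_gap_m)))
    h <- gap$size_m / n
    x <- c(x, x[length(x)] + cumsum(rep(h, n)))
    mat <- c(mat, rep(0L, n)); dx <- c(dx, rep(h, n))
    rho_cp <- c(rho_cp, rep(RHO_CP_AIR, n))
    k_scale <- c(k_scale, rep(NA_real_, n))
    kappa <- c(kappa, rep(gap$kappa_air_m1, n))
  }
  N <- length(x)
  # per-node control volumes (half-interval each side; half cells at the ends)
  cv <- numeric(N)
  cv[1] <- rho_cp[1] * dx[1] / 2
  if (N > 2) {
    cv[2:(N - 1)] <- rho_cp[1:(N - 2)] * dx[1:(N - 2)] / 2 +
      rho_cp[2:(N - 1)] * dx[2:(N - 1)] / 2
  }
  cv[N] <- rho_cp[N - 1] * dx[N - 1] / 2
  # cumulative optical depth at control-volume faces -> exact per-CV
  # deposition fractions for the in-depth source radiation
  tau_nodes <- c(0, cumsum(kappa * dx)) # optical depth at nodes
  face_tau <- c(0, (tau_nodes[-N] + tau_nodes[-1]) / 2, tau_nodes[N])
  att <- exp(-face_tau) # length N + 1: faces bounding each node CV
  frac_src <- att[1:N] - att[2:(N + 1)]
  frac_src_skin <- att[N + 1] + frac_src[N] # transmitted + last half-cell
  frac_src[N] <- 0
  # same construction for the liner->skin gap radiation (starts at idx_liner)
  frac_gap <- numeric(N)
  frac_gap_skin <- 0
  if (gap$size_m > 0) {
    tau_g <- pmax(0, tau_nodes - tau_nodes[idx_liner])
    tau_g[seq_len(idx_liner - 1)] <- 0
    face_g <- c(0, (tau_g[-N] + tau_g[-1]) / 2, tau_g[N])
    att_g <- exp(-face_g)
    frac_gap <- att_g[1:N] - att_g[2:(N + 1)]
    frac_gap[seq_len(idx_liner)] <- 0
    frac_gap_skin <- att_g[N + 1] + frac_gap[N]
    frac_gap[N] <- 0
  }
  structure(list(
    x_m = x, mat = mat, dx_m = dx, rho_cp = rho_cp, k_scale = k_scale,
    kappa_m1 = kappa, cv_J_m2K = cv, frac_src = frac_src,
    frac_src_skin = frac_src_skin, frac_gap = frac_gap,
    frac_gap_skin = frac_gap_skin, idx_liner = idx_liner,
    n_nodes = N, has_gap = gap$size_m > 0,
    L_fab_m = x[idx_liner], L_total_m = x[N],
    layer_names = vapply(layers, `[[`, "", "name")
  ), class = "grid1d")
}

#' @export
print.grid1d <- function(x, ...) {
  cat(sprintf("<grid1d> %d nodes, fabric %.3g mm (%d nodes), gap %.3g mm%s\n",
              x$n_nodes, 1e3 * x$L_fab_m, x$idx_liner,
              1e3 * (x$L_total_m - x$L_fab_m),
              if (x$has_gap) "" else " (none)"))
  invisible(x)
}
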