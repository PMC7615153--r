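# Long-wave model: evolution of a layer of arbitrary thickness. State:
# interface radius R(z, t) and surfactant concentration Gamma(z, t), with t
# in capillary time units. The exact interface curvature is retained, which
# improves accuracy in near-static regions and permits plug formation
# (min R -> 0.3) to be tracked.

#' Construct a long-wave state
#'
#' @param R Interface radius per node, strictly inside (0, 1).
#' @param Gamma Surfactant concentration per node (non-negative).
#' @param t Unscaled time of the state (capillary units).
#' @return An object of class `long_wave_state`.
#' @export
long_wave_state <- function(R, Gamma, t = 0) {
  stopifnot(length(R) == length(Gamma), all(R > 0), all(R < 1),
            all(Gamma >= 0))
  structure(list(t = t, R = R, Gamma = Gamma),
            class = c("long_wave_state", "film_state"))
}

#' Exact interface curvature
#'
#' \eqn{\kappa = [1/R - R_{zz}/(1 + R_z^2)] / \sqrt{1 + R_z^2}}: the full
#' mean curvature of the axisymmetric interface, not its long-wave
#' linearisation.
#'
#' @param R Interface radius per node (positive).
#' @param grid A [film_grid()].
#' @return Curvature per node.
#' @examples
#' g <- film_grid(N = 64)
#' all.equal(lw_curvature(rep(0.86, g$N), g), rep(1 / 0.86, g$N))
#' @export
lw_curvature <- function(R, grid) {
  check_field(R, grid)
  if (any(R <= 0)) stop("interface radius must be positive", call. = FALSE)
  Rz <- d1(R, grid)
  Rzz <- d2(R, grid)
  m <- 1 + Rz^2
  (1 / R - Rzz / m) / sqrt(m)
}

#' Surfactant-dependent capillary pressure
#'
#' \eqn{p = -\kappa\,[1 + \mathcal{M}(1 - \Gamma)]}: the capillary pressure
#' with the linear surfactant equation of state
#' \eqn{\sigma = 1 + \mathcal{M}(1-\Gamma)}.
#'
#' @param R,Gamma Interface radius and surfactant concentration per node.
#' @param cM Marangoni number \eqn{\mathcal{M}}.
#' @param grid A [film_grid()].
#' @return Pressure per node.
#' @export
lw_pressure <- function(R, Gamma, cM, grid) {
  -lw_curvature(R, grid) * (1 + cM * (1 - Gamma))
}

# F and G auxiliaries of the flux and surface velocity. `lg` is
# log(R * Psi_plus / Psi_minus), well defined because Psi_minus >= R > 0.
lw_F <- function(R, Pm, Pp) {
  lg <- log(R * Pp / Pm)
  list(
    F1 = Pm^4 - 4 * R^2 * Pm^2 + R^4 * (3 - 4 * lg) - Pp^4 + 4 * R^2 * Pp^2 -
      4 * R^2 + 1,
    F2 = Pm^2 - R^2 - Pp^2 + 1 + 2 * R^2 * lg,
    F3 = (Pp - 1) * (-3 * R^2 + 1 + Pp + Pp^2),
    F4 = Pm^3 - 3 * R^2 * Pm + 2 * R^3
  )
}

lw_G <- function(R, Pm, Pp) {
  lg <- log(R * Pp / Pm)
  list(
    G1 = R^2 + Pp^2 - Pm^2 - 1 - 2 * R^2 * lg,
    G2 = lg,
    G3 = 1 - Pp,
    G4 = R - Pm
  )
}

# Branch indicator shared by flux and surface velocity: the same stress
# ratio s = 2 M Gamma_z / (R pz) that selects the psi branches.
lw_branch <- function(R, pz, MGz) {
  pz0 <- abs(pz) < PZ_FLOOR
  s <- ifelse(pz0, 0, 2 * MGz / (R * pz))
  list(pz0 = pz0, upper = !pz0 & s >= 1)
}

#' Long-wave axial volume flux
#'
#' The axial volume flux through the layer, assembled from the annular
#' velocity profile of the Bingham fluid between the (regularised) yield
#' surfaces. With \eqn{\mathcal{M} = 0} it reduces to the surfactant-free
#' viscoplastic flux, and in the thin-film limit it agrees with
#' \eqn{\epsilon^4 q} to leading order in \eqn{\epsilon}.
#'
#' @param R Interface radius per node.
#' @param p Pressure per node (from [lw_pressure()]).
#' @param Gamma Surfactant concentration per node.
#' @param params A [long_wave_params()].
#' @param grid A [film_grid()].
#' @param regularise Cap the yield surfaces at `1 - Y_min` before flux
#'   evaluation (as the time integrator does).
#' @return Flux `Q` per node (zero at both ends).
#' @export
lw_flux <- function(R, p, Gamma, params, grid, regularise = TRUE) {
  f <- lw_fields_core(R, p, Gamma, params, grid, regularise)
  f$Q
}

#' Long-wave surface velocity
#'
#' Axial velocity of the gas-liquid interface, which advects the surfactant.
#'
#' @inheritParams lw_flux
#' @return Surface velocity `ws` per node (zero at both ends).
#' @export
lw_surface_velocity <- function(R, p, Gamma, params, grid, regularise = TRUE) {
  f <- lw_fields_core(R, p, Gamma, params, grid, regularise)
  f$ws
}

#' Long-wave wall shear stress
#'
#' \eqn{\tau_w = \tfrac{p_z}{2}(1 - R^2) + R\,\mathcal{M}\Gamma_z}: the
#' shear stress exerted on the tube wall. At stations classified as fully
#' rigid its magnitude never exceeds \eqn{\mathcal{B}}.
#'
#' @param R,Gamma Interface radius and surfactant concentration per node.
#' @param p Pressure per node.
#' @param cM Marangoni number.
#' @param grid A [film_grid()].
#' @return Wall stress per node.
#' @export
lw_wall_stress <- function(R, p, Gamma, cM, grid) {
  pz <- d1(p, grid)
  pz / 2 * (1 - R^2) + R * cM * d1(Gamma, grid)
}

# All pointwise long-wave fields from (R, Gamma).
lw_fields_core <- function(R, p, Gamma, params, grid, regularise = TRUE) {
  check_field(R, grid)
  pz <- d1(p, grid)
  Gz <- d1(Gamma, grid)
  MGz <- params$cM * Gz
  surf <- lw_yield_surfaces(R, pz, MGz, params$cB)
  Pm <- surf$Psi_minus
  Pp <- surf$Psi_plus
  if (regularise) {
    Pm <- pmin(1 - params$Y_min, Pm)
    Pp <- pmin(1 - params$Y_min, Pp)
  }
  Fa <- lw_F(R, Pm, Pp)
  Ga <- lw_G(R, Pm, Pp)
  br <- lw_branch(R, pz, MGz)
  sgn_pz <- sign(pz)
  s34 <- ifelse(br$upper, Fa$F3 - Fa$F4, Fa$F3 + Fa$F4)
  Q <- -pz / 16 * Fa$F1 - R * MGz / 4 * Fa$F2 - params$cB / 6 * sgn_pz * s34
  g34 <- ifelse(br$upper, Ga$G3 - Ga$G4, Ga$G3 + Ga$G4)
  ws <- pz / 4 * Ga$G1 + R * MGz * Ga$G2 + params$cB * sgn_pz * g34
  if (any(br$pz0)) {
    i <- which(br$pz0)
    sgn_G <- sign(Gz[i])
    Q[i] <- -R[i] * MGz[i] / 4 * Fa$F2[i] + params$cB / 6 * sgn_G * Fa$F4[i]
    ws[i] <- R[i] * MGz[i] * Ga$G2[i] - params$cB * sgn_G * Ga$G4[i]
  }
  Q[c(1L, grid$N)] <- 0
  ws[c(1L, grid$N)] <- 0
  list(pz = pz, Gz = Gz, MGz = MGz, surfaces = surf, Q = Q, ws = ws)
}

#' Long-wave diagnostic fields
#'
#' Computes all pointwise fields of the long-wave model from a state:
#' curvature, surface tension, pressure and its gradient, yield surfaces,
#' flux, surface velocity and wall stress.
#'
#' @param state A [long_wave_state()].
#' @param params A [long_wave_params()].
#' @param grid A [film_grid()].
#' @param regularise Cap the yield surfaces before flux evaluation.
#' @return A list with fields `kappa`, `sigma`, `p`, `pz`, `Gz`, `MGz`,
#'   `surfaces`, `Q`, `ws`, `tau_w`.
#' @export
lw_fields <- function(state, params, grid, regularise = TRUE) {
  R <- state$R
  Gamma <- state$Gamma
  kappa <- lw_curvature(R, grid)
  sigma <- 1 + params$cM * (1 - Gamma)
  p <- -kappa * sigma
  f <- lw_fields_core(R, p, Gamma, params, grid, regularise)
  c(list(kappa = kappa, sigma = sigma, p = p,
         tau_w = f$pz / 2 * (1 - R^2) + R * f$MGz), f)
}

#' Long-wave evolution tendencies
#'
#' Right-hand side of the long-wave system. The state variables integrated
#' are `R` and the conserved surface density `RGamma`, so both conservation
#' laws hold discretely: \eqn{R_t = Q_z / R} conserves the liquid volume
#' \eqn{\int (1 - R^2)\,dz}, and \eqn{(R\Gamma)_t = -(w_s R \Gamma)_z}
#' conserves the total surfactant \eqn{\int R\Gamma\,dz}.
#'
#' @param state A [long_wave_state()].
#' @param params A [long_wave_params()].
#' @param grid A [film_grid()].
#' @return A list with fields `dR` and `dRGamma`.
#' @export
lw_rhs <- function(state, params, grid) {
  check_field(state$R, grid)
  if (any(state$R <= 0) || any(state$R >= 1))
    stop("interface radius left (0, 1) during evolution", call. = FALSE)
  d <- lw_rhs_core(state$R, state$R * state$Gamma, params, grid)
  if (!all(is.finite(d$dR)) || !all(is.finite(d$dRGamma)))
    stop("non-finite fields in long-wave right-hand side", call. = FALSE)
  d
}

#' Strong-surfactant diagnostics for a long-wave run
#'
#' In the limit of large Marangoni number the surfactant concentration is
#' spatially uniform at leading order, set by conservation of the total
#' amount of surfactant over a changing interfacial measure:
#' \eqn{\mathcal{G}_0(t) = \int R|_{t=0} dz / \int R\,dz}. The leading-order
#' surface velocity \eqn{\mathcal{W}_0} follows from the difference between
#' the local rate of change of the interface and its global average; it is
#' generic for any rheology and any equation of state with
#' \eqn{\sigma'(\Gamma) \neq 0}. Time derivatives are estimated by finite
#' differencing of the stored profiles.
#'
#' @param R_series Matrix of interface profiles, one column per stored time
#'   (at least 2 columns).
#' @param times Unscaled times of the columns.
#' @param grid A [film_grid()].
#' @return A list with `times`, `G0` (per time), `W0` and `I_field`
#'   (node-by-time matrices).
#' @export
lw_largeM_diagnostics <- function(R_series, times, grid) {
  R_series <- as.matrix(R_series)
  nt <- ncol(R_series)
  if (nt < 2L)
    stop("need at least 2 stored profiles to difference in time",
         call. = FALSE)
  stopifnot(length(times) == nt, nrow(R_series) == grid$N)
  int_R <- apply(R_series, 2L, grid_integral, grid = grid)
  G0 <- int_R[1L] / int_R
  # centred differences in time (one-sided at the ends)
  dtR <- R_series
  for (j in seq_len(nt)) {
    jm <- max(1L, j - 1L)
    jp <- min(nt, j + 1L)
    dtR[, j] <- (R_series[, jp] - R_series[, jm]) / (times[jp] - times[jm])
  }
  int_dtR <- apply(dtR, 2L, grid_integral, grid = grid)
  I_field <- W0 <- matrix(0, grid$N, nt)
  for (j in seq_len(nt)) {
    I_field[, j] <- (R_series[, j] * int_dtR[j] - dtR[, j] * int_R[j]) /
      int_R[j]
    W0[, j] <- grid_cumintegral(I_field[, j], grid) / R_series[, j]
  }
  list(times = times, G0 = G0, W0 = W0, I_field = I_field)
}
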