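# Thin-film model: evolution of a surfactant-laden viscoplastic film whose
# thickness is a small fraction of the tube radius. State: scaled thickness
# H(z, t~) and surfactant concentration Gamma(z, t~), with t~ the thin-film
# time. Driving: linearised capillary pressure gradient and Marangoni stress.

#' Construct a thin-film state
#'
#' @param H Scaled layer thickness per node (positive).
#' @param Gamma Surfactant concentration per node (non-negative).
#' @param t_tilde Thin-film time of the state.
#' @return An object of class `thin_film_state`.
#' @export
thin_film_state <- function(H, Gamma, t_tilde = 0) {
  stopifnot(length(H) == length(Gamma), all(H > 0), all(Gamma >= 0))
  structure(list(t = t_tilde, H = H, Gamma = Gamma),
            class = c("thin_film_state", "film_state"))
}

#' Thin-film capillary pressure gradient
#'
#' \eqn{\tilde p_z = -H_z - H_{zzz}}: the linearised capillary pressure
#' gradient, combining the destabilising azimuthal curvature with the
#' stabilising axial curvature. Vanishes exactly at both domain ends under
#' the symmetry boundary conditions.
#'
#' @param H Layer thickness per node.
#' @param grid A [film_grid()].
#' @return \eqn{\tilde p_z} per node.
#' @examples
#' g <- film_grid(N = 128)
#' # a full-wavelength mode (k = 1) has neutral curvature: pz == 0
#' max(abs(tf_pressure_gradient(1 - 0.1 * cos(g$z), g))) < 1e-10
#' @export
tf_pressure_gradient <- function(H, grid) {
  -d1(H, grid) - d3(H, grid)
}

# Shared algebra for flux and surface velocity. Takes regularised (floored)
# yield surfaces; `sgn_pz` is pz/|pz| with the pz-floor convention.
tf_flux_from_surfaces <- function(H, pz, MGz, B, Ym, Yp) {
  pz0 <- abs(pz) < PZ_FLOOR
  sgn_pz <- sign(pz)
  hm <- H - Ym
  hp <- H - Yp
  q <- -pz / 3 * (H^3 + hp^3 - hm^3) -
    MGz / 2 * (H^2 - hm^2 + hp^2) +
    B / 2 * sgn_pz * (H^2 - hm^2 - hp^2)
  if (any(pz0)) {
    mar <- abs(MGz) > B
    q[pz0] <- ifelse(mar[pz0],
                     -0.5 * sign(MGz[pz0]) * H[pz0]^2 * (abs(MGz[pz0]) - B),
                     0)
  }
  q
}

tf_ws_from_surfaces <- function(H, pz, MGz, B, Ym, Yp) {
  pz0 <- abs(pz) < PZ_FLOOR
  sgn_pz <- sign(pz)
  hm <- H - Ym
  hp <- H - Yp
  ws <- -pz / 2 * (H^2 + hp^2 - hm^2) -
    MGz * (H + Ym - Yp) -
    B * sgn_pz * (H - Ym - Yp)
  if (any(pz0)) {
    mar <- abs(MGz) > B
    ws[pz0] <- ifelse(mar[pz0],
                      -sign(MGz[pz0]) * H[pz0] * (abs(MGz[pz0]) - B),
                      0)
  }
  ws
}

#' Thin-film diagnostic fields
#'
#' Computes, from a thickness and concentration profile, all the pointwise
#' fields of the thin-film model: pressure gradient, yield surfaces (clipped
#' and regularised), axial volume flux, surface velocity and wall shear
#' stress. [tf_flux()], [tf_surface_velocity()] and [tf_wall_stress()] are
#' thin wrappers returning single fields.
#'
#' @param H,Gamma Thickness and surfactant concentration per node.
#' @param params A [thin_film_params()].
#' @param grid A [film_grid()].
#' @param regularise Apply the `Y_min` floor to the yield surfaces before
#'   evaluating fluxes (as the time integrator does).
#' @return A list with fields `pz`, `MGz`, `surfaces` (a
#'   [tf_yield_surfaces()] object), `q`, `ws`, `tau_w`.
#' @export
tf_fields <- function(H, Gamma, params, grid, regularise = TRUE) {
  check_field(H, grid)
  check_field(Gamma, grid)
  pz <- tf_pressure_gradient(H, grid)
  MGz <- params$M * d1(Gamma, grid)
  surf <- tf_yield_surfaces(H, pz, MGz, params$B)
  Ym <- surf$Y_minus
  Yp <- surf$Y_plus
  if (regularise) {
    Ym <- pmax(params$Y_min, Ym)
    Yp <- pmax(params$Y_min, Yp)
  }
  q <- tf_flux_from_surfaces(H, pz, MGz, params$B, Ym, Yp)
  ws <- tf_ws_from_surfaces(H, pz, MGz, params$B, Ym, Yp)
  q[c(1L, grid$N)] <- 0
  ws[c(1L, grid$N)] <- 0
  list(pz = pz, MGz = MGz, surfaces = surf, q = q, ws = ws,
       tau_w = H * pz + MGz)
}

#' Thin-film axial volume flux
#'
#' The scaled axial volume flux of the film, assembled from the cubic
#' contributions of the two fully-yielded regions and the plug-like region
#' between the (regularised) yield surfaces. Reduces to the Newtonian
#' lubrication flux \eqn{-\tilde p_z H^3/3 - M\Gamma_z H^2/2} when `B = 0`.
#'
#' @inheritParams tf_fields
#' @return Flux `q` per node (zero at both ends).
#' @export
tf_flux <- function(H, Gamma, params, grid, regularise = TRUE) {
  tf_fields(H, Gamma, params, grid, regularise)$q
}

#' Thin-film surface velocity
#'
#' The axial velocity of the interface. Vanishes identically where the layer
#' is rigid and wherever \eqn{H\tilde p_z = -2 M \Gamma_z}, the interface
#' immobilisation condition on which Marangoni and capillary shear balance.
#'
#' @inheritParams tf_fields
#' @return Surface velocity per node (zero at both ends).
#' @export
tf_surface_velocity <- function(H, Gamma, params, grid, regularise = TRUE) {
  tf_fields(H, Gamma, params, grid, regularise)$ws
}

#' Thin-film wall shear stress
#'
#' \eqn{\tilde\tau_w = H \tilde p_z + M \Gamma_z}. In unstable runs that
#' approach the marginally-yielded static shape, \eqn{\max_z|\tilde\tau_w|}
#' tends to `B` at late times.
#'
#' @inheritParams tf_fields
#' @return Wall stress per node.
#' @export
tf_wall_stress <- function(H, Gamma, params, grid) {
  check_field(H, grid)
  H * tf_pressure_gradient(H, grid) + params$M * d1(Gamma, grid)
}

#' Thin-film evolution tendencies
#'
#' Right-hand side of the thin-film system in conservative form:
#' \eqn{H_{\tilde t} = -q_z} and
#' \eqn{\Gamma_{\tilde t} = -(\tilde w_s \Gamma)_z}, evaluated on the
#' staggered flux grid used by [evolve()] (fluxes at cell faces, zero at the
#' domain ends). The quadrature-weighted sums of both tendencies vanish to
#' round-off, so \eqn{\int H\,dz} and \eqn{\int\Gamma\,dz} are conserved
#' discretely.
#'
#' @param state A [thin_film_state()].
#' @param params A [thin_film_params()].
#' @param grid A [film_grid()].
#' @return A list with fields `dH` and `dGamma` (tendencies per node).
#' @export
tf_rhs <- function(state, params, grid) {
  check_field(state$H, grid)
  d <- tf_rhs_core(state$H, state$Gamma, params, grid)
  if (!all(is.finite(d$dH)) || !all(is.finite(d$dGamma)))
    stop("non-finite fields in thin-film right-hand side", call. = FALSE)
  d
}

#' Strong-surfactant (immobilised-interface) thin-film tendency
#'
#' Evolution of the thickness in the limit of asymptotically strong
#' surfactant, where the interface is immobilised and the concentration is
#' not evolved: \eqn{H_{\tilde t} + [\tfrac16 \tilde p_z \tilde Y^2 (2\tilde
#' Y - 3H)]_z = 0} with \eqn{\tilde Y = \max(0, H/2 - B/|\tilde p_z|)}.
#' Replacing `B` with `B/2` and slowing time by a factor of four reproduces
#' the surfactant-free dynamics exactly, so strong surfactant doubles the
#' effective capillary Bingham number and quarters the mobility.
#'
#' @param state A [thin_film_state()] (only `H` is used).
#' @param params A [thin_film_params()] (only `B` and `Y_min` are used).
#' @param grid A [film_grid()].
#' @return A list with field `dH`.
#' @export
tf_largeM_rhs <- function(state, params, grid) {
  check_field(state$H, grid)
  tf_largeM_rhs_core(state$H, params, grid)
}
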