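# Staggered conservative spatial discretisation used for time evolution.
#
# Scalar fields (H or R, Gamma) live at the N nodes including both
# endpoints; fluxes are evaluated at the N-1 cell faces from second-order
# compact differences and face averages, and each node tendency is the
# divergence of its two adjacent face fluxes (half cells at the ends, where
# the boundary flux is zero). This face-flux form is exactly conservative
# under trapezoidal quadrature and - unlike a collocated central divergence,
# whose response to the 2-dz mode vanishes (odd-even decoupling) - damps
# grid-scale noise, which matters because the yield-surface switching can
# otherwise pump a neutrally-stable checkerboard mode.

# divergence of face fluxes (length N-1) with zero boundary flux
face_div <- function(qf, grid) {
  N <- grid$N
  c(2 * qf[1L], qf[-1L] - qf[-(N - 1L)], -2 * qf[N - 2L + 1L]) / grid$dz
}

# face-centred first difference of a nodal field
face_diff <- function(f, grid) diff(f) / grid$dz

face_avg <- function(f) (f[-1L] + f[-length(f)]) / 2

# upwind-limited face value for an advected density: the surfactant
# gradient steepens into near-shocks, and a centred face average traps
# dispersive over/undershoots there (the transport has no diffusion to
# remove them). A second-order reconstruction with a minmod-limited slope
# keeps the profile monotone at the front while preserving the steep
# gradients that set the Marangoni stresses.
face_upwind <- function(f, vel_f) {
  n <- length(f)
  df <- diff(f)                      # increments at the n-1 faces
  dfe <- c(0, df, 0)                 # zero-slope ghosts (zero-flux ends)
  minmod <- function(a, b) ifelse(a * b <= 0, 0,
                                  ifelse(abs(a) < abs(b), a, b))
  slope <- minmod(dfe[-(n + 1L)], dfe[-1L]) # limited slope at each node
  ifelse(vel_f >= 0,
         f[-n] + 0.5 * slope[-n],
         f[-1L] - 0.5 * slope[-1L])
}

# Thin-film tendencies on the staggered grid.
tf_rhs_core <- function(H, G, params, grid) {
  B <- params$B
  H <- pmax(H, 1e-6)
  phi <- H + d2(H, grid) # capillary potential: p~ = -(H + Hzz)
  pzf <- -face_diff(phi, grid)
  Hf <- face_avg(H)
  MGzf <- params$M * face_diff(G, grid)
  s <- tf_yield_surfaces(Hf, pzf, MGzf, B, classify = FALSE)
  Ym <- pmax(params$Y_min, s$Y_minus)
  Yp <- pmax(params$Y_min, s$Y_plus)
  qf <- tf_flux_from_surfaces(Hf, pzf, MGzf, B, Ym, Yp)
  wsf <- tf_ws_from_surfaces(Hf, pzf, MGzf, B, Ym, Yp)
  list(dH = -face_div(qf, grid),
       dGamma = -face_div(wsf * face_upwind(G, wsf), grid))
}

# Strong-surfactant (immobilised interface) thin-film tendency.
tf_largeM_rhs_core <- function(H, params, grid) {
  H <- pmax(H, 1e-6)
  phi <- H + d2(H, grid)
  pzf <- -face_diff(phi, grid)
  Hf <- face_avg(H)
  apz <- pmax(abs(pzf), PZ_FLOOR)
  Y <- pmax(params$Y_min, Hf / 2 - params$B / apz)
  qf <- pzf / 6 * Y^2 * (2 * Y - 3 * Hf)
  list(dH = -face_div(qf, grid))
}

# Long-wave tendencies on the staggered grid; state (R, R*Gamma).
# Trial states proposed by the integrator can leave the physical range
# (0, 1); fluxes are evaluated on a clamped copy so they stay finite and
# the step-size control can recover.
lw_rhs_core <- function(R, RG, params, grid) {
  cB <- params$cB
  cM <- params$cM
  R <- pmin(pmax(R, 0.02), 1 - 1e-9)
  G <- RG / R
  Rz <- d1(R, grid)
  m <- 1 + Rz^2
  kappa <- (1 / R - d2(R, grid) / m) / sqrt(m)
  p <- -kappa * (1 + cM * (1 - G))
  pzf <- face_diff(p, grid)
  Rf <- face_avg(R)
  Gzf <- face_diff(G, grid)
  MGzf <- cM * Gzf
  s <- lw_yield_surfaces(Rf, pzf, MGzf, cB, classify = FALSE)
  Pm <- pmin(1 - params$Y_min, s$Psi_minus)
  Pp <- pmin(1 - params$Y_min, s$Psi_plus)
  Fa <- lw_F(Rf, Pm, Pp)
  Ga <- lw_G(Rf, Pm, Pp)
  br <- lw_branch(Rf, pzf, MGzf)
  sgn_pz <- sign(pzf)
  Qf <- -pzf / 16 * Fa$F1 - Rf * MGzf / 4 * Fa$F2 -
    cB / 6 * sgn_pz * ifelse(br$upper, Fa$F3 - Fa$F4, Fa$F3 + Fa$F4)
  wsf <- pzf / 4 * Ga$G1 + Rf * MGzf * Ga$G2 +
    cB * sgn_pz * ifelse(br$upper, Ga$G3 - Ga$G4, Ga$G3 + Ga$G4)
  if (any(br$pz0)) {
    i <- which(br$pz0)
    sg <- sign(Gzf[i])
    Qf[i] <- -Rf[i] * MGzf[i] / 4 * Fa$F2[i] + cB / 6 * sg * Fa$F4[i]
    wsf[i] <- Rf[i] * MGzf[i] * Ga$G2[i] - cB * sg * Ga$G4[i]
  }
  list(dR = face_div(Qf, grid) / R,
       dRGamma = -face_div(wsf * face_upwind(RG, wsf), grid))
}
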