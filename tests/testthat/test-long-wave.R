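test_that("curvature matches the closed form", {
  g <- tiny_grid()
  expect_equal(lw_curvature(rep(0.86, g$N), g), rep(1 / 0.86, g$N),
               tolerance = 1e-12)
  g2 <- film_grid(2 * pi, 200)
  R <- 0.9 - 0.05 * cos(g2$z / 2)
  Rz <- 0.025 * sin(g2$z / 2)
  Rzz <- 0.0125 * cos(g2$z / 2)
  exact <- (1 / R - Rzz / (1 + Rz^2)) / sqrt(1 + Rz^2)
  expect_lt(max(abs(lw_curvature(R, g2) - exact)), 1e-5) # O(dz^2)
  expect_error(lw_curvature(rep(-1, g$N), g), "positive")
})

test_that("pressure combines curvature with the surfactant equation of state", {
  g <- tiny_grid()
  R <- rep(0.8, g$N)
  expect_equal(lw_pressure(R, rep(1, g$N), cM = 0.5, g), rep(-1 / 0.8, g$N))
  expect_equal(lw_pressure(R, rep(0.3, g$N), cM = 0, g), rep(-1 / 0.8, g$N))
  expect_equal(lw_pressure(R, rep(0.9, g$N), cM = 0.02, g),
               rep(-1.002 / 0.8, g$N), tolerance = 1e-12)
})

test_that("rigid layers carry no flux; flat states are equilibria", {
  g <- tiny_grid()
  st <- manufactured_lw_state(g, amp = 0.02, gamp = 0.001)
  p <- long_wave_params(cB = 10, cM = 0.01, eps = 0.2)
  f <- lw_fields(st, p, g)
  expect_true(all(f$surfaces$regime == "V"))
  expect_lt(max(abs(f$Q)), 1e-6)
  flat <- long_wave_state(rep(0.8, g$N), rep(1, g$N))
  r <- lw_rhs(flat, long_wave_params(cB = 0.01, cM = 0.5, eps = 0.2), g)
  expect_lt(max(abs(r$dR)), 1e-12)
  expect_lt(max(abs(r$dRGamma)), 1e-12)
})

test_that("surfactant-free reduction and rigid-node stress consistency", {
  g <- tiny_grid(96L)
  st <- manufactured_lw_state(g, gamp = 0.08)
  p0 <- long_wave_params(cB = 0.01, cM = 0, eps = 0.2)
  f0 <- lw_fields(st, p0, g)
  # with cM = 0 the interface-adjacent fully-yielded region is absent
  expect_equal(f0$surfaces$Psi_minus, st$R)
  # wall stress never exceeds the yield stress at fully rigid stations
  p1 <- long_wave_params(cB = 0.05, cM = 0.3, eps = 0.2)
  f1 <- lw_fields(st, p1, g)
  rigid <- f1$surfaces$regime == "V"
  if (any(rigid)) expect_true(all(abs(f1$tau_w[rigid]) <= p1$cB + 1e-12))
})

test_that("tendencies conserve volume and surfactant discretely", {
  g <- tiny_grid(96L)
  w <- trap_w(g)
  st <- manufactured_lw_state(g)
  p <- long_wave_params(cB = 0.01, cM = 0.5, eps = 0.2)
  r <- lw_rhs(st, p, g)
  # volume: d/dt int (1 - R^2) = -2 int R dR/dt
  expect_lt(abs(sum(w * 2 * st$R * r$dR)), 1e-13)
  expect_lt(abs(sum(w * r$dRGamma)), 1e-13)
})

test_that("long-wave fluxes agree with thin-film fluxes as eps -> 0", {
  g <- film_grid(2 * pi, 200)
  B <- 0.04; M <- 0.2
  H <- 1 - 0.3 * cos(pi * g$z / g$L)
  Gam <- 1 + 0.05 * cos(pi * g$z / g$L)
  tfp <- thin_film_params(B = B, M = M)
  ftf <- tf_fields(H, Gam, tfp, g, regularise = FALSE)
  err <- sapply(c(3e-3, 1e-3), function(eps) {
    lwp <- long_wave_params(cB = eps^2 * B, cM = eps^2 * M, eps = eps)
    stl <- long_wave_state(1 - eps * H, Gam)
    flw <- lw_fields(stl, lwp, g, regularise = FALSE)
    c(Q = max(abs(flw$Q / eps^4 - ftf$q)) / max(abs(ftf$q)),
      ws = max(abs(flw$ws / eps^3 - ftf$ws)) / max(abs(ftf$ws)),
      tw = max(abs(flw$tau_w / eps^2 - ftf$tau_w)) / max(abs(ftf$tau_w)))
  })
  expect_lt(err["Q", 2], 0.01)
  expect_lt(err["ws", 2], 0.01)
  expect_lt(err["tw", 2], 0.01)
  # errors shrink linearly with eps
  expect_gt(err["Q", 1] / err["Q", 2], 2)
})

test_that("strong-surfactant diagnostics recover conservation and stasis", {
  g <- tiny_grid()
  # static series: G0 constant at 1, W0 identically zero
  R <- matrix(0.8, g$N, 3)
  d <- lw_largeM_diagnostics(R, times = c(0, 1, 2), g)
  expect_equal(d$G0, rep(1, 3))
  expect_lt(max(abs(d$W0)), 1e-12)
  expect_error(lw_largeM_diagnostics(R[, 1, drop = FALSE], 0, g), "at least 2")
  # a uniformly contracting interface raises G0 by the area ratio
  R2 <- cbind(rep(0.8, g$N), rep(0.72, g$N))
  d2 <- lw_largeM_diagnostics(R2, times = c(0, 1), g)
  expect_equal(d2$G0[2], 0.8 / 0.72, tolerance = 1e-12)
  # and (being spatially uniform) still induces no surface velocity
  expect_lt(max(abs(d2$W0)), 1e-10)
})
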