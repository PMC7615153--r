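test_that("pressure gradient matches the analytic curvature gradient", {
  g <- film_grid(2 * pi, 128)
  expect_lt(max(abs(tf_pressure_gradient(rep(1.3, g$N), g))), 1e-13)
  # H = 1 - 0.2 cos(kz), k = 1/2: pz = -0.2 (k - k^3) sin(kz), driving
  # flux from the depression towards the peak
  H <- 1 - 0.2 * cos(g$z / 2)
  pz <- tf_pressure_gradient(H, g)
  exact <- -0.2 * (1 / 2 - (1 / 2)^3) * sin(g$z / 2)
  expect_lt(max(abs(pz - exact)), 2e-4) # O(dz^2)
  # a k = 1 mode is curvature-neutral (to discretisation accuracy)
  expect_lt(max(abs(tf_pressure_gradient(1 - 0.2 * cos(g$z), g))), 1e-4)
})

test_that("flux and surface velocity reduce correctly when B = 0", {
  g <- tiny_grid()
  st <- manufactured_tf_state(g)
  H <- st$H; Gam <- st$Gamma
  p0 <- thin_film_params(B = 0, M = 0, A = 0.3)
  pz <- tf_pressure_gradient(H, g)
  q0 <- tf_flux(H, Gam, p0, g, regularise = FALSE)
  expect_equal(q0, -pz * H^3 / 3, tolerance = 1e-12)
  pM <- thin_film_params(B = 0, M = 0.5, A = 0.3)
  MGz <- pM$M * d1(Gam, g)
  expect_equal(tf_flux(H, Gam, pM, g, regularise = FALSE),
               -pz * H^3 / 3 - MGz * H^2 / 2, tolerance = 1e-12)
  expect_equal(tf_surface_velocity(H, Gam, pM, g, regularise = FALSE),
               -pz * H^2 / 2 - MGz * H, tolerance = 1e-12)
})

test_that("rigid layers carry no flux and flat states are equilibria", {
  g <- tiny_grid()
  st <- manufactured_tf_state(g, amp = 0.01, gamp = 0.001)
  p <- thin_film_params(B = 5, M = 0.01, A = 0.01) # far below yield
  f <- tf_fields(st$H, st$Gamma, p, g)
  expect_true(all(f$surfaces$regime == "V"))
  expect_lt(max(abs(f$q)), 1e-6) # only the Y_min creep remains
  flat <- thin_film_state(rep(1, g$N), rep(1, g$N))
  r <- tf_rhs(flat, thin_film_params(B = 0.04, M = 0.2), g)
  expect_lt(max(abs(r$dH)), 1e-13)
  expect_lt(max(abs(r$dGamma)), 1e-13)
})

test_that("wall stress is the sum of capillary and Marangoni tractions", {
  g <- tiny_grid()
  st <- manufactured_tf_state(g)
  p <- thin_film_params(B = 0.04, M = 0.2)
  tw <- tf_wall_stress(st$H, st$Gamma, p, g)
  expect_equal(tw, st$H * tf_pressure_gradient(st$H, g) +
                 p$M * d1(st$Gamma, g))
  expect_lt(max(abs(tf_wall_stress(rep(1, g$N), rep(1, g$N), p, g))), 1e-13)
})

test_that("tendencies conserve mass and surfactant discretely", {
  g <- tiny_grid(96L)
  w <- trap_w(g)
  st <- manufactured_tf_state(g)
  p <- thin_film_params(B = 0.04, M = 0.2)
  r <- tf_rhs(st, p, g)
  expect_lt(abs(sum(w * r$dH)), 1e-14)
  expect_lt(abs(sum(w * r$dGamma)), 1e-14)
  rl <- tf_largeM_rhs(st, p, g)
  expect_lt(abs(sum(w * rl$dH)), 1e-14)
})

test_that("the initial perturbation yields only away from the ends", {
  g <- film_grid(2 * pi, 200)
  st <- initial_condition_tf(0.2, g)
  p <- thin_film_params(B = 0.04, M = 0.2, A = 0.2)
  f <- tf_fields(st$H, st$Gamma, p, g)
  reg <- as.character(f$surfaces$regime)
  expect_true(all(reg[c(1:3, (g$N - 2):g$N)] == "V")) # rigid at the ends
  expect_true(any(reg != "V")) # yielded patch in the interior
  mid <- reg[50:150]
  expect_true(mean(mid != "V") > 0.5)
})

test_that("strong-surfactant limit quarters the Newtonian mobility", {
  g <- tiny_grid()
  st <- manufactured_tf_state(g, gamp = 0)
  p0 <- thin_film_params(B = 0, M = 0, A = 0.3, Y_min = 1e-12)
  # compare tendencies: immobilised-interface flux = -pz H^3/12
  r <- tf_largeM_rhs(st, p0, g)
  H <- st$H
  phi <- H + d2(H, g)
  pzf <- -diff(phi) / g$dz
  Hf <- (H[-1] + H[-g$N]) / 2
  qf <- -pzf * Hf^3 / 12
  expect_equal(r$dH, -vpfilm:::face_div(qf, g), tolerance = 1e-10)
  # fully rigid when B dominates
  pB <- thin_film_params(B = 10, M = 0, A = 0.3)
  r2 <- tf_largeM_rhs(st, pB, g)
  expect_lt(max(abs(r2$dH)), 1e-6)
})

test_that("doubled-B time-slowed mapping holds along trajectories", {
  # strong-surfactant trajectories at (B, t) coincide with surfactant-free
  # trajectories at (2B, 4t)
  g <- film_grid(2 * pi, 64)
  A <- 0.3
  st <- initial_condition_tf(A, g)
  tt <- c(0, 10, 25, 40)
  rM <- evolve(st, thin_film_params(B = 0.015, M = 0, A = A), g,
               events = event_spec(t_end = 160, output_times = 4 * tt),
               large_M = TRUE)
  r0 <- evolve(st, thin_film_params(B = 0.03, M = 0, A = A), g,
               events = event_spec(t_end = 40, output_times = tt))
  expect_equal(r0$stop_reason, "t_end")
  for (j in 2:4) {
    expect_lt(max(abs(rM$H[, j] - r0$H[, j])) / max(r0$H[, j]), 0.005)
  }
})
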