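test_that("regularisation floors the yield surfaces as specified", {
  s <- tf_yield_surfaces(H = 1, pz = 0, MGz = 0, B = 0.1) # rigid: Y- = 0
  r <- regularise_surfaces(s, Y_min = 1e-8)
  expect_equal(r$Y_minus, 1e-8)
  expect_equal(r$Y_plus, 1) # unchanged (already above the floor)
  s2 <- tf_yield_surfaces(1, 0.7, 0, 0.1)
  r2 <- regularise_surfaces(s2, 1e-8)
  expect_equal(r2$Y_minus, s2$Y_minus) # 0.5 > Y_min: unchanged
  sl <- lw_yield_surfaces(0.8, 0.001, 0, 10) # rigid: Psi+ = 1
  rl <- regularise_surfaces(sl, 1e-8)
  expect_equal(rl$Psi_plus, 1 - 1e-8)
  expect_error(regularise_surfaces(list()), "unknown")
})

test_that("flat states stay constant and event bookkeeping is sane", {
  g <- tiny_grid(32L)
  p <- thin_film_params(B = 0.05, M = 0.3, A = 0)
  r <- evolve(initial_condition_tf(0, g), p, g,
              events = event_spec(t_end = 50, output_times = c(0, 25, 50)))
  expect_equal(r$stop_reason, "t_end")
  expect_lt(max(abs(r$H - 1)), 1e-8)
  expect_false(r$plug_formed)
  expect_true(is.na(r$t_p))
  expect_true(is.na(detect_plug(r)))
  expect_error(event_spec(plug_threshold = 2), "plug_threshold")
})

test_that("a thick Newtonian layer plugs and the plug time is localised", {
  g <- film_grid(2 * pi, 64)
  p <- long_wave_params(cB = 0, cM = 0, eps = 0.2, A = 0.3)
  r <- evolve(initial_condition_lw(0.3, 0.2, g), p, g,
              events = event_spec(t_end = 50))
  expect_equal(r$stop_reason, "plugged")
  expect_true(r$plug_formed)
  # the stored final state sits on the threshold
  expect_equal(min(r$R[, ncol(r$R)]), 0.3, tolerance = 5e-3)
  expect_equal(detect_plug(r), r$t_p, tolerance = 1e-3)
  expect_lte(r$t_p, max(r$times) + 1e-9)
  # conservation held throughout
  expect_lt(max(r$conservation$max_rel_drift), 1e-5)
})

test_that("yield stress delays growth and surfactant lowers the peak", {
  g <- film_grid(2 * pi, 48)
  tt <- c(0, 40, 80)
  ev <- event_spec(t_end = 80, output_times = tt)
  base <- evolve(initial_condition_tf(0.2, g),
                 thin_film_params(B = 0.04, M = 0.2, A = 0.2), g, events = ev)
  newt <- evolve(initial_condition_tf(0.2, g),
                 thin_film_params(B = 0, M = 0.2, A = 0.2), g, events = ev)
  clean <- evolve(initial_condition_tf(0.2, g),
                  thin_film_params(B = 0.04, M = 0, A = 0.2), g, events = ev)
  # Newtonian grows faster than viscoplastic at every stored time
  expect_true(all(apply(newt$H, 2, max) >= apply(base$H, 2, max) - 1e-9))
  # surfactant slows growth relative to the surfactant-free run
  expect_gt(max(clean$H[, 3]), max(base$H[, 3]))
})

test_that("tightening tolerances leaves the plugging time unchanged", {
  g <- film_grid(2 * pi, 48)
  p <- long_wave_params(cB = 0, cM = 0, eps = 0.2, A = 0.3)
  st <- initial_condition_lw(0.3, 0.2, g)
  r1 <- evolve(st, p, g, events = event_spec(t_end = 50),
               rtol = 1e-7, atol = 1e-9)
  r2 <- evolve(st, p, g, events = event_spec(t_end = 50),
               rtol = 1e-8, atol = 1e-10)
  expect_lt(abs(r1$t_p / r2$t_p - 1), 0.01)
})

test_that("the critical-thickness bisection brackets and converges", {
  g <- film_grid(2 * pi, 40)
  s <- epsilon_crit_search(cB = 0, cM = 0, A = 0.3, bracket = c(0.08, 0.3),
                           tol = 0.02, t_end = 25, grid = g)
  expect_lt(s$bracket[2] - s$bracket[1], 0.041)
  expect_true(all(!s$runs$plugged[s$runs$eps <= s$bracket[1]]))
  expect_true(all(s$runs$plugged[s$runs$eps >= s$bracket[2]]))
  expect_error(
    epsilon_crit_search(cB = 0, cM = 0, A = 0.3, bracket = c(0.3, 0.35),
                        tol = 0.02, t_end = 25, grid = g),
    "bracket")
})

test_that("tidy and glance summarise runs; autoplot returns ggplots", {
  g <- tiny_grid(32L)
  p <- thin_film_params(B = 0, M = 0.2, A = 0.2)
  r <- evolve(initial_condition_tf(0.2, g), p, g,
              events = event_spec(t_end = 5, output_times = c(0, 5)))
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2L)
  expect_true(all(c("time", "max_H", "max_abs_tau_w", "mass") %in% names(td)))
  expect_equal(td$mass, rep(2 * pi, 2), tolerance = 1e-8)
  gl <- glance(r)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$stop_reason, "t_end")
  expect_s3_class(autoplot(r), "ggplot")
  m <- regime_map("thin_film", seq(-2, 2, 1), seq(-1, 1, 1))
  expect_s3_class(autoplot(m), "ggplot")
  cont <- static_continuation(c(0.1, 0.2), grid = film_grid(2 * pi, 48))
  expect_s3_class(autoplot(cont), "ggplot")
  expect_s3_class(tidy(cont), "tbl_df")
})
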