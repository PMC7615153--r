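test_that("thin-film yield surfaces reproduce the limiting branches", {
  # rigid branch: no pressure gradient, Marangoni stress below yield
  s <- tf_yield_surfaces(H = 1.2, pz = 0, MGz = 0.02, B = 0.04)
  expect_equal(s$Y_minus, 0)
  expect_equal(s$Y_plus, 1.2)
  expect_equal(as.character(s$regime), "V")
  # Marangoni-yielded branch at pz = 0 is fully yielded (type III)
  s2 <- tf_yield_surfaces(H = 1.2, pz = 0, MGz = 0.1, B = 0.04)
  expect_equal(as.character(s2$regime), "III")
  # B = 0 with pure capillary forcing: both surfaces collapse onto H
  s3 <- tf_yield_surfaces(H = 1.5, pz = 0.7, MGz = 0, B = 0)
  expect_equal(s3$Y_minus, 1.5)
  expect_equal(s3$Y_plus, 1.5)
  expect_equal(as.character(s3$regime), "III")
  expect_error(tf_yield_surfaces(-1, 0.1, 0, 0.1), "non-negative")
})

test_that("immobilised interface gives symmetric surfaces and zero slip", {
  H <- 1.3; pz <- -0.8; MGz <- -H * pz / 2; B <- 0.1
  s <- tf_yield_surfaces(H, pz, MGz, B)
  expect_equal(s$Y_minus, H - s$Y_plus, tolerance = 1e-12)
  ws <- vpfilm:::tf_ws_from_surfaces(H, pz, MGz, B, s$Y_minus, s$Y_plus)
  expect_lt(abs(ws), 1e-14)
})

test_that("thin-film fluxes match direct quadrature of the velocity profile", {
  # independent oracle: integrate the Bingham shear profile
  # tau(y) = MGz + pz (H - y), w_y = -sgn(tau)(|tau| - B) where |tau| > B
  quad <- function(H, pzv, MGzv, B) {
    tau <- function(y) MGzv + pzv * (H - y)
    wp <- function(y) ifelse(abs(tau(y)) > B,
                             -sign(tau(y)) * (abs(tau(y)) - B), 0)
    w <- function(y) sapply(y, function(yi)
      integrate(wp, 0, yi, rel.tol = 1e-11, subdivisions = 500L)$value)
    list(q = integrate(function(y) w(y), 0, H, rel.tol = 1e-9,
                       subdivisions = 500L)$value,
         ws = w(H))
  }
  set.seed(42)
  for (k in 1:25) {
    H <- runif(1, 0.4, 2.2); pzv <- runif(1, -2, 2)
    MGzv <- runif(1, -0.4, 0.4); B <- runif(1, 0, 0.25)
    o <- tryCatch(quad(H, pzv, MGzv, B), error = function(e) NULL)
    if (is.null(o)) next
    s <- tf_yield_surfaces(H, pzv, MGzv, B)
    q <- vpfilm:::tf_flux_from_surfaces(H, pzv, MGzv, B, s$Y_minus, s$Y_plus)
    ws <- vpfilm:::tf_ws_from_surfaces(H, pzv, MGzv, B, s$Y_minus, s$Y_plus)
    expect_equal(q, o$q, tolerance = 1e-4)
    expect_equal(ws, o$ws, tolerance = 1e-4)
  }
})

test_that("long-wave yield surfaces: limits, reduction and quadrature oracle", {
  # deep below yield everywhere: fully rigid
  s <- lw_yield_surfaces(R = 0.8, pz = 0.01, MGz = 0.001, cB = 10)
  expect_equal(s$Psi_minus, 0.8)
  expect_equal(s$Psi_plus, 1)
  expect_equal(as.character(s$regime), "V")
  # no Marangoni stress: no interface-adjacent fully-yielded region
  s2 <- lw_yield_surfaces(R = 0.7, pz = 1.5, MGz = 0, cB = 0.05)
  expect_equal(s2$Psi_minus, 0.7)
  expect_error(lw_yield_surfaces(1.2, 1, 0, 0.1), "inside")
  # quadrature oracle for flux and surface velocity across branches
  quad <- function(R0, pzv, MGzv, cB) {
    tau <- function(r) pzv / 2 * (r - R0^2 / r) + R0 / r * MGzv
    wp <- function(r) ifelse(abs(tau(r)) > cB,
                             sign(tau(r)) * (abs(tau(r)) - cB), 0)
    w <- function(r) sapply(r, function(ri)
      -integrate(wp, ri, 1, rel.tol = 1e-11, subdivisions = 400L)$value)
    list(Q = integrate(function(r) w(r) * r, R0, 1, rel.tol = 1e-9,
                       subdivisions = 400L)$value,
         ws = w(R0))
  }
  set.seed(7)
  for (k in 1:25) {
    R0 <- runif(1, 0.35, 0.92); pzv <- runif(1, -3, 3)
    MGzv <- runif(1, -0.8, 0.8); cB <- runif(1, 0, 0.25)
    if (abs(pzv) < 1e-3) pzv <- 0
    o <- tryCatch(quad(R0, pzv, MGzv, cB), error = function(e) NULL)
    if (is.null(o)) next
    st <- long_wave_state(rep(R0, 8), rep(1, 8))
    p <- long_wave_params(cB = cB, cM = 1, eps = 1 - R0)
    s <- lw_yield_surfaces(R0, pzv, MGzv, cB)
    FG <- vpfilm:::lw_F(R0, s$Psi_minus, s$Psi_plus)
    GG <- vpfilm:::lw_G(R0, s$Psi_minus, s$Psi_plus)
    br <- vpfilm:::lw_branch(R0, pzv, MGzv)
    if (br$pz0) {
      Q <- -R0 * MGzv / 4 * FG$F2 + cB / 6 * sign(MGzv) * FG$F4
      ws <- R0 * MGzv * GG$G2 - cB * sign(MGzv) * GG$G4
    } else {
      s34 <- if (br$upper) FG$F3 - FG$F4 else FG$F3 + FG$F4
      g34 <- if (br$upper) GG$G3 - GG$G4 else GG$G3 + GG$G4
      Q <- -pzv / 16 * FG$F1 - R0 * MGzv / 4 * FG$F2 - cB / 6 * sign(pzv) * s34
      ws <- pzv / 4 * GG$G1 + R0 * MGzv * GG$G2 + cB * sign(pzv) * g34
    }
    if (abs(o$Q) > 1e-6) expect_equal(Q, o$Q, tolerance = 1e-3)
    if (abs(o$ws) > 1e-6) expect_equal(ws, o$ws, tolerance = 1e-4)
  }
})

test_that("clipped surfaces are continuous across branch boundaries", {
  # sweep the stress ratio through both thresholds at fixed R, cB
  R0 <- 0.8; cB <- 0.01
  set.seed(11)
  for (k in 1:40) {
    pzv <- runif(1, 0.05, 2) * sample(c(-1, 1), 1)
    # place MGz exactly at a branch boundary and straddle it
    for (thr in c(1, 1 + cB^2 / (R0^2 * pzv^2))) {
      MGz0 <- thr * R0 * pzv / 2
      del <- 1e-9 * abs(MGz0)
      sm <- lw_yield_surfaces(R0, pzv, MGz0 - del, cB)
      sp <- lw_yield_surfaces(R0, pzv, MGz0 + del, cB)
      expect_lt(abs(sm$Psi_minus - sp$Psi_minus), 1e-6)
      expect_lt(abs(sm$Psi_plus - sp$Psi_plus), 1e-6)
    }
  }
  # continuity across pz = 0 at fixed Marangoni stress
  for (MGzv in c(-0.3, 0.02, 0.3)) {
    sm <- lw_yield_surfaces(R0, -1e-12, MGzv, cB)
    s0 <- lw_yield_surfaces(R0, 0, MGzv, cB)
    sp <- lw_yield_surfaces(R0, 1e-12, MGzv, cB)
    expect_lt(abs(sm$Psi_minus - s0$Psi_minus), 1e-6)
    expect_lt(abs(sp$Psi_minus - s0$Psi_minus), 1e-6)
    expect_lt(abs(sm$Psi_plus - s0$Psi_plus), 1e-6)
    expect_lt(abs(sp$Psi_plus - s0$Psi_plus), 1e-6)
  }
})

test_that("clipping is idempotent", {
  set.seed(3)
  R <- runif(50, 0.3, 0.95)
  s <- lw_yield_surfaces(R, runif(50, -2, 2), runif(50, -1, 1), 0.05)
  expect_equal(pmax(R, pmin(1, s$Psi_minus)), s$Psi_minus)
  expect_equal(pmax(R, pmin(1, s$Psi_plus)), s$Psi_plus)
  H <- runif(50, 0.5, 2)
  st <- tf_yield_surfaces(H, runif(50, -2, 2), runif(50, -0.5, 0.5), 0.05)
  expect_equal(pmax(0, pmin(H, st$Y_minus)), st$Y_minus)
  expect_equal(pmax(0, pmin(H, st$Y_plus)), st$Y_plus)
})

test_that("long-wave surfaces reduce to thin-film surfaces as eps -> 0", {
  H <- seq(0.5, 2, length.out = 30)
  pz <- seq(-1.5, 1.5, length.out = 30)
  MGz <- seq(-0.3, 0.3, length.out = 30)
  B <- 0.08
  stf <- tf_yield_surfaces(H, pz, MGz, B)
  err <- sapply(c(1e-2, 1e-3), function(eps) {
    # stresses scale with eps^2 in the thin-film limit (pz itself with eps)
    slw <- lw_yield_surfaces(1 - eps * H, eps * pz, eps^2 * MGz, eps^2 * B)
    max(abs((1 - slw$Psi_plus) / eps - stf$Y_minus),
        abs((1 - slw$Psi_minus) / eps - stf$Y_plus))
  })
  expect_lt(err[2], 0.01)      # O(eps) at eps = 1e-3
  expect_gt(err[1] / err[2], 5) # and shrinking roughly linearly
})

test_that("regime classification covers the five types with tie-breaks", {
  H <- 1
  expect_equal(as.character(classify_regime(0, 1, 1)), "V")
  expect_equal(as.character(classify_regime(0.3, 1, 1)), "II")
  expect_equal(as.character(classify_regime(0, 0.6, 1)), "IV")
  expect_equal(as.character(classify_regime(0.2, 0.6, 1)), "I")
  expect_equal(as.character(classify_regime(0.4, 0.4, 1)), "III")
  expect_equal(as.character(classify_regime(1, 1, 1)), "III")
  expect_equal(as.character(classify_regime(0, 0, 1)), "III")
  # round-off sized plug region counts as fully yielded (lower-numbered III)
  expect_equal(as.character(classify_regime(0.5, 0.5 + 1e-14, 1)), "III")
  expect_error(classify_regime(0.7, 0.3, 1), "ordering")
})

test_that("regime maps have the expected layout and symmetry", {
  x <- seq(-4, 4, length.out = 41)
  y <- seq(-3, 3, length.out = 41)
  m <- regime_map("thin_film", x, y)
  expect_equal(as.character(m$regime[m$x == 0 & m$y == 0]), "V")
  imm <- regime_map("thin_film", -2, 1)
  expect_equal(as.character(imm$regime), "I")
  # symmetric under simultaneous sign flip of both stress ratios
  key <- paste(round(m$x, 10), round(m$y, 10))
  lut <- setNames(as.character(m$regime), key)
  flip_key <- paste(round(-m$x, 10), round(-m$y, 10))
  expect_equal(unname(lut[flip_key]), as.character(m$regime))
  # the long-wave map contains a type-I pocket adjacent to
  # (2/(1-R), -1), where the nonlinear radial stress profile dips below
  # yield between two yielded layers
  R0 <- 0.8
  lobe <- regime_map("long_wave", 2 / (1 - R0) * 1.1, -1.2, R = R0)
  expect_equal(as.character(lobe$regime), "I")
})
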