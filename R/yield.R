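# Yield-surface computation and flow-regime classification.
#
# In both theories the film cross-section splits into fully-yielded shear
# regions and plug-like regions, separated by two internal yield surfaces.
# Five qualitative configurations (types I-V) can occur depending on the
# competition between the capillary pressure gradient and the Marangoni
# surface stress, measured against the yield stress.

# Pressure gradients below this magnitude are treated as exactly zero so the
# pz = 0 branch formulas are selected; the clipped surfaces are continuous
# there, so the exact threshold is uncritical.
PZ_FLOOR <- 1e-30

REGIME_LEVELS <- c("I", "II", "III", "IV", "V")

#' Thin-film yield surfaces
#'
#' Computes the heights above the tube wall of the two yield surfaces
#' bounding the plug-like region of a thin film:
#' \eqn{y_\pm = H + M\Gamma_z/\tilde p_z \pm B/|\tilde p_z|}, clipped to
#' \eqn{Y_\pm = \max[0, \min(H, y_\pm)]}. When the pressure gradient
#' vanishes, the layer is fully yielded (type III) if the Marangoni stress
#' \eqn{|M\Gamma_z|} exceeds \eqn{B}, and rigid (type V) otherwise.
#'
#' @param H Layer thickness (scaled), per node. Must be non-negative.
#' @param pz Thin-film capillary pressure gradient \eqn{\tilde p_z} per node.
#' @param MGz Marangoni stress \eqn{M\Gamma_z} per node.
#' @param B Scaled capillary Bingham number.
#' @param classify Attach the per-node regime label; the time integrator
#'   disables this on its inner path since fluxes never branch on the label.
#' @return A list of class `yield_surfaces_tf` with per-node fields
#'   `Y_minus`, `Y_plus` (clipped), `y_minus`, `y_plus` (unclipped) and
#'   `regime` (factor with levels I-V, or `NULL` if `classify = FALSE`).
#' @export
tf_yield_surfaces <- function(H, pz, MGz, B, classify = TRUE) {
  if (any(H < 0)) stop("layer thickness H must be non-negative", call. = FALSE)
  stopifnot(length(B) == 1L, B >= 0, length(pz) == length(H),
            length(MGz) == length(H))
  pz0 <- abs(pz) < PZ_FLOOR
  apz <- ifelse(pz0, 1, abs(pz)) # placeholder to avoid 0/0; overwritten below
  y_c <- H + MGz / ifelse(pz0, Inf, pz) # centre of the plug region
  y_minus <- y_c - B / apz
  y_plus <- y_c + B / apz
  Y_minus <- pmax(0, pmin(H, y_minus))
  Y_plus <- pmax(0, pmin(H, y_plus))
  # pz = 0: fully yielded if Marangoni stress exceeds the yield stress,
  # rigid otherwise. Y_minus = Y_plus marks the absence of a plug region;
  # the common value (0 or H) is the one-sided limit in sgn(Gamma_z).
  if (any(pz0)) {
    mar <- abs(MGz) > B
    yld <- pz0 & mar
    rig <- pz0 & !mar
    Y_full <- ifelse(MGz > 0, H, 0)
    Y_minus[yld] <- Y_full[yld]
    Y_plus[yld] <- Y_full[yld]
    Y_minus[rig] <- 0
    Y_plus[rig] <- H[rig]
    y_minus[pz0] <- Y_minus[pz0]
    y_plus[pz0] <- Y_plus[pz0]
  }
  regime <- NULL
  if (classify) {
    # a station whose unclipped surface sits exactly on a clip bound is on a
    # regime boundary; the tie goes to the adjacent lower-numbered regime,
    # which means treating Y- as interior when y- ~ 0 and Y+ as interior
    # when y+ ~ H
    eps <- 1e-12 * pmax(H, 1e-300)
    tie <- !pz0 # the pz = 0 branches assign exact values, not clip ties
    Ym_c <- ifelse(tie & abs(y_minus) <= eps, 2 * eps, Y_minus)
    Yp_c <- ifelse(tie & abs(y_plus - H) <= eps, H - 2 * eps, Y_plus)
    Yp_c <- pmax(Yp_c, Ym_c)
    regime <- classify_regime(Ym_c, Yp_c, H)
  }
  structure(list(Y_minus = Y_minus, Y_plus = Y_plus,
                 y_minus = y_minus, y_plus = y_plus, regime = regime),
            class = "yield_surfaces_tf")
}

#' Long-wave yield surfaces
#'
#' Computes the radial positions \eqn{\Psi_\pm \in [R, 1]} of the surfaces
#' separating the fully-yielded regions (adjacent to the interface and to the
#' wall) from the plug-like region in between. The unclipped values
#' \eqn{\psi_\pm} follow a three-branch formula selected by the stress ratio
#' \eqn{s = 2\mathcal{M}\Gamma_z/(R p_z)} with thresholds 1 and
#' \eqn{1 + \mathcal{B}^2/(R^2 p_z^2)}; the clipped surfaces
#' \eqn{\Psi_\pm = \max[R, \min(1, \psi_\pm)]} are continuous everywhere,
#' including across the branch boundaries and at \eqn{p_z = 0}.
#'
#' @param R Interface radius per node, in (0, 1).
#' @param pz Axial pressure gradient per node.
#' @param MGz Marangoni stress \eqn{\mathcal{M}\Gamma_z} per node.
#' @param cB Capillary Bingham number \eqn{\mathcal{B}}.
#' @param classify Attach the per-node regime label (see
#'   [tf_yield_surfaces()]).
#' @return A list of class `yield_surfaces_lw` with per-node fields
#'   `Psi_minus`, `Psi_plus` (clipped), `psi_minus`, `psi_plus` (unclipped)
#'   and `regime` (factor with levels I-V, or `NULL` if `classify = FALSE`).
#' @export
lw_yield_surfaces <- function(R, pz, MGz, cB, classify = TRUE) {
  if (any(R <= 0 | R >= 1))
    stop("interface radius R must lie strictly inside (0, 1)", call. = FALSE)
  stopifnot(length(cB) == 1L, cB >= 0, length(pz) == length(R),
            length(MGz) == length(R))
  n <- length(R)
  pz0 <- abs(pz) < PZ_FLOOR
  psi_minus <- numeric(n)
  psi_plus <- numeric(n)

  if (any(!pz0)) {
    i <- which(!pz0)
    pzi <- pz[i]
    Ri <- R[i]
    s <- 2 * MGz[i] / (Ri * pzi)
    disc <- (cB / pzi)^2 + Ri^2 - 2 * Ri * MGz[i] / pzi
    hi <- 1 + cB^2 / (Ri^2 * pzi^2)
    pm <- numeric(length(i))
    pp <- numeric(length(i))
    bA <- s < 1
    bB <- !bA & s <= hi
    bC <- !bA & !bB
    if (any(bA)) {
      rt <- sqrt(pmax(0, disc[bA]))
      pm[bA] <- -cB / abs(pzi[bA]) + rt
      pp[bA] <- cB / abs(pzi[bA]) + rt
    }
    if (any(bB)) {
      rt <- sqrt(pmax(0, disc[bB]))
      pm[bB] <- cB / abs(pzi[bB]) - rt
      pp[bB] <- cB / abs(pzi[bB]) + rt
    }
    if (any(bC)) {
      pm[bC] <- Ri[bC]
      pp[bC] <- Ri[bC]
    }
    psi_minus[i] <- pm
    psi_plus[i] <- pp
  }
  if (any(pz0)) {
    i <- which(pz0)
    # psi_minus = R M |Gamma_z| / cB; with cB = 0 any Marangoni stress fully
    # yields the layer, so the surface sits at the wall.
    pm <- if (cB > 0) R[i] * abs(MGz[i]) / cB else
      ifelse(abs(MGz[i]) > 0, 1, R[i])
    psi_minus[i] <- pm
    psi_plus[i] <- 1
  }
  Psi_minus <- pmax(R, pmin(1, psi_minus))
  Psi_plus <- pmax(R, pmin(1, psi_plus))
  regime <- NULL
  if (classify) {
    eps <- 1e-12 * pmax(1 - R, 1e-300)
    # ties at the clip bounds go to the adjacent lower-numbered regime
    tie <- !pz0
    Pm_c <- ifelse(tie & abs(psi_minus - R) <= eps, R + 2 * eps, Psi_minus)
    Pp_c <- ifelse(tie & abs(psi_plus - 1) <= eps, 1 - 2 * eps, Psi_plus)
    Pm_c <- pmin(Pm_c, Pp_c)
    regime <- classify_regime(1 - Pp_c, 1 - Pm_c, 1 - R)
  }
  structure(list(Psi_minus = Psi_minus, Psi_plus = Psi_plus,
                 psi_minus = psi_minus, psi_plus = psi_plus,
                 regime = regime),
            class = "yield_surfaces_lw")
}

#' Classify the yielding type of each axial station
#'
#' Maps the (clipped) yield-surface positions to one of the five yielding
#' types: I internal pseudo-plug (`0 < Y- < Y+ < H`), II surface pseudo-plug
#' (`0 < Y- < Y+ = H`), III fully yielded (`Y- = Y+`), IV near-wall plug
#' (`Y- = 0 < Y+ < H`), V fully rigid (`Y- = 0`, `Y+ = H`). For the
#' long-wave model pass `Y- = 1 - Psi_plus`, `Y+ = 1 - Psi_minus`,
#' `H = 1 - R` (distances from the tube wall).
#'
#' Equalities are detected with a relative tolerance `tol * H` to absorb
#' round-off; a station exactly on a regime boundary takes the label of the
#' adjacent lower-numbered regime. Labels are diagnostics only - fluxes never
#' branch on them.
#'
#' @param Y_minus,Y_plus Clipped yield-surface heights, `0 <= Y- <= Y+ <= H`.
#' @param H Layer thickness per node.
#' @param tol Relative tolerance for boundary equalities.
#' @return Factor with levels `I`-`V`, one per node.
#' @export
classify_regime <- function(Y_minus, Y_plus, H, tol = 1e-12) {
  n <- length(H)
  stopifnot(length(Y_minus) == n, length(Y_plus) == n)
  eps <- tol * pmax(H, 1e-300)
  if (any(Y_minus < -eps | Y_plus > H + eps | Y_plus < Y_minus - eps))
    stop("yield-surface ordering violated (need 0 <= Y- <= Y+ <= H)",
         call. = FALSE)
  lo0 <- Y_minus <= eps
  hiH <- Y_plus >= H - eps
  collapsed <- (Y_plus - Y_minus) <= eps
  lab <- ifelse(collapsed, "III",
         ifelse(lo0 & hiH, "V",
         ifelse(!lo0 & hiH, "II",
         ifelse(lo0, "IV", "I"))))
  factor(lab, levels = REGIME_LEVELS)
}

#' Map of yielding types over the stress-ratio plane
#'
#' Evaluates the yielding type on a grid of stress ratios, reproducing the
#' regime maps of the two theories. For the thin-film model the axes are
#' \eqn{(H\tilde p_z/B,\, M\Gamma_z/B)}; for the long-wave model they are
#' \eqn{(p_z/\mathcal{B},\, \mathcal{M}\Gamma_z/\mathcal{B})} at fixed
#' interface radius `R`. Only the ratios matter, so the map is independent of
#' the individual stress scales.
#'
#' @param model `"thin_film"` or `"long_wave"`.
#' @param x,y Numeric vectors of stress ratios spanning the two axes.
#' @param R Interface radius (long-wave map only).
#' @param H Layer thickness (thin-film map only).
#' @return A tibble of class `regime_map` with columns `x`, `y`, `regime`.
#' @examples
#' m <- regime_map("thin_film", seq(-4, 4, length.out = 41),
#'                 seq(-3, 3, length.out = 41))
#' table(m$regime)
#' @export
regime_map <- function(model = c("thin_film", "long_wave"),
                       x, y, R = 0.8, H = 1) {
  model <- match.arg(model)
  gridxy <- expand.grid(x = x, y = y, KEEP.OUT.ATTRS = FALSE)
  if (model == "thin_film") {
    Hv <- rep(H, nrow(gridxy))
    s <- tf_yield_surfaces(Hv, pz = gridxy$x / H, MGz = gridxy$y, B = 1)
  } else {
    Rv <- rep(R, nrow(gridxy))
    s <- lw_yield_surfaces(Rv, pz = gridxy$x, MGz = gridxy$y, cB = 1)
  }
  out <- tibble::tibble(x = gridxy$x, y = gridxy$y, regime = s$regime)
  class(out) <- c("regime_map", class(out))
  attr(out, "model") <- model
  out
}

#' Write a regime map as an integer-coded CSV matrix
#'
#' @param map A [regime_map()] tibble.
#' @param path Output CSV path. Axis vectors are stored in the header columns.
#' @return `path`, invisibly.
#' @export
write_regime_map_csv <- function(map, path) {
  stopifnot(inherits(map, "regime_map"))
  wide <- tidyr::pivot_wider(
    dplyr::mutate(map, code = as.integer(.data$regime)),
    id_cols = "y", names_from = "x", values_from = "code")
  utils::write.csv(wide, path, row.names = FALSE)
  invisible(path)
}
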