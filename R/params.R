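#' Dimensionless parameters of the thin-film model
#'
#' The thin-film theory describes a layer whose mean thickness is a small
#' fraction \eqn{\epsilon} of the tube radius. Its dynamics depend on two
#' rescaled dimensionless groups: the scaled capillary Bingham number
#' \eqn{B = \mathcal{B}/\epsilon^2} (yield stress relative to the capillary
#' stress scale) and the scaled Marangoni number
#' \eqn{M = \mathcal{M}/\epsilon^2} (sensitivity of surface tension to
#' surfactant concentration).
#'
#' @param B Scaled capillary Bingham number, `B >= 0`.
#' @param M Scaled Marangoni number, `M >= 0`.
#' @param A Amplitude of the initial interface perturbation, `0 <= A < 1`.
#' @param L Domain length in tube radii.
#' @param Y_min Regularisation floor applied to the yield surfaces before
#'   flux evaluation. The default `1e-8` is small enough that its exact value
#'   does not affect the solutions.
#' @return An object of class `thin_film_params`.
#' @examples
#' thin_film_params(B = 0.04, M = 0.2)
#' @export
thin_film_params <- function(B, M, A = 0.2, L = 2 * pi, Y_min = 1e-8) {
  stopifnot(is.numeric(B), length(B) == 1L, B >= 0,
            is.numeric(M), length(M) == 1L, M >= 0,
            is.numeric(A), length(A) == 1L, A >= 0, A < 1,
            is.numeric(L), length(L) == 1L, L > 0,
            is.numeric(Y_min), length(Y_min) == 1L, Y_min > 0)
  structure(list(B = B, M = M, A = A, L = L, Y_min = Y_min),
            class = c("thin_film_params", "film_params"))
}

#' Dimensionless parameters of the long-wave model
#'
#' The long-wave theory keeps the full dependence on the film-thickness ratio
#' \eqn{\epsilon} (mean layer thickness over tube radius) and retains the
#' exact interface curvature. It is parameterised by the unscaled capillary
#' Bingham number \eqn{\mathcal{B} = a\tau_y/\sigma_0} and Marangoni number
#' \eqn{\mathcal{M} = K\Gamma_0/\sigma_0}. The thin-film groups are recovered
#' as \eqn{B = \mathcal{B}/\epsilon^2}, \eqn{M = \mathcal{M}/\epsilon^2}.
#'
#' @param cB Capillary Bingham number \eqn{\mathcal{B} \ge 0}.
#' @param cM Marangoni number \eqn{\mathcal{M} \ge 0}.
#' @param eps Film-thickness ratio \eqn{\epsilon \in (0, 1)}.
#' @inheritParams thin_film_params
#' @return An object of class `long_wave_params`.
#' @examples
#' long_wave_params(cB = 0.001, cM = 0.02, eps = 0.14)
#' @export
long_wave_params <- function(cB, cM, eps, A = 0.2, L = 2 * pi, Y_min = 1e-8) {
  stopifnot(is.numeric(cB), length(cB) == 1L, cB >= 0,
            is.numeric(cM), length(cM) == 1L, cM >= 0,
            is.numeric(eps), length(eps) == 1L, eps > 0, eps < 1,
            is.numeric(A), length(A) == 1L, A >= 0,
            is.numeric(L), length(L) == 1L, L > 0,
            is.numeric(Y_min), length(Y_min) == 1L, Y_min > 0)
  structure(list(cB = cB, cM = cM, eps = eps, A = A, L = L, Y_min = Y_min),
            class = c("long_wave_params", "film_params"))
}

#' @export
print.thin_film_params <- function(x, ...) {
  cat(sprintf("<thin_film_params> B = %g, M = %g, A = %g, L = %g, Y_min = %g\n",
              x$B, x$M, x$A, x$L, x$Y_min))
  invisible(x)
}

#' @export
print.long_wave_params <- function(x, ...) {
  cat(sprintf(
    "<long_wave_params> cB = %g, cM = %g, eps = %g, A = %g, L = %g, Y_min = %g\n",
    x$cB, x$cM, x$eps, x$A, x$L, x$Y_min))
  invisible(x)
}

#' Convert long-wave parameters to the equivalent thin-film parameters
#'
#' Applies the thin-film rescaling \eqn{B = \mathcal{B}/\epsilon^2},
#' \eqn{M = \mathcal{M}/\epsilon^2}.
#'
#' @param params A [long_wave_params()] object.
#' @return A [thin_film_params()] object.
#' @export
as_thin_film_params <- function(params) {
  stopifnot(inherits(params, "long_wave_params"))
  thin_film_params(B = params$cB / params$eps^2, M = params$cM / params$eps^2,
                   A = params$A, L = params$L, Y_min = params$Y_min)
}

#' Dimensional parameters of a liquid-lined tube
#'
#' Bundles the dimensional quantities from which the dimensionless groups are
#' formed: the capillary Bingham number \eqn{\mathcal{B} = a\tau_y/\sigma_0},
#' the Marangoni number \eqn{\mathcal{M} = K\Gamma_0/\sigma_0}, and the
#' capillary time unit \eqn{a\eta/\sigma_0}.
#'
#' @param tube_radius Tube radius \eqn{a} in metres.
#' @param surface_tension Equilibrium surface tension \eqn{\sigma_0} in N/m.
#' @param viscosity Liquid viscosity \eqn{\eta} in Pa s.
#' @param yield_stress Yield stress \eqn{\tau_y} in Pa (0 for Newtonian).
#' @param surfactant_elasticity Optional surface elasticity \eqn{K\Gamma_0}
#'   in N/m; needed only to form the Marangoni number.
#' @return An object of class `dimensional_params` with derived fields `cB`,
#'   `cM` (or `NA`) and `time_unit` (seconds).
#' @examples
#' # a 12th-generation human airway
#' dimensional_params(tube_radius = 0.4e-3, surface_tension = 30e-3,
#'                    viscosity = 0.01, yield_stress = 0)
#' @export
dimensional_params <- function(tube_radius, surface_tension, viscosity,
                               yield_stress, surfactant_elasticity = NULL) {
  stopifnot(tube_radius > 0, surface_tension > 0, viscosity > 0,
            yield_stress >= 0)
  cM <- if (is.null(surfactant_elasticity)) NA_real_ else {
    stopifnot(surfactant_elasticity > 0)
    surfactant_elasticity / surface_tension
  }
  structure(list(
    tube_radius = tube_radius, surface_tension = surface_tension,
    viscosity = viscosity, yield_stress = yield_stress,
    surfactant_elasticity = surfactant_elasticity,
    cB = tube_radius * yield_stress / surface_tension,
    cM = cM,
    time_unit = tube_radius * viscosity / surface_tension
  ), class = "dimensional_params")
}

#' Convert a thin-film-scaled time to seconds
#'
#' Dimensionless times reported by the simulators are in thin-film units
#' \eqn{\tilde t = \epsilon^3 t}, where \eqn{t} is measured in capillary time
#' units \eqn{a\eta/\sigma_0}. The dimensional time is therefore
#' \eqn{t^* = \tilde t \, a\eta/(\sigma_0 \epsilon^3)}.
#'
#' @param t_tilde Dimensionless time(s) in thin-film units.
#' @param eps Film-thickness ratio used in the simulation.
#' @param params A [dimensional_params()] object.
#' @return Time(s) in seconds.
#' @examples
#' airway <- dimensional_params(0.4e-3, 30e-3, 0.01, 0)
#' dimensional_time(35, eps = 0.14, airway)  # ~1.7 s
#' dimensional_time(268, eps = 0.14, airway) # ~13 s
#' @export
dimensional_time <- function(t_tilde, eps, params) {
  stopifnot(inherits(params, "dimensional_params"), eps > 0, eps < 1)
  t_tilde * params$time_unit / eps^3
}
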