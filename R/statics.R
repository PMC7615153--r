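# Marginally-yielded static profiles, their continuation in amplitude,
# the static surfactant profile, the O(1/t) late-time correction system and
# the Rankine-Hugoniot shock-speed diagnostic.

# The static profile equation H0 (H0_z + H0_zzz) = 2B has no smooth
# solution on a domain that resonates with the neutral curvature mode
# (cos z on L = 2*pi): along the volume-constrained family the end-slope
# defect equals -12*pi*B^2 exactly, so the marginally-yielded state carries
# a localised corner where the defect is absorbed. The solver therefore
# works with the same discrete face form used by the evolution operator:
# marginal yield Hf * pz_f = -2B on every interior face except the one
# carrying the corner (the first face, consistent with the late-time
# correction fields vanishing at z = 0), closed by the volume and amplitude
# conditions and by orthogonality to the neutral cosine mode. The resulting
# family is grid-independent and reproduces the linearised limit
# B -> A/(2*pi) as A -> 0.
static_equations <- function(u, A, grid, drop_face = 1L) {
  N <- grid$N
  H <- u[seq_len(N)]
  B <- u[N + 1L]
  phi <- H + d2(H, grid)
  pzf <- -diff(phi) / grid$dz
  Hf <- (H[-1L] + H[-N]) / 2
  marg <- Hf * pzf + 2 * B
  resonant <- abs(sin(grid$L)) < 1e-8
  if (resonant) {
    w <- c(0.5, rep(1, N - 2L), 0.5) * grid$dz
    c(marg[-drop_face],
      grid_integral(H, grid) - grid$L,
      (1 - H[1L]) - A,
      sum(w * (H - 1) * cos(grid$z)))
  } else {
    c(marg, grid_integral(H, grid) - grid$L, (1 - H[1L]) - A)
  }
}

static_newton <- function(u, A, grid, itmax = 80L, tol = 1e-11) {
  f <- function(u) static_equations(u, A, grid)
  N <- grid$N
  for (it in seq_len(itmax)) {
    r0 <- f(u)
    if (max(abs(r0)) < tol) return(list(u = u, ok = TRUE, it = it))
    J <- matrix(0, length(r0), length(u))
    for (j in seq_along(u)) {
      h <- 1e-7 * max(abs(u[j]), 1e-3)
      up <- u
      up[j] <- up[j] + h
      J[, j] <- (f(up) - r0) / h
    }
    du <- tryCatch(solve(J, -r0), error = function(e) NULL)
    if (is.null(du)) break
    lam <- 1
    repeat {
      un <- u + lam * du
      if ((all(un[seq_len(N)] > 1e-3) &&
           max(abs(f(un))) < max(abs(r0))) || lam < 1e-6) break
      lam <- lam / 2
    }
    u <- u + lam * du
  }
  list(u = u, ok = max(abs(static_equations(u, A, grid))) < 1e-9, it = itmax)
}

# near-flat profile of the genuine branch (no neutral-mode content)
static_flat_guess <- function(A, grid) {
  h <- -A - (A / pi) * sin(grid$z) + (A / pi) * grid$z
  c(1 + h, A / (2 * pi))
}

#' Marginally-yielded static profile
#'
#' Solves the static profile equation \eqn{H_0 (H_{0,z} + H_{0,zzz}) = 2B}
#' with symmetry end conditions, unit mean thickness
#' \eqn{\int_0^L H_0\,dz = L} and \eqn{B} as an unknown eigenparameter
#' closed by the depression-amplitude condition \eqn{1 - H_0(0) = A}. These
#' are the shapes on which the capillary stress exactly balances twice the
#' Marangoni stress everywhere, with resultant magnitude equal to the yield
#' stress: the final states approached by unstable surfactant-laden thin
#' films. The surfactant-free static family satisfies the same equation
#' with \eqn{2B} replaced by \eqn{B}, so sufficiently strong surfactant
#' effectively doubles the capillary Bingham number of the final shape.
#'
#' The equation is solved in the same discrete face-marginality form used
#' by the time integrator, with a boundary corner absorbing the end-slope
#' defect of the smooth problem and orthogonality to the neutral curvature
#' mode closing the system on resonant domains (see the methods vignette);
#' Newton iteration is started from the linearised near-flat profile, for
#' which \eqn{B \approx A/(2\pi)}, with continuation in amplitude for
#' strongly deformed targets.
#'
#' @param amplitude Interface depression amplitude `A = 1 - H0(0)`, in (0,1).
#' @param L Domain length.
#' @param grid A [film_grid()] on which to solve.
#' @param guess Optional starting vector `c(H0, B)` (e.g. a neighbouring
#'   solution during continuation).
#' @param step Amplitude step of the continuation.
#' @return An object of class `static_solution`: list with `H0` (per node),
#'   `B`, `amplitude`, `max_H0`, `L`, `grid` and `u` (the solution vector).
#' @examples
#' \donttest{
#' sol <- solve_static_profile(0.2)
#' sol$B # ~ 0.030
#' }
#' @export
solve_static_profile <- function(amplitude, L = 2 * pi,
                                 grid = film_grid(L, 128L), guess = NULL,
                                 step = 0.05) {
  stopifnot(amplitude > 0, amplitude < 1)
  if (is.null(guess)) {
    A_seq <- unique(c(seq(min(0.05, amplitude), amplitude, by = step),
                      amplitude))
    u <- static_flat_guess(A_seq[1L], grid)
  } else {
    A_seq <- amplitude
    u <- guess
  }
  for (A in A_seq) {
    r <- static_newton(u, A, grid)
    if (!r$ok)
      stop("static-profile Newton iteration did not converge at amplitude ",
           signif(A, 4), call. = FALSE)
    u <- r$u
  }
  N <- grid$N
  structure(list(H0 = u[seq_len(N)], B = u[N + 1L], amplitude = amplitude,
                 max_H0 = max(u[seq_len(N)]), L = L, grid = grid, u = u),
            class = "static_solution")
}

#' @export
print.static_solution <- function(x, ...) {
  cat(sprintf(
    "<static_solution> A = %.4g, B = %.6g, max H0 = %.4g (L = %.4g)\n",
    x$amplitude, x$B, x$max_H0, x$L))
  invisible(x)
}

#' Continuation of the static family in amplitude
#'
#' Traces the \eqn{(A, B)} curve of marginally-yielded static solutions by
#' stepping the depression amplitude from near-flat to `max(A_values)`,
#' reusing each converged solution as the next starting guess. Branch labels
#' split the curve at the fold (the amplitude of maximum `B`): `"lower"`
#' solutions are near-flat and set the minimum perturbation required to
#' yield; `"upper"` solutions are the strongly deformed final shapes.
#'
#' @param A_values Amplitudes at which to report solutions (increasing).
#' @param L Domain length.
#' @param grid A [film_grid()].
#' @return A tibble of class `static_continuation` with columns `A`, `B`,
#'   `max_H0`, `branch`, and a list-column `solution`.
#' @export
static_continuation <- function(A_values, L = 2 * pi,
                                grid = film_grid(L, 128L)) {
  A_values <- sort(unique(A_values))
  stopifnot(all(A_values > 0), all(A_values < 1))
  sols <- vector("list", length(A_values))
  u <- NULL
  A_prev <- 0
  for (i in seq_along(A_values)) {
    A_target <- A_values[i]
    if (is.null(u)) {
      sols[[i]] <- solve_static_profile(A_target, L, grid)
    } else {
      while (A_target - A_prev > 0.06) { # keep Newton within its basin
        A_prev <- A_prev + 0.05
        u <- static_newton(u, A_prev, grid)$u
      }
      sols[[i]] <- solve_static_profile(A_target, L, grid, guess = u)
    }
    u <- sols[[i]]$u
    A_prev <- A_target
  }
  B <- vapply(sols, `[[`, numeric(1L), "B")
  fold <- which.max(B)
  out <- tibble::tibble(
    A = A_values, B = B,
    max_H0 = vapply(sols, `[[`, numeric(1L), "max_H0"),
    branch = ifelse(seq_along(B) <= fold, "lower", "upper"),
    solution = sols)
  class(out) <- c("static_continuation", class(out))
  out
}

#' Critical capillary Bingham number versus perturbation amplitude
#'
#' \eqn{B_m(A)} is the capillary Bingham number of the lower-branch static
#' solution with depression amplitude `A`. It predicts the stability
#' boundary of a thin film perturbed with amplitude `A`: instability
#' requires \eqn{B < B_m(A)} at large Marangoni number and
#' \eqn{B < 2B_m(A)} in the surfactant-free limit. For small `A`,
#' \eqn{B_m \approx A/(2\pi)} on the default domain.
#'
#' @param A_values Perturbation amplitudes in (0, 1), along the lower branch.
#' @param L Domain length.
#' @return A tibble with columns `A` and `B_m`.
#' @examples
#' \donttest{
#' bm_of_A(0.2)$B_m # ~ 0.0289
#' }
#' @export
bm_of_A <- function(A_values, L = 2 * pi) {
  cont <- static_continuation(A_values, L, grid = film_grid(L, 128L))
  tibble::tibble(A = cont$A, B_m = cont$B)
}

#' Static surfactant profile
#'
#' The late-time limit of the surfactant concentration in an unstable
#' thin film: a linear profile with slope \eqn{B/M} and mass `L`,
#' \eqn{M\Gamma_0 = M - BL/2 + Bz}. It is non-negative everywhere (and
#' hence attainable) if and only if \eqn{2M \ge BL}; runs violating this
#' approach different static states with only partial interface yielding.
#'
#' @param B,M Scaled capillary Bingham and Marangoni numbers (`M > 0`).
#' @param L Domain length.
#' @param grid A [film_grid()].
#' @return A list with `Gamma0` (per node) and `valid` (`2M >= BL`).
#' @export
gamma0_profile <- function(B, M, L = 2 * pi, grid = film_grid(L)) {
  if (M <= 0) stop("the static surfactant profile requires M > 0",
                   call. = FALSE)
  list(Gamma0 = 1 + B * (grid$z - L / 2) / M, valid = 2 * M >= B * L)
}

#' Late-time O(1/t) correction fields
#'
#' At late times an unstable thin film with \eqn{2M \ge BL} approaches the
#' marginally-yielded static state \eqn{(H_0, \Gamma_0)} with corrections
#' decaying as \eqn{1/(B\tilde t)}:
#' \eqn{H = H_0 + H_1/(B\tilde t) + \dots},
#' \eqn{\Gamma = \Gamma_0 + \Gamma_1/(B\tilde t)},
#' \eqn{Y_- = Y_{-,1}/(B\tilde t)}, \eqn{Y_+ = H_0 + Y_{+,1}/(B\tilde t)},
#' and a surface velocity \eqn{\tilde w_s \sim W_1/(B\tilde t)^2}, with
#' \eqn{W_1 = B Y_{-,1}^2/H_0 - \tfrac{H_0}{4B}(M\partial_z\Gamma_1)^2
#' \le 0} in the interior (a weak Marangoni-driven reverse flow; the
#' interface immobilises as \eqn{O(1/M)} for strong surfactant).
#'
#' The correction fields are extracted from a late-time simulation by their
#' defining scaling: the run is integrated to `t_check` and the scaled
#' residuals about the static state are reported as the correction fields.
#' Mass conservation makes \eqn{\int H_1 dz} and \eqn{\int\Gamma_1 dz}
#' vanish up to the residual \eqn{O(1/\tilde t)} truncation error.
#'
#' @param static A [solve_static_profile()] result (requires `2M >= B L`).
#' @param M Scaled Marangoni number.
#' @param grid A [film_grid()]; defaults to the grid of `static`.
#' @param t_check Thin-film time at which the scaled residuals are read off.
#' @param A Amplitude of the initial perturbation of the extraction run
#'   (must be large enough to trigger instability at this `B`).
#' @param ... Passed to [evolve()].
#' @return A list of class `late_time_correction` with per-node fields `H1`,
#'   `Gamma1`, `Y_minus1`, `Y_plus1`, `W1`, plus `B`, `M`, `t_check`.
#' @export
late_time_correction <- function(static, M, grid = static$grid,
                                 t_check = 2e3, A = NULL, ...) {
  stopifnot(inherits(static, "static_solution"), M > 0)
  B <- static$B
  L <- static$L
  if (2 * M < B * L)
    stop("the late-time regime requires 2M >= BL", call. = FALSE)
  if (is.null(A)) A <- min(0.95, 2.5 * static$amplitude)
  params <- thin_film_params(B = B, M = M, A = A, L = L)
  run <- evolve(initial_condition_tf(A, grid), params, grid,
                events = event_spec(t_end = t_check,
                                    output_times = c(0, t_check / 2, t_check)),
                ...)
  if (run$stop_reason != "t_end")
    stop("late-time extraction run did not reach t_check", call. = FALSE)
  j <- length(run$times)
  tt <- run$times[j]
  H <- run$H[, j]
  G <- run$Gamma[, j]
  f <- tf_fields(H, G, params, grid, regularise = FALSE)
  G0 <- gamma0_profile(B, M, L, grid)$Gamma0
  a <- f$surfaces$Y_minus * B * tt
  G1 <- (G - G0) * B * tt
  W1 <- f$ws * (B * tt)^2
  structure(list(H1 = (H - static$H0) * B * tt,
                 Gamma1 = G1,
                 Y_minus1 = a,
                 Y_plus1 = (f$surfaces$Y_plus - H) * B * tt,
                 W1 = W1,
                 B = B, M = M, t_check = tt, run = run),
            class = "late_time_correction")
}

#' Check the O(1/t) convergence of a late-time run
#'
#' Compares the scaled residuals of a thin-film run about the static state
#' at two times: if the approach is \eqn{O(1/\tilde t)}, the products
#' \eqn{[H - H_0]\,B\tilde t}, \eqn{Y_- B\tilde t},
#' \eqn{[Y_+ - H] B \tilde t} and \eqn{[\Gamma - \Gamma_0] B\tilde t}
#' are time-independent, so their discrepancy between the two check times
#' measures the departure from the asymptotic regime.
#'
#' @param result A thin-film [evolve()] result in the late-time regime.
#' @param static The [solve_static_profile()] solution it approaches.
#' @param t_check Two times (thin-film units) at which to compare; defaults
#'   to the last two stored snapshot times.
#' @return A tibble with columns `field`, `sup_diff` (discrepancy between
#'   the two scaled residuals) and `sup_scale` (magnitude of the later one).
#' @export
validate_late_time <- function(result, static, t_check = NULL) {
  stopifnot(inherits(result, "film_evolution"), result$model == "thin_film")
  if (is.null(t_check)) {
    nt <- length(result$times)
    t_check <- result$times[c(nt - 1L, nt)]
  }
  stopifnot(length(t_check) == 2L)
  grid <- result$grid
  params <- result$params
  B <- params$B
  G0 <- gamma0_profile(B, params$M, params$L, grid)$Gamma0
  scaled <- lapply(t_check, function(tc) {
    j <- which.min(abs(result$times - tc))
    tt <- result$times[j]
    H <- result$H[, j]
    G <- result$Gamma[, j]
    f <- tf_fields(H, G, params, grid, regularise = FALSE)
    list(H1 = (H - static$H0) * B * tt,
         Y_minus1 = f$surfaces$Y_minus * B * tt,
         Y_plus1_minus_H1 = (f$surfaces$Y_plus - H) * B * tt,
         Gamma1 = (G - G0) * B * tt)
  })
  tibble::tibble(
    field = names(scaled[[1L]]),
    sup_diff = vapply(names(scaled[[1L]]), function(nm)
      max(abs(scaled[[2L]][[nm]] - scaled[[1L]][[nm]])), numeric(1L)),
    sup_scale = vapply(names(scaled[[1L]]), function(nm)
      max(abs(scaled[[2L]][[nm]])), numeric(1L)))
}

#' Rankine-Hugoniot shock-speed diagnostic
#'
#' During the intermediate evolution of a surfactant-laden thin film, the
#' surfactant gradient \eqn{\Gamma_z} steepens into travelling near-shocks.
#' Differentiating the transport equation gives a jump condition for the
#' front speed, \eqn{u_s = [(\tilde w_s\Gamma)_z]_-^+ / [\Gamma_z]_-^+}.
#' The front is located at the node of steepest \eqn{|\Gamma_{zz}|} (within
#' `window`, if given); one-sided values on each side are obtained by linear
#' extrapolation from 3 nodes, skipping the 2 nodes nearest the front where
#' the scheme smears the discontinuity.
#'
#' @param Gamma Surfactant concentration per node.
#' @param ws Surface velocity per node (e.g. from [tf_surface_velocity()]).
#' @param grid A [film_grid()].
#' @param window Optional `c(z_lo, z_hi)` restricting the front search.
#' @param min_jump Floor on \eqn{|[\Gamma_z]|} below which the speed is
#'   reported as undefined (`NA`).
#' @return A list of class `shock_diagnostic` with `u_s`, `jump_Gz`,
#'   `jump_flux`, `location` (z of the front) and `index`.
#' @export
shock_speed <- function(Gamma, ws, grid, window = NULL, min_jump = 1e-8) {
  check_field(Gamma, grid)
  check_field(ws, grid)
  Gz <- d1(Gamma, grid)
  fluxz <- d1(ws * Gamma, grid)
  Gzz <- d2(Gamma, grid)
  cand <- seq_len(grid$N)
  if (!is.null(window))
    cand <- cand[grid$z >= window[1L] & grid$z <= window[2L]]
  i0 <- cand[which.max(abs(Gzz[cand]))]
  if (i0 < 6L || i0 > grid$N - 5L)
    stop("shock front too close to a boundary to extrapolate", call. = FALSE)
  one_sided <- function(f, side) {
    idx <- if (side > 0) i0 + 3:5 else i0 - 3:5
    fit <- stats::lm.fit(cbind(1, grid$z[idx] - grid$z[i0]), f[idx])
    unname(fit$coefficients[1L])
  }
  jump_Gz <- one_sided(Gz, +1) - one_sided(Gz, -1)
  jump_flux <- one_sided(fluxz, +1) - one_sided(fluxz, -1)
  u_s <- if (abs(jump_Gz) < min_jump) NA_real_ else jump_flux / jump_Gz
  structure(list(u_s = u_s, jump_Gz = jump_Gz, jump_flux = jump_flux,
                 location = grid$z[i0], index = i0),
            class = "shock_diagnostic")
}
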