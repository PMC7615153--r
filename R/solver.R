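# Simulation driver for both models: regularised yield surfaces, adaptive
# linearly-implicit time integration (see integrator.R), plug-event
# detection by interpolation plus re-integration, conservation auditing,
# and the critical-thickness bisection.

#' Stopping rules and output control for a simulation
#'
#' @param plug_threshold Minimum interface radius at which the simulation is
#'   stopped and the plugging time recorded (long-wave model only). The
#'   default 0.3 is the standard proxy for imminent plug formation.
#' @param t_end Maximum reported time, in thin-film units \eqn{\tilde t} for
#'   both models (long-wave runs convert internally via
#'   \eqn{t = \tilde t/\epsilon^3}).
#' @param output_times Optional explicit vector of output times (thin-film
#'   units). If `NULL`, a logarithmically spaced set of `n_out` times is used.
#' @param n_out Number of output times when `output_times` is `NULL`.
#' @return An object of class `event_spec`.
#' @export
event_spec <- function(plug_threshold = 0.3, t_end = 1e4,
                       output_times = NULL, n_out = 61L) {
  stopifnot(plug_threshold > 0, plug_threshold < 1, t_end > 0)
  if (!is.null(output_times))
    stopifnot(all(diff(output_times) > 0), all(output_times >= 0))
  structure(list(plug_threshold = plug_threshold, t_end = t_end,
                 output_times = output_times, n_out = as.integer(n_out)),
            class = "event_spec")
}

#' Apply the yield-surface regularisation
#'
#' Floors the yield surfaces away from the wall before flux evaluation:
#' \eqn{\hat Y_\pm = \max(Y_{\min}, Y_\pm)} in the thin-film model,
#' \eqn{\hat\Psi_\pm = \min(1 - Y_{\min}, \Psi_\pm)} in the long-wave model.
#' This leaves a vanishingly thin yielded film against the wall so that
#' nominally rigid regions creep at a negligible rate, smoothing the
#' otherwise non-smooth rigid/yielded transition for the implicit
#' integrator. Classification always uses the unregularised surfaces.
#'
#' @param surfaces A [tf_yield_surfaces()] or [lw_yield_surfaces()] object.
#' @param Y_min Regularisation floor (default `1e-8`).
#' @return The surfaces object with the floor applied.
#' @export
regularise_surfaces <- function(surfaces, Y_min = 1e-8) {
  stopifnot(Y_min > 0)
  if (inherits(surfaces, "yield_surfaces_tf")) {
    surfaces$Y_minus <- pmax(Y_min, surfaces$Y_minus)
    surfaces$Y_plus <- pmax(Y_min, surfaces$Y_plus)
  } else if (inherits(surfaces, "yield_surfaces_lw")) {
    surfaces$Psi_minus <- pmin(1 - Y_min, surfaces$Psi_minus)
    surfaces$Psi_plus <- pmin(1 - Y_min, surfaces$Psi_plus)
  } else {
    stop("unknown surfaces object", call. = FALSE)
  }
  surfaces
}

# integrator-facing derivative closures --------------------------------------

# Sparsity pattern of the stacked Jacobian: couplings are local within
# `bw` nodes; `nblock` fields of length N. Supplied to the solver explicitly
# (column-sorted) so the sparse structure never depends on the state.
jac_pattern <- function(N, nblock, bw = 2L) {
  ij <- do.call(rbind, lapply(seq_len(nblock * N), function(i) {
    node <- ((i - 1L) %% N) + 1L
    cols_nodes <- max(1L, node - bw):min(N, node + bw)
    cbind(i, c(outer(cols_nodes, (seq_len(nblock) - 1L) * N, `+`)))
  }))
  ij[order(ij[, 2L], ij[, 1L]), , drop = FALSE]
}

# Derivative closures in deSolve form. When the Marangoni number is zero the
# surfactant has no dynamical effect and its passive advection can steepen
# into a tracer shock that stalls the integrator, so Gamma is not evolved.
make_tf_deriv <- function(params, grid) {
  N <- grid$N
  iH <- seq_len(N)
  if (params$M == 0) {
    G0 <- rep(1, N)
    function(t, y, parms) {
      list(tf_rhs_core(y, G0, params, grid)$dH)
    }
  } else {
    iG <- N + iH
    function(t, y, parms) {
      d <- tf_rhs_core(y[iH], y[iG], params, grid)
      list(c(d$dH, d$dGamma))
    }
  }
}

make_tf_largeM_deriv <- function(params, grid) {
  function(t, y, parms) list(tf_largeM_rhs_core(y, params, grid)$dH)
}

make_lw_deriv <- function(params, grid) {
  N <- grid$N
  iR <- seq_len(N)
  if (params$cM == 0) {
    function(t, y, parms) {
      list(lw_rhs_core(y, y, params, grid)$dR) # RG unused when cM = 0
    }
  } else {
    iG <- N + iR
    function(t, y, parms) {
      d <- lw_rhs_core(y[iR], y[iG], params, grid)
      list(c(d$dR, d$dRGamma))
    }
  }
}

default_output_times <- function(t_end, n_out) {
  unique(c(0, 10^seq(log10(t_end) - 4, log10(t_end), length.out = n_out - 1L)))
}

# One chunk of stiff BDF integration (lsodes with the explicit band-block
# sparsity pattern); returns partial output rows when the chunk could not be
# completed so the plug logic still sees every earlier snapshot.
lsodes_safely <- function(y0, times, deriv, inz, rtol, atol) {
  nnz <- nrow(inz)
  out <- tryCatch(
    suppressWarnings(
      deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                   method = "lsodes", sparsetype = "sparseusr", inz = inz,
                   rtol = rtol, atol = atol, maxsteps = 50000L,
                   lrw = 30L * length(y0) + 8L * nnz + 1000L)),
    error = function(e) NULL)
  if (is.null(out)) return(list(ok = FALSE, mat = NULL))
  keep <- stats::complete.cases(out)
  mat <- unclass(out)[keep, , drop = FALSE]
  list(ok = sum(keep) == length(times), mat = mat)
}

#' Integrate a film model in time
#'
#' Method-of-lines integration of the thin-film or long-wave system
#' (selected by the class of `params`). Space is discretised in staggered
#' conservative flux form; time is advanced by the stiff implicit multistep
#' solver (`lsodes`, variable order/step BDF) with an explicit sparse
#' Jacobian pattern. The stacked state is `(H, Gamma)` for the thin-film
#' model and `(R, R*Gamma)` for the long-wave model, so both discrete
#' conservation laws hold to round-off; when the Marangoni number is zero
#' the surfactant is dynamically inert and is not evolved. Long-wave runs
#' are stopped at the plug event (`min R <= plug_threshold`); the crossing
#' is located by re-integration of the bracketing interval and interpolation
#' of the min-R descent.
#'
#' @param state0 Initial [thin_film_state()] or [long_wave_state()]
#'   (see [initial_condition_tf()] and [initial_condition_lw()]).
#' @param params A [thin_film_params()] or [long_wave_params()].
#' @param grid A [film_grid()].
#' @param events An [event_spec()] (stopping rules and output times).
#' @param rtol,atol Relative and absolute integration tolerances.
#' @param large_M Thin-film only: evolve the strong-surfactant
#'   (immobilised-interface) equation instead of the full system; `Gamma` is
#'   held fixed.
#' @return An object of class `film_evolution`: a list with `model`,
#'   `times` (reported, thin-film units), `H` or `R` and `Gamma`
#'   (node-by-time matrices), `plug_formed`, `t_p`, `conservation`
#'   (tibble of relative drifts), `stop_reason`
#'   (`"plugged"`, `"t_end"` or `"failure"`), `params`, `grid`.
#' @examples
#' g <- film_grid(N = 48)
#' p <- thin_film_params(B = 0, M = 0.2, A = 0.2)
#' r <- evolve(initial_condition_tf(0.2, g), p, g,
#'             events = event_spec(t_end = 10))
#' r$stop_reason
#' @export
evolve <- function(state0, params, grid, events = event_spec(),
                   rtol = 1e-8, atol = 1e-10, large_M = FALSE) {
  long_wave <- inherits(params, "long_wave_params")
  if (long_wave && !inherits(state0, "long_wave_state"))
    stop("long-wave parameters require a long-wave state", call. = FALSE)
  if (!long_wave && !inherits(state0, "thin_film_state"))
    stop("thin-film parameters require a thin-film state", call. = FALSE)
  N <- grid$N

  t_out <- events$output_times
  if (is.null(t_out)) t_out <- default_output_times(events$t_end, events$n_out)
  t_out <- t_out[t_out <= events$t_end]
  if (t_out[length(t_out)] < events$t_end) t_out <- c(t_out, events$t_end)
  # native time: t~ for thin film, t = t~ / eps^3 for long wave
  scale <- if (long_wave) params$eps^3 else 1
  t_native <- t_out / scale

  gamma_frozen <- large_M ||
    (if (long_wave) params$cM == 0 else params$M == 0)
  if (long_wave) {
    y0 <- if (gamma_frozen) state0$R else c(state0$R, state0$R * state0$Gamma)
    deriv <- make_lw_deriv(params, grid)
  } else if (large_M) {
    y0 <- state0$H
    deriv <- make_tf_largeM_deriv(params, grid)
  } else {
    y0 <- if (gamma_frozen) state0$H else c(state0$H, state0$Gamma)
    deriv <- make_tf_deriv(params, grid)
  }
  inz <- jac_pattern(N, if (gamma_frozen) 1L else 2L)

  # integrate output-by-output so the run can stop as soon as the plug
  # threshold is crossed (the post-plug state is outside the validity of the
  # long-wave model and integrating into it is expensive)
  rows <- matrix(y0, nrow = 1L)
  times_done <- t_native[1L]
  stop_reason <- "t_end"
  plug_formed <- FALSE
  t_p_native <- NA_real_

  check_plug <- function() {
    if (!long_wave) return(FALSE)
    minR <- apply(rows[, seq_len(N), drop = FALSE], 1L, min)
    hit <- which(minR <= events$plug_threshold)
    if (!length(hit)) return(FALSE)
    j <- hit[1L]
    if (j == 1L) {
      t_p_native <<- times_done[1L]
    } else {
      ref <- refine_plug(rows[j - 1L, ], times_done[j - 1L], times_done[j],
                         deriv, inz, N, events$plug_threshold, rtol, atol)
      rows <<- rbind(rows[seq_len(j - 1L), , drop = FALSE], ref$y_p)
      times_done <<- c(times_done[seq_len(j - 1L)], ref$t_p)
      t_p_native <<- ref$t_p
    }
    plug_formed <<- TRUE
    stop_reason <<- "plugged"
    TRUE
  }

  for (k in seq_len(length(t_native) - 1L)) {
    seg <- t_native[k:(k + 1L)]
    res <- lsodes_safely(rows[nrow(rows), ], seg, deriv, inz, rtol, atol)
    new <- res$mat
    if (!is.null(new) && nrow(new) > 1L) {
      rows <- rbind(rows, new[-1L, -1L, drop = FALSE])
      times_done <- c(times_done, new[-1L, 1L])
    }
    if (check_plug()) break
    if (!res$ok) {
      stop_reason <- "failure"
      break
    }
  }

  build_film_evolution(long_wave, gamma_frozen, rows, times_done * scale,
                       state0, params, grid, plug_formed, t_p_native * scale,
                       stop_reason)
}

# Locate the plug crossing inside [ta, tb] by re-integration with dense
# output and interpolation of the min-R series; returns the crossing time
# and a linearly interpolated state there.
refine_plug <- function(y_a, ta, tb, deriv, inz, N, threshold,
                        rtol, atol, n_fine = 33L, depth = 2L) {
  tt <- seq(ta, tb, length.out = n_fine)
  y <- y_a
  t_prev <- ta
  minR_prev <- min(y[seq_len(N)])
  for (k in 2:n_fine) {
    res <- lsodes_safely(y, tt[(k - 1L):k], deriv, inz, rtol, atol)
    if (is.null(res$mat) || nrow(res$mat) < 2L)
      return(list(t_p = t_prev, y_p = y)) # keep the last state reached
    y_new <- res$mat[2L, -1L]
    minR <- min(y_new[seq_len(N)])
    if (minR <= threshold) {
      # recurse into the bracketing interval while the descent is steep,
      # then land on the crossing with one short exact integration so the
      # reported plug state lies on the trajectory
      if (depth > 1L)
        return(refine_plug(y, t_prev, tt[k], deriv, inz, N, threshold,
                           rtol, atol, n_fine, depth - 1L))
      f <- (threshold - minR_prev) / (minR - minR_prev)
      t_p <- t_prev + f * (tt[k] - t_prev)
      res2 <- lsodes_safely(y, c(t_prev, t_p), deriv, inz, rtol, atol)
      y_p <- if (!is.null(res2$mat) && nrow(res2$mat) == 2L)
        res2$mat[2L, -1L] else (1 - f) * y + f * y_new
      return(list(t_p = t_p, y_p = y_p))
    }
    y <- y_new
    t_prev <- tt[k]
    minR_prev <- minR
  }
  list(t_p = tb, y_p = y)
}

build_film_evolution <- function(long_wave, gamma_frozen, rows, times_tilde,
                                 state0, params, grid, plug_formed, t_p,
                                 stop_reason) {
  N <- grid$N
  nt <- nrow(rows)
  if (long_wave) {
    R <- t(rows[, seq_len(N), drop = FALSE])
    Gamma <- if (gamma_frozen) matrix(state0$Gamma, N, nt) else
      t(rows[, N + seq_len(N), drop = FALSE]) / R
    H <- NULL
    vol <- apply(R, 2L, function(r) grid_integral(1 - r^2, grid))
    cons <- tibble::tibble(
      quantity = "liquid volume",
      initial = vol[1L],
      max_rel_drift = max(abs(vol / vol[1L] - 1)),
      t_worst = times_tilde[which.max(abs(vol / vol[1L] - 1))])
    if (!gamma_frozen) { # with frozen Gamma the surface density is not tracked
      surf <- apply(R * Gamma, 2L, grid_integral, grid = grid)
      cons <- dplyr::bind_rows(cons, tibble::tibble(
        quantity = "total surfactant",
        initial = surf[1L],
        max_rel_drift = max(abs(surf / surf[1L] - 1)),
        t_worst = times_tilde[which.max(abs(surf / surf[1L] - 1))]))
    }
  } else {
    H <- t(rows[, seq_len(N), drop = FALSE])
    Gamma <- if (gamma_frozen) matrix(state0$Gamma, N, nt) else
      t(rows[, N + seq_len(N), drop = FALSE])
    R <- NULL
    mass <- apply(H, 2L, grid_integral, grid = grid)
    cons <- tibble::tibble(
      quantity = "film mass",
      initial = mass[1L],
      max_rel_drift = max(abs(mass / mass[1L] - 1)),
      t_worst = times_tilde[which.max(abs(mass / mass[1L] - 1))])
    if (!gamma_frozen) {
      surf <- apply(Gamma, 2L, grid_integral, grid = grid)
      cons <- dplyr::bind_rows(cons, tibble::tibble(
        quantity = "total surfactant",
        initial = surf[1L],
        max_rel_drift = max(abs(surf / surf[1L] - 1)),
        t_worst = times_tilde[which.max(abs(surf / surf[1L] - 1))]))
    }
  }
  structure(list(
    model = if (long_wave) "long_wave" else "thin_film",
    times = times_tilde, H = H, R = R, Gamma = Gamma,
    plug_formed = plug_formed, t_p = if (plug_formed) t_p else NA_real_,
    conservation = cons, stop_reason = stop_reason,
    params = params, grid = grid), class = "film_evolution")
}

#' @export
print.film_evolution <- function(x, ...) {
  cat(sprintf("<film_evolution> %s model, %d snapshots to t~ = %.4g (%s)\n",
              x$model, length(x$times), max(x$times), x$stop_reason))
  if (isTRUE(x$plug_formed))
    cat(sprintf("  plug formed at t~_p = %.4g\n", x$t_p))
  cat(sprintf("  max conservation drift: %.3g\n",
              max(x$conservation$max_rel_drift)))
  invisible(x)
}

#' Plugging time of a simulation
#'
#' First time at which the minimum interface radius reaches the plug
#' threshold, located by monotone interpolation of the stored min-R series.
#' Returns `NA` for stable runs and for thin-film runs (no plug can form in
#' the thin-film theory).
#'
#' @param result A [evolve()] result.
#' @param plug_threshold Threshold on \eqn{\min_z R}; defaults to 0.3.
#' @return Plugging time in thin-film units, or `NA`.
#' @export
detect_plug <- function(result, plug_threshold = 0.3) {
  stopifnot(inherits(result, "film_evolution"))
  if (is.null(result$R)) return(NA_real_)
  minR <- apply(result$R, 2L, min)
  if (min(minR) > plug_threshold * (1 + 1e-3)) return(NA_real_)
  j <- which(minR <= plug_threshold * (1 + 1e-3))[1L]
  if (j == 1L) return(unname(result$times[1L]))
  f <- min(1, (plug_threshold - minR[j - 1L]) / (minR[j] - minR[j - 1L]))
  unname(result$times[j - 1L] + f * (result$times[j] - result$times[j - 1L]))
}

#' Critical film thickness for plug formation
#'
#' Bisection on the film-thickness ratio \eqn{\epsilon}: the critical value
#' \eqn{\epsilon_{crit}} is such that a long-wave simulation with
#' \eqn{\epsilon_{crit} + tol} forms a plug before `t_end` while one with
#' \eqn{\epsilon_{crit} - tol} does not. Each bisection step runs a full
#' simulation.
#'
#' @param cB,cM Capillary Bingham and Marangoni numbers.
#' @param A Initial perturbation amplitude.
#' @param bracket Length-2 vector `c(lo, hi)` of thickness ratios straddling
#'   the transition (`lo` stable, `hi` plugging).
#' @param tol Half-width of the final bracket.
#' @param t_end Simulation horizon in thin-film units.
#' @param grid A [film_grid()].
#' @param ... Passed to [evolve()] (e.g. `rtol`, `atol`).
#' @return A list with `eps_crit` (bracket midpoint), `bracket` (final
#'   bracket), `n_runs`, and `runs` (tibble: eps, plugged, t_p).
#' @export
epsilon_crit_search <- function(cB, cM, A = 0.25, bracket = c(0.1, 0.2),
                                tol = 0.001, t_end = 1e4,
                                grid = film_grid(), ...) {
  stopifnot(length(bracket) == 2L, bracket[1L] < bracket[2L], tol > 0)
  runs <- list()
  plugs <- function(eps) {
    p <- long_wave_params(cB = cB, cM = cM, eps = eps, A = A, L = grid$L)
    r <- evolve(initial_condition_lw(A, eps, grid), p, grid,
                events = event_spec(t_end = t_end), ...)
    runs[[length(runs) + 1L]] <<- tibble::tibble(
      eps = eps, plugged = r$plug_formed, t_p = r$t_p)
    if (r$stop_reason == "failure" && !r$plug_formed)
      stop("simulation failed at eps = ", eps, call. = FALSE)
    r$plug_formed
  }
  lo <- bracket[1L]
  hi <- bracket[2L]
  if (plugs(lo)) stop("lower bracket already forms a plug", call. = FALSE)
  if (!plugs(hi)) stop("upper bracket does not form a plug", call. = FALSE)
  while ((hi - lo) / 2 > tol) {
    mid <- (lo + hi) / 2
    if (plugs(mid)) hi <- mid else lo <- mid
  }
  list(eps_crit = (lo + hi) / 2, bracket = c(lo, hi), n_runs = length(runs),
       runs = dplyr::bind_rows(runs))
}
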