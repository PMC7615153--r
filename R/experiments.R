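# Initial-condition generators, figure-style experiment presets, parameter
# sweeps and file I/O. The initial conditions double as the synthetic-data
# surface of the package: every test state is built from them or from
# manufactured profiles; there is no external data path.

#' Thin-film initial condition
#'
#' A single-mode interface perturbation with wavelength `2L` and uniform
#' surfactant: \eqn{H(z,0) = 1 - A\cos(\pi z/L)}, \eqn{\Gamma(z,0) = 1}.
#' The cosine integrates to zero, so \eqn{\int H\,dz = L} for every `A`.
#'
#' @param A Perturbation amplitude, `0 <= A < 1`.
#' @param grid A [film_grid()].
#' @return A [thin_film_state()] at \eqn{\tilde t = 0}.
#' @export
initial_condition_tf <- function(A, grid) {
  stopifnot(A >= 0, A < 1)
  thin_film_state(H = 1 - A * cos(pi * grid$z / grid$L),
                  Gamma = rep(1, grid$N))
}

#' Long-wave initial condition
#'
#' \eqn{R(z,0) = \sqrt{(1-\epsilon)^2 - \epsilon^2 A^2/2} - \epsilon A
#' \cos(\pi z/L)}, \eqn{\Gamma(z,0) = 1}. The constant offset makes the
#' liquid volume independent of the perturbation amplitude:
#' \eqn{\int R^2 dz = (1-\epsilon)^2 L} exactly, so \eqn{\epsilon} is the
#' thickness ratio of the equivalent unperturbed layer.
#'
#' @param A Perturbation amplitude.
#' @param eps Film-thickness ratio \eqn{\epsilon \in (0,1)}.
#' @param grid A [film_grid()].
#' @return A [long_wave_state()] at `t = 0`.
#' @export
initial_condition_lw <- function(A, eps, grid) {
  stopifnot(A >= 0, eps > 0, eps < 1)
  base2 <- (1 - eps)^2 - eps^2 * A^2 / 2
  if (base2 <= 0)
    stop("perturbation too large: initial radius would leave (0, 1)",
         call. = FALSE)
  R <- sqrt(base2) - eps * A * cos(pi * grid$z / grid$L)
  if (any(R <= 0) || any(R >= 1))
    stop("initial radius leaves (0, 1); reduce A or eps", call. = FALSE)
  long_wave_state(R = R, Gamma = rep(1, grid$N))
}

#' Named experiment presets
#'
#' Returns the configuration of the package's standard example experiments
#' (the sample thin-film evolution, the plug-forming long-wave runs with
#' weak and strong surfactant, and the critical-thickness sweeps), as a list
#' with `model`, `params`, `events` and `N`.
#'
#' @param name One of `"tf_sample"` (thin film, B = 0.04, M = 0.2, A = 0.2),
#'   `"tf_small_M"` (B = 0.04, M = 0.08), `"lw_clean"` (long wave,
#'   eps = 0.14, cB = 0.001, cM = 0, A = 0.2), `"lw_surfactant"` (as
#'   `lw_clean` with cM = 0.02), `"lw_strong_surfactant"` (eps = 0.14,
#'   cM = 10, cB = 0.001, A = 0.25), `"ecrit_clean"`, `"ecrit_surfactant"`
#'   (cB = 0.0024 sweeps at cM = 0 / 0.4, A = 0.25).
#' @return A list describing the experiment.
#' @export
preset_experiment <- function(name) {
  presets <- list(
    tf_sample = list(model = "thin_film",
                     params = thin_film_params(B = 0.04, M = 0.2, A = 0.2)),
    tf_small_M = list(model = "thin_film",
                      params = thin_film_params(B = 0.04, M = 0.08, A = 0.2)),
    lw_clean = list(model = "long_wave",
                    params = long_wave_params(cB = 0.001, cM = 0, eps = 0.14,
                                              A = 0.2)),
    lw_surfactant = list(model = "long_wave",
                         params = long_wave_params(cB = 0.001, cM = 0.02,
                                                   eps = 0.14, A = 0.2)),
    lw_strong_surfactant = list(model = "long_wave",
                                params = long_wave_params(cB = 0.001, cM = 10,
                                                          eps = 0.14,
                                                          A = 0.25)),
    ecrit_clean = list(model = "ecrit", cB = 0.0024, cM = 0, A = 0.25),
    ecrit_surfactant = list(model = "ecrit", cB = 0.0024, cM = 0.4, A = 0.25)
  )
  if (!name %in% names(presets))
    stop("unknown preset; available: ", paste(names(presets), collapse = ", "),
         call. = FALSE)
  c(presets[[name]], list(events = event_spec(), N = 200L, name = name))
}

#' Run a preset experiment
#'
#' @param name A [preset_experiment()] name (simulation presets only).
#' @param N Grid resolution override.
#' @param ... Passed to [evolve()].
#' @return A [evolve()] result.
#' @export
run_preset <- function(name, N = 200L, ...) {
  cfg <- preset_experiment(name)
  if (cfg$model == "ecrit")
    stop("use sweep_ecrit() for the critical-thickness presets",
         call. = FALSE)
  g <- film_grid(cfg$params$L, N)
  state0 <- if (cfg$model == "thin_film")
    initial_condition_tf(cfg$params$A, g)
  else
    initial_condition_lw(cfg$params$A, cfg$params$eps, g)
  evolve(state0, cfg$params, g, events = cfg$events, ...)
}

#' Final peak height over a (B, M) grid of thin-film runs
#'
#' Runs one thin-film simulation per grid point and reports the final peak
#' height \eqn{\max_z H} together with the predicted stability references:
#' the surface-yielding boundary `2M = BL` and the static thresholds
#' \eqn{B_m(A)} and \eqn{2B_m(A)}.
#'
#' @param B_values,M_values Axes of the sweep.
#' @param A Initial perturbation amplitude.
#' @param t_end Horizon of each run (thin-film units).
#' @param grid A [film_grid()].
#' @param ... Passed to [evolve()].
#' @return A tibble with one row per run: `B`, `M`, `final_peak`, `growth`,
#'   `plus` the reference thresholds as attributes `B_m` and `2B_m`.
#' @export
sweep_final_peak <- function(B_values, M_values, A = 0.2, t_end = 1e4,
                             grid = film_grid(), ...) {
  cases <- tidyr::expand_grid(B = B_values, M = M_values)
  res <- purrr::pmap_dfr(cases, function(B, M) {
    p <- thin_film_params(B = B, M = M, A = A, L = grid$L)
    r <- evolve(initial_condition_tf(A, grid), p, grid,
                events = event_spec(t_end = t_end), ...)
    nt <- ncol(r$H)
    tibble::tibble(B = B, M = M,
                   final_peak = max(r$H[, nt]),
                   growth = max(r$H[, nt]) - max(r$H[, 1L]),
                   surface_yielded = 2 * M >= B * grid$L,
                   stop_reason = r$stop_reason)
  })
  Bm <- bm_of_A(A, L = grid$L)$B_m
  attr(res, "B_m") <- Bm
  attr(res, "2B_m") <- 2 * Bm
  attr(res, "A") <- A
  res
}

#' Critical-thickness sweep
#'
#' Runs [epsilon_crit_search()] for each value of the chosen axis
#' (capillary Bingham number or Marangoni number), reproducing the
#' critical-thickness curves for plug formation.
#'
#' @param cB_values,cM_values Exactly one of these of length > 1 (the sweep
#'   axis); the other is a single fixed value.
#' @param A Initial perturbation amplitude.
#' @param bracket,tol,t_end,grid,... Passed to [epsilon_crit_search()].
#' @return A tibble with columns `cB`, `cM`, `eps_crit`, `n_runs`.
#' @export
sweep_ecrit <- function(cB_values, cM_values, A = 0.25,
                        bracket = c(0.1, 0.22), tol = 0.001, t_end = 1e4,
                        grid = film_grid(), ...) {
  cases <- tidyr::expand_grid(cB = cB_values, cM = cM_values)
  purrr::pmap_dfr(cases, function(cB, cM) {
    s <- epsilon_crit_search(cB = cB, cM = cM, A = A, bracket = bracket,
                             tol = tol, t_end = t_end, grid = grid, ...)
    tibble::tibble(cB = cB, cM = cM, eps_crit = s$eps_crit,
                   n_runs = s$n_runs)
  })
}

# --- configuration and result I/O ------------------------------------------

#' Read a simulation configuration file
#'
#' Flat key-value YAML: `model` (`thin_film` or `long_wave`), the model's
#' dimensionless groups (`B`, `M` or `cB`, `cM`, `eps`), `A`, `L`, `N`,
#' `t_end`, `plug_threshold`, `rtol`, `atol`. Missing keys take the package
#' defaults. The simulators are deterministic, so no seed is involved.
#'
#' @param path Path to a YAML file.
#' @return A list with `model`, `params`, `grid`, `events`, `rtol`, `atol`.
#' @export
read_film_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 parses a bare `N` key as a boolean; recover it
  names(cfg)[names(cfg) %in% c("FALSE", "false")] <- "N"
  model <- match.arg(cfg$model, c("thin_film", "long_wave"))
  L <- cfg$L %||% 2 * pi
  A <- cfg$A %||% 0.2
  Y_min <- cfg$Y_min %||% 1e-8
  params <- if (model == "thin_film")
    thin_film_params(B = cfg$B %||% 0, M = cfg$M %||% 0, A = A, L = L,
                     Y_min = Y_min)
  else
    long_wave_params(cB = cfg$cB %||% 0, cM = cfg$cM %||% 0,
                     eps = cfg$eps %||% stop("long_wave config needs `eps`"),
                     A = A, L = L, Y_min = Y_min)
  list(model = model, params = params,
       grid = film_grid(L, cfg$N %||% 200L),
       events = event_spec(plug_threshold = cfg$plug_threshold %||% 0.3,
                           t_end = cfg$t_end %||% 1e4,
                           n_out = cfg$n_out %||% 61L),
       rtol = cfg$rtol %||% 1e-8, atol = cfg$atol %||% 1e-10)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the tabular summary of a run to CSV
#'
#' One row per stored time with the scalar diagnostics (peak thickness or
#' minimum radius, maximum wall stress, conserved integrals); see
#' [tidy.film_evolution()].
#'
#' @param result A [evolve()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(result, path) {
  utils::write.csv(generics::tidy(result), path, row.names = FALSE)
  invisible(path)
}

#' Write per-node snapshot arrays of a run
#'
#' Plain-text array container: one `z.csv` axis file plus one CSV per field
#' (`H` or `R`, `Gamma`, `pz`, `q` or `Q`, `ws`, `tau_w`, `Y_minus`/
#' `Psi_minus`, `Y_plus`/`Psi_plus`, integer `regime` codes), each with one
#' column per stored time, named by the time value.
#'
#' @param result A [evolve()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_snapshots <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid <- result$grid
  fields <- snapshot_fields(result)
  utils::write.csv(data.frame(z = grid$z), file.path(dir, "z.csv"),
                   row.names = FALSE)
  tnames <- sprintf("t_%.8g", result$times)
  for (nm in names(fields)) {
    m <- fields[[nm]]
    colnames(m) <- tnames
    utils::write.csv(m, file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  invisible(dir)
}

# per-snapshot diagnostic fields of a finished run
snapshot_fields <- function(result) {
  grid <- result$grid
  params <- result$params
  nt <- length(result$times)
  if (result$model == "long_wave") {
    out <- list(R = result$R, Gamma = result$Gamma)
    extra <- c("pz", "Q", "ws", "tau_w", "Psi_minus", "Psi_plus", "regime")
    for (nm in extra) out[[nm]] <- matrix(0, grid$N, nt)
    for (j in seq_len(nt)) {
      st <- long_wave_state(result$R[, j], result$Gamma[, j])
      f <- lw_fields(st, params, grid)
      out$pz[, j] <- f$pz
      out$Q[, j] <- f$Q
      out$ws[, j] <- f$ws
      out$tau_w[, j] <- f$tau_w
      out$Psi_minus[, j] <- f$surfaces$Psi_minus
      out$Psi_plus[, j] <- f$surfaces$Psi_plus
      out$regime[, j] <- as.integer(f$surfaces$regime)
    }
  } else {
    out <- list(H = result$H, Gamma = result$Gamma)
    extra <- c("pz", "q", "ws", "tau_w", "Y_minus", "Y_plus", "regime")
    for (nm in extra) out[[nm]] <- matrix(0, grid$N, nt)
    for (j in seq_len(nt)) {
      f <- tf_fields(result$H[, j], result$Gamma[, j], params, grid)
      out$pz[, j] <- f$pz
      out$q[, j] <- f$q
      out$ws[, j] <- f$ws
      out$tau_w[, j] <- f$tau_w
      out$Y_minus[, j] <- f$surfaces$Y_minus
      out$Y_plus[, j] <- f$surfaces$Y_plus
      out$regime[, j] <- as.integer(f$surfaces$regime)
    }
  }
  out
}
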