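# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the scalar time series of a simulation
#'
#' @param x A [evolve()] result.
#' @param ... Unused.
#' @return A tibble with one row per stored time: `time` (thin-film units),
#'   `max_H`, `min_R` (long-wave runs; `NA` otherwise), `max_abs_tau_w`,
#'   `mass` and `surfactant` (the conserved integrals).
#' @export
tidy.film_evolution <- function(x, ...) {
  grid <- x$grid
  nt <- length(x$times)
  long_wave <- x$model == "long_wave"
  max_H <- min_R <- tau <- mass <- surf <- numeric(nt)
  for (j in seq_len(nt)) {
    if (long_wave) {
      st <- long_wave_state(x$R[, j], x$Gamma[, j])
      f <- lw_fields(st, x$params, grid)
      max_H <- replace(max_H, j, (1 - min(x$R[, j])) / x$params$eps)
      min_R[j] <- min(x$R[, j])
      mass[j] <- grid_integral(1 - x$R[, j]^2, grid)
      surf[j] <- grid_integral(x$R[, j] * x$Gamma[, j], grid)
    } else {
      f <- tf_fields(x$H[, j], x$Gamma[, j], x$params, grid)
      max_H[j] <- max(x$H[, j])
      min_R[j] <- NA_real_
      mass[j] <- grid_integral(x$H[, j], grid)
      surf[j] <- grid_integral(x$Gamma[, j], grid)
    }
    tau[j] <- max(abs(f$tau_w))
  }
  tibble::tibble(time = x$times, max_H = max_H, min_R = min_R,
                 max_abs_tau_w = tau, mass = mass, surfactant = surf)
}

#' One-row summary of a simulation
#'
#' @param x A [evolve()] result.
#' @param ... Unused.
#' @return A one-row tibble: `model`, `n_times`, `t_final`, `plug_formed`,
#'   `t_p`, `max_drift`, `stop_reason`.
#' @export
glance.film_evolution <- function(x, ...) {
  tibble::tibble(model = x$model, n_times = length(x$times),
                 t_final = max(x$times), plug_formed = x$plug_formed,
                 t_p = x$t_p, max_drift = max(x$conservation$max_rel_drift),
                 stop_reason = x$stop_reason)
}

#' Tidy a static continuation curve
#'
#' @param x A [static_continuation()] tibble.
#' @param ... Unused.
#' @return The `(A, B, max_H0, branch)` columns as a plain tibble.
#' @export
tidy.static_continuation <- function(x, ...) {
  tibble::as_tibble(x[c("A", "B", "max_H0", "branch")])
}

#' Plot the interface evolution of a run
#'
#' Interface profiles (thickness `H` for thin-film runs, radius `R` for
#' long-wave runs) at the stored times, coloured by time.
#'
#' @param object A [evolve()] result.
#' @param times Optional subset of times to draw (nearest stored snapshots).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.film_evolution <- function(object, times = NULL, ...) {
  long_wave <- object$model == "long_wave"
  mat <- if (long_wave) object$R else object$H
  idx <- if (is.null(times)) seq_along(object$times) else
    unique(vapply(times, function(t) which.min(abs(object$times - t)),
                  integer(1L)))
  df <- purrr::map_dfr(idx, function(j) tibble::tibble(
    z = object$grid$z, value = mat[, j], time = object$times[j]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$value,
                                   colour = .data$time,
                                   group = .data$time)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z", colour = "t~",
                  y = if (long_wave) "interface radius R" else
                    "layer thickness H") +
    ggplot2::theme_minimal()
}

#' Plot a regime map
#'
#' @param object A [regime_map()] tibble.
#' @param ... Unused.
#' @return A ggplot object (tile map of yielding types I-V).
#' @export
autoplot.regime_map <- function(object, ...) {
  lab <- if (attr(object, "model") == "thin_film")
    c(x = "H pz / B", y = "M Gamma_z / B")
  else c(x = "pz / B", y = "M Gamma_z / B")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y,
                                       fill = .data$regime)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_d(drop = FALSE) +
    ggplot2::labs(x = lab[["x"]], y = lab[["y"]], fill = "yielding type") +
    ggplot2::theme_minimal()
}

#' Plot a static continuation curve
#'
#' @param object A [static_continuation()] tibble.
#' @param ... Unused.
#' @return A ggplot object of `max_H0` against `B` by branch.
#' @export
autoplot.static_continuation <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$B, y = .data$max_H0,
                               linetype = .data$branch)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "B", y = "max H0", linetype = "branch") +
    ggplot2::theme_minimal()
}
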