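#' Uniform computational grid on \eqn{[0, L]}
#'
#' Node-centred uniform grid including both endpoints, used by both the
#' thin-film and long-wave models. Lengths are measured in units of the tube
#' radius. The default domain length \eqn{L = 2\pi} accommodates the most
#' unstable Fourier mode of the Newtonian Rayleigh-Plateau instability; the
#' default resolution is \eqn{N = 200} nodes.
#'
#' @param L Domain length (tube-radius units). Must be positive.
#' @param N Number of nodes, including both endpoints. Must be at least 8.
#' @return An object of class `film_grid`: a list with fields `z` (node
#'   positions), `dz` (uniform spacing `L/(N-1)`), `N` and `L`.
#' @examples
#' g <- film_grid(L = 2 * pi, N = 200)
#' g$dz # 2*pi/199
#' @export
film_grid <- function(L = 2 * pi, N = 200L) {
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L <= 0)
    stop("`L` must be a single positive number", call. = FALSE)
  N <- as.integer(N)
  if (is.na(N) || N < 8L)
    stop("`N` must be an integer >= 8", call. = FALSE)
  dz <- L / (N - 1)
  structure(
    list(z = seq(0, L, length.out = N), dz = dz, N = N, L = L),
    class = "film_grid"
  )
}

#' @export
print.film_grid <- function(x, ...) {
  cat(sprintf("<film_grid> N = %d nodes on [0, %.6g], dz = %.6g\n",
              x$N, x$L, x$dz))
  invisible(x)
}

check_field <- function(f, grid) {
  if (length(f) != grid$N)
    stop("field length (", length(f), ") does not match grid (", grid$N, ")",
         call. = FALSE)
  invisible(f)
}

# Ghost-padded copies implementing the symmetry (even-extension) boundary
# conditions: fields such as H, R and Gamma are even about z = 0 and z = L,
# so f[-k] = f[k] and f[N+k] = f[N-k].
pad_even <- function(f, n) {
  N <- length(f)
  if (n == 1L) c(f[2L], f, f[N - 1L])
  else c(f[3L], f[2L], f, f[N - 1L], f[N - 2L])
}

# Odd extension about both ends for flux-like quantities (q, w_s*Gamma, Q),
# which vanish at the boundaries and are odd under reflection.
pad_odd <- function(f, n) {
  N <- length(f)
  if (n == 1L) c(-f[2L], f, -f[N - 1L])
  else c(-f[3L], -f[2L], f, -f[N - 1L], -f[N - 2L])
}

#' Finite-difference derivatives with symmetry boundary handling
#'
#' Second-order central differences on a [film_grid()], using even ghost
#' extension at both ends (so first and third derivatives of symmetric fields
#' vanish exactly at `z = 0` and `z = L`). `d3()` uses a 5-point stencil; the
#' two nodes adjacent to each boundary use ghost-reflected values, preserving
#' uniform second-order accuracy.
#'
#' @param f Numeric field sampled at the grid nodes.
#' @param grid A [film_grid()].
#' @return Numeric vector of the same length: the first (`d1`), second (`d2`)
#'   or third (`d3`) derivative of `f`.
#' @examples
#' g <- film_grid(N = 64)
#' max(abs(d1(rep(1, g$N), g))) # exactly 0
#' @export
d1 <- function(f, grid) {
  check_field(f, grid)
  p <- pad_even(f, 1L)
  N <- grid$N
  (p[3:(N + 2)] - p[1:N]) / (2 * grid$dz)
}

#' @rdname d1
#' @export
d2 <- function(f, grid) {
  check_field(f, grid)
  p <- pad_even(f, 1L)
  N <- grid$N
  (p[3:(N + 2)] - 2 * f + p[1:N]) / grid$dz^2
}

#' @rdname d1
#' @export
d3 <- function(f, grid) {
  check_field(f, grid)
  p <- pad_even(f, 2L)
  N <- grid$N
  i <- 3:(N + 2) # position of node i in the padded vector
  (-p[i - 2] + 2 * p[i - 1] - 2 * p[i + 1] + p[i + 2]) / (2 * grid$dz^3)
}

#' Divergence of a boundary-vanishing flux
#'
#' Central difference of a flux that is zero at both domain ends and odd under
#' reflection there (as the volume flux and surfactant flux are, by the
#' zero-flux boundary conditions). The boundary values of `flux` are pinned to
#' zero before differencing. With trapezoidal quadrature this operator is
#' discretely conservative: the weighted sum of the divergence vanishes to
#' round-off.
#'
#' @param flux Numeric flux field at the nodes.
#' @param grid A [film_grid()].
#' @return The derivative d(flux)/dz at the nodes.
#' @export
flux_div <- function(flux, grid) {
  check_field(flux, grid)
  N <- grid$N
  flux[c(1L, N)] <- 0
  p <- pad_odd(flux, 1L)
  (p[3:(N + 2)] - p[1:N]) / (2 * grid$dz)
}

#' Composite trapezoidal integral over the grid
#'
#' @param f Numeric field at the nodes.
#' @param grid A [film_grid()].
#' @return Scalar value of \eqn{\int_0^L f\, dz} (second-order accurate).
#' @examples
#' g <- film_grid()
#' grid_integral(rep(1, g$N), g) # 2*pi
#' @export
grid_integral <- function(f, grid) {
  check_field(f, grid)
  N <- grid$N
  grid$dz * (sum(f) - (f[1L] + f[N]) / 2)
}

# Cumulative trapezoidal integral from z = 0 to each node.
grid_cumintegral <- function(f, grid) {
  check_field(f, grid)
  c(0, cumsum((f[-1L] + f[-grid$N]) / 2)) * grid$dz
}

# --- generic (non-symmetric) finite differences -----------------------------
# The late-time asymptotic fields are not all symmetric about the domain ends
# (the static surfactant profile is linear in z), so these variants use
# skewed one-sided stencils near the boundaries instead of ghost reflection.

# Finite-difference weights for the m-th derivative at offset 0 given
# integer node offsets `offs` (in units of dz), by solving the Taylor system.
fd_weights <- function(offs, m) {
  n <- length(offs)
  A <- outer(0:(n - 1), offs, function(k, s) s^k / factorial(k))
  b <- numeric(n)
  b[m + 1] <- 1
  solve(A, b)
}

d1_general <- function(f, grid) {
  check_field(f, grid)
  N <- grid$N
  out <- numeric(N)
  out[2:(N - 1)] <- (f[3:N] - f[1:(N - 2)]) / (2 * grid$dz)
  out[1] <- sum(fd_weights(0:2, 1L) * f[1:3]) / grid$dz
  out[N] <- sum(fd_weights(0:-2, 1L) * f[N:(N - 2)]) / grid$dz
  out
}

d3_general <- function(f, grid) {
  check_field(f, grid)
  N <- grid$N
  out <- numeric(N)
  i <- 3:(N - 2)
  out[i] <- (-f[i - 2] + 2 * f[i - 1] - 2 * f[i + 1] + f[i + 2]) /
    (2 * grid$dz^3)
  out[1] <- sum(fd_weights(0:5, 3L) * f[1:6]) / grid$dz^3
  out[2] <- sum(fd_weights(-1:4, 3L) * f[1:6]) / grid$dz^3
  out[N] <- sum(fd_weights(0:-5, 3L) * f[N:(N - 5)]) / grid$dz^3
  out[N - 1] <- sum(fd_weights(1:-4, 3L) * f[N:(N - 5)]) / grid$dz^3
  out
}
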