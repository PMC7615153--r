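# Shared fixtures: manufactured smooth states and small grids. Everything is
# generated in code; no data files are involved.

tiny_grid <- function(N = 64L, L = 2 * pi) film_grid(L, N)

# smooth even-symmetric thin-film state with yielded structure
manufactured_tf_state <- function(grid, amp = 0.3, gamp = 0.05) {
  thin_film_state(H = 1 - amp * cos(pi * grid$z / grid$L),
                  Gamma = 1 + gamp * cos(pi * grid$z / grid$L))
}

manufactured_lw_state <- function(grid, eps = 0.2, amp = 0.3, gamp = 0.05) {
  long_wave_state(R = 1 - eps * (1 - amp * cos(pi * grid$z / grid$L)),
                  Gamma = 1 + gamp * cos(pi * grid$z / grid$L))
}

# trapezoid weights (independent of grid_integral, for adjointness checks)
trap_w <- function(grid) c(0.5, rep(1, grid$N - 2L), 0.5) * grid$dz

expect_rel_equal <- function(x, y, tol) {
  testthat::expect_lt(max(abs(x - y)) / max(abs(y), 1e-300), tol)
}
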