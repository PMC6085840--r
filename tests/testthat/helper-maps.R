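# Programmatic map fixtures for the 2-D solver tests.

uniform_map <- function(ncell, n0, lambda0, half = 5e-6) {
  xe <- seq(-half, half, length.out = ncell + 1)
  x <- (xe[-1] + xe[-length(xe)]) / 2
  structure(
    list(
      x = x, y = x, xe = xe, ye = xe,
      eps = matrix(complex(real = n0^2), ncell, ncell),
      region = matrix("core", ncell, ncell),
      lambda0 = lambda0, design = "uniform"
    ),
    class = "permittivity_map"
  )
}

# step-index circular fiber; `averaged` controls sub-cell index averaging
step_fiber_map <- function(ncell, n_core, n_clad, lambda0,
                           a = 5e-6, half = 10e-6, averaged = TRUE) {
  xe <- seq(-half, half, length.out = ncell + 1)
  x <- (xe[-1] + xe[-length(xe)]) / 2
  if (averaged) {
    off <- (seq_len(4) - 0.5) / 4
    dx <- diff(xe)
    acc <- matrix(0, ncell, ncell)
    for (ox in off) {
      for (oy in off) {
        sx <- xe[-length(xe)] + ox * dx
        pxs <- matrix(sx, ncell, ncell)
        pys <- t(pxs)
        acc <- acc + ifelse(pxs^2 + pys^2 < a^2, n_core^2, n_clad^2)
      }
    }
    eps <- matrix(complex(real = acc / 16), ncell, ncell)
  } else {
    px <- matrix(x, ncell, ncell)
    py <- t(px)
    eps <- matrix(
      complex(real = ifelse(px^2 + py^2 < a^2, n_core^2, n_clad^2)),
      ncell, ncell
    )
  }
  structure(
    list(
      x = x, y = x, xe = xe, ye = xe, eps = eps,
      region = matrix("core", ncell, ncell),
      lambda0 = lambda0, design = "fiber"
    ),
    class = "permittivity_map"
  )
}

# 1-D-invariant slab stack extruded along x: silica | gold(t) | buffer
extruded_slab_map <- function(lambda0, t_gold = 50e-9, nx = 9,
                              y_half = 1.5e-6, x_half = 10e-6) {
  ye <- plasmorec:::.graded_axis(
    -y_half, y_half, 2 * y_half / 80,
    list(list(a = -2e-7, b = t_gold + 2e-7, h = t_gold / 10))
  )
  y <- (ye[-1] + ye[-length(ye)]) / 2
  xe <- seq(-x_half, x_half, length.out = nx + 1)
  x <- (xe[-1] + xe[-length(xe)]) / 2
  eps_si <- Re(silica_permittivity(lambda0))
  eps_au <- drude_lorentz_permittivity(lambda0, gold_drude_lorentz())
  eps_w <- 1.334^2
  eps_row <- ifelse(y < 0, eps_si + 0i, ifelse(y < t_gold, eps_au, eps_w + 0i))
  reg_row <- ifelse(y < 0, "core", ifelse(y < t_gold, "gold", "buffer"))
  structure(
    list(
      x = x, y = y, xe = xe, ye = ye,
      eps = matrix(rep(eps_row, each = nx), nx, length(y)),
      region = matrix(rep(reg_row, each = nx), nx, length(y)),
      lambda0 = lambda0, design = "slab"
    ),
    class = "permittivity_map"
  )
}
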