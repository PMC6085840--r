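lam_test <- 680e-9

test_that("homogeneous medium: fundamental mode matches the analytic box mode at O(h^2)", {
  n0 <- 1.45
  L <- 10e-6
  k0 <- 2 * pi / lam_test
  n_exact <- sqrt(n0^2 - 2 * (pi / L / k0)^2)
  errs <- sapply(c(40L, 80L), function(nc) {
    md <- solve_modes(wave_problem(uniform_map(nc, n0, lam_test),
      n_modes = 1, n_eff_guess = n0
    ))
    expect_lt(md[[1]]$residual, 1e-8)
    abs(Re(md[[1]]$n_eff) - n_exact)
  })
  # Richardson: halving h divides the error by ~4
  expect_gt(errs[1] / errs[2], 2.5)
  expect_lt(errs[1] / errs[2], 6)
  expect_lt(errs[2], 1e-6)
})

test_that("step-index fiber fundamental matches the Bessel dispersion root within 1e-4", {
  n_core <- sqrt(Re(silica_permittivity(lam_test)))
  n_clad <- sqrt(n_core^2 - 0.22^2)
  n_oracle <- lp01_neff(5e-6, n_core, n_clad, lam_test)
  md <- solve_modes(wave_problem(
    step_fiber_map(80L, n_core, n_clad, lam_test),
    n_modes = 1, n_eff_guess = n_core
  ))
  expect_lt(abs(Re(md[[1]]$n_eff) - n_oracle), 1e-4)
  # lossless structure: no spurious modal gain/loss
  expect_gt(Im(md[[1]]$n_eff), -1e-12)
  expect_lt(abs(Im(md[[1]]$n_eff)), 1e-6)
})

test_that("grid refinement shrinks successive effective-index differences", {
  n_core <- sqrt(Re(silica_permittivity(lam_test)))
  n_clad <- sqrt(n_core^2 - 0.22^2)
  ns <- sapply(c(40L, 80L, 160L), function(nc) {
    Re(solve_modes(wave_problem(
      step_fiber_map(nc, n_core, n_clad, lam_test, averaged = FALSE),
      n_modes = 1, n_eff_guess = n_core
    ))[[1]]$n_eff)
  })
  expect_lt(abs(ns[3] - ns[2]), abs(ns[2] - ns[1]))
})

test_that("extruded plasmonic slab matches the 1-D pole search within 1 percent", {
  lam <- 550e-9
  eps_au <- drude_lorentz_permittivity(lam, gold_drude_lorentz())
  st <- layer_stack(
    list(medium_silica(), medium_gold(), medium_buffer(1.334)),
    c(Inf, 50e-9, Inf)
  )
  pole <- planar_pole_search(st, lam, spp_effective_index(eps_au, 1.334^2))
  md <- solve_modes(wave_problem(extruded_slab_map(lam),
    n_modes = 1,
    n_eff_guess = pole
  ))
  expect_lt(abs(Re(md[[1]]$n_eff) - Re(pole)) / Re(pole), 0.01)
  expect_lt(abs(Im(md[[1]]$n_eff) - Im(pole)) / Im(pole), 0.01)
})

test_that("mode fields of mirror-symmetric designs are symmetric or antisymmetric", {
  geom <- fiber_geometry("half_clad_removed")
  map <- build_cross_section(geom, lam_test, base_cells = 80L)
  md <- solve_modes(wave_problem(map, n_modes = 4))
  expect_gte(length(md), 2)
  for (m in md) {
    for (comp in c("Ex", "Ey")) {
      f <- m$fields[[comp]]
      fr <- f[rev(seq_len(nrow(f))), ]
      s <- sqrt(sum(Mod(f - fr)^2))
      a <- sqrt(sum(Mod(f + fr)^2))
      expect_lt(min(s, a) / max(s, a), 1e-6)
    }
    # passive map: no gain
    expect_gt(Im(m$n_eff), -1e-12)
  }
})

test_that("modal attenuation closed forms hold", {
  lam <- 680e-9
  expect_identical(modal_attenuation(complex(real = 1.45), lam, 1e-3), 0)
  # alpha * L = ln 2 -> half the power absorbed
  im <- log(2) * lam / (4 * pi) / 1e-3
  f1 <- modal_attenuation(complex(real = 1.45, imaginary = im), lam, 1e-3)
  expect_equal(f1, 0.5, tolerance = 1e-12)
  # doubling the length composes exponentially
  f2 <- modal_attenuation(complex(real = 1.45, imaginary = im), lam, 2e-3)
  expect_equal(f2, 1 - (1 - f1)^2, tolerance = 1e-12)
  expect_error(
    modal_attenuation(complex(real = 1.45, imaginary = -1e-6), lam, 1e-3),
    "negative modal loss"
  )
})

test_that("aggregate absorption is a weighted mean, invariant under permutation", {
  lam <- 680e-9
  mk <- function(im) {
    structure(
      list(
        n_eff = complex(real = 1.45, imaginary = im),
        fields = NULL, power = 1, residual = 0, lambda0 = lam
      ),
      class = "mode"
    )
  }
  modes <- lapply(c(0, 1e-6, 5e-6), mk)
  w <- c(0.2, 0.5, 0.3)
  direct <- sum(w * vapply(
    modes,
    function(m) modal_attenuation(m, lam, 1e-3), numeric(1)
  ))
  expect_equal(aggregate_absorption(modes, w, lam, 1e-3), direct)
  p <- c(3, 1, 2)
  expect_equal(
    aggregate_absorption(modes[p], w[p], lam, 1e-3),
    aggregate_absorption(modes, w, lam, 1e-3),
    tolerance = 1e-14
  )
  # single mode, weight one
  expect_equal(
    aggregate_absorption(modes[2], 1, lam, 1e-3),
    modal_attenuation(modes[[2]], lam, 1e-3)
  )
  # all lossless -> zero
  expect_identical(
    aggregate_absorption(lapply(c(0, 0), mk), NULL, lam, 1e-3), 0
  )
  expect_error(aggregate_absorption(modes, c(0.5, 0.5), lam, 1e-3), "mismatch")
})
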