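test_that("lossless Drude limit reduces to the closed form", {
  p <- drude_lorentz_params(
    eps_inf = 3, omega_D = 1.2e16, gamma_D = 0,
    omega_L = 4e15, gamma_L = 1e14, delta_eps = 0
  )
  for (lam in c(400e-9, 633e-9, 1500e-9)) {
    w <- 2 * pi * c0_oracle / lam
    eps <- drude_lorentz_permittivity(lam, p)
    expect_equal(Re(eps), 3 - (1.2e16)^2 / w^2, tolerance = 1e-12)
    expect_equal(Im(eps), 0)
  }
})

test_that("Drude-Lorentz reduces to pure Drude when delta_eps = 0", {
  p_dl <- drude_lorentz_params(9, 1.3e16, 1e14, 4e15, 6e14, 0)
  lam <- seq(350e-9, 1800e-9, length.out = 40)
  w <- 2 * pi * c0_oracle / lam
  drude <- 9 - (1.3e16)^2 / (w^2 + 1i * 1e14 * w)
  expect_equal(drude_lorentz_permittivity(lam, p_dl), drude, tolerance = 1e-13)
})

test_that("default gold agrees with tabulated optical constants at 633 nm", {
  tab <- read.table(
    system.file("extdata", "gold_nk_synthetic.tsv", package = "plasmorec"),
    header = FALSE, comment.char = "#",
    col.names = c("wl_nm", "n", "k")
  )
  n633 <- approx(tab$wl_nm, tab$n, 633)$y
  k633 <- approx(tab$wl_nm, tab$k, 633)$y
  eps_tab <- complex(real = n633^2 - k633^2, imaginary = 2 * n633 * k633)
  eps <- drude_lorentz_permittivity(633e-9, gold_drude_lorentz())
  expect_lt(abs(Re(eps) - Re(eps_tab)) / abs(Re(eps_tab)), 0.15)
  expect_lt(abs(Im(eps) - Im(eps_tab)) / abs(Im(eps_tab)), 0.15)
})

test_that("gold permittivity is metallic and lossy across the visible window", {
  lam <- seq(500e-9, 1000e-9, by = 10e-9)
  eps <- drude_lorentz_permittivity(lam, gold_drude_lorentz())
  expect_true(all(Re(eps) < 0))
  lam_all <- seq(300e-9, 2000e-9, by = 25e-9)
  eps_all <- drude_lorentz_permittivity(lam_all, gold_drude_lorentz())
  expect_true(all(Im(eps_all) > 0))
})

test_that("wavelengths outside the validity window are rejected", {
  expect_error(
    drude_lorentz_permittivity(200e-9, gold_drude_lorentz()),
    "validity window"
  )
  expect_error(silica_permittivity(2500e-9), "validity window")
  expect_error(buffer_permittivity(100e-9), "validity window")
})

test_that("zero excess charge leaves the permittivity unchanged exactly", {
  ch0 <- charge_state(potential = 0)
  lam <- c(500e-9, 680e-9, 900e-9)
  expect_identical(
    drude_lorentz_permittivity(lam, gold_drude_lorentz(), ch0),
    drude_lorentz_permittivity(lam, gold_drude_lorentz())
  )
})

test_that("modified plasma frequency satisfies the algebraic identity", {
  wD <- 1.37e16
  N <- gold_electron_density()
  expect_identical(modified_plasma_frequency(wD, 0, N), wD)
  expect_equal(modified_plasma_frequency(wD, 3 * N, N), 2 * wD,
    tolerance = 1e-15
  )
  expect_equal(modified_plasma_frequency(wD, -0.75 * N, N), 0.5 * wD,
    tolerance = 1e-15
  )
  set.seed(7)
  dn <- runif(50, -0.9, 3) * N
  wf <- modified_plasma_frequency(wD, dn, N)
  expect_equal((wf / wD)^2, 1 + dn / N, tolerance = 1e-14)
  # strictly increasing in delta_N
  ord <- order(dn)
  expect_true(all(diff(wf[ord]) > 0))
  expect_error(modified_plasma_frequency(wD, -1.5 * N, N), "positive")
})

test_that("voltage to excess-density mapping is linear with the right scale", {
  expect_identical(voltage_to_delta_N(0, 0.2, 1e-10), 0)
  dn <- voltage_to_delta_N(0.1, 0.2, 1e-10, sign_convention = 1)
  expect_equal(dn, 0.02 / (1.602176634e-19 * 1e-10), tolerance = 1e-14)
  # odd in V
  expect_equal(
    voltage_to_delta_N(-0.05, 0.3, 5e-10),
    -voltage_to_delta_N(0.05, 0.3, 5e-10)
  )
  # superposition over random triples
  set.seed(11)
  for (i in 1:20) {
    v1 <- runif(1, -0.1, 0.1)
    v2 <- runif(1, -0.1, 0.1)
    a <- runif(1, -2, 2)
    expect_equal(
      voltage_to_delta_N(v1 + a * v2, 0.2, 1e-10),
      voltage_to_delta_N(v1, 0.2, 1e-10) +
        a * voltage_to_delta_N(v2, 0.2, 1e-10),
      tolerance = 1e-10
    )
  }
  expect_error(voltage_to_delta_N(0.1, -1, 1e-10), "positive")
  expect_error(voltage_to_delta_N(0.1, 0.2, 0), "positive")
})

test_that("silica Sellmeier and buffer permittivities behave as dielectrics", {
  # independent evaluation of the three-term Sellmeier sum at 589 nm
  l2 <- 0.589^2
  n589 <- sqrt(1 + 0.6961663 * l2 / (l2 - 0.0684043^2) +
    0.4079426 * l2 / (l2 - 0.1162414^2) +
    0.8974794 * l2 / (l2 - 9.896161^2))
  expect_lt(abs(sqrt(Re(silica_permittivity(589e-9))) - 1.458), 0.002)
  expect_equal(sqrt(Re(silica_permittivity(589e-9))), n589, tolerance = 1e-12)
  # normal dispersion
  expect_gt(
    Re(silica_permittivity(400e-9)),
    Re(silica_permittivity(700e-9))
  )
  expect_equal(
    buffer_permittivity(c(500e-9, 800e-9)),
    rep(complex(real = 1.334^2, imaginary = 0), 2)
  )
  expect_true(all(Re(silica_permittivity(seq(300e-9, 2000e-9, 50e-9))) > 1))
})

test_that("charge state construction enforces its invariants", {
  ch <- charge_state(potential = 0.1)
  expect_lt(ch$delta_N, 0) # default convention: +V depletes electrons
  expect_identical(charge_state(potential = 0)$delta_N, 0)
  expect_error(
    charge_state(
      potential = 40, capacitance_per_area = 0.5,
      charge_layer_thickness = 1e-11
    ),
    "delta_N"
  )
})
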