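# 1-D multilayer transfer-matrix optics and the multimode-fiber ray
# transmission model. Fast spectrum engine and oracle for the 2-D solver.

#' Planar layer stack
#'
#' Ordered list of media with thicknesses; the first and last layers are
#' semi-infinite (`Inf` thickness).
#'
#' @param media list of [medium()] objects
#' @param thicknesses numeric vector (m); first and last must be `Inf`,
#'   interior thicknesses finite and positive
#' @return object of class `layer_stack`
#' @export
layer_stack <- function(media, thicknesses) {
  stopifnot(
    length(media) == length(thicknesses), length(media) >= 2,
    all(vapply(media, inherits, logical(1), "medium"))
  )
  if (!is.infinite(thicknesses[1]) ||
    !is.infinite(thicknesses[length(thicknesses)])) {
    stop("first and last layers must be semi-infinite (Inf thickness)",
      call. = FALSE
    )
  }
  inner <- thicknesses[setdiff(
    seq_along(thicknesses),
    c(1, length(thicknesses))
  )]
  if (any(!is.finite(inner)) || any(inner <= 0)) {
    stop("interior layer thicknesses must be finite and positive", call. = FALSE)
  }
  structure(list(media = media, thicknesses = thicknesses),
    class = "layer_stack"
  )
}

# Permittivities of all layers at lambda0 (list of complex vectors)
.stack_eps <- function(stack, lambda0) {
  lapply(stack$media, permittivity, lambda0 = lambda0)
}

#' Multilayer reflectance (characteristic-matrix method)
#'
#' Abeles/characteristic-matrix reflectance of a planar stack for a plane
#' wave incident from the first (semi-infinite) layer. Vectorized over
#' `lambda0`. Under the adopted \eqn{e^{-i\omega t}} convention the normal
#' wavevector branch is chosen with non-negative imaginary part so that
#' evanescent and lossy waves decay.
#'
#' @param stack a [layer_stack()]
#' @param lambda0 vacuum wavelength (m), vectorized
#' @param theta angle of incidence in the first layer (rad), in (0, pi/2)
#' @param polarization `"p"` (TM) or `"s"` (TE)
#' @return list with `R` (power reflectance), `r` (complex amplitude
#'   coefficient), and `T` (power transmittance into the last layer)
#' @export
reflectance <- function(stack, lambda0, theta, polarization = c("p", "s")) {
  polarization <- match.arg(polarization)
  stopifnot(inherits(stack, "layer_stack"))
  .check_lambda(lambda0)
  if (theta <= 0 || theta >= pi / 2) {
    stop("theta must lie in (0, pi/2)", call. = FALSE)
  }
  eps <- .stack_eps(stack, lambda0)
  k0 <- 2 * pi / lambda0
  kx2 <- k0^2 * eps[[1]] * sin(theta)^2
  nlay <- length(eps)

  q_of <- function(j) {
    kz <- sqrt(k0^2 * eps[[j]] - kx2 + 0i)
    kz <- ifelse(Im(kz) < 0, -kz, kz)
    # lossless propagating branch: ensure Re >= 0
    kz <- ifelse(Im(kz) == 0 & Re(kz) < 0, -kz, kz)
    if (polarization == "p") kz / (k0 * eps[[j]]) else kz / k0
  }
  kz_of <- function(j) {
    kz <- sqrt(k0^2 * eps[[j]] - kx2 + 0i)
    kz <- ifelse(Im(kz) < 0, -kz, kz)
    ifelse(Im(kz) == 0 & Re(kz) < 0, -kz, kz)
  }

  one <- rep(1 + 0i, length(lambda0))
  zero <- rep(0 + 0i, length(lambda0))
  M11 <- one
  M12 <- zero
  M21 <- zero
  M22 <- one
  for (j in seq_len(nlay)[-c(1, nlay)]) {
    d <- stack$thicknesses[j]
    delta <- kz_of(j) * d
    qj <- q_of(j)
    cd <- cos(delta)
    sd <- sin(delta)
    m11 <- cd
    m12 <- -1i * sd / qj
    m21 <- -1i * qj * sd
    m22 <- cd
    n11 <- M11 * m11 + M12 * m21
    n12 <- M11 * m12 + M12 * m22
    n21 <- M21 * m11 + M22 * m21
    n22 <- M21 * m12 + M22 * m22
    M11 <- n11
    M12 <- n12
    M21 <- n21
    M22 <- n22
  }
  q1 <- q_of(1)
  qN <- q_of(nlay)
  denom <- (M11 + M12 * qN) * q1 + (M21 + M22 * qN)
  r <- ((M11 + M12 * qN) * q1 - (M21 + M22 * qN)) / denom
  t <- 2 * q1 / denom
  R <- Mod(r)^2
  if (any(R > 1 + 1e-9)) {
    stop("reflectance exceeded unity: evanescent-branch bookkeeping failure",
      call. = FALSE
    )
  }
  Tpow <- Re(qN) / Re(q1) * Mod(t)^2
  list(R = pmin(R, 1), r = r, T = Tpow)
}

#' Surface-plasmon phase-matching wavevector
#'
#' Normalized SPP propagation constant of a single metal/dielectric
#' interface, \eqn{k_{spp}/k_0 = \sqrt{\varepsilon_m\varepsilon_d /
#' (\varepsilon_m+\varepsilon_d)}}.
#'
#' @param eps_metal,eps_dielectric complex permittivities
#' @return complex effective index of the SPP
#' @export
spp_effective_index <- function(eps_metal, eps_dielectric) {
  sqrt(eps_metal * eps_dielectric / (eps_metal + eps_dielectric) + 0i)
}

#' Ray-model parameters for multimode fiber transmission
#'
#' @param sensing_length length of the gold-coated sensing region (m);
#'   default 0.2 mm (see the methods vignette for the choice)
#' @param core_diameter fiber core diameter (m), default 10 um
#' @param numerical_aperture launch NA fixing the critical angle (default 0.22)
#' @param angular_distribution `"uniform_angle"` (default) or `"mode_power"`
#'   (weight proportional to sin(theta) cos(theta), a uniformly filled launch)
#' @param n_angles Gauss-Legendre quadrature order (>= 16, default 64)
#' @param polarization `"unpolarized"` (50/50 average of Rp and Rs applied per
#'   reflection; default), `"p"`, or `"s"`
#' @param theta_max_deg grazing-angle cap (default 89.5)
#' @return object of class `ray_model_params`
#' @export
ray_model_params <- function(sensing_length = 0.2e-3,
                             core_diameter = 10e-6,
                             numerical_aperture = 0.22,
                             angular_distribution = c(
                               "uniform_angle",
                               "mode_power"
                             ),
                             n_angles = 64L,
                             polarization = c("unpolarized", "p", "s"),
                             theta_max_deg = 89.5) {
  angular_distribution <- match.arg(angular_distribution)
  polarization <- match.arg(polarization)
  stopifnot(
    sensing_length >= 0, core_diameter > 0,
    numerical_aperture > 0, numerical_aperture < 1,
    n_angles >= 16
  )
  structure(
    list(
      sensing_length = sensing_length, core_diameter = core_diameter,
      numerical_aperture = numerical_aperture,
      angular_distribution = angular_distribution,
      n_angles = as.integer(n_angles), polarization = polarization,
      theta_max_deg = theta_max_deg
    ),
    class = "ray_model_params"
  )
}

#' Multimode-fiber power transmission through the sensing region
#'
#' Geometric-optics power integral over guided ray angles,
#' \deqn{T(\lambda) = \frac{\int P(\theta)\, \bar R(\theta,\lambda)^{N(\theta)}
#'   d\theta}{\int P(\theta) d\theta},}
#' where \eqn{N(\theta) = f_{gold} L / (D \tan\theta)} is the number of
#' film reflections of a meridional ray at wall-incidence angle
#' \eqn{\theta} (measured from the interface normal) and \eqn{\bar R} is
#' the per-reflection reflectance (unpolarized mix by default).
#' `gold_fraction` encodes how many wall bounces hit gold: 1 for the fully
#' coated and half-core-removed designs, 1/2 for the half-removed-cladding
#' design (alternate bounces hit the intact cladding side).
#'
#' @param stack a [layer_stack()] whose first layer is the fiber core
#' @param params [ray_model_params()]
#' @param lambda0 vacuum wavelength (m), vectorized
#' @param gold_fraction fraction of wall bounces that hit the film
#' @return transmission in [0, 1], same length as `lambda0`
#' @export
fiber_transmission <- function(stack, params = ray_model_params(), lambda0,
                               gold_fraction = 1) {
  stopifnot(inherits(params, "ray_model_params"))
  .check_lambda(lambda0)
  eps1 <- .stack_eps(stack, lambda0)[[1]]
  n_core <- mean(Re(sqrt(eps1)))
  sin_tc <- sqrt(n_core^2 - params$numerical_aperture^2) / n_core
  if (sin_tc >= 1 || sin_tc <= 0) {
    stop("numerical aperture inconsistent with core index", call. = FALSE)
  }
  theta_c <- asin(sin_tc)
  theta_max <- params$theta_max_deg * pi / 180
  if (theta_max <= theta_c) {
    stop("empty angular range: critical angle beyond grazing cap", call. = FALSE)
  }
  if (params$sensing_length == 0) {
    return(rep(1, length(lambda0)))
  }
  gq <- pracma::gaussLegendre(params$n_angles, theta_c, theta_max)
  w <- gq$w
  if (params$angular_distribution == "mode_power") {
    w <- w * sin(gq$x) * cos(gq$x)
  }
  Tsum <- rep(0, length(lambda0))
  for (i in seq_along(gq$x)) {
    th <- gq$x[i]
    Rbar <- switch(params$polarization,
      unpolarized = 0.5 * (reflectance(stack, lambda0, th, "p")$R +
        reflectance(stack, lambda0, th, "s")$R),
      p = reflectance(stack, lambda0, th, "p")$R,
      s = reflectance(stack, lambda0, th, "s")$R
    )
    nref <- gold_fraction * params$sensing_length /
      (params$core_diameter * tan(th))
    Tsum <- Tsum + w[i] * Rbar^nref
  }
  Tval <- Tsum / sum(w)
  pmin(pmax(Tval, 0), 1)
}

#' Complex pole of the planar reflection coefficient
#'
#' Finds the complex effective index at which the p-polarized reflection
#' coefficient of a layer stack diverges (a guided/plasmonic slab mode).
#' Works on the analytic continuation of the characteristic-matrix
#' denominator in the transverse effective index; used as the independent
#' 1-D oracle for the 2-D mode solver and for the peak-shift cross-check.
#'
#' @param stack a [layer_stack()]
#' @param lambda0 vacuum wavelength (m), scalar
#' @param n_eff_guess complex starting guess (e.g. [spp_effective_index()])
#' @param tol convergence tolerance on |f| step (default 1e-12)
#' @param max_iter maximum secant/Muller iterations
#' @return complex effective index of the pole
#' @export
planar_pole_search <- function(stack, lambda0, n_eff_guess,
                               tol = 1e-12, max_iter = 100L) {
  stopifnot(length(lambda0) == 1)
  eps <- .stack_eps(stack, lambda0)
  k0 <- 2 * pi / lambda0
  nlay <- length(eps)
  d <- stack$thicknesses

  # denominator of the p reflection coefficient as a function of n_eff
  denom_fn <- function(neff) {
    kx2 <- k0^2 * neff^2
    kz <- lapply(seq_len(nlay), function(j) {
      kzj <- sqrt(k0^2 * eps[[j]] - kx2 + 0i)
      if (Im(kzj) < 0) kzj <- -kzj
      kzj
    })
    q <- lapply(seq_len(nlay), function(j) kz[[j]] / (k0 * eps[[j]]))
    M <- diag(2) + 0i
    for (j in seq_len(nlay)[-c(1, nlay)]) {
      delta <- kz[[j]] * d[j]
      m <- matrix(c(
        cos(delta), -1i * q[[j]] * sin(delta),
        -1i * sin(delta) / q[[j]], cos(delta)
      ), 2, 2)
      M <- M %*% m
    }
    (M[1, 1] + M[1, 2] * q[[nlay]]) * q[[1]] + (M[2, 1] + M[2, 2] * q[[nlay]])
  }

  # secant iteration in the complex plane
  z0 <- n_eff_guess
  z1 <- n_eff_guess * (1 + 1e-4) + 1e-6i
  f0 <- denom_fn(z0)
  f1 <- denom_fn(z1)
  for (it in seq_len(max_iter)) {
    if (f1 == f0) break
    z2 <- z1 - f1 * (z1 - z0) / (f1 - f0)
    if (!is.finite(Re(z2)) || !is.finite(Im(z2))) {
      stop("pole search diverged", call. = FALSE)
    }
    z0 <- z1
    f0 <- f1
    z1 <- z2
    f1 <- denom_fn(z1)
    if (Mod(z1 - z0) < tol * max(1, Mod(z1))) break
  }
  if (Mod(z1 - z0) > 1e-8 * max(1, Mod(z1))) {
    stop(sprintf(
      "pole search did not converge after %d iterations (last step %.3g)",
      max_iter, Mod(z1 - z0)
    ), call. = FALSE)
  }
  z1
}

# Standard design-B stack: core | gold [| charged sublayer] | buffer.
# With a surface_layer charge the charged sub-layer is inserted as an
# explicit extra layer between gold and buffer; with uniform_film the whole
# film permittivity is modified.
.design_stack <- function(geom, charge = NULL) {
  t <- geom$gold_thickness
  core <- geom$media$core
  buf <- geom$media$buffer
  if (t <= 0) {
    return(layer_stack(list(core, buf), c(Inf, Inf)))
  }
  if (is.null(charge) || charge$delta_N == 0) {
    return(layer_stack(
      list(core, medium_gold(geom$gold_params), buf),
      c(Inf, t, Inf)
    ))
  }
  if (charge$localization == "surface_layer") {
    d <- charge$charge_layer_thickness
    stopifnot(d < t)
    layer_stack(
      list(
        core,
        medium_gold(geom$gold_params),
        medium_gold(geom$gold_params, charge),
        buf
      ),
      c(Inf, t - d, d, Inf)
    )
  } else {
    # same total excess charge C*V/e per unit area, spread over the film
    gc <- charge
    gc$delta_N <- charge$delta_N * charge$charge_layer_thickness / t
    layer_stack(
      list(core, medium_gold(geom$gold_params, gc), buf),
      c(Inf, t, Inf)
    )
  }
}
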