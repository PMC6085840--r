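# Independent oracles used across the suite. These are deliberately written
# from closed forms, not by calling the package's own code paths.

c0_oracle <- 299792458

# Fresnel amplitude reflection coefficients for a single interface,
# written directly from the textbook closed forms.
fresnel_r <- function(n1, n2, theta, pol) {
  ct1 <- cos(theta)
  st1 <- sin(theta)
  ct2 <- sqrt(1 - (n1 * st1 / n2)^2 + 0i)
  if (pol == "s") {
    (n1 * ct1 - n2 * ct2) / (n1 * ct1 + n2 * ct2)
  } else {
    (n2 * ct1 - n1 * ct2) / (n2 * ct1 + n1 * ct2)
  }
}

# Independently coded 3-layer (Airy summation) reflectance: incidence
# medium eps1 | film eps2, thickness d | substrate eps3.
airy_R <- function(eps1, eps2, eps3, d, lambda0, theta, pol) {
  k0 <- 2 * pi / lambda0
  kx <- k0 * sqrt(eps1 + 0i) * sin(theta)
  kz <- function(e) {
    v <- sqrt(k0^2 * e - kx^2 + 0i)
    if (Im(v) < 0) v <- -v
    if (Im(v) == 0 && Re(v) < 0) v <- -v
    v
  }
  rij <- function(ei, ej) {
    ki <- kz(ei)
    kj <- kz(ej)
    if (pol == "p") {
      (ej * ki - ei * kj) / (ej * ki + ei * kj)
    } else {
      (ki - kj) / (ki + kj)
    }
  }
  r12 <- rij(eps1, eps2)
  r23 <- rij(eps2, eps3)
  ph <- exp(2i * kz(eps2) * d)
  r <- (r12 + r23 * ph) / (1 + r12 * r23 * ph)
  Mod(r)^2
}

# Scalar (LP01) step-index fiber dispersion root: returns n_eff of the
# fundamental mode from the Bessel characteristic equation
#   u J1(u)/J0(u) = w K1(w)/K0(w),  u^2 + w^2 = V^2.
lp01_neff <- function(a, n_core, n_clad, lambda0) {
  k0 <- 2 * pi / lambda0
  V <- a * k0 * sqrt(n_core^2 - n_clad^2)
  f <- function(u) {
    w <- sqrt(V^2 - u^2)
    u * besselJ(u, 1) / besselJ(u, 0) - w * besselK(w, 1) / besselK(w, 0)
  }
  j0_first_zero <- 2.404825557695773
  upper <- min(V, j0_first_zero) - 1e-9
  u <- uniroot(f, c(1e-6, upper), tol = 1e-14)$root
  beta <- sqrt(k0^2 * n_core^2 - (u / a)^2)
  beta / k0
}

# Coarse explicit-Euler Hodgkin-Huxley point neuron, independent of the
# package's RK4 implementation. Returns membrane potential (mV).
hh_euler <- function(duration_ms, dt_ms, i_amp, i_on, i_off) {
  alpha_n <- function(v) 0.01 * (v + 55) / (1 - exp(-(v + 55) / 10))
  beta_n <- function(v) 0.125 * exp(-(v + 65) / 80)
  alpha_m <- function(v) 0.1 * (v + 40) / (1 - exp(-(v + 40) / 10))
  beta_m <- function(v) 4 * exp(-(v + 65) / 18)
  alpha_h <- function(v) 0.07 * exp(-(v + 65) / 20)
  beta_h <- function(v) 1 / (1 + exp(-(v + 35) / 10))
  gna <- 120
  gk <- 36
  gl <- 0.3
  ena <- 50
  ek <- -77
  el <- -54.387
  cm <- 1
  v <- -65
  n <- alpha_n(v) / (alpha_n(v) + beta_n(v))
  m <- alpha_m(v) / (alpha_m(v) + beta_m(v))
  h <- alpha_h(v) / (alpha_h(v) + beta_h(v))
  nt <- ceiling(duration_ms / dt_ms)
  out <- numeric(nt + 1)
  out[1] <- v
  for (i in seq_len(nt)) {
    t <- (i - 1) * dt_ms
    istim <- if (t >= i_on && t < i_off) i_amp else 0
    ina <- gna * m^3 * h * (v - ena)
    ik <- gk * n^4 * (v - ek)
    il <- gl * (v - el)
    v <- v + dt_ms * (istim - ina - ik - il) / cm
    n <- n + dt_ms * (alpha_n(v) * (1 - n) - beta_n(v) * n)
    m <- m + dt_ms * (alpha_m(v) * (1 - m) - beta_m(v) * m)
    h <- h + dt_ms * (alpha_h(v) * (1 - h) - beta_h(v) * h)
    out[i + 1] <- v
  }
  out
}

# Default lossless test media
med_n <- function(name, n) medium_constant(name, n)
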