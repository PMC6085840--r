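# Full-vector finite-difference frequency-domain eigenmode solver for the
# fiber cross-section. Transverse-field (Ex, Ey) formulation on a
# (possibly nonuniform) tensor grid with zero-field (PEC) window boundaries:
#
#   beta^2 Ex = d/dx[(1/eps) d(eps Ex)/dx] + d2Ex/dy2 + k0^2 eps Ex
#             + d/dx[(1/eps) d(eps Ey)/dy] - d2Ey/dxdy
#   beta^2 Ey = d/dy[(1/eps) d(eps Ey)/dy] + d2Ey/dx2 + k0^2 eps Ey
#             + d/dy[(1/eps) d(eps Ex)/dx] - d2Ex/dydx
#
# The complex sparse eigenproblem is solved by shift-invert Arnoldi; the
# complex linear solves are carried out on the equivalent augmented real
# system [[Br,-Bi],[Bi,Br]] factorized once per shift (the Matrix package
# provides real sparse LU only).

#' Waveguide eigenproblem definition
#'
#' @param map [build_cross_section()] permittivity map
#' @param n_modes number of eigenpairs requested (>= 1)
#' @param n_eff_guess complex effective-index shift target; default is the
#'   largest dielectric (non-metal) index on the map
#' @return object of class `wave_problem`
#' @export
wave_problem <- function(map, n_modes = 4L, n_eff_guess = NULL) {
  stopifnot(inherits(map, "permittivity_map"), n_modes >= 1)
  if (is.null(n_eff_guess)) {
    diel <- Re(map$eps) > 0
    n_eff_guess <- max(Re(sqrt(map$eps[diel])))
  }
  k0 <- 2 * pi / map$lambda0
  structure(
    list(
      map = map, lambda0 = map$lambda0, k0 = k0,
      n_modes = as.integer(n_modes), n_eff_guess = n_eff_guess
    ),
    class = "wave_problem"
  )
}

# Assemble the full-vector operator as triplets; returns list(i, j, v)
# (1-based, complex v) with total dimension 2*nx*ny (Ex block then Ey block).
.assemble_operator <- function(map, k0) {
  eps <- map$eps
  nx <- length(map$x)
  ny <- length(map$y)
  dx <- diff(map$xe)
  dy <- diff(map$ye)
  # center-to-neighbor spacings; at the window boundary the zero-field
  # (PEC) wall sits on the cell edge, half a cell from the first center
  hxm <- c(dx[1] / 2, (dx[-nx] + dx[-1]) / 2)
  hxp <- c((dx[-nx] + dx[-1]) / 2, dx[nx] / 2)
  hym <- c(dy[1] / 2, (dy[-ny] + dy[-1]) / 2)
  hyp <- c((dy[-ny] + dy[-1]) / 2, dy[ny] / 2)

  N <- nx * ny
  II <- integer(0)
  JJ <- integer(0)
  VV <- complex(0)
  push <- function(rows, cols, vals) {
    II <<- c(II, rows)
    JJ <<- c(JJ, cols)
    VV <<- c(VV, vals)
  }

  ig <- matrix(seq_len(nx), nx, ny)
  jg <- matrix(rep(seq_len(ny), each = nx), nx, ny)
  node <- matrix(seq_len(N), nx, ny)

  HXM <- matrix(hxm[ig], nx, ny)
  HXP <- matrix(hxp[ig], nx, ny)
  HYM <- matrix(hym[jg], nx, ny)
  HYP <- matrix(hyp[jg], nx, ny)
  DX <- matrix(dx[ig], nx, ny)
  DY <- matrix(dy[jg], nx, ny)

  shift_x <- function(M, s) {
    # neighbor value in x direction; out-of-range -> NA
    out <- matrix(NA_complex_, nx, ny)
    if (s == 1) out[1:(nx - 1), ] <- M[2:nx, ] else out[2:nx, ] <- M[1:(nx - 1), ]
    out
  }
  shift_y <- function(M, s) {
    out <- matrix(NA_complex_, nx, ny)
    if (s == 1) out[, 1:(ny - 1)] <- M[, 2:ny] else out[, 2:ny] <- M[, 1:(ny - 1)]
    out
  }

  # --- conservative second derivative with eps weighting, along x:
  # d/dx[(1/eps_face) d(eps E)/dx]; returns legs (west, center-part, east)
  add_dxx_eps <- function(block_row, block_col, with_eps) {
    epsE <- shift_x(eps, 1)
    epsW <- shift_x(eps, -1)
    if (with_eps) {
      fE <- (eps + ifelse(is.na(epsE), eps, epsE)) / 2
      fW <- (eps + ifelse(is.na(epsW), eps, epsW)) / 2
      cE <- ifelse(is.na(epsE), 0, epsE / fE) / (HXP * DX)
      cW <- ifelse(is.na(epsW), 0, epsW / fW) / (HXM * DX)
      c0 <- -(eps / fE) / (HXP * DX) - (eps / fW) / (HXM * DX)
    } else {
      cE <- ifelse(is.na(epsE), 0, 1) / (HXP * DX)
      cW <- ifelse(is.na(epsW), 0, 1) / (HXM * DX)
      c0 <- -1 / (HXP * DX) - 1 / (HXM * DX)
    }
    sel <- ig < nx
    push(
      block_row + node[sel], block_col + node[sel] + 1L,
      cE[sel]
    )
    sel <- ig > 1
    push(
      block_row + node[sel], block_col + node[sel] - 1L,
      cW[sel]
    )
    push(block_row + as.vector(node), block_col + as.vector(node), as.vector(c0))
  }
  add_dyy_eps <- function(block_row, block_col, with_eps) {
    epsN <- shift_y(eps, 1)
    epsS <- shift_y(eps, -1)
    if (with_eps) {
      fN <- (eps + ifelse(is.na(epsN), eps, epsN)) / 2
      fS <- (eps + ifelse(is.na(epsS), eps, epsS)) / 2
      cN <- ifelse(is.na(epsN), 0, epsN / fN) / (HYP * DY)
      cS <- ifelse(is.na(epsS), 0, epsS / fS) / (HYM * DY)
      c0 <- -(eps / fN) / (HYP * DY) - (eps / fS) / (HYM * DY)
    } else {
      cN <- ifelse(is.na(epsN), 0, 1) / (HYP * DY)
      cS <- ifelse(is.na(epsS), 0, 1) / (HYM * DY)
      c0 <- -1 / (HYP * DY) - 1 / (HYM * DY)
    }
    sel <- jg < ny
    push(block_row + node[sel], block_col + node[sel] + nx, cN[sel])
    sel <- jg > 1
    push(block_row + node[sel], block_col + node[sel] - nx, cS[sel])
    push(block_row + as.vector(node), block_col + as.vector(node), as.vector(c0))
  }

  # Ex row: Dxx_eps(Ex) + Dyy(Ex) + k0^2 eps Ex
  add_dxx_eps(0L, 0L, TRUE)
  add_dyy_eps(0L, 0L, FALSE)
  push(as.vector(node), as.vector(node), as.vector(k0^2 * eps))
  # Ey row: Dyy_eps(Ey) + Dxx(Ey) + k0^2 eps Ey
  add_dyy_eps(N, N, TRUE)
  add_dxx_eps(N, N, FALSE)
  push(N + as.vector(node), N + as.vector(node), as.vector(k0^2 * eps))

  # --- cross terms (interior nodes only; they vanish where eps is locally
  # uniform in the coupling direction)
  SX <- HXM + HXP
  SY <- HYM + HYP
  interior <- ig > 1 & ig < nx & jg > 1 & jg < ny
  cross <- function(di, dj, ratio, sgn) {
    val <- sgn * (ratio - 1) / (SX * SY)
    sel <- interior
    list(
      rows = node[sel],
      cols = node[sel] + di + dj * nx,
      vals = val[sel]
    )
  }
  eps_pp <- shift_y(shift_x(eps, 1), 1)
  eps_pm <- shift_y(shift_x(eps, 1), -1)
  eps_mp <- shift_y(shift_x(eps, -1), 1)
  eps_mm <- shift_y(shift_x(eps, -1), -1)
  eps_p0 <- shift_x(eps, 1)
  eps_m0 <- shift_x(eps, -1)
  eps_0p <- shift_y(eps, 1)
  eps_0m <- shift_y(eps, -1)

  # Pxy acting on Ey (added to the Ex rows):
  #   sum over corners of sgn * (eps_corner/eps_xneighbor - 1) / (SX*SY)
  for (cc in list(
    cross(1L, 1L, eps_pp / eps_p0, +1),
    cross(1L, -1L, eps_pm / eps_p0, -1),
    cross(-1L, 1L, eps_mp / eps_m0, -1),
    cross(-1L, -1L, eps_mm / eps_m0, +1)
  )) {
    push(cc$rows, N + cc$cols, cc$vals)
  }
  # Pyx acting on Ex (added to the Ey rows): eps ratio uses the y neighbor
  for (cc in list(
    cross(1L, 1L, eps_pp / eps_0p, +1),
    cross(-1L, 1L, eps_mp / eps_0p, -1),
    cross(1L, -1L, eps_pm / eps_0m, -1),
    cross(-1L, -1L, eps_mm / eps_0m, +1)
  )) {
    push(N + cc$rows, cc$cols, cc$vals)
  }

  list(i = II, j = JJ, v = VV, n = 2L * N, nx = nx, ny = ny)
}

# Complex shift-invert Arnoldi on the assembled operator.
# Returns eigenvalues mu (of the original operator, = beta^2) and vectors.
.shift_invert_arnoldi <- function(trip, sigma, k, m = NULL, tol = 1e-8) {
  n <- trip$n
  Ar <- Matrix::sparseMatrix(
    i = trip$i, j = trip$j, x = Re(trip$v),
    dims = c(n, n)
  )
  Ai <- Matrix::sparseMatrix(
    i = trip$i, j = trip$j, x = Im(trip$v),
    dims = c(n, n)
  )
  Br <- Ar - Matrix::Diagonal(n, Re(sigma))
  Bi <- Ai - Matrix::Diagonal(n, Im(sigma))
  K <- rbind(cbind(Br, -Bi), cbind(Bi, Br))
  KF <- Matrix::lu(K)
  solve_c <- function(z) {
    rhs <- c(Re(z), Im(z))
    s <- Matrix::solve(KF, rhs)
    s <- as.numeric(s)
    complex(real = s[1:n], imaginary = s[(n + 1):(2 * n)])
  }
  matvec <- function(z) {
    xr <- Re(z)
    xi <- Im(z)
    complex(
      real = as.numeric(Ar %*% xr - Ai %*% xi),
      imaginary = as.numeric(Ar %*% xi + Ai %*% xr)
    )
  }

  if (is.null(m)) m <- min(n, max(36L, 6L * k + 12L))
  # deterministic symmetry-breaking start vector
  v <- complex(
    real = sin(0.7 * seq_len(n) + 0.3),
    imaginary = cos(1.3 * seq_len(n))
  )
  v <- v / sqrt(sum(Mod(v)^2))
  V <- matrix(0 + 0i, n, m + 1)
  H <- matrix(0 + 0i, m + 1, m)
  V[, 1] <- v
  mused <- m
  for (jj in seq_len(m)) {
    w <- solve_c(V[, jj])
    wnorm0 <- sqrt(sum(Mod(w)^2))
    # modified Gram-Schmidt with one re-orthogonalization
    for (pass in 1:2) {
      for (ii in seq_len(jj)) {
        h <- sum(Conj(V[, ii]) * w)
        H[ii, jj] <- H[ii, jj] + h
        w <- w - h * V[, ii]
      }
    }
    hn <- sqrt(sum(Mod(w)^2))
    H[jj + 1, jj] <- hn
    if (hn < 1e-10 * wnorm0) { # true invariant-subspace breakdown
      mused <- jj
      break
    }
    V[, jj + 1] <- w / hn
  }
  Hm <- H[seq_len(mused), seq_len(mused), drop = FALSE]
  ed <- eigen(Hm)
  ord <- order(Mod(ed$values), decreasing = TRUE)
  take <- ord[seq_len(min(k, mused))]
  theta <- ed$values[take]
  Y <- ed$vectors[, take, drop = FALSE]
  X <- V[, seq_len(mused), drop = FALSE] %*% Y
  mu <- sigma + 1 / theta
  # explicit residuals on the original operator
  res <- vapply(seq_along(mu), function(l) {
    x <- X[, l]
    x <- x / sqrt(sum(Mod(x)^2))
    r <- matvec(x) - mu[l] * x
    sqrt(sum(Mod(r)^2)) / Mod(mu[l])
  }, numeric(1))
  list(mu = mu, X = X, res = res, m = mused)
}

#' Solve for guided/plasmonic modes of a cross-section
#'
#' Shift-invert eigenmode solution of the full-vector transverse-field
#' problem nearest the effective-index guess. Returned modes are
#' power-normalized (discrete cross-section integral of |Ex|^2+|Ey|^2 is 1)
#' and sorted by decreasing real effective index. Modes with real effective
#' index above the largest material index are discarded as spurious and
#' reported in the `spurious` attribute.
#'
#' @param problem a [wave_problem()]
#' @param tol relative residual tolerance on the discrete eigen-relation
#' @return list of `mode` objects (fields `n_eff`, `fields$Ex`, `fields$Ey`,
#'   `power`, `residual`, `lambda0`)
#' @export
solve_modes <- function(problem, tol = 1e-8) {
  stopifnot(inherits(problem, "wave_problem"))
  map <- problem$map
  k0 <- problem$k0
  trip <- .assemble_operator(map, k0)
  sigma <- (k0 * problem$n_eff_guess)^2
  # ask for extras so that filtering cannot starve the request
  k_ask <- problem$n_modes + 4L
  m0 <- max(36L, 6L * k_ask + 12L)
  sol <- NULL
  # escalate the Krylov dimension until the leading pairs converge; near
  # SPR anti-crossings the spectrum clusters and small subspaces stall
  for (mtry in unique(pmin(trip$n, c(m0, 2L * m0, 4L * m0)))) {
    cand <- .shift_invert_arnoldi(trip, sigma, k_ask, m = mtry)
    if (is.null(sol) ||
      min(cand$res) < min(sol$res)) {
      sol <- cand
    }
    if (sum(sol$res <= max(tol, 1e-6)) >= problem$n_modes ||
      all(sol$res <= max(tol, 1e-6))) {
      break
    }
  }
  keep <- sol$res <= max(tol, 1e-6)
  if (!any(keep)) {
    stop(sprintf(
      "eigensolver did not converge: best residual %.3g after Krylov dim %d",
      min(sol$res), sol$m
    ), call. = FALSE)
  }
  mu <- sol$mu[keep]
  X <- sol$X[, keep, drop = FALSE]
  res <- sol$res[keep]

  n_eff <- sqrt(mu + 0i) / k0
  n_eff <- ifelse(Re(n_eff) < 0, -n_eff, n_eff)
  # physical upper bound on Re(n_eff): the largest dielectric index, or for
  # maps containing metal the largest bound-SPP index of any metal/dielectric
  # pair present
  uv <- unique(signif(as.vector(map$eps), 8))
  diel <- uv[Re(uv) > 0]
  mets <- uv[Re(uv) < 0]
  n_max <- max(Re(sqrt(diel)))
  if (length(mets) > 0 && length(diel) > 0) {
    # the SPP bound grows as |Re eps_m| approaches eps_d from above, so the
    # extremes of both sets suffice
    for (em in unique(c(
      mets[which.max(Re(mets))],
      mets[which.min(Re(mets))]
    ))) {
      for (ed in unique(c(
        diel[which.max(Re(diel))],
        diel[which.min(Re(diel))]
      ))) {
        nsp <- suppressWarnings(sqrt(em * ed / (em + ed)))
        if (is.finite(Re(nsp))) n_max <- max(n_max, Re(nsp))
      }
    }
  }
  spurious <- Re(n_eff) > n_max + 1e-3
  ord <- order(Re(n_eff[!spurious]), decreasing = TRUE)

  nx <- length(map$x)
  ny <- length(map$y)
  area <- as.vector(outer(diff(map$xe), diff(map$ye)))
  modes <- lapply(which(!spurious)[ord][seq_len(min(
    problem$n_modes,
    sum(!spurious)
  ))], function(l) {
    v <- X[, l]
    ex <- v[seq_len(nx * ny)]
    ey <- v[nx * ny + seq_len(nx * ny)]
    pw <- sum((Mod(ex)^2 + Mod(ey)^2) * area)
    scl <- 1 / sqrt(pw)
    structure(
      list(
        n_eff = n_eff[l],
        fields = list(
          Ex = matrix(ex * scl, nx, ny),
          Ey = matrix(ey * scl, nx, ny)
        ),
        power = 1,
        residual = res[l],
        lambda0 = map$lambda0
      ),
      class = "mode"
    )
  })
  attr(modes, "spurious") <- n_eff[spurious]
  modes
}

#' @export
print.mode <- function(x, ...) {
  cat(sprintf(
    "<mode> n_eff = %.6f %+.3e i  (lambda0 = %.1f nm, residual %.2e)\n",
    Re(x$n_eff), Im(x$n_eff), x$lambda0 * 1e9, x$residual
  ))
  invisible(x)
}

#' Fraction of modal power absorbed over a propagation length
#'
#' Power attenuation coefficient \eqn{\alpha = 4\pi\,\mathrm{Im}(n_{eff})/
#' \lambda_0} (power, i.e. twice the field decay rate); absorbed fraction
#' \eqn{1 - e^{-\alpha L}}.
#'
#' @param mode a `mode` (or complex n_eff)
#' @param lambda0 vacuum wavelength (m); defaults to the mode's own
#' @param length propagation length (m)
#' @return absorbed power fraction in [0, 1)
#' @export
modal_attenuation <- function(mode, lambda0 = NULL, length) {
  n_eff <- if (inherits(mode, "mode")) mode$n_eff else mode
  if (is.null(lambda0)) {
    stopifnot(inherits(mode, "mode"))
    lambda0 <- mode$lambda0
  }
  im <- Im(n_eff)
  if (im < -1e-12) {
    stop("negative modal loss beyond tolerance: Im(n_eff) = ", im,
      call. = FALSE
    )
  }
  alpha <- 4 * pi * max(im, 0) / lambda0
  1 - exp(-alpha * length)
}

#' Launch-weighted absorbance over a set of modes
#'
#' Weighted mean of per-mode absorbed fractions; default equal weights.
#'
#' @param modes list of `mode` objects
#' @param weights nonnegative launch weights summing to 1 (default equal)
#' @param lambda0 vacuum wavelength (m); defaults to the modes' own
#' @param length propagation length (m)
#' @return absorbance in [0, 1)
#' @export
aggregate_absorption <- function(modes, weights = NULL, lambda0 = NULL,
                                 length) {
  stopifnot(length(modes) >= 1)
  if (is.null(weights)) weights <- rep(1 / length(modes), length(modes))
  if (length(weights) != length(modes)) {
    stop("weights and modes length mismatch", call. = FALSE)
  }
  stopifnot(all(weights >= 0), abs(sum(weights) - 1) < 1e-9)
  sum(weights * vapply(
    modes,
    function(m) modal_attenuation(m, lambda0, length), numeric(1)
  ))
}
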