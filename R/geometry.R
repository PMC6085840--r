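# Discretized complex-permittivity cross-section maps for the three
# gold-coated fiber sensor designs.

#' Fiber sensor geometry
#'
#' Describes one of the three sensor cross-sections:
#' \itemize{
#'   \item `full_clad_removed`: circular silica core fully coated by an
#'     annular gold shell, surrounded by buffer.
#'   \item `half_clad_removed`: fiber polished flat to the core surface on
#'     one side (flat at y = +core_radius), gold slab on the flat, cladding
#'     intact below, buffer above.
#'   \item `half_core_removed`: fiber polished through to the core mid-plane
#'     (flat at y = 0), gold slab on the cut, buffer above.
#' }
#' The cladding index is the core index scaled by (1 - Delta) with Delta
#' fixed so that the numerical aperture is `na` at 633 nm.
#'
#' @param design one of `"full_clad_removed"`, `"half_clad_removed"`,
#'   `"half_core_removed"`
#' @param core_radius core radius (m), default 5 um
#' @param gold_thickness gold film thickness (m), default 50 nm
#' @param na numerical aperture setting the cladding index (default 0.22)
#' @param buffer_n ambient (PBS) refractive index
#' @param gold_params [drude_lorentz_params()] for the film
#' @return object of class `fiber_geometry`
#' @export
fiber_geometry <- function(design = c(
                             "half_clad_removed", "full_clad_removed",
                             "half_core_removed"
                           ),
                           core_radius = 5e-6, gold_thickness = 50e-9,
                           na = 0.22, buffer_n = 1.334,
                           gold_params = gold_drude_lorentz()) {
  design <- match.arg(design)
  stopifnot(
    core_radius > 0,
    gold_thickness >= 0, gold_thickness < core_radius,
    na > 0, na < 1
  )
  n_core_633 <- sqrt(Re(silica_permittivity(633e-9)))
  delta <- 1 - sqrt(n_core_633^2 - na^2) / n_core_633
  media <- list(
    core = medium_silica(),
    cladding = medium("cladding", function(lambda0) {
      eps_core <- silica_permittivity(lambda0)
      complex(real = Re(eps_core) * (1 - delta)^2, imaginary = 0)
    }),
    gold = medium_gold(gold_params),
    buffer = medium_buffer(buffer_n)
  )
  structure(
    list(
      design = design, core_radius = core_radius,
      gold_thickness = gold_thickness, na = na, delta = delta,
      buffer_n = buffer_n, gold_params = gold_params, media = media
    ),
    class = "fiber_geometry"
  )
}

# Nonuniform axis: base spacing h0 over [lo, hi] with fine spacing h_fine in
# [a, b] bands; returns cell edges (strictly increasing, symmetric if the
# bands are symmetric about the window center).
.graded_axis <- function(lo, hi, h0, bands) {
  pts <- c(lo, hi)
  for (b in bands) pts <- c(pts, b$a, b$b)
  pts <- sort(unique(pmin(pmax(pts, lo), hi)))
  edges <- numeric(0)
  for (k in seq_len(length(pts) - 1)) {
    a <- pts[k]
    b <- pts[k + 1]
    h <- h0
    for (bd in bands) {
      if (a >= bd$a - 1e-15 && b <= bd$b + 1e-15) h <- min(h, bd$h)
    }
    n <- max(1L, ceiling((b - a) / h - 1e-9))
    edges <- c(edges, seq(a, b, length.out = n + 1)[-(n + 1)])
  }
  c(edges, hi)
}

#' Build a discretized permittivity cross-section
#'
#' Discretizes the chosen sensor design onto a rectilinear (tensor-product)
#' grid, refined so that at least `min_cells_in_film` cells span the gold
#' film along its normal. Material is assigned by cell center by default; the
#' `average_boundary` flag replaces each cell's permittivity by a 4x4
#' sub-sampled area average (useful at curved film boundaries).
#'
#' @param geom [fiber_geometry()]
#' @param lambda0 vacuum wavelength (m)
#' @param charge optional [charge_state()] applied to the gold; under the
#'   `"surface_layer"` localization the excess density is rescaled into an
#'   area-weighted effective shift of the whole film (thin-layer equivalent)
#' @param min_cells_in_film minimum cells across the 50 nm film (>= 5)
#' @param window_factor computational window side, in units of core radius
#' @param base_cells number of coarse cells per axis outside refinement bands
#' @param average_boundary logical; sub-cell dielectric averaging
#' @return object of class `permittivity_map` with fields `x`, `y` (cell
#'   centers, m), `xe`, `ye` (cell edges), `eps` (complex nx-by-ny matrix),
#'   `region` (character nx-by-ny matrix), `lambda0`, `design`
#' @export
build_cross_section <- function(geom, lambda0, charge = NULL,
                                min_cells_in_film = 5L,
                                window_factor = 4,
                                base_cells = 120L,
                                average_boundary = FALSE) {
  stopifnot(inherits(geom, "fiber_geometry"))
  .check_lambda(lambda0)
  if (min_cells_in_film < 5L) {
    stop("resolution policy must place at least 5 cells across the gold film",
      call. = FALSE
    )
  }
  r <- geom$core_radius
  t <- geom$gold_thickness
  half <- window_factor * r / 2
  h_fine <- if (t > 0) t / min_cells_in_film else half / base_cells
  h0 <- 2 * half / base_cells
  if (t > 0 && h_fine > h0) {
    stop("meshing error: base resolution finer than film refinement", call. = FALSE)
  }
  pad <- if (t > 0) 2 * t else 0

  design <- geom$design
  if (design == "full_clad_removed") {
    # fine everywhere the annulus lives (its normal sweeps all directions)
    bands_x <- if (t > 0) {
      list(list(a = -(r + t + pad), b = r + t + pad, h = h_fine))
    } else {
      list()
    }
    bands_y <- bands_x
  } else if (design == "half_clad_removed") {
    bands_x <- list()
    bands_y <- if (t > 0) {
      list(list(a = r - pad, b = r + t + pad, h = h_fine))
    } else {
      list()
    }
  } else {
    bands_x <- list()
    bands_y <- if (t > 0) {
      list(list(a = -pad, b = t + pad, h = h_fine))
    } else {
      list()
    }
  }
  xe <- .graded_axis(-half, half, h0, bands_x)
  ye <- .graded_axis(-half, half, h0, bands_y)
  x <- (xe[-1] + xe[-length(xe)]) / 2
  y <- (ye[-1] + ye[-length(ye)]) / 2

  region_at <- function(px, py) {
    r2 <- px^2 + py^2
    if (design == "full_clad_removed") {
      ifelse(r2 < r^2, "core",
        ifelse(t > 0 & r2 < (r + t)^2, "gold", "buffer")
      )
    } else if (design == "half_clad_removed") {
      ifelse(py > r + t, "buffer",
        ifelse(py > r & t > 0, "gold",
          ifelse(r2 < r^2, "core", ifelse(py > r, "buffer", "cladding"))
        )
      )
    } else { # half_core_removed
      ifelse(py > t, "buffer",
        ifelse(py > 0 & t > 0, "gold",
          ifelse(r2 < r^2, "core", "cladding")
        )
      )
    }
  }

  px <- matrix(x, nrow = length(x), ncol = length(y))
  py <- matrix(y, nrow = length(x), ncol = length(y), byrow = TRUE)
  region <- region_at(px, py)

  eps_of <- .region_permittivities(geom, lambda0, charge)
  eps <- matrix(eps_of[region], nrow = length(x), ncol = length(y))

  if (average_boundary) {
    # 4x4 sub-sampled area average of permittivity within each cell
    off <- (seq_len(4) - 0.5) / 4
    dx <- diff(xe)
    dy <- diff(ye)
    acc <- matrix(0 + 0i, length(x), length(y))
    for (ox in off) {
      for (oy in off) {
        sx <- xe[-length(xe)] + ox * dx
        sy <- ye[-length(ye)] + oy * dy
        pxs <- matrix(sx, length(sx), length(sy))
        pys <- matrix(sy, length(sx), length(sy), byrow = TRUE)
        acc <- acc + eps_of[region_at(pxs, pys)]
      }
    }
    eps <- acc / 16
  }

  structure(
    list(
      x = x, y = y, xe = xe, ye = ye, eps = eps, region = region,
      lambda0 = lambda0, design = design, geom = geom
    ),
    class = "permittivity_map"
  )
}

# Permittivity of every region label at lambda0, as a named complex vector.
# Under surface_layer localization the excess charge (confined to a layer
# thinner than a mesh cell) is folded into the film as the thickness-weighted
# effective plasma-frequency shift delta_N * d_layer / t_film.
.region_permittivities <- function(geom, lambda0, charge) {
  gold_charge <- NULL
  if (!is.null(charge)) {
    gold_charge <- charge
    if (charge$localization == "surface_layer" && geom$gold_thickness > 0) {
      eff <- charge$delta_N * charge$charge_layer_thickness /
        geom$gold_thickness
      gold_charge <- charge_state(
        potential = charge$potential,
        capacitance_per_area = charge$capacitance_per_area,
        charge_layer_thickness = geom$gold_thickness,
        N = charge$N, sign_convention = charge$sign_convention,
        localization = "uniform_film"
      )
      gold_charge$delta_N <- eff
    }
  }
  c(
    core = permittivity(geom$media$core, lambda0),
    cladding = permittivity(geom$media$cladding, lambda0),
    gold = if (geom$gold_thickness > 0) {
      drude_lorentz_permittivity(lambda0, geom$gold_params, gold_charge)
    } else {
      permittivity(geom$media$buffer, lambda0)
    },
    buffer = permittivity(geom$media$buffer, lambda0)
  )
}

#' Area of a region in a permittivity map
#'
#' Sums cell areas over cells labeled `label` (cell-center assignment).
#'
#' @param map a `permittivity_map`
#' @param label region label
#' @return area (m^2)
#' @export
region_area <- function(map, label) {
  stopifnot(inherits(map, "permittivity_map"))
  dx <- diff(map$xe)
  dy <- diff(map$ye)
  cell_area <- outer(dx, dy)
  sum(cell_area[map$region == label])
}

#' Export a permittivity map as a data frame
#'
#' Long-format dump (x, y, region, Re and Im of permittivity) suitable for
#' CSV export and plotting.
#'
#' @param x a `permittivity_map`
#' @param ... unused
#' @return data.frame
#' @export
as.data.frame.permittivity_map <- function(x, ...) {
  nx <- length(x$x)
  ny <- length(x$y)
  data.frame(
    x = rep(x$x, times = ny),
    y = rep(x$y, each = nx),
    region = as.vector(x$region),
    eps_re = as.vector(Re(x$eps)),
    eps_im = as.vector(Im(x$eps))
  )
}

#' @export
print.permittivity_map <- function(x, ...) {
  cat(sprintf(
    "<permittivity_map> design=%s  lambda0=%.1f nm  grid %d x %d\n",
    x$design, x$lambda0 * 1e9, length(x$x), length(x$y)
  ))
  tab <- table(x$region)
  cat("  regions:", paste(names(tab), tab, sep = "=", collapse = "  "), "\n")
  invisible(x)
}
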