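# Package-level configuration: one nested list of defaults, overridable
# programmatically or from a YAML file.

#' Default sensor configuration
#'
#' Returns the nested list of defaults used by the pipeline functions:
#' \describe{
#'   \item{fiber}{`design`, `core_radius_um` (5), `gold_nm` (50), `na` (0.22)}
#'   \item{gold}{Drude-Lorentz parameters, see [gold_drude_lorentz()]}
#'   \item{charge}{`capacitance_per_area` (0.5 F/m^2, i.e. 50 uF/cm^2, the
#'     calibrated in-bounds value), `layer_thickness` (0.5 nm),
#'     `sign_convention` (-1), `localization` ("surface_layer"),
#'     `N` (5.90e28 m^-3)}
#'   \item{buffer}{`n` (1.334)}
#'   \item{ray}{`length_mm` (0.2), `core_diameter_um` (10), `n_angles` (64),
#'     `polarization` ("unpolarized"), `angular_distribution`
#'     ("uniform_angle")}
#'   \item{mesh}{`min_cells_in_film` (5), `window_factor` (4),
#'     `base_cells` (120)}
#'   \item{solver}{`n_modes` (6), `tol` (1e-8), `base_cells` (80)}
#'   \item{pipeline}{`coupling_factor` (1.0), wavelength grids for the two
#'     engines (nm)}
#' }
#'
#' @return nested configuration list
#' @export
sensor_config <- function() {
  list(
    fiber = list(
      design = "half_clad_removed", core_radius_um = 5, gold_nm = 50,
      na = 0.22
    ),
    gold = unclass(gold_drude_lorentz()),
    charge = list(
      capacitance_per_area = 0.5, layer_thickness = 0.5e-9,
      sign_convention = -1, localization = "surface_layer",
      N = gold_electron_density()
    ),
    buffer = list(n = 1.334),
    ray = list(
      length_mm = 0.2, core_diameter_um = 10, n_angles = 64L,
      polarization = "unpolarized", angular_distribution = "uniform_angle"
    ),
    mesh = list(min_cells_in_film = 5L, window_factor = 4, base_cells = 120L),
    solver = list(n_modes = 6L, tol = 1e-8, base_cells = 80L),
    pipeline = list(
      coupling_factor = 1.0,
      planar_grid_nm = seq(500, 900, by = 0.25),
      modal_grid_nm = seq(550, 750, by = 2)
    )
  )
}

#' Load a configuration file
#'
#' Reads a YAML file and merges it (recursively) over the defaults of
#' [sensor_config()].
#'
#' @param path YAML file path
#' @return nested configuration list
#' @export
load_sensor_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read configuration files",
      call. = FALSE
    )
  }
  user <- yaml::read_yaml(path)
  merge_rec <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        base[[nm]] <- merge_rec(base[[nm]], over[[nm]])
      } else {
        base[[nm]] <- over[[nm]]
      }
    }
    base
  }
  merge_rec(sensor_config(), user)
}

# internal constructors from a config list
.config_geometry <- function(design, config) {
  gp <- config$gold
  fiber_geometry(
    design = design,
    core_radius = config$fiber$core_radius_um * 1e-6,
    gold_thickness = config$fiber$gold_nm * 1e-9,
    na = config$fiber$na,
    buffer_n = config$buffer$n,
    gold_params = drude_lorentz_params(
      gp$eps_inf, gp$omega_D, gp$gamma_D, gp$omega_L, gp$gamma_L, gp$delta_eps
    )
  )
}

.config_charge <- function(potential, config) {
  cc <- config$charge
  charge_state(
    potential = potential * config$pipeline$coupling_factor,
    capacitance_per_area = cc$capacitance_per_area,
    charge_layer_thickness = cc$layer_thickness,
    N = cc$N,
    sign_convention = cc$sign_convention,
    localization = cc$localization
  )
}

.config_ray <- function(config) {
  ray_model_params(
    sensing_length = config$ray$length_mm * 1e-3,
    core_diameter = config$ray$core_diameter_um * 1e-6,
    numerical_aperture = config$fiber$na,
    angular_distribution = config$ray$angular_distribution,
    n_angles = config$ray$n_angles,
    polarization = config$ray$polarization
  )
}

# fraction of wall bounces that hit the gold film, per design
.gold_fraction <- function(design) {
  switch(design,
    full_clad_removed = 1, # film covers the whole perimeter
    half_clad_removed = 0.5, # alternate bounces hit the intact cladding
    half_core_removed = 1, # gold flat and curved wall alternate over D/2
    stop("unknown design: ", design, call. = FALSE)
  )
}
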