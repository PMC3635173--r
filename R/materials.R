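#' Bundled photon interaction data
#'
#' Loads the bundled mass-attenuation compilation: photoelectric and
#' incoherent (Compton) mass attenuation coefficients (cm^2/g) on a 10-200 keV
#' grid for the phantom materials (soft tissue, bone, lung, brain, air) plus
#' water and PMMA used for oracle checks and CTDI phantoms. Coherent
#' scattering is excluded by default (see the transport documentation), so the
#' total is the sum of the two bundled components.
#'
#' @return tibble with columns `material`, `density_g_cm3`, `energy_kev`,
#'   `mu_photoelectric`, `mu_incoherent`, `mu_total` (all mass coefficients in
#'   cm^2/g).
#' @export
load_materials <- function() {
  df <- read.csv(extdata_path("attenuation.csv"), stringsAsFactors = FALSE)
  as_tibble(df) %>%
    mutate(mu_total = .data$mu_photoelectric + .data$mu_incoherent)
}

#' Interpolate a mass attenuation coefficient
#'
#' Log-log interpolation between bundled grid points; log-log extrapolation
#' below the grid (photoelectric cross sections are near power-law there).
#'
#' @param material material name present in [load_materials()].
#' @param energy_kev photon energies (keV), vectorized.
#' @param component one of "total", "photoelectric", "incoherent".
#' @param materials optional pre-loaded materials table.
#' @return mass attenuation coefficients, cm^2/g.
#' @export
material_mu <- function(material, energy_kev,
                        component = c("total", "photoelectric", "incoherent"),
                        materials = load_materials()) {
  component <- match.arg(component)
  m <- materials[materials$material == material, ]
  if (nrow(m) == 0L) stop_validation(paste0("unknown material: ", material))
  col <- switch(component, total = "mu_total",
                photoelectric = "mu_photoelectric",
                incoherent = "mu_incoherent")
  le <- log(m$energy_kev)
  lv <- log(m[[col]])
  lq <- log(energy_kev)
  # rule = 2 clamps above the grid; below the grid extend the first segment
  out <- approx(le, lv, xout = pmax(lq, le[1]), rule = 2)$y
  below <- lq < le[1]
  if (any(below)) {
    slope <- (lv[2] - lv[1]) / (le[2] - le[1])
    out[below] <- lv[1] + slope * (lq[below] - le[1])
  }
  exp(out)
}

material_density <- function(material, materials = load_materials()) {
  m <- materials[materials$material == material, ]
  if (nrow(m) == 0L) stop_validation(paste0("unknown material: ", material))
  m$density_g_cm3[1]
}

# Linear attenuation tables on a fine 2..200 keV grid for the transport
# kernel: matrices [n_energy x n_material] in 1/mm, split photoelectric /
# incoherent, plus the material name -> column index map.
build_mu_tables <- function(materials = load_materials()) {
  mats <- unique(materials$material)
  egrid <- seq(ENERGY_CUTOFF_KEV, 200, by = 1)
  mu_pe <- matrix(0, length(egrid), length(mats))
  mu_inc <- matrix(0, length(egrid), length(mats))
  for (j in seq_along(mats)) {
    rho <- material_density(mats[j], materials)
    # cm^2/g * g/cm^3 = 1/cm; /10 -> 1/mm
    mu_pe[, j] <- material_mu(mats[j], egrid, "photoelectric", materials) * rho / 10
    mu_inc[, j] <- material_mu(mats[j], egrid, "incoherent", materials) * rho / 10
  }
  list(energy = egrid, materials = mats, mu_pe = mu_pe, mu_inc = mu_inc)
}

mu_tables_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_mu_tables()
    cache
  }
})
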