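#' CT beam model
#'
#' A rotating, collimated fan beam. By default the spectrum is a single
#' effective energy looked up from the bundled tube-voltage table
#' (80 -> 50, 100 -> 56, 120 -> 62, 140 -> 69 keV; implementation constants);
#' a user-supplied `spectrum` (tibble/data.frame with `energy_kev`, `weight`)
#' overrides it.
#'
#' @param kvp tube voltage, kV.
#' @param spectrum optional data frame `energy_kev`, `weight` (weights are
#'   normalized; all energies must be below `kvp`).
#' @param fan_angle_deg full fan angle, degrees.
#' @param collimation_mm z-collimation at isocenter, mm.
#' @param source_radius_mm source-isocenter distance, mm.
#' @return object of class `beam_model`.
#' @export
beam_model <- function(kvp = 120, spectrum = NULL, fan_angle_deg = 50,
                       collimation_mm = 10, source_radius_mm = 600) {
  if (!is_scalar_number(kvp) || kvp <= 0) stop_validation("kvp must be a positive number")
  if (!is_scalar_number(collimation_mm) || collimation_mm <= 0) {
    stop_validation("collimation must be > 0")
  }
  if (is.null(spectrum)) {
    key <- as.character(kvp)
    if (!key %in% names(EFFECTIVE_ENERGY_KEV)) {
      stop_config(paste0("no bundled effective energy for kVp = ", kvp,
                         "; supply a spectrum"))
    }
    spectrum <- tibble(energy_kev = unname(EFFECTIVE_ENERGY_KEV[key]), weight = 1)
  } else {
    spectrum <- as_tibble(spectrum)
    stopifnot(all(c("energy_kev", "weight") %in% names(spectrum)))
    if (any(spectrum$weight < 0)) stop_validation("spectrum weights must be >= 0")
    if (any(spectrum$energy_kev >= kvp)) {
      stop_validation("spectrum energies must be below kvp")
    }
    spectrum$weight <- spectrum$weight / sum(spectrum$weight)
  }
  structure(list(kvp = kvp, spectrum = spectrum, fan_angle_deg = fan_angle_deg,
                 collimation_mm = collimation_mm,
                 source_radius_mm = source_radius_mm),
            class = "beam_model")
}

#' Sample Compton scattering events
#'
#' Draws (scattered energy, polar angle) pairs from the Klein-Nishina
#' differential cross section at the given incident energy. The returned
#' energies satisfy the Compton relation for the sampled angles exactly.
#'
#' @param energy_kev incident photon energy, keV (1 to 200).
#' @param n number of samples.
#' @param seed integer seed.
#' @return tibble with `energy_kev` (scattered) and `theta` (radians).
#' @export
sample_compton <- function(energy_kev, n = 1, seed = 1) {
  if (!is_scalar_number(energy_kev) || energy_kev < 1 || energy_kev > 200) {
    stop_validation("energy_kev must be in [1, 200]")
  }
  as_tibble(as.data.frame(cpp_sample_compton(energy_kev, as.integer(n),
                                             as.integer(seed))))
}

# subset mu tables to the materials actually present in a geometry and remap
# material ids; keeps the Woodcock majorant tight
subset_mu_args <- function(args) {
  mu <- mu_tables_cached()
  used <- sort(unique(c(args$slab_mat, args$reg_mat, args$air_mat)))
  remap <- setNames(seq_along(used) - 1L, used)
  args$slab_mat <- unname(remap[as.character(args$slab_mat)])
  args$reg_mat <- unname(remap[as.character(args$reg_mat)])
  args$air_mat <- unname(remap[as.character(args$air_mat)])
  args$mu_pe <- args$mu_pe[, used + 1L, drop = FALSE]
  args$mu_inc <- args$mu_inc[, used + 1L, drop = FALSE]
  args
}

run_transport <- function(geom, beam, z_center, n_photons, seed,
                          rotate_source = TRUE, fixed_angle = 0,
                          scatter_on = TRUE, fan_override = NULL,
                          coll_override = NULL) {
  args <- subset_mu_args(geom$args)
  res <- cpp_simulate_rotation(
    slab_z = args$slab_z, slab_a = args$slab_a, slab_b = args$slab_b,
    slab_mat = as.integer(args$slab_mat), slab_tally = as.integer(args$slab_tally),
    reg_slab = as.integer(args$reg_slab), reg_cx = args$reg_cx,
    reg_cy = args$reg_cy, reg_a = args$reg_a, reg_b = args$reg_b,
    reg_mat = as.integer(args$reg_mat), reg_tally = as.integer(args$reg_tally),
    mu_pe = args$mu_pe, mu_inc = args$mu_inc,
    e_first = ENERGY_CUTOFF_KEV, air_mat = args$air_mat,
    n_tally = args$n_tally,
    spectrum_e = beam$spectrum$energy_kev, spectrum_w = beam$spectrum$weight,
    fan_deg = fan_override %||% beam$fan_angle_deg,
    coll_mm = coll_override %||% beam$collimation_mm,
    src_radius = beam$source_radius_mm,
    z_center = z_center, rotate_source = rotate_source,
    fixed_angle = fixed_angle, scatter_on = scatter_on,
    cutoff_kev = ENERGY_CUTOFF_KEV,
    n_photons = as.integer(n_photons), seed = as.integer(seed))
  res
}

#' Simulate one axial rotation
#'
#' Transports `n_photons` source photons through the phantom for a single
#' axial rotation centred at `z_center` (source angle uniform on \[0, 2pi)
#' per photon, modelling continuous rotation). Photoelectric events absorb
#' locally (kerma approximation); Compton events deposit the energy transfer
#' locally and scatter the photon; photons are followed until absorption,
#' escape, or the 2 keV cutoff (residual deposited locally).
#'
#' @param phantom a `stylized_phantom`.
#' @param beam a `beam_model`.
#' @param z_center rotation plane, phantom mm.
#' @param n_photons number of source photons (>= 1).
#' @param seed integer seed; identical seeds give bit-identical results.
#' @param scatter_on `FALSE` switches to attenuation-only transport (any
#'   interaction terminates the photon); used for oracle checks.
#' @return object of class `transport_result`: per-tally energies with Monte
#'   Carlo standard errors, energy bookkeeping (emitted = deposited + escaped)
#'   and the seed.
#' @export
simulate_axial_rotation <- function(phantom, beam, z_center, n_photons, seed,
                                    scatter_on = TRUE) {
  stopifnot(inherits(phantom, "stylized_phantom"), inherits(beam, "beam_model"))
  H <- phantom$height_cm * 10
  if (!is_scalar_number(z_center) || z_center < 0 || z_center > H) {
    stop_validation("z_center outside phantom extent")
  }
  if (n_photons < 1) stop_validation("n_photons must be >= 1")
  geom <- phantom_transport_args(phantom)
  res <- run_transport(geom, beam, z_center, n_photons, seed,
                       scatter_on = scatter_on)
  new_transport_result(res, geom$tallies, n_photons, seed,
                       organ_fracs = phantom$organs)
}

new_transport_result <- function(res, tallies, n_photons, seed,
                                 organ_fracs = NULL) {
  e <- res$tally_energy
  e2 <- res$tally_energy_sq
  n <- n_photons
  # SE of the total tally: sd of per-photon contributions times sqrt(n)
  se <- sqrt(pmax(0, e2 / n - (e / n)^2) / n) * n
  tallies$energy_kev <- e
  tallies$se_kev <- se
  structure(list(
    tallies = tallies,
    emitted = res$emitted, deposited = res$deposited,
    escaped = res$escaped, cutoff_bank = res$cutoff_bank,
    n_intact = res$n_intact, n_photons = n_photons, seed = seed,
    organ_fracs = organ_fracs
  ), class = "transport_result")
}

#' @export
print.transport_result <- function(x, ...) {
  cat("<transport_result>", x$n_photons, "photons, seed", x$seed, "\n")
  cat("  emitted:", signif(x$emitted, 6), "keV; deposited:",
      signif(x$deposited, 6), "; escaped:", signif(x$escaped, 6), "\n")
  invisible(x)
}

#' Per-organ dose from a transport result
#'
#' Converts tallied energies to organ dose per source photon. Organ dose is
#' the site-fraction-weighted mean of site doses (energy / site mass); for
#' ordinary organs the sites are mass-weighted so this equals total energy
#' over total mass, while red bone marrow uses the fixed age-specific skeletal
#' site fractions.
#'
#' @param result a `transport_result`.
#' @return tibble `organ`, `dose_mgy_per_photon`, `se_mgy_per_photon`.
#' @export
transport_organ_dose <- function(result) {
  stopifnot(inherits(result, "transport_result"))
  if (is.null(result$organ_fracs)) {
    stop_validation("transport result carries no organ table")
  }
  n <- result$n_photons
  result$tallies %>%
    filter(!is.na(.data$organ)) %>%
    group_by(.data$organ, .data$site) %>%
    summarise(energy_kev = sum(.data$energy_kev),
              var_kev = sum(.data$se_kev^2), .groups = "drop") %>%
    left_join(result$organ_fracs %>%
                select("organ", "site", site_mass_g = "mass_g", "frac"),
              by = c("organ", "site")) %>%
    mutate(site_dose = .data$energy_kev / .data$site_mass_g *
             KEV_PER_G_TO_MGY / n,
           site_se = sqrt(.data$var_kev) / .data$site_mass_g *
             KEV_PER_G_TO_MGY / n) %>%
    group_by(.data$organ) %>%
    summarise(dose_mgy_per_photon = sum(.data$frac * .data$site_dose),
              se_mgy_per_photon = sqrt(sum((.data$frac * .data$site_se)^2)),
              .groups = "drop")
}
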