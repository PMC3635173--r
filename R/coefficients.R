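#' CTDI phantom specification
#'
#' Standard PMMA dosimetry cylinder: 160 mm diameter for head, 320 mm for
#' body, 150 mm long, with a 100 mm pencil chamber at the centre and at four
#' peripheral positions 10 mm below the surface.
#'
#' @param diameter_mm 160 (head) or 320 (body).
#' @return list with the phantom geometry parameters.
#' @export
ctdi_phantom_spec <- function(diameter_mm = 160) {
  if (!diameter_mm %in% c(160, 320)) {
    stop_validation("CTDI phantom diameter must be 160 or 320 mm")
  }
  list(diameter_mm = diameter_mm, material = "pmma", length_mm = 150,
       chamber_length_mm = 100, chamber_radius_mm = 4.5, depth_mm = 10)
}

# transport geometry for the CTDI cylinder; tallies 0..4 = centre, +x, -x,
# +y, -y chambers
ctdi_transport_args <- function(spec) {
  mu <- mu_tables_cached()
  mat_id <- setNames(seq_along(mu$materials) - 1L, mu$materials)
  r <- spec$diameter_mm / 2
  L <- spec$length_mm
  ch0 <- (L - spec$chamber_length_mm) / 2
  rp <- r - spec$depth_mm
  cr <- spec$chamber_radius_mm
  pos <- rbind(c(0, 0), c(rp, 0), c(-rp, 0), c(0, rp), c(0, -rp))
  n_ch <- nrow(pos)
  args <- list(
    slab_z = c(0, ch0, L - ch0, L),
    slab_a = rep(r, 3), slab_b = rep(r, 3),
    slab_mat = rep(unname(mat_id[[spec$material]]), 3),
    slab_tally = rep(-1L, 3),
    reg_slab = rep(1L, n_ch),
    reg_cx = pos[, 1], reg_cy = pos[, 2],
    reg_a = rep(cr, n_ch), reg_b = rep(cr, n_ch),
    reg_mat = rep(unname(mat_id[[spec$material]]), n_ch),
    reg_tally = 0:(n_ch - 1L),
    mu_pe = mu$mu_pe, mu_inc = mu$mu_inc,
    air_mat = unname(mat_id[["air"]]),
    n_tally = n_ch
  )
  rho <- material_density(spec$material)
  chamber_mass_g <- pi * cr^2 * spec$chamber_length_mm * rho / 1000
  list(args = args, chamber_mass_g = chamber_mass_g, z_center = L / 2)
}

#' Simulate the weighted CT dose index
#'
#' Monte Carlo estimate of CTDIw for one axial rotation in the standard PMMA
#' phantom: CTDIw = (1/3) CTDI100,centre + (2/3) CTDI100,periphery, with
#' CTDI100 tallied along the 100 mm chamber and normalized by the beam
#' collimation. The absolute scale is fixed by the bundled photons-per-mAs
#' calibration constant.
#'
#' @param beam a `beam_model`.
#' @param spec a [ctdi_phantom_spec()].
#' @param n_photons number of source photons.
#' @param seed integer seed.
#' @return list: `ctdiw_mgy_per_100mas`, `ctdiw_mgy_per_photon`, per-position
#'   CTDI100 values, and the seed.
#' @export
simulate_ctdiw <- function(beam, spec = ctdi_phantom_spec(160),
                           n_photons = 2e4, seed = 1) {
  stopifnot(inherits(beam, "beam_model"))
  if (n_photons < 1) stop_validation("n_photons must be >= 1")
  g <- ctdi_transport_args(spec)
  res <- run_transport(g, beam, g$z_center, n_photons, seed)
  # mean chamber dose (mGy per photon), integrated over the 100 mm chamber
  d_pp <- res$tally_energy / g$chamber_mass_g * KEV_PER_G_TO_MGY / n_photons
  ctdi100_pp <- d_pp * spec$chamber_length_mm / beam$collimation_mm
  ctdiw_pp <- ctdi100_pp[1] / 3 + 2 / 3 * mean(ctdi100_pp[2:5])
  list(ctdiw_mgy_per_100mas = ctdiw_pp * PHOTONS_PER_MAS * 100,
       ctdiw_mgy_per_photon = ctdiw_pp,
       ctdi100_mgy_per_photon = ctdi100_pp,
       diameter_mm = spec$diameter_mm, n_photons = n_photons, seed = seed)
}

#' Generate a CTDIw-normalized organ dose coefficient table
#'
#' Runs the transport simulation for one axial rotation at every (tube
#' voltage, z-position) cell of a grid covering the phantom, and stores the
#' per-organ dose per rotation normalized to the simulated CTDIw of the
#' matching standard phantom (head cylinder for z inside the head landmark,
#' body cylinder elsewhere). Every cell uses a derivable sub-seed
#' (`derive_seed(seed, "cell", kvp, z)`), so any cell can be reproduced
#' exactly.
#'
#' @param phantom a `stylized_phantom`.
#' @param kvp vector of tube voltages with bundled effective energies.
#' @param z_step_mm grid step; cells are placed at bin midpoints.
#' @param n_photons photons per cell.
#' @param seed master seed.
#' @param collimation_mm,fan_angle_deg,source_radius_mm beam geometry.
#' @param ctdi_n_photons photons for the CTDIw normalization runs.
#' @param ctdiw optional precomputed CTDIw normalization table (as produced
#'   in the `ctdiw` field of an earlier run with the same beam settings);
#'   avoids re-simulating the standard phantoms when generating tables for a
#'   whole phantom family.
#' @return object of class `coefficient_table`.
#' @export
generate_coefficient_table <- function(phantom, kvp = c(80, 100, 120, 140),
                                       z_step_mm = 40, n_photons = 5000,
                                       seed = 1, collimation_mm = 10,
                                       fan_angle_deg = 50,
                                       source_radius_mm = 600,
                                       ctdi_n_photons = max(n_photons, 2e4),
                                       ctdiw = NULL) {
  stopifnot(inherits(phantom, "stylized_phantom"))
  if (length(kvp) == 0) stop_validation("kvp list must be non-empty")
  kvp <- sort(unique(kvp))
  H <- phantom$height_cm * 10
  z <- seq(z_step_mm / 2, H, by = z_step_mm)
  head_lm <- locate_region(phantom, "head")
  ctdi_spec <- if_else(z <= head_lm[2], "head", "body")
  organs <- sort(unique(stats::na.omit(phantom$organs$organ)))
  geom <- phantom_transport_args(phantom)

  if (is.null(ctdiw)) ctdiw <- purrr::map_dfr(kvp, function(kv) {
    beam <- beam_model(kv, collimation_mm = collimation_mm,
                       fan_angle_deg = fan_angle_deg,
                       source_radius_mm = source_radius_mm)
    purrr::map_dfr(c(head = 160, body = 320), function(diam) {
      s <- simulate_ctdiw(beam, ctdi_phantom_spec(diam), ctdi_n_photons,
                          derive_seed(seed, "ctdi", kv, diam))
      tibble(kvp = kv, spec = if (diam == 160) "head" else "body",
             ctdiw_mgy_per_photon = s$ctdiw_mgy_per_photon,
             ctdiw_mgy_per_100mas = s$ctdiw_mgy_per_100mas)
    })
  })

  coeff <- array(NA_real_, c(length(z), length(kvp), length(organs)),
                 dimnames = list(NULL, kvp, organs))
  se <- coeff
  for (ik in seq_along(kvp)) {
    beam <- beam_model(kvp[ik], collimation_mm = collimation_mm,
                       fan_angle_deg = fan_angle_deg,
                       source_radius_mm = source_radius_mm)
    for (iz in seq_along(z)) {
      sub <- derive_seed(seed, "cell", kvp[ik], round(z[iz], 3))
      res <- run_transport(geom, beam, z[iz], n_photons, sub)
      tr <- new_transport_result(res, geom$tallies, n_photons, sub,
                                 organ_fracs = phantom$organs)
      od <- transport_organ_dose(tr)
      norm <- ctdiw$ctdiw_mgy_per_photon[ctdiw$kvp == kvp[ik] &
                                           ctdiw$spec == ctdi_spec[iz]]
      coeff[iz, ik, od$organ] <- od$dose_mgy_per_photon / norm
      se[iz, ik, od$organ] <- od$se_mgy_per_photon / norm
    }
  }
  structure(list(
    phantom_id = phantom$id, age_class = phantom$age_class, sex = phantom$sex,
    kvp = kvp, z = z, organs = organs, coeff = coeff, se = se,
    ctdi_spec = ctdi_spec, ctdiw = ctdiw,
    collimation_mm = collimation_mm, fan_angle_deg = fan_angle_deg,
    source_radius_mm = source_radius_mm,
    n_photons = n_photons, seed = seed,
    version = .ctdosim_version(),
    physics = "kerma approximation; coherent scattering excluded; 2 keV cutoff"
  ), class = "coefficient_table")
}

#' @export
print.coefficient_table <- function(x, ...) {
  cat("<coefficient_table>", x$phantom_id, "\n")
  cat("  kVp:", paste(x$kvp, collapse = ", "), " z cells:", length(x$z),
      " organs:", length(x$organs), "\n")
  cat("  photons/cell:", x$n_photons, " seed:", x$seed, "\n")
  invisible(x)
}

#' @method as_tibble coefficient_table
#' @export
as_tibble.coefficient_table <- function(x, ...) {
  grid <- expand.grid(iz = seq_along(x$z), ik = seq_along(x$kvp),
                      io = seq_along(x$organs))
  tibble(phantom_id = x$phantom_id,
         z_mm = x$z[grid$iz], kvp = x$kvp[grid$ik],
         organ = x$organs[grid$io],
         ctdi_spec = x$ctdi_spec[grid$iz],
         coeff = x$coeff[cbind(grid$iz, grid$ik, grid$io)],
         se = x$se[cbind(grid$iz, grid$ik, grid$io)])
}

#' Persist / load a coefficient table
#'
#' Plain-text store: a directory holding `meta.json` (phantom id, grids,
#' photons, seed, CTDIw normalization, software version) and `coefficients.csv`
#' (long format with Monte Carlo standard errors).
#'
#' @param table a `coefficient_table`.
#' @param dir directory to create/overwrite.
#' @return `dir` (save) / a `coefficient_table` (load).
#' @export
save_coefficient_table <- function(table, dir) {
  stopifnot(inherits(table, "coefficient_table"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- table[c("phantom_id", "age_class", "sex", "kvp", "z", "organs",
                  "ctdi_spec", "collimation_mm", "fan_angle_deg",
                  "source_radius_mm", "n_photons", "seed", "version",
                  "physics")]
  meta$ctdiw <- table$ctdiw
  jsonlite::write_json(meta, file.path(dir, "meta.json"), digits = NA,
                       auto_unbox = TRUE)
  write.csv(as_tibble(table), file.path(dir, "coefficients.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Build (or load cached) coefficient tables for a phantom family
#'
#' Convenience wrapper generating one coefficient table per requested phantom
#' id (`"<age_class>_<sex>"`), sharing the CTDIw normalization runs across
#' phantoms. With `cache_dir` set, previously saved tables with matching
#' settings are loaded instead of re-simulated.
#'
#' @param phantom_ids character vector like `"5y_female"`.
#' @param kvp,z_step_mm,n_photons,seed,collimation_mm passed to
#'   [generate_coefficient_table()].
#' @param cache_dir optional directory for the plain-text table store.
#' @return named list of `coefficient_table`s.
#' @export
default_coefficient_tables <- function(phantom_ids,
                                       kvp = c(80, 100, 120, 140),
                                       z_step_mm = 40, n_photons = 4000,
                                       seed = 1, collimation_mm = 10,
                                       cache_dir = NULL) {
  ctdiw <- NULL
  out <- list()
  for (id in phantom_ids) {
    if (!is.null(cache_dir)) {
      d <- file.path(cache_dir, id)
      if (file.exists(file.path(d, "meta.json"))) {
        tb <- load_coefficient_table(d)
        if (identical(tb$n_photons, n_photons) &&
            identical(as.double(tb$kvp), as.double(kvp)) &&
            identical(tb$seed, derive_seed(seed, id))) {
          out[[id]] <- tb
          ctdiw <- ctdiw %||% tb$ctdiw
          next
        }
      }
    }
    parts <- strsplit(id, "_", fixed = TRUE)[[1]]
    ph <- build_reference_phantom(parts[1], parts[2])
    tb <- generate_coefficient_table(
      ph, kvp = kvp, z_step_mm = z_step_mm, n_photons = n_photons,
      seed = derive_seed(seed, id), collimation_mm = collimation_mm,
      ctdiw = ctdiw)
    ctdiw <- ctdiw %||% tb$ctdiw
    if (!is.null(cache_dir)) save_coefficient_table(tb, file.path(cache_dir, id))
    out[[id]] <- tb
  }
  out
}

#' @rdname save_coefficient_table
#' @export
load_coefficient_table <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  df <- read.csv(file.path(dir, "coefficients.csv"), stringsAsFactors = FALSE)
  z <- meta$z; kvp <- meta$kvp; organs <- meta$organs
  coeff <- array(NA_real_, c(length(z), length(kvp), length(organs)),
                 dimnames = list(NULL, kvp, organs))
  se <- coeff
  iz <- match(round(df$z_mm, 6), round(z, 6))
  ik <- match(df$kvp, kvp)
  io <- match(df$organ, organs)
  coeff[cbind(iz, ik, io)] <- df$coeff
  se[cbind(iz, ik, io)] <- df$se
  structure(list(
    phantom_id = meta$phantom_id, age_class = meta$age_class, sex = meta$sex,
    kvp = kvp, z = z, organs = organs, coeff = coeff, se = se,
    ctdi_spec = meta$ctdi_spec, ctdiw = as_tibble(meta$ctdiw),
    collimation_mm = meta$collimation_mm, fan_angle_deg = meta$fan_angle_deg,
    source_radius_mm = meta$source_radius_mm,
    n_photons = meta$n_photons, seed = meta$seed, version = meta$version,
    physics = meta$physics
  ), class = "coefficient_table")
}
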