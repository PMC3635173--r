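test_that("Compton sampling honours the scattering kinematics exactly", {
  E <- 60
  s <- sample_compton(E, n = 5000, seed = 3)
  alpha <- E / 510.998950
  # energy-angle relation holds for every sample
  expect_equal(s$energy_kev,
               E / (1 + alpha * (1 - cos(s$theta))), tolerance = 1e-10)
  # backscatter bound: E' >= E / (1 + 2 alpha)
  expect_true(all(s$energy_kev >= E / (1 + 2 * alpha) - 1e-9))
  expect_true(all(s$energy_kev <= E + 1e-9))
  expect_error(sample_compton(0.5), class = "ctdosim_validation_error")
  expect_error(sample_compton(250), class = "ctdosim_validation_error")
})

test_that("mean scattered energy matches the Klein-Nishina quadrature oracle", {
  E <- 60
  alpha <- E / 510.998950
  # independent oracle: numeric integration of the Klein-Nishina-weighted
  # Compton energy over the scattering angle
  kn <- function(theta) {
    eps <- 1 / (1 + alpha * (1 - cos(theta)))
    eps^2 * (eps + 1 / eps - sin(theta)^2) * sin(theta)
  }
  num <- stats::integrate(function(t) kn(t) / (1 + alpha * (1 - cos(t))),
                          0, pi, rel.tol = 1e-10)$value
  den <- stats::integrate(kn, 0, pi, rel.tol = 1e-10)$value
  expected_mean <- E * num / den
  n <- 1e5
  s <- sample_compton(E, n = n, seed = 11)
  se <- sd(s$energy_kev) / sqrt(n)
  expect_lt(abs(mean(s$energy_kev) - expected_mean), 3 * se)
})

test_that("axial rotation transport is deterministic and conserves energy", {
  ph <- build_reference_phantom("1y", "male")
  beam <- beam_model(120)
  r1 <- simulate_axial_rotation(ph, beam, 80, 5000, seed = 9)
  r2 <- simulate_axial_rotation(ph, beam, 80, 5000, seed = 9)
  expect_identical(r1$tallies$energy_kev, r2$tallies$energy_kev)
  expect_identical(r1$deposited, r2$deposited)
  r3 <- simulate_axial_rotation(ph, beam, 80, 5000, seed = 10)
  expect_false(identical(r1$deposited, r3$deposited))
  for (r in list(r1, r3)) {
    expect_lt(abs(r$emitted - r$deposited - r$escaped) / r$emitted, 1e-9)
    expect_true(all(r$tallies$energy_kev >= 0))
  }
})

test_that("in-field organs receive far more dose than out-of-field organs", {
  ph <- build_reference_phantom("1y", "male")
  beam <- beam_model(120)
  head_z <- mean(locate_region(ph, "head"))
  r <- simulate_axial_rotation(ph, beam, head_z, 2e4, seed = 5)
  od <- transport_organ_dose(r)
  brain <- od$dose_mgy_per_photon[od$organ == "brain"]
  colon <- od$dose_mgy_per_photon[od$organ == "colon"]
  expect_gt(brain, 10 * max(colon, 1e-18))
})

test_that("z_center outside the phantom is rejected", {
  ph <- build_reference_phantom("1y", "male")
  expect_error(simulate_axial_rotation(ph, beam_model(120), -5, 100, 1),
               class = "ctdosim_validation_error")
  expect_error(simulate_axial_rotation(ph, beam_model(120), 1e5, 100, 1),
               class = "ctdosim_validation_error")
})

test_that("scatter-free pencil transmission equals exponential attenuation", {
  # water cylinder built directly in transport-geometry form
  r_mm <- 80
  mu <- ctdosim:::mu_tables_cached()
  mat_id <- setNames(seq_along(mu$materials) - 1L, mu$materials)
  args <- list(
    slab_z = c(0, 150), slab_a = r_mm, slab_b = r_mm,
    slab_mat = unname(mat_id[["water"]]), slab_tally = 0L,
    reg_slab = integer(), reg_cx = numeric(), reg_cy = numeric(),
    reg_a = numeric(), reg_b = numeric(),
    reg_mat = integer(), reg_tally = integer(),
    mu_pe = mu$mu_pe, mu_inc = mu$mu_inc,
    air_mat = unname(mat_id[["air"]]), n_tally = 1L)
  geom <- list(args = args)
  beam <- beam_model(120)  # effective energy 62 keV
  n <- 1e5
  res <- ctdosim:::run_transport(geom, beam, 75, n, seed = 21,
                                 rotate_source = FALSE, fixed_angle = 0,
                                 scatter_on = FALSE,
                                 fan_override = 0, coll_override = 0)
  trans <- res$n_intact / n
  mu_lin <- material_mu("water", 62, "total") * 1.0 / 10  # 1/mm
  expected <- exp(-mu_lin * 2 * r_mm)
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(trans - expected), 3 * se)
})

test_that("tallies scale linearly and errors shrink as one over root n", {
  ph <- build_reference_phantom("5y", "male")
  beam <- beam_model(120)
  z <- mean(locate_region(ph, "head"))
  ns <- c(2000, 4000, 8000, 16000)
  per_photon <- se_brain <- numeric(length(ns))
  for (i in seq_along(ns)) {
    r <- simulate_axial_rotation(ph, beam, z, ns[i], seed = 33)
    od <- transport_organ_dose(r)
    per_photon[i] <- od$dose_mgy_per_photon[od$organ == "brain"]
    se_brain[i] <- od$se_mgy_per_photon[od$organ == "brain"]
  }
  # dose per photon is stable (doubling photons does not bias the tally)
  expect_equal(per_photon / per_photon[1], rep(1, 4), tolerance = 0.15)
  # MC standard error shrinks roughly as 1/sqrt(n) over three doublings
  ratio <- se_brain[1] / se_brain[4]
  expect_gt(ratio, sqrt(8) * 0.6)
  expect_lt(ratio, sqrt(8) * 1.6)
})

test_that("CTDIw simulation reflects phantom attenuation and beam quality", {
  beam <- beam_model(120)
  head <- simulate_ctdiw(beam, ctdi_phantom_spec(160), 2e4, seed = 4)
  body <- simulate_ctdiw(beam, ctdi_phantom_spec(320), 2e4, seed = 4)
  # larger phantom attenuates more: body CTDIw below head CTDIw at equal beam
  expect_lt(body$ctdiw_mgy_per_100mas, head$ctdiw_mgy_per_100mas)
  expect_gt(head$ctdiw_mgy_per_100mas, 0)
  expect_error(ctdi_phantom_spec(200), class = "ctdosim_validation_error")
})

test_that("coefficient tables are reproducible cell by cell", {
  ph <- build_reference_phantom("1y", "female")
  tab <- generate_coefficient_table(ph, kvp = 120, z_step_mm = 120,
                                    n_photons = 800, seed = 77,
                                    ctdi_n_photons = 5000)
  expect_true(all(is.finite(tab$coeff)))
  expect_true(all(tab$coeff >= 0))
  # brain coefficient in the head dwarfs the abdomen value
  head_z <- which(tab$z <= locate_region(ph, "head")[2])
  abd_z <- which(tab$z >= locate_region(ph, "abdomen")[1] &
                   tab$z <= locate_region(ph, "abdomen")[2])
  expect_gt(max(tab$coeff[head_z, 1, "brain"]),
            10 * max(tab$coeff[abd_z, 1, "brain"], 1e-12))
  # regenerating one cell from its derivable sub-seed reproduces it exactly
  iz <- head_z[1]
  sub <- derive_seed(77, "cell", 120, round(tab$z[iz], 3))
  geom <- ctdosim:::phantom_transport_args(ph)
  beam <- beam_model(120, collimation_mm = tab$collimation_mm,
                     fan_angle_deg = tab$fan_angle_deg,
                     source_radius_mm = tab$source_radius_mm)
  res <- ctdosim:::run_transport(geom, beam, tab$z[iz], 800, sub)
  tr <- ctdosim:::new_transport_result(res, geom$tallies, 800, sub,
                                       organ_fracs = ph$organs)
  od <- transport_organ_dose(tr)
  norm <- tab$ctdiw$ctdiw_mgy_per_photon[tab$ctdiw$spec == "head"]
  expect_equal(unname(tab$coeff[iz, 1, "brain"]),
               od$dose_mgy_per_photon[od$organ == "brain"] / norm)
  expect_error(generate_coefficient_table(ph, kvp = numeric()),
               class = "ctdosim_validation_error")
})

test_that("coefficient tables survive a plain-text save/load round trip", {
  ph <- build_reference_phantom("newborn", "male")
  tab <- generate_coefficient_table(ph, kvp = c(100, 120), z_step_mm = 150,
                                    n_photons = 500, seed = 5,
                                    ctdi_n_photons = 3000)
  d <- file.path(tempdir(), "coef_store")
  save_coefficient_table(tab, d)
  tab2 <- load_coefficient_table(d)
  expect_equal(tab2$coeff, tab$coeff, tolerance = 1e-12)
  expect_equal(tab2$z, tab$z)
  expect_equal(tab2$seed, tab$seed)
  expect_equal(tab2$ctdiw$ctdiw_mgy_per_photon, tab$ctdiw$ctdiw_mgy_per_photon,
               tolerance = 1e-12)
  unlink(d, recursive = TRUE)
})
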