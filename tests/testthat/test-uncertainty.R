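test_that("parameter PDFs validate their families and bounds", {
  expect_s3_class(parameter_pdf("mas", "lognormal",
                                list(median = 100, gsd = 1.5)),
                  "parameter_pdf")
  expect_error(parameter_pdf("mas", "lognormal", list(median = 100, gsd = 0.9)),
               class = "ctdosim_validation_error")
  expect_error(parameter_pdf("mas", "uniform", list(min = 5, max = 1)),
               class = "ctdosim_validation_error")
  expect_error(parameter_pdf("mas", "spline", list()),
               class = "ctdosim_validation_error")
  expect_error(parameter_pdf("mas", "point", list(value = 1), trunc = c(2, 1)),
               class = "ctdosim_validation_error")
})

test_that("elicitation follows the observation ladder", {
  # identical observations collapse to a point mass
  p <- elicit_pdf("mas", c(100, 100, 100), era = "pre_pacs")
  expect_equal(p$family, "point")
  expect_equal(p$params$value, 100)
  # geometric median oracle: {50, 100, 200} -> lognormal with median 100
  p <- elicit_pdf("mas", c(50, 100, 200), era = "pre_pacs")
  expect_equal(p$family, "lognormal")
  expect_equal(p$params$median, exp(mean(log(c(50, 100, 200)))))
  expect_equal(p$params$median, 100)
  expect_equal(p$params$gsd, exp(sd(log(c(50, 100, 200)))))
  # one or two observations: triangular with era bounds
  p <- elicit_pdf("mas", 120, era = "pre_pacs")
  expect_equal(p$family, "triangular")
  expect_equal(p$params$mode, 120)
  expect_equal(p$tier, "sparse")
  # none: the era default, flagged lowest-confidence
  p <- elicit_pdf("kvp", numeric(), era = "pre_pacs")
  expect_equal(p$tier, "era_default")
  # no observations and no registry entry is an elicitation error
  expect_error(elicit_pdf("unknown_param", numeric(), era = "pre_pacs"),
               class = "ctdosim_elicitation_error")
})

test_that("recent-era elicited PDFs are not wider than early-era defaults", {
  wide_obs <- c(20, 400, 40, 350, 30)
  early <- elicit_pdf("mas", wide_obs, era = "pre_pacs")
  late <- elicit_pdf("mas", wide_obs, era = "post_pacs")
  expect_true(late$trunc[1] >= early$trunc[1])
  expect_true(late$trunc[2] <= early$trunc[2])
})

test_that("scope keys control sharing in parameter sampling", {
  pdfs <- list(mas = parameter_pdf("mas", "lognormal",
                                   list(median = 100, gsd = 1.5),
                                   scope = "group"))
  a1 <- sample_parameters(pdfs, "G1", "pA", realization = 1, master_seed = 9)
  b1 <- sample_parameters(pdfs, "G1", "pB", realization = 1, master_seed = 9)
  a2 <- sample_parameters(pdfs, "G1", "pA", realization = 2, master_seed = 9)
  c1 <- sample_parameters(pdfs, "G2", "pA", realization = 1, master_seed = 9)
  expect_identical(a1$mas, b1$mas)      # shared within group and realization
  expect_false(identical(a1$mas, a2$mas))  # varies across realizations
  expect_false(identical(a1$mas, c1$mas))  # differs between groups
  # patient scope: same patient same draw, different patients differ
  pdfs$mas$scope <- "patient"
  a1 <- sample_parameters(pdfs, "G1", "pA", realization = 1, master_seed = 9)
  b1 <- sample_parameters(pdfs, "G1", "pB", realization = 1, master_seed = 9)
  a1g2 <- sample_parameters(pdfs, "G2", "pA", realization = 1, master_seed = 9)
  expect_false(identical(a1$mas, b1$mas))
  expect_identical(a1$mas, a1g2$mas)
  # point masses: every realization identical
  pp <- list(kvp = parameter_pdf("kvp", "point", list(value = 120)))
  expect_identical(sample_parameters(pp, "G1", "pA", 1, 9),
                   sample_parameters(pp, "G1", "pA", 50, 9))
  expect_error(sample_parameters(list(bad = 1), "G1", "pA", 1, 9),
               class = "ctdosim_reconstruction_error")
})

test_that("linked parameters are drawn as joint rows, never marginals", {
  tab <- tibble::tibble(kvp = c(80, 120), mas = c(150, 60))
  pdfs <- list(
    kvp = parameter_pdf("kvp", "discrete_joint", list(table = tab),
                        scope = "group", linkage = "proto"),
    mas = parameter_pdf("mas", "discrete_joint", list(table = tab),
                        scope = "group", linkage = "proto"))
  draws <- lapply(1:40, function(r) {
    sample_parameters(pdfs, "G1", "pA", realization = r, master_seed = 3)
  })
  pairs <- unique(vapply(draws, function(d) paste(d$kvp, d$mas), character(1)))
  expect_true(all(pairs %in% c("80 150", "120 60")))
  expect_equal(length(pairs), 2L)  # both rows eventually drawn
})

test_that("degenerate PDFs make the realization module the identity", {
  co <- fixture_cohort(n = 40, seed = 31)
  det <- reconstruct_doses(co)
  # V = 1 with no registered PDFs reduces to the deterministic engine
  dcoh <- dose_cohort(co$patients, co$series, co$tables)
  rs <- generate_realizations(dcoh, list(), V = 1, master_seed = 77)
  expect_equal(as_tibble(rs)$dose_mgy,
               det$dose_mgy[match(paste(as_tibble(rs)$patient_id,
                                        as_tibble(rs)$organ),
                                  paste(det$patient_id, det$organ))],
               tolerance = 1e-12)
  expect_identical(unname(co$truth$doses$dose_mgy), unname(det$dose_mgy))
})

test_that("same-group patients move in lockstep under shared-only error", {
  dcoh <- fixture_shared_cohort(n = 3)
  reg <- list(G1 = list(mas = parameter_pdf("mas", "lognormal",
                                            list(median = 120, gsd = 1.4),
                                            scope = "group")))
  rs <- generate_realizations(dcoh, reg, V = 30, master_seed = 13)
  d <- rs$doses[, , "brain"]
  # within-realization ratios constant at machine precision
  r12 <- d[, 1] / d[, 2]
  expect_equal(r12, rep(r12[1], 30), tolerance = 1e-14)
  expect_equal(cor(d[, 1], d[, 2], method = "spearman"), 1)
  # doses genuinely vary across realizations
  expect_gt(sd(d[, 1]) / mean(d[, 1]), 0.05)
})

test_that("patient order does not affect realized doses", {
  dcoh <- fixture_shared_cohort(n = 3)
  reg <- list(G1 = list(mas = parameter_pdf("mas", "lognormal",
                                            list(median = 120, gsd = 1.4),
                                            scope = "patient")))
  rs <- generate_realizations(dcoh, reg, V = 5, master_seed = 21)
  perm <- c(3, 1, 2)
  dcoh2 <- dose_cohort(dcoh$patients[perm, ], dcoh$series[perm, ],
                       dcoh$tables)
  rs2 <- generate_realizations(dcoh2, reg, V = 5, master_seed = 21)
  expect_equal(rs2$doses[, dcoh$patients$patient_id, ],
               rs$doses[, dcoh$patients$patient_id, ], tolerance = 1e-14)
})

test_that("variance decomposition matches closed-form lognormal moments", {
  dcoh <- fixture_shared_cohort(n = 2)
  g_gsd <- 1.5; p_gsd <- 1.3
  reg <- list(G1 = list(
    mas = parameter_pdf("mas", "lognormal", list(median = 100, gsd = g_gsd),
                        scope = "group"),
    modulation_factor = parameter_pdf("modulation_factor", "lognormal",
                                      list(median = 1, gsd = p_gsd),
                                      scope = "patient")))
  rs <- generate_realizations(dcoh, reg, V = 1000, master_seed = 5,
                              inner_reps = 20)
  sm <- summarize_realizations(rs)
  sm1 <- sm[sm$patient_id == "S01" & sm$organ == "brain", ]
  # dose = C * X * Y with X, Y lognormal; closed-form moments
  sx <- log(g_gsd); sy <- log(p_gsd)
  EX <- exp(sx^2 / 2); EY <- exp(sy^2 / 2)
  VX <- (exp(sx^2) - 1) * exp(sx^2); VY <- (exp(sy^2) - 1) * exp(sy^2)
  C <- sm1$mean_mgy / (EX * EY)
  shared_expect <- C^2 * EY^2 * VX
  unshared_expect <- C^2 * (VX + EX^2) * VY
  expect_equal(sm1$var_shared, shared_expect,
               tolerance = 0.25)
  expect_equal(sm1$var_unshared, unshared_expect,
               tolerance = 0.25)
  # decomposition is exact: shared + unshared = total
  expect_equal(sm1$var_shared + sm1$var_unshared, sm1$var_total,
               tolerance = 1e-9)
})

test_that("dispersion summaries require V >= 2 and flag missing nesting", {
  dcoh <- fixture_shared_cohort(n = 2)
  regp0 <- list(G1 = list(mas = parameter_pdf("mas", "point",
                                              list(value = 120),
                                              scope = "group")))
  rs1 <- generate_realizations(dcoh, regp0, V = 1, master_seed = 1)
  expect_error(summarize_realizations(rs1, dispersion = TRUE),
               class = "ctdosim_validation_error")
  reg <- list(G1 = list(mas = parameter_pdf("mas", "uniform",
                                            list(min = 80, max = 160),
                                            scope = "group")))
  rs <- generate_realizations(dcoh, reg, V = 10, master_seed = 1)
  expect_message(sm <- summarize_realizations(rs), "decomposition")
  expect_true(all(is.na(sm$var_shared)))
  # point-mass-only uncertainty: zero variance, mean equals deterministic
  regp <- list(G1 = list(mas = parameter_pdf("mas", "point",
                                             list(value = 120),
                                             scope = "group")))
  rsp <- generate_realizations(dcoh, regp, V = 4, master_seed = 2)
  smp <- summarize_realizations(rsp)
  expect_true(all(smp$var_total == 0))
})

test_that("realization sets survive a plain-text save/load round trip", {
  dcoh <- fixture_shared_cohort(n = 2)
  reg <- list(G1 = list(mas = parameter_pdf("mas", "lognormal",
                                            list(median = 120, gsd = 1.3),
                                            scope = "group")))
  rs <- generate_realizations(dcoh, reg, V = 6, master_seed = 3)
  d <- file.path(tempdir(), "rs_store")
  save_realization_set(rs, d)
  rs2 <- load_realization_set(d)
  expect_equal(rs2$doses, rs$doses, tolerance = 1e-12)
  expect_equal(rs2$V, rs$V)
  expect_equal(rs2$master_seed, rs$master_seed)
  expect_equal(rs2$realization_seeds, rs$realization_seeds)
  unlink(d, recursive = TRUE)
})

test_that("the PDF registry covers every group with missing parameters", {
  co <- fixture_cohort(n = 60, seed = 19)
  m <- mask_for_scenario(co)
  reg <- build_pdf_registry(m$series, protocols = m$protocols)
  miss_groups <- unique(m$series$group_key[is.na(m$series$kvp)])
  for (g in miss_groups) {
    expect_true("kvp" %in% names(reg$groups[[g]]),
                label = paste("kvp pdf for", g))
  }
  # masked pre-PACS series can be realized without reconstruction errors
  dcoh <- dose_cohort(m$patients, m$series, m$tables)
  rs <- generate_realizations(dcoh, reg, V = 3, master_seed = 4)
  expect_true(all(is.finite(rs$doses)))
  expect_true(all(rs$doses >= 0))
})
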