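#' Stylized reference phantoms
#'
#' The phantom family is a set of age- and sex-specific stylized body models
#' built from stacked elliptical axial slabs (crown origin, z in mm increasing
#' caudally). Each slab carries an outer body envelope and nested elliptical
#' tissue regions (checked innermost-first); named organ regions cover brain,
#' red bone marrow (distributed over skull, spine, pelvis and femora sites),
#' colon, thyroid, breast, lungs and a trunk-soft-tissue remainder. The family
#' is a deliberately simplified geometric surrogate for anatomically realistic
#' hybrid phantoms, exposing the same interface (age classes, landmarks, organ
#' masses) so that the rest of the pipeline is phantom-agnostic.
#'
#' @name phantoms
NULL

load_anthropometry <- function() {
  yaml::read_yaml(extdata_path("anthropometry.yaml"))
}

anthropometry_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_anthropometry()
    cache
  }
})

#' Reference anthropometry table
#'
#' @return tibble with one row per (age_class, sex): reference age (years),
#'   height (cm) and body mass (kg).
#' @export
reference_anthropometry <- function() {
  a <- anthropometry_cached()
  purrr::map_dfr(AGE_CLASSES, function(cl) {
    e <- a$classes[[cl]]
    tibble(age_class = cl,
           reference_age = a$reference_ages[[cl]],
           sex = c("male", "female"),
           height_cm = c(e$height_cm$male, e$height_cm$female),
           mass_kg = c(e$mass_kg$male, e$mass_kg$female))
  })
}

# ellipse area in mm^2
.ell_area <- function(a, b) pi * a * b

# is ellipse (cx1,cy1,a1,b1) geometrically inside ellipse (cx2,cy2,a2,b2)?
# boundary-sampling test; exact enough for construction-time checks
.ellipse_inside <- function(cx1, cy1, a1, b1, cx2, cy2, a2, b2, n = 72) {
  th <- seq(0, 2 * pi, length.out = n)
  x <- cx1 + a1 * cos(th)
  y <- cy1 + b1 * sin(th)
  all(((x - cx2) / a2)^2 + ((y - cy2) / b2)^2 <= 1 + 1e-9)
}

#' Build a reference stylized phantom
#'
#' Deterministically constructs the stylized phantom for one of the six
#' reference age classes. Geometry is a template (in adult proportions) scaled
#' axially by stature and laterally by body mass, with age-specific head
#' proportions and landmark fractions taken from the bundled anthropometry
#' file.
#'
#' @param age_class one of `"newborn"`, `"1y"`, `"5y"`, `"10y"`, `"15y"`,
#'   `"adult"`.
#' @param sex `"male"` or `"female"`.
#' @return object of class `stylized_phantom`: a list with `slabs`, `regions`,
#'   `organs`, `landmarks` tibbles plus scalar anthropometry. Regions carry a
#'   per-slab priority (innermost first) and a computed net mass.
#' @examples
#' ph <- build_reference_phantom("5y", "female")
#' ph$landmarks
#' @export
build_reference_phantom <- function(age_class, sex) {
  assert_choice(age_class, AGE_CLASSES, "age_class", error = stop_config)
  assert_choice(sex, c("male", "female"), "sex", error = stop_config)
  a <- anthropometry_cached()$classes[[age_class]]
  H <- a$height_cm[[sex]] * 10          # mm
  M <- a$mass_kg[[sex]]
  sz <- H / 1760                        # axial scale vs adult male template
  sl <- sqrt((M / 73) / sz)             # lateral scale preserving mass trend
  sh <- sl * a$head_boost               # head lateral scale
  lf <- a$landmark_frac
  L1 <- lf$head_end * H; L2 <- lf$neck_end * H
  L3 <- lf$chest_end * H; L4 <- lf$abd_end * H
  Lp <- L4 + 0.10 * H                   # pelvis end

  slab <- function(group, z0, z1, a_, b_, mat = "soft_tissue", organ = "remainder") {
    tibble(group = group, z0 = z0, z1 = z1, a = a_, b = b_,
           material = mat, body_organ = organ)
  }
  # body envelope slabs (implicit region organ: remainder in trunk, none in
  # head/legs)
  slabs <- bind_rows(
    slab("head", 0, 0.62 * L1, 75 * sh, 92 * sh, organ = NA),
    slab("head", 0.62 * L1, L1, 70 * sh, 85 * sh, organ = NA),
    slab("neck", L1, L2, 55 * sl, 55 * sl),
    slab("chest", L2, L2 + 0.12 * (L3 - L2), 170 * sl, 110 * sl),
    slab("chest", L2 + 0.12 * (L3 - L2), L2 + 0.85 * (L3 - L2), 170 * sl, 110 * sl),
    slab("chest", L2 + 0.85 * (L3 - L2), L3, 165 * sl, 108 * sl),
    slab("abdomen", L3, L4, 160 * sl, 105 * sl),
    slab("pelvis", L4, Lp, 165 * sl, 108 * sl),
    slab("legs", Lp, H, 160 * sl, 90 * sl, organ = NA)
  ) %>% mutate(slab = row_number())

  reg <- function(slab, priority, cx, cy, a_, b_, material, organ, site) {
    tibble(slab = slab, priority = priority, cx = cx, cy = cy, a = a_, b = b_,
           material = material, organ = organ, site = site)
  }
  regions <- bind_rows(
    # cranium: brain inside skull ring inside scalp
    reg(1, 1, 0, 0, 62 * sh, 79 * sh, "brain", "brain", "all"),
    reg(1, 2, 0, 0, 70 * sh, 87 * sh, "bone", "red_bone_marrow", "skull"),
    # face: facial bone block
    reg(2, 1, 0, 0, 40 * sh, 55 * sh, "bone", "red_bone_marrow", "skull"),
    # neck: cervical spine + thyroid
    reg(3, 1, 0, 18 * sl, 14 * sl, 14 * sl, "bone", "red_bone_marrow", "spine"),
    reg(3, 2, 0, -30 * sl, 18 * sl, 8 * sl, "soft_tissue", "thyroid", "all"),
    # upper chest: thoracic spine
    reg(4, 1, 0, 75 * sl, 15 * sl, 17 * sl, "bone", "red_bone_marrow", "spine"),
    # mid chest: lungs + spine
    reg(5, 1, -72 * sl, 5 * sl, 58 * sl, 78 * sl, "lung", "lungs", "all"),
    reg(5, 2, 72 * sl, 5 * sl, 58 * sl, 78 * sl, "lung", "lungs", "all"),
    reg(5, 3, 0, 75 * sl, 15 * sl, 17 * sl, "bone", "red_bone_marrow", "spine"),
    # lower chest: breasts (anterior, y negative) + spine
    reg(6, 1, -58 * sl, -84 * sl, 28 * sl, 11 * sl, "soft_tissue", "breast", "all"),
    reg(6, 2, 58 * sl, -84 * sl, 28 * sl, 11 * sl, "soft_tissue", "breast", "all"),
    reg(6, 3, 0, 75 * sl, 15 * sl, 17 * sl, "bone", "red_bone_marrow", "spine"),
    # abdomen: colon limbs + lumbar spine
    reg(7, 1, -78 * sl, 0, 26 * sl, 30 * sl, "soft_tissue", "colon", "all"),
    reg(7, 2, 78 * sl, 0, 26 * sl, 30 * sl, "soft_tissue", "colon", "all"),
    reg(7, 3, 0, 70 * sl, 16 * sl, 18 * sl, "bone", "red_bone_marrow", "spine"),
    # pelvis: iliac wings + sacrum
    reg(8, 1, -70 * sl, 25 * sl, 32 * sl, 45 * sl, "bone", "red_bone_marrow", "pelvis"),
    reg(8, 2, 70 * sl, 25 * sl, 32 * sl, 45 * sl, "bone", "red_bone_marrow", "pelvis"),
    reg(8, 3, 0, 70 * sl, 18 * sl, 22 * sl, "bone", "red_bone_marrow", "pelvis"),
    # legs: femora
    reg(9, 1, -80 * sl, 0, 16 * sl, 16 * sl, "bone", "red_bone_marrow", "femora"),
    reg(9, 2, 80 * sl, 0, 16 * sl, 16 * sl, "bone", "red_bone_marrow", "femora")
  )

  # net cross-section areas: subtract higher-priority (inner) regions that lie
  # wholly inside a region (e.g. brain inside the skull ellipse)
  regions <- regions %>%
    group_by(.data$slab) %>%
    mutate(gross_area = .ell_area(.data$a, .data$b)) %>%
    mutate(net_area = {
      ga <- .data$gross_area
      na_ <- ga
      if (n() > 1) {
        for (i in seq_len(n())) {
          for (k in seq_len(n())) {
            if (k < i && .ellipse_inside(.data$cx[k], .data$cy[k], .data$a[k],
                                         .data$b[k], .data$cx[i], .data$cy[i],
                                         .data$a[i], .data$b[i])) {
              na_[i] <- na_[i] - ga[k]
            }
          }
        }
      }
      na_
    }) %>%
    ungroup()

  materials <- load_materials()
  dens <- setNames(
    vapply(unique(materials$material), material_density, 0, materials = materials),
    unique(materials$material))
  thick <- slabs$z1 - slabs$z0
  regions <- regions %>%
    mutate(thickness = thick[.data$slab],
           # mm^3 * g/cm^3 / 1000 = g
           mass_g = .data$net_area * .data$thickness * dens[.data$material] / 1000)

  # implicit body region masses (envelope minus nested regions)
  body_net <- slabs %>%
    left_join(regions %>% group_by(.data$slab) %>%
                summarise(reg_area = sum(.data$net_area)),
              by = "slab") %>%
    mutate(reg_area = if_else(is.na(.data$reg_area), 0, .data$reg_area),
           net_area = .ell_area(.data$a, .data$b) - .data$reg_area,
           mass_g = .data$net_area * (.data$z1 - .data$z0) *
             dens[.data$material] / 1000)
  slabs$body_mass_g <- body_net$mass_g
  slabs$body_net_area <- body_net$net_area

  # organ/site aggregation with red-bone-marrow site weighting
  rbm <- a$rbm
  site_mass <- bind_rows(
    regions %>% filter(!is.na(.data$organ)) %>%
      group_by(organ = .data$organ, site = .data$site) %>%
      summarise(mass_g = sum(.data$mass_g), .groups = "drop"),
    slabs %>% filter(!is.na(.data$body_organ)) %>%
      group_by(organ = .data$body_organ) %>%
      summarise(mass_g = sum(.data$body_mass_g), .groups = "drop") %>%
      mutate(site = "all")
  ) %>%
    group_by(.data$organ, .data$site) %>%
    summarise(mass_g = sum(.data$mass_g), .groups = "drop")
  organs <- site_mass %>%
    group_by(.data$organ) %>%
    mutate(frac = if (first(.data$organ) == "red_bone_marrow") {
      unlist(rbm)[.data$site]
    } else {
      .data$mass_g / sum(.data$mass_g)
    }) %>%
    ungroup()

  landmarks <- tibble(region = BODY_REGIONS,
                      z0 = c(0, L2, L3), z1 = c(L1, L3, L4))

  structure(list(
    age_class = age_class, sex = sex,
    height_cm = a$height_cm[[sex]], mass_kg = M,
    slabs = slabs, regions = regions, organs = organs,
    landmarks = landmarks,
    lateral_scale = sl, head_scale = sh,
    id = paste0(age_class, "_", sex)
  ), class = "stylized_phantom")
}

#' @export
print.stylized_phantom <- function(x, ...) {
  cat("<stylized_phantom>", x$id, "\n")
  cat("  height:", x$height_cm, "cm  mass:", x$mass_kg, "kg\n")
  cat("  slabs:", nrow(x$slabs), " regions:", nrow(x$regions),
      " organs:", length(unique(x$organs$organ)), "\n")
  invisible(x)
}

#' Select the reference phantom class for a patient
#'
#' Without stature, returns the nearest reference age among 0, 1, 5, 10, 15
#' and 20 years, breaking ties toward the younger class (conservative toward
#' higher dose per unit exposure in smaller bodies). With both height and
#' weight, returns the class minimizing Euclidean distance in standardized
#' (height/sd_h, weight/sd_w) space over the reference family of the given
#' sex; age is then not used.
#'
#' @param age age at examination, years (vectorized); must be in 0..25.
#' @param sex `"male"`/`"female"` (vectorized or scalar).
#' @param height_cm,weight_kg optional stature (vectorized); both must be
#'   present (non-NA) for stature-based selection of that element.
#' @return character vector of age classes.
#' @export
select_phantom <- function(age, sex, height_cm = NULL, weight_kg = NULL) {
  if (any(!is.finite(age)) || any(age < 0)) {
    stop_validation("age must be finite and non-negative")
  }
  if (any(age > 25)) stop_validation("age must be <= 25 years")
  n <- length(age)
  sex <- rep_len(sex, n)
  height_cm <- if (is.null(height_cm)) rep(NA_real_, n) else rep_len(height_cm, n)
  weight_kg <- if (is.null(weight_kg)) rep(NA_real_, n) else rep_len(weight_kg, n)
  ref <- reference_anthropometry()
  ref_age <- setNames(ref$reference_age[!duplicated(ref$age_class)],
                      ref$age_class[!duplicated(ref$age_class)])
  out <- character(n)
  for (i in seq_len(n)) {
    if (is.finite(height_cm[i]) && is.finite(weight_kg[i])) {
      fam <- ref[ref$sex == sex[i], ]
      sd_h <- sd(fam$height_cm); sd_w <- sd(fam$mass_kg)
      d <- ((fam$height_cm - height_cm[i]) / sd_h)^2 +
        ((fam$mass_kg - weight_kg[i]) / sd_w)^2
      # ties toward the younger class: which.min picks the first (youngest)
      out[i] <- fam$age_class[which.min(round(d, 12))]
    } else {
      d <- abs(ref_age - age[i])
      out[i] <- names(ref_age)[which.min(round(d, 12))]
    }
  }
  out
}

#' Locate a body-region landmark interval on a phantom
#'
#' @param phantom a `stylized_phantom`.
#' @param body_region `"head"`, `"chest"` or `"abdomen"`.
#' @return numeric `c(z0, z1)` in phantom mm.
#' @export
locate_region <- function(phantom, body_region) {
  stopifnot(inherits(phantom, "stylized_phantom"))
  assert_choice(body_region, BODY_REGIONS, "body region")
  lm <- phantom$landmarks[phantom$landmarks$region == body_region, ]
  c(lm$z0, lm$z1)
}

#' Organ mass of a phantom
#'
#' Total organ mass in grams; for red bone marrow this is the mass of the
#' marrow-bearing bone regions summed over skeletal sites.
#'
#' @param phantom a `stylized_phantom`.
#' @param organ organ label.
#' @return mass in g.
#' @export
organ_mass <- function(phantom, organ) {
  stopifnot(inherits(phantom, "stylized_phantom"))
  o <- phantom$organs[phantom$organs$organ == organ, ]
  if (nrow(o) == 0L) stop_validation(paste0("organ not present: ", organ))
  sum(o$mass_g)
}

#' Export phantom geometry to JSON
#'
#' @param phantom a `stylized_phantom`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
phantom_to_json <- function(phantom, path) {
  jsonlite::write_json(
    list(id = phantom$id, age_class = phantom$age_class, sex = phantom$sex,
         height_cm = phantom$height_cm, mass_kg = phantom$mass_kg,
         slabs = phantom$slabs, regions = phantom$regions,
         organs = phantom$organs, landmarks = phantom$landmarks),
    path, digits = 6, auto_unbox = TRUE)
  invisible(path)
}

# flatten phantom geometry for the C++ transport kernel; returns the argument
# list plus the tally metadata table (tally id -> organ/site/mass)
phantom_transport_args <- function(phantom) {
  slabs <- phantom$slabs
  regions <- phantom$regions %>% arrange(.data$slab, .data$priority)
  mu <- mu_tables_cached()
  mat_id <- setNames(seq_along(mu$materials) - 1L, mu$materials)
  # tally ids: one per explicit region row, then one per slab body region
  regions$tally <- seq_len(nrow(regions)) - 1L
  slabs$tally <- nrow(regions) + seq_len(nrow(slabs)) - 1L
  tallies <- bind_rows(
    regions %>% select(tally = "tally", organ = "organ", site = "site",
                       mass_g = "mass_g"),
    slabs %>% select(tally = "tally", organ = "body_organ",
                     mass_g = "body_mass_g") %>% mutate(site = "all")
  ) %>% arrange(.data$tally)
  list(
    args = list(
      slab_z = c(slabs$z0[1], slabs$z1),
      slab_a = slabs$a, slab_b = slabs$b,
      slab_mat = unname(mat_id[slabs$material]),
      slab_tally = slabs$tally,
      reg_slab = regions$slab - 1L,
      reg_cx = regions$cx, reg_cy = regions$cy,
      reg_a = regions$a, reg_b = regions$b,
      reg_mat = unname(mat_id[regions$material]),
      reg_tally = regions$tally,
      mu_pe = mu$mu_pe, mu_inc = mu$mu_inc,
      air_mat = unname(mat_id[["air"]]),
      n_tally = nrow(tallies)
    ),
    tallies = tallies
  )
}
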