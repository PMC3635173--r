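#' Cohort container for dose reconstruction
#'
#' Bundles the three inputs the reconstruction engine needs: a patient
#' roster, a per-series examination table, and the per-phantom coefficient
#' tables.
#'
#' @param patients tibble: `patient_id`, `sex`, plus whatever the caller
#'   carries (ages, hospital, stature).
#' @param series tibble with one row per series: `patient_id`, `exam_id`,
#'   `region`, `scenario` ("pre_pacs"/"post_pacs"), `group_key`,
#'   `phantom_id`, `kvp`, `exposure_mas`, `pitch`, `collimation_mm`,
#'   `scan_length_mm`, `reported_ctdiw_mgy`, `scanner_class` (missing
#'   technical values as `NA`).
#' @param tables named list of `coefficient_table`s keyed by `phantom_id`.
#' @return object of class `dose_cohort`.
#' @export
dose_cohort <- function(patients, series, tables) {
  patients <- as_tibble(patients)
  series <- as_tibble(series)
  need <- c("patient_id", "region", "group_key", "phantom_id", "kvp",
            "exposure_mas", "pitch", "collimation_mm", "scan_length_mm")
  miss <- setdiff(need, names(series))
  if (length(miss)) {
    stop_validation(paste0("series table lacks columns: ",
                           paste(miss, collapse = ", ")))
  }
  bad <- setdiff(unique(series$phantom_id), names(tables))
  if (length(bad)) {
    stop_config(paste0("no coefficient table for phantom(s): ",
                       paste(bad, collapse = ", ")))
  }
  structure(list(patients = patients, series = series, tables = tables),
            class = "dose_cohort")
}

#' @export
print.dose_cohort <- function(x, ...) {
  cat("<dose_cohort>", nrow(x$patients), "patients,", nrow(x$series),
      "series,", length(x$tables), "coefficient tables\n")
  invisible(x)
}

# per-organ dose for one filled series at 100 mAs and unit systematic factor;
# mode "unit" = per mGy of reported CTDIw, "lookup" = with bundled normalized
# CTDIw built in. Memoized across realizations via `cache`.
series_dose_kernel <- function(table, phantom, region, kvp, pitch,
                               scan_length, collimation, mode, scanner_class,
                               cache) {
  key <- paste(table$phantom_id, region, round(kvp, 3), round(pitch, 4),
               round(scan_length, 1), collimation, mode, scanner_class,
               sep = "~")
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  lm <- locate_region(phantom, region)
  mid <- mean(lm); H <- phantom$height_cm * 10
  z0 <- max(0, mid - scan_length / 2); z1 <- min(H, mid + scan_length / 2)
  rot <- rotation_positions(z0, z1, collimation, pitch)
  cf <- coeff_lookup(table, rot$z, kvp)
  c100 <- if (mode == "unit") {
    rep(1, length(rot$z))
  } else {
    head_end <- locate_region(phantom, "head")[2]
    ch <- nctdiw_fast(kvp, "head", scanner_class)
    cb <- nctdiw_fast(kvp, "body", scanner_class)
    ifelse(rot$z <= head_end, ch, cb)
  }
  out <- colSums(cf * (rot$w * c100))
  cache[[key]] <- out
  out
}

# memoized log-log interpolators over the bundled normalized-CTDIw table
nctdiw_fast <- local({
  funs <- NULL
  function(kvp, ctdi_spec, scanner_class) {
    if (is.null(funs)) {
      tab <- nctdiw_cached()
      f <- list()
      for (cl in unique(tab$scanner_class)) {
        for (sp in unique(tab$ctdi_spec)) {
          t2 <- tab[tab$scanner_class == cl & tab$ctdi_spec == sp, ]
          f[[paste0(cl, ".", sp)]] <- stats::approxfun(
            log(t2$kvp), log(t2$nctdiw_mgy_per_100mas))
        }
      }
      funs <<- f
    }
    fn <- funs[[paste0(scanner_class, ".", ctdi_spec)]]
    if (is.null(fn)) stop_validation("unknown scanner class / CTDI spec")
    v <- fn(log(kvp))
    if (is.na(v)) stop_reconstruction("kVp outside the normalized-CTDIw table")
    exp(v)
  }
})

#' Generate correlated cohort dose realizations
#'
#' The two-dimensional Monte Carlo: for each realization, every missing
#' acquisition parameter is drawn from its registered PDF honouring the
#' sharing scope (group-scope draws are identical for all patients of a
#' protocol group within a realization and vary across realizations), doses
#' are recomputed by the deterministic engine for every patient, and the
#' whole cohort dose vector is stored. With `inner_reps > 1` the realizations
#' are nested: `V / inner_reps` outer draws of the shared (group/cohort)
#' parameters, each combined with `inner_reps` independent draws of the
#' patient-scope parameters -- the structure needed to decompose shared vs
#' unshared dose variance.
#'
#' Everything is reproducible from `master_seed`: each scoped draw uses
#' `derive_seed(master_seed, scope key, parameter, realization index)`, so
#' results do not depend on patient order or evaluation order.
#'
#' @param cohort a [dose_cohort()].
#' @param registry a [build_pdf_registry()] result (or compatible named
#'   list).
#' @param V number of realizations (>= 1).
#' @param master_seed integer master seed.
#' @param inner_reps patient-scope draws per shared draw (must divide `V`).
#' @param organs organ set to tally.
#' @return object of class `realization_set`: `doses` array
#'   (realization x patient x organ, mGy), seeds, group map and metadata.
#' @export
generate_realizations <- function(cohort, registry, V = 200, master_seed = 1,
                                  inner_reps = 1, organs = ORGANS) {
  stopifnot(inherits(cohort, "dose_cohort"))
  if (V < 1) stop_validation("V must be >= 1")
  if (V %% inner_reps != 0) stop_validation("inner_reps must divide V")
  reg <- if (inherits(registry, "pdf_registry")) registry$groups else registry
  patients <- cohort$patients
  series <- cohort$series
  n_pat <- nrow(patients)
  pat_idx <- match(series$patient_id, patients$patient_id)
  phantoms <- lapply(setNames(nm = unique(series$phantom_id)), function(id) {
    parts <- strsplit(id, "_", fixed = TRUE)[[1]]
    build_reference_phantom(parts[1], parts[2])
  })
  param_cols <- c(kvp = "kvp", mas = "exposure_mas", pitch = "pitch",
                  scan_length = "scan_length_mm")
  n_ser <- nrow(series)
  # plain vectors for the hot loop
  sv <- list(
    group = series$group_key, patient = series$patient_id,
    kvp = series$kvp, mas = series$exposure_mas, pitch = series$pitch,
    slen = series$scan_length_mm, coll = series$collimation_mm,
    region = series$region, phantom = series$phantom_id,
    reported = series$reported_ctdiw_mgy,
    class = if ("scanner_class" %in% names(series)) series$scanner_class
            else rep("multi_slice", n_ser)
  )
  sv$class[is.na(sv$class)] <- "multi_slice"
  missing_mask <- vapply(param_cols, function(cl) is.na(series[[cl]]),
                         logical(n_ser))
  if (n_ser == 1) missing_mask <- matrix(missing_mask, nrow = 1,
                                         dimnames = list(NULL, names(param_cols)))
  # per-series missing parameter names, registry consistency checked up front
  need_params <- lapply(seq_len(n_ser), function(i) {
    nm <- names(param_cols)[missing_mask[i, ]]
    pdfs <- reg[[sv$group[i]]]
    if (length(setdiff(nm, names(pdfs)))) {
      stop_reconstruction(paste0(
        "unregistered missing parameter(s) for group ", sv$group[i], ": ",
        paste(setdiff(nm, names(pdfs)), collapse = ", ")),
        patient = sv$patient[i])
    }
    nm
  })
  # split each group's registry by sharing scope
  scope_of <- function(pdfs) vapply(pdfs, function(p) p$scope, character(1))
  groups <- unique(sv$group)
  # a scanner unit is the hospital|period|scanner prefix of the group key
  scanner_unit <- function(g) {
    paste(utils::head(strsplit(g, "|", fixed = TRUE)[[1]], 4), collapse = "|")
  }
  grp_shared <- lapply(setNames(nm = groups), function(g) {
    p <- reg[[g]]
    p[scope_of(p) %in% c("group", "scanner", "cohort")]
  })
  grp_patient <- lapply(setNames(nm = groups), function(g) {
    p <- reg[[g]]
    p[scope_of(p) == "patient"]
  })

  # RNG state is preserved once around the whole run; each draw re-seeds from
  # its scope key, so draws are order-independent
  draw_set <- function(pdfs, scope_keys, ridx) {
    out <- list()
    joint <- list()
    for (nm in names(pdfs)) {
      pdf <- pdfs[[nm]]
      sk <- scope_keys[[pdf$scope]]
      if (!is.null(pdf$linkage) && pdf$family == "discrete_joint") {
        lk <- paste0("link:", pdf$linkage)
        if (is.null(joint[[lk]])) {
          set.seed(derive_seed(master_seed, sk, lk, ridx))
          joint[[lk]] <- ppdf_draw(pdf, 1)
        }
        out[[nm]] <- pdf$params$table[[nm]][joint[[lk]]]
      } else {
        set.seed(derive_seed(master_seed, sk, nm, ridx))
        val <- ppdf_draw(pdf, 1)
        out[[nm]] <- if (pdf$family == "discrete_joint") {
          pdf$params$table[[nm]][val]
        } else val
      }
    }
    out
  }

  kernel_cache <- new.env(parent = emptyenv())
  doses <- array(0, c(V, n_pat, length(organs)),
                 dimnames = list(NULL, patients$patient_id, organs))
  realization_seeds <- integer(V)
  shared_draws <- NULL
  cur_outer <- -1L
  rng_had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (rng_had) rng_old <- get(".Random.seed", envir = globalenv())
  on.exit(if (rng_had) assign(".Random.seed", rng_old, envir = globalenv()))
  for (v in seq_len(V)) {
    r_outer <- ((v - 1) %/% inner_reps) + 1L
    realization_seeds[v] <- derive_seed(master_seed, "realization", v)
    if (r_outer != cur_outer) {
      shared_draws <- lapply(setNames(nm = groups), function(g) {
        draw_set(grp_shared[[g]],
                 list(group = g, scanner = scanner_unit(g),
                      cohort = "cohort"), r_outer)
      })
      cur_outer <- r_outer
    }
    patient_draw_cache <- new.env(parent = emptyenv())
    dm <- matrix(0, n_pat, length(organs))
    for (i in seq_len(n_ser)) {
      g <- sv$group[i]
      fill <- shared_draws[[g]]
      pp <- grp_patient[[g]]
      if (length(pp)) {
        pkey <- paste0(sv$patient[i], "\r", g)
        pd <- patient_draw_cache[[pkey]]
        if (is.null(pd)) {
          pd <- draw_set(pp, list(patient = paste0("pt:", sv$patient[i])), v)
          patient_draw_cache[[pkey]] <- pd
        }
        fill <- c(fill, pd)
      }
      need <- need_params[[i]]
      mult <- 1
      if (is.na(sv$reported[i]) && !is.null(fill$nctdiw_factor)) {
        mult <- mult * fill$nctdiw_factor
      }
      if (!is.null(fill$modulation_factor)) mult <- mult * fill$modulation_factor
      kvp <- if ("kvp" %in% need) fill$kvp else sv$kvp[i]
      mas <- if ("mas" %in% need) fill$mas else sv$mas[i]
      pitch <- if ("pitch" %in% need) fill$pitch else sv$pitch[i]
      slen <- if ("scan_length" %in% need) round(fill$scan_length) else sv$slen[i]
      mode <- if (!is.na(sv$reported[i])) "unit" else "lookup"
      base <- series_dose_kernel(cohort$tables[[sv$phantom[i]]],
                                 phantoms[[sv$phantom[i]]], sv$region[i],
                                 kvp, pitch, slen, sv$coll[i],
                                 mode, sv$class[i], kernel_cache)
      scale <- if (mode == "unit") sv$reported[i] * mas / 100 * mult
               else mas / 100 * mult
      dm[pat_idx[i], ] <- dm[pat_idx[i], ] + base[organs] * scale
    }
    doses[v, , ] <- dm
  }
  group_map <- series %>%
    group_by(.data$patient_id) %>%
    summarise(group_key = first(.data$group_key), .groups = "drop")
  structure(list(
    doses = doses, V = V, inner_reps = inner_reps,
    outer = V %/% inner_reps,
    master_seed = master_seed, realization_seeds = realization_seeds,
    patients = patients, organs = organs, group_map = group_map,
    registry_version = if (inherits(registry, "pdf_registry")) registry$version else NA_character_,
    version = .ctdosim_version()
  ), class = "realization_set")
}

#' @export
print.realization_set <- function(x, ...) {
  cat("<realization_set>", x$V, "realizations x", nrow(x$patients),
      "patients x", length(x$organs), "organs\n")
  if (x$inner_reps > 1) {
    cat("  nested:", x$outer, "shared draws x", x$inner_reps, "patient draws\n")
  }
  cat("  master seed:", x$master_seed, "\n")
  invisible(x)
}

#' @method as_tibble realization_set
#' @export
as_tibble.realization_set <- function(x, ...) {
  grid <- expand.grid(v = seq_len(x$V),
                      ip = seq_len(nrow(x$patients)),
                      io = seq_along(x$organs))
  tibble(realization = grid$v,
         patient_id = x$patients$patient_id[grid$ip],
         organ = x$organs[grid$io],
         dose_mgy = x$doses[cbind(grid$v, grid$ip, grid$io)])
}

#' Persist / load a realization set
#'
#' Plain-text store: `meta.json` (V, nesting, seeds, organs, patient order,
#' PDF registry version, software version) plus `doses.csv` in long format.
#'
#' @param set a `realization_set`.
#' @param dir directory to create/overwrite.
#' @return `dir` (save) / a `realization_set` (load).
#' @export
save_realization_set <- function(set, dir) {
  stopifnot(inherits(set, "realization_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(V = set$V, inner_reps = set$inner_reps, outer = set$outer,
               master_seed = set$master_seed,
               realization_seeds = set$realization_seeds,
               organs = set$organs, patients = set$patients,
               group_map = set$group_map,
               registry_version = set$registry_version, version = set$version)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), digits = NA,
                       auto_unbox = TRUE, na = "null")
  write.csv(as_tibble(set), file.path(dir, "doses.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname save_realization_set
#' @export
load_realization_set <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  df <- read.csv(file.path(dir, "doses.csv"), stringsAsFactors = FALSE)
  patients <- as_tibble(meta$patients)
  organs <- meta$organs
  doses <- array(NA_real_, c(meta$V, nrow(patients), length(organs)),
                 dimnames = list(NULL, patients$patient_id, organs))
  doses[cbind(df$realization,
              match(df$patient_id, patients$patient_id),
              match(df$organ, organs))] <- df$dose_mgy
  structure(list(
    doses = doses, V = meta$V, inner_reps = meta$inner_reps,
    outer = meta$outer, master_seed = meta$master_seed,
    realization_seeds = meta$realization_seeds,
    patients = patients, organs = organs,
    group_map = as_tibble(meta$group_map),
    registry_version = meta$registry_version, version = meta$version
  ), class = "realization_set")
}

#' Summarize a realization set
#'
#' Per-patient, per-organ summaries across realizations (mean, median, 2.5
#' and 97.5 percentiles) plus -- when the set was generated with nested inner
#' replication -- a decomposition of the dose variance into shared
#' (between-group-draw) and unshared (within) components by the law of total
#' variance conditioning on the group-level draws. Population (1/n) variances
#' are used so shared + unshared equals the total exactly.
#'
#' @param set a `realization_set`.
#' @param dispersion whether dispersion summaries are required (errors for
#'   `V = 1`).
#' @return tibble with one row per (patient, organ).
#' @export
summarize_realizations <- function(set, dispersion = TRUE) {
  stopifnot(inherits(set, "realization_set"))
  if (dispersion && set$V < 2) {
    stop_validation("dispersion summaries require V >= 2")
  }
  varp <- function(x) mean((x - mean(x))^2)
  grid <- expand.grid(ip = seq_len(nrow(set$patients)),
                      io = seq_along(set$organs))
  res <- purrr::map_dfr(seq_len(nrow(grid)), function(k) {
    d <- set$doses[, grid$ip[k], grid$io[k]]
    out <- tibble(
      patient_id = set$patients$patient_id[grid$ip[k]],
      organ = set$organs[grid$io[k]],
      mean_mgy = mean(d),
      median_mgy = median(d),
      q025_mgy = if (set$V >= 2) unname(quantile(d, 0.025)) else NA_real_,
      q975_mgy = if (set$V >= 2) unname(quantile(d, 0.975)) else NA_real_,
      var_total = if (set$V >= 2) varp(d) else NA_real_
    )
    if (set$inner_reps >= 2) {
      m <- matrix(d, nrow = set$inner_reps)  # [inner x outer]
      inner_means <- colMeans(m)
      out$var_shared <- varp(inner_means)
      out$var_unshared <- mean(apply(m, 2, varp))
    } else {
      out$var_shared <- NA_real_
      out$var_unshared <- NA_real_
    }
    out
  })
  if (set$inner_reps < 2 && dispersion) {
    message("no nested inner replication: shared/unshared decomposition unavailable")
  }
  res
}
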