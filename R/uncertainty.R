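#' Missing-parameter probability density functions
#'
#' A `parameter_pdf` represents the state of knowledge about one missing
#' acquisition parameter: a distribution family with parameters, optional
#' truncation bounds, and -- crucially -- a sharing scope. `scope = "group"`
#' parameters are drawn once per (protocol group, realization) and shared by
#' every patient of the group, encoding dose errors that are correlated
#' across patients (e.g. an unknown hospital protocol); `scope = "patient"`
#' parameters are drawn independently per patient; `scope = "cohort"` once
#' per realization for everyone. Parameters carrying the same `linkage` id
#' must belong to one `discrete_joint` table and are drawn as a single joint
#' row, never as independent marginals. The `scanner` scope sits between
#' cohort and group: one draw per hospital/period/scanner unit, shared
#' across that scanner's exam-type and age-group protocol cells -- the
#' natural scope for a scanner calibration quantity.
#'
#' @param parameter parameter name (e.g. "kvp", "mas", "pitch",
#'   "scan_length", "nctdiw_factor", "modulation_factor",
#'   "stature_deviation").
#' @param family one of "point", "uniform", "triangular", "lognormal",
#'   "discrete_joint".
#' @param params family parameters: point: `value`; uniform: `min`, `max`;
#'   triangular: `min`, `mode`, `max`; lognormal: `median`, `gsd`;
#'   discrete_joint: `table` (data frame of joint rows incl. optional
#'   `weight`).
#' @param trunc optional `c(lo, hi)` truncation bounds.
#' @param scope "cohort", "scanner", "group" or "patient".
#' @param linkage optional linkage id for jointly drawn tuples.
#' @param tier provenance tier ("elicited", "sparse", "era_default").
#' @return object of class `parameter_pdf`.
#' @export
parameter_pdf <- function(parameter, family, params, trunc = NULL,
                          scope = "group", linkage = NULL,
                          tier = "elicited") {
  assert_choice(family, c("point", "uniform", "triangular", "lognormal",
                          "discrete_joint"), "pdf family")
  assert_choice(scope, c("cohort", "scanner", "group", "patient"), "sharing scope")
  ok <- switch(family,
    point = is_scalar_number(params$value),
    uniform = is_scalar_number(params$min) && is_scalar_number(params$max) &&
      params$min <= params$max,
    triangular = is_scalar_number(params$min) && is_scalar_number(params$mode) &&
      is_scalar_number(params$max) && params$min <= params$mode &&
      params$mode <= params$max,
    lognormal = is_scalar_number(params$median) && params$median > 0 &&
      is_scalar_number(params$gsd) && params$gsd >= 1,
    discrete_joint = is.data.frame(params$table) && nrow(params$table) >= 1
  )
  if (!isTRUE(ok)) stop_validation(paste0("invalid ", family, " parameters"))
  if (!is.null(trunc)) {
    if (length(trunc) != 2 || trunc[1] > trunc[2]) {
      stop_validation("truncation bounds must be ordered c(lo, hi)")
    }
  }
  structure(list(parameter = parameter, family = family, params = params,
                 trunc = trunc, scope = scope, linkage = linkage, tier = tier),
            class = "parameter_pdf")
}

#' @export
print.parameter_pdf <- function(x, ...) {
  cat("<parameter_pdf>", x$parameter, "~", x$family,
      "| scope:", x$scope, "| tier:", x$tier, "\n")
  invisible(x)
}

# quantile-based single draw using the current RNG state; discrete_joint
# returns a row index
ppdf_draw <- function(pdf, n = 1) {
  p <- pdf$params
  x <- switch(pdf$family,
    point = rep(p$value, n),
    uniform = runif(n, p$min, p$max),
    triangular = {
      u <- runif(n)
      fc <- (p$mode - p$min) / (p$max - p$min)
      ifelse(u < fc,
             p$min + sqrt(u * (p$max - p$min) * (p$mode - p$min)),
             p$max - sqrt((1 - u) * (p$max - p$min) * (p$max - p$mode)))
    },
    lognormal = {
      mu <- log(p$median); sig <- log(p$gsd)
      if (sig <= 0) rep(p$median, n) else {
        lo <- if (is.null(pdf$trunc)) 0 else pdf$trunc[1]
        hi <- if (is.null(pdf$trunc)) Inf else pdf$trunc[2]
        plo <- stats::plnorm(lo, mu, sig); phi <- stats::plnorm(hi, mu, sig)
        stats::qlnorm(runif(n, plo, phi), mu, sig)
      }
    },
    discrete_joint = {
      w <- p$table[["weight"]] %||% rep(1, nrow(p$table))
      sample.int(nrow(p$table), n, replace = TRUE, prob = w)
    }
  )
  if (!is.null(pdf$trunc) && pdf$family %in% c("uniform", "triangular")) {
    x <- pmin(pmax(x, pdf$trunc[1]), pdf$trunc[2])
  }
  x
}

era_defaults_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- yaml::read_yaml(extdata_path("era_defaults.yaml"))
    cache
  }
})

# era-default registry entry -> parameter_pdf (NULL when absent)
era_default_pdf <- function(parameter, era, exam_type = NULL) {
  reg <- era_defaults_cached()$eras[[era]]
  key <- parameter
  if (parameter == "scan_length" && !is.null(exam_type)) {
    key <- paste0("scan_length_", exam_type)
  }
  e <- reg[[key]]
  if (is.null(e)) return(NULL)
  parameter_pdf(parameter, e$family, e$params,
                trunc = if (!is.null(e$trunc)) unlist(e$trunc),
                scope = e$scope %||% "group", tier = "era_default")
}

# 95% width helper used to enforce that recent-era PDFs are not wider than
# earlier-era defaults
.pdf_width <- function(pdf) {
  p <- pdf$params
  switch(pdf$family,
    point = 0,
    uniform = 0.95 * (p$max - p$min),
    triangular = (p$max - p$min) * (1 - 0.05),
    lognormal = {
      mu <- log(p$median); sig <- log(p$gsd)
      stats::qlnorm(0.975, mu, sig) - stats::qlnorm(0.025, mu, sig)
    },
    discrete_joint = NA_real_
  )
}

#' Derive a missing-parameter PDF from observed protocol values
#'
#' Encodes the elicitation ladder: three or more observed values give a
#' lognormal with the geometric median and geometric standard deviation,
#' truncated to the era bounds; one or two values give a triangular with mode
#' at their mean and era-default bounds; none falls back to the bundled
#' era-default PDF (lowest-confidence tier). Recent-era results are never
#' wider than the earlier-era default for the same parameter: the truncation
#' range is intersected with the earlier era's bounds when needed.
#'
#' @param parameter parameter name.
#' @param values numeric vector of observed values from similar protocol
#'   groups (may be empty).
#' @param era "pre_pacs" or "post_pacs".
#' @param exam_type used to pick scan-length defaults.
#' @param scope sharing scope of the result.
#' @return a `parameter_pdf`.
#' @export
elicit_pdf <- function(parameter, values = numeric(), era = "pre_pacs",
                       exam_type = NULL, scope = NULL) {
  values <- values[is.finite(values)]
  default <- era_default_pdf(parameter, era, exam_type)
  scope <- scope %||% (if (!is.null(default)) default$scope else "group")
  bounds <- if (!is.null(default)) {
    default$trunc %||% switch(default$family,
      uniform = c(default$params$min, default$params$max),
      triangular = c(default$params$min, default$params$max),
      point = rep(default$params$value, 2),
      NULL)
  }
  # recent-era widths are capped by the earlier era's default bounds
  if (era == "post_pacs") {
    early <- era_default_pdf(parameter, "pre_pacs", exam_type)
    if (!is.null(early)) {
      eb <- early$trunc %||% switch(early$family,
        uniform = c(early$params$min, early$params$max),
        triangular = c(early$params$min, early$params$max),
        NULL)
      if (!is.null(eb) && !is.null(bounds)) {
        bounds <- c(max(bounds[1], eb[1]), min(bounds[2], eb[2]))
      }
    }
  }
  n <- length(values)
  if (n >= 3) {
    gm <- exp(mean(log(values)))
    gsd <- exp(sd(log(values)))
    if (gsd <= 1 + 1e-9) {
      return(parameter_pdf(parameter, "point", list(value = gm),
                           scope = scope, tier = "elicited"))
    }
    tr <- bounds %||% range(values)
    parameter_pdf(parameter, "lognormal", list(median = gm, gsd = gsd),
                  trunc = tr, scope = scope, tier = "elicited")
  } else if (n >= 1) {
    if (is.null(bounds)) bounds <- mean(values) * c(0.75, 1.25)
    m <- min(max(mean(values), bounds[1]), bounds[2])
    parameter_pdf(parameter, "triangular",
                  list(min = bounds[1], mode = m, max = bounds[2]),
                  scope = scope, tier = "sparse")
  } else {
    if (is.null(default)) {
      stop_elicitation(paste0("no observations and no era default for ",
                              parameter, " (", era, ")"))
    }
    default
  }
}

#' Sample missing parameters for one (patient, realization)
#'
#' Draws every registered PDF honouring its sharing scope: group-scope
#' parameters use a seed keyed by (group, parameter, realization), so all
#' patients of a group receive identical values within a realization;
#' patient-scope parameters are keyed by the patient id. Parameters sharing a
#' linkage id are drawn as one joint row of their `discrete_joint` table.
#' Recorded (non-missing) values are not touched by this function -- callers
#' only request PDFs for parameters that are actually missing.
#'
#' @param pdfs named list of `parameter_pdf` objects (names = parameter
#'   names).
#' @param group_key protocol group key of the exam.
#' @param patient_id patient identifier.
#' @param realization realization index (use the outer index for group/cohort
#'   scopes when running nested two-dimensional sampling).
#' @param master_seed integer master seed.
#' @param patient_realization optional separate index for patient-scope draws
#'   (defaults to `realization`).
#' @return named list of sampled values.
#' @export
sample_parameters <- function(pdfs, group_key, patient_id, realization,
                              master_seed, patient_realization = realization) {
  out <- list()
  joint_rows <- list()
  for (nm in names(pdfs)) {
    pdf <- pdfs[[nm]]
    if (!inherits(pdf, "parameter_pdf")) {
      stop_reconstruction(paste0("unregistered missing parameter: ", nm))
    }
    scope_key <- switch(pdf$scope, cohort = "cohort", group = group_key,
                        patient = paste0("pt:", patient_id))
    ridx <- if (pdf$scope == "patient") patient_realization else realization
    if (!is.null(pdf$linkage) && pdf$family == "discrete_joint") {
      lk <- paste0("link:", pdf$linkage)
      if (is.null(joint_rows[[lk]])) {
        seed <- derive_seed(master_seed, scope_key, lk, ridx)
        joint_rows[[lk]] <- with_seed(seed, ppdf_draw(pdf, 1))
      }
      row <- pdf$params$table[joint_rows[[lk]], ]
      out[[nm]] <- row[[nm]]
    } else {
      seed <- derive_seed(master_seed, scope_key, nm, ridx)
      val <- with_seed(seed, ppdf_draw(pdf, 1))
      if (pdf$family == "discrete_joint") {
        out[[nm]] <- pdf$params$table[[nm]][val]
      } else {
        out[[nm]] <- val
      }
    }
  }
  out
}

#' Build a PDF registry for a masked cohort
#'
#' For every protocol group and every dose-relevant parameter, elicits a PDF
#' from the observed values in the group's protocol rows (Scenario 1) or from
#' the pooled recorded values of similar groups, falling back to era
#' defaults. Systematic factors (normalized-CTDIw spread, unknown tube
#' current modulation) are taken from the era-default registry.
#'
#' @param series series tibble (see [generate_realizations()]).
#' @param protocols optional protocol table for [lookup_protocol()].
#' @return named list: per group key, a named list of `parameter_pdf`s.
#' @export
build_pdf_registry <- function(series, protocols = NULL) {
  params <- c("kvp", "mas", "pitch", "scan_length")
  col_of <- c(kvp = "kvp", mas = "exposure_mas", pitch = "pitch",
              scan_length = "scan_length_mm")
  groups <- unique(series$group_key)
  reg <- list()
  for (g in groups) {
    rows <- series[series$group_key == g, ]
    era <- rows$scenario[1] %||% "pre_pacs"
    exam_type <- rows$region[1]
    proto <- if (!is.null(protocols)) lookup_protocol(g, protocols) else NULL
    pdfs <- list()
    for (p in params) {
      if (!any(is.na(rows[[col_of[p]]]))) next  # nothing missing
      obs <- if (!is.null(proto) && nrow(proto) > 0) {
        pc <- c(kvp = "kvp", mas = "mas", pitch = "pitch",
                scan_length = "scan_length_mm")[p]
        if (pc %in% names(proto)) proto[[pc]] else numeric()
      } else {
        # pool recorded values for the same exam type and era
        sim <- series[series$region == exam_type & series$scenario == era, ]
        stats::na.omit(sim[[col_of[p]]])
      }
      pdfs[[p]] <- elicit_pdf(p, obs, era = era, exam_type = exam_type)
    }
    # systematic factors from the era registry
    if (any(is.na(rows$reported_ctdiw_mgy))) {
      f <- era_default_pdf("nctdiw_factor", era)
      if (!is.null(f)) pdfs[["nctdiw_factor"]] <- f
    }
    if (era == "post_pacs") {
      f <- era_default_pdf("modulation_factor", era)
      if (!is.null(f)) pdfs[["modulation_factor"]] <- f
    }
    reg[[g]] <- pdfs
  }
  structure(list(groups = reg, version = .ctdosim_version()),
            class = "pdf_registry")
}

#' @export
print.pdf_registry <- function(x, ...) {
  cat("<pdf_registry>", length(x$groups), "groups\n")
  invisible(x)
}
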