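# ggplot2 views of the main result types

#' Plot organ dose coefficient profiles
#'
#' Coefficient (organ dose per rotation per mGy CTDIw) against axial
#' position, one line per tube voltage.
#'
#' @param table a `coefficient_table`.
#' @param organs organs to show.
#' @return a ggplot.
#' @export
plot_coefficient_profile <- function(table, organs = c("brain",
                                                       "red_bone_marrow",
                                                       "colon")) {
  df <- as_tibble(table) %>% filter(.data$organ %in% organs)
  ggplot(df, aes(x = .data$z_mm, y = .data$coeff,
                 colour = factor(.data$kvp))) +
    geom_line() +
    facet_wrap(~organ, scales = "free_y") +
    labs(x = "axial position z (mm, crown origin)",
         y = "organ dose per rotation / CTDIw",
         colour = "kVp",
         title = paste("Dose coefficients:", table$phantom_id)) +
    theme_minimal()
}

#' @rdname autoplot_ctdosim
#' @param organ organ to display.
#' @param n_patients number of patients shown (ordered as in the set).
#' @export
autoplot.realization_set <- function(object, organ = "red_bone_marrow",
                                     n_patients = 30, ...) {
  sm <- summarize_realizations(object, dispersion = object$V >= 2) %>%
    filter(.data$organ == .env$organ) %>%
    head(n_patients) %>%
    mutate(patient = factor(.data$patient_id, levels = .data$patient_id))
  ggplot(sm, aes(x = .data$patient, y = .data$mean_mgy)) +
    geom_point() +
    geom_errorbar(aes(ymin = .data$q025_mgy, ymax = .data$q975_mgy),
                  width = 0.2) +
    labs(x = NULL, y = paste(organ, "dose (mGy)"),
         title = paste0("Cumulative dose across ", object$V,
                        " realizations")) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}

#' Autoplot methods for dose and risk results
#'
#' `realization_set`: per-patient mean and 95% realization interval;
#' `err_fit`: profile likelihood with the 95% cutoff; `err_fit_combined`:
#' per-realization estimates (weight-shaded) with the combined interval.
#'
#' @param object the result object.
#' @param ... unused.
#' @name autoplot_ctdosim
#' @export
autoplot.err_fit <- function(object, ...) {
  if (is.null(object$profile) || !isTRUE(object$converged)) {
    stop_validation("no profile available for this fit")
  }
  lo <- if (is.finite(object$ci[1])) object$ci[1] else object$beta - 1
  hi <- if (is.finite(object$ci[2])) object$ci[2] else object$beta + 1
  grid <- seq(lo - 0.2 * (hi - lo), hi + 0.2 * (hi - lo), length.out = 200)
  df <- tibble(beta = grid,
               loglik = vapply(grid, object$profile, numeric(1)))
  ggplot(df, aes(x = .data$beta, y = .data$loglik)) +
    geom_line() +
    ggplot2::geom_vline(xintercept = object$beta, linetype = 2) +
    ggplot2::geom_hline(yintercept = object$loglik - qchisq(0.95, 1) / 2,
                        linetype = 3) +
    labs(x = "excess relative risk per Gy",
         y = "profile log-likelihood") +
    theme_minimal()
}

#' @rdname autoplot_ctdosim
#' @export
autoplot.err_fit_combined <- function(object, ...) {
  ggplot(object$fits, aes(x = .data$beta, weight = .data$weight)) +
    geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$combined$beta, linetype = 2) +
    ggplot2::geom_vline(xintercept = object$combined$ci, linetype = 3) +
    labs(x = "per-realization ERR per Gy (likelihood-weighted)",
         y = "weighted count",
         title = "All-realizations dose-response") +
    theme_minimal()
}
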