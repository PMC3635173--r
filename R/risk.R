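#' Fit an excess-relative-risk dose-response model
#'
#' Poisson disease model with rate `lambda = lambda0(stratum) * (1 + beta *
#' D)` where `D` is organ dose in Gy. Stratum baselines are profiled out
#' analytically, leaving a one-dimensional profile likelihood in `beta`
#' maximized subject to `beta > -1/max(D)`; the 95% confidence interval is
#' the profile-likelihood interval at the chi-square(1) cutoff. Degenerate
#' data (no dose contrast, no cases) yield flagged fits, not exceptions.
#'
#' @param data data frame with one row per person (or cell): dose, cases and
#'   person-years columns plus any stratum columns.
#' @param dose_gy name of the dose column (Gy). Doses in mGy must be
#'   converted by the caller; [mgy_to_gy()] is provided for that.
#' @param cases,pyr names of the case-count and person-years columns.
#' @param strata character vector of stratum column names (may be empty for
#'   a single baseline).
#' @return object of class `err_fit`: `beta` (ERR per Gy), `ci`, `loglik`,
#'   `converged`, `flag`, and the profile-likelihood function.
#' @export
fit_err <- function(data, dose_gy = "dose_gy", cases = "cases", pyr = "pyr",
                    strata = c("sex", "age_band")) {
  data <- as_tibble(data)
  D <- data[[dose_gy]]
  d <- data[[cases]]
  py <- data[[pyr]]
  if (any(is.na(D)) || any(D < 0)) stop_validation("doses must be >= 0")
  if (any(py <= 0)) stop_validation("person-years must be > 0")
  if (any(d < 0)) stop_validation("case counts must be >= 0")
  stratum <- if (length(strata)) {
    interaction(data[strata], drop = TRUE)
  } else {
    factor(rep(1, nrow(data)))
  }
  # drop strata with no cases: their profiled baseline is zero and they
  # contribute nothing to the profile likelihood
  n_s <- tapply(d, stratum, sum)
  keep_strata <- names(n_s)[n_s > 0]
  keep <- stratum %in% keep_strata
  dropped <- sum(!keep)
  D0 <- D; d0 <- d
  D <- D[keep]; d <- d[keep]; py <- py[keep]
  stratum <- droplevels(stratum[keep])

  if (sum(d) == 0) {
    lb <- if (max(D0) > 0) -1 / max(D0) else -Inf
    return(new_err_fit(beta = lb, ci = c(NA_real_, NA_real_),
                       loglik = 0, converged = FALSE,
                       flag = "no cases: slope at lower boundary",
                       n = length(D0), n_cases = 0))
  }
  if (max(D0) - min(D0) < 1e-12) {
    return(new_err_fit(beta = NA_real_, ci = c(NA_real_, NA_real_),
                       loglik = NA_real_, converged = FALSE,
                       flag = "degenerate: no dose contrast",
                       n = length(D0), n_cases = sum(d0)))
  }

  sidx <- as.integer(stratum)
  n_str <- tapply(d, sidx, sum)
  prof <- function(beta) {
    rr <- 1 + beta * D
    if (any(rr <= 0)) return(-Inf)
    T_s <- tapply(py * rr, sidx, sum)
    sum(d * log(rr)) + sum(n_str * (log(n_str / T_s))) - sum(n_str)
  }
  lb <- -1 / max(D) + 1e-9
  ub <- 1e4
  opt <- optimize(prof, c(lb, ub), maximum = TRUE, tol = 1e-9)
  beta_hat <- opt$maximum
  ll <- opt$objective
  # boundary diagnostics
  at_upper <- (ub - beta_hat) < 1e-3 * (ub - lb)
  cut <- ll - qchisq(0.95, 1) / 2
  ci_lo <- tryCatch({
    if (prof(lb) < cut) {
      uniroot(function(b) prof(b) - cut, c(lb, beta_hat), tol = 1e-8)$root
    } else lb
  }, error = function(e) NA_real_)
  ci_hi <- tryCatch({
    if (prof(ub) < cut) {
      uniroot(function(b) prof(b) - cut, c(beta_hat, ub), tol = 1e-8)$root
    } else Inf
  }, error = function(e) NA_real_)
  new_err_fit(beta = beta_hat, ci = c(ci_lo, ci_hi), loglik = ll,
              converged = !at_upper,
              flag = if (at_upper) "estimate at search boundary" else NA_character_,
              n = length(D0), n_cases = sum(d),
              profile = prof, dropped_strata = dropped)
}

new_err_fit <- function(beta, ci, loglik, converged, flag, n, n_cases,
                        profile = NULL, dropped_strata = 0,
                        realization = "single") {
  structure(list(beta = beta, ci = ci, loglik = loglik, converged = converged,
                 flag = flag, n = n, n_cases = n_cases, profile = profile,
                 dropped_strata = dropped_strata, realization = realization),
            class = "err_fit")
}

#' @export
print.err_fit <- function(x, ...) {
  cat("<err_fit> ERR/Gy =", signif(x$beta, 4),
      " 95% CI [", signif(x$ci[1], 4), ",", signif(x$ci[2], 4), "]\n")
  cat("  log-likelihood:", signif(x$loglik, 6), " cases:", x$n_cases,
      " n:", x$n, "\n")
  if (!is.na(x$flag %||% NA)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' @method tidy err_fit
#' @export
tidy.err_fit <- function(x, ...) {
  tibble(term = "err_per_gy", estimate = x$beta,
         conf.low = x$ci[1], conf.high = x$ci[2])
}

#' @method glance err_fit
#' @export
glance.err_fit <- function(x, ...) {
  tibble(logLik = x$loglik, converged = x$converged, nobs = x$n,
         n_cases = x$n_cases, flag = x$flag %||% NA_character_)
}

#' Convert mGy to Gy
#'
#' Explicit dose unit conversion at the risk-module boundary.
#'
#' @param dose_mgy dose in mGy.
#' @return dose in Gy.
#' @export
mgy_to_gy <- function(dose_mgy) dose_mgy / 1000

# extract the per-patient dose matrix [V x n] in Gy for one organ
.realization_dose_gy <- function(set, organ) {
  io <- match(organ, set$organs)
  if (is.na(io)) stop_validation(paste0("organ not in realization set: ", organ))
  mgy_to_gy(set$doses[, , io, drop = FALSE][, , 1])
}

#' Mean-dose risk analysis over realizations
#'
#' The simple strategy: average each patient's dose over all realizations,
#' then fit the excess-relative-risk model once to the mean doses.
#'
#' @param set a `realization_set`.
#' @param outcomes tibble keyed by `patient_id` with cases, person-years and
#'   stratum columns.
#' @param organ organ whose dose drives the model.
#' @inheritParams fit_err
#' @return an `err_fit` (realization label `"mean_dose"`).
#' @export
fit_mean_dose <- function(set, outcomes, organ = "red_bone_marrow",
                          cases = "cases", pyr = "pyr",
                          strata = c("sex", "age_band")) {
  stopifnot(inherits(set, "realization_set"))
  dmat <- .realization_dose_gy(set, organ)
  if (set$V == 1) dmat <- matrix(dmat, nrow = 1)
  dose <- colMeans(dmat)
  df <- tibble(patient_id = set$patients$patient_id, dose_gy = dose) %>%
    left_join(as_tibble(outcomes), by = "patient_id")
  fit <- fit_err(df, "dose_gy", cases, pyr, strata)
  fit$realization <- "mean_dose"
  fit
}

#' All-realizations risk analysis
#'
#' Fits the excess-relative-risk model to every realization separately, then
#' combines: the point estimate is the likelihood-weighted mean of the
#' per-realization estimates (weights proportional to `exp(l_v - max l)`),
#' and the combined interval is the 2.5/97.5 percentile of the
#' likelihood-weighted mixture of per-realization profile-likelihood
#' distributions, so that between-realization (shared) dose uncertainty
#' widens the interval. Non-converged realizations are excluded and counted.
#'
#' @inheritParams fit_mean_dose
#' @param grid_size evaluation grid for the mixture interval.
#' @return list of class `err_fit_combined`: `combined` (an `err_fit`),
#'   `fits` (per-realization tibble), `weights`, `n_excluded`.
#' @export
fit_all_realizations <- function(set, outcomes, organ = "red_bone_marrow",
                                 cases = "cases", pyr = "pyr",
                                 strata = c("sex", "age_band"),
                                 grid_size = 400) {
  stopifnot(inherits(set, "realization_set"))
  if (set$V < 2) stop_validation("all-realizations analysis requires V >= 2")
  dmat <- .realization_dose_gy(set, organ)
  out <- as_tibble(outcomes)
  fits <- vector("list", set$V)
  for (v in seq_len(set$V)) {
    df <- tibble(patient_id = set$patients$patient_id, dose_gy = dmat[v, ]) %>%
      left_join(out, by = "patient_id")
    f <- fit_err(df, "dose_gy", cases, pyr, strata)
    f$realization <- v
    fits[[v]] <- f
  }
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  n_excluded <- sum(!ok)
  if (!any(ok)) stop_reconstruction("no realization fit converged")
  fl <- fits[ok]
  ll <- vapply(fl, function(f) f$loglik, numeric(1))
  w <- exp(ll - max(ll))
  w <- w / sum(w)
  betas <- vapply(fl, function(f) f$beta, numeric(1))
  beta_comb <- sum(w * betas)
  # weighted mixture of normalized profile-likelihood densities on a shared grid
  lo <- min(vapply(fl, function(f) if (is.finite(f$ci[1])) f$ci[1] else f$beta, numeric(1)))
  hi <- max(vapply(fl, function(f) if (is.finite(f$ci[2])) f$ci[2] else f$beta, numeric(1)))
  span <- hi - lo
  grid <- seq(lo - 0.25 * span, hi + 0.25 * span, length.out = grid_size)
  mix <- rep(0, grid_size)
  for (k in seq_along(fl)) {
    lp <- vapply(grid, fl[[k]]$profile, numeric(1))
    dens <- exp(lp - max(lp))
    area <- sum((dens[-1] + dens[-grid_size]) / 2 * diff(grid))
    mix <- mix + w[k] * dens / area
  }
  cdf <- cumsum(c(0, (mix[-1] + mix[-grid_size]) / 2 * diff(grid)))
  cdf <- cdf / cdf[grid_size]
  ci <- c(approx(cdf, grid, xout = 0.025, ties = "ordered")$y,
          approx(cdf, grid, xout = 0.975, ties = "ordered")$y)
  combined <- new_err_fit(beta = beta_comb, ci = ci,
                          loglik = sum(w * ll), converged = TRUE,
                          flag = if (n_excluded) paste(n_excluded, "realizations excluded") else NA_character_,
                          n = fl[[1]]$n, n_cases = fl[[1]]$n_cases,
                          realization = "combined")
  structure(list(
    combined = combined,
    fits = tibble(realization = which(ok),
                  beta = betas,
                  loglik = ll,
                  weight = w,
                  ci_lo = vapply(fl, function(f) f$ci[1], numeric(1)),
                  ci_hi = vapply(fl, function(f) f$ci[2], numeric(1))),
    weights = w, n_excluded = n_excluded
  ), class = "err_fit_combined")
}

#' @export
print.err_fit_combined <- function(x, ...) {
  cat("<err_fit_combined> over", nrow(x$fits), "realizations",
      if (x$n_excluded) paste0("(", x$n_excluded, " excluded)") else "", "\n")
  print(x$combined)
  invisible(x)
}

#' @method tidy err_fit_combined
#' @export
tidy.err_fit_combined <- function(x, ...) tidy(x$combined)

#' @method glance err_fit_combined
#' @export
glance.err_fit_combined <- function(x, ...) {
  g <- glance(x$combined)
  g$n_realizations <- nrow(x$fits)
  g$n_excluded <- x$n_excluded
  g
}
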