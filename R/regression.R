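#' Filter (sigmaPSII, Y(NPQ)) points of one light curve
#'
#' Implements the point-retention rules used before pooling curves for the
#' sigmaPSII-vs-Y(NPQ) regression, designed to discern antenna-based qE
#' from slow qI-type quenching that does not act on sigmaPSII:
#'
#' * points with negative Y(NPQ) are removed (`negative_ynpq`);
#' * points above an irradiance cutoff (default 600 umol photons m^-2
#'   s^-1) are removed (`high_irradiance`);
#' * for each point after the first, if Y(NPQ) increased relative to the
#'   previous measured step but sigmaPSII dropped by less than
#'   `drop_fraction` (default 5%) of the total measured decrease of that
#'   curve (max sigma - min sigma), the point is removed
#'   (`small_sigma_drop`).
#'
#' Reasons are assigned in that order; the first matching rule wins. The
#' drop rule always compares against the previous *measured* step in the
#' original ordering, whether or not that step was itself retained, and
#' the first step is never tested by it. If the curve shows no net sigma
#' decrease the drop threshold degenerates to 0 (any non-decrease while
#' Y(NPQ) rises is omitted) and the result is flagged via the
#' `degenerate_total_decrease` attribute.
#'
#' @param points data.frame for ONE strain x replicate x acclimation
#'   curve, ordered by `step_index`, with columns `step_index`, `E`,
#'   `sigma`, `y_npq` (extra columns pass through).
#' @param drop_fraction Fraction of the total per-curve sigma decrease
#'   below which a step-to-step drop counts as "no further
#'   downregulation". Default 0.05.
#' @param e_max Irradiance cutoff, umol photons m^-2 s^-1. Default 600.
#' @return The input with logical `retained` and character `omit_reason`
#'   (one of none, negative_ynpq, high_irradiance, small_sigma_drop).
#' @examples
#' pts <- data.frame(step_index = 1:6,
#'                   E = c(50, 100, 200, 350, 500, 700),
#'                   sigma = c(500, 490, 450, 420, 415, 414),
#'                   y_npq = c(0, 0.05, 0.2, 0.35, 0.45, 0.5))
#' filter_points(pts)$omit_reason
#' @export
filter_points <- function(points, drop_fraction = 0.05, e_max = 600) {
  req <- c("step_index", "E", "sigma", "y_npq")
  if (!all(req %in% names(points))) {
    stop("points need columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (nrow(points) == 0) {
    points$retained <- logical(0); points$omit_reason <- character(0)
    return(points)
  }
  if (is.unsorted(points$step_index, strictly = TRUE)) {
    stop("points must be ordered by step_index (one curve at a time)",
         call. = FALSE)
  }
  for (col in c("strain", "acclimation", "replicate")) {
    if (col %in% names(points) && length(unique(points[[col]])) > 1) {
      stop("mixed-curve input: column `", col, "` is not constant",
           call. = FALSE)
    }
  }
  total_decrease <- max(points$sigma) - min(points$sigma)
  degenerate <- total_decrease <= 0
  thr <- if (degenerate) 0 else drop_fraction * total_decrease

  n <- nrow(points)
  reason <- rep("none", n)
  for (i in seq_len(n)) {
    if (points$y_npq[i] < 0) {
      reason[i] <- "negative_ynpq"
    } else if (points$E[i] > e_max) {
      reason[i] <- "high_irradiance"
    } else if (i >= 2) {
      y_rose <- points$y_npq[i] > points$y_npq[i - 1]
      drop <- points$sigma[i - 1] - points$sigma[i]
      # degenerate curves (no net decrease): any non-decrease while
      # Y(NPQ) rises is omitted
      small <- if (degenerate) drop <= thr else drop < thr
      if (y_rose && small) reason[i] <- "small_sigma_drop"
    }
  }
  points$retained <- reason == "none"
  points$omit_reason <- reason
  attr(points, "degenerate_total_decrease") <- degenerate
  points
}

#' Pooled OLS regression of sigmaPSII on Y(NPQ)
#'
#' Ordinary least squares of sigma on Y(NPQ) over the retained points of
#' all curves pooled (all strains, replicates and acclimations together),
#' with classical t-based 95% confidence intervals and the extrapolated
#' cross-section at Y(NPQ) = 1 (intercept + slope), interpreted as the
#' residual cross-section when all absorbed energy is thermally
#' dissipated.
#'
#' @param points data.frame with columns `sigma`, `y_npq` and, if present,
#'   logical `retained` (only retained rows are used).
#' @return A `qe_regression` object: list with `slope`, `intercept`, `r2`,
#'   `ci95_slope`, `ci95_intercept`, `n_points`, `sigma_at_ynpq1`,
#'   `ci95_sigma_at_ynpq1`, and the underlying `lm` fit.
#' @examples
#' pts <- data.frame(y_npq = c(0, 0.5, 1), sigma = c(500, 300, 100))
#' fit_sigma_ynpq(pts)$sigma_at_ynpq1  # 100
#' @export
fit_sigma_ynpq <- function(points) {
  if ("retained" %in% names(points)) points <- points[points$retained, ]
  if (nrow(points) < 3) {
    stop("need >= 3 retained points for the regression (got ",
         nrow(points), "); check filtering", call. = FALSE)
  }
  if (length(unique(points$y_npq)) < 2) {
    stop("degenerate design: all Y(NPQ) values identical", call. = FALSE)
  }
  fit <- stats::lm(sigma ~ y_npq, data = points)
  cf <- stats::coef(fit)
  ci <- suppressWarnings(stats::confint(fit, level = 0.95))
  # CI of the fitted mean at y_npq = 1 (the extrapolated cross-section)
  pred1 <- suppressWarnings(
    stats::predict(fit, newdata = data.frame(y_npq = 1),
                   interval = "confidence", level = 0.95))
  structure(list(slope = unname(cf[2]),
                 intercept = unname(cf[1]),
                 r2 = suppressWarnings(summary(fit)$r.squared),
                 ci95_slope = unname(ci["y_npq", ]),
                 ci95_intercept = unname(ci["(Intercept)", ]),
                 n_points = nrow(points),
                 sigma_at_ynpq1 = unname(cf[1] + cf[2]),
                 ci95_sigma_at_ynpq1 = unname(pred1[1, c("lwr", "upr")]),
                 lm = fit),
            class = "qe_regression")
}

#' @export
print.qe_regression <- function(x, ...) {
  cat("sigmaPSII ~ Y(NPQ) pooled linear regression\n")
  cat(sprintf("  sigma = %.1f %+.1f * Y(NPQ)   (r2 = %.3f, n = %d)\n",
              x$intercept, x$slope, x$r2, x$n_points))
  cat(sprintf("  95%% CI slope: [%.1f, %.1f]  intercept: [%.1f, %.1f]\n",
              x$ci95_slope[1], x$ci95_slope[2],
              x$ci95_intercept[1], x$ci95_intercept[2]))
  cat(sprintf("  extrapolated sigmaPSII at Y(NPQ)=1: %.1f A^2 (95%% CI [%.1f, %.1f])\n",
              x$sigma_at_ynpq1, x$ci95_sigma_at_ynpq1[1],
              x$ci95_sigma_at_ynpq1[2]))
  invisible(x)
}

#' Pigment-based functional cross-section of the PSII core
#'
#' sigma_core = a* . n_chl . M_chl / N_A, converted to A^2: the optical
#' cross-section of the chlorophyll a complement of one PSII core, from
#' the chlorophyll-a-specific absorption coefficient for blue light a*
#' (m^2 per g chl a), the number of chlorophyll a per PSII core (70 for a
#' dimeric diatom core) and the chlorophyll a molar mass.
#'
#' @param a_star Chl-a-specific absorption coefficient, m^2 (g chl a)^-1.
#'   Default 9.8 (blue light).
#' @param n_chl Chlorophyll a molecules per PSII unit. Default 70.
#' @param m_chl Chlorophyll a molar mass, g mol^-1. Default 893.5.
#' @return Cross-section, A^2.
#' @examples
#' core_cross_section()  # ~101.8 A^2 with the defaults
#' @export
core_cross_section <- function(a_star = 9.8, n_chl = 70, m_chl = 893.5) {
  if (any(c(a_star, n_chl, m_chl) <= 0)) {
    stop("all core parameters must be > 0", call. = FALSE)
  }
  a_star * n_chl * m_chl / .const$avogadro * .const$A2_per_m2
}

#' Full filtering + regression + extrapolation report
#'
#' Assembles (sigma, Y(NPQ)) points from per-step parameter tables of many
#' curves, applies the per-curve retention rules, fits the pooled OLS
#' regression, extrapolates to Y(NPQ) = 1 and compares the result with the
#' pigment-based PSII core cross-section.
#'
#' @param params_tables Either one data.frame holding the stacked output
#'   of [compute_params()] for several curves (columns `strain`,
#'   `acclimation`, `replicate` identify curves) or a list of such tables.
#' @param one_second_dark Use the 1-s-dark readouts (`sigma_prime_1s`) as
#'   the sigma variable instead of `sigma_prime`? Default FALSE. The
#'   switch governs the provenance of the sigma variable only; Y(NPQ) is
#'   always computed from the in-light F'/Fm'.
#' @param drop_fraction,e_max Passed to [filter_points()].
#' @param a_star,n_chl,m_chl Passed to [core_cross_section()].
#' @param reference_core_A2 Optional published core cross-section value
#'   (A^2) to display alongside the one computed from `a_star`, `n_chl`,
#'   `m_chl`; never used in any calculation.
#' @return A `qe_report`: list with `points` (retention table),
#'   `regression` (a `qe_regression`), `core_sigma_A2`, `delta_A2`
#'   (extrapolated minus core), `n_curves`, `retention` (per-curve counts).
#' @export
qe_report <- function(params_tables, one_second_dark = FALSE,
                      drop_fraction = 0.05, e_max = 600,
                      a_star = 9.8, n_chl = 70, m_chl = 893.5,
                      reference_core_A2 = NA_real_) {
  if (is.data.frame(params_tables)) params_tables <- list(params_tables)
  stacked <- do.call(rbind, lapply(params_tables, as.data.frame))
  req <- c("strain", "acclimation", "replicate", "step_index", "E",
           "sigma_prime", "sigma_prime_1s", "y_npq")
  if (!all(req %in% names(stacked))) {
    stop("params tables need columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  sig_col <- if (one_second_dark) "sigma_prime_1s" else "sigma_prime"
  key <- interaction(stacked$strain, stacked$acclimation,
                     stacked$replicate, drop = TRUE)
  filtered <- lapply(split(stacked, key), function(cv) {
    cv <- cv[order(cv$step_index), ]
    pts <- data.frame(strain = cv$strain, acclimation = cv$acclimation,
                      replicate = cv$replicate, step_index = cv$step_index,
                      E = cv$E, sigma = cv[[sig_col]], y_npq = cv$y_npq)
    filter_points(pts, drop_fraction = drop_fraction, e_max = e_max)
  })
  points <- do.call(rbind, filtered)
  rownames(points) <- NULL
  if (!any(points$retained)) {
    stop("no points retained after filtering; relax `drop_fraction`/`e_max` ",
         "or check that Y(NPQ) is non-negative in the input", call. = FALSE)
  }
  reg <- fit_sigma_ynpq(points)
  core <- core_cross_section(a_star = a_star, n_chl = n_chl, m_chl = m_chl)
  retention <- do.call(rbind, lapply(filtered, function(p) {
    data.frame(strain = p$strain[1], acclimation = p$acclimation[1],
               replicate = p$replicate[1], n_total = nrow(p),
               n_retained = sum(p$retained))
  }))
  rownames(retention) <- NULL
  structure(list(points = points, regression = reg,
                 core_sigma_A2 = core,
                 reference_core_A2 = reference_core_A2,
                 delta_A2 = reg$sigma_at_ynpq1 - core,
                 n_curves = length(filtered),
                 retention = retention,
                 one_second_dark = one_second_dark),
            class = "qe_report")
}

#' @export
print.qe_report <- function(x, ...) {
  cat(sprintf("qE / sigmaPSII report: %d curves, %d points (%d retained)\n",
              x$n_curves, nrow(x$points), sum(x$points$retained)))
  if (x$one_second_dark) cat("  (sigma from 1-s-dark readouts)\n")
  print(x$regression)
  cat(sprintf("  pigment-based PSII core cross-section: %.1f A^2\n",
              x$core_sigma_A2))
  if (is.finite(x$reference_core_A2)) {
    cat(sprintf("  published core reference value: %.1f A^2\n",
                x$reference_core_A2))
  }
  cat(sprintf("  delta (extrapolated - core): %+.1f A^2\n", x$delta_A2))
  invisible(x)
}
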