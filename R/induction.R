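#' Specify a single-turnover excitation flash
#'
#' A flash is described by its wavelength, its intensity (either as peak
#' optical power in W cm^-2 or directly as a photon flux in photons A^-2
#' s^-1; exactly one is authoritative and the other is derived), its
#' duration and the sampling interval of the detector. The default mirrors
#' a mini-FIRe blue single-turnover flash: 80 us at 1 W cm^-2, 450 nm.
#'
#' @param wavelength_nm Wavelength, nm, in 350-750.
#' @param peak_power_W_cm2 Peak optical power, W cm^-2. Ignored if
#'   `photon_flux` is given.
#' @param photon_flux Photon flux, photons A^-2 s^-1; overrides
#'   `peak_power_W_cm2` when supplied.
#' @param duration_us Flash duration, us (> 0).
#' @param sampling_interval_us Detector sampling interval, us (> 0,
#'   <= duration).
#' @return An object of class `flash_spec` with fields `wavelength_nm`,
#'   `peak_power_W_cm2`, `photon_flux`, `duration_us`,
#'   `sampling_interval_us`.
#' @examples
#' fl <- flash_spec()
#' fl$photon_flux           # ~226.5
#' fl$photon_flux * fl$duration_us * 1e-6  # fluence, photons A^-2
#' @export
flash_spec <- function(wavelength_nm = 450, peak_power_W_cm2 = 1,
                       photon_flux = NULL, duration_us = 80,
                       sampling_interval_us = 0.5) {
  stopifnot(is.numeric(duration_us), duration_us > 0,
            is.numeric(sampling_interval_us), sampling_interval_us > 0)
  if (wavelength_nm < 350 || wavelength_nm > 750) {
    stop("`wavelength_nm` must lie in [350, 750] nm", call. = FALSE)
  }
  if (sampling_interval_us > duration_us) {
    stop("`sampling_interval_us` must not exceed `duration_us`", call. = FALSE)
  }
  if (is.null(photon_flux)) {
    photon_flux <- photon_flux_from_power(peak_power_W_cm2, wavelength_nm)
  } else {
    if (!is.numeric(photon_flux) || photon_flux < 0) {
      stop("`photon_flux` must be >= 0", call. = FALSE)
    }
    # derive the non-authoritative power for completeness
    e_photon <- .const$h * .const$c / (wavelength_nm * 1e-9)
    peak_power_W_cm2 <- photon_flux * .const$A2_per_cm2 * e_photon
  }
  structure(list(wavelength_nm = wavelength_nm,
                 peak_power_W_cm2 = peak_power_W_cm2,
                 photon_flux = photon_flux,
                 duration_us = duration_us,
                 sampling_interval_us = sampling_interval_us),
            class = "flash_spec")
}

#' Cumulative one-hit Poisson closure fraction
#'
#' Fraction of PSII reaction centers closed (Q_A reduced) after receiving a
#' cumulative photon fluence, under single-hit Poisson statistics:
#' C = 1 - exp(-sigma * fluence).
#'
#' @param sigma_psii Functional absorption cross-section, A^2 (>= 0).
#' @param fluence Cumulative photon fluence, photons A^-2 (>= 0).
#' @return Closed fraction in \[0, 1\].
#' @examples
#' closure_fraction(500, log(2) / 500)  # 0.5
#' @export
closure_fraction <- function(sigma_psii, fluence) {
  if (any(sigma_psii < 0) || any(fluence < 0)) {
    stop("`sigma_psii` and `fluence` must be >= 0", call. = FALSE)
  }
  1 - exp(-sigma_psii * fluence)
}

#' Model a single-turnover fluorescence-induction transient
#'
#' Fluorescence rise during a saturating single-turnover flash. With
#' connectivity p the yield follows the joined-units form
#' F(t) = Fo + (Fm - Fo) * C(t) * (1 - p) / (1 - p * C(t)),
#' where C(t) is the one-hit Poisson closed fraction at the cumulative
#' fluence flux * t. p = 0 recovers the pure cumulative one-hit Poisson
#' rise.
#'
#' @param fo Minimal fluorescence (all centers open), arbitrary units.
#' @param fm Maximal fluorescence (all centers closed); `fm > fo`.
#' @param sigma_psii Functional absorption cross-section, A^2 (> 0).
#' @param connectivity_p Exciton connectivity parameter in \[0, 1).
#' @param flash A [flash_spec()].
#' @return An object of class `fluorescence_transient`: a data.frame with
#'   columns `t_us`, `signal` and the flash stored as attribute `flash`.
#' @examples
#' tr <- model_transient(1, 3, 500, 0, flash_spec())
#' head(tr)
#' @export
model_transient <- function(fo, fm, sigma_psii, connectivity_p = 0,
                            flash = flash_spec()) {
  .check_induction_params(fo, fm, sigma_psii, connectivity_p)
  t_us <- seq(0, flash$duration_us, by = flash$sampling_interval_us)
  signal <- .induction_curve(t_us, fo, fm, sigma_psii, connectivity_p,
                             flash$photon_flux)
  structure(data.frame(t_us = t_us, signal = signal),
            flash = flash,
            class = c("fluorescence_transient", "data.frame"))
}

.check_induction_params <- function(fo, fm, sigma_psii, connectivity_p) {
  if (!(fo > 0) || !(fm > fo)) {
    stop("require fm > fo > 0", call. = FALSE)
  }
  if (!(sigma_psii > 0)) stop("`sigma_psii` must be > 0", call. = FALSE)
  if (connectivity_p < 0 || connectivity_p >= 1) {
    stop("`connectivity_p` must lie in [0, 1)", call. = FALSE)
  }
  invisible(TRUE)
}

# the induction curve on an arbitrary time grid (t in us, flux in
# photons A^-2 s^-1, sigma in A^2)
.induction_curve <- function(t_us, fo, fm, sigma, p, flux) {
  C <- closure_fraction(sigma, flux * t_us * 1e-6)
  fo + (fm - fo) * C * (1 - p) / (1 - p * C)
}

#' Fit a fluorescence-induction transient
#'
#' Recovers Fo, Fm and sigmaPSII (and optionally the connectivity
#' parameter p) from a single-turnover induction transient by bounded
#' nonlinear least squares on the cumulative one-hit Poisson model.
#'
#' Initialization is deterministic and scale-free: Fo0 is the mean of the
#' first 3 samples, Fm0 the mean of the last 3, and sigma0 is the initial
#' slope of the rise (linear fit over the first quarter of the record)
#' divided by Fv0 times the photon flux. Optimization uses
#' Levenberg-Marquardt with bounds, relative tolerance 1e-10 and at most
#' 500 iterations; p, when fitted, is bounded to \[0, 0.8\].
#'
#' @param transient A `fluorescence_transient` (or data.frame with columns
#'   `t_us`, `signal` plus a `flash` attribute or explicit `flash`).
#' @param fit_connectivity Fit the connectivity parameter p? Default FALSE
#'   (p fixed at 0, the plain one-hit Poisson fit).
#' @param init Optional list with starting values `fo`, `fm`, `sigma_psii`
#'   (and `connectivity_p`).
#' @param flash Flash override when `transient` carries none.
#' @return An `induction_fit`: list with `fo`, `fm`, `fv`, `sigma_psii`
#'   (A^2), `connectivity_p`, `rmse`, `converged`, `n_iter`.
#' @examples
#' tr <- model_transient(1, 3, 500, 0, flash_spec())
#' fit_transient(tr)$sigma_psii  # 500
#' @export
fit_transient <- function(transient, fit_connectivity = FALSE, init = NULL,
                          flash = NULL) {
  if (is.null(flash)) flash <- attr(transient, "flash")
  if (is.null(flash)) stop("no flash specification available", call. = FALSE)
  flux <- flash$photon_flux
  if (!is.finite(flux) || flux <= 0) {
    stop("flash photon flux must be > 0 (sigma unidentifiable otherwise)",
         call. = FALSE)
  }
  t_us <- transient$t_us
  y <- transient$signal
  if (length(y) < 8) stop("need >= 8 samples to fit", call. = FALSE)
  if (any(!is.finite(y))) stop("non-finite signal values", call. = FALSE)

  if (is.null(init)) {
    fo0 <- mean(y[1:3])
    fm0 <- mean(y[(length(y) - 2):length(y)])
    fv0 <- fm0 - fo0
    if (fv0 <= 0 || stats::sd(y) < 1e-12 * max(abs(y), 1)) {
      return(.induction_fit(fo = fo0, fm = fm0, sigma = NA_real_,
                            p = 0, rmse = NA_real_, converged = FALSE,
                            n_iter = 0L))
    }
    # initial slope of the rise over the first quarter of the record
    n4 <- max(3L, ceiling(length(y) / 4))
    sl <- stats::coef(stats::lm(y[1:n4] ~ t_us[1:n4]))[2]  # per us
    sigma0 <- as.numeric(sl) * 1e6 / (fv0 * flux)
    if (!is.finite(sigma0) || sigma0 <= 0) sigma0 <- 200
    p0 <- 0.1
  } else {
    fo0 <- init$fo; fm0 <- init$fm; sigma0 <- init$sigma_psii
    p0 <- if (!is.null(init$connectivity_p)) init$connectivity_p else 0.1
  }

  resid_fn <- function(par) {
    p <- if (fit_connectivity) par[["p"]] else 0
    y - .induction_curve(t_us, par[["fo"]], par[["fm"]], par[["sigma"]],
                         p, flux)
  }
  par0 <- c(fo = fo0, fm = fm0, sigma = sigma0)
  lower <- c(fo = 0, fm = 0, sigma = 1e-6)
  upper <- c(fo = Inf, fm = Inf, sigma = Inf)
  if (fit_connectivity) {
    par0 <- c(par0, p = p0)
    lower <- c(lower, p = 0)
    upper <- c(upper, p = 0.8)
  }
  res <- tryCatch(
    minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                       fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         ftol = 1e-10, ptol = 1e-10, maxiter = 500)),
    error = function(e) NULL)
  if (is.null(res)) {
    return(.induction_fit(fo = fo0, fm = fm0, sigma = NA_real_, p = 0,
                          rmse = NA_real_, converged = FALSE, n_iter = 0L))
  }
  est <- res$par
  converged <- res$info %in% 1:4 && est[["fm"]] > est[["fo"]]
  .induction_fit(fo = est[["fo"]], fm = est[["fm"]],
                 sigma = est[["sigma"]],
                 p = if (fit_connectivity) est[["p"]] else 0,
                 rmse = sqrt(mean(res$fvec^2)),
                 converged = converged, n_iter = res$niter)
}

.induction_fit <- function(fo, fm, sigma, p, rmse, converged, n_iter) {
  structure(list(fo = fo, fm = fm, fv = fm - fo, sigma_psii = sigma,
                 connectivity_p = p, rmse = rmse, converged = converged,
                 n_iter = as.integer(n_iter)),
            class = "induction_fit")
}

#' @export
print.induction_fit <- function(x, ...) {
  cat("Single-turnover induction fit\n")
  cat(sprintf("  Fo = %.4g   Fm = %.4g   Fv/Fm = %.4f\n",
              x$fo, x$fm, x$fv / x$fm))
  cat(sprintf("  sigmaPSII = %.1f A^2   p = %.3f\n",
              x$sigma_psii, x$connectivity_p))
  cat(sprintf("  rmse = %.3g   converged: %s (%d iter)\n",
              x$rmse, x$converged, x$n_iter))
  invisible(x)
}
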