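#' Phenomenological strain phenotype for the synthetic panel
#'
#' A strain is a bundle of quenching-phenotype parameters, not a
#' mechanistic model: its maximal qE expressed as a Y(NPQ) ceiling, the
#' irradiance dependence of qE (Hill form), a slow sigma-independent qI
#' accrual, the dark and residual-core cross-sections, basal fluorescence
#' levels, and an apparent-cross-section connectivity rise for qE-less
#' strains. Strains that cannot form diatoxanthin (`dt_capable = FALSE`)
#' or are DTT-treated (`dtt_treated = TRUE`) have no qE: `qe_ymax` is
#' forced to 0.
#'
#' @param name Strain label.
#' @param qe_ymax Maximal Y(NPQ) attributable to qE, in \[0, 1).
#' @param e50 Half-saturation irradiance of qE, umol photons m^-2 s^-1.
#' @param hill Hill exponent of the qE light response (> 0).
#' @param qi_slope Slow quenching accrual, NPQ per (umol photons m^-2
#'   s^-1) above the onset irradiance (>= 0). The default reproduces a
#'   qE-less line reaching NPQ ~0.2 at 800 umol photons m^-2 s^-1.
#' @param e_qi_onset Irradiance above which the slow qI component
#'   accrues, umol photons m^-2 s^-1. Set to 0 for a purely linear qI.
#' @param sigma_dark Dark-acclimated sigmaPSII, A^2.
#' @param sigma_core Residual sigmaPSII at full qE, A^2 (< sigma_dark).
#' @param fo,fm Minimal/maximal dark fluorescence, arbitrary units,
#'   fm > fo > 0.
#' @param kappa_conn Apparent sigma rise with closure for qE-less strains
#'   (>= 0).
#' @param dt_capable Can the strain form diatoxanthin?
#' @param dtt_treated Was de-epoxidation inhibited with DTT?
#' @param acclimation Growth-light label carried through outputs.
#' @return A `strain_spec` list.
#' @export
strain_spec <- function(name, qe_ymax = 0.35, e50 = 200, hill = 2,
                        qi_slope = 0.2 / 550, e_qi_onset = 250,
                        sigma_dark = 525, sigma_core = 110, fo = 0.35,
                        fm = 1, kappa_conn = 0, dt_capable = TRUE,
                        dtt_treated = FALSE, acclimation = "LL") {
  if (!(fm > fo) || !(fo > 0)) stop("require fm > fo > 0", call. = FALSE)
  if (!(sigma_core > 0) || !(sigma_core < sigma_dark)) {
    stop("require 0 < sigma_core < sigma_dark", call. = FALSE)
  }
  if (qe_ymax < 0 || qe_ymax >= 1) stop("`qe_ymax` in [0, 1)", call. = FALSE)
  if (e50 <= 0 || hill <= 0 || qi_slope < 0 || e_qi_onset < 0 ||
      kappa_conn < 0) {
    stop("invalid qE/qI shape parameters", call. = FALSE)
  }
  if (!dt_capable || dtt_treated) qe_ymax <- 0  # no Dt, no qE
  structure(list(name = name, qe_ymax = qe_ymax, e50 = e50, hill = hill,
                 qi_slope = qi_slope, e_qi_onset = e_qi_onset,
                 sigma_dark = sigma_dark,
                 sigma_core = sigma_core, fo = fo, fm = fm,
                 kappa_conn = kappa_conn, dt_capable = dt_capable,
                 dtt_treated = dtt_treated, acclimation = acclimation),
            class = "strain_spec")
}

#' Rapid-light-curve measurement protocol
#'
#' @param step_irradiances Nondecreasing actinic irradiances, umol
#'   photons m^-2 s^-1. Default: 15 steps from 0 to 800.
#' @param step_duration Acclimation time per step, s. Default 60.
#' @param dark_probe Measure Fo' and sigma'_1s after 1 s darkness?
#' @param flash A [flash_spec()] for the single-turnover probe.
#' @return A `protocol_spec` list.
#' @export
protocol_spec <- function(step_irradiances = c(0, 25, 50, 75, 100, 150, 200,
                                               250, 300, 350, 400, 500, 600,
                                               700, 800),
                          step_duration = 60, dark_probe = TRUE,
                          flash = flash_spec()) {
  if (length(step_irradiances) == 0 || any(step_irradiances < 0)) {
    stop("irradiances must be a non-empty list of values >= 0", call. = FALSE)
  }
  if (is.unsorted(step_irradiances)) {
    stop("irradiances must be nondecreasing", call. = FALSE)
  }
  if (step_duration <= 0) stop("`step_duration` must be > 0", call. = FALSE)
  structure(list(step_irradiances = step_irradiances,
                 step_duration = step_duration, dark_probe = dark_probe,
                 flash = flash),
            class = "protocol_spec")
}

#' Panel configuration for an end-to-end synthetic run
#'
#' @param strains List of [strain_spec()] objects.
#' @param protocol A [protocol_spec()].
#' @param n_replicates Biological replicates per strain (>= 1).
#' @param noise_rel_sd Relative Gaussian SD on fluorescence and sigma
#'   readouts (>= 0, < 0.5).
#' @param seed Integer master seed.
#' @return A `panel_config` list.
#' @export
panel_config <- function(strains, protocol = protocol_spec(),
                         n_replicates = 5, noise_rel_sd = 0.02, seed = 1) {
  if (!length(strains)) stop("need at least one strain", call. = FALSE)
  if (n_replicates < 1) stop("`n_replicates` must be >= 1", call. = FALSE)
  if (noise_rel_sd < 0 || noise_rel_sd >= 0.5) {
    stop("`noise_rel_sd` must lie in [0, 0.5)", call. = FALSE)
  }
  structure(list(strains = strains, protocol = protocol,
                 n_replicates = as.integer(n_replicates),
                 noise_rel_sd = noise_rel_sd, seed = as.integer(seed)),
            class = "panel_config")
}

#' Default eight-strain mutant panel
#'
#' Strain phenotypes for the wild type and seven Lhcx knockout /
#' complementation lines, with qE capacities ordered
#' x2KO+x2 > wild-type = x2KO = x2KO+x3 > x1KO+x3a > x1KO+x2a >
#' x1KO = x1KO+x4a. Under low-light (LL) acclimation the x1KO and
#' x1KO+x4a lines have no qE at all; after high-light (HL) acclimation
#' every strain has some qE (Lhcx2/3 accumulation partially rescues it)
#' and the qE light response shifts to lower irradiances.
#'
#' @param acclimation `"LL"` or `"HL"`.
#' @return Named list of 8 [strain_spec()] objects.
#' @examples
#' sapply(default_panel("LL"), function(s) s$qe_ymax)
#' @export
default_panel <- function(acclimation = c("LL", "HL")) {
  acclimation <- match.arg(acclimation)
  qe <- if (acclimation == "LL") {
    c("wild-type" = 0.35, "x1KO" = 0, "x1KO+x2a" = 0.15, "x1KO+x3a" = 0.25,
      "x1KO+x4a" = 0, "x2KO" = 0.35, "x2KO+x2" = 0.45, "x2KO+x3" = 0.35)
  } else {
    c("wild-type" = 0.60, "x1KO" = 0.38, "x1KO+x2a" = 0.48,
      "x1KO+x3a" = 0.55, "x1KO+x4a" = 0.38, "x2KO" = 0.60,
      "x2KO+x2" = 0.68, "x2KO+x3" = 0.60)
  }
  e50 <- if (acclimation == "LL") 200 else 120
  sigma_dark <- 525
  out <- lapply(names(qe), function(nm) {
    strain_spec(name = nm, qe_ymax = qe[[nm]], e50 = e50, hill = 2,
                sigma_dark = sigma_dark, sigma_core = 110,
                acclimation = acclimation)
  })
  names(out) <- names(qe)
  out
}

# deterministic per-(seed, strain, replicate) substream seed, < 2^31
.derive_seed <- function(seed, strain_name, replicate_index) {
  h <- sum(utf8ToInt(strain_name) * seq_along(utf8ToInt(strain_name)))
  as.integer((as.numeric(seed) * 48271 + h * 7919 +
                replicate_index * 104729) %% 2147483647)
}

# run expr with a locally seeded RNG, restoring global state afterwards
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# slow sigma-independent quenching: linear in E above the onset
.qi <- function(strain, E) {
  strain$qi_slope * pmax(E - strain$e_qi_onset, 0)
}

# steady-state qE expressed as Y(NPQ) at irradiance E (Hill form)
.y_qe <- function(strain, E) {
  if (strain$qe_ymax == 0) return(rep(0, length(E)))
  strain$qe_ymax * E^strain$hill / (strain$e50^strain$hill + E^strain$hill)
}

# solve Y_qE = (F'/Fm) * NPQ_qE for NPQ_qE, with F' itself a function of
# NPQ_total = NPQ_qE + qI through Fm' and the Oxborough-Baker Fo'.
# Fixed-point iteration (F' depends only weakly on NPQ, so this is a
# contraction); tolerance tight enough that downstream Y(NPQ) reproduces
# the generative value to < 1e-9 in sigma units.
.solve_npq_qe <- function(y_qe, qi, C, fo, fm, y_no_init = 1) {
  if (y_qe == 0) return(0)
  fvfm <- (fm - fo) / fm
  npq_qe <- y_qe / max(y_no_init, 1e-6)
  for (i in 1:200) {
    fm_p <- fm / (1 + npq_qe + qi)
    fo_p <- fo / (fvfm + fo / fm_p)
    f_p <- fo_p + (fm_p - fo_p) * C
    new <- y_qe * fm / f_p
    if (abs(new - npq_qe) < 1e-13) return(new)
    npq_qe <- new
  }
  npq_qe
}

#' Simulate one rapid light curve
#'
#' Generates the per-step readouts (F', Fm', Fo', sigma', sigma'_1s) of a
#' rapid light curve for one strain and replicate. Noise-free values per
#' step at irradiance E:
#'
#' * qE as a yield, Y_qE(E) = qe_ymax E^hill / (e50^hill + E^hill);
#' * slow quenching qI(E) = qi_slope * max(E - e_qi_onset, 0);
#' * PSII closure C(E) = E / (E + k_half);
#' * sigma'(E) = sigma_dark - (sigma_dark - sigma_core) * Y_qE, plus, for
#'   qE-less strains only, the connectivity rise
#'   kappa_conn * sigma_dark * C(E);
#' * total NPQ = NPQ_qE + qI, with NPQ_qE solved self-consistently from
#'   Y_qE = (F'/Fm) * NPQ_qE;
#' * Fm' = Fm / (1 + NPQ), Fo' by the Oxborough-Baker estimate
#'   Fo / (Fv/Fm + Fo/Fm') (replaced by the directly measured value when
#'   the protocol has a 1-s dark probe; numerically identical here),
#'   F' = Fo' + (Fm' - Fo') C.
#'
#' Each fluorescence and sigma readout is then multiplied by an
#' independent Gaussian factor N(1, noise_rel_sd); F' is clamped into
#' \[Fo', Fm'\] so records remain physically ordered. The 1-s dark
#' readout sigma'_1s equals sigma' before noise (1 s darkness re-opens
#' centers but does not relax quenching) and receives its own noise draw.
#'
#' @param strain A [strain_spec()].
#' @param protocol A [protocol_spec()].
#' @param noise_rel_sd Relative Gaussian SD (>= 0).
#' @param seed Master seed; combined deterministically with the strain
#'   name and replicate index.
#' @param replicate_index Replicate number (>= 1).
#' @param k_half Closure half-saturation irradiance, umol photons m^-2
#'   s^-1. Default 150 (electron transport saturating near 130).
#' @return A `light_curve` data.frame with columns `strain`,
#'   `acclimation`, `replicate`, `step_index`, `E`, `f_prime`,
#'   `fm_prime`, `fo_prime`, `sigma_prime`, `sigma_prime_1s`; attributes
#'   `fv_over_fm_dark`, `true_fm`.
#' @export
simulate_light_curve <- function(strain, protocol = protocol_spec(),
                                 noise_rel_sd = 0.02, seed = 1,
                                 replicate_index = 1, k_half = 150) {
  stopifnot(inherits(strain, "strain_spec"),
            inherits(protocol, "protocol_spec"))
  E <- protocol$step_irradiances
  n <- length(E)
  fo <- strain$fo; fm <- strain$fm
  fvfm <- (fm - fo) / fm

  y_qe <- .y_qe(strain, E)
  qi <- .qi(strain, E)
  C <- E / (E + k_half)
  sigma <- strain$sigma_dark - (strain$sigma_dark - strain$sigma_core) * y_qe
  if (strain$qe_ymax == 0) {
    sigma <- sigma + strain$kappa_conn * strain$sigma_dark * C
  }

  fm_p <- fo_p <- f_p <- npq_tot <- numeric(n)
  y_no_prev <- 1
  for (k in seq_len(n)) {
    npq_qe <- .solve_npq_qe(y_qe[k], qi[k], C[k], fo, fm, y_no_prev)
    npq_tot[k] <- npq_qe + qi[k]
    fm_p[k] <- fm / (1 + npq_tot[k])
    fo_p[k] <- fo / (fvfm + fo / fm_p[k])
    f_p[k] <- fo_p[k] + (fm_p[k] - fo_p[k]) * C[k]
    y_no_prev <- f_p[k] / fm
  }

  out <- data.frame(strain = strain$name, acclimation = strain$acclimation,
                    replicate = as.integer(replicate_index),
                    step_index = seq_len(n), E = E,
                    f_prime = f_p, fm_prime = fm_p, fo_prime = fo_p,
                    sigma_prime = sigma, sigma_prime_1s = sigma)
  if (noise_rel_sd > 0) {
    sub_seed <- .derive_seed(seed, strain$name, replicate_index)
    out <- .with_seed(sub_seed, {
      for (col in c("f_prime", "fm_prime", "fo_prime",
                    "sigma_prime", "sigma_prime_1s")) {
        out[[col]] <- out[[col]] * stats::rnorm(n, 1, noise_rel_sd)
      }
      out
    })
    # keep records physically ordered after noise
    out$f_prime <- pmin(pmax(out$f_prime, out$fo_prime), out$fm_prime)
  }
  structure(out, fv_over_fm_dark = fvfm, true_fm = fm,
            class = c("light_curve", "data.frame"))
}

#' Simulate a full strain panel of light curves
#'
#' Runs [simulate_light_curve()] for every strain and replicate in a
#' [panel_config()] and stacks the results.
#'
#' @param config A [panel_config()].
#' @return A `light_curve` data.frame holding all curves; attributes as
#'   in [simulate_light_curve()].
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  curves <- list()
  for (strain in config$strains) {
    for (r in seq_len(config$n_replicates)) {
      curves[[length(curves) + 1L]] <-
        simulate_light_curve(strain, config$protocol,
                             noise_rel_sd = config$noise_rel_sd,
                             seed = config$seed, replicate_index = r)
    }
  }
  out <- do.call(rbind, curves)
  rownames(out) <- NULL
  structure(out,
            fv_over_fm_dark = attr(curves[[1]], "fv_over_fm_dark"),
            true_fm = attr(curves[[1]], "true_fm"),
            class = c("light_curve", "data.frame"))
}

#' Simulate a single-turnover induction transient
#'
#' Samples [model_transient()] on the flash time grid and applies
#' multiplicative Gaussian noise.
#'
#' @inheritParams model_transient
#' @param noise_rel_sd Relative Gaussian SD per sample (>= 0).
#' @param seed Integer seed.
#' @return A `fluorescence_transient` data.frame.
#' @export
simulate_transient <- function(fo, fm, sigma_psii, connectivity_p = 0,
                               flash = flash_spec(), noise_rel_sd = 0.01,
                               seed = 1) {
  tr <- model_transient(fo, fm, sigma_psii, connectivity_p, flash)
  if (noise_rel_sd > 0) {
    tr$signal <- .with_seed(as.integer(seed), {
      tr$signal * stats::rnorm(nrow(tr), 1, noise_rel_sd)
    })
  }
  tr
}

#' Simulate an NPQ induction / recovery time course
#'
#' NPQ during a supra-optimal light exposure rises as the qE component
#' NPQ_qE_max(E) (1 - exp(-t/tau_ind)) plus a slow linear qI term; during
#' the subsequent low-light recovery the qE term relaxes exponentially
#' (tau_rel) while the qI term stays constant. Strains without qE (no
#' diatoxanthin, or DTT-treated) show only the linear, non-relaxing term.
#'
#' @param strain A [strain_spec()].
#' @param hl_irradiance High-light irradiance, umol photons m^-2 s^-1.
#' @param hl_duration_s High-light phase duration, s.
#' @param recovery_irradiance Recovery irradiance (only label; qE is
#'   assumed fully relaxing at it).
#' @param recovery_duration_s Recovery phase duration, s.
#' @param seed Integer seed (used only when `noise_rel_sd > 0`).
#' @param dt_s Sampling interval, s.
#' @param tau_ind qE induction time constant, s. Default 60.
#' @param tau_rel qE relaxation time constant, s. Default 120.
#' @param t_qi_ref Reference time over which the qI term accrues
#'   qi_slope * E, s. Default 600.
#' @param noise_rel_sd Optional multiplicative Gaussian noise.
#' @param k_half Closure half-saturation, as in [simulate_light_curve()].
#' @return data.frame with columns `time_s`, `npq`, `phase`.
#' @export
simulate_npq_timecourse <- function(strain, hl_irradiance = 1700,
                                    hl_duration_s = 600,
                                    recovery_irradiance = 40,
                                    recovery_duration_s = 1080,
                                    seed = 1, dt_s = 10, tau_ind = 60,
                                    tau_rel = 120, t_qi_ref = 600,
                                    noise_rel_sd = 0, k_half = 150) {
  stopifnot(hl_duration_s > 0, recovery_duration_s > 0, dt_s > 0)
  E <- hl_irradiance
  y_qe <- .y_qe(strain, E)
  C <- E / (E + k_half)
  npq_qe_max <- .solve_npq_qe(y_qe, 0, C, strain$fo, strain$fm)
  r_qi <- .qi(strain, E) / t_qi_ref

  t_hl <- seq(0, hl_duration_s, by = dt_s)
  npq_hl <- npq_qe_max * (1 - exp(-t_hl / tau_ind)) + r_qi * t_hl
  qe_end <- npq_qe_max * (1 - exp(-hl_duration_s / tau_ind))
  qi_end <- r_qi * hl_duration_s
  t_rec <- seq(dt_s, recovery_duration_s, by = dt_s)
  npq_rec <- qe_end * exp(-t_rec / tau_rel) + qi_end

  out <- data.frame(
    time_s = c(t_hl, hl_duration_s + t_rec),
    npq = c(npq_hl, npq_rec),
    phase = c(rep("HL", length(t_hl)), rep("recovery", length(t_rec))))
  if (noise_rel_sd > 0) {
    out$npq <- .with_seed(as.integer(seed), {
      out$npq + stats::rnorm(nrow(out), 0, noise_rel_sd)
    })
  }
  out
}

#' Simulate a fluorescence decay histogram
#'
#' Convolves a multiexponential decay with an instrument response
#' function, adds a baseline and optionally Poisson counting noise.
#'
#' @param amplitudes Component amplitudes (counts scale), >= 0.
#' @param lifetimes_ns Component lifetimes, ns, distinct.
#' @param irf An `irf` defining the output grid.
#' @param baseline Constant background counts (>= 0).
#' @param noise_model `"none"` or `"poisson"`.
#' @param seed Integer seed for the Poisson draw.
#' @return data.frame with columns `t_ns`, `counts`.
#' @export
simulate_decay <- function(amplitudes, lifetimes_ns, irf, baseline = 0,
                           noise_model = c("none", "poisson"), seed = 1) {
  noise_model <- match.arg(noise_model)
  if (length(amplitudes) != length(lifetimes_ns)) {
    stop("amplitudes and lifetimes must have the same length", call. = FALSE)
  }
  if (anyDuplicated(lifetimes_ns)) {
    stop("lifetimes must be distinct", call. = FALSE)
  }
  m <- convolve_decay(amplitudes, lifetimes_ns, baseline, irf)
  counts <- if (noise_model == "poisson") {
    .with_seed(as.integer(seed), stats::rpois(length(m), m))
  } else m
  data.frame(t_ns = irf$times_ns, counts = counts)
}
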