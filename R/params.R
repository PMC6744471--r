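#' Non-photochemical quenching parameter
#'
#' NPQ = Fm_ref / Fm' - 1. By the first-light-step convention Fm_ref is the
#' first light step's Fm' (usually higher than the dark-acclimated Fm in
#' P. tricornutum), so NPQ can be negative when Fm' rises above Fm_ref.
#'
#' @param fm_ref Reference maximal fluorescence (> 0).
#' @param fm_prime Light-acclimated maximal fluorescence (> 0).
#' @return NPQ, dimensionless (may be negative).
#' @examples
#' npq(2.0, 1.6)  # 0.25
#' @export
npq <- function(fm_ref, fm_prime) {
  if (any(fm_ref <= 0) || any(fm_prime <= 0)) {
    stop("`fm_ref` and `fm_prime` must be > 0", call. = FALSE)
  }
  fm_ref / fm_prime - 1
}

#' Quantum-yield partition Y(II), Y(NPQ), Y(NO)
#'
#' Partitions absorbed excitation into PSII photochemistry
#' Y(II) = (Fm' - F')/Fm', regulated thermal dissipation
#' Y(NPQ) = F'/Fm' - F'/Fm_ref, and non-regulated losses
#' Y(NO) = F'/Fm_ref. The three sum to 1 identically.
#'
#' @param f_prime Steady-state fluorescence in light (0 < F' <= Fm').
#' @param fm_prime Light-acclimated maximal fluorescence.
#' @param fm_ref Reference maximal fluorescence (> 0).
#' @return Named list `y_ii`, `y_npq`, `y_no`.
#' @examples
#' quantum_yields(0.5, 1.6, 2.0)  # Y(II)=0.6875, Y(NPQ)=0.0625, Y(NO)=0.25
#' @export
quantum_yields <- function(f_prime, fm_prime, fm_ref) {
  if (any(f_prime <= 0) || any(fm_prime <= 0) || any(fm_ref <= 0)) {
    stop("fluorescence values must be > 0", call. = FALSE)
  }
  if (any(f_prime > fm_prime)) {
    stop("require f_prime <= fm_prime", call. = FALSE)
  }
  list(y_ii  = (fm_prime - f_prime) / fm_prime,
       y_npq = f_prime / fm_prime - f_prime / fm_ref,
       y_no  = f_prime / fm_ref)
}

#' Fraction of open PSII centers (lake model)
#'
#' qL = ((Fm' - F')/(Fm' - Fo')) * (Fo'/F'). 1 - qL is the excitation
#' pressure on PSII, a proxy for the plastoquinone-pool reduction state;
#' it requires Fo' measured directly (here after 1 s darkness).
#'
#' @param f_prime Steady-state fluorescence (Fo' <= F' <= Fm').
#' @param fm_prime Light-acclimated maximal fluorescence.
#' @param fo_prime Light-acclimated minimal fluorescence (< Fm').
#' @return qL in \[0, 1\].
#' @examples
#' q_l(0.5, 1.6, 0.3)  # 0.50769...
#' @export
q_l <- function(f_prime, fm_prime, fo_prime) {
  if (any(fm_prime <= fo_prime)) {
    stop("qL undefined: fm_prime must exceed fo_prime", call. = FALSE)
  }
  if (any(f_prime < fo_prime) || any(f_prime > fm_prime)) {
    stop("require fo_prime <= f_prime <= fm_prime", call. = FALSE)
  }
  ((fm_prime - f_prime) / (fm_prime - fo_prime)) * (fo_prime / f_prime)
}

#' Absolute PSII electron transport rate
#'
#' ETR = E * sigmaPSII' * (Fv'/Fm')/(Fv/Fm), with E converted to a photon
#' flux per A^2 so the result is in electrons PSII^-1 s^-1.
#'
#' @param E Irradiance, umol photons m^-2 s^-1.
#' @param sigma_prime Light-acclimated cross-section, A^2.
#' @param fv_fm_prime Fv'/Fm' at this light step.
#' @param fv_fm_dark Dark-acclimated Fv/Fm (> 0).
#' @return Electrons PSII^-1 s^-1.
#' @examples
#' etr(100, 450, 0.5, 0.65)  # ~208.5
#' @export
etr <- function(E, sigma_prime, fv_fm_prime, fv_fm_dark) {
  if (any(fv_fm_dark <= 0)) stop("`fv_fm_dark` must be > 0", call. = FALSE)
  photon_flux_from_quanta(E) * sigma_prime * (fv_fm_prime / fv_fm_dark)
}

#' Xanthophyll-cycle de-epoxidation state
#'
#' DES = Dt / (Dd + Dt) for the diatom diadinoxanthin (Dd) /
#' diatoxanthin (Dt) cycle.
#'
#' @param dd Diadinoxanthin, mol per 100 mol chlorophyll a (>= 0).
#' @param dt Diatoxanthin, same units (>= 0).
#' @return DES in \[0, 1\].
#' @examples
#' des(9, 1)  # 0.1
#' @export
des <- function(dd, dt) {
  if (any(dd < 0) || any(dt < 0)) stop("pigments must be >= 0", call. = FALSE)
  if (any(dd + dt <= 0)) {
    stop("DES undefined: dd + dt must be > 0", call. = FALSE)
  }
  dt / (dd + dt)
}

#' Quenching parameters for every step of a light curve
#'
#' Applies [npq()], [quantum_yields()], [q_l()] and [etr()] to each light
#' step of a rapid light curve and passes through E, sigma' and sigma'_1s
#' for downstream regression. The reference Fm defaults to the first light
#' step's Fm' (override with `fm_ref` for a dark-Fm convention).
#'
#' @param curve A `light_curve` (see [simulate_light_curve()] /
#'   [read_light_curves()]): data.frame with columns `step_index`, `E`,
#'   `f_prime`, `fm_prime`, `fo_prime`, `sigma_prime`, `sigma_prime_1s`.
#' @param fm_ref Reference Fm; default the first step's Fm'.
#' @param fv_fm_dark Dark-acclimated Fv/Fm used in the ETR conversion;
#'   taken from the curve's `fv_over_fm_dark` attribute when present,
#'   else 0.65.
#' @return The input data.frame extended with columns `npq`, `y_npq`,
#'   `y_no`, `y_ii`, `q_l`, `one_minus_ql`, `etr`.
#' @export
compute_params <- function(curve, fm_ref = NULL, fv_fm_dark = NULL) {
  req <- c("step_index", "E", "f_prime", "fm_prime", "fo_prime",
           "sigma_prime", "sigma_prime_1s")
  missing_cols <- setdiff(req, names(curve))
  if (length(missing_cols)) {
    stop("light curve lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(curve) == 0) stop("empty light curve", call. = FALSE)
  # stacked multi-curve input: apply per curve, each with its own fm_ref
  id_cols <- c("strain", "acclimation", "replicate")
  if (all(id_cols %in% names(curve))) {
    key <- interaction(curve$strain, curve$acclimation, curve$replicate,
                       drop = TRUE)
    if (nlevels(key) > 1) {
      fvfm <- if (is.null(fv_fm_dark)) attr(curve, "fv_over_fm_dark")
              else fv_fm_dark
      parts <- lapply(split(curve, key), function(cv) {
        cv <- cv[order(cv$step_index), ]
        compute_params(cv, fm_ref = fm_ref, fv_fm_dark = fvfm)
      })
      out <- do.call(rbind, parts)
      rownames(out) <- NULL
      attributes(out)[c("fv_over_fm_dark", "true_fm")] <-
        attributes(curve)[c("fv_over_fm_dark", "true_fm")]
      return(out)
    }
  }
  if (is.unsorted(curve$step_index, strictly = TRUE)) {
    stop("steps must be ordered by step_index", call. = FALSE)
  }
  if (is.null(fm_ref)) fm_ref <- curve$fm_prime[1]
  if (is.null(fv_fm_dark)) {
    fv_fm_dark <- attr(curve, "fv_over_fm_dark")
    if (is.null(fv_fm_dark)) fv_fm_dark <- 0.65
  }
  out <- curve
  step_try <- function(expr, k) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("step_index %s: %s", k, conditionMessage(e)),
           call. = FALSE)
    })
  }
  n <- nrow(curve)
  out$npq <- out$y_npq <- out$y_no <- out$y_ii <- NA_real_
  out$q_l <- out$one_minus_ql <- out$etr <- NA_real_
  for (i in seq_len(n)) {
    k <- curve$step_index[i]
    out$npq[i] <- step_try(npq(fm_ref, curve$fm_prime[i]), k)
    ys <- step_try(quantum_yields(curve$f_prime[i], curve$fm_prime[i],
                                  fm_ref), k)
    out$y_ii[i] <- ys$y_ii; out$y_npq[i] <- ys$y_npq; out$y_no[i] <- ys$y_no
    out$q_l[i] <- step_try(q_l(curve$f_prime[i], curve$fm_prime[i],
                               curve$fo_prime[i]), k)
    out$one_minus_ql[i] <- 1 - out$q_l[i]
    # Fv'/Fm' with Fo' measured directly after 1 s darkness
    fv_fm_prime <- (curve$fm_prime[i] - curve$fo_prime[i]) / curve$fm_prime[i]
    out$etr[i] <- step_try(etr(curve$E[i], curve$sigma_prime[i],
                               fv_fm_prime, fv_fm_dark), k)
  }
  out
}
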