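# canonical light-curve CSV dialect (one row per light step)
.lc_dialect <- c(strain = "strain", acclimation = "acclimation",
                 replicate = "replicate", step_index = "step",
                 E = "E_umol_m2_s", f_prime = "F_prime",
                 fm_prime = "Fm_prime", fo_prime = "Fo_prime",
                 sigma_prime = "sigma_A2", sigma_prime_1s = "sigma_1s_A2")

#' Write light curves to CSV
#'
#' One flat CSV, one row per light step, with the columns
#' `strain,acclimation,replicate,step,E_umol_m2_s,F_prime,Fm_prime,
#' Fo_prime,sigma_A2,sigma_1s_A2` (UTF-8, '.' decimal separator). Values
#' survive a write/read round trip to at least 12 significant digits.
#'
#' @param curves A `light_curve` data.frame (possibly many curves
#'   stacked).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_light_curves <- function(curves, path) {
  missing_cols <- setdiff(names(.lc_dialect), names(curves))
  if (length(missing_cols)) {
    stop("curves lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- curves[names(.lc_dialect)]
  names(out) <- unname(.lc_dialect)
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      out[[col]] <- formatC(out[[col]], digits = 15, format = "g")
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read light curves from CSV
#'
#' Reads the dialect written by [write_light_curves()], validates it
#' (required columns, monotone step index within each curve, the ordering
#' Fo' <= F' <= Fm' on every row) and returns a `light_curve` data.frame.
#'
#' @param path CSV file path.
#' @param fv_over_fm_dark Dark Fv/Fm to attach (needed for absolute ETR).
#'   Default 0.65.
#' @return A `light_curve` data.frame (empty if the file has only a
#'   header).
#' @export
read_light_curves <- function(path, fv_over_fm_dark = 0.65) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  missing_cols <- setdiff(unname(.lc_dialect), names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- raw[unname(.lc_dialect)]
  names(out) <- names(.lc_dialect)
  if (nrow(out)) {
    bad <- which(out$fo_prime > out$f_prime | out$f_prime > out$fm_prime)
    if (length(bad)) {
      stop("invalid record: need Fo' <= F' <= Fm' (data row ", bad[1], ")",
           call. = FALSE)
    }
    key <- interaction(out$strain, out$acclimation, out$replicate,
                       drop = TRUE)
    for (cv in split(out$step_index, key)) {
      if (is.unsorted(cv, strictly = TRUE)) {
        stop("non-monotone step index within a curve", call. = FALSE)
      }
    }
  }
  structure(out, fv_over_fm_dark = fv_over_fm_dark,
            class = c("light_curve", "data.frame"))
}

# FNV-1a hash of the serialized config, as hex (for provenance stamping)
.config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Run the full analysis pipeline on a synthetic panel
#'
#' Simulates every strain x replicate light curve of the panel, computes
#' the quenching-parameter table per curve, applies the per-curve point
#' filter and the pooled sigmaPSII ~ Y(NPQ) regression, extrapolates to
#' Y(NPQ) = 1 and compares with the pigment-based core cross-section.
#' Deterministic for a fixed config (bit-identical outputs, including
#' written files).
#'
#' @param config A [panel_config()].
#' @param out_dir Optional output directory; when given, writes
#'   `curves.csv`, `params.csv`, `retention.csv` and `summary.json`.
#' @param one_second_dark,drop_fraction,e_max,a_star,n_chl,m_chl Passed
#'   to [qe_report()].
#' @return A `run_report`: list with `panel` (curves), `params`
#'   (parameter table), `report` (a `qe_report`), `n_curves`, `n_points`,
#'   `config_hash`, `package_version`.
#' @export
run_pipeline <- function(config, out_dir = NULL, one_second_dark = FALSE,
                         drop_fraction = 0.05, e_max = 600,
                         a_star = 9.8, n_chl = 70, m_chl = 893.5,
                         reference_core_A2 = NA_real_) {
  if (!inherits(config, "panel_config")) {
    stop("`config` must be a panel_config", call. = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage %s: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  panel <- stage("simulate", simulate_panel(config))
  params <- stage("params", compute_params(panel))
  report <- stage("regress",
                  qe_report(params, one_second_dark = one_second_dark,
                            drop_fraction = drop_fraction, e_max = e_max,
                            a_star = a_star, n_chl = n_chl, m_chl = m_chl,
                            reference_core_A2 = reference_core_A2))
  out <- structure(list(panel = panel, params = params, report = report,
                        n_curves = report$n_curves,
                        n_points = nrow(report$points),
                        config_hash = .config_hash(config),
                        package_version =
                          as.character(utils::packageVersion("sigmaqe"))),
                   class = "run_report")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    stage("write", {
      write_light_curves(panel, file.path(out_dir, "curves.csv"))
      utils::write.csv(params, file.path(out_dir, "params.csv"),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(report$points, file.path(out_dir, "retention.csv"),
                       row.names = FALSE, quote = FALSE)
      reg <- report$regression
      jsonlite::write_json(
        list(slope = reg$slope, intercept = reg$intercept, r2 = reg$r2,
             ci95_slope = reg$ci95_slope,
             ci95_intercept = reg$ci95_intercept,
             n_points = reg$n_points,
             sigma_at_ynpq1 = reg$sigma_at_ynpq1,
             core_sigma_A2 = report$core_sigma_A2,
             reference_core_A2 = report$reference_core_A2,
             delta_A2 = report$delta_A2,
             config_hash = out$config_hash,
             package_version = out$package_version),
        file.path(out_dir, "summary.json"),
        auto_unbox = TRUE, digits = NA)
    })
  }
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Pipeline run: %d curves, %d points (config %s, sigmaqe %s)\n",
              x$n_curves, x$n_points, x$config_hash, x$package_version))
  print(x$report)
  invisible(x)
}
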