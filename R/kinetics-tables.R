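# Tidy (data-frame) layer over the per-object kinetics operations.

#' Fit every pot in a long-format depletion table
#'
#' Splits a long table of concentration readings by cultivar x treatment
#' x replicate, fits each pot's quadratic, and returns one row per fit
#' with coefficients and kinetic parameters.
#'
#' @param depletion data.frame with columns `cultivar`, `treatment`,
#'   `replicate`, `time_h`, `conc_mg_per_L`.
#' @param pots optional data.frame with columns `cultivar`, `treatment`,
#'   `replicate`, `volume_L`, `frw_g`; when absent, `volume_L` is used
#'   for every pot and `i_max` is NA unless `frw_g` is given.
#' @param volume_L,frw_g fallback pot metadata when `pots` is NULL.
#' @return data.frame with columns `cultivar`, `treatment`, `replicate`,
#'   `n_points`, `a`, `b`, `c`, `r_squared`, `i_max`, `c_min`,
#'   `t_vertex`, `extrapolated`, `flagged`.
#' @export
fit_depletion_set <- function(depletion, pots = NULL, volume_L = 2,
                              frw_g = NA_real_) {
  need <- c("cultivar", "treatment", "replicate", "time_h", "conc_mg_per_L")
  if (!all(need %in% names(depletion))) {
    mgk_stop(paste("depletion table must have columns:",
                   paste(need, collapse = ", ")), "schema")
  }
  key <- interaction(depletion$cultivar, depletion$treatment,
                     depletion$replicate, drop = TRUE)
  rows <- lapply(split(depletion, key), function(d) {
    d <- d[order(d$time_h), ]
    v <- volume_L
    w <- frw_g
    if (!is.null(pots)) {
      m <- pots$cultivar == d$cultivar[1] &
        pots$treatment == d$treatment[1] &
        pots$replicate == d$replicate[1]
      if (sum(m) == 1) {
        v <- pots$volume_L[m]
        w <- pots$frw_g[m]
      }
    }
    ser <- depletion_series(d$time_h, d$conc_mg_per_L, volume_L = v,
                            frw_g = w, cultivar = as.character(d$cultivar[1]),
                            treatment = as.character(d$treatment[1]),
                            replicate = d$replicate[1])
    fit <- fit_depletion_quadratic(ser)
    kp <- kinetic_params(fit, volume_L = v, frw_g = w)
    data.frame(cultivar = ser$cultivar, treatment = ser$treatment,
               replicate = ser$replicate, n_points = fit$n_points,
               a = fit$a, b = fit$b, c = fit$c,
               r_squared = fit$r_squared,
               i_max = kp$i_max, c_min = kp$c_min,
               t_vertex = kp$t_vertex, extrapolated = kp$extrapolated,
               flagged = kp$flagged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$cultivar, match(out$treatment, TREATMENTS), out$replicate), ,
      drop = FALSE]
}

#' Kinetic parameters from a table of known coefficients
#'
#' For coefficient tables (e.g. the packaged reference fits, where the
#' raw series are not available) this computes the same per-fit kinetic
#' parameters as [fit_depletion_set()] without refitting.
#'
#' @param coefs data.frame with columns `cultivar`, `treatment`,
#'   `replicate`, `a`, `b`, `c` and optionally `r_squared`.
#' @param volume_L solution volume (litres) used for Imax.
#' @param frw_g fresh root weight (g); NA leaves `i_max` NA (Cmin does
#'   not depend on it).
#' @param time_range observed window for the extrapolation flag.
#' @return data.frame in the layout of [fit_depletion_set()].
#' @examples
#' kin <- kinetics_from_coefficients(table1_fixture())
#' head(kin)
#' @export
kinetics_from_coefficients <- function(coefs, volume_L = 2, frw_g = NA_real_,
                                       time_range = c(0, 15)) {
  need <- c("cultivar", "treatment", "replicate", "a", "b", "c")
  if (!all(need %in% names(coefs))) {
    mgk_stop(paste("coefficient table must have columns:",
                   paste(need, collapse = ", ")), "schema")
  }
  rows <- lapply(seq_len(nrow(coefs)), function(i) {
    fit <- suppressWarnings(quadratic_fit(
      a = coefs$a[i], b = coefs$b[i], c = coefs$c[i],
      r_squared = if ("r_squared" %in% names(coefs))
        coefs$r_squared[i] else NA_real_,
      time_range = time_range,
      cultivar = as.character(coefs$cultivar[i]),
      treatment = as.character(coefs$treatment[i]),
      replicate = coefs$replicate[i]))
    kp <- suppressWarnings(
      kinetic_params(fit, volume_L = volume_L, frw_g = frw_g))
    data.frame(cultivar = fit$cultivar, treatment = fit$treatment,
               replicate = fit$replicate, n_points = NA_integer_,
               a = fit$a, b = fit$b, c = fit$c,
               r_squared = fit$r_squared,
               i_max = kp$i_max, c_min = kp$c_min,
               t_vertex = kp$t_vertex, extrapolated = kp$extrapolated,
               flagged = kp$flagged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-treatment kinetic summary with deltas versus control
#'
#' Averages per-replicate kinetic parameters within each cultivar x
#' treatment cell (mean and sample SD), then subtracts the same
#' cultivar's control-cell mean to obtain the delta columns. Flagged
#' replicates are dropped from the means.
#'
#' @param per_fit output of [fit_depletion_set()] or
#'   [kinetics_from_coefficients()].
#' @param control_label treatment label of the control; default
#'   `"Mg_control"`. Deltas are NA for the control row itself and when
#'   the cultivar has no control cell.
#' @return data.frame with one row per cultivar x treatment: `n`,
#'   `mean_i_max`, `sd_i_max`, `mean_c_min`, `sd_c_min`, `delta_i_max`,
#'   `delta_c_min`.
#' @examples
#' summarize_kinetics(kinetics_from_coefficients(table1_fixture()))
#' @export
summarize_kinetics <- function(per_fit, control_label = "Mg_control") {
  key <- interaction(per_fit$cultivar, per_fit$treatment, drop = TRUE)
  rows <- lapply(split(per_fit, key), function(d) {
    ok <- !d$flagged
    mean_or_na <- function(x) if (!any(ok) || all(is.na(x[ok]))) NA_real_
      else mean(x[ok], na.rm = TRUE)
    sd_or_na <- function(x) if (sum(!is.na(x[ok])) < 2) NA_real_
      else stats::sd(x[ok], na.rm = TRUE)
    data.frame(cultivar = d$cultivar[1], treatment = d$treatment[1],
               n = sum(ok),
               mean_i_max = mean_or_na(d$i_max),
               sd_i_max = sd_or_na(d$i_max),
               mean_c_min = mean_or_na(d$c_min),
               sd_c_min = sd_or_na(d$c_min),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$delta_i_max <- NA_real_
  out$delta_c_min <- NA_real_
  for (cv in unique(out$cultivar)) {
    ctrl <- out$cultivar == cv & out$treatment == control_label
    if (sum(ctrl) == 1) {
      sel <- out$cultivar == cv & !ctrl
      out$delta_i_max[sel] <- out$mean_i_max[sel] - out$mean_i_max[ctrl]
      out$delta_c_min[sel] <- out$mean_c_min[sel] - out$mean_c_min[ctrl]
    }
  }
  out[order(out$cultivar, match(out$treatment, TREATMENTS)), , drop = FALSE]
}

#' Extremes of the per-treatment mean deltas, per cultivar
#'
#' @param summary output of [summarize_kinetics()].
#' @param what which delta column to take extremes of: `"c_min"` or
#'   `"i_max"`.
#' @return data.frame with columns `cultivar`, `min_delta`, `max_delta`
#'   over the non-control treatments.
#' @export
kinetics_delta_range <- function(summary, what = c("c_min", "i_max")) {
  what <- match.arg(what)
  col <- paste0("delta_", what)
  rows <- lapply(split(summary, summary$cultivar), function(d) {
    r <- delta_range(d[[col]])
    data.frame(cultivar = d$cultivar[1], min_delta = r[["min"]],
               max_delta = r[["max"]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
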