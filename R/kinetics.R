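# Depletion-curve kinetics: quadratic fits and the Imax/Cmin parameters.
#
# The ion-depletion method follows the concentration C(t) of a nutrient in
# a hydroponic pot over time. A quadratic C = c + b*t + a*t^2 is fitted to
# each pot; for a depleting pot a > 0 and b < 0, the instantaneous uptake
# rate is -dC/dt, and two parameters summarise the curve:
#   Imax = |b| * V / FRW  (maximum uptake rate, at t = 0, per g fresh root)
#   Cmin = c - b^2/(4a)   (vertex value: solution concentration at which
#                          net uptake falls to zero)

#' Construct a depletion series
#'
#' One pot's solution concentration-versus-time record, together with the
#' pot metadata needed to scale uptake rates (solution volume and fresh
#' root weight).
#'
#' @param times sampling times in hours; strictly increasing, at least 4
#'   points, starting at or after 0.
#' @param concentrations solution concentrations in mg/L, same length as
#'   `times`, non-negative.
#' @param volume_L solution volume in litres (> 0).
#' @param frw_g fresh root weight in the pot, grams (> 0). May be `NA`
#'   when only concentration-based parameters (Cmin) are needed.
#' @param cultivar,treatment,replicate optional design labels carried
#'   through to fits and summaries.
#' @return An object of class `depletion_series`.
#' @examples
#' t <- 0:15
#' s <- depletion_series(t, 40.243 - 0.8309 * t + 0.0193 * t^2,
#'                       volume_L = 2, frw_g = 8)
#' fit_depletion_quadratic(s)
#' @export
depletion_series <- function(times, concentrations, volume_L = 2,
                             frw_g = NA_real_,
                             cultivar = NA_character_,
                             treatment = NA_character_,
                             replicate = NA_integer_) {
  if (!is.numeric(times) || !is.numeric(concentrations)) {
    mgk_stop("'times' and 'concentrations' must be numeric", "invalid_input")
  }
  if (length(times) != length(concentrations)) {
    mgk_stop("'times' and 'concentrations' must have the same length",
             "invalid_input")
  }
  if (anyNA(times) || anyNA(concentrations)) {
    mgk_stop("missing values in depletion series", "invalid_input")
  }
  if (length(unique(times)) < 4) {
    mgk_stop("a depletion series needs at least 4 distinct time points",
             "invalid_input")
  }
  if (any(diff(times) <= 0)) {
    mgk_stop("'times' must be strictly increasing", "invalid_input")
  }
  if (times[1] < 0) {
    mgk_stop("'times' must start at or after 0", "invalid_input")
  }
  if (any(concentrations < 0)) {
    mgk_stop("concentrations must be non-negative", "invalid_input")
  }
  if (!is_scalar_number(volume_L) || volume_L <= 0) {
    mgk_stop("'volume_L' must be a single positive number", "invalid_input")
  }
  if (!is.na(frw_g) && (!is_scalar_number(frw_g) || frw_g <= 0)) {
    mgk_stop("'frw_g' must be positive (or NA if unknown)", "invalid_input")
  }
  structure(
    list(times = as.numeric(times),
         concentrations = as.numeric(concentrations),
         volume_L = volume_L, frw_g = as.numeric(frw_g),
         cultivar = cultivar, treatment = treatment,
         replicate = replicate),
    class = "depletion_series"
  )
}

#' @export
print.depletion_series <- function(x, ...) {
  cat(sprintf(
    "Depletion series: %s / %s / rep %s, %d points over %g-%g h, V = %g L, FRW = %g g\n",
    x$cultivar, x$treatment, x$replicate, length(x$times),
    min(x$times), max(x$times), x$volume_L, x$frw_g))
  invisible(x)
}

#' Construct a quadratic fit object from known coefficients
#'
#' Builds the same object [fit_depletion_quadratic()] returns, from
#' externally supplied coefficients of C = c + b t + a t^2 (e.g. a
#' published table of fitted depletion equations).
#'
#' @param a,b,c coefficients, in mg·L^-1·h^-2, mg·L^-1·h^-1 and mg/L.
#' @param r_squared goodness of fit in \[0, 1\] (optional).
#' @param n_points number of points behind the fit (optional).
#' @param time_range observed time window in hours, used to flag
#'   extrapolated vertices; default `c(0, 15)`.
#' @param cultivar,treatment,replicate optional design labels.
#' @return An object of class `quadratic_fit`. If the coefficients do not
#'   describe a depleting pot (a > 0, b < 0) the object is flagged via its
#'   `depletion_shape` field (a warning is emitted, not an error).
#' @seealso [fit_depletion_quadratic()], [compute_cmin()], [compute_imax()]
#' @export
quadratic_fit <- function(a, b, c, r_squared = NA_real_,
                          n_points = NA_integer_, time_range = c(0, 15),
                          cultivar = NA_character_,
                          treatment = NA_character_,
                          replicate = NA_integer_) {
  for (v in list(a, b, c)) {
    if (!is_scalar_number(v)) {
      mgk_stop("coefficients a, b, c must be single finite numbers",
               "invalid_input")
    }
  }
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1)) {
    mgk_stop("'r_squared' must lie in [0, 1]", "invalid_input")
  }
  shape_ok <- a > 0 && b < 0
  if (!shape_ok) {
    warning(sprintf(
      "coefficients (a = %g, b = %g) do not describe a depleting pot (need a > 0, b < 0)",
      a, b), call. = FALSE)
  }
  structure(
    list(a = a, b = b, c = c, r_squared = r_squared,
         n_points = n_points, se = NULL, sigma = NA_real_,
         time_range = as.numeric(time_range),
         depletion_shape = shape_ok,
         cultivar = cultivar, treatment = treatment, replicate = replicate),
    class = "quadratic_fit"
  )
}

#' @export
print.quadratic_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Quadratic depletion fit: C(t) = %s %s t %s t^2\n",
              format(x$c, digits = digits),
              ifelse(x$b < 0, paste0("- ", format(abs(x$b), digits = digits)),
                     paste0("+ ", format(x$b, digits = digits))),
              ifelse(x$a < 0, paste0("- ", format(abs(x$a), digits = digits)),
                     paste0("+ ", format(x$a, digits = digits)))))
  cat(sprintf("  R^2 = %s on %s points%s\n",
              format(x$r_squared, digits = digits), x$n_points,
              if (!x$depletion_shape) " [flagged: not a depletion shape]" else ""))
  invisible(x)
}

#' Fit the quadratic depletion model to a series
#'
#' Ordinary least squares of C = c + b t + a t^2 on one pot's record, via
#' the QR decomposition of the Vandermonde design (numerically stable;
#' normal equations are never formed). R^2 = 1 - SS_res/SS_tot, with the
#' convention R^2 = 1 when SS_tot = 0 (a constant series is fitted
#' exactly).
#'
#' @param series a [depletion_series()].
#' @return A `quadratic_fit` with coefficients, R^2, residual sd `sigma`,
#'   and estimated coefficient standard errors `se` (named `c`, `b`, `a`).
#'   Non-depletion shapes (a <= 0 or b >= 0) are flagged with a warning,
#'   not rejected; downstream kinetic parameters for such fits are NA.
#' @examples
#' t <- 0:15
#' f <- fit_depletion_quadratic(
#'   depletion_series(t, 40.243 - 0.8309 * t + 0.0193 * t^2))
#' c(f$a, f$b, f$c, f$r_squared)
#' @export
fit_depletion_quadratic <- function(series) {
  if (!inherits(series, "depletion_series")) {
    mgk_stop("'series' must be a depletion_series", "invalid_input")
  }
  t <- series$times
  y <- series$concentrations
  X <- cbind(`(Intercept)` = 1, t = t, t2 = t^2)
  qrX <- qr(X)
  if (qrX$rank < 3L) {
    mgk_stop("degenerate design: time points do not support a quadratic fit",
             "singular_fit")
  }
  beta <- qr.coef(qrX, y)
  fitted <- drop(X %*% beta)
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  df <- length(y) - 3L
  sigma <- if (df > 0) sqrt(ss_res / df) else NA_real_
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sigma * sqrt(diag(XtXinv))
  names(se) <- c("c", "b", "a")
  fit <- suppressWarnings(quadratic_fit(
    a = unname(beta[3]), b = unname(beta[2]), c = unname(beta[1]),
    r_squared = max(0, min(1, r2)), n_points = length(y),
    time_range = range(t),
    cultivar = series$cultivar, treatment = series$treatment,
    replicate = series$replicate))
  if (!fit$depletion_shape) {
    warning(sprintf(
      "fit for %s/%s/rep %s is not a depletion shape (a = %g, b = %g); kinetic parameters will be NA",
      series$cultivar, series$treatment, series$replicate,
      fit$a, fit$b), call. = FALSE)
  }
  fit$se <- se
  fit$sigma <- sigma
  fit
}

#' Solution concentration at zero net uptake (Cmin)
#'
#' Evaluates b^2/(4a) - b^2/(2a) + c, i.e. the vertex value c - b^2/(4a)
#' of the fitted parabola: the solution concentration at which the net
#' uptake rate -dC/dt reaches zero.
#'
#' @param fit a `quadratic_fit` with a > 0.
#' @return Cmin in mg/L.
#' @examples
#' compute_cmin(quadratic_fit(0.0193, -0.8309, 40.243)) # 31.30 mg/L
#' @export
compute_cmin <- function(fit) {
  stopifnot(inherits(fit, "quadratic_fit"))
  if (fit$a <= 0) {
    mgk_stop("Cmin undefined: parabola has no minimum (a <= 0)", "no_minimum")
  }
  fit$b^2 / (4 * fit$a) - fit$b^2 / (2 * fit$a) + fit$c
}

#' Maximum uptake rate (Imax)
#'
#' Imax = |b| * V / FRW. The fitted slope at t = 0 is b mg·L^-1·h^-1, so
#' |b|·V is the pot's initial depletion rate in mg/h; dividing by the
#' fresh root weight and converting mg to µg gives µg per g fresh root
#' per hour, the scale on which uptake rates are reported.
#'
#' @param fit a `quadratic_fit`.
#' @param volume_L solution volume in litres (> 0).
#' @param frw_g fresh root weight in grams (> 0).
#' @return Imax in µg·g^-1·h^-1.
#' @examples
#' compute_imax(quadratic_fit(0.0193, -0.8309, 40.243), 2, 10) # 166.18
#' @export
compute_imax <- function(fit, volume_L, frw_g) {
  stopifnot(inherits(fit, "quadratic_fit"))
  if (!is_scalar_number(volume_L) || volume_L <= 0) {
    mgk_stop("'volume_L' must be positive", "invalid_input")
  }
  if (!is_scalar_number(frw_g) || frw_g <= 0) {
    mgk_stop("'frw_g' must be positive", "invalid_input")
  }
  abs(fit$b) * volume_L * 1000 / frw_g
}

#' Time at which the fitted uptake rate reaches zero
#'
#' The vertex time -b/(2a) of the fitted parabola. When it lies beyond
#' the observed window the Cmin value is an extrapolation; callers flag
#' this via [kinetic_params()].
#'
#' @param fit a `quadratic_fit` with a != 0.
#' @return Vertex time in hours.
#' @export
vertex_time <- function(fit) {
  stopifnot(inherits(fit, "quadratic_fit"))
  if (fit$a == 0) {
    mgk_stop("vertex undefined for a = 0", "no_vertex")
  }
  -fit$b / (2 * fit$a)
}

#' Kinetic parameters of one fitted depletion curve
#'
#' Derives Imax, Cmin and the vertex time from a quadratic fit, flagging
#' extrapolated vertices (outside the observed time window — such Cmin
#' values are retained, not rejected). Fits without a depletion shape
#' (a <= 0 or b >= 0) yield NA parameters with a warning rather than an
#' error, so a pipeline over many pots keeps running.
#'
#' @param fit a `quadratic_fit`.
#' @param volume_L solution volume in litres; defaults to 2 L.
#' @param frw_g fresh root weight in grams; `NA` gives `i_max = NA`.
#' @param time_range observed window in hours used for the extrapolation
#'   flag; defaults to the fit's own.
#' @return An object of class `kinetic_params`: list with `i_max`,
#'   `c_min`, `t_vertex`, `extrapolated`, `flagged`, plus design labels.
#' @export
kinetic_params <- function(fit, volume_L = 2, frw_g = NA_real_,
                           time_range = fit$time_range) {
  stopifnot(inherits(fit, "quadratic_fit"))
  if (!fit$depletion_shape) {
    warning(sprintf(
      "non-depletion fit (%s/%s/rep %s): kinetic parameters set to NA",
      fit$cultivar, fit$treatment, fit$replicate), call. = FALSE)
    out <- list(i_max = NA_real_, c_min = NA_real_, t_vertex = NA_real_,
                extrapolated = NA, flagged = TRUE)
  } else {
    tv <- vertex_time(fit)
    out <- list(
      i_max = if (is.na(frw_g)) NA_real_ else
        compute_imax(fit, volume_L, frw_g),
      c_min = compute_cmin(fit),
      t_vertex = tv,
      extrapolated = tv < min(time_range) || tv > max(time_range),
      flagged = FALSE)
  }
  out$cultivar <- fit$cultivar
  out$treatment <- fit$treatment
  out$replicate <- fit$replicate
  structure(out, class = "kinetic_params")
}

#' Aggregate replicate fits of one cultivar x treatment cell
#'
#' Computes per-replicate kinetic parameters first, then their arithmetic
#' mean and sample standard deviation (replicates are never pooled and
#' refitted). A single replicate gives an NA standard deviation. Flagged
#' (non-depletion) replicates are excluded from the means with a warning.
#'
#' @param fits list of `quadratic_fit`s, all from the same cultivar and
#'   treatment (mixed labels are an error).
#' @param volume_L,frw_g pot metadata, recycled across replicates.
#' @return An object of class `treatment_kinetics` with fields `cultivar`,
#'   `treatment`, `n`, `params` (per-replicate [kinetic_params()]),
#'   `mean_i_max`, `sd_i_max`, `mean_c_min`, `sd_c_min`, and delta slots
#'   (`delta_i_max`, `delta_c_min`), NA until [delta_vs_control()].
#' @export
summarize_treatment <- function(fits, volume_L = 2, frw_g = NA_real_) {
  if (!is.list(fits) || length(fits) < 1 ||
      !all(vapply(fits, inherits, logical(1), "quadratic_fit"))) {
    mgk_stop("'fits' must be a non-empty list of quadratic_fit objects",
             "invalid_input")
  }
  cultivars <- unique(vapply(fits, `[[`, character(1), "cultivar"))
  treatments <- unique(vapply(fits, `[[`, character(1), "treatment"))
  if (length(cultivars) > 1 || length(treatments) > 1) {
    mgk_stop("all fits must share one cultivar and one treatment",
             "invalid_input")
  }
  volume_L <- rep_len(volume_L, length(fits))
  frw_g <- rep_len(frw_g, length(fits))
  params <- Map(function(f, v, w) kinetic_params(f, v, w),
                fits, volume_L, frw_g)
  imax <- vapply(params, `[[`, numeric(1), "i_max")
  cmin <- vapply(params, `[[`, numeric(1), "c_min")
  flagged <- vapply(params, `[[`, logical(1), "flagged")
  mean_or_na <- function(x) if (all(is.na(x))) NA_real_ else
    mean(x, na.rm = TRUE)
  sd_or_na <- function(x) if (sum(!is.na(x)) < 2) NA_real_ else
    stats::sd(x, na.rm = TRUE)
  structure(
    list(cultivar = cultivars, treatment = treatments,
         n = sum(!flagged), params = params,
         mean_i_max = mean_or_na(imax), sd_i_max = sd_or_na(imax),
         mean_c_min = mean_or_na(cmin), sd_c_min = sd_or_na(cmin),
         delta_i_max = NA_real_, delta_c_min = NA_real_),
    class = "treatment_kinetics"
  )
}

#' Treatment-minus-control kinetic differences
#'
#' Fills the delta slots of a treatment summary: the rate of change of
#' the kinetic parameters relative to the unstarved control, computed as
#' treatment mean minus control mean (so a treatment that lowers Cmin has
#' a negative delta).
#'
#' @param summary a `treatment_kinetics`.
#' @param control the `treatment_kinetics` of the same cultivar's control
#'   cell (treatment label `control_label`).
#' @param control_label label identifying the control treatment; default
#'   `"Mg_control"`.
#' @return `summary` with `delta_i_max` and `delta_c_min` filled.
#' @export
delta_vs_control <- function(summary, control, control_label = "Mg_control") {
  stopifnot(inherits(summary, "treatment_kinetics"),
            inherits(control, "treatment_kinetics"))
  if (!identical(summary$cultivar, control$cultivar)) {
    mgk_stop("treatment and control summaries are from different cultivars",
             "invalid_input")
  }
  if (!identical(control$treatment, control_label)) {
    mgk_stop(sprintf("'control' must be the %s cell", control_label),
             "invalid_input")
  }
  summary$delta_i_max <- summary$mean_i_max - control$mean_i_max
  summary$delta_c_min <- summary$mean_c_min - control$mean_c_min
  summary
}

#' Range of treatment-versus-control deltas
#'
#' @param deltas numeric vector of per-treatment mean deltas (at least
#'   one value).
#' @return Named numeric vector `c(min = , max = )`.
#' @export
delta_range <- function(deltas) {
  deltas <- deltas[!is.na(deltas)]
  if (length(deltas) < 1) {
    mgk_stop("need at least one delta value", "invalid_input")
  }
  c(min = min(deltas), max = max(deltas))
}
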