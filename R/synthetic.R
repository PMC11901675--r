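# Synthetic experiment generator.
#
# Emulates the two-cultivar x seven-treatment x three-replicate Mg
# depletion design: a latent relative-expression level per pot
# propagates through the structural chain
#   expression -> Imax -> Cmin -> root Mg content
# with configured standardized path coefficients; (Imax, Cmin) are then
# translated into each pot's quadratic depletion curve and noisy hourly
# concentration readings, and the content/expression values are encoded
# as digest readings and qPCR cycle thresholds that back-calculate to
# the intended quantities through the assay arithmetic.

#' Configuration for a synthetic depletion experiment
#'
#' Defaults mirror the reference design: 2 cultivars x 7 treatments x 3
#' replicate pots of 2 L sampled at t = 0, 1, ..., 15 h; treatment-level
#' relative-expression means taken from the reported fold changes
#' (highest under `Mg_Mg`, lowest under `Mg_All`/`Mg_control`); path
#' coefficients (0.94, -0.94, -0.95). Fresh root weight, never reported
#' for the reference experiment, is drawn per pot from a lognormal with
#' mean 8 g and CV 0.2 (a plausible mass for six one-year seedlings) —
#' a modelling choice recorded in the generated manifest.
#'
#' @param seed integer seed; a fixed seed makes [generate_experiment()]
#'   byte-deterministic.
#' @param cultivars,treatments,replicates design grid; the control
#'   treatment must be among `treatments`.
#' @param times sampling times in hours.
#' @param volume_L pot volume (litres).
#' @param frw_mean_g,frw_cv lognormal fresh-root-weight distribution
#'   (mean in g, coefficient of variation).
#' @param conc_noise_sd additive Gaussian measurement noise on each
#'   concentration reading, mg/L (readings are truncated at 0).
#' @param initial_conc,initial_conc_sd mean and pot-to-pot sd of the
#'   starting solution concentration c, mg/L.
#' @param path_coefficients standardized structural coefficients of the
#'   three chain edges (expression -> Imax, Imax -> Cmin, Cmin ->
#'   content).
#' @param indicator_noise_sd extra measurement noise, in standardized
#'   units, added to the observed Imax / Cmin / content indicators after
#'   the structural chain (length 3); 0 gives exact coefficient
#'   recovery.
#' @param expression_folds named list per cultivar of per-treatment mean
#'   relative-expression folds (control = 1).
#' @param expr_noise_sd pot-to-pot sd of the expression fold.
#' @param imax_mean,imax_sd,cmin_mean,cmin_sd,content_mean,content_sd
#'   physical scales (ug/g/h, mg/L, ug/g) onto which the standardized
#'   chain variables are mapped.
#' @param ct_reference,ct_target_baseline reference-gene Ct and the
#'   target-gene Ct corresponding to fold 1 (the reference gene is a
#'   fabricated stable control; the design requires explicit reference
#'   Cts).
#' @param dry_mass_g,digest_volume_mL digest geometry for the emitted
#'   root-content readings.
#' @param withdrawal_dilution if TRUE, simulate the 1 mL hourly sample
#'   withdrawals being replaced with water (a ~0.05% per-sample dilution
#'   in a 2 L pot); OFF by default because the quadratic depletion model
#'   ignores it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    seed = 1L,
    cultivars = c("Rougui", "Shuixian"),
    treatments = TREATMENTS,
    replicates = 3L,
    times = 0:15,
    volume_L = 2,
    frw_mean_g = 8, frw_cv = 0.2,
    conc_noise_sd = 0.6,
    initial_conc = 40, initial_conc_sd = 1,
    path_coefficients = c(0.94, -0.94, -0.95),
    indicator_noise_sd = c(0.05, 0.05, 0.05),
    expression_folds = list(
      Rougui = c(Mg_control = 1, Mg_All = 0.88, Mg_N = 6.58, Mg_P = 6.78,
                 Mg_K = 6.32, Mg_other = 0.94, Mg_Mg = 10.58),
      Shuixian = c(Mg_control = 1, Mg_All = 0.95, Mg_N = 8.09, Mg_P = 8.39,
                   Mg_K = 7.46, Mg_other = 1.09, Mg_Mg = 13.81)),
    expr_noise_sd = 0.4,
    imax_mean = 400, imax_sd = 120,
    cmin_mean = 28, cmin_sd = 4.5,
    content_mean = 90, content_sd = 35,
    ct_reference = 18, ct_target_baseline = 25,
    dry_mass_g = 0.2, digest_volume_mL = 50,
    withdrawal_dilution = FALSE) {
  if (conc_noise_sd < 0 || expr_noise_sd < 0 || any(indicator_noise_sd < 0) ||
      initial_conc_sd < 0) {
    mgk_stop("noise standard deviations must be >= 0", "invalid_input")
  }
  if (length(path_coefficients) != 3 || any(abs(path_coefficients) > 1)) {
    mgk_stop("'path_coefficients' must be 3 values in [-1, 1]",
             "invalid_input")
  }
  if (!all(cultivars %in% names(expression_folds))) {
    mgk_stop("'expression_folds' must name every cultivar", "invalid_input")
  }
  if (replicates < 1 || length(times) < 4) {
    mgk_stop("need >= 1 replicate and >= 4 sampling times", "invalid_input")
  }
  cfg <- as.list(environment())
  structure(cfg, class = "synthetic_config")
}

#' Generate one noisy depletion series from known coefficients
#'
#' Evaluates C(t) = c + b t + a t^2 on the sampling grid, adds Gaussian
#' measurement noise truncated at zero, and wraps the result as a
#' [depletion_series()]. Deterministic for a given seed.
#'
#' @param coefficients numeric vector `c(a, b, c)` (or a
#'   `quadratic_fit`).
#' @param times sampling times in hours.
#' @param noise_sd Gaussian noise sd, mg/L (>= 0).
#' @param seed optional seed; the caller's RNG state is restored.
#' @param volume_L,frw_g,cultivar,treatment,replicate pot metadata
#'   passed to [depletion_series()].
#' @return A `depletion_series`.
#' @examples
#' s <- generate_depletion_series(c(0.0193, -0.8309, 40.243), seed = 7)
#' fit_depletion_quadratic(s)
#' @export
generate_depletion_series <- function(coefficients, times = 0:15,
                                      noise_sd = 0.6, seed = NULL,
                                      volume_L = 2, frw_g = NA_real_,
                                      cultivar = NA_character_,
                                      treatment = NA_character_,
                                      replicate = NA_integer_) {
  if (inherits(coefficients, "quadratic_fit")) {
    coefficients <- c(coefficients$a, coefficients$b, coefficients$c)
  }
  if (length(coefficients) != 3 || any(!is.finite(coefficients))) {
    mgk_stop("'coefficients' must be finite (a, b, c)", "invalid_input")
  }
  if (!is_scalar_number(noise_sd) || noise_sd < 0) {
    mgk_stop("'noise_sd' must be >= 0", "invalid_input")
  }
  a <- coefficients[1]; b <- coefficients[2]; cc <- coefficients[3]
  mu <- cc + b * times + a * times^2
  conc <- with_seed(seed, pmax(mu + stats::rnorm(length(times), 0, noise_sd), 0))
  depletion_series(times, conc, volume_L = volume_L, frw_g = frw_g,
                   cultivar = cultivar, treatment = treatment,
                   replicate = replicate)
}

# draw z = beta * x + disturbance, with the disturbance made exactly
# orthogonal to x in-sample and scaled so that the sample variance of z
# is 1: the fitted standardized slope then equals beta exactly (the
# "empirical" calibration also used by MASS::mvrnorm(empirical = TRUE)).
chain_step <- function(x, beta) {
  n <- length(x)
  e <- stats::rnorm(n)
  e <- stats::residuals(stats::lm(e ~ x))
  if (abs(beta) >= 1 || stats::sd(e) == 0) {
    return(beta * x)
  }
  beta * x + e * sqrt(1 - beta^2) / stats::sd(e)
}

#' Generate a complete synthetic experiment
#'
#' Draws the full dataset the analysis pipeline consumes: per-pot
#' depletion series, pot metadata (volume and fresh root weight), root
#' digest readings and qPCR cycle thresholds. The pot-level latent
#' chain is calibrated empirically, so with `indicator_noise_sd = 0` the
#' standardized path coefficients recovered from the latent table equal
#' the configured values exactly; the emitted measurement files add the
#' configured assay noise on top. Identical configurations (including
#' the seed) give identical output.
#'
#' @param config a [synthetic_config()].
#' @return List of class `synthetic_experiment`: `depletion` (long
#'   data.frame `cultivar, treatment, replicate, time_h, conc_mg_per_L`),
#'   `pots` (`..., volume_L, frw_g`), `digests` (`..., dry_mass_g,
#'   digest_volume_mL, aas_mg_per_L`), `qpcr` (`..., ct_target,
#'   ct_reference, ct_target_control, ct_reference_control`), `truth`
#'   (per-pot generating `i_max`, `c_min`, `mg_content`,
#'   `expression_fold`, and quadratic `a`, `b`, `c`), and `config`.
#' @examples
#' exp <- generate_experiment(synthetic_config(seed = 11))
#' nrow(exp$truth) # 42 pots
#' @export
generate_experiment <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, generate_experiment_impl(config))
}

generate_experiment_impl <- function(cfg) {
  grid <- expand.grid(replicate = seq_len(cfg$replicates),
                      treatment = cfg$treatments,
                      cultivar = cfg$cultivars,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("cultivar", "treatment", "replicate")]
  n <- nrow(grid)

  # latent expression fold per pot: treatment mean + pot noise
  fold_mean <- mapply(function(cv, tr) cfg$expression_folds[[cv]][[tr]],
                      grid$cultivar, grid$treatment)
  fold <- pmax(fold_mean + stats::rnorm(n, 0, cfg$expr_noise_sd), 0.01)

  # structural chain on standardized scales (empirically calibrated)
  z_expr <- zstd(fold)
  z_imax <- chain_step(z_expr, cfg$path_coefficients[1])
  z_cmin <- chain_step(z_imax, cfg$path_coefficients[2])
  z_cont <- chain_step(z_cmin, cfg$path_coefficients[3])
  ind <- cfg$indicator_noise_sd
  z_imax_obs <- z_imax + stats::rnorm(n, 0, ind[1])
  z_cmin_obs <- z_cmin + stats::rnorm(n, 0, ind[2])
  z_cont_obs <- z_cont + stats::rnorm(n, 0, ind[3])

  i_max <- cfg$imax_mean + cfg$imax_sd * z_imax_obs
  c_min <- cfg$cmin_mean + cfg$cmin_sd * z_cmin_obs
  content <- cfg$content_mean + cfg$content_sd * z_cont_obs

  # pot metadata and quadratic coefficients
  sdlog <- sqrt(log(1 + cfg$frw_cv^2))
  meanlog <- log(cfg$frw_mean_g) - sdlog^2 / 2
  frw <- stats::rlnorm(n, meanlog, sdlog)
  c0 <- cfg$initial_conc + stats::rnorm(n, 0, cfg$initial_conc_sd)

  bad <- which(i_max <= 0 | c_min <= 0 | content <= 0 |
                 c_min >= c0 - 0.5)
  if (length(bad)) {
    mgk_stop(sprintf(
      "infeasible parameters for pot %s/%s/rep %d (Imax = %.3g, Cmin = %.3g, content = %.3g, c0 = %.3g)",
      grid$cultivar[bad[1]], grid$treatment[bad[1]], grid$replicate[bad[1]],
      i_max[bad[1]], c_min[bad[1]], content[bad[1]], c0[bad[1]]),
      "generation")
  }

  b <- -i_max * frw / (1000 * cfg$volume_L)
  a <- b^2 / (4 * (c0 - c_min))

  depletion <- do.call(rbind, lapply(seq_len(n), function(i) {
    mu <- c0[i] + b[i] * cfg$times + a[i] * cfg$times^2
    if (cfg$withdrawal_dilution) {
      # each 1 mL sample replaced with water dilutes subsequent readings
      mu <- mu * (1 - 0.001 / cfg$volume_L)^(seq_along(cfg$times) - 1)
    }
    conc <- pmax(mu + stats::rnorm(length(cfg$times), 0, cfg$conc_noise_sd), 0)
    data.frame(cultivar = grid$cultivar[i], treatment = grid$treatment[i],
               replicate = grid$replicate[i], time_h = cfg$times,
               conc_mg_per_L = conc, stringsAsFactors = FALSE)
  }))
  rownames(depletion) <- NULL

  pots <- cbind(grid, volume_L = cfg$volume_L, frw_g = frw)

  digests <- cbind(grid, dry_mass_g = cfg$dry_mass_g,
                   digest_volume_mL = cfg$digest_volume_mL,
                   aas_mg_per_L = content * cfg$dry_mass_g /
                     (cfg$digest_volume_mL / 1000) / 1000)

  qpcr <- cbind(grid,
                ct_target = cfg$ct_target_baseline - log2(fold),
                ct_reference = cfg$ct_reference,
                ct_target_control = cfg$ct_target_baseline,
                ct_reference_control = cfg$ct_reference)

  truth <- cbind(grid, expression_fold = fold, i_max = i_max,
                 c_min = c_min, mg_content = content,
                 a = a, b = b, c = c0, frw_g = frw)

  structure(list(depletion = depletion, pots = pots, digests = digests,
                 qpcr = qpcr, truth = truth, config = cfg),
            class = "synthetic_experiment")
}

#' Write a synthetic experiment to CSV files with a manifest
#'
#' Emits the four CSVs in exactly the schemas the ingestion functions
#' expect, plus `manifest.json` recording the configuration, seed and
#' per-file MD5 checksums (fresh-root-weight variability is a modelling
#' choice, so the manifest keeps the full configuration for provenance).
#'
#' @param experiment a `synthetic_experiment`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "synthetic_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(depletion = "depletion.csv", pots = "pots.csv",
             digests = "digests.csv", qpcr = "qpcr.csv")
  paths <- file.path(dir, files)
  names(paths) <- names(files)
  for (nm in names(files)) {
    utils::write.csv(experiment[[nm]], paths[[nm]], row.names = FALSE)
  }
  cfg <- experiment$config
  manifest <- list(
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "expression_folds")],
    expression_folds = cfg$expression_folds,
    files = as.list(stats::setNames(unname(tools::md5sum(paths)),
                                    basename(paths))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, manifest = file.path(dir, "manifest.json")))
}
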