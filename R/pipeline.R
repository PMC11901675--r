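# End-to-end orchestration: ingestion, analysis report, report writing.

#' Pipeline run configuration
#'
#' @param mode input mode: `"table1-fixture"` (the packaged reference
#'   coefficient set), `"synthetic"` (a generated experiment), or
#'   `"user-files"` (CSV paths supplied in `paths`). Exactly one mode is
#'   active per run.
#' @param paths named list of CSV paths for `user-files` mode:
#'   `depletion` (required), `pots`, `digests`, `qpcr` (optional).
#' @param alpha significance level for Duncan letter displays.
#' @param n_boot bootstrap replicates for the path model.
#' @param seed seed used for the synthetic mode and the bootstrap.
#' @param digits decimals for rounded display tables (half away from
#'   zero); JSON output keeps full precision.
#' @param control_label control treatment label.
#' @param synthetic a [synthetic_config()] for synthetic mode; its seed
#'   is overridden by `seed`.
#' @return List of class `run_config`.
#' @export
run_config <- function(mode = c("table1-fixture", "synthetic", "user-files"),
                       paths = list(), alpha = 0.05, n_boot = 999,
                       seed = 1L, digits = 2,
                       control_label = "Mg_control",
                       synthetic = synthetic_config(seed = seed)) {
  mode <- match.arg(mode)
  if (mode == "user-files" && is.null(paths$depletion)) {
    mgk_stop("user-files mode needs at least paths$depletion", "invalid_input")
  }
  synthetic$seed <- seed
  structure(list(mode = mode, paths = paths, alpha = alpha,
                 n_boot = n_boot, seed = seed, digits = digits,
                 control_label = control_label, synthetic = synthetic),
            class = "run_config")
}

read_csv_checked <- function(path, required_cols, what) {
  if (!file.exists(path)) {
    mgk_stop(sprintf("cannot read %s file: '%s' does not exist", what, path),
             "io")
  }
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) {
                   mgk_stop(sprintf("failed to parse %s file '%s': %s",
                                    what, path, conditionMessage(e)), "io")
                 })
  if (nrow(df) == 0) {
    mgk_stop(sprintf("%s file '%s' is empty", what, path), "schema")
  }
  missing <- setdiff(required_cols, names(df))
  if (length(missing)) {
    mgk_stop(sprintf("%s file '%s' lacks required columns: %s", what, path,
                     paste(missing, collapse = ", ")), "schema")
  }
  df
}

#' Read and validate a long-format depletion CSV
#'
#' Checks the schema (`cultivar,treatment,replicate,time_h,conc_mg_per_L`),
#' rejects duplicate `(cultivar, treatment, replicate, time_h)` rows
#' (listing them) and negative concentrations (naming the rows), sorts
#' times within each pot, and assembles one [depletion_series()] per
#' pot, joining `volume_L`/`frw_g` from the pot metadata when given.
#'
#' @param path CSV path.
#' @param pots optional pot-metadata data.frame (columns `cultivar`,
#'   `treatment`, `replicate`, `volume_L`, `frw_g`) or CSV path.
#' @param volume_L fallback volume when no metadata is given.
#' @return Named list of `depletion_series`.
#' @export
ingest_depletion_csv <- function(path, pots = NULL, volume_L = 2) {
  df <- read_csv_checked(
    path, c("cultivar", "treatment", "replicate", "time_h", "conc_mg_per_L"),
    "depletion")
  if (is.character(pots)) {
    pots <- read_csv_checked(
      pots, c("cultivar", "treatment", "replicate", "volume_L", "frw_g"),
      "pot metadata")
  }
  key4 <- paste(df$cultivar, df$treatment, df$replicate, df$time_h)
  if (anyDuplicated(key4)) {
    dups <- unique(key4[duplicated(key4)])
    mgk_stop(paste("duplicate (cultivar, treatment, replicate, time) rows:",
                   paste(utils::head(dups, 5), collapse = "; ")), "schema")
  }
  if (any(df$conc_mg_per_L < 0)) {
    bad <- which(df$conc_mg_per_L < 0)
    mgk_stop(paste("negative concentration in row(s):",
                   paste(utils::head(bad, 5), collapse = ", ")), "schema")
  }
  key <- interaction(df$cultivar, df$treatment, df$replicate, drop = TRUE)
  out <- lapply(split(df, key), function(d) {
    d <- d[order(d$time_h), ]
    v <- volume_L
    w <- NA_real_
    if (!is.null(pots)) {
      m <- pots$cultivar == d$cultivar[1] & pots$treatment == d$treatment[1] &
        pots$replicate == d$replicate[1]
      if (sum(m) == 1) {
        v <- pots$volume_L[m]
        w <- pots$frw_g[m]
      }
    }
    depletion_series(d$time_h, d$conc_mg_per_L, volume_L = v, frw_g = w,
                     cultivar = as.character(d$cultivar[1]),
                     treatment = as.character(d$treatment[1]),
                     replicate = d$replicate[1])
  })
  out
}

duncan_by_cultivar <- function(df, value_col, alpha) {
  rows <- lapply(split(df, df$cultivar), function(d) {
    ok <- is.finite(d[[value_col]])
    if (length(unique(d$treatment[ok])) < 2 ||
        any(table(d$treatment[ok]) < 2)) {
      return(NULL)
    }
    ld <- duncan_mrt(d[[value_col]][ok], as.character(d$treatment[ok]),
                     alpha = alpha)
    cbind(cultivar = d$cultivar[1], as.data.frame(ld),
          response = value_col)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (!is.null(out)) rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Executes kinetics -> assays -> inference in order on the configured
#' input. Pots whose fits are not depletion-shaped are reported in the
#' `warnings` element (and excluded from means), never silently dropped.
#'
#' @param config a [run_config()].
#' @return List of class `analysis_report`: `fits` (per-pot coefficient
#'   and kinetic-parameter table), `treatments` (per-treatment means,
#'   SDs and deltas), `delta_ranges`, `letters` (Duncan compact letter
#'   displays per response), `contents`, `expression`, `merged`
#'   (per-pot joined indicators), `pca`, `rda`, `path_model`,
#'   `warnings`, and a `provenance` block (mode, seed, alpha, package
#'   version).
#' @examples
#' rep <- run_pipeline(run_config("table1-fixture"))
#' rep$delta_ranges
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  warn <- character(0)
  experiment <- NULL
  withCallingHandlers({
    if (config$mode == "table1-fixture") {
      fits <- kinetics_from_coefficients(table1_fixture())
    } else if (config$mode == "synthetic") {
      experiment <- generate_experiment(config$synthetic)
      fits <- fit_depletion_set(experiment$depletion, experiment$pots)
    } else {
      pots <- config$paths$pots
      series <- ingest_depletion_csv(config$paths$depletion, pots = pots)
      depl <- do.call(rbind, lapply(series, function(s) {
        data.frame(cultivar = s$cultivar, treatment = s$treatment,
                   replicate = s$replicate, time_h = s$times,
                   conc_mg_per_L = s$concentrations,
                   stringsAsFactors = FALSE)
      }))
      potdf <- do.call(rbind, lapply(series, function(s) {
        data.frame(cultivar = s$cultivar, treatment = s$treatment,
                   replicate = s$replicate, volume_L = s$volume_L,
                   frw_g = s$frw_g, stringsAsFactors = FALSE)
      }))
      fits <- fit_depletion_set(depl, potdf)
    }
  }, warning = function(w) {
    warn <<- c(warn, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  treatments <- summarize_kinetics(fits, config$control_label)
  delta_ranges <- kinetics_delta_range(treatments, "c_min")
  if (!all(is.na(fits$i_max))) {
    ir <- kinetics_delta_range(treatments, "i_max")
    names(ir)[2:3] <- c("min_delta", "max_delta")
    delta_ranges <- rbind(cbind(delta_ranges, what = "c_min"),
                          cbind(ir, what = "i_max"))
  } else {
    delta_ranges$what <- "c_min"
  }

  letters <- duncan_by_cultivar(fits, "c_min", config$alpha)
  if (!all(is.na(fits$i_max))) {
    letters <- rbind(letters, duncan_by_cultivar(fits, "i_max", config$alpha))
  }

  contents <- expression_tab <- merged <- NULL
  pca <- rda <- path_model <- NULL
  digests <- qpcr <- NULL
  if (config$mode == "synthetic") {
    digests <- experiment$digests
    qpcr <- experiment$qpcr
  } else if (config$mode == "user-files") {
    if (!is.null(config$paths$digests)) {
      digests <- read_csv_checked(
        config$paths$digests,
        c("cultivar", "treatment", "replicate", "dry_mass_g",
          "digest_volume_mL", "aas_mg_per_L"), "digest")
    }
    if (!is.null(config$paths$qpcr)) {
      qpcr <- read_csv_checked(
        config$paths$qpcr,
        c("cultivar", "treatment", "replicate", "ct_target", "ct_reference"),
        "qPCR")
    }
  }

  if (!is.null(digests)) {
    digests$mg_content <- root_mg_content(
      digests$aas_mg_per_L, digests$dry_mass_g, digests$digest_volume_mL)
    contents <- digests[, c("cultivar", "treatment", "replicate",
                            "mg_content")]
    letters <- rbind(letters,
                     duncan_by_cultivar(contents, "mg_content", config$alpha))
  }
  if (!is.null(qpcr)) {
    if (is.null(qpcr$ct_target_control)) {
      # calibrate against the cultivar's mean control-cell Cts
      for (cv in unique(qpcr$cultivar)) {
        sel <- qpcr$cultivar == cv
        ctrl <- sel & qpcr$treatment == config$control_label
        if (!any(ctrl)) {
          mgk_stop(sprintf("qPCR table has no %s rows for cultivar %s",
                           config$control_label, cv), "invalid_input")
        }
        qpcr$ct_target_control[sel] <- mean(qpcr$ct_target[ctrl])
        qpcr$ct_reference_control[sel] <- mean(qpcr$ct_reference[ctrl])
      }
    }
    qpcr$expression_fold <- fold_change_ddct(
      qpcr$ct_target, qpcr$ct_reference,
      qpcr$ct_target_control, qpcr$ct_reference_control)
    expression_tab <- qpcr[, c("cultivar", "treatment", "replicate",
                               "expression_fold")]
    letters <- rbind(letters, duncan_by_cultivar(expression_tab,
                                                 "expression_fold",
                                                 config$alpha))
  }

  if (!is.null(contents) && !is.null(expression_tab)) {
    merged <- Reduce(function(x, y)
      merge(x, y, by = c("cultivar", "treatment", "replicate")),
      list(fits[, c("cultivar", "treatment", "replicate", "i_max", "c_min")],
           contents, expression_tab))
    complete <- stats::complete.cases(
      merged[, c("i_max", "c_min", "mg_content", "expression_fold")])
    m <- merged[complete, ]
    if (nrow(m) >= 4) {
      pca <- pca_ordination(m[, c("i_max", "c_min")])
      rda <- rda_ordination(m[, c("i_max", "c_min", "mg_content")],
                            m[, "expression_fold", drop = FALSE])
      path_model <- plspm_chain(
        m, c("expression_fold", "i_max", "c_min", "mg_content"),
        n_boot = config$n_boot, seed = config$seed)
    }
  } else if (sum(!is.na(fits$i_max) & !is.na(fits$c_min)) >= 4) {
    ok <- !is.na(fits$i_max) & !is.na(fits$c_min)
    pca <- pca_ordination(fits[ok, c("i_max", "c_min")])
  }

  structure(
    list(fits = fits, treatments = treatments, delta_ranges = delta_ranges,
         letters = letters, contents = contents,
         expression = expression_tab, merged = merged,
         pca = pca, rda = rda, path_model = path_model,
         warnings = warn,
         provenance = list(
           mode = config$mode, seed = config$seed, alpha = config$alpha,
           n_boot = config$n_boot, digits = config$digits,
           control_label = config$control_label,
           package_version = as.character(utils::packageVersion("mgkinetics")))),
    class = "analysis_report"
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("Analysis report (%s mode): %d fits, %d treatment cells\n",
              x$provenance$mode, nrow(x$fits), nrow(x$treatments)))
  cat("Delta ranges (treatment - control):\n")
  print(x$delta_ranges, row.names = FALSE)
  if (!is.null(x$path_model)) {
    print(x$path_model)
  }
  if (length(x$warnings)) {
    cat(sprintf("%d warning(s); see $warnings\n", length(x$warnings)))
  }
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Emits CSV tables (rounded half-away-from-zero to the configured
#' number of decimals for display), a full-precision JSON report, a
#' plain-text log of flagged fits, and a checksum manifest. Re-running
#' on identical inputs reproduces identical files.
#'
#' @param report an `analysis_report`.
#' @param outdir output directory (created if needed, must be writable).
#' @param digits display rounding; defaults to the report's configured
#'   value.
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(report, outdir,
                         digits = report$provenance$digits) {
  stopifnot(inherits(report, "analysis_report"))
  ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) {
    mgk_stop(sprintf("cannot create output directory '%s'", outdir), "io")
  }
  round_df <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], round_half_up, digits = digits)
    df
  }
  files <- character(0)
  emit_csv <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.csv(round_df(df), p, row.names = FALSE)
    files <<- c(files, p)
  }
  emit_csv(report$fits, "fits.csv")
  emit_csv(report$treatments, "treatment_kinetics.csv")
  if (!is.null(report$letters)) emit_csv(report$letters, "duncan_letters.csv")
  if (!is.null(report$contents)) emit_csv(report$contents, "contents.csv")
  if (!is.null(report$expression)) emit_csv(report$expression,
                                            "expression.csv")
  json_path <- file.path(outdir, "report.json")
  json_body <- list(
    provenance = report$provenance,
    delta_ranges = report$delta_ranges,
    treatments = report$treatments,
    path_model = if (!is.null(report$path_model))
      as.data.frame(report$path_model),
    pca_explained = if (!is.null(report$pca)) report$pca$explained,
    rda_constrained_fraction = if (!is.null(report$rda))
      report$rda$constrained_fraction,
    warnings = report$warnings)
  jsonlite::write_json(json_body[!vapply(json_body, is.null, logical(1))],
                       json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  files <- c(files, json_path)
  log_path <- file.path(outdir, "log.txt")
  writeLines(c(sprintf("mode: %s", report$provenance$mode),
               sprintf("seed: %s", report$provenance$seed),
               sprintf("fits: %d (%d flagged)", nrow(report$fits),
                       sum(report$fits$flagged)),
               if (length(report$warnings))
                 paste("WARNING:", report$warnings) else "no warnings"),
             log_path)
  files <- c(files, log_path)
  manifest <- list(files = as.list(stats::setNames(
    unname(tools::md5sum(files)), basename(files))),
    provenance = report$provenance)
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(files, manifest_path))
}
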