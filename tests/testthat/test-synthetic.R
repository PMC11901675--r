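# Reference fixture and synthetic experiment generator.

test_that("the packaged coefficient table matches its source records", {
  tab <- table1_fixture()
  expect_equal(nrow(tab), 42)
  expect_equal(nrow(unique(tab[, c("cultivar", "treatment")])), 14)
  expect_true(all(table(tab$cultivar, tab$treatment) == 3))

  r1 <- subset(tab, cultivar == "Rougui" & treatment == "Mg_control" &
                 replicate == 1)
  expect_equal(c(r1$a, r1$b, r1$c, r1$r_squared),
               c(0.0193, -0.8309, 40.243, 0.9744))
  s2 <- subset(tab, cultivar == "Shuixian" & treatment == "Mg_Mg" &
                 replicate == 2)
  expect_equal(c(s2$a, s2$b, s2$c, s2$r_squared),
               c(0.1287, -3.1176, 38.757, 0.9878))
  # every curve is depletion-shaped with a plausible R^2
  expect_true(all(tab$a > 0 & tab$b < 0))
  expect_true(all(tab$r_squared >= 0.92 & tab$r_squared <= 1))
})

test_that("generated depletion series are exact at zero noise and seeded", {
  s0 <- generate_depletion_series(c(0.0193, -0.8309, 40.243), noise_sd = 0)
  expect_equal(s0$concentrations,
               40.243 - 0.8309 * (0:15) + 0.0193 * (0:15)^2)
  sa <- generate_depletion_series(c(0.05, -1.5, 38), noise_sd = 0.6, seed = 9)
  sb <- generate_depletion_series(c(0.05, -1.5, 38), noise_sd = 0.6, seed = 9)
  expect_identical(sa$concentrations, sb$concentrations)
  expect_error(generate_depletion_series(c(0.05, -1.5, 38), noise_sd = -1),
               class = "mgk_invalid_input")
})

test_that("noisy series from steep reference curves refit inside the printed R^2 range", {
  # Applies to curves with substantial depletion; very shallow pots
  # (total drop of a few mg/L) cannot reach R^2 >= 0.92 under
  # measurement noise of this size, so they are not asserted here.
  tab <- table1_fixture()
  steep <- subset(tab, abs(b) > 1)
  set.seed(60)
  r2 <- replicate(200, {
    i <- sample(nrow(steep), 1)
    s <- generate_depletion_series(c(steep$a[i], steep$b[i], steep$c[i]),
                                   noise_sd = 0.6)
    fit_depletion_quadratic(s)$r_squared
  })
  expect_gte(mean(r2 >= 0.92 & r2 <= 1), 0.95)
})

test_that("a full experiment is deterministic and internally consistent", {
  cfg <- synthetic_config(seed = 11)
  e1 <- generate_experiment(cfg)
  e2 <- generate_experiment(cfg)
  expect_identical(e1, e2)

  # shape contract: 42 pots in every table
  expect_equal(nrow(e1$truth), 42)
  expect_equal(nrow(e1$pots), 42)
  expect_equal(nrow(e1$digests), 42)
  expect_equal(nrow(e1$qpcr), 42)
  expect_equal(nrow(e1$depletion), 42 * 16)

  # noiseless refits recover each pot's generating parameters exactly
  cfg0 <- synthetic_config(seed = 3, conc_noise_sd = 0,
                           indicator_noise_sd = c(0, 0, 0))
  e0 <- generate_experiment(cfg0)
  f0 <- fit_depletion_set(e0$depletion, e0$pots)
  key <- paste(f0$cultivar, f0$treatment, f0$replicate)
  tkey <- paste(e0$truth$cultivar, e0$truth$treatment, e0$truth$replicate)
  truth <- e0$truth[match(key, tkey), ]
  expect_lt(max(abs(f0$c_min - truth$c_min)), 1e-9)
  expect_lt(max(abs(f0$i_max - truth$i_max)), 1e-6)

  # digest reads and Ct values back-calculate to the intended quantities
  expect_equal(root_mg_content(e0$digests$aas_mg_per_L,
                               e0$digests$dry_mass_g,
                               e0$digests$digest_volume_mL),
               e0$truth$mg_content, tolerance = 1e-12)
  expect_equal(fold_change_ddct(e0$qpcr$ct_target, e0$qpcr$ct_reference,
                                e0$qpcr$ct_target_control,
                                e0$qpcr$ct_reference_control),
               e0$truth$expression_fold, tolerance = 1e-12)
})

test_that("zero indicator/measurement noise recovers the configured path exactly", {
  cfg0 <- synthetic_config(seed = 5, conc_noise_sd = 0,
                           indicator_noise_sd = c(0, 0, 0))
  m <- join_indicators(generate_experiment(cfg0))
  fit <- plspm_chain(m, c("expression_fold", "i_max", "c_min", "mg_content"),
                     n_boot = 0)
  expect_equal(fit$coefficient, c(0.94, -0.94, -0.95), tolerance = 0.02)
})

test_that("treatment-mean structure mirrors the reported orderings", {
  e <- generate_experiment(synthetic_config(seed = 21))
  tr <- e$truth
  fold_means <- tapply(tr$expression_fold, tr$treatment, mean)
  cont_means <- tapply(tr$mg_content, tr$treatment, mean)
  low <- c("Mg_All", "Mg_control", "Mg_other")
  npk <- c("Mg_N", "Mg_P", "Mg_K")
  # expression and content: highest under Mg_Mg, lowest under All/control
  expect_true(all(fold_means["Mg_Mg"] > fold_means[names(fold_means) != "Mg_Mg"]))
  expect_true(all(cont_means["Mg_Mg"] > cont_means[names(cont_means) != "Mg_Mg"]))
  expect_true(max(cont_means[low]) < min(cont_means[npk]))
})

test_that("the pipeline recovers each pot's generating Imax (round trip)", {
  # with known noise, fitted Imax should sit within ~3 design standard
  # errors of the generating value for nearly all pots
  cfg <- synthetic_config(seed = 31)
  e <- generate_experiment(cfg)
  f <- suppressWarnings(fit_depletion_set(e$depletion, e$pots))
  key <- paste(f$cultivar, f$treatment, f$replicate)
  tkey <- paste(e$truth$cultivar, e$truth$treatment, e$truth$replicate)
  truth <- e$truth[match(key, tkey), ]
  t <- cfg$times
  se_b <- cfg$conc_noise_sd *
    sqrt(diag(solve(crossprod(cbind(1, t, t^2))))[2])
  se_imax <- se_b * cfg$volume_L * 1000 / truth$frw_g
  frac <- mean(abs(f$i_max - truth$i_max) <= 3 * se_imax, na.rm = TRUE)
  expect_gte(frac, 0.90)
})

test_that("infeasible configurations fail loudly, naming the cell", {
  cfg_bad <- synthetic_config(seed = 1, cmin_mean = 45)  # above c0 = 40
  err <- tryCatch(generate_experiment(cfg_bad), error = identity)
  expect_s3_class(err, "mgk_generation")
  expect_match(conditionMessage(err), "infeasible")
})

test_that("written experiments carry a checksum manifest and reproduce", {
  e <- generate_experiment(synthetic_config(seed = 2))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- write_experiment(e, d1)
  f2 <- write_experiment(e, d2)
  expect_true(file.exists(file.path(d1, "manifest.json")))
  m1 <- jsonlite::read_json(file.path(d1, "manifest.json"))
  m2 <- jsonlite::read_json(file.path(d2, "manifest.json"))
  expect_identical(m1$files, m2$files)  # byte-identical CSVs
  expect_equal(length(m1$files), 4)
})
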