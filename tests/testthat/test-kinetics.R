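# Quadratic depletion fitting and the Imax/Cmin parameters.

test_that("noiseless series are refitted exactly (round trip)", {
  # reference curve: Rougui Mg_control rep 1
  f <- fit_depletion_quadratic(quadratic_series(0.0193, -0.8309, 40.243))
  expect_equal(f$a, 0.0193, tolerance = 1e-12)
  expect_equal(f$b, -0.8309, tolerance = 1e-12)
  expect_equal(f$c, 40.243, tolerance = 1e-12)
  expect_equal(f$r_squared, 1)

  # property: any depletion-shaped quadratic on >= 4 points
  set.seed(101)
  for (i in 1:25) {
    a <- runif(1, 0.005, 0.15)
    b <- -runif(1, 0.2, 3)
    c <- runif(1, 30, 45)
    n <- sample(4:20, 1)
    t <- sort(sample(seq(0, 15, by = 0.5), n))
    y <- c + b * t + a * t^2
    if (min(y) < 0) {           # keep the curve physical
      c <- c - min(y) + 1
      y <- y - min(y) + 1
    }
    s <- depletion_series(t, y)
    fit <- fit_depletion_quadratic(s)
    expect_equal(c(fit$a, fit$b, fit$c), c(a, b, c), tolerance = 1e-8)
    expect_equal(fit$r_squared, 1)
  }
})

test_that("a constant series fits with R^2 = 1 by convention", {
  s <- suppressWarnings(depletion_series(0:15, rep(40, 16)))
  f <- suppressWarnings(fit_depletion_quadratic(s))
  expect_equal(c(f$a, f$b, f$c), c(0, 0, 40), tolerance = 1e-12)
  expect_equal(f$r_squared, 1)
  expect_false(f$depletion_shape)
})

test_that("noisy fits agree with a normal-equations oracle and recover truth", {
  set.seed(7)
  t <- 0:15
  truth <- c(c = 40.243, b = -0.8309, a = 0.0193)
  X <- cbind(1, t, t^2)
  se_design <- sqrt(diag(solve(crossprod(X)))) * 0.8
  r2s <- numeric(50)
  for (i in 1:50) {
    y <- pmax(truth["c"] + truth["b"] * t + truth["a"] * t^2 +
                rnorm(16, 0, 0.8), 0)
    fit <- suppressWarnings(fit_depletion_quadratic(depletion_series(t, y)))
    expect_equal(c(fit$c, fit$b, fit$a),
                 unname(oracle_normal_equations(t, y)), tolerance = 1e-8,
                 ignore_attr = TRUE)
    # within 3 design standard errors of the generating coefficients
    expect_lt(abs(fit$c - truth["c"]), 3.5 * se_design[1])
    expect_lt(abs(fit$b - truth["b"]), 3.5 * se_design[2])
    expect_lt(abs(fit$a - truth["a"]), 3.5 * se_design[3])
    r2s[i] <- fit$r_squared
  }
  expect_gt(median(r2s), 0.9)
})

test_that("invalid series and degenerate designs are rejected", {
  expect_error(depletion_series(0:2, c(40, 39, 38)), class = "mgk_invalid_input")
  expect_error(depletion_series(c(0, 1, 1, 2), c(40, 39, 38, 37)),
               class = "mgk_invalid_input")
  expect_error(depletion_series(0:4, c(40, 39, 38, 37, -1)),
               class = "mgk_invalid_input")
  expect_error(depletion_series(0:4, 40:36, volume_L = 0),
               class = "mgk_invalid_input")
  expect_error(fit_depletion_quadratic(1:10), class = "mgk_invalid_input")
})

test_that("Cmin equals the printed-form vertex value and a grid oracle", {
  f1 <- quadratic_fit(0.0193, -0.8309, 40.243)
  expect_equal(compute_cmin(f1), oracle_grid_cmin(0.0193, -0.8309, 40.243),
               tolerance = 1e-6)
  expect_equal(round_half_up(compute_cmin(f1)), 31.30)

  f2 <- quadratic_fit(0.0584, -1.7316, 37.554)
  expect_equal(round_half_up(compute_cmin(f2)), 24.72)
  expect_equal(compute_cmin(f2), oracle_grid_cmin(0.0584, -1.7316, 37.554),
               tolerance = 1e-6)

  # vertex at t = 0
  f3 <- suppressWarnings(quadratic_fit(1, 0, 5))
  expect_equal(compute_cmin(f3), 5)

  # property: Cmin is the minimum of the parabola for random fits
  set.seed(11)
  for (i in 1:30) {
    a <- runif(1, 0.01, 0.2); b <- -runif(1, 0.2, 3); c <- runif(1, 25, 45)
    expect_equal(compute_cmin(quadratic_fit(a, b, c)),
                 oracle_grid_cmin(a, b, c), tolerance = 1e-6)
  }

  expect_error(compute_cmin(suppressWarnings(quadratic_fit(-0.01, -1, 40))),
               class = "mgk_no_minimum")
  expect_error(compute_cmin(suppressWarnings(quadratic_fit(0, -1, 40))),
               class = "mgk_no_minimum")
})

test_that("Imax applies |b| V / FRW with the mg-to-ug conversion", {
  f <- quadratic_fit(0.0193, -0.8309, 40.243)
  expect_equal(compute_imax(f, 2, 10), 166.18)
  expect_equal(compute_imax(suppressWarnings(quadratic_fit(0.01, 0, 40)),
                            2, 10), 0)
  # doubling FRW halves the rate; Cmin ignores V and FRW entirely
  set.seed(5)
  for (i in 1:10) {
    f <- quadratic_fit(runif(1, 0.01, 0.1), -runif(1, 0.3, 3),
                       runif(1, 30, 45))
    v <- runif(1, 1, 3); w <- runif(1, 4, 12)
    expect_equal(compute_imax(f, v, 2 * w), compute_imax(f, v, w) / 2)
    expect_identical(compute_cmin(f), compute_cmin(f))
  }
  expect_error(compute_imax(f, 0, 10), class = "mgk_invalid_input")
  expect_error(compute_imax(f, 2, -1), class = "mgk_invalid_input")
})

test_that("vertex time is -b/(2a) and drives the extrapolation flag", {
  expect_equal(vertex_time(quadratic_fit(0.0193, -0.8309, 40.243)),
               0.8309 / (2 * 0.0193), tolerance = 1e-12) # 21.53 h
  expect_equal(vertex_time(quadratic_fit(0.0584, -1.7316, 37.554)),
               1.7316 / (2 * 0.0584), tolerance = 1e-12) # 14.83 h
  expect_equal(vertex_time(suppressWarnings(quadratic_fit(1, 0, 5))), 0)
  expect_error(vertex_time(suppressWarnings(quadratic_fit(0, -1, 40))),
               class = "mgk_no_vertex")

  kp_out <- kinetic_params(quadratic_fit(0.0193, -0.8309, 40.243),
                           volume_L = 2, frw_g = 10)
  expect_true(kp_out$extrapolated)   # vertex 21.5 h beyond the 0-15 h window
  kp_in <- kinetic_params(quadratic_fit(0.0584, -1.7316, 37.554),
                          volume_L = 2, frw_g = 10)
  expect_false(kp_in$extrapolated)   # vertex 14.8 h inside the window
})

test_that("non-depletion fits are flagged with NA parameters, not errors", {
  f <- suppressWarnings(quadratic_fit(-0.02, -1, 40))
  expect_warning(kp <- kinetic_params(f, 2, 10), "NA")
  expect_true(kp$flagged)
  expect_true(is.na(kp$c_min) && is.na(kp$i_max))
})

test_that("treatment summaries average per-replicate parameters", {
  tab <- table1_fixture()
  ctrl <- subset(tab, cultivar == "Rougui" & treatment == "Mg_control")
  fits <- lapply(seq_len(3), function(i)
    quadratic_fit(ctrl$a[i], ctrl$b[i], ctrl$c[i], cultivar = "Rougui",
                  treatment = "Mg_control", replicate = i))
  s <- summarize_treatment(fits, volume_L = 2)
  expect_equal(round_half_up(s$mean_c_min), 30.92)
  expect_equal(s$n, 3)
  expect_equal(s$sd_c_min,
               sd(ctrl$c - ctrl$b^2 / (4 * ctrl$a)), tolerance = 1e-12)

  # single replicate: mean = value, SD undefined
  s1 <- summarize_treatment(fits[1], volume_L = 2)
  expect_equal(s1$mean_c_min, compute_cmin(fits[[1]]))
  expect_true(is.na(s1$sd_c_min))

  # identical replicates: SD = 0
  s3 <- summarize_treatment(fits[c(1, 1, 1)], volume_L = 2)
  expect_equal(s3$sd_c_min, 0)

  # mixed labels rejected
  other <- quadratic_fit(0.0584, -1.7316, 37.554, cultivar = "Rougui",
                         treatment = "Mg_Mg", replicate = 1)
  expect_error(summarize_treatment(c(fits[1], list(other))),
               class = "mgk_invalid_input")
})

test_that("deltas are treatment minus control, with matching guards", {
  tab <- table1_fixture()
  cell <- function(tr) {
    d <- subset(tab, cultivar == "Rougui" & treatment == tr)
    summarize_treatment(lapply(seq_len(nrow(d)), function(i)
      quadratic_fit(d$a[i], d$b[i], d$c[i], cultivar = "Rougui",
                    treatment = tr, replicate = i)), volume_L = 2)
  }
  ctrl <- cell("Mg_control")
  expect_equal(round_half_up(delta_vs_control(cell("Mg_Mg"), ctrl)$delta_c_min),
               -6.50)
  expect_equal(round_half_up(delta_vs_control(cell("Mg_All"), ctrl)$delta_c_min),
               1.12)
  # control versus itself is zero
  expect_equal(delta_vs_control(ctrl, ctrl)$delta_c_min, 0)

  shui <- summarize_treatment(list(quadratic_fit(
    0.1192, -2.9243, 38.356, cultivar = "Shuixian", treatment = "Mg_Mg",
    replicate = 1)))
  expect_error(delta_vs_control(shui, ctrl), class = "mgk_invalid_input")
  expect_error(delta_vs_control(ctrl, cell("Mg_Mg")),
               class = "mgk_invalid_input")
})

test_that("delta_range returns the extremes", {
  expect_equal(delta_range(c(-6.5, 1.12, -3.8)), c(min = -6.5, max = 1.12))
  expect_equal(delta_range(2.5), c(min = 2.5, max = 2.5))
  expect_error(delta_range(NA_real_), class = "mgk_invalid_input")
})
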