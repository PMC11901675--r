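# One-way ANOVA, studentized range quantiles, Duncan letter displays.

test_that("one-way ANOVA decomposes sums of squares and matches t^2", {
  set.seed(3)
  vals <- c(rnorm(5, 0), rnorm(6, 1), rnorm(7, 3))
  grp <- rep(c("a", "b", "c"), c(5, 6, 7))
  a <- anova_oneway(vals, grp)
  expect_equal(a$ss_between + a$ss_within, a$ss_total, tolerance = 1e-10)
  expect_equal(a$df_between, 2)
  expect_equal(a$df_within, 15)

  # k = 2: F equals the squared pooled-variance t statistic
  v2 <- c(rnorm(6, 0), rnorm(8, 1))
  g2 <- rep(c("x", "y"), c(6, 8))
  a2 <- anova_oneway(v2, g2)
  tt <- t.test(v2 ~ g2, var.equal = TRUE)
  expect_equal(a2$f, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a2$p, tt$p.value, tolerance = 1e-10)

  # near-separated groups: tiny jitter, huge F
  v3 <- c(0, 0, 0, 1, 1, 1) + rnorm(6, 0, 1e-4)
  a3 <- anova_oneway(v3, rep(c("lo", "hi"), each = 3))
  expect_lt(a3$p, 1e-6)

  # all observations identical -> F = 0, p = 1 by convention
  a4 <- anova_oneway(rep(5, 9), rep(c("a", "b", "c"), 3))
  expect_equal(a4$f, 0)
  expect_equal(a4$p, 1)

  expect_error(anova_oneway(1:3, c("a", "b", "c")),
               class = "mgk_invalid_input")
})

test_that("studentized range quantiles match identities and quadrature", {
  # two means: q = sqrt(2) * central-t quantile
  for (df in c(4, 10, 30)) {
    expect_equal(studentized_range_quantile(2, df, 0.05),
                 sqrt(2) * qt(0.975, df), tolerance = 1e-4)
  }
  # independent double-quadrature oracle
  expect_equal(studentized_range_quantile(3, 10, 0.05),
               oracle_qtukey(0.95, 3, 10), tolerance = 1e-3)
  # monotone increasing in the number of means spanned
  q <- vapply(2:8, studentized_range_quantile, numeric(1), df = 12,
              alpha = 0.05)
  expect_true(all(diff(q) > 0))
  expect_error(studentized_range_quantile(3, 0.5, 0.05),
               class = "mgk_invalid_input")
})

test_that("Duncan letters separate clear groups and join identical ones", {
  # identical draws in every group: a single shared letter
  ld0 <- duncan_mrt(rep(c(4, 4, 4), each = 3), rep(c("g1", "g2", "g3"), each = 3))
  expect_true(all(ld0$letters == "a"))

  # two groups 100 sds apart
  set.seed(1)
  ld2 <- duncan_mrt(c(rnorm(3, 100), rnorm(3, 0)),
                    rep(c("hi", "lo"), each = 3))
  expect_equal(ld2$letters, c("a", "b"))
  expect_equal(ld2$group, c("hi", "lo"))

  # n_i < 2 is an inference error
  expect_error(duncan_mrt(c(1, 2, 3), c("a", "a", "b")),
               class = "mgk_inference")
})

test_that("seven treatments with the reported content means give the reported grouping", {
  means <- c(Mg_Mg = 137.34, Mg_P = 107.75, Mg_N = 104.96, Mg_K = 102.83,
             Mg_other = 52.57, Mg_control = 50.65, Mg_All = 48.56)
  set.seed(1)
  vals <- unlist(lapply(means, function(m) rnorm(3, m, 3)))
  grp <- rep(names(means), each = 3)
  ld <- duncan_mrt(vals, grp, alpha = 0.05)
  pat <- setNames(ld$letters, ld$group)
  # Mg_Mg stands alone, N/P/K share a letter, other/control/All share one
  expect_length(unique(pat[c("Mg_N", "Mg_P", "Mg_K")]), 1)
  expect_length(unique(pat[c("Mg_other", "Mg_control", "Mg_All")]), 1)
  expect_false(pat["Mg_Mg"] %in% pat[names(pat) != "Mg_Mg"])
  expect_false(any(pat[c("Mg_N", "Mg_P", "Mg_K")] %in%
                     pat[c("Mg_other", "Mg_control", "Mg_All")]))
})

test_that("letter displays are order-consistent (absorb correctness)", {
  set.seed(20)
  for (i in 1:25) {
    k <- sample(3:7, 1)
    vals <- rnorm(k * 3, mean = rep(runif(k, 0, 6), each = 3))
    ld <- duncan_mrt(vals, rep(paste0("g", 1:k), each = 3))
    # if two groups share a letter, every group ranked between them does too
    for (lab in unique(unlist(strsplit(ld$letters, "")))) {
      idx <- which(grepl(lab, ld$letters, fixed = TRUE))
      expect_equal(idx, seq(min(idx), max(idx)))
    }
  }
})

test_that("Duncan with k = 2 is the pooled-variance t-test decision", {
  set.seed(99)
  for (i in 1:50) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    v <- c(rnorm(n1, 0), rnorm(n2, runif(1, 0, 2)))
    g <- rep(c("a", "b"), c(n1, n2))
    ld <- duncan_mrt(v, g, alpha = 0.05)
    duncan_separates <- ld$letters[1] != ld$letters[2]
    t_rejects <- t.test(v ~ g, var.equal = TRUE)$p.value < 0.05
    expect_equal(duncan_separates, t_rejects)
  }
})
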