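# One-way ANOVA and Duncan's multiple range test with compact letters.

#' One-way analysis of variance
#'
#' Standard one-way decomposition (SS_between + SS_within = SS_total),
#' computed through [stats::lm()]. Its mean square error is also the
#' error term for Duncan's multiple range test. When every observation
#' is identical the F statistic is 0 and p = 1 by convention.
#'
#' @param values numeric response.
#' @param groups group labels, same length as `values`; k >= 2 groups,
#'   each non-empty, total n > k.
#' @return List of class `anova_oneway`: `f`, `df_between`, `df_within`,
#'   `mse`, `p`, `ss_between`, `ss_within`, `ss_total`, `group_means`,
#'   `group_n`.
#' @export
anova_oneway <- function(values, groups) {
  if (length(values) != length(groups)) {
    mgk_stop("'values' and 'groups' must have equal length", "invalid_input")
  }
  if (any(!is.finite(values))) {
    mgk_stop("'values' must be finite", "invalid_input")
  }
  g <- factor(groups)
  k <- nlevels(g)
  if (k < 2) {
    mgk_stop("need at least 2 groups", "invalid_input")
  }
  n <- length(values)
  if (n <= k) {
    mgk_stop("degenerate design: no within-group degrees of freedom",
             "invalid_input")
  }
  fit <- stats::lm(values ~ g)
  ss_within <- sum(stats::residuals(fit)^2)
  ss_total <- sum((values - mean(values))^2)
  ss_between <- ss_total - ss_within
  df_b <- k - 1L
  df_w <- n - k
  mse <- ss_within / df_w
  tol <- 1e-12 * (sum(values^2) + 1)
  if (ss_within <= tol && ss_between <= tol) {
    f <- 0
    p <- 1
  } else if (ss_within <= tol) {
    f <- Inf
    p <- 0
  } else {
    f <- (ss_between / df_b) / mse
    p <- stats::pf(f, df_b, df_w, lower.tail = FALSE)
  }
  structure(
    list(f = f, df_between = df_b, df_within = df_w, mse = mse, p = p,
         ss_between = ss_between, ss_within = ss_within,
         ss_total = ss_total,
         group_means = tapply(values, g, mean),
         group_n = tapply(values, g, length)),
    class = "anova_oneway"
  )
}

#' Upper quantile of the studentized range distribution
#'
#' The critical points of Duncan's shortest significant ranges are upper
#' quantiles of the studentized range of `n_means` normal means with
#' `df` error degrees of freedom, evaluated numerically (no tabulated
#' values), so arbitrary degrees of freedom and protection levels are
#' supported.
#'
#' @param n_means number of means spanned (>= 2).
#' @param df error degrees of freedom (>= 1).
#' @param alpha upper-tail probability in (0, 1).
#' @return The quantile q with P(Q > q) = alpha.
#' @examples
#' studentized_range_quantile(2, 10, 0.05) # sqrt(2) * qt(0.975, 10)
#' @export
studentized_range_quantile <- function(n_means, df, alpha = 0.05) {
  if (!is_scalar_number(n_means) || n_means < 2 ||
      n_means != round(n_means)) {
    mgk_stop("'n_means' must be an integer >= 2", "invalid_input")
  }
  if (!is_scalar_number(df) || df < 1) {
    mgk_stop("'df' must be >= 1", "invalid_input")
  }
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha >= 1) {
    mgk_stop("'alpha' must be in (0, 1)", "invalid_input")
  }
  stats::qtukey(alpha, nmeans = n_means, df = df, lower.tail = FALSE)
}

#' Duncan's multiple range test with a compact letter display
#'
#' Sorts the group means in descending order and compares every pair
#' means `p` ranks apart against the shortest significant range
#' `R_p = q(p, df_error; alpha_p) * sqrt(MSE / n_h)`, where the
#' protection level rises with the span, `alpha_p = 1 - (1 - alpha)^(p-1)`,
#' and `n_h` is the harmonic mean group size (Kramer adjustment for
#' mildly unbalanced designs). The stepwise protection rule applies: a
#' non-significant range renders all ranges it contains non-significant.
#' Letters are assigned to the maximal non-significant stretches,
#' starting at "a" for the largest mean, so groups sharing a letter do
#' not differ at level `alpha` and groups sharing none do.
#'
#' @param values numeric response.
#' @param groups group labels; every group needs n >= 2 for inference.
#' @param alpha significance level; default 0.05.
#' @return data.frame of class `duncan_letters`, one row per group in
#'   descending-mean order: `group`, `mean`, `n`, `letters`. Attributes
#'   `alpha`, `mse`, `df_error`, `n_harmonic` and `anova` carry the error
#'   term used.
#' @examples
#' set.seed(1)
#' duncan_mrt(c(rnorm(3, 0), rnorm(3, 100)), rep(c("lo", "hi"), each = 3))
#' @export
duncan_mrt <- function(values, groups, alpha = 0.05) {
  aov1 <- anova_oneway(values, groups)
  if (any(aov1$group_n < 2)) {
    mgk_stop("every group needs at least 2 observations for Duncan's test",
             "inference")
  }
  means <- sort(aov1$group_means, decreasing = TRUE)
  k <- length(means)
  n_h <- k / sum(1 / aov1$group_n)
  sem <- sqrt(aov1$mse / n_h)
  # nonsig[i, j]: means ranked i..j (descending) are not separated
  nonsig <- diag(TRUE, k)
  if (sem == 0) {
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) nonsig[i, j] <- means[i] == means[j]
    }
  } else {
    for (span in rev(seq_len(k)[-1])) {
      alpha_p <- 1 - (1 - alpha)^(span - 1)
      r_p <- studentized_range_quantile(span, aov1$df_within, alpha_p) * sem
      for (i in seq_len(k - span + 1)) {
        j <- i + span - 1
        if (nonsig[i, j]) next  # protected by an enclosing range
        if (means[i] - means[j] <= r_p) {
          # mark the whole window, protecting every enclosed range
          for (ii in i:j) for (jj in ii:j) nonsig[ii, jj] <- TRUE
        }
      }
    }
  }
  # maximal non-significant stretches -> letters
  reach <- vapply(seq_len(k), function(i) max(which(nonsig[i, ])), integer(1))
  letters_per_group <- rep("", k)
  next_letter <- 1L
  prev_reach <- 0L
  for (i in seq_len(k)) {
    if (reach[i] > prev_reach) {
      lab <- make_letter_label(next_letter)
      idx <- i:reach[i]
      letters_per_group[idx] <- paste0(letters_per_group[idx], lab)
      next_letter <- next_letter + 1L
      prev_reach <- reach[i]
    }
  }
  out <- data.frame(group = names(means), mean = as.numeric(means),
                    n = as.integer(aov1$group_n[names(means)]),
                    letters = letters_per_group, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("duncan_letters", "data.frame"),
            alpha = alpha, mse = aov1$mse, df_error = aov1$df_within,
            n_harmonic = n_h, anova = aov1)
}

# "a", "b", ..., "z", "aa", "ab", ... for pathological many-group cases
make_letter_label <- function(i) {
  out <- ""
  i <- i - 1L
  repeat {
    out <- paste0(letters[i %% 26L + 1L], out)
    i <- i %/% 26L
    if (i == 0L) break
    i <- i - 1L
  }
  out
}

#' @export
print.duncan_letters <- function(x, digits = 4, ...) {
  cat(sprintf("Duncan's multiple range test (alpha = %g, df error = %d)\n",
              attr(x, "alpha"), attr(x, "df_error")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
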