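# Independent oracles used across the suite. Each re-derives a quantity
# by a different route than the implementation under test.

# exact series on a quadratic, as a depletion_series
quadratic_series <- function(a, b, c, times = 0:15, ...) {
  depletion_series(times, c + b * times + a * times^2, ...)
}

# brute-force normal-equations least squares (the implementation uses QR)
oracle_normal_equations <- function(times, conc) {
  X <- cbind(1, times, times^2)
  solve(t(X) %*% X, t(X) %*% conc)[, 1]
}

# grid minimization of the fitted parabola over t in [0, 100]
oracle_grid_cmin <- function(a, b, c, step = 1e-4) {
  t <- seq(0, 100, by = step)
  min(c + b * t + a * t^2)
}

# studentized range CDF by direct double quadrature:
# P(Q <= q) = int f_s(s) * k * int phi(z) [Phi(z) - Phi(z - q s)]^(k-1) dz ds
# where s is the root-mean-square error sd with df degrees of freedom.
oracle_ptukey <- function(q, k, df) {
  prange <- function(w) {
    if (w <= 0) return(0)
    stats::integrate(function(z) {
      k * stats::dnorm(z) * (stats::pnorm(z) - stats::pnorm(z - w))^(k - 1)
    }, -Inf, Inf, rel.tol = 1e-10)$value
  }
  ds <- function(s) {
    # density of sqrt(chi^2_df / df)
    2 * s * stats::dchisq(s^2 * df, df) * df
  }
  stats::integrate(Vectorize(function(s) ds(s) * prange(q * s)),
                   0, Inf, rel.tol = 1e-8)$value
}

oracle_qtukey <- function(p, k, df) {
  stats::uniroot(function(q) oracle_ptukey(q, k, df) - p,
                 c(0.1, 50), tol = 1e-7)$root
}

# assemble the per-pot joined indicator table from a synthetic experiment
join_indicators <- function(experiment) {
  fits <- suppressWarnings(
    fit_depletion_set(experiment$depletion, experiment$pots))
  m <- merge(fits, experiment$digests,
             by = c("cultivar", "treatment", "replicate"))
  m$mg_content <- root_mg_content(m$aas_mg_per_L, m$dry_mass_g,
                                  m$digest_volume_mL)
  m <- merge(m, experiment$qpcr,
             by = c("cultivar", "treatment", "replicate"))
  m$expression_fold <- fold_change_ddct(
    m$ct_target, m$ct_reference, m$ct_target_control, m$ct_reference_control)
  m[stats::complete.cases(
    m[, c("expression_fold", "i_max", "c_min", "mg_content")]), ]
}
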