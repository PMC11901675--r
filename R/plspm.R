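# Chain-structured path model: expression -> Imax -> Cmin -> content.
#
# With one indicator per construct a PLS path model degenerates to
# sequential regressions on standardized columns: each edge coefficient
# is the OLS slope of the standardized endogenous variable on its single
# standardized predecessor, i.e. their Pearson correlation. The outer
# weight iteration of the general algorithm is therefore skipped rather
# than emulated — it would be a no-op.

#' Fit a single-indicator chain path model
#'
#' Standardizes the chain columns and estimates each directed edge of
#' the (acyclic) chain by ordinary least squares; for single-predecessor
#' chains every coefficient equals the Pearson correlation of the two
#' standardized columns and lies in \[-1, 1\]. Uncertainty comes from a
#' non-parametric bootstrap: rows are resampled with replacement, the
#' chain refitted (re-standardizing within each resample), and two-sided
#' percentile p-values and standard errors reported. Coefficients are
#' invariant to affine rescaling of any input column.
#'
#' @param data data.frame or matrix containing the chain columns.
#' @param chain character vector of column names in causal order, e.g.
#'   `c("expression_fold", "i_max", "c_min", "mg_content")`; each
#'   consecutive pair is one directed edge.
#' @param n_boot bootstrap replicates (default 999); `0` skips the
#'   bootstrap (`boot_se`, `p_value`, `stars` become NA).
#' @param seed optional seed for the bootstrap; the caller's RNG state
#'   is untouched.
#' @return data.frame of class `path_model_fit`, one row per edge:
#'   `from`, `to`, `coefficient` (standardized), `r_squared` (of the
#'   endogenous construct), `boot_se`, `p_value`, `stars` (`**` p < 0.01,
#'   `*` p < 0.05). Attributes `n`, `n_boot`, `seed`.
#' @examples
#' set.seed(42)
#' x <- rnorm(40); y <- 0.9 * x + rnorm(40, 0, 0.4)
#' plspm_chain(data.frame(x = x, y = y), c("x", "y"), n_boot = 199)
#' @export
plspm_chain <- function(data, chain, n_boot = 999, seed = NULL) {
  data <- as.data.frame(data)
  if (length(chain) < 2) {
    mgk_stop("'chain' needs at least two constructs", "invalid_input")
  }
  if (anyDuplicated(chain)) {
    mgk_stop("'chain' must be acyclic: repeated constructs not allowed",
             "invalid_input")
  }
  missing_cols <- setdiff(chain, names(data))
  if (length(missing_cols)) {
    mgk_stop(paste("chain columns not in data:",
                   paste(missing_cols, collapse = ", ")), "schema")
  }
  x <- as.matrix(data[, chain, drop = FALSE])
  if (anyNA(x) || any(!is.finite(x))) {
    mgk_stop("chain columns must be finite with no missing values",
             "invalid_input")
  }
  n <- nrow(x)
  if (n <= 2) {  # each edge regresses on one predecessor
    mgk_stop("need more observations than predecessors + 1", "invalid_input")
  }
  est <- chain_coefficients(x)
  edges <- data.frame(from = chain[-length(chain)], to = chain[-1],
                      coefficient = est, r_squared = est^2,
                      stringsAsFactors = FALSE)
  if (n_boot > 0) {
    boot <- with_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        idx <- sample.int(n, n, replace = TRUE)
        xb <- x[idx, , drop = FALSE]
        if (any(apply(xb, 2, stats::sd) == 0)) {
          return(rep(NA_real_, length(est)))
        }
        chain_coefficients(xb)
      }, numeric(length(est)))
    })
    boot <- matrix(boot, nrow = length(est))
    edges$boot_se <- apply(boot, 1, stats::sd, na.rm = TRUE)
    edges$p_value <- apply(boot, 1, function(b) {
      b <- b[!is.na(b)]
      lo <- (1 + sum(b <= 0)) / (length(b) + 1)
      hi <- (1 + sum(b >= 0)) / (length(b) + 1)
      min(1, 2 * min(lo, hi))
    })
    edges$stars <- ifelse(edges$p_value < 0.01, "**",
                          ifelse(edges$p_value < 0.05, "*", ""))
  } else {
    edges$boot_se <- NA_real_
    edges$p_value <- NA_real_
    edges$stars <- NA_character_
  }
  structure(edges, class = c("path_model_fit", "data.frame"),
            n = n, n_boot = n_boot, seed = seed)
}

# slopes of consecutive standardized columns (= Pearson correlations)
chain_coefficients <- function(x) {
  z <- apply(x, 2, zstd)
  vapply(seq_len(ncol(z) - 1), function(k) {
    sum(z[, k] * z[, k + 1]) / sum(z[, k]^2)
  }, numeric(1))
}

#' @export
print.path_model_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Chain path model (n = %d, %d bootstrap replicates)\n",
              attr(x, "n"), attr(x, "n_boot")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
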