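# Ordination: PCA of the kinetic parameters and RDA of the joint
# kinetics/content/expression table.

#' Principal component analysis of a samples x variables matrix
#'
#' Eigendecomposition of the (by default standardized) covariance, via
#' [stats::prcomp()]. Standardization is the default because the kinetic
#' parameters live on very different scales (Imax in ug/g/h, Cmin in
#' mg/L).
#'
#' @param x numeric matrix or data.frame, samples in rows (>= 2 rows,
#'   >= 2 columns, no missing values).
#' @param standardize scale each variable to unit variance before the
#'   decomposition (default TRUE). A constant column is an error when
#'   standardizing.
#' @return Object of class `ordination`: `method = "pca"`, `scores`
#'   (samples x axes), `loadings` (variables x axes), `explained`
#'   (proportion of variance per axis, summing to 1 over all axes),
#'   `sdev`.
#' @export
pca_ordination <- function(x, standardize = TRUE) {
  x <- as.matrix(x)
  if (!is.numeric(x) || nrow(x) < 2 || ncol(x) < 2) {
    mgk_stop("'x' must be a numeric matrix with >= 2 rows and >= 2 columns",
             "invalid_input")
  }
  if (anyNA(x)) {
    mgk_stop("'x' must not contain missing values", "invalid_input")
  }
  sds <- apply(x, 2, stats::sd)
  if (standardize && any(sds == 0)) {
    mgk_stop("cannot standardize a constant column", "invalid_input")
  }
  p <- stats::prcomp(x, center = TRUE, scale. = standardize)
  expl <- p$sdev^2 / sum(p$sdev^2)
  structure(
    list(method = "pca", scores = p$x, loadings = p$rotation,
         sdev = p$sdev, explained = expl,
         constrained_fraction = NA_real_),
    class = "ordination"
  )
}

#' Redundancy analysis (constrained ordination)
#'
#' Projects the (standardized) response matrix onto the space spanned by
#' the explanatory variables and decomposes the fitted values — ordination
#' constrained to variation explainable by the predictors. Implemented
#' through [vegan::rda()]. The default variable assignment for the
#' magnesium-uptake design is response = kinetic parameters + root
#' content, explanatory = relative transporter expression; both sides
#' are configurable.
#'
#' @param response numeric matrix/data.frame of response variables.
#' @param explanatory numeric matrix/data.frame of explanatory
#'   variables, same number of rows.
#' @param standardize standardize the response variables first (default
#'   TRUE); explanatory variables are always centred by the projection.
#' @return Object of class `ordination`: `method = "rda"`, `scores`
#'   (site scores on the constrained axes), `loadings` (response-variable
#'   scores), `explained` (per-axis proportion of total response
#'   variance; constrained axes first), and `constrained_fraction`, the
#'   share of total variance explained by the predictors.
#' @export
rda_ordination <- function(response, explanatory, standardize = TRUE) {
  response <- as.matrix(response)
  explanatory <- as.matrix(explanatory)
  if (nrow(response) != nrow(explanatory)) {
    mgk_stop("response and explanatory must have the same number of rows",
             "invalid_input")
  }
  if (anyNA(response) || anyNA(explanatory)) {
    mgk_stop("missing values are not allowed", "invalid_input")
  }
  if (qr(scale(explanatory, scale = FALSE))$rank < 1) {
    mgk_stop("explanatory matrix has rank 0 after centring", "invalid_input")
  }
  if (standardize) {
    if (any(apply(response, 2, stats::sd) == 0)) {
      mgk_stop("cannot standardize a constant response column",
               "invalid_input")
    }
    response <- scale(response)
  }
  ord <- vegan::rda(X = response, Y = explanatory)
  total <- ord$tot.chi
  eig_c <- if (!is.null(ord$CCA)) ord$CCA$eig else numeric(0)
  eig_u <- if (!is.null(ord$CA)) ord$CA$eig else numeric(0)
  n_axes <- max(1, length(eig_c))
  sc <- vegan::scores(ord, display = c("sites", "species"),
                      choices = seq_len(n_axes))
  structure(
    list(method = "rda", scores = sc$sites, loadings = sc$species,
         explained = c(eig_c, eig_u) / total,
         eig_constrained = eig_c, eig_unconstrained = eig_u,
         constrained_fraction = sum(eig_c) / total),
    class = "ordination"
  )
}

#' @export
print.ordination <- function(x, digits = 4, ...) {
  cat(sprintf("%s ordination: %d axes\n", toupper(x$method),
              length(x$explained)))
  cat("  variance explained:",
      paste(format(x$explained, digits = digits), collapse = ", "), "\n")
  if (!is.na(x$constrained_fraction)) {
    cat(sprintf("  constrained fraction: %s\n",
                format(x$constrained_fraction, digits = digits)))
  }
  invisible(x)
}
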