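# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

TREATMENTS <- c("Mg_control", "Mg_All", "Mg_N", "Mg_P", "Mg_K",
                "Mg_other", "Mg_Mg")

# Classed errors so callers/tests can distinguish failure modes.
mgk_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(paste0("mgk_", class), "mgk_error")))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state,
#' so seeded generators do not perturb the global random stream. With
#' `seed = NULL` the expression runs against the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  if (!is_scalar_number(seed)) {
    mgk_stop("'seed' must be a single finite number or NULL", "invalid_input")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

#' Round half away from zero
#'
#' Reported tables round to a fixed number of decimals with ties going
#' away from zero (the convention of the source tables), unlike base
#' [round()], which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 2).
#' @return `x` rounded.
#' @examples
#' round_half_up(c(0.125, -0.125), 2) # 0.13, -0.13
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# standardize a numeric vector to mean 0, sd 1 (sample sd)
zstd <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    mgk_stop("cannot standardize a constant column", "invalid_input")
  }
  (x - mean(x)) / s
}
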