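# Packaged reference coefficient set for the Mg depletion experiment.

#' Reference depletion-curve coefficients (2 cultivars x 7 treatments x 3
#' replicates)
#'
#' The packaged, read-only transcription of the 42 fitted depletion
#' equations C = c + b t + a t^2 (with their reported R^2) from the
#' motivating magnesium-uptake experiment on the tea cultivars Rougui
#' and Shuixian: seven culture-solution treatments (`Mg_control`,
#' `Mg_All`, `Mg_N`, `Mg_P`, `Mg_K`, `Mg_other`, `Mg_Mg`), three
#' replicate 2 L pots each, sampled hourly over 0-15 h. These
#' coefficients are the ground truth behind the package's worked
#' examples, the synthetic generator's defaults, and the reproduction of
#' the reported treatment-versus-control Cmin differences.
#'
#' @return data.frame of class `table1_fixture` with columns `cultivar`,
#'   `treatment` (factor with the seven design levels), `replicate`,
#'   `a`, `b`, `c`, `r_squared`; exactly 42 rows.
#' @examples
#' tab <- table1_fixture()
#' subset(tab, cultivar == "Rougui" & treatment == "Mg_control")
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_depletion_fits.csv",
                      package = "mgkinetics", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$treatment <- factor(tab$treatment, levels = TREATMENTS)
  stopifnot(nrow(tab) == 42L, !anyNA(tab))
  class(tab) <- c("table1_fixture", "data.frame")
  tab
}
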