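# Loaders for the small packaged reference tables.

#' Microelectrode O2 flux survey across springs and years
#'
#' The packaged table of net areal O2 fluxes, penetration depths and Thiele
#' moduli measured in thermoacidic Fe(III)-oxide mats over several
#' campaigns. The midpoint is used where a depth range was reported.
#'
#' @return data.frame with columns `spring`, `temperature_c`, `sample_date`,
#'   `flux_umol_cm2_s`, `penetration_depth_um`, `thiele`.
#' @examples
#' fs <- fluxSurvey()
#' mean(fs$flux_umol_cm2_s)  # ~1.2e-4 umol cm-2 s-1
#' @export
fluxSurvey <- function() {
  utils::read.csv(system.file("extdata", "o2_flux_survey.csv",
                              package = "ferromat", mustWork = TRUE),
                  comment.char = "#", stringsAsFactors = FALSE)
}

#' Phylotype abundances in mature mats, amplicon vs random sequencing
#'
#' The packaged table of relative abundances (percent) of the main
#' phylotypes in mature (0.5-2 cm) Fe(III)-oxide mats, measured by random
#' shotgun sequencing and by universal-primer 16S amplicon (iTag)
#' sequencing of matching samples. The amplicon columns carry a strong
#' primer bias against the Fe(II)-oxidizer (a 515F primer mismatch), which
#' [primerBias()] quantifies.
#'
#' @return Numeric matrix (taxa x assays), percentages; `NA` = not detected.
#' @examples
#' mm <- matureMatAbundance()
#' primerBias(mm[, "osp_itag"] / 100, mm[, "osp_illumina"] / 100)
#' @export
matureMatAbundance <- function() {
  df <- utils::read.delim(system.file("extdata", "mature_mat_abundance.tsv",
                                      package = "ferromat", mustWork = TRUE),
                          comment.char = "#", stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$taxon
  m
}
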