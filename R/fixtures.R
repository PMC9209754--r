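#' Path to a packaged example data file
#'
#' @param file file name under the package's `extdata` directory; empty to
#'   list the directory.
#' @return absolute path.
#' @export
ser_fixture_path <- function(file = "") {
  p <- system.file("extdata", file, package = "qtlpyramid", mustWork = file != "")
  p
}

#' The published 11-locus, 31-line genotype panel
#'
#' Line-by-QTL presence/absence matrix of the rice SER pyramiding study:
#' the HJX74 control plus 31 lines carrying 2-6 QTL substitution segments
#' (seven 2-QTL lines of which two, A35 and A88, are single-segment lines
#' whose segment carries two linked QTLs; ten 3-QTL, seven 4-QTL, five
#' 5-QTL and two 6-QTL lines).
#'
#' @return a [genotype_panel()] with metadata attached.
#' @export
ser_study_panel <- function() {
  md <- ser_study_metadata()
  read_genotype_table(ser_fixture_path("ser_study_genotypes.csv"),
                      control = "HJX74", loci = md)
}

#' QTL metadata with reconstructed single-QTL additive effects
#'
#' Donor species and linkage annotations are as published. The per-locus
#' `known_additive_effect` values are NOT published individually; the
#' packaged values are a numerical reconstruction constrained to reproduce
#' the published aggregates (mean/range of single effects, group and
#' subgroup epistasis) from the genotype matrix, and should be treated as
#' synthetic stand-ins at the level of individual loci.
#'
#' @return data frame: `name`, `donor_species`, `linked_group`,
#'   `known_additive_effect`.
#' @export
ser_study_metadata <- function() {
  read_qtl_metadata(ser_fixture_path("qtl_metadata_reconstructed.tsv"))
}

#' Reconstructed single-QTL additive effects as a named vector
#'
#' @return named numeric vector, percentage points (see
#'   [ser_study_metadata()] for the reconstruction caveat).
#' @export
ser_study_effects <- function() {
  additive_effects_from_metadata(ser_study_metadata())
}

#' Published group-level trait summaries
#'
#' Mean SER of the HJX74 control and the 1- to 6-QTL groups over three
#' cropping seasons, as printed; standard errors were not published
#' numerically.
#'
#' @return `trait_summary` data frame.
#' @export
ser_study_group_summaries <- function() {
  read_trait_summaries(ser_fixture_path("group_summaries.csv"))
}

#' Published focal-QTL subgroup summaries
#'
#' Mean SER of the 2- to 4-QTL lines split by presence of `qSER3a-sat`,
#' with subgroup line counts, as printed.
#'
#' @return data frame: `group`, `subgroup`, `mean`, `n`.
#' @export
ser_study_focal_summaries <- function() {
  utils::read.csv(ser_fixture_path("focal_subgroup_summaries.csv"),
                  stringsAsFactors = FALSE)
}

#' Reconstructed single-QTL line summaries
#'
#' Pseudo 1-QTL-line trait summaries derived from the reconstructed
#' additive effects (`control mean + effect`), one per locus. The identities
#' of the actual SSSLs behind each published single-QTL mean are not
#' recoverable; these entries exist to exercise estimator plumbing that
#' needs per-SSSL summaries and are synthetic.
#'
#' @param P0 control mean used as the baseline.
#' @return `trait_summary` data frame with subjects `SSSL(<locus>)`.
#' @export
ser_study_ssl_summaries <- function(P0 = 29.2) {
  eff <- ser_study_effects()
  out <- data.frame(subject = paste0("SSSL(", names(eff), ")"),
                    mean = P0 + unname(eff), se = NA_real_, n = 3L,
                    scale = "raw_percent", stringsAsFactors = FALSE)
  class(out) <- c("trait_summary", "data.frame")
  out
}
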