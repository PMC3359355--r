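#' Validated codon-level SNV records (packaged fixture)
#'
#' The seven Sanger-validated coding SNVs used throughout the consequence
#' tests, stored at codon level (gene, codon index, reference codon,
#' mutated codon, amino acids, effect class) together with pass-through
#' annotation strings from external effect predictors. Genomic coordinates
#' refer to an older human assembly and are carried as labels only;
#' consequence computations run against gene models, not these
#' coordinates.
#'
#' @return \code{data.table} with one row per validated SNV.
#' @export
validated_snv_records <- function() {
  fread(system.file("extdata", "table1_validated_snvs.tsv",
                    package = "somaticpair"), sep = "\t")
}

#' The five validated coding indel records (packaged fixture)
#'
#' @return \code{data.table}: gene, contig, start, kind, sequence (and
#'   derived end).
#' @export
coding_indel_records <- function() {
  x <- fread(system.file("extdata", "coding_indels.tsv",
                         package = "somaticpair"), sep = "\t",
             colClasses = list(character = c("gene", "contig", "kind",
                                             "sequence"),
                               integer = "start"))
  x[, end := fifelse(kind == "deletion", start + nchar(sequence) - 1L,
                     start)]
  x[]
}

#' Path of the packaged longitudinal presence matrix
#'
#' @return Path to the TSV fixture for
#'   \code{\link{load_presence_matrix}}.
#' @export
presence_matrix_path <- function() {
  system.file("extdata", "table2_presence.tsv", package = "somaticpair")
}
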