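#' Published RAS amplification primer pairs
#'
#' The gene-specific touchdown-PCR primer pairs used for targeted
#' full-length amplification of KRAS, NRAS and HRAS transcripts (forward
#' primer in the first annotated exon, reverse primer in the last), shipped
#' as a plain-text input table.
#'
#' @return `data.frame(gene, direction, sequence)`.
#' @export
ras_primers <- function() {
  path <- system.file("extdata", "ras_primers.tsv", package = "splicescout",
                      mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = "character")
}

#' Path to the four-exon toy gene fixture
#'
#' A deterministic 4-exon toy locus (exon lengths 60/50/55/70 nt, introns
#' 40/45/50 nt, forward strand) shipped as exact FASTA + JSON files; the
#' k-mer dictionary over it is collision-free at the default parameters.
#'
#' @return Named list with `json` and `fasta` paths.
#' @export
toy4_paths <- function() {
  list(
    json = system.file("extdata", "toy4.json", package = "splicescout",
                       mustWork = TRUE),
    fasta = system.file("extdata", "toy4.fa", package = "splicescout",
                        mustWork = TRUE)
  )
}
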