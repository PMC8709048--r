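#!/usr/bin/env Rscript
# Stage 1: generate the three RAS-like targeted-amplicon datasets, in two
# sequencing regimes.
#
# Three synthetic genes mirror the targeted-RAS topology (6 exons with two
# alternative exon-1 5' forms; 7 exons; 7 exons with a retainable intron
# between the last two exons). Each carries its annotated transcript set,
# a panel of planted novel exon-skipping / intron-retention variants, and
# three sample pools with distinct abundances, sequenced as full-length
# amplicon reads. Two regimes are emitted: "clean" (error-free reads, the
# oracle regime in which detection should be lossless) and "nanopore"
# (about 6% per-base substitution/insertion/deletion errors plus end
# truncation), so later stages can contrast logical correctness with
# measured sensitivity under realistic errors. Outputs per regime/gene:
# model JSON + locus FASTA, annotated GFF3, per-sample FASTQ, truth tables.

suppressPackageStartupMessages(library(splicescout))

seed <- 20211210L %% 99999L
coverage <- 50L

regimes <- list(
  clean = list(sub_rate = 0, ins_rate = 0, del_rate = 0, trunc_prob = 0),
  nanopore = list(sub_rate = 0.015, ins_rate = 0.02, del_rate = 0.025,
                  trunc_prob = 0.05)
)

for (rg in names(regimes)) {
  rates <- regimes[[rg]]
  preset <- ras_like_preset(seed = seed, coverage = coverage,
                            sub_rate = rates$sub_rate,
                            ins_rate = rates$ins_rate,
                            del_rate = rates$del_rate,
                            trunc_prob = rates$trunc_prob)
  for (g in names(preset)) {
    setup <- preset[[g]]
    dir <- file.path("results", "sim", rg, gsub("[^A-Za-z0-9]", "_", g))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_gene_model_json(setup$model, file.path(dir, "model.json"))
    write_locus_fasta(setup$model, file.path(dir, "locus.fa"))
    write_transcripts_gff3(setup$model, setup$annotated,
                           file.path(dir, "annotated.gff3"))
    sim <- simulate_reads(setup$model, setup$cfg, dir)
    cat(sprintf("[%-8s] %-10s %d exons, %d annotated + %d planted novel, %d reads\n",
                rg, g, nrow(setup$model$exons), length(setup$annotated),
                length(setup$novel), nrow(sim$truth)))
  }
}
cat("simulated inputs written under results/sim/{clean,nanopore}\n")
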