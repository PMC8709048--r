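#!/usr/bin/env Rscript
# Stage 4: coding-potential annotation of the called transcripts.
#
# For every called structure: exhaustive forward-frame ORF scan of the
# mature mRNA, ORF selection (annotated initiation codon preferred, else
# the longest ORF), premature-termination-codon classification under the
# 50-nt last-junction rule (NMD candidates are treated as non-coding),
# and the micropeptide flag for coding products under 100 aa.

suppressPackageStartupMessages(library(splicescout))

dirs <- Filter(function(d) file.exists(file.path(d, "model.json")),
               list.dirs("results/sim", recursive = TRUE))
for (dir in dirs) {
  regime <- basename(dirname(dir))
  model <- load_gene_model(file.path(dir, "model.json"),
                           file.path(dir, "locus.fa"))
  annotated <- read_transcripts_gff3(file.path(dir, "annotated.gff3"), model)
  calls_structs <- read_transcripts_gff3(file.path(dir, "calls", "calls.gff3"),
                                         model)
  names(calls_structs) <- vapply(calls_structs, function(x) x$name, "")
  ann <- annotate_transcripts(calls_structs, model, min_len_aa = 10L)
  write_orf_outputs(ann, file.path(dir, "orfs.tsv"),
                    file.path(dir, "peptides.fasta"))
  cat(sprintf("[%-8s] %-10s %d transcripts: %d coding (%d micropeptides), %d NMD candidates, %d non-coding\n",
              regime, model$gene_name, nrow(ann),
              sum(ann$coding_status == "coding"), sum(ann$micropeptide),
              sum(ann$coding_status == "NMD_candidate"),
              sum(ann$coding_status == "non_coding")))
}
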