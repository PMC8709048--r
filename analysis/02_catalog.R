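#!/usr/bin/env Rscript
# Stage 2: build the junction k-mer detection catalogs.
#
# For each simulated gene: every possible splicing event between annotated
# exons becomes a set of 24-mers spanning the boundary at 9 offsets,
# introns are tiled for retention detection, amplicon anchors are tiled
# for full-length calling, and the dictionary is screened so only k-mers
# unique to their event survive. Reports the catalog composition.

suppressPackageStartupMessages(library(splicescout))

dirs <- Filter(function(d) file.exists(file.path(d, "model.json")),
               list.dirs("results/sim", recursive = TRUE))
for (dir in dirs) {
  regime <- basename(dirname(dir))
  model <- load_gene_model(file.path(dir, "model.json"),
                           file.path(dir, "locus.fa"))
  catal <- build_catalog(model)
  write_catalog(catal, file.path(dir, "catalog.tsv"))
  km <- catal$kmers
  cat(sprintf("[%-8s] %-10s %2d junctions  %3d junction k-mers  %2d intron tiles  %2d anchor tiles  %d ambiguous\n",
              regime, model$gene_name,
              nrow(unique(km[km$type == "junction", c("donor", "acceptor")])),
              sum(km$type == "junction"),
              sum(km$type == "intron_tile"),
              sum(km$type %in% c("anchor_first", "anchor_last")),
              sum(km$ambiguous)))
}
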