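## End-to-end orchestration: catalog -> scan -> call -> orf -> quant over
## one gene, with a machine-readable run manifest. All stage logic lives in
## the module functions; this is glue with provenance.

default_params <- function() {
  list(k = 24L, min_flank = 8L, stride = 12L, min_offsets = 2L,
       retention_frac = 0.8, min_support = 3L, min_len_aa = 25L,
       nmd_threshold = 50L, pseudocount = 0.5, denominator = "sum")
}

#' Run the full splice-variant pipeline
#'
#' Executes catalog construction, read scanning, variant calling, ORF
#' annotation and quantification over one gene, writing every intermediate
#' artifact plus a machine-readable manifest (package version, parameters,
#' input checksums, stage outputs) under `outdir`. Re-running on identical
#' inputs reproduces identical artifact checksums.
#'
#' @param config List (or path to a JSON file) with fields `model` (gene
#'   model JSON/GFF3 path), `fasta` (locus FASTA), `annotated` (GFF3 of
#'   annotated structures), `fastq` (named list/vector sample -> FASTQ
#'   path), `outdir`, optional `primers` (list with `forward`, `reverse`)
#'   and optional `params` overriding [default_params()].
#' @return Invisibly, a list with the loaded objects, result tables and
#'   written paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  for (f in c("model", "fasta", "annotated")) {
    if (is.null(config[[f]]) || !file.exists(config[[f]])) {
      stop("config field '", f, "' missing or file not found")
    }
  }
  fq <- unlist(config$fastq)
  if (is.null(fq) || is.null(names(fq)) || any(!file.exists(fq))) {
    stop("config field 'fastq' must name existing per-sample files")
  }
  outdir <- config$outdir
  if (is.null(outdir)) stop("config field 'outdir' missing")
  params <- utils::modifyList(default_params(), as.list(config$params))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  model <- load_gene_model(config$model, config$fasta)
  annotated <- read_transcripts_gff3(config$annotated, model)
  primers <- if (!is.null(config$primers)) {
    primer_pair(config$primers$forward, config$primers$reverse)
  }

  catalog <- build_catalog(model, k = params$k, min_flank = params$min_flank,
                           stride = params$stride, primers = primers)
  write_catalog(catalog, file.path(outdir, "catalog.tsv"))

  evidence <- scan_fastq(fq, catalog, model,
                         params = scan_params(params$min_offsets,
                                              params$retention_frac))
  write_evidence_tsv(evidence, file.path(outdir, "evidence.tsv"))

  calls <- call_variants(evidence, model, annotated,
                         min_support = params$min_support)
  call_files <- export_calls(calls, model, file.path(outdir, "calls"))

  orfs <- annotate_transcripts(calls, model, min_len_aa = params$min_len_aa,
                               nmd_threshold = params$nmd_threshold)
  write_orf_outputs(orfs, file.path(outdir, "orfs.tsv"),
                    file.path(outdir, "peptides.fasta"))

  quant <- quantify_variants(evidence, calls, pseudocount = params$pseudocount,
                             denominator = params$denominator)
  qdir <- file.path(outdir, "quant")
  dir.create(qdir, showWarnings = FALSE)
  utils::write.table(
    data.frame(variant = rownames(quant$counts), quant$counts,
               check.names = FALSE),
    file.path(qdir, "counts.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  utils::write.table(
    data.frame(sample = names(quant$size_factors),
               size_factor = as.numeric(quant$size_factors)),
    file.path(qdir, "size_factors.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  hm <- export_heatmap(quant$log2fc, qdir)

  manifest <- list(
    package = "splicescout",
    version = as.character(utils::packageVersion("splicescout")),
    parameters = params,
    inputs = as.list(tools::md5sum(c(model = config$model,
                                     fasta = config$fasta,
                                     annotated = config$annotated, fq))),
    stages = list(
      catalog = "catalog.tsv", scan = "evidence.tsv", call = "calls",
      orf = "orfs.tsv", quant = "quant"
    ),
    n_reads = nrow(evidence),
    n_calls = nrow(calls$calls)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(model = model, catalog = catalog, evidence = evidence,
                 calls = calls, orfs = orfs, quant = quant,
                 outdir = outdir, manifest = manifest,
                 files = c(call_files, hm)))
}
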