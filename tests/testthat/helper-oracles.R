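# Shared fixtures and independent oracles. Oracles deliberately avoid the
# package's own code paths: sequence slicing by hand, sliding-window
# scanning, explicit arithmetic.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc_str <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

toy4 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- toy4_paths()
      cache <<- load_gene_model(p$json, p$fasta)
    }
    cache
  }
})

toy4_catalog <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_catalog(toy4())
    cache
  }
})

# Naive sliding-window scanner: every active catalog row is searched at
# every read position, on both strands; orientation chosen like the
# scanner (more hits, ties forward).
naive_strand_hits <- function(seq, catalog) {
  km <- catalog$kmers
  act <- which(!km$ambiguous)
  L <- nchar(seq)
  rows <- integer(0); pos <- integer(0)
  subs_by_w <- list()
  for (i in act) {
    w <- nchar(km$sequence[i])
    if (L < w) next
    key <- as.character(w)
    if (is.null(subs_by_w[[key]])) {
      subs_by_w[[key]] <- substring(seq, 1:(L - w + 1L), w:L)
    }
    p <- which(subs_by_w[[key]] == km$sequence[i])
    if (length(p)) {
      rows <- c(rows, rep(i, length(p)))
      pos <- c(pos, p)
    }
  }
  data.frame(kmer_row = rows, position = pos)
}

naive_scan <- function(read, catalog) {
  hf <- naive_strand_hits(read, catalog)
  hr <- naive_strand_hits(rc_str(read), catalog)
  if (nrow(hr) > nrow(hf)) {
    list(orientation = "revcomp", hits = hr)
  } else {
    list(orientation = "forward", hits = hf)
  }
}

hit_set <- function(sc) {
  s <- sc$hits
  sort(paste(s$kmer_row, s$position))
}

write_fastq <- function(reads, path, ids = paste0("r", seq_along(reads))) {
  writeLines(as.vector(rbind(paste0("@", ids), reads, "+",
                             vapply(reads, function(r) strrep("I", nchar(r)),
                                    ""))),
             path)
  path
}

# one shared error-free simulation of the 6-exon two-5'-form setup, reused
# across caller/quantifier/generator tests (computed once per test run)
ef_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      preset <- ras_like_preset(seed = 11, coverage = 10, sub_rate = 0,
                                ins_rate = 0, del_rate = 0, trunc_prob = 0)
      g <- preset[["KRAS-like"]]
      sim <- simulate_reads(g$model, g$cfg, file.path(tempdir(), "ef_kras"))
      catal <- build_catalog(g$model)
      ev <- scan_fastq(sim$fastq, catal, g$model)
      calls <- call_variants(ev, g$model, g$annotated)
      cache <<- list(g = g, sim = sim, catalog = catal, evidence = ev,
                     calls = calls)
    }
    cache
  }
})
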