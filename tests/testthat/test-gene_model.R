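test_that("the toy fixture loads with the expected geometry", {
  m <- toy4()
  expect_s3_class(m, "gene_model")
  expect_equal(nrow(m$exons), 4L)
  expect_equal(m$exons$end - m$exons$start, c(60L, 50L, 55L, 70L))
  expect_equal(splicescout:::intron_lengths(m), c(40L, 45L, 50L))
})

test_that("spliced sequences have the lengths forced by the exon chain", {
  m <- toy4()
  expect_equal(nchar(spliced_sequence(m, transcript_structure("TOY4", 1:4))),
               235L)
  expect_equal(nchar(spliced_sequence(m, transcript_structure("TOY4", c(1, 4)))),
               130L)
  expect_equal(
    nchar(spliced_sequence(m, transcript_structure("TOY4", 1:4,
                                                   retained_introns = 3L))),
    285L
  )
})

test_that("spliced sequence equals an independent slice-and-join oracle", {
  m <- toy4()
  oracle <- paste(vapply(1:4, function(i)
    substr(m$locus_seq, m$exons$start[i] + 1L, m$exons$end[i]), ""),
    collapse = "")
  expect_identical(spliced_sequence(m, transcript_structure("TOY4", 1:4)),
                   oracle)
  # with retention: intron 2 sequence spliced in between exons 2 and 3
  oracle_ri <- paste(
    c(substr(m$locus_seq, m$exons$start[1] + 1L, m$exons$end[1]),
      substr(m$locus_seq, m$exons$start[2] + 1L, m$exons$end[2]),
      substr(m$locus_seq, m$exons$end[2] + 1L, m$exons$start[3]),
      substr(m$locus_seq, m$exons$start[3] + 1L, m$exons$end[3]),
      substr(m$locus_seq, m$exons$start[4] + 1L, m$exons$end[4])),
    collapse = "")
  expect_identical(
    spliced_sequence(m, transcript_structure("TOY4", 1:4,
                                             retained_introns = 2L)),
    oracle_ri
  )
})

test_that("a minus-strand mirror of the model yields the identical mRNA", {
  m <- toy4()
  L <- nchar(m$locus_seq)
  ex <- m$exons
  mirrored <- data.frame(exon_id = 1:4,
                         start = L - ex$end,
                         end = L - ex$start)
  mm <- gene_model("TOY4", mirrored, "-", rc_str(m$locus_seq))
  for (chain in list(1:4, c(1, 4), c(1, 3, 4))) {
    expect_identical(
      spliced_sequence(mm, transcript_structure("TOY4", chain)),
      spliced_sequence(m, transcript_structure("TOY4", chain))
    )
  }
  expect_identical(
    spliced_sequence(mm, transcript_structure("TOY4", 1:4,
                                              retained_introns = 2L)),
    spliced_sequence(m, transcript_structure("TOY4", 1:4,
                                             retained_introns = 2L))
  )
})

test_that("invalid models are rejected with the offending record named", {
  m <- toy4()
  bad <- m$exons
  bad$start[3] <- bad$start[3] - 60L   # overlap exon 2
  expect_error(gene_model("X", bad, "+", m$locus_seq), "overlap")
  oob <- m$exons
  oob$end[4] <- nchar(m$locus_seq) + 10L
  expect_error(gene_model("X", oob, "+", m$locus_seq), "out of bounds")
  expect_error(gene_model("X", m$exons, "*", m$locus_seq), "strand")
  expect_error(gene_model("X", m$exons[1, , drop = FALSE], "+", m$locus_seq),
               ">= 2 exons")
})

test_that("structure invariants are enforced", {
  m <- toy4()
  expect_error(validate_structure(transcript_structure("TOY4", c(2, 3, 4)), m),
               "start at exon 1")
  expect_error(validate_structure(transcript_structure("TOY4", c(1, 2)), m),
               "end at exon 4")
  # retained intron whose flanks are not adjacent in the chain
  expect_error(
    spliced_sequence(m, transcript_structure("TOY4", c(1, 2, 4),
                                             retained_introns = 2L)),
    "retained intron"
  )
})

test_that("intron count is exon count minus one across random models", {
  set.seed(42)
  for (n in 2:8) {
    len <- 30L
    starts <- cumsum(c(10L, rep(len + 15L, n - 1L)))
    ex <- data.frame(exon_id = seq_len(n), start = starts,
                     end = starts + len)
    m <- gene_model(paste0("G", n), ex, "+",
                    rand_dna(max(ex$end) + 10L))
    expect_equal(length(splicescout:::intron_lengths(m)), n - 1L)
  }
})

test_that("JSON + FASTA round trip is lossless", {
  m <- toy4()
  j <- tempfile(fileext = ".json")
  f <- tempfile(fileext = ".fa")
  write_gene_model_json(m, j)
  write_locus_fasta(m, f)
  m2 <- load_gene_model(j, f)
  expect_identical(m2$exons, m$exons)
  expect_identical(m2$locus_seq, m$locus_seq)
  expect_identical(m2$alt_first_exon_starts, m$alt_first_exon_starts)
  expect_identical(m2$strand, m$strand)
  expect_identical(m2$gene_name, m$gene_name)
})

test_that("transcript GFF3 export round-trips structures", {
  m <- toy4()
  sts <- list(
    transcript_structure("TOY4", 1:4, name = "t1", status = "annotated"),
    transcript_structure("TOY4", c(1, 3, 4), name = "t2", status = "novel"),
    transcript_structure("TOY4", 1:4, retained_introns = 3L, name = "t3",
                         status = "novel")
  )
  p <- tempfile(fileext = ".gff3")
  write_transcripts_gff3(m, sts, p)
  back <- read_transcripts_gff3(p, m)
  expect_equal(vapply(back, structure_key, ""),
               vapply(sts, structure_key, ""))
  expect_equal(vapply(back, function(x) x$name, ""), c("t1", "t2", "t3"))
  # empty set: valid GFF3 with header only
  p0 <- tempfile(fileext = ".gff3")
  write_transcripts_gff3(m, list(), p0)
  expect_identical(readLines(p0), "##gff-version 3")
  expect_length(read_transcripts_gff3(p0, m), 0L)
})

test_that("amplicon anchors come from unique primer sites", {
  m <- toy4()
  e1 <- exon_seq(m, 1L)
  e4 <- exon_seq(m, 4L)
  pp <- primer_pair(substr(e1, 1, 20), rc_str(substr(e4, 51, 70)))
  amp <- define_amplicon(m, pp)
  expect_identical(amp$first_anchor, e1)
  expect_identical(amp$last_anchor, e4)
  expect_equal(amp$first_offset, 0L)
  # interior primer: anchor runs from the site to the exon boundary
  pp2 <- primer_pair(substr(e1, 11, 30), rc_str(substr(e4, 51, 70)))
  expect_identical(define_amplicon(m, pp2)$first_anchor,
                   substr(e1, 11, nchar(e1)))
  expect_error(primer_pair("ACGTN", "ACGT"), "\\{A,C,G,T\\}")
  expect_error(primer_pair("", "ACGT"), "empty|\\{A,C,G,T\\}")
  # ambiguous primer site: occurs twice
  dup <- paste0(substr(e1, 1, 25), substr(e1, 1, 25), substr(e1, 51, 60))
  ex <- m$exons
  locus2 <- paste0(substr(m$locus_seq, 1L, ex$start[1]), dup,
                   substr(m$locus_seq, ex$end[1] + 1L, nchar(m$locus_seq)))
  m2 <- gene_model("TOY4", ex, "+", locus2)
  expect_error(define_amplicon(m2, primer_pair(substr(e1, 1, 20),
                                               rc_str(substr(e4, 51, 70)))),
               "found 2 times")
})

test_that("genomic coordinates map through structures correctly", {
  m <- toy4()
  ts <- transcript_structure("TOY4", c(1, 3, 4))
  # first base of exon 3 sits right after exon 1 in this chain
  expect_equal(genomic_to_mrna(m, ts, m$exons$start[3]), 60L)
  # a base inside skipped exon 2 is absent
  expect_true(is.na(genomic_to_mrna(m, ts, m$exons$start[2] + 5L)))
  # retained intron bases are part of the mRNA
  ts_ri <- transcript_structure("TOY4", 1:4, retained_introns = 2L)
  expect_equal(genomic_to_mrna(m, ts_ri, m$exons$end[2]), 110L)
})
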