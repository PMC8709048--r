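test_that("splice-event enumeration covers all exon pairs", {
  set.seed(7)
  for (n in c(2L, 3L, 6L, 7L, 12L)) {
    len <- 30L
    starts <- cumsum(c(5L, rep(len + 12L, n - 1L)))
    m <- gene_model(paste0("G", n),
                    data.frame(exon_id = seq_len(n), start = starts,
                               end = starts + len),
                    "+", rand_dna(max(starts) + len + 5L))
    ev <- enumerate_splice_events(m)
    expect_equal(nrow(ev), n * (n - 1L) / 2L)
    expect_equal(sum(ev$kind == "adjacent"), n - 1L)
    expect_true(all(ev$donor < ev$acceptor))
  }
})

test_that("junction k-mers reconstruct from donor suffix and acceptor prefix", {
  m <- toy4()
  jk <- build_junction_kmers(m, 1L, 2L, k = 24L, min_flank = 8L)
  expect_equal(nrow(jk), 9L)   # 24 - 16 + 1 offsets
  d <- exon_seq(m, 1L); a <- exon_seq(m, 2L)
  for (i in seq_len(nrow(jk))) {
    o <- jk$offset[i]
    expect_identical(jk$sequence[i],
                     paste0(substr(d, nchar(d) - o + 1L, nchar(d)),
                            substr(a, 1L, 24L - o)))
  }
  # k=12, m=6: the single offset-6 k-mer joins the flanks of (1,3)
  jk13 <- build_junction_kmers(m, 1L, 3L, k = 12L, min_flank = 6L)
  expect_equal(nrow(jk13), 1L)
  e3 <- exon_seq(m, 3L)
  expect_identical(jk13$sequence,
                   paste0(substr(d, nchar(d) - 5L, nchar(d)),
                          substr(e3, 1L, 6L)))
  expect_error(build_junction_kmers(m, 1L, 3L, k = 12L, min_flank = 7L),
               "exceeds k")
})

test_that("short exons skip unusable offsets and fail only when none remain", {
  set.seed(9)
  # exon 2 of length 5: donor-side offsets > 5 must be skipped
  starts <- c(10L, 80L, 120L)
  m <- gene_model("SHORT",
                  data.frame(exon_id = 1:3, start = starts,
                             end = starts + c(40L, 5L, 40L)),
                  "+", rand_dna(200L))
  jk <- build_junction_kmers(m, 2L, 3L, k = 24L, min_flank = 2L)
  expect_true(all(jk$offset <= 5L))
  expect_equal(nrow(jk), 4L)   # offsets 2..5 usable
  expect_error(build_junction_kmers(m, 2L, 3L, k = 24L, min_flank = 6L),
               "no usable boundary offset", fixed = FALSE)
})

test_that("intron tiling covers introns with a right-aligned final tile", {
  m <- toy4()
  tiles3 <- build_intron_tiles(m, k = 24L, stride = 12L)
  t3 <- tiles3[tiles3$intron_id == 3L, ]
  expect_equal(nrow(t3), 4L)   # intron length 50: starts 0, 12, 24, 26
  iseq <- intron_seq(m, 3L)
  oracle_starts <- c(0L, 12L, 24L, 26L)
  expect_identical(t3$sequence,
                   vapply(oracle_starts, function(s)
                     substr(iseq, s + 1L, s + 24L), ""))
  expect_false(any(t3$short))

  # intron exactly k long: one tile; intron shorter than k: one short tile
  set.seed(3)
  starts <- c(5L, 59L, 99L)
  m2 <- gene_model("T2",
                   data.frame(exon_id = 1:3, start = starts,
                              end = starts + 30L),
                   "+", rand_dna(160L))
  tiles <- build_intron_tiles(m2, k = 24L, stride = 12L)
  expect_equal(sum(tiles$intron_id == 1L), 1L)     # 24-nt intron
  expect_false(tiles$short[tiles$intron_id == 1L])
  t2 <- tiles[tiles$intron_id == 2L, ]             # 10-nt intron
  expect_equal(nrow(t2), 1L)
  expect_true(t2$short)
  expect_equal(nchar(t2$sequence), 10L)
})

test_that("the toy catalog screens clean and flags constructed collisions", {
  cat_ <- toy4_catalog()
  expect_true(cat_$screened)
  expect_equal(sum(cat_$kmers$ambiguous), 0L)

  # exons 2 and 3 sharing a 24-nt prefix: acceptor-side k-mers collide
  m <- toy4()
  ex <- m$exons
  shared <- substr(exon_seq(m, 2L), 1, 24)
  locus <- m$locus_seq
  substr(locus, ex$start[3] + 1L, ex$start[3] + 24L) <- shared
  m2 <- gene_model("COLL", ex, "+", locus)
  cat2 <- suppressWarnings(build_catalog(m2))
  amb <- cat2$kmers[cat2$kmers$ambiguous & cat2$kmers$type == "junction", ]
  expect_true(nrow(amb) > 0L)
  expect_true(all(amb$acceptor %in% c(2L, 3L)))

  # a junction k-mer planted inside an intron is flagged
  jk <- build_junction_kmers(m, 1L, 3L, k = 24L, min_flank = 8L)$sequence[1]
  locus3 <- m$locus_seq
  substr(locus3, ex$end[3] + 5L, ex$end[3] + 28L) <- jk
  m3 <- gene_model("COLL2", ex, "+", locus3)
  cat3 <- suppressWarnings(build_catalog(m3))
  expect_true(any(cat3$kmers$ambiguous &
                  cat3$kmers$type == "junction" &
                  cat3$kmers$donor == 1L & cat3$kmers$acceptor == 3L))
})

test_that("retained k-mers occur exactly once in the cDNAs they witness", {
  m <- toy4()
  cat_ <- toy4_catalog()
  km <- cat_$kmers
  jx <- unique(km[km$type == "junction" & !km$ambiguous,
                  c("donor", "acceptor")])
  count_occ <- function(needle, hay) {
    w <- nchar(needle)
    sum(substring(hay, 1:(nchar(hay) - w + 1L), w:nchar(hay)) == needle)
  }
  for (i in seq_len(nrow(jx))) {
    d <- jx$donor[i]; a <- jx$acceptor[i]
    chain <- sort(unique(c(1L, seq_len(d), a, seq(a, 4L))))
    cdna <- spliced_sequence(m, transcript_structure("TOY4", chain))
    seqs <- km$sequence[km$type == "junction" & !km$ambiguous &
                        km$donor == d & km$acceptor == a]
    for (s in seqs) expect_equal(count_occ(s, cdna), 1L)
  }
})

test_that("catalog construction is deterministic and serializable", {
  m <- toy4()
  # round-trip the model, rebuild: identical catalog
  j <- tempfile(fileext = ".json"); f <- tempfile(fileext = ".fa")
  write_gene_model_json(m, j); write_locus_fasta(m, f)
  c1 <- toy4_catalog()
  c2 <- build_catalog(load_gene_model(j, f))
  expect_identical(c1$kmers, c2$kmers)
  # TSV + sidecar round trip
  p <- tempfile(fileext = ".tsv")
  write_catalog(c1, p)
  c3 <- read_catalog(p)
  expect_equal(c3$kmers$sequence, c1$kmers$sequence)
  expect_equal(c3$kmers$ambiguous, c1$kmers$ambiguous)
  expect_equal(c3$k, c1$k)
})
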