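test_that("an exact skipping read yields every offset of its junctions", {
  m <- toy4()
  cat_ <- toy4_catalog()
  read <- spliced_sequence(m, transcript_structure("TOY4", c(1, 3, 4)))
  sc <- scan_read(read, cat_)
  expect_equal(sc$orientation, "forward")
  km <- cat_$kmers
  got <- km[sc$hits$kmer_row, ]
  jx <- unique(got[got$type == "junction", c("donor", "acceptor")])
  expect_equal(unname(as.matrix(jx)), rbind(c(1L, 3L), c(3L, 4L)),
               ignore_attr = TRUE)
  # all 9 offsets of each junction present, at positions matching the
  # boundary location
  for (d in c(1L, 3L)) {
    sel <- got$type == "junction" & got$donor == d
    expect_equal(sort(got$offset[sel]), 8:16)
    boundary <- if (d == 1L) 60L else 115L   # nt upstream of the boundary
    expect_equal(sort(sc$hits$position[sel]),
                 sort(boundary - got$offset[sel] + 1L))
  }
})

test_that("reverse-complement reads give the same evidence", {
  m <- toy4()
  cat_ <- toy4_catalog()
  for (chain in list(c(1, 2, 3, 4), c(1, 3, 4), c(1, 4))) {
    read <- spliced_sequence(m, transcript_structure("TOY4", chain))
    ev_f <- chain_hits(scan_read(read, cat_), cat_)
    ev_r <- chain_hits(scan_read(rc_str(read), cat_), cat_)
    expect_equal(ev_r$orientation, "revcomp")
    expect_identical(structure_key(evidence_to_structure(ev_f, m)),
                     structure_key(evidence_to_structure(ev_r, m)))
  }
})

test_that("reads of N and hitless reads produce empty evidence", {
  cat_ <- toy4_catalog()
  sc <- scan_read(strrep("N", 300), cat_)
  expect_equal(nrow(sc$hits), 0L)
  ev <- chain_hits(sc, cat_)
  expect_false(ev$has_first_anchor || ev$has_last_anchor)
  expect_false(ev$conflict)
  expect_null(evidence_to_structure(ev, toy4()))
})

test_that("the scanner equals the naive sliding-window oracle", {
  m <- toy4()
  cat_ <- toy4_catalog()
  set.seed(77)
  reads <- character(0)
  chains <- list(1:4, c(1, 2, 4), c(1, 3, 4), c(1, 4))
  for (i in 1:40) {
    if (i %% 2L == 0L) {
      reads <- c(reads, rand_dna(sample(60:400, 1)))
    } else {
      ts <- transcript_structure("TOY4", chains[[1L + (i %% 4L)]])
      r <- spliced_sequence(m, ts)
      # sprinkle a few substitutions
      nmut <- sample(0:8, 1)
      if (nmut) {
        pos <- sample(nchar(r), nmut)
        for (p in pos) substr(r, p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
      if (runif(1) < 0.5) r <- rc_str(r)
      reads <- c(reads, r)
    }
  }
  scans <- splicescout:::scan_reads_batch(reads, cat_)
  for (i in seq_along(reads)) {
    oracle <- naive_scan(reads[i], cat_)
    expect_identical(scans[[i]]$orientation, oracle$orientation)
    expect_identical(hit_set(scans[[i]]), hit_set(oracle))
  }
})

test_that("chaining keeps collinear junctions and full-length anchoring", {
  m <- toy4()
  cat_ <- toy4_catalog()
  read <- spliced_sequence(m, transcript_structure("TOY4", c(1, 2, 4)))
  ev <- chain_hits(scan_read(read, cat_), cat_, read_id = "r1")
  expect_false(ev$conflict)
  expect_true(ev$has_first_anchor && ev$has_last_anchor)
  expect_equal(unname(as.matrix(ev$junctions)),
               rbind(c(1L, 2L), c(2L, 4L)), ignore_attr = TRUE)
  st <- evidence_to_structure(ev, m)
  expect_equal(st$exon_chain, c(1L, 2L, 4L))
})

test_that("contradictory junction evidence marks the read conflicted", {
  m <- toy4()
  cat_ <- toy4_catalog()
  km <- cat_$kmers
  grab <- function(d, a, n = 3) {
    head(km$sequence[km$type == "junction" & km$donor == d &
                     km$acceptor == a & !km$ambiguous], n)
  }
  # k-mers of (1,2) and of (1,3) in one molecule cannot coexist
  read <- paste(c(grab(1, 2), strrep("N", 10), grab(1, 3)), collapse = "")
  ev <- chain_hits(scan_read(read, cat_), cat_)
  expect_true(ev$conflict)
  expect_null(evidence_to_structure(ev, m))
})

test_that("planted intron retention is called from tile coverage", {
  m <- toy4()
  cat_ <- toy4_catalog()
  ts <- transcript_structure("TOY4", 1:4, retained_introns = 3L)
  read <- spliced_sequence(m, ts)
  ev <- chain_hits(scan_read(read, cat_), cat_)
  expect_equal(ev$retained_intron_calls, 3L)
  expect_false(ev$conflict)
  st <- evidence_to_structure(ev, m)
  expect_identical(structure_key(st), structure_key(ts))
  # retention call requires most of the intron, not a sliver: a read with
  # only the first intron tile present stays unretained
  part <- paste0(
    spliced_sequence(m, transcript_structure("TOY4", c(1, 2, 3, 4))),
    strrep("N", 5),
    substr(intron_seq(m, 3L), 1, 24)
  )
  ev2 <- chain_hits(scan_read(part, cat_), cat_)
  expect_length(ev2$retained_intron_calls, 0L)
})

test_that("anchors without junction evidence cannot invent a structure", {
  m <- toy4()
  cat_ <- toy4_catalog()
  read <- paste0(exon_seq(m, 1L), strrep("N", 30), exon_seq(m, 4L))
  ev <- chain_hits(scan_read(read, cat_), cat_)
  expect_true(ev$has_first_anchor && ev$has_last_anchor)
  expect_equal(nrow(ev$junctions), 0L)
  expect_null(evidence_to_structure(ev, m))
})

test_that("substitution errors never create structures absent error-free", {
  m <- toy4()
  cat_ <- toy4_catalog()
  set.seed(123)
  chains <- list(1:4, c(1, 2, 4), c(1, 3, 4), c(1, 4))
  for (rep_i in 1:30) {
    ts <- transcript_structure("TOY4", chains[[1L + (rep_i %% 4L)]])
    clean <- spliced_sequence(m, ts)
    key_clean <- structure_key(ts)
    noisy <- clean
    pos <- sample(nchar(noisy), max(1L, round(0.02 * nchar(noisy))))
    for (p in pos) substr(noisy, p, p) <- sample(c("A", "C", "G", "T"), 1)
    ev <- chain_hits(scan_read(noisy, cat_), cat_)
    st <- evidence_to_structure(ev, m)
    if (!is.null(st)) expect_identical(structure_key(st), key_clean)
  }
})
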