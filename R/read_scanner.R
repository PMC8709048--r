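## Read scanning: exact detection of catalog k-mers in long reads
## (Biostrings dictionary matching), chaining of per-read hits into a
## consistent junction path, full-length anchoring and intron-retention
## calling. Conflicting evidence (chimeric or ambiguous reads) is data, not
## an error: such reads are flagged and never create structure calls.

#' Scanner parameter set
#'
#' @param min_offsets Distinct boundary offsets required to call a junction
#'   within one read (default 2; single-offset hits on error-prone reads
#'   risk chance matches).
#' @param retention_frac Fraction of an intron's unambiguous tiles that must
#'   hit to call the intron retained in a read (default 0.8).
#' @return Named list of scanner parameters.
#' @export
scan_params <- function(min_offsets = 2L, retention_frac = 0.8) {
  stopifnot(min_offsets >= 1L, retention_frac > 0, retention_frac <= 1)
  list(min_offsets = as.integer(min_offsets), retention_frac = retention_frac)
}

active_kmers <- function(catalog) {
  if (!catalog$screened) stop("catalog must be screened before scanning")
  which(!catalog$kmers$ambiguous)
}

## Precompiled dictionary for fast scanning: a Biostrings PDict over the
## constant-width entries plus the (rare) short tiles kept separately.
catalog_pdict <- function(catalog) {
  idx <- active_kmers(catalog)
  km <- catalog$kmers[idx, ]
  wk <- nchar(km$sequence) == catalog$k
  list(
    idx_k = idx[wk],
    pdict = if (any(wk)) Biostrings::PDict(km$sequence[wk]) else NULL,
    idx_short = idx[!wk],
    short_seqs = km$sequence[!wk]
  )
}

## Batch detection: all reads of a sample plus their reverse complements
## are concatenated with N spacers into one subject so the whole dictionary
## is matched in a single pass (k-mers are ACGT-only, so no match can cross
## a spacer); hits are then binned back to (read, orientation) by position.
scan_reads_batch <- function(reads, catalog, dict = NULL) {
  if (is.null(dict)) dict <- catalog_pdict(catalog)
  n <- length(reads)
  if (!n) {
    return(list())
  }
  if (any(!nzchar(reads))) stop("empty read")
  rcs <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(reads)))
  spacer_len <- max(catalog$k, 2L)
  segs <- as.vector(rbind(reads, rcs))            # r1, rc1, r2, rc2, ...
  widths <- nchar(segs)
  offsets <- cumsum(c(0L, (widths + spacer_len)[-length(widths)]))
  subject <- Biostrings::DNAString(
    paste(segs, collapse = strrep("N", spacer_len)))

  all_rows <- integer(0)
  all_pos <- integer(0)
  if (!is.null(dict$pdict)) {
    m <- Biostrings::matchPDict(dict$pdict, subject)
    st <- Biostrings::startIndex(m)
    nh <- lengths(st)
    if (sum(nh)) {
      all_rows <- rep(dict$idx_k, nh)
      all_pos <- unlist(st[nh > 0L], use.names = FALSE)
    }
  }
  if (length(dict$idx_short)) {
    for (i in seq_along(dict$idx_short)) {
      mm <- Biostrings::matchPattern(dict$short_seqs[i], subject)
      if (length(mm)) {
        all_rows <- c(all_rows, rep(dict$idx_short[i], length(mm)))
        all_pos <- c(all_pos, BiocGenerics::start(mm))
      }
    }
  }

  seg_of <- findInterval(all_pos - 1L, offsets)    # 1-based segment index
  local_pos <- all_pos - offsets[seg_of]
  read_idx <- (seg_of + 1L) %/% 2L
  is_rc <- seg_of %% 2L == 0L

  by_read <- split(seq_along(read_idx), factor(read_idx, levels = seq_len(n)))
  out <- vector("list", n)
  for (r in seq_len(n)) {
    ii <- by_read[[r]]
    sel_f <- ii[!is_rc[ii]]
    sel_r <- ii[is_rc[ii]]
    if (length(sel_r) > length(sel_f)) {
      out[[r]] <- list(orientation = "revcomp",
                       hits = data.frame(kmer_row = all_rows[sel_r],
                                         position = local_pos[sel_r]))
    } else {
      out[[r]] <- list(orientation = "forward",
                       hits = data.frame(kmer_row = all_rows[sel_f],
                                         position = local_pos[sel_f]))
    }
  }
  out
}

#' Detect catalog k-mers in one read
#'
#' Finds every exact occurrence of the unambiguous catalog k-mers in the
#' read and in its reverse complement; the orientation with more hits wins
#' (ties go forward) and only that orientation's hits are returned, with
#' positions on the chosen strand.
#'
#' @param read Nucleotide string.
#' @param catalog A screened `junction_catalog`.
#' @param dict Optional precompiled dictionary (internal reuse across reads).
#' @return List with `orientation` (`"forward"` or `"revcomp"`) and `hits`,
#'   a `data.frame(kmer_row, position)` indexing `catalog$kmers` rows.
#' @export
scan_read <- function(read, catalog, dict = NULL) {
  scan_reads_batch(read, catalog, dict)[[1L]]
}

## distinct-offset support per junction from a hit table
junction_support <- function(hits, km) {
  jr <- which(km$type[hits$kmer_row] == "junction")
  if (!length(jr)) {
    return(data.frame(donor = integer(0), acceptor = integer(0),
                      n_offsets = integer(0), pos = numeric(0)))
  }
  rows <- hits$kmer_row[jr]
  d <- km$donor[rows]; a <- km$acceptor[rows]; o <- km$offset[rows]
  p <- hits$position[jr]
  sp <- split(seq_along(d), d * 10000L + a)
  dd <- vapply(sp, function(ii) d[ii[1]], 0L)
  aa <- vapply(sp, function(ii) a[ii[1]], 0L)
  no <- vapply(sp, function(ii) length(unique(o[ii])), 0L)
  pm <- vapply(sp, function(ii) stats::median(p[ii]), 0)
  ord <- order(dd, aa)
  data.frame(donor = dd[ord], acceptor = aa[ord], n_offsets = no[ord],
             pos = pm[ord], row.names = NULL)
}

#' Chain the k-mer hits of one read into read-level evidence
#'
#' Junctions supported by at least `min_offsets` distinct boundary offsets
#' are kept; an intron is called retained when at least `retention_frac` of
#' its unambiguous tiles hit. Kept junctions and retention calls must
#' describe a single molecule: a junction (i,j) and a retention both provide
#' an i -> j adjacency edge, and the edge set must be pairwise chainable
#' (no shared donors/acceptors, no interleaving, and no simultaneous spliced
#' junction and retention over the same intron); violations set
#' `conflict = TRUE`. Anchor-tile hits set the full-length flags, and
#' alternative exon-1 start probes record which 5' form the read carries.
#'
#' @param scan Result of [scan_read()].
#' @param catalog A screened `junction_catalog`.
#' @param params A [scan_params()] list.
#' @param read_id Identifier carried into the evidence.
#' @return An object of class `read_evidence`.
#' @export
chain_hits <- function(scan, catalog, params = scan_params(),
                       read_id = NA_character_) {
  km <- catalog$kmers
  hits <- scan$hits
  js <- junction_support(hits, km)
  kept <- js[js$n_offsets >= params$min_offsets, , drop = FALSE]

  ## intron retention: fraction of unambiguous tiles present
  tiles_all <- km[km$type == "intron_tile" & !km$ambiguous, , drop = FALSE]
  tile_hits <- hits[km$type[hits$kmer_row] == "intron_tile", , drop = FALSE]
  retained <- integer(0)
  ret_pos <- numeric(0)
  for (i in unique(tiles_all$intron_id)) {
    tot <- sum(tiles_all$intron_id == i)
    rows <- tile_hits[km$intron_id[tile_hits$kmer_row] == i, , drop = FALSE]
    got <- length(unique(km$tile_index[rows$kmer_row]))
    if (tot > 0L && got / tot >= params$retention_frac) {
      retained <- c(retained, i)
      ret_pos <- c(ret_pos, stats::median(rows$position))
    }
  }

  conflict <- FALSE
  ## retention and spliced junction over the same intron are mutually
  ## exclusive in one molecule
  if (length(retained) &&
      any(kept$acceptor == kept$donor + 1L & kept$donor %in% retained)) {
    conflict <- TRUE
  }
  ## edges: junctions + retention adjacencies
  edges <- rbind(
    if (nrow(kept)) data.frame(donor = kept$donor, acceptor = kept$acceptor,
                               pos = kept$pos, from_retention = FALSE),
    if (length(retained)) data.frame(donor = retained,
                                     acceptor = retained + 1L,
                                     pos = ret_pos, from_retention = TRUE)
  )
  if (is.null(edges)) {
    edges <- data.frame(donor = integer(0), acceptor = integer(0),
                        pos = numeric(0), from_retention = logical(0))
  }
  edges <- edges[order(edges$donor, edges$acceptor), , drop = FALSE]
  if (nrow(edges) > 1L) {
    for (i in seq_len(nrow(edges) - 1L)) {
      if (edges$donor[i + 1L] == edges$donor[i] ||
          edges$acceptor[i + 1L] == edges$acceptor[i] ||
          edges$donor[i + 1L] < edges$acceptor[i]) {
        conflict <- TRUE
      }
    }
    ## collinearity: hit positions must increase with exon order
    if (!conflict && is.unsorted(edges$pos, strictly = FALSE)) {
      conflict <- TRUE
    }
  }

  ty <- km$type[hits$kmer_row]
  probes <- sort(unique(km$variant[hits$kmer_row[ty == "alt_start_probe"]]))
  structure(
    list(
      read_id = read_id,
      orientation = scan$orientation,
      junctions = kept[, c("donor", "acceptor")],
      edges = edges,
      retained_intron_calls = retained,
      has_first_anchor = any(ty == "anchor_first"),
      has_last_anchor = any(ty == "anchor_last"),
      probe_variants = probes,
      conflict = conflict,
      n_hits = nrow(hits)
    ),
    class = "read_evidence"
  )
}

#' @export
print.read_evidence <- function(x, ...) {
  cat("<read_evidence> ", ifelse(is.na(x$read_id), "?", x$read_id),
      " [", x$orientation, "] junctions: ",
      if (nrow(x$junctions))
        paste(paste0("(", x$junctions$donor, ",", x$junctions$acceptor, ")"),
              collapse = " ") else "none",
      "; anchors ", x$has_first_anchor, "/", x$has_last_anchor,
      "; conflict ", x$conflict, "\n", sep = "")
  invisible(x)
}

#' Reconstruct a transcript structure from read evidence
#'
#' A junction (i, j) asserts that exons i and j are adjacent in the mature
#' mRNA (skipping everything between); a retention call asserts exon i,
#' the intron, and exon i+1 are contiguous. The exon chain is rebuilt by
#' walking these adjacency edges from exon 1 to the last exon. Interior
#' exons are never filled in silently: if the walk hits an exon with no
#' observed outgoing edge before reaching the last exon, the read is
#' unresolvable and `NULL` is returned. Reads that are not full-length
#' (both anchors) or are conflicted also return `NULL`. With several
#' alternative exon-1 forms, the 5'-most form whose probe k-mer was seen is
#' assigned; a read with no probe hit is unresolvable.
#'
#' @param ev A `read_evidence`.
#' @param model The `gene_model`.
#' @return A `transcript_structure`, or `NULL`.
#' @export
evidence_to_structure <- function(ev, model) {
  if (ev$conflict || !ev$has_first_anchor || !ev$has_last_anchor) {
    return(NULL)
  }
  n <- n_exons(model)
  edges <- ev$edges
  chain <- 1L
  retained <- integer(0)
  cur <- 1L
  while (cur != n) {
    nxt <- which(edges$donor == cur)
    if (length(nxt) != 1L) return(NULL)   # gap (or conflict already flagged)
    if (edges$from_retention[nxt]) retained <- c(retained, cur)
    cur <- edges$acceptor[nxt]
    chain <- c(chain, cur)
  }
  ## leftover edges whose donor never appeared on the walk would mean
  ## inconsistent evidence; the pairwise chainability check makes this
  ## impossible without a prior conflict, but guard anyway
  if (any(!edges$donor %in% chain[-length(chain)])) return(NULL)

  alt <- model$alt_first_exon_starts
  fev <- 1L
  if (length(alt) > 1L) {
    if (!length(ev$probe_variants)) return(NULL)
    fev <- min(ev$probe_variants)
  }
  transcript_structure(model$gene_name, chain, retained, fev)
}

#' Scan FASTQ samples into a per-read evidence table
#'
#' Runs [scan_read()], [chain_hits()] and [evidence_to_structure()] over
#' every read of every sample and tabulates the results; this table is the
#' input to [call_variants()] and [build_count_matrix()].
#'
#' @param fastq_files Named character vector: `sample name -> FASTQ path`
#'   (plain or gzipped).
#' @param catalog A screened `junction_catalog`.
#' @param model The `gene_model`.
#' @param params A [scan_params()] list.
#' @return `data.frame` with one row per read: `read_id`, `sample`,
#'   `orientation`, `n_hits`, `full_length`, `conflict`, `resolvable`,
#'   `key` (structure key or `NA`), `chain`, `retained`, `fev`.
#' @export
scan_fastq <- function(fastq_files, catalog, model, params = scan_params()) {
  if (is.null(names(fastq_files)) || any(!nzchar(names(fastq_files)))) {
    stop("fastq_files must be a named vector (sample -> path)")
  }
  dict <- catalog_pdict(catalog)
  out <- list()
  for (s in names(fastq_files)) {
    reads <- Biostrings::readDNAStringSet(fastq_files[[s]], format = "fastq")
    ids <- sub("\\s.*$", "", names(reads))
    scans <- scan_reads_batch(as.character(reads), catalog, dict = dict)
    for (i in seq_along(scans)) {
      ev <- chain_hits(scans[[i]], catalog, params = params, read_id = ids[i])
      ts <- evidence_to_structure(ev, model)
      out[[length(out) + 1L]] <- data.frame(
        read_id = ids[i], sample = s, orientation = ev$orientation,
        n_hits = ev$n_hits,
        full_length = ev$has_first_anchor && ev$has_last_anchor,
        conflict = ev$conflict,
        resolvable = !is.null(ts),
        key = if (is.null(ts)) NA_character_ else structure_key(ts),
        chain = if (is.null(ts)) NA_character_
                else paste(ts$exon_chain, collapse = "-"),
        retained = if (is.null(ts)) NA_character_
                   else paste(ts$retained_introns, collapse = "-"),
        fev = if (is.null(ts)) NA_integer_ else ts$first_exon_variant
      )
    }
  }
  do.call(rbind, out)
}

#' Write a per-read evidence table as TSV
#' @param evidence Output of [scan_fastq()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evidence_tsv <- function(evidence, path) {
  utils::write.table(evidence, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
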