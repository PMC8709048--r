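#' @importFrom Biostrings DNAString DNAStringSet reverseComplement readDNAStringSet
#'   writeXStringSet
#' @importFrom jsonlite fromJSON toJSON read_json write_json
NULL

## Internal coordinate frame: 0-based, half-open, on the forward genomic
## strand. GFF3 I/O converts to/from 1-based inclusive. Exon ranks follow
## transcription order, so '-'-strand genes store exons in descending
## genomic coordinate.

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Construct a validated single-gene model
#'
#' A gene model is the coordinate frame for everything downstream: an ordered
#' set of exons on one locus sequence, with optional alternative 5' start
#' offsets for exon 1 (modelling 5'-truncated first-exon forms such as the
#' 179-nt vs 166-nt first exons seen in targeted RAS amplicon work) and
#' optional annotated translation-start coordinates.
#'
#' @param gene_name Gene symbol, e.g. `"KRAS"`.
#' @param exons `data.frame` with columns `exon_id` (1-based rank in
#'   transcription order), `start`, `end` (0-based half-open, forward genomic
#'   strand).
#' @param strand `"+"` or `"-"`.
#' @param locus_seq Nucleotide string of the locus (forward genomic strand).
#' @param alt_first_exon_starts Integer offsets (nt, 0-based, in transcript
#'   orientation) of the alternative 5' boundaries of exon 1; `0` is the full
#'   annotated form and must be present.
#' @param annotated_starts Optional genomic coordinates (0-based, forward
#'   strand, position of the first base of the codon's 5'-most base in
#'   transcript orientation) of annotated translation-initiation codons.
#' @param seqname Sequence identifier the model lives on (FASTA record name).
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_name, exons, strand, locus_seq,
                       alt_first_exon_starts = 0L,
                       annotated_starts = integer(0),
                       seqname = "locus") {
  model <- structure(
    list(
      gene_name = as.character(gene_name),
      strand = strand,
      seqname = seqname,
      exons = data.frame(
        exon_id = as.integer(exons$exon_id),
        start = as.integer(exons$start),
        end = as.integer(exons$end)
      ),
      alt_first_exon_starts = sort(unique(as.integer(alt_first_exon_starts))),
      annotated_starts = as.integer(annotated_starts),
      locus_seq = toupper(as.character(locus_seq))
    ),
    class = "gene_model"
  )
  validate_gene_model(model)
  model
}

#' Validate a gene model
#'
#' Checks the structural invariants: at least two exons, `start < end`,
#' non-overlapping exons, exon ranks in transcription order, introns of
#' length >= 1, coordinates within the locus, and alternative 5' starts
#' inside exon 1.
#'
#' @param model A `gene_model`.
#' @return The model, invisibly; stops with a message naming the offending
#'   record otherwise.
#' @export
validate_gene_model <- function(model) {
  ex <- model$exons
  if (!model$strand %in% c("+", "-")) {
    stop("unknown strand '", model$strand, "' for gene ", model$gene_name)
  }
  if (nrow(ex) < 2L) {
    stop("gene ", model$gene_name, " must have >= 2 exons, found ", nrow(ex))
  }
  if (!identical(ex$exon_id, seq_len(nrow(ex)))) {
    stop("exon_id must be 1..n in transcription order for gene ",
         model$gene_name)
  }
  bad <- which(ex$start >= ex$end)
  if (length(bad)) {
    stop("exon ", ex$exon_id[bad[1]], " of ", model$gene_name,
         " has start >= end (", ex$start[bad[1]], ", ", ex$end[bad[1]], ")")
  }
  if (any(ex$start < 0L) || any(ex$end > nchar(model$locus_seq))) {
    off <- which(ex$start < 0L | ex$end > nchar(model$locus_seq))[1]
    stop("exon ", ex$exon_id[off], " of ", model$gene_name,
         " is out of bounds for the locus sequence")
  }
  ord <- order(ex$start)
  sorted <- ex[ord, ]
  if (any(sorted$start[-1] < sorted$end[-nrow(ex)])) {
    i <- which(sorted$start[-1] < sorted$end[-nrow(ex)])[1]
    stop("exons ", sorted$exon_id[i], " and ", sorted$exon_id[i + 1],
         " of ", model$gene_name, " overlap")
  }
  genomic_order <- ex$start
  if (model$strand == "+") {
    if (is.unsorted(genomic_order, strictly = TRUE)) {
      stop("exon ranks of '+' gene ", model$gene_name,
           " do not follow ascending genomic order")
    }
  } else if (is.unsorted(rev(genomic_order), strictly = TRUE)) {
    stop("exon ranks of '-' gene ", model$gene_name,
         " do not follow descending genomic order")
  }
  il <- intron_lengths(model)
  if (any(il < 1L)) {
    stop("intron ", which(il < 1L)[1], " of ", model$gene_name,
         " has length < 1")
  }
  alt <- model$alt_first_exon_starts
  e1 <- exon_length(model, 1L)
  if (!0L %in% alt) {
    stop("alt_first_exon_starts must contain 0 (the full exon-1 form)")
  }
  if (any(alt < 0L) || any(alt >= e1)) {
    stop("alternative 5' start ", alt[alt < 0L | alt >= e1][1],
         " lies outside exon 1 (length ", e1, ")")
  }
  if (!grepl("^[ACGTN]*$", model$locus_seq)) {
    stop("locus sequence contains characters outside {A,C,G,T,N}")
  }
  invisible(model)
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> ", x$gene_name, " (", x$strand, ") ",
      nrow(x$exons), " exons, locus ", nchar(x$locus_seq), " nt, ",
      length(x$alt_first_exon_starts), " exon-1 form(s)\n", sep = "")
  invisible(x)
}

n_exons <- function(model) nrow(model$exons)
n_introns <- function(model) nrow(model$exons) - 1L

exon_length <- function(model, i) {
  model$exons$end[i] - model$exons$start[i]
}

#' Exon sequence in transcript orientation
#' @param model A `gene_model`.
#' @param i Exon rank (1-based, transcription order).
#' @return Nucleotide string of exon `i`, reverse-complemented for `-` genes.
#' @export
exon_seq <- function(model, i) {
  s <- substr(model$locus_seq, model$exons$start[i] + 1L, model$exons$end[i])
  if (model$strand == "-") revcomp(s) else s
}

intron_lengths <- function(model) {
  ex <- model$exons
  n <- nrow(ex)
  if (model$strand == "+") {
    ex$start[-1] - ex$end[-n]
  } else {
    ex$start[-n] - ex$end[-1]
  }
}

#' Intron sequence in transcript orientation
#' @param model A `gene_model`.
#' @param i Intron id (= donor exon rank), in `1..n_exons-1`.
#' @return Nucleotide string of the intron between exons `i` and `i+1`.
#' @export
intron_seq <- function(model, i) {
  ex <- model$exons
  if (model$strand == "+") {
    s <- substr(model$locus_seq, ex$end[i] + 1L, ex$start[i + 1L])
    s
  } else {
    revcomp(substr(model$locus_seq, ex$end[i + 1L] + 1L, ex$start[i]))
  }
}

#' Construct a transcript structure
#'
#' A transcript structure is the unit of discovery, naming and counting: an
#' ordered exon chain (always starting at exon 1 and ending at the last exon
#' of the model, the full-length amplicon convention), a set of retained
#' introns, and which alternative exon-1 5' form the transcript uses.
#'
#' @param gene_name Gene symbol.
#' @param exon_chain Strictly increasing integer vector of exon ranks.
#' @param retained_introns Intron ids retained in the mature mRNA (an intron
#'   id is its donor exon rank); each retained intron's flanking exons must
#'   be adjacent in the chain.
#' @param first_exon_variant Index into the model's `alt_first_exon_starts`.
#' @param name Display name, e.g. `"KRAS v.9"` (may be `NA` before calling).
#' @param status `"annotated"`, `"novel"`, or `NA`.
#' @return An object of class `transcript_structure`.
#' @export
transcript_structure <- function(gene_name, exon_chain,
                                 retained_introns = integer(0),
                                 first_exon_variant = 1L,
                                 name = NA_character_,
                                 status = NA_character_) {
  structure(
    list(
      gene_name = as.character(gene_name),
      exon_chain = as.integer(exon_chain),
      retained_introns = sort(unique(as.integer(retained_introns))),
      first_exon_variant = as.integer(first_exon_variant),
      name = name,
      status = status
    ),
    class = "transcript_structure"
  )
}

#' Validate a transcript structure against its gene model
#' @param ts A `transcript_structure`.
#' @param model The `gene_model` it refers to.
#' @return The structure, invisibly; stops on violation.
#' @export
validate_structure <- function(ts, model) {
  ch <- ts$exon_chain
  n <- n_exons(model)
  if (length(ch) < 1L || is.unsorted(ch, strictly = TRUE)) {
    stop("exon chain must be strictly increasing")
  }
  if (ch[1] != 1L || ch[length(ch)] != n) {
    stop("exon chain must start at exon 1 and end at exon ", n,
         " (full-length convention)")
  }
  if (any(ch < 1L) || any(ch > n)) stop("exon chain out of range")
  for (ri in ts$retained_introns) {
    pos <- match(ri, ch)
    if (is.na(pos) || pos == length(ch) || ch[pos + 1L] != ri + 1L) {
      stop("retained intron ", ri, ": donor exon must be in the chain and",
           " immediately followed by its acceptor exon")
    }
  }
  if (ts$first_exon_variant < 1L ||
      ts$first_exon_variant > length(model$alt_first_exon_starts)) {
    stop("first_exon_variant out of range")
  }
  invisible(ts)
}

#' @export
print.transcript_structure <- function(x, ...) {
  cat("<transcript_structure> ", x$gene_name,
      ifelse(is.na(x$name), "", paste0(" ", x$name)),
      " chain [", paste(x$exon_chain, collapse = ","), "]",
      if (length(x$retained_introns))
        paste0(" +intron ", paste(x$retained_introns, collapse = ",")) else "",
      " exon-1 form ", x$first_exon_variant, "\n", sep = "")
  invisible(x)
}

#' Canonical identity key of a transcript structure
#'
#' Two structures are the same variant iff their keys are equal; used for
#' grouping read evidence and matching calls against annotated transcripts.
#' @param ts A `transcript_structure`.
#' @return A string key.
#' @export
structure_key <- function(ts) {
  paste0("c", paste(ts$exon_chain, collapse = "-"),
         "|r", paste(ts$retained_introns, collapse = "-"),
         "|f", ts$first_exon_variant)
}

#' Mature mRNA sequence of a transcript structure
#'
#' Concatenates exon sequences in chain order, inserts retained-intron
#' sequence between its flanking exons, 5'-truncates exon 1 to the chosen
#' alternative start, and reverse-complements for `-` genes (handled at the
#' exon level, so the result is always 5'->3' mRNA).
#'
#' @param model A `gene_model`.
#' @param ts A `transcript_structure` consistent with `model`.
#' @return Nucleotide string of the mature mRNA.
#' @export
spliced_sequence <- function(model, ts) {
  validate_structure(ts, model)
  parts <- character(0)
  ch <- ts$exon_chain
  for (idx in seq_along(ch)) {
    e <- ch[idx]
    s <- exon_seq(model, e)
    if (idx == 1L) {
      off <- model$alt_first_exon_starts[ts$first_exon_variant]
      s <- substr(s, off + 1L, nchar(s))
    }
    parts <- c(parts, s)
    if (e %in% ts$retained_introns) parts <- c(parts, intron_seq(model, e))
  }
  paste(parts, collapse = "")
}

## Block map of a structure: transcript-order genomic blocks (exon or
## exon+retained-intron merges) with mRNA offsets. Used for coordinate
## mapping and GFF3 export.
structure_blocks <- function(model, ts) {
  ch <- ts$exon_chain
  blocks <- list()
  cur <- NULL
  for (idx in seq_along(ch)) {
    e <- ch[idx]
    gs <- model$exons$start[e]
    ge <- model$exons$end[e]
    if (idx == 1L) {
      off <- model$alt_first_exon_starts[ts$first_exon_variant]
      if (model$strand == "+") gs <- gs + off else ge <- ge - off
    }
    if (is.null(cur)) {
      cur <- c(gs, ge)
    } else {
      cur <- c(min(cur[1], gs), max(cur[2], ge))
    }
    if (!(e %in% ts$retained_introns)) {
      blocks[[length(blocks) + 1L]] <- cur
      cur <- NULL
    }
    ## retained intron: merge with next exon (genomically contiguous)
  }
  if (!is.null(cur)) blocks[[length(blocks) + 1L]] <- cur
  m <- do.call(rbind, blocks)
  colnames(m) <- c("start", "end")
  m
}

#' Map a genomic coordinate onto a mature mRNA
#'
#' @param model A `gene_model`.
#' @param ts A `transcript_structure`.
#' @param gpos Genomic coordinate (0-based, forward strand, position of a
#'   base).
#' @return 0-based position on the mature mRNA, or `NA` if the base is not
#'   part of the transcript.
#' @export
genomic_to_mrna <- function(model, ts, gpos) {
  blocks <- structure_blocks(model, ts)
  if (model$strand == "-") blocks <- blocks[rev(seq_len(nrow(blocks))), , drop = FALSE]
  offset <- 0L
  for (i in seq_len(nrow(blocks))) {
    w <- blocks[i, 2] - blocks[i, 1]
    if (gpos >= blocks[i, 1] && gpos < blocks[i, 2]) {
      within <- if (model$strand == "+") gpos - blocks[i, 1] else blocks[i, 2] - 1L - gpos
      return(as.integer(unname(offset + within)))
    }
    offset <- offset + w
  }
  NA_integer_
}

#' Load a gene model from GFF3/GTF or JSON plus a locus FASTA
#'
#' The JSON schema is
#' `{gene, strand, seqname, exons: [{id, start, end}], alt_first_exon_starts,
#' annotated_starts}` with 0-based half-open coordinates (the package's
#' internal frame). GFF3/GTF input uses the standard 1-based inclusive
#' coordinates; exon features are taken in transcription order and ranked.
#'
#' @param model_file Path to a `.json`, `.gff3`/`.gff` or `.gtf` file.
#' @param fasta Path to the locus FASTA; the model's `seqname` must resolve
#'   to a record.
#' @return A validated `gene_model`.
#' @export
load_gene_model <- function(model_file, fasta) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  ext <- tolower(tools::file_ext(model_file))
  if (ext == "json") {
    j <- jsonlite::read_json(model_file, simplifyVector = TRUE)
    seqname <- if (!is.null(j$seqname)) j$seqname else names(seqs)[1]
    if (!seqname %in% names(seqs)) {
      stop("sequence '", seqname, "' not found in ", fasta)
    }
    gene_model(
      gene_name = j$gene,
      exons = data.frame(exon_id = j$exons$id, start = j$exons$start,
                         end = j$exons$end),
      strand = j$strand,
      locus_seq = as.character(seqs[[seqname]]),
      alt_first_exon_starts = if (!is.null(j$alt_first_exon_starts))
        j$alt_first_exon_starts else 0L,
      annotated_starts = if (!is.null(j$annotated_starts))
        j$annotated_starts else integer(0),
      seqname = seqname
    )
  } else if (ext %in% c("gff3", "gff", "gtf")) {
    gr <- rtracklayer::import(model_file)
    gr <- gr[tolower(as.character(gr$type)) == "exon"]
    if (!length(gr)) stop("no exon features in ", model_file)
    seqname <- as.character(GenomicRanges::seqnames(gr))[1]
    if (!seqname %in% names(seqs)) {
      stop("sequence '", seqname, "' not found in ", fasta)
    }
    strand <- as.character(BiocGenerics::strand(gr))[1]
    if (!strand %in% c("+", "-")) {
      stop("unknown strand '", strand, "' in ", model_file)
    }
    gene <- if (!is.null(gr$gene_id)) gr$gene_id[1]
            else if (!is.null(gr$Parent) && length(gr$Parent[[1]]))
              as.character(gr$Parent[[1]][1])
            else if (!is.null(gr$ID)) sub("\\.exon.*$", "", gr$ID[1])
            else "gene"
    st <- GenomicRanges::start(gr) - 1L   # to 0-based half-open
    en <- GenomicRanges::end(gr)
    ord <- if (strand == "+") order(st) else order(-st)
    gene_model(
      gene_name = gene,
      exons = data.frame(exon_id = seq_along(ord), start = st[ord],
                         end = en[ord]),
      strand = strand,
      locus_seq = as.character(seqs[[seqname]]),
      seqname = seqname
    )
  } else {
    stop("unsupported gene-model format: .", ext)
  }
}

#' Serialize a gene model to the JSON schema
#' @param model A `gene_model`.
#' @param path Output path (`.json`).
#' @return `path`, invisibly. Round-trips losslessly with
#'   [load_gene_model()] given the matching FASTA.
#' @export
write_gene_model_json <- function(model, path) {
  j <- list(
    gene = model$gene_name,
    strand = model$strand,
    seqname = model$seqname,
    exons = data.frame(id = model$exons$exon_id, start = model$exons$start,
                       end = model$exons$end),
    alt_first_exon_starts = model$alt_first_exon_starts,
    annotated_starts = model$annotated_starts
  )
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a locus FASTA for a gene model
#' @param model A `gene_model`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_locus_fasta <- function(model, path) {
  s <- Biostrings::DNAStringSet(model$locus_seq)
  names(s) <- model$seqname
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

#' Construct a validated primer pair
#'
#' The reverse primer is given 5'->3' on the antisense strand (the
#' convention of published primer tables) and is matched in the transcript
#' as its reverse complement.
#'
#' @param forward,reverse Primer sequences, alphabet `{A,C,G,T}`.
#' @return An object of class `primer_pair`.
#' @export
primer_pair <- function(forward, reverse) {
  forward <- toupper(forward); reverse <- toupper(reverse)
  for (p in c(forward, reverse)) {
    if (!nzchar(p) || !grepl("^[ACGT]+$", p)) {
      stop("primer '", p, "' is empty or contains characters outside {A,C,G,T}")
    }
  }
  structure(list(forward = forward, reverse = reverse), class = "primer_pair")
}

count_occurrences <- function(pattern, subject) {
  Biostrings::countPattern(pattern, Biostrings::DNAString(subject))
}

#' Define the targeted amplicon anchors from a primer pair
#'
#' The forward primer must occur exactly once in exon 1 (full form) and the
#' reverse complement of the reverse primer exactly once in the last exon.
#' The returned anchors are the exon-1 subsequence from the forward-primer
#' site to the exon's 3' boundary and the last-exon subsequence from the
#' exon's 5' boundary to the end of the reverse-primer site; the read
#' scanner tiles them with k-mers to decide full-length status.
#'
#' @param model A `gene_model`.
#' @param primers A `primer_pair`.
#' @return List with `first_anchor`, `last_anchor` (nucleotide strings) and
#'   `first_offset` (0-based offset of the forward primer within the full
#'   exon 1).
#' @export
define_amplicon <- function(model, primers) {
  stopifnot(inherits(primers, "primer_pair"))
  e1 <- exon_seq(model, 1L)
  el <- exon_seq(model, n_exons(model))
  nf <- count_occurrences(primers$forward, e1)
  if (nf != 1L) {
    stop("forward primer found ", nf, " times in exon 1 (need exactly 1)")
  }
  rr <- revcomp(primers$reverse)
  nr <- count_occurrences(rr, el)
  if (nr != 1L) {
    stop("reverse primer (reverse complement) found ", nr,
         " times in the last exon (need exactly 1)")
  }
  fpos <- as.integer(regexpr(primers$forward, e1, fixed = TRUE)) - 1L
  rpos <- as.integer(regexpr(rr, el, fixed = TRUE)) - 1L
  list(
    first_anchor = substr(e1, fpos + 1L, nchar(e1)),
    last_anchor = substr(el, 1L, rpos + nchar(rr)),
    first_offset = fpos
  )
}

## ---- transcript GFF3 / FASTA export ----------------------------------

#' Write transcript structures as GFF3
#'
#' Each structure becomes an mRNA feature with exon children; a retained
#' intron appears as a single exon block spanning its flanking exons plus
#' the intron (genomically contiguous), which is how retention is encoded
#' and recovered on re-import. Coordinates follow GFF3 (1-based inclusive).
#'
#' @param model A `gene_model`.
#' @param structures List of `transcript_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcripts_gff3 <- function(model, structures, path) {
  rows <- list()
  for (ts in structures) {
    blocks <- structure_blocks(model, ts)
    id <- gsub("[^A-Za-z0-9._-]", "_", ifelse(is.na(ts$name),
                                              structure_key(ts), ts$name))
    rows[[length(rows) + 1L]] <- data.frame(
      start = min(blocks[, 1]) + 1L, end = max(blocks[, 2]),
      type = "mRNA", ID = id, Parent = NA_character_,
      Name = ifelse(is.na(ts$name), id, ts$name),
      status = ifelse(is.na(ts$status), ".", ts$status)
    )
    for (i in seq_len(nrow(blocks))) {
      rows[[length(rows) + 1L]] <- data.frame(
        start = blocks[i, 1] + 1L, end = blocks[i, 2],
        type = "exon", ID = paste0(id, ".exon", i), Parent = id,
        Name = NA_character_, status = NA_character_
      )
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (!length(rows)) return(invisible(path))
  df <- do.call(rbind, rows)
  attr_col <- ifelse(
    df$type == "mRNA",
    paste0("ID=", df$ID, ";Name=", df$Name, ";status=", df$status),
    paste0("ID=", df$ID, ";Parent=", df$Parent)
  )
  lines <- paste(model$seqname, "splicescout", df$type, df$start, df$end,
                 ".", model$strand, ".", attr_col, sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read transcript structures back from a GFF3 written by
#' [write_transcripts_gff3()]
#'
#' @param path GFF3 path.
#' @param model The `gene_model` the structures refer to.
#' @return List of `transcript_structure`.
#' @export
read_transcripts_gff3 <- function(path, model) {
  gr <- rtracklayer::import(path)
  if (!length(gr)) return(list())
  mrna <- gr[as.character(gr$type) == "mRNA"]
  out <- list()
  for (i in seq_along(mrna)) {
    id <- mrna$ID[i]
    kids <- gr[as.character(gr$type) == "exon" &
               vapply(gr$Parent, function(p) length(p) && p[1] == id, logical(1))]
    bs <- GenomicRanges::start(kids) - 1L
    be <- GenomicRanges::end(kids)
    ord <- if (model$strand == "+") order(bs) else order(-bs)
    bs <- bs[ord]; be <- be[ord]
    chain <- integer(0); retained <- integer(0)
    for (b in seq_along(bs)) {
      ## any exon overlapping the block belongs to it (exon 1 may be
      ## 5'-truncated, so containment would miss it)
      covered <- which(model$exons$end > bs[b] & model$exons$start < be[b])
      covered <- covered[order(covered)]
      chain <- c(chain, covered)
      if (length(covered) > 1L) {
        retained <- c(retained, covered[-length(covered)])
      }
    }
    chain <- sort(chain)
    fev <- 1L
    if (length(model$alt_first_exon_starts) > 1L) {
      b1 <- if (model$strand == "+") min(bs) else NA
      off <- if (model$strand == "+") {
        b1 - model$exons$start[1]
      } else {
        model$exons$end[1] - max(be)
      }
      hit <- match(off, model$alt_first_exon_starts)
      if (!is.na(hit)) fev <- hit
    }
    nm <- if (!is.null(mrna$Name)) mrna$Name[i] else id
    st <- if (!is.null(mrna$status)) mrna$status[i] else NA_character_
    if (identical(st, ".")) st <- NA_character_
    out[[length(out) + 1L]] <- transcript_structure(
      model$gene_name, chain, retained, fev, name = nm, status = st
    )
  }
  out
}

#' Write spliced cDNA FASTA for a set of structures
#' @param model A `gene_model`.
#' @param structures List of `transcript_structure`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_cdna_fasta <- function(model, structures, path) {
  seqs <- vapply(structures, function(ts) spliced_sequence(model, ts), "")
  nm <- vapply(structures, function(ts)
    ifelse(is.na(ts$name), structure_key(ts), ts$name), "")
  s <- Biostrings::DNAStringSet(seqs)
  names(s) <- nm
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}
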