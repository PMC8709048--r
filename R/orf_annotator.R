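## ORF selection and coding-status classification of called transcripts:
## exhaustive forward-frame ORF scan, annotated-start-first selection
## policy, premature-termination-codon calling under the 50-nt
## exon-junction rule (NMD candidates are reported as non-coding), and the
## <100-aa micropeptide flag.

translate_orf <- function(dna) {
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(dna),
                                           no.init.codon = TRUE))
  sub("\\*$", "", aa)
}

#' Find all forward-frame ORFs of an mRNA
#'
#' Every `ATG ... {TAA,TAG,TGA}` span with an in-frame stop inside the
#' sequence and a peptide of at least `min_len_aa` amino acids (stop
#' excluded). Each qualifying start codon is its own candidate. Results are
#' sorted by peptide length descending, ties broken by the 5'-most start.
#'
#' @param mrna Nucleotide string (uppercase ACGT).
#' @param min_len_aa Minimum peptide length in aa (default 25).
#' @return `data.frame(orf_start, orf_end, len_aa, peptide)` with 0-based
#'   `orf_start` and `orf_end` = position after the stop codon.
#' @export
find_orfs <- function(mrna, min_len_aa = 25L) {
  mrna <- toupper(mrna)
  if (!grepl("^[ACGT]*$", mrna)) stop("mRNA must be uppercase ACGT")
  empty <- data.frame(orf_start = integer(0), orf_end = integer(0),
                      len_aa = integer(0), peptide = character(0))
  L <- nchar(mrna)
  if (L < 6L) return(empty)
  codon_at <- function(p) substring(mrna, p + 1L, p + 3L)   # 0-based p
  starts <- as.integer(gregexpr("ATG", mrna, fixed = TRUE)[[1]]) - 1L
  starts <- starts[starts >= 0L]
  if (!length(starts)) return(empty)
  stops_re <- gregexpr("TAA|TAG|TGA", mrna)[[1]]
  stop_pos <- as.integer(stops_re) - 1L
  stop_pos <- stop_pos[stop_pos >= 0L]
  rows <- list()
  for (f in 0:2) {
    fstarts <- starts[starts %% 3L == f]
    fstops <- sort(stop_pos[stop_pos %% 3L == f])
    ## gregexpr with alternation misses overlapping stops; re-derive
    ## in-frame stops exhaustively for safety
    cand <- seq.int(f, L - 3L, by = 3L)
    fstops <- cand[codon_at(cand) %in% c("TAA", "TAG", "TGA")]
    for (s in fstarts) {
      nxt <- fstops[fstops > s]
      if (!length(nxt)) next
      e <- nxt[1] + 3L
      len_aa <- (e - s) %/% 3L - 1L
      if (len_aa < min_len_aa) next
      rows[[length(rows) + 1L]] <- data.frame(
        orf_start = s, orf_end = e, len_aa = len_aa,
        peptide = translate_orf(substr(mrna, s + 1L, e))
      )
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(-out$len_aa, out$orf_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the transcript's ORF
#'
#' If any candidate ORF starts at an annotated translation-initiation
#' position (mapped onto the mature mRNA), the 5'-most such ORF is chosen —
#' transcripts keeping the annotated start use it. Otherwise the longest
#' candidate is chosen (the alternative-initiation-codon case, e.g. a
#' transcript whose skipping event removed the annotated start exon).
#'
#' @param orfs Output of [find_orfs()].
#' @param annotated_start_positions 0-based mRNA positions of annotated
#'   start codons (may be empty).
#' @return One row of `orfs` with a `uses_annotated_start` column, or
#'   `NULL` when no candidate exists.
#' @export
select_orf <- function(orfs, annotated_start_positions = integer(0)) {
  if (!nrow(orfs)) return(NULL)
  ann <- orfs[orfs$orf_start %in% annotated_start_positions, , drop = FALSE]
  if (nrow(ann)) {
    out <- ann[which.min(ann$orf_start), , drop = FALSE]
    out$uses_annotated_start <- TRUE
  } else {
    out <- orfs[1L, , drop = FALSE]   # longest (5'-most on ties)
    out$uses_annotated_start <- FALSE
  }
  rownames(out) <- NULL
  out
}

#' Exon-junction positions on a mature mRNA
#'
#' 0-based positions of the spliced exon-exon boundaries (the position is
#' the number of nt 5' of the boundary). A retained intron removes the
#' junction it replaces: the exon-intron-exon block is junction-free for
#' NMD purposes.
#'
#' @param model A `gene_model`.
#' @param ts A `transcript_structure`.
#' @return Integer vector of junction positions (possibly empty).
#' @export
mrna_junction_positions <- function(model, ts) {
  validate_structure(ts, model)
  ch <- ts$exon_chain
  pos <- integer(0)
  cum <- 0L
  for (idx in seq_along(ch)) {
    e <- ch[idx]
    len <- exon_length(model, e)
    if (idx == 1L) {
      len <- len - model$alt_first_exon_starts[ts$first_exon_variant]
    }
    cum <- cum + len
    if (e %in% ts$retained_introns) {
      cum <- cum + nchar(intron_seq(model, e))
      ## boundary into and out of the retained intron: not a junction
    } else if (idx < length(ch)) {
      pos <- c(pos, cum)
    }
  }
  pos
}

#' Classify the coding status of a selected ORF
#'
#' No ORF: `non_coding`. A stop codon ending more than `nmd_threshold` nt
#' upstream of the transcript's last exon-exon junction is a premature
#' termination codon, making the transcript an NMD candidate (treated as
#' non-coding downstream). Otherwise `coding`. Junction-free transcripts
#' (single block) cannot trigger the rule and are `coding` whenever an ORF
#' exists.
#'
#' @param orf Output of [select_orf()] (or `NULL`).
#' @param ts The `transcript_structure`.
#' @param model The `gene_model`.
#' @param nmd_threshold Distance rule in nt (default 50, the standard
#'   exon-junction-complex model).
#' @return `"coding"`, `"NMD_candidate"` or `"non_coding"`.
#' @export
classify_coding <- function(orf, ts, model, nmd_threshold = 50L) {
  if (is.null(orf)) return("non_coding")
  jpos <- mrna_junction_positions(model, ts)
  if (!length(jpos)) return("coding")
  last_junction <- max(jpos)
  if (last_junction - orf$orf_end > nmd_threshold) "NMD_candidate" else "coding"
}

#' Annotate called transcripts with ORF and coding status
#'
#' Runs the full ORF workflow per call: candidate scan, annotated-start
#' mapping through each structure, ORF selection, PTC/NMD classification
#' and the micropeptide flag (`coding` with a peptide under 100 aa).
#'
#' @param calls A `variant_calls` (or a named list of
#'   `transcript_structure`).
#' @param model The `gene_model` (its `annotated_starts` genomic
#'   coordinates supply the annotated initiation codons).
#' @param min_len_aa Minimum ORF length in aa (default 25).
#' @param nmd_threshold PTC distance rule in nt (default 50).
#' @return `data.frame(name, orf_start, orf_end, peptide_length,
#'   uses_annotated_start, coding_status, micropeptide, peptide)`.
#' @export
annotate_transcripts <- function(calls, model, min_len_aa = 25L,
                                 nmd_threshold = 50L) {
  structures <- if (inherits(calls, "variant_calls")) calls$structures
                else calls
  rows <- lapply(structures, function(ts) {
    mrna <- spliced_sequence(model, ts)
    ann_pos <- vapply(model$annotated_starts, function(g)
      genomic_to_mrna(model, ts, g), integer(1))
    ann_pos <- ann_pos[!is.na(ann_pos)]
    orf <- select_orf(find_orfs(mrna, min_len_aa = min_len_aa), ann_pos)
    status <- classify_coding(orf, ts, model, nmd_threshold = nmd_threshold)
    data.frame(
      name = ifelse(is.na(ts$name), structure_key(ts), ts$name),
      orf_start = if (is.null(orf)) NA_integer_ else orf$orf_start,
      orf_end = if (is.null(orf)) NA_integer_ else orf$orf_end,
      peptide_length = if (is.null(orf)) NA_integer_ else orf$len_aa,
      uses_annotated_start = if (is.null(orf)) NA else orf$uses_annotated_start,
      coding_status = status,
      micropeptide = !is.null(orf) && status == "coding" && orf$len_aa < 100L,
      peptide = if (is.null(orf)) NA_character_ else orf$peptide
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an ORF annotation table and its peptide FASTA
#' @param annotations Output of [annotate_transcripts()].
#' @param tsv Output TSV path.
#' @param peptide_fasta Optional output FASTA of coding peptides.
#' @return `tsv`, invisibly.
#' @export
write_orf_outputs <- function(annotations, tsv, peptide_fasta = NULL) {
  utils::write.table(annotations, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(peptide_fasta)) {
    keep <- annotations$coding_status == "coding" & !is.na(annotations$peptide)
    aa <- Biostrings::AAStringSet(annotations$peptide[keep])
    names(aa) <- annotations$name[keep]
    Biostrings::writeXStringSet(aa, peptide_fasta)
  }
  invisible(tsv)
}
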