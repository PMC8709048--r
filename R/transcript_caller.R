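## Aggregate per-read evidence into supported transcript structures,
## separate annotated from novel, and name novel variants deterministically.

chain_from_key <- function(key) {
  parts <- strsplit(sub("^c", "", key), "\\|")[[1]]
  chain <- as.integer(strsplit(parts[1], "-")[[1]])
  r <- sub("^r", "", parts[2])
  retained <- if (nzchar(r)) as.integer(strsplit(r, "-")[[1]]) else integer(0)
  fev <- as.integer(sub("^f", "", parts[3]))
  list(chain = chain, retained = retained, fev = fev)
}

structure_from_key <- function(key, gene_name) {
  p <- chain_from_key(key)
  transcript_structure(gene_name, p$chain, p$retained, p$fev)
}

## deterministic novel ordering: more exons first, then lexicographic exon
## chain, then retained introns, then exon-1 form
novel_order_key <- function(keys) {
  vapply(keys, function(k) {
    p <- chain_from_key(k)
    sprintf("%03d|%s|%s|%02d",
            999L - length(p$chain),
            paste(sprintf("%03d", p$chain), collapse = "-"),
            paste(sprintf("%03d", p$retained), collapse = "-"),
            p$fev)
  }, "", USE.NAMES = FALSE)
}

#' Call transcript variants from read evidence
#'
#' Full-length, conflict-free, resolvable reads are grouped by identical
#' structure (exon chain, retained introns, exon-1 form) with support pooled
#' across samples. Groups matching an annotated structure are reported under
#' its name; the rest are reported as novel when their total support reaches
#' `min_support`, named `"<gene> v.<n>"` continuing after the annotated
#' count (a gene with 4 annotated transcripts gets novels from v.5).
#' Below-threshold groups are preserved in a separate low-support table so
#' no read evidence is silently dropped. Grouping and naming are order-free:
#' identical evidence in any row order yields identical calls, with novel
#' numbering sorted by (exon count descending, lexicographic chain,
#' retained introns, exon-1 form).
#'
#' @param evidence Evidence table from [scan_fastq()].
#' @param model The `gene_model`.
#' @param annotated List of annotated `transcript_structure` (named).
#' @param min_support Minimum pooled read support for a novel call
#'   (default 3).
#' @return An object of class `variant_calls`: list with `calls` and
#'   `low_support` data.frames (per-sample and total supports) and the
#'   matched `structures` list.
#' @export
call_variants <- function(evidence, model, annotated, min_support = 3L) {
  samples <- sort(unique(evidence$sample))
  usable <- evidence[!is.na(evidence$key) & evidence$full_length &
                     !evidence$conflict & evidence$resolvable, , drop = FALSE]
  ann_keys <- vapply(annotated, structure_key, "")
  ann_names <- vapply(annotated, function(ts) ts$name, "")
  if (anyDuplicated(ann_keys)) stop("duplicate annotated structures")

  tab_rows <- function(keys) {
    do.call(rbind, lapply(keys, function(k) {
      sel <- usable$key == k
      sup <- vapply(samples, function(s) sum(sel & usable$sample == s), 0L)
      p <- chain_from_key(k)
      row <- data.frame(
        key = k,
        chain = paste(p$chain, collapse = "-"),
        retained = paste(p$retained, collapse = "-"),
        fev = p$fev,
        support_total = sum(sup)
      )
      for (s in samples) row[[paste0("support_", s)]] <- sup[[s]]
      row
    }))
  }

  keys <- sort(unique(usable$key))
  counts <- vapply(keys, function(k) sum(usable$key == k), 0L)

  is_ann <- keys %in% ann_keys
  ann_tab <- NULL
  if (any(is_ann)) {
    ann_tab <- tab_rows(keys[is_ann])
    ann_tab$name <- ann_names[match(ann_tab$key, ann_keys)]
    ann_tab$status <- "annotated"
  }
  nov_keys <- keys[!is_ann & counts >= min_support]
  low_keys <- keys[!is_ann & counts < min_support]
  nov_tab <- NULL
  if (length(nov_keys)) {
    nov_keys <- nov_keys[order(novel_order_key(nov_keys))]
    nov_tab <- tab_rows(nov_keys)
    nov_tab$name <- paste0(model$gene_name, " v.",
                           length(annotated) + seq_along(nov_keys))
    nov_tab$status <- "novel"
  }
  low_tab <- if (length(low_keys)) {
    lt <- tab_rows(low_keys)
    lt$name <- NA_character_
    lt$status <- "low_support"
    lt
  } else {
    NULL
  }

  cols <- c("name", "status", "key", "chain", "retained", "fev",
            paste0("support_", samples), "support_total")
  calls <- rbind(ann_tab, nov_tab)
  if (is.null(calls)) {
    calls <- data.frame(name = character(0), status = character(0),
                        key = character(0), chain = character(0),
                        retained = character(0), fev = integer(0),
                        support_total = integer(0))
    for (s in samples) calls[[paste0("support_", s)]] <- integer(0)
  }
  calls <- calls[, intersect(cols, names(calls)), drop = FALSE]
  rownames(calls) <- NULL
  if (!is.null(low_tab)) {
    low_tab <- low_tab[, intersect(cols, names(low_tab)), drop = FALSE]
    rownames(low_tab) <- NULL
  }

  structures <- lapply(seq_len(nrow(calls)), function(i) {
    ts <- structure_from_key(calls$key[i], model$gene_name)
    ts$name <- calls$name[i]
    ts$status <- calls$status[i]
    ts
  })
  names(structures) <- calls$name

  structure(
    list(calls = calls, low_support = low_tab, structures = structures,
         samples = samples, min_support = as.integer(min_support),
         gene_name = model$gene_name),
    class = "variant_calls"
  )
}

#' @export
print.variant_calls <- function(x, ...) {
  cat("<variant_calls> ", x$gene_name, ": ", nrow(x$calls), " calls (",
      sum(x$calls$status == "annotated"), " annotated, ",
      sum(x$calls$status == "novel"), " novel), ",
      if (is.null(x$low_support)) 0L else nrow(x$low_support),
      " low-support groups\n", sep = "")
  invisible(x)
}

#' Export variant calls to GFF3, cDNA FASTA and support TSVs
#'
#' @param calls A `variant_calls`.
#' @param model The `gene_model`.
#' @param dir Output directory (created if absent).
#' @return Named list of written paths, invisibly.
#' @export
export_calls <- function(calls, model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gff <- file.path(dir, "calls.gff3")
  fa <- file.path(dir, "calls.fasta")
  tsv <- file.path(dir, "supports.tsv")
  low <- file.path(dir, "low_support.tsv")
  write_transcripts_gff3(model, calls$structures, gff)
  if (length(calls$structures)) {
    write_cdna_fasta(model, calls$structures, fa)
  } else {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(), fa)
  }
  utils::write.table(calls$calls, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(calls$low_support)) {
    utils::write.table(calls$low_support, low, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(list(gff3 = gff, fasta = fa, supports = tsv,
                 low_support = if (!is.null(calls$low_support)) low))
}
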