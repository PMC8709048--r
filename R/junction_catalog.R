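## Junction k-mer catalog: the detection dictionary. Every possible
## splicing event between annotated exons is materialized as a set of
## boundary-spanning k-mers (one per allowed donor/acceptor offset), introns
## are tiled with k-mers for retention detection, amplicon anchors are tiled
## for full-length calling, and alternative exon-1 5' starts get
## discriminative probe k-mers. Matching is exact; robustness to read errors
## comes from the multiple offsets per junction.

#' Enumerate every possible splicing event between annotated exons
#'
#' All ordered exon pairs (i, j) with i < j: the adjacent pairs are the
#' annotated splice junctions, the rest are candidate exon-skipping events.
#' A model with n exons yields n(n-1)/2 junctions.
#'
#' @param model A `gene_model`.
#' @return `data.frame` with columns `donor`, `acceptor`, `kind`
#'   (`"adjacent"` or `"skipping"`).
#' @export
enumerate_splice_events <- function(model) {
  n <- n_exons(model)
  pairs <- t(utils::combn(n, 2L))
  data.frame(
    donor = as.integer(pairs[, 1]),
    acceptor = as.integer(pairs[, 2]),
    kind = ifelse(pairs[, 2] == pairs[, 1] + 1L, "adjacent", "skipping")
  )
}

#' Build the boundary-spanning k-mers of one junction
#'
#' One k-mer per boundary offset in `[min_flank, k - min_flank]`: the offset
#' is the number of donor-exon bases the k-mer contains, so each k-mer is
#' (suffix of donor exon, length offset) + (prefix of acceptor exon, length
#' k - offset). Offsets that would need more sequence than an exon has are
#' skipped; if every offset is skipped the junction is undetectable and an
#' error is raised.
#'
#' @param model A `gene_model`.
#' @param donor,acceptor Exon ranks with `donor < acceptor`.
#' @param k k-mer length.
#' @param min_flank Minimum bases on each side of the boundary.
#' @return `data.frame(sequence, donor, acceptor, offset)`.
#' @export
build_junction_kmers <- function(model, donor, acceptor, k = 24L,
                                 min_flank = 8L) {
  if (min_flank < 1L) stop("min_flank must be >= 1")
  if (2L * min_flank > k) {
    stop("2 * min_flank (", 2L * min_flank, ") exceeds k (", k, ")")
  }
  if (donor >= acceptor) stop("donor must precede acceptor")
  dseq <- exon_seq(model, donor)
  aseq <- exon_seq(model, acceptor)
  if (k > nchar(dseq) + nchar(aseq)) {
    stop("k = ", k, " exceeds combined exon length for junction (",
         donor, ",", acceptor, ")")
  }
  offsets <- seq.int(min_flank, k - min_flank)
  offsets <- offsets[offsets <= nchar(dseq) & (k - offsets) <= nchar(aseq)]
  if (!length(offsets)) {
    stop("no usable boundary offset for junction (", donor, ",", acceptor,
         "): flanking exons too short")
  }
  seqs <- vapply(offsets, function(o) {
    paste0(substr(dseq, nchar(dseq) - o + 1L, nchar(dseq)),
           substr(aseq, 1L, k - o))
  }, "")
  data.frame(sequence = seqs, donor = as.integer(donor),
             acceptor = as.integer(acceptor), offset = as.integer(offsets))
}

tile_region <- function(seq, k, stride) {
  len <- nchar(seq)
  if (len < k) {
    return(data.frame(sequence = seq, tile_index = 1L, short = TRUE))
  }
  starts <- seq.int(0L, len - k, by = stride)
  if (starts[length(starts)] != len - k) starts <- c(starts, len - k)
  data.frame(
    sequence = vapply(starts, function(s) substr(seq, s + 1L, s + k), ""),
    tile_index = seq_along(starts),
    short = FALSE
  )
}

#' Tile intronic regions with k-mers
#'
#' Tiles at stride 0, s, 2s, ... plus a final right-aligned tile so the
#' whole intron is covered; introns shorter than k yield one short-flagged
#' tile of the entire intron. Intron tile hits in reads are the signal for
#' intron retention (and for novel exons / exon extensions, which this
#' package reports as retained intronic tile clusters).
#'
#' @param model A `gene_model`.
#' @param k Tile length.
#' @param stride Tile stride (nt).
#' @return `data.frame(sequence, intron_id, tile_index, short)`.
#' @export
build_intron_tiles <- function(model, k = 24L, stride = 12L) {
  if (stride < 1L) stop("stride must be >= 1")
  out <- lapply(seq_len(n_introns(model)), function(i) {
    t <- tile_region(intron_seq(model, i), k, stride)
    t$intron_id <- i
    t
  })
  do.call(rbind, out)[, c("sequence", "intron_id", "tile_index", "short")]
}

#' Build the full detection catalog for a gene
#'
#' Assembles junction k-mers for every possible splicing event, intron
#' tiles, amplicon anchor tiles (whole first/last exon when no primers are
#' given) and alternative exon-1 start probes, then screens the dictionary
#' for ambiguous k-mers with [screen_ambiguity()].
#'
#' @param model A `gene_model`.
#' @param k k-mer length (default 24).
#' @param min_flank Minimum bases on each side of a junction (default 8,
#'   giving k - 2*min_flank + 1 = 9 offsets per junction at the defaults).
#' @param stride Intron/anchor tile stride (default 12).
#' @param primers Optional `primer_pair`; when given, anchors span from the
#'   primer sites to the inner exon boundaries (see [define_amplicon()]).
#' @param screen Screen for ambiguity immediately (default `TRUE`).
#' @return An object of class `junction_catalog`.
#' @export
build_catalog <- function(model, k = 24L, min_flank = 8L, stride = 12L,
                          primers = NULL, screen = TRUE) {
  events <- enumerate_splice_events(model)
  jk <- do.call(rbind, lapply(seq_len(nrow(events)), function(i) {
    build_junction_kmers(model, events$donor[i], events$acceptor[i],
                         k = k, min_flank = min_flank)
  }))
  jk$type <- "junction"
  it <- build_intron_tiles(model, k = k, stride = stride)
  it$type <- "intron_tile"

  if (is.null(primers)) {
    anchors <- list(first_anchor = exon_seq(model, 1L),
                    last_anchor = exon_seq(model, n_exons(model)),
                    first_offset = 0L)
  } else {
    anchors <- define_amplicon(model, primers)
  }
  af <- tile_region(anchors$first_anchor, k, stride)
  af$type <- "anchor_first"
  al <- tile_region(anchors$last_anchor, k, stride)
  al$type <- "anchor_last"

  alt <- model$alt_first_exon_starts
  probes <- NULL
  if (length(alt) > 1L) {
    e1 <- exon_seq(model, 1L)
    if (any(alt + k > nchar(e1))) {
      stop("exon 1 too short for alternative-start probes at k = ", k)
    }
    probes <- data.frame(
      sequence = vapply(alt, function(s) substr(e1, s + 1L, s + k), ""),
      variant = seq_along(alt),
      type = "alt_start_probe",
      short = FALSE
    )
  }

  fill <- function(df, cols) {
    for (cc in setdiff(cols, names(df))) {
      df[[cc]] <- if (cc == "short") FALSE else NA_integer_
    }
    df[, cols]
  }
  cols <- c("sequence", "type", "donor", "acceptor", "offset",
            "intron_id", "tile_index", "variant", "short")
  kmers <- rbind(fill(jk, cols), fill(it, cols), fill(af, cols),
                 fill(al, cols), if (!is.null(probes)) fill(probes, cols))
  rownames(kmers) <- NULL
  kmers$ambiguous <- NA

  cat <- structure(
    list(gene_name = model$gene_name, k = as.integer(k),
         min_flank = as.integer(min_flank), stride = as.integer(stride),
         kmers = kmers, anchors = anchors, n_exons = n_exons(model),
         screened = FALSE, exclusions = NULL),
    class = "junction_catalog"
  )
  if (screen) screen_ambiguity(cat, model) else cat
}

#' Screen a catalog for ambiguous k-mers
#'
#' A k-mer is diagnostic only if it occurs exactly where expected. Each
#' entry's occurrences are counted in the locus sequence (both strands) and
#' across the catalog itself; intron tiles, anchor tiles and start probes
#' are genomic and expected once on the forward locus, junction k-mers span
#' spliced boundaries and are expected zero times. Any excess occurrence,
#' any reverse-strand occurrence, or an identical sequence shared by two
#' entries flags the k-mer ambiguous; ambiguous k-mers are excluded from
#' scanning. A junction that loses every k-mer triggers a warning naming it.
#'
#' @param catalog A `junction_catalog`.
#' @param model The `gene_model` the catalog was built from.
#' @return The catalog with `ambiguous` flags set, `screened = TRUE`, and an
#'   `exclusions` report data.frame.
#' @export
screen_ambiguity <- function(catalog, model) {
  km <- catalog$kmers
  locus <- model$locus_seq
  locus_rc <- revcomp(locus)
  fwd <- vapply(km$sequence, count_occurrences, 0L, subject = locus,
                USE.NAMES = FALSE)
  rc <- vapply(km$sequence, count_occurrences, 0L, subject = locus_rc,
               USE.NAMES = FALSE)
  dup <- duplicated(km$sequence) | duplicated(km$sequence, fromLast = TRUE)
  ## entries sharing a sequence are harmless when they all mark the same
  ## unique exonic locus position (e.g. an exon-1 start probe that
  ## coincides with the first anchor tile); any other duplication is real
  ## ambiguity
  exonic <- km$type %in% c("anchor_first", "anchor_last", "alt_start_probe")
  if (any(dup)) {
    for (sq in unique(km$sequence[dup])) {
      ii <- which(km$sequence == sq)
      if (all(exonic[ii]) && fwd[ii[1]] == 1L && rc[ii[1]] == 0L) {
        dup[ii] <- FALSE
      }
    }
  }
  expected_fwd <- ifelse(km$type == "junction", 0L, 1L)
  km$ambiguous <- dup | (fwd > expected_fwd) | (rc > 0L)
  catalog$kmers <- km
  catalog$screened <- TRUE
  catalog$exclusions <- km[km$ambiguous,
                           c("sequence", "type", "donor", "acceptor",
                             "intron_id", "tile_index")]
  lost <- unique(km[km$type == "junction", c("donor", "acceptor")])
  for (i in seq_len(nrow(lost))) {
    sel <- km$type == "junction" & km$donor == lost$donor[i] &
      km$acceptor == lost$acceptor[i]
    if (all(km$ambiguous[sel])) {
      warning("junction (", lost$donor[i], ",", lost$acceptor[i],
              ") lost all its k-mers to ambiguity")
    }
  }
  catalog
}

#' @export
print.junction_catalog <- function(x, ...) {
  km <- x$kmers
  cat("<junction_catalog> ", x$gene_name, ": k=", x$k,
      ", min_flank=", x$min_flank, ", stride=", x$stride, "\n  ",
      sum(km$type == "junction"), " junction k-mers (",
      nrow(unique(km[km$type == "junction", c("donor", "acceptor")])),
      " junctions), ", sum(km$type == "intron_tile"), " intron tiles, ",
      sum(km$type %in% c("anchor_first", "anchor_last")), " anchor tiles",
      if (x$screened) paste0("; ", sum(km$ambiguous), " ambiguous (excluded)")
      else "; unscreened", "\n", sep = "")
  invisible(x)
}

#' Serialize a catalog as TSV plus a JSON parameter sidecar
#' @param catalog A screened `junction_catalog`.
#' @param path Output TSV path; the sidecar is written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  utils::write.table(catalog$kmers, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(gene_name = catalog$gene_name, k = catalog$k,
         min_flank = catalog$min_flank, stride = catalog$stride,
         n_exons = catalog$n_exons, screened = catalog$screened,
         anchors = catalog$anchors),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a catalog written by [write_catalog()]
#' @param path TSV path (sidecar expected at `<path>.json`).
#' @return A `junction_catalog`.
#' @export
read_catalog <- function(path) {
  km <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(sequence = "character"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(
    list(gene_name = meta$gene_name, k = as.integer(meta$k),
         min_flank = as.integer(meta$min_flank),
         stride = as.integer(meta$stride), kmers = km,
         anchors = meta$anchors, n_exons = as.integer(meta$n_exons),
         screened = isTRUE(meta$screened),
         exclusions = km[km$ambiguous, , drop = FALSE]),
    class = "junction_catalog"
  )
}
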