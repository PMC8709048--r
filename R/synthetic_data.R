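## Seeded generator of gene models, planted transcript variants and
## nanopore-like full-length amplicon reads with ground truth, so every
## pipeline stage is testable without external data. Reads are emulated at
## the sequence level only (substitutions, insertions, deletions, optional
## end truncation, random orientation); there is no signal-level or
## quality-score model — the scanner ignores qualities.

#' Simulation configuration
#'
#' @param n_exons Number of exons of the generated gene (>= 2).
#' @param exon_len_range,intron_len_range Length ranges in nt.
#' @param alt_first_exon_starts Alternative exon-1 5' start offsets
#'   (0 = full form; must include 0).
#' @param strand `"+"` or `"-"`.
#' @param structures Named list of planted `transcript_structure`s.
#' @param abundances Integer matrix (structures x samples) of reads to emit.
#' @param sub_rate,ins_rate,del_rate Per-base error fractions, each in
#'   [0, 0.2]. Defaults 0.015/0.02/0.025 (about 6% total, the R9.4.1
#'   nanopore regime).
#' @param trunc_prob Probability a read loses up to `trunc_max` nt from one
#'   end.
#' @param trunc_max Maximum truncation extent (nt).
#' @param seed Mandatory RNG seed.
#' @return Validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_exons,
                              exon_len_range = c(80L, 200L),
                              intron_len_range = c(40L, 120L),
                              alt_first_exon_starts = 0L,
                              strand = "+",
                              structures = NULL,
                              abundances = NULL,
                              sub_rate = 0.015, ins_rate = 0.02,
                              del_rate = 0.025,
                              trunc_prob = 0.05, trunc_max = 30L,
                              seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(rates < 0) || any(rates > 0.2)) {
    stop("error rates must lie in [0, 0.2]")
  }
  if (!is.null(abundances) && any(abundances < 0)) {
    stop("abundances must be >= 0")
  }
  structure(
    list(n_exons = as.integer(n_exons),
         exon_len_range = as.integer(exon_len_range),
         intron_len_range = as.integer(intron_len_range),
         alt_first_exon_starts = sort(unique(as.integer(alt_first_exon_starts))),
         strand = strand,
         structures = structures, abundances = abundances,
         sub_rate = sub_rate, ins_rate = ins_rate, del_rate = del_rate,
         trunc_prob = trunc_prob, trunc_max = as.integer(trunc_max),
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a random gene model with a k-mer-unique locus
#'
#' Draws exon and intron lengths and random-base sequence, plants an ATG at
#' the start of exon 2 as the annotated translation-initiation codon, and
#' rejection-samples against [screen_ambiguity()] until the default
#' detection catalog has zero ambiguous k-mers (at most 100 draws).
#'
#' @param cfg A `simulation_config`.
#' @param k,min_flank,stride Catalog parameters used for the uniqueness
#'   screen (the scanner defaults).
#' @return A `gene_model`.
#' @export
make_gene_model <- function(cfg, k = 24L, min_flank = 8L, stride = 12L) {
  if (cfg$n_exons < 2L) stop("a gene model needs >= 2 exons")
  set.seed(cfg$seed)
  alt <- cfg$alt_first_exon_starts
  min_e1 <- max(alt) + k + 1L
  for (draw in seq_len(100L)) {
    elens <- sample(seq(cfg$exon_len_range[1], cfg$exon_len_range[2]),
                    cfg$n_exons, replace = TRUE)
    if (elens[1] < min_e1) elens[1] <- min_e1
    ilens <- sample(seq(cfg$intron_len_range[1], cfg$intron_len_range[2]),
                    cfg$n_exons - 1L, replace = TRUE)
    flank <- 25L
    pieces <- character(0)
    starts <- integer(cfg$n_exons)
    pos <- flank
    for (i in seq_len(cfg$n_exons)) {
      starts[i] <- pos
      e <- random_dna(elens[i])
      if (i == 2L) e <- paste0("ATG", substr(e, 4L, nchar(e)))
      pieces <- c(pieces, e)
      pos <- pos + elens[i]
      if (i < cfg$n_exons) {
        pieces <- c(pieces, random_dna(ilens[i]))
        pos <- pos + ilens[i]
      }
    }
    locus <- paste0(random_dna(flank), paste(pieces, collapse = ""),
                    random_dna(flank))
    exons <- data.frame(exon_id = seq_len(cfg$n_exons), start = starts,
                        end = starts + elens)
    ann_start <- starts[2]
    if (cfg$strand == "-") {
      L <- nchar(locus)
      locus <- revcomp(locus)
      new_start <- L - exons$end
      exons$end <- L - exons$start
      exons$start <- new_start
      ann_start <- exons$end[2] - 1L
    }
    model <- gene_model(paste0("SYN", cfg$n_exons), exons, cfg$strand, locus,
                        alt_first_exon_starts = alt,
                        annotated_starts = ann_start)
    cat_ok <- tryCatch({
      catalog <- build_catalog(model, k = k, min_flank = min_flank,
                               stride = stride)
      sum(catalog$kmers$ambiguous) == 0L
    }, warning = function(w) FALSE, error = function(e) FALSE)
    if (cat_ok) return(model)
  }
  stop("could not draw a k-mer-unique locus in 100 attempts; ",
       "try longer exons or a smaller k")
}

## apply the per-base error process to one oriented sequence; returns the
## read plus edit counts
apply_read_errors <- function(seq, sub_rate, ins_rate, del_rate) {
  bases <- strsplit(seq, "")[[1]]
  n <- length(bases)
  alphabet <- c("A", "C", "G", "T")
  keep <- stats::runif(n) >= del_rate
  n_del <- sum(!keep)
  bases <- bases[keep]
  m <- length(bases)
  n_sub <- 0L
  if (m) {
    subm <- stats::runif(m) < sub_rate
    n_sub <- sum(subm)
    if (n_sub) {
      bases[subm] <- vapply(bases[subm], function(b)
        sample(setdiff(alphabet, b), 1L), "", USE.NAMES = FALSE)
    }
  }
  insm <- stats::runif(m) < ins_rate
  n_ins <- sum(insm)
  if (n_ins) {
    ins_bases <- sample(alphabet, n_ins, replace = TRUE)
    out <- character(m + n_ins)
    j <- 1L
    ii <- 1L
    for (i in seq_len(m)) {
      out[j] <- bases[i]
      j <- j + 1L
      if (insm[i]) {
        out[j] <- ins_bases[ii]
        ii <- ii + 1L
        j <- j + 1L
      }
    }
    bases <- out
  }
  list(read = paste(bases, collapse = ""), n_sub = n_sub, n_ins = n_ins,
       n_del = n_del)
}

#' Simulate full-length amplicon reads with ground truth
#'
#' For each sample and planted structure, emits the configured number of
#' reads: spliced cDNA, random orientation (p = 0.5 reverse complement),
#' per-base substitution/insertion/deletion at the configured rates, and
#' optional single-end truncation. FASTQ qualities are a constant
#' placeholder. Byte-identical output under a fixed seed.
#'
#' @param model A `gene_model`.
#' @param cfg A `simulation_config` carrying `structures` (named list) and
#'   `abundances` (structures x samples integer matrix with sample column
#'   names).
#' @param outdir Output directory for per-sample FASTQ and truth TSVs.
#' @return List with `fastq` (named paths), `truth` (per-read table),
#'   `true_counts` (structures x samples), `keys` (structure keys).
#' @export
simulate_reads <- function(model, cfg, outdir) {
  if (is.null(cfg$structures) || is.null(cfg$abundances)) {
    stop("cfg must carry planted structures and abundances")
  }
  ab <- cfg$abundances
  if (is.null(colnames(ab)) || is.null(rownames(ab))) {
    stop("abundances must have structure rownames and sample colnames")
  }
  stopifnot(all(rownames(ab) %in% names(cfg$structures)))
  for (ts in cfg$structures) validate_structure(ts, model)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  cdnas <- vapply(cfg$structures, function(ts) spliced_sequence(model, ts), "")
  samples <- colnames(ab)
  fastq <- character(0)
  truth_rows <- list()
  for (s in samples) {
    path <- file.path(outdir, paste0(s, ".fastq"))
    con <- file(path, "w")
    for (v in rownames(ab)) {
      nreads <- ab[v, s]
      if (nreads < 1L) next
      for (i in seq_len(nreads)) {
        rid <- paste(s, gsub("[^A-Za-z0-9]", "_", v), i, sep = "_")
        orient <- if (stats::runif(1) < 0.5) "revcomp" else "forward"
        tmpl <- if (orient == "revcomp") revcomp(cdnas[[v]]) else cdnas[[v]]
        er <- apply_read_errors(tmpl, cfg$sub_rate, cfg$ins_rate,
                                cfg$del_rate)
        read <- er$read
        trunc <- 0L
        if (cfg$trunc_max > 0L && stats::runif(1) < cfg$trunc_prob) {
          trunc <- sample.int(cfg$trunc_max, 1L)
          if (stats::runif(1) < 0.5) {
            read <- substr(read, trunc + 1L, nchar(read))
          } else {
            read <- substr(read, 1L, nchar(read) - trunc)
          }
        }
        writeLines(c(paste0("@", rid), read, "+",
                     strrep("I", nchar(read))), con)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          read_id = rid, sample = s, variant = v, orientation = orient,
          n_sub = er$n_sub, n_ins = er$n_ins, n_del = er$n_del,
          truncated = trunc, template_len = nchar(tmpl)
        )
      }
    }
    close(con)
    fastq[s] <- path
  }
  truth <- do.call(rbind, truth_rows)
  true_counts <- ab[, , drop = FALSE]
  stopifnot(sum(true_counts) == nrow(truth))
  keys <- vapply(cfg$structures, structure_key, "")
  utils::write.table(truth, file.path(outdir, "truth_reads.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(variant = rownames(true_counts), key = keys[rownames(true_counts)],
               true_counts, check.names = FALSE),
    file.path(outdir, "truth_counts.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  list(fastq = fastq, truth = truth, true_counts = true_counts, keys = keys)
}

#' Score structure recovery against simulation ground truth
#'
#' Structure-level precision and recall of the reported calls against the
#' planted set, plus the mean absolute error between reported per-sample
#' supports and the true read counts over the recovered planted variants.
#'
#' @param calls A `variant_calls`.
#' @param sim Result of [simulate_reads()].
#' @return List with `precision`, `recall`, `count_mae`, `n_tp`,
#'   `n_called`, `n_planted`.
#' @export
score_recovery <- function(calls, sim) {
  planted <- sim$keys[rownames(sim$true_counts)]
  called <- calls$calls$key
  tp <- intersect(called, planted)
  precision <- if (length(called)) length(tp) / length(called) else NA_real_
  recall <- length(tp) / length(planted)
  mae <- NA_real_
  if (length(tp)) {
    samples <- colnames(sim$true_counts)
    err <- vapply(tp, function(k) {
      i <- match(k, calls$calls$key)
      v <- names(planted)[match(k, planted)]
      got <- as.numeric(calls$calls[i, paste0("support_", samples)])
      mean(abs(got - as.numeric(sim$true_counts[v, samples])))
    }, 0)
    mae <- mean(err)
  }
  list(precision = precision, recall = recall, count_mae = mae,
       n_tp = length(tp), n_called = length(called),
       n_planted = length(planted))
}

## ---- RAS-like preset --------------------------------------------------

ras_like_structures <- function(gene) {
  ts <- function(chain, retained = integer(0), fev = 1L, name, status) {
    transcript_structure(gene, chain, retained, fev, name = name,
                         status = status)
  }
  if (gene == "KRAS-like") {
    ## 6 exons, two exon-1 5' forms (mirrors the 179/166-nt first-exon
    ## pair), annotated a-d, novels with the characteristic skip patterns
    ann <- list(
      "v.a" = ts(1:6, fev = 1L, name = "v.a", status = "annotated"),
      "v.b" = ts(c(1:4, 6), fev = 1L, name = "v.b", status = "annotated"),
      "v.c" = ts(1:6, fev = 2L, name = "v.c", status = "annotated"),
      "v.d" = ts(c(1:4, 6), fev = 2L, name = "v.d", status = "annotated")
    )
    nov <- list(
      "skip3" = ts(c(1, 2, 4, 5, 6), fev = 1L, name = NA, status = "novel"),
      "skip3_alt1" = ts(c(1, 2, 4, 5, 6), fev = 2L, name = NA, status = "novel"),
      "skip34" = ts(c(1, 2, 5, 6), fev = 2L, name = NA, status = "novel"),
      "skip2" = ts(c(1, 3, 4, 5, 6), fev = 1L, name = NA, status = "novel"),
      "skip23" = ts(c(1, 4, 5, 6), fev = 1L, name = NA, status = "novel"),
      "skip2345" = ts(c(1, 6), fev = 1L, name = NA, status = "novel")
    )
    list(n_exons = 6L, alt = c(0L, 13L), annotated = ann, novel = nov)
  } else if (gene == "NRAS-like") {
    ann <- list("v.1" = ts(1:7, name = "v.1", status = "annotated"))
    nov <- list(
      "skip3" = ts(c(1, 2, 4, 5, 6, 7), name = NA, status = "novel"),
      "skip34" = ts(c(1, 2, 5, 6, 7), name = NA, status = "novel"),
      "skip6" = ts(c(1:5, 7), name = NA, status = "novel"),
      "skip23" = ts(c(1, 4, 5, 6, 7), name = NA, status = "novel"),
      "skip234" = ts(c(1, 5, 6, 7), name = NA, status = "novel")
    )
    list(n_exons = 7L, alt = 0L, annotated = ann, novel = nov)
  } else {
    ## HRAS-like: 7 exons with retention of the intron between exons 6 and
    ## 7 in part of the annotated and novel sets
    ann <- list(
      "v.1" = ts(1:7, name = "v.1", status = "annotated"),
      "v.2" = ts(1:7, retained = 6L, name = "v.2", status = "annotated"),
      "v.3" = ts(c(1:4, 6, 7), retained = 6L, name = "v.3",
                 status = "annotated"),
      "v.4" = ts(c(1:4, 6, 7), name = "v.4", status = "annotated")
    )
    nov <- list(
      "skip2" = ts(c(1, 3:7), name = NA, status = "novel"),
      "skip2_ri6" = ts(c(1, 3:7), retained = 6L, name = NA, status = "novel"),
      "skip23" = ts(c(1, 4, 5, 6, 7), name = NA, status = "novel"),
      "skip234" = ts(c(1, 5, 6, 7), name = NA, status = "novel"),
      "skip2345" = ts(c(1, 6, 7), retained = 6L, name = NA, status = "novel")
    )
    list(n_exons = 7L, alt = 0L, annotated = ann, novel = nov)
  }
}

#' RAS-like simulation preset
#'
#' Three synthetic gene setups mirroring the targeted-RAS topology: a
#' 6-exon gene with two alternative exon-1 5' forms, and two 7-exon genes,
#' one with intron retention between its last two exons in part of the
#' transcript set. Each setup carries annotated structures, planted novel
#' structures with exon-skipping/retention/5'-variant patterns, and a
#' per-sample abundance matrix in which annotated transcripts are several
#' times more abundant than the novel ones and samples differ by fixed
#' multipliers (distinct per-sample abundances).
#'
#' @param seed RNG seed (each gene derives its own sub-seed).
#' @param coverage Reads per novel variant in the reference sample
#'   (annotated variants get 4x; samples scale by 1 / 1.5 / 0.5).
#' @param samples Sample names (default three pools).
#' @param sub_rate,ins_rate,del_rate,trunc_prob Passed to the config;
#'   defaults are the nanopore-like regime, set them to 0 for the
#'   error-free oracle regime.
#' @return Named list (`KRAS-like`, `NRAS-like`, `HRAS-like`) of setups:
#'   `model`, `cfg`, `annotated`, `novel`, `catalog_params`.
#' @export
ras_like_preset <- function(seed, coverage = 50L,
                            samples = c("pool1", "pool2", "pool3"),
                            sub_rate = 0.015, ins_rate = 0.02,
                            del_rate = 0.025, trunc_prob = 0.05) {
  genes <- c("KRAS-like", "NRAS-like", "HRAS-like")
  mult <- c(1, 1.5, 0.5)[seq_along(samples)]
  out <- list()
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    spec <- ras_like_structures(g)
    structures <- c(spec$annotated, spec$novel)
    ab <- matrix(0L, nrow = length(structures), ncol = length(samples),
                 dimnames = list(names(structures), samples))
    for (si in seq_along(samples)) {
      ab[names(spec$annotated), si] <- as.integer(round(4 * coverage * mult[si]))
      ab[names(spec$novel), si] <- as.integer(round(coverage * mult[si]))
    }
    cfg <- simulation_config(
      n_exons = spec$n_exons, alt_first_exon_starts = spec$alt,
      structures = structures, abundances = ab,
      sub_rate = sub_rate, ins_rate = ins_rate, del_rate = del_rate,
      trunc_prob = trunc_prob, seed = seed + 7L * gi
    )
    model <- make_gene_model(cfg)
    model$gene_name <- g
    for (v in names(structures)) structures[[v]]$gene_name <- g
    cfg$structures <- structures
    out[[g]] <- list(model = model, cfg = cfg,
                     annotated = lapply(spec$annotated, function(ts) {
                       ts$gene_name <- g; ts
                     }),
                     novel = lapply(spec$novel, function(ts) {
                       ts$gene_name <- g; ts
                     }))
  }
  out
}
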