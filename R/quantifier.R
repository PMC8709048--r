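## Variant x sample quantification: full-length read counts,
## median-of-ratios (MRN) size factors, and per-novel-variant log2 fold
## change against the summed annotated transcripts — the heatmap matrix.

#' Build the variant x sample count matrix
#'
#' Cell (v, s) is the number of full-length, conflict-free, resolvable
#' reads of sample s whose structure equals call v. Usable reads matching
#' no reported call (e.g. low-support structures) are tallied in an
#' `"unassigned"` diagnostics row, which is excluded from normalization by
#' [quantify_variants()].
#'
#' @param evidence Evidence table from [scan_fastq()].
#' @param calls A `variant_calls`.
#' @param samples Sample names (columns). Defaults to the samples seen in
#'   the calls; evidence carrying an unknown sample tag is an error.
#' @return Integer matrix with variant-name rows plus `"unassigned"`.
#' @export
build_count_matrix <- function(evidence, calls, samples = NULL) {
  if (is.null(samples)) samples <- calls$samples
  unknown <- setdiff(unique(evidence$sample), samples)
  if (length(unknown)) {
    stop("unknown sample tag(s): ", paste(unknown, collapse = ", "))
  }
  usable <- evidence[!is.na(evidence$key) & evidence$full_length &
                     !evidence$conflict & evidence$resolvable, , drop = FALSE]
  keys <- calls$calls$key
  m <- matrix(0L, nrow = length(keys) + 1L, ncol = length(samples),
              dimnames = list(c(calls$calls$name, "unassigned"), samples))
  for (s in samples) {
    es <- usable[usable$sample == s, , drop = FALSE]
    idx <- match(es$key, keys)
    tab <- table(factor(idx, levels = seq_along(keys)))
    m[seq_along(keys), s] <- as.integer(tab)
    m["unassigned", s] <- sum(is.na(idx))
  }
  zero <- colSums(m) == 0L
  if (any(zero)) {
    attr(m, "zero_samples") <- samples[zero]
  }
  m
}

#' Median-of-ratios size factors
#'
#' The normalization the count matrix is put through before fold-change
#' computation: rows (variants) with all-positive counts define per-row
#' geometric means; each sample's size factor is the median over those rows
#' of count / geometric mean. `method = "poscounts"` relaxes the reference
#' set to rows with at least one positive count, taking geometric means and
#' medians over the positive entries only (useful for sparse matrices).
#'
#' @param cm Non-negative count matrix (variants x samples).
#' @param method `"all-positive"` (standard MRN) or `"poscounts"`.
#' @return Named numeric vector of size factors (one per sample), with the
#'   number of reference rows in attribute `"n_reference_rows"`.
#' @export
mrn_size_factors <- function(cm, method = c("all-positive", "poscounts")) {
  method <- match.arg(method)
  if (any(cm < 0)) stop("counts must be non-negative")
  if (!is.null(rownames(cm))) {
    cm <- cm[rownames(cm) != "unassigned", , drop = FALSE]
  }
  if (method == "all-positive") {
    ref <- which(apply(cm, 1L, function(r) all(r > 0)))
    if (!length(ref)) {
      stop("no variant has positive counts in every sample; ",
           "use method = 'poscounts' or pool samples")
    }
    geo <- exp(rowMeans(log(cm[ref, , drop = FALSE])))
    ratios <- sweep(cm[ref, , drop = FALSE], 1L, geo, "/")
    sf <- apply(ratios, 2L, stats::median)
  } else {
    ref <- which(rowSums(cm > 0) > 0)
    if (!length(ref)) stop("all-zero count matrix")
    loggeo <- apply(cm[ref, , drop = FALSE], 1L, function(r)
      mean(log(r[r > 0])))
    sf <- apply(sweep(log(cm[ref, , drop = FALSE]), 1L, loggeo, "-"), 2L,
                function(col) exp(stats::median(col[is.finite(col)])))
  }
  if (any(!is.finite(sf) | sf <= 0)) {
    stop("non-positive size factor; samples with no computable ratios: ",
         paste(names(sf)[!is.finite(sf) | sf <= 0], collapse = ", "))
  }
  attr(sf, "n_reference_rows") <- length(ref)
  sf
}

#' Normalize a count matrix by size factors
#' @param cm Count matrix.
#' @param sf Size factors from [mrn_size_factors()].
#' @return Matrix of normalized counts (`count / size factor`).
#' @export
normalize_counts <- function(cm, sf) {
  sweep(cm, 2L, sf, "/")
}

#' Per-variant log2 fold change vs the annotated transcripts
#'
#' For each novel variant v and sample s:
#' `log2((norm(v, s) + pseudocount) / (sum over annotated a of norm(a, s) +
#' pseudocount))`. The pseudocount (default 0.5) keeps every value finite
#' when either side is zero. `denominator = "max"` uses the most abundant
#' annotated transcript instead of the sum.
#'
#' @param norm_cm Normalized count matrix from [normalize_counts()].
#' @param calls A `variant_calls` (to know which rows are annotated).
#' @param pseudocount Additive constant (default 0.5).
#' @param denominator `"sum"` (all annotated transcripts) or `"max"`.
#' @return Matrix (novel variants x samples) of log2FC values.
#' @export
log2fc_table <- function(norm_cm, calls, pseudocount = 0.5,
                         denominator = c("sum", "max")) {
  denominator <- match.arg(denominator)
  ann <- calls$calls$name[calls$calls$status == "annotated"]
  nov <- calls$calls$name[calls$calls$status == "novel"]
  if (!length(ann)) stop("no annotated transcripts in the call set")
  am <- norm_cm[ann, , drop = FALSE]
  denom <- if (denominator == "sum") colSums(am) else apply(am, 2L, max)
  out <- matrix(NA_real_, nrow = length(nov), ncol = ncol(norm_cm),
                dimnames = list(nov, colnames(norm_cm)))
  for (v in nov) {
    out[v, ] <- log2((norm_cm[v, ] + pseudocount) / (denom + pseudocount))
  }
  out
}

#' Quantify called variants end to end
#'
#' Count matrix, MRN size factors (computed without the `"unassigned"`
#' diagnostics row), normalized counts and the novel-variant log2FC table.
#'
#' @inheritParams build_count_matrix
#' @inheritParams log2fc_table
#' @param method Size-factor method, see [mrn_size_factors()].
#' @return List with `counts`, `size_factors`, `normalized`, `log2fc`,
#'   `pseudocount`.
#' @export
quantify_variants <- function(evidence, calls, samples = NULL,
                              pseudocount = 0.5,
                              denominator = c("sum", "max"),
                              method = c("all-positive", "poscounts")) {
  cm <- build_count_matrix(evidence, calls, samples = samples)
  core <- cm[rownames(cm) != "unassigned", , drop = FALSE]
  sf <- mrn_size_factors(core, method = method)
  norm <- normalize_counts(core, sf)
  fc <- log2fc_table(norm, calls, pseudocount = pseudocount,
                     denominator = match.arg(denominator))
  list(counts = cm, size_factors = sf, normalized = norm, log2fc = fc,
       pseudocount = pseudocount)
}

#' Export the log2FC matrix as TSV and a clustered heatmap
#'
#' The heatmap uses a blue-white-red palette (red = relatively abundant,
#' blue = rare or undetectable). With no novel variants a warning is issued
#' and only an empty TSV is written.
#'
#' @param log2fc Matrix from [log2fc_table()].
#' @param dir Output directory.
#' @param prefix File prefix (default `"log2fc"`).
#' @return Named list of written paths, invisibly.
#' @export
export_heatmap <- function(log2fc, dir, prefix = "log2fc") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, paste0(prefix, ".tsv"))
  utils::write.table(
    data.frame(variant = rownames(log2fc), log2fc, check.names = FALSE),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE
  )
  if (!nrow(log2fc)) {
    warning("no novel variants; heatmap not rendered")
    return(invisible(list(tsv = tsv, image = NULL)))
  }
  img <- file.path(dir, paste0(prefix, "_heatmap.png"))
  pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(101)
  rng <- range(log2fc, finite = TRUE)
  if (!all(is.finite(rng))) rng <- c(-1, 1)
  if (diff(rng) < 1e-8) rng <- rng + c(-1, 1)    # constant matrix
  pheatmap::pheatmap(
    log2fc, color = pal,
    breaks = seq(rng[1], rng[2], length.out = length(pal) + 1L),
    cluster_rows = nrow(log2fc) > 1L, cluster_cols = FALSE,
    filename = img, silent = TRUE
  )
  invisible(list(tsv = tsv, image = img))
}
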