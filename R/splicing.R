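# Splice-site ratio metrics.
#
# At each intron-exon boundary the 5'SS ratio is the read coverage of the first
# intronic base divided by the coverage of the last base of the upstream exon;
# the 3'SS ratio mirrors this at the downstream boundary. Junction-spanning
# spliced reads (N skip across the intron) contribute to the exonic side only,
# so each ratio estimates the unspliced (retained) fraction among molecules
# covering that junction: 0 = fully co-transcriptionally spliced, 1 = fully
# retained. Ratios are negatively correlated with splicing efficiency.

.boundary_positions <- function(introns, window) {
  w <- as.integer(window)
  stopifnot(w >= 1L)
  plus <- introns$strand == "+"
  ilen <- introns$end - introns$start
  wi <- pmin(w, ilen)  # intronic windows never spill past the intron
  list(
    # each element: list(anchor pos vector, widths, direction) expanded later
    intronic_5p = list(pos = ifelse(plus, introns$start, introns$end - 1L),
                       dir = ifelse(plus, 1L, -1L), w = wi),
    exonic_5p   = list(pos = ifelse(plus, introns$start - 1L, introns$end),
                       dir = ifelse(plus, -1L, 1L), w = rep(w, nrow(introns))),
    intronic_3p = list(pos = ifelse(plus, introns$end - 1L, introns$start),
                       dir = ifelse(plus, -1L, 1L), w = wi),
    exonic_3p   = list(pos = ifelse(plus, introns$end, introns$start - 1L),
                       dir = ifelse(plus, 1L, -1L), w = rep(w, nrow(introns)))
  )
}

.window_mean_cov <- function(aln, introns, spec, strand_policy) {
  n <- nrow(introns)
  out <- numeric(n)
  # expand each window into its base positions, count, average
  reps <- spec$w
  base_off <- sequence(reps) - 1L
  idx <- rep.int(seq_len(n), reps)
  pos <- spec$pos[idx] + spec$dir[idx] * base_off
  ok <- pos >= 0L
  counts <- numeric(length(pos))
  want_strand <- switch(strand_policy,
    unstranded = rep(NA_character_, n),
    sense = introns$strand,
    antisense = ifelse(introns$strand == "+", "-", "+"))
  for (ch in unique(introns$chrom)) {
    for (st in unique(want_strand[introns$chrom == ch])) {
      sel <- ok & introns$chrom[idx] == ch &
        (is.na(st) | want_strand[idx] == st)
      if (!any(sel)) next
      counts[sel] <- coverage_at(aln, ch, pos[sel],
                                 strand = if (is.na(st)) NULL else st)
    }
  }
  sums <- rowsum(counts, idx)
  out[as.integer(rownames(sums))] <- sums[, 1] / reps[as.integer(rownames(sums))]
  out
}

#' Count boundary reads at intron splice sites
#'
#' For each intron, counts reads covering the first intronic base and the
#' adjacent (last) exonic base at the 5' splice site, and their mirror images
#' at the 3' splice site. With `window > 1` each count becomes the mean
#' per-base coverage over `window` flanking bases on its side of the boundary
#' (the intronic window never extends past the intron).
#'
#' @param aln an `alignments` object.
#' @param introns intron table as returned by [introns()].
#' @param window number of flanking bases averaged per side (default 1,
#'   single-base adjacency).
#' @param strand_policy `"unstranded"` (default; antisense reads kept),
#'   `"sense"` or `"antisense"` relative to each intron's gene strand.
#' @return The intron table with columns `intronic_5p`, `exonic_5p`,
#'   `intronic_3p`, `exonic_3p` appended.
#' @export
count_boundary_reads <- function(aln, introns, window = 1L,
                                 strand_policy = c("unstranded", "sense", "antisense")) {
  strand_policy <- match.arg(strand_policy)
  if (nrow(introns) == 0L) {
    introns$intronic_5p <- introns$exonic_5p <- numeric(0)
    introns$intronic_3p <- introns$exonic_3p <- numeric(0)
    return(introns)
  }
  if (any(introns$end - introns$start < 1L)) stop("intron of length < 1")
  specs <- .boundary_positions(introns, window)
  for (nm in names(specs))
    introns[[nm]] <- .window_mean_cov(aln, introns, specs[[nm]], strand_policy)
  introns
}

#' Splice-site ratio from boundary counts
#'
#' `intronic / exonic` for the requested side; `NA` (undefined) when the exonic
#' denominator is zero. Undefined is a value, not an error.
#'
#' @param counts data.frame from [count_boundary_reads()].
#' @param side `"5p"` or `"3p"`.
#' @return Numeric vector of ratios (NA where undefined).
#' @export
ss_ratio <- function(counts, side = c("5p", "3p")) {
  side <- match.arg(side)
  num <- counts[[paste0("intronic_", side)]]
  den <- counts[[paste0("exonic_", side)]]
  ifelse(den > 0, num / den, NA_real_)
}

#' Fragments per kilobase of exon model per million mapped fragments
#'
#' `fragment_count * 1e9 / (exonic_length * total_mapped_fragments)`.
#'
#' @param fragment_count fragments overlapping the gene's exon model.
#' @param exonic_length summed exon length of the representative transcript (bp).
#' @param total_mapped_fragments library-wide filtered fragment count.
#' @return FPKM value(s).
#' @export
compute_fpkm <- function(fragment_count, exonic_length, total_mapped_fragments) {
  if (any(exonic_length <= 0)) stop("exonic_length must be > 0")
  if (any(total_mapped_fragments <= 0)) stop("total_mapped_fragments must be > 0")
  fragment_count * 1e9 / (exonic_length * total_mapped_fragments)
}

#' Gene-level mean splice-site ratios
#'
#' The gene's SS ratio is the unweighted arithmetic mean of its defined
#' per-intron ratios; introns whose exonic denominator was zero (NA ratio) are
#' skipped, and the mean is NA when no intron qualifies.
#'
#' @param ratio_5p,ratio_3p per-intron ratio vectors for one gene.
#' @return Named numeric vector `c(mean_5p, mean_3p)`.
#' @export
gene_ss_ratio <- function(ratio_5p, ratio_3p) {
  m <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  c(mean_5p = m(ratio_5p), mean_3p = m(ratio_3p))
}

# fragment counts over representative-transcript exon models (>= 1 bp overlap)
.gene_fragment_counts <- function(gene_set, aln) {
  g <- gene_set$genes
  rep_ex <- gene_set$exons[gene_set$exons$transcript_id %in% g$representative, , drop = FALSE]
  rep_ex$gene_id <- gene_set$transcripts$gene_id[
    match(rep_ex$transcript_id, gene_set$transcripts$transcript_id)]
  rep_ex$chrom <- g$chrom[match(rep_ex$gene_id, g$gene_id)]
  counts <- stats::setNames(numeric(nrow(g)), g$gene_id)
  for (ch in unique(g$chrom)) {
    ex <- rep_ex[rep_ex$chrom == ch, , drop = FALSE]
    bl <- aln[aln$chrom == ch, , drop = FALSE]
    if (nrow(ex) == 0L || nrow(bl) == 0L) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(bl$start + 1L, bl$end),
      IRanges::IRanges(ex$start + 1L, ex$end))
    if (length(ov) == 0L) next
    pairs <- unique(data.frame(frag = bl$frag_id[S4Vectors::queryHits(ov)],
                               gene = ex$gene_id[S4Vectors::subjectHits(ov)]))
    tab <- table(pairs$gene)
    counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
  }
  counts
}

#' Length-normalised intron/exon read ratio per gene
#'
#' Mean per-base intronic coverage divided by mean per-base exonic coverage
#' over the representative transcript; the CB-RNA hallmark of nascent-RNA
#' capture (higher than in mRNA-seq). NA when exonic coverage is zero.
#'
#' @param gene_set a [gene_set].
#' @param aln an `alignments` object.
#' @return Named numeric vector, one value per gene (NA where undefined or
#'   intronless).
#' @export
intron_exon_ratio <- function(gene_set, aln) {
  g <- gene_set$genes
  itab <- introns(gene_set)
  rep_ex <- gene_set$exons[gene_set$exons$transcript_id %in% g$representative, , drop = FALSE]
  rep_ex$gene_id <- gene_set$transcripts$gene_id[
    match(rep_ex$transcript_id, gene_set$transcripts$transcript_id)]
  rep_ex$chrom <- g$chrom[match(rep_ex$gene_id, g$gene_id)]

  covsum <- function(feat) {
    out <- stats::setNames(numeric(nrow(g)), g$gene_id)
    for (ch in unique(feat$chrom)) {
      fe <- feat[feat$chrom == ch, , drop = FALSE]
      bl <- aln[aln$chrom == ch, , drop = FALSE]
      if (nrow(fe) == 0L || nrow(bl) == 0L) next
      q <- IRanges::IRanges(bl$start + 1L, bl$end)
      s <- IRanges::IRanges(fe$start + 1L, fe$end)
      ov <- IRanges::findOverlaps(q, s)
      if (length(ov) == 0L) next
      w <- BiocGenerics::width(IRanges::pintersect(
        q[S4Vectors::queryHits(ov)], s[S4Vectors::subjectHits(ov)]))
      sums <- rowsum(w, fe$gene_id[S4Vectors::subjectHits(ov)])
      out[rownames(sums)] <- out[rownames(sums)] + sums[, 1]
    }
    out
  }
  isum <- covsum(itab)
  esum <- covsum(rep_ex)
  ilen <- stats::setNames(numeric(nrow(g)), g$gene_id)
  t1 <- rowsum(itab$end - itab$start, itab$gene_id)
  ilen[rownames(t1)] <- t1[, 1]
  elen <- stats::setNames(numeric(nrow(g)), g$gene_id)
  t2 <- rowsum(rep_ex$end - rep_ex$start, rep_ex$gene_id)
  elen[rownames(t2)] <- t2[, 1]
  ifelse(ilen > 0 & esum > 0, (isum / pmax(ilen, 1)) / (esum / elen), NA_real_)
}

#' Estimate co-transcriptional splicing ratios from aligned reads
#'
#' The central estimator: resolves boundary counts for every intron of every
#' representative transcript, forms per-intron 5'SS and 3'SS ratios, computes
#' per-gene FPKM (fragment-based, over the representative exon model) and
#' gene-level mean ratios, and records which genes pass the expression filter
#' (`FPKM >= fpkm_min`; only those genes enter downstream summaries and
#' stratifications).
#'
#' @param gene_set a [gene_set].
#' @param aln an `alignments` object (or a SAM/BAM path, loaded with `filters`).
#' @param fpkm_min expression filter threshold (default 1).
#' @param window flanking-base window per boundary side (default 1).
#' @param filters a [read_filters] configuration; its `strand_policy` drives the
#'   counting mode.
#' @param exclude_overlaps drop introns that overlap an exon of another gene's
#'   representative transcript (default keeps them, flagged).
#' @return Object of class `splice_ratios` with elements `introns` (per-intron
#'   counts and ratios), `genes` (`fpkm`, `n_introns`, `mean_5p`, `mean_3p`,
#'   `intron_exon_ratio`, `expressed`), and the call parameters.
#' @seealso [stratify_by_intron_order()], [stratify_by_intron_number()],
#'   [filter_expressed()]
#' @export
splice_ratios <- function(gene_set, aln, fpkm_min = 1, window = 1L,
                          filters = read_filters(), exclude_overlaps = FALSE) {
  stopifnot(inherits(gene_set, "gene_set"))
  if (is.character(aln)) aln <- read_alignments(aln, filters)
  itab <- introns(gene_set)

  # flag introns overlapping another gene's representative exon model
  g <- gene_set$genes
  rep_ex <- gene_set$exons[gene_set$exons$transcript_id %in% g$representative, , drop = FALSE]
  rep_ex$gene_id <- gene_set$transcripts$gene_id[
    match(rep_ex$transcript_id, gene_set$transcripts$transcript_id)]
  rep_ex$chrom <- g$chrom[match(rep_ex$gene_id, g$gene_id)]
  itab$overlaps_exon <- FALSE
  for (ch in unique(itab$chrom)) {
    ii <- which(itab$chrom == ch)
    ex <- rep_ex[rep_ex$chrom == ch, , drop = FALSE]
    if (!length(ii) || !nrow(ex)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(itab$start[ii] + 1L, itab$end[ii]),
      IRanges::IRanges(ex$start + 1L, ex$end))
    other <- itab$gene_id[ii][S4Vectors::queryHits(ov)] !=
      ex$gene_id[S4Vectors::subjectHits(ov)]
    itab$overlaps_exon[ii[unique(S4Vectors::queryHits(ov)[other])]] <- TRUE
  }
  if (exclude_overlaps) itab <- itab[!itab$overlaps_exon, , drop = FALSE]

  itab <- count_boundary_reads(aln, itab, window = window,
                               strand_policy = filters$strand_policy)
  itab$ratio_5p <- ss_ratio(itab, "5p")
  itab$ratio_3p <- ss_ratio(itab, "3p")

  elen <- stats::setNames(numeric(nrow(g)), g$gene_id)
  exlen <- rowsum(rep_ex$end - rep_ex$start, rep_ex$gene_id)
  elen[rownames(exlen)] <- exlen[, 1]
  fc <- .gene_fragment_counts(gene_set, aln)
  fpkm <- ifelse(elen > 0,
                 compute_fpkm(fc, pmax(elen, 1), attr(aln, "n_fragments")), 0)

  n_int <- stats::setNames(integer(nrow(g)), g$gene_id)
  if (nrow(itab)) {
    tt <- table(itab$gene_id)
    n_int[names(tt)] <- as.integer(tt)
  }
  m5 <- m3 <- stats::setNames(rep(NA_real_, nrow(g)), g$gene_id)
  if (nrow(itab)) {
    sp <- split(seq_len(nrow(itab)), itab$gene_id)
    for (gid in names(sp)) {
      gm <- gene_ss_ratio(itab$ratio_5p[sp[[gid]]], itab$ratio_3p[sp[[gid]]])
      m5[gid] <- gm["mean_5p"]
      m3[gid] <- gm["mean_3p"]
    }
  }
  genes <- data.frame(
    gene_id = g$gene_id,
    strand = g$strand,
    fpkm = unname(fpkm[g$gene_id]),
    n_introns = unname(n_int[g$gene_id]),
    mean_5p = unname(m5[g$gene_id]),
    mean_3p = unname(m3[g$gene_id]),
    intron_exon_ratio = unname(intron_exon_ratio(gene_set, aln)[g$gene_id]),
    stringsAsFactors = FALSE
  )
  genes$expressed <- genes$fpkm >= fpkm_min

  structure(list(
    introns = itab,
    genes = genes,
    fpkm_min = fpkm_min,
    window = window,
    strand_policy = filters$strand_policy,
    n_fragments = attr(aln, "n_fragments")
  ), class = "splice_ratios")
}

#' Apply (or re-apply) the expression filter
#'
#' Returns the gene-level table restricted to genes with `FPKM >= fpkm_min`,
#' order preserved. The boundary-inclusive threshold matches the analysis
#' convention (FPKM exactly 1 is kept at the default threshold).
#'
#' @param x a `splice_ratios` object (or its `genes` data.frame).
#' @param fpkm_min threshold; defaults to the one stored in the fit.
#' @return data.frame of expressed genes.
#' @export
filter_expressed <- function(x, fpkm_min = NULL) {
  genes <- if (inherits(x, "splice_ratios")) x$genes else x
  if (is.null(fpkm_min))
    fpkm_min <- if (inherits(x, "splice_ratios")) x$fpkm_min else 1
  genes[genes$fpkm >= fpkm_min, , drop = FALSE]
}

.qsum <- function(v) {
  v <- v[!is.na(v)]
  if (!length(v))
    return(c(n = 0, q25 = NA_real_, median = NA_real_, q75 = NA_real_))
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  c(n = length(v), q25 = q[1], median = q[2], q75 = q[3])
}

#' Per-intron-order ratio distributions for genes with k introns
#'
#' Restricts to expressed genes whose representative transcript has exactly
#' `k` introns and collects, for each order 1..k, the defined per-intron 5'SS
#' and 3'SS ratios across genes with summary quantiles. In nascent (RNAe)
#' libraries the median rises from the first to the last intron ("first come,
#' first serve" co-transcriptional splicing).
#'
#' @param sr a `splice_ratios` fit.
#' @param k intron count selecting the gene class.
#' @return list with `values` (long data.frame: `order`, `side`, `gene_id`,
#'   `ratio`) and `summary` (per order and side: n, quartiles, median).
#' @export
stratify_by_intron_order <- function(sr, k) {
  stopifnot(inherits(sr, "splice_ratios"))
  keep <- filter_expressed(sr)
  keep <- keep$gene_id[keep$n_introns == k]
  it <- sr$introns[sr$introns$gene_id %in% keep, , drop = FALSE]
  values <- rbind(
    data.frame(order = it$order, side = "5p", gene_id = it$gene_id,
               ratio = it$ratio_5p, stringsAsFactors = FALSE),
    data.frame(order = it$order, side = "3p", gene_id = it$gene_id,
               ratio = it$ratio_3p, stringsAsFactors = FALSE)
  )
  values <- values[!is.na(values$ratio), , drop = FALSE]
  if (nrow(values) == 0L)
    return(list(values = values,
                summary = data.frame(order = integer(), side = character(),
                                     n = integer(), q25 = numeric(),
                                     median = numeric(), q75 = numeric())))
  grid <- expand.grid(order = seq_len(k), side = c("5p", "3p"),
                      stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    v <- values$ratio[values$order == grid$order[i] & values$side == grid$side[i]]
    data.frame(order = grid$order[i], side = grid$side[i],
               t(.qsum(v)), stringsAsFactors = FALSE)
  }))
  list(values = values, summary = summ)
}

#' Gene-mean ratio distributions by intron number
#'
#' For each intron count `k` in `k_range`, the distribution of gene-level
#' `mean_5p` and `mean_3p` over expressed genes with exactly `k` introns.
#' Empty classes are reported with `n = 0`.
#'
#' @param sr a `splice_ratios` fit.
#' @param k_range intron counts to tabulate (default 1:10).
#' @return data.frame: `n_introns`, `side`, `n`, `q25`, `median`, `q75`.
#' @export
stratify_by_intron_number <- function(sr, k_range = 1:10) {
  stopifnot(inherits(sr, "splice_ratios"))
  keep <- filter_expressed(sr)
  grid <- expand.grid(n_introns = k_range, side = c("5p", "3p"),
                      stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    col <- if (grid$side[i] == "5p") "mean_5p" else "mean_3p"
    v <- keep[[col]][keep$n_introns == grid$n_introns[i]]
    data.frame(n_introns = grid$n_introns[i], side = grid$side[i],
               t(.qsum(v)), stringsAsFactors = FALSE)
  }))
}

#' @export
print.splice_ratios <- function(x, ...) {
  ng <- nrow(x$genes)
  ne <- sum(x$genes$expressed)
  cat(sprintf("splice_ratios fit: %d gene(s), %d intron(s)\n", ng, nrow(x$introns)))
  cat(sprintf("  expressed (FPKM >= %g): %d gene(s)\n", x$fpkm_min, ne))
  e <- filter_expressed(x)
  if (nrow(e)) {
    cat(sprintf("  median gene 5'SS ratio: %.4f | 3'SS ratio: %.4f\n",
                stats::median(e$mean_5p, na.rm = TRUE),
                stats::median(e$mean_3p, na.rm = TRUE)))
  }
  invisible(x)
}

#' @export
summary.splice_ratios <- function(object, ...) {
  e <- filter_expressed(object)
  out <- list(
    n_genes = nrow(object$genes),
    n_expressed = nrow(e),
    n_introns = nrow(object$introns),
    gene_5p = .qsum(e$mean_5p),
    gene_3p = .qsum(e$mean_3p),
    intron_exon = .qsum(e$intron_exon_ratio),
    fpkm_min = object$fpkm_min,
    window = object$window,
    strand_policy = object$strand_policy
  )
  class(out) <- "summary.splice_ratios"
  out
}

#' @export
print.summary.splice_ratios <- function(x, ...) {
  cat(sprintf("splice_ratios: %d/%d genes expressed (FPKM >= %g), %d introns\n",
              x$n_expressed, x$n_genes, x$fpkm_min, x$n_introns))
  cat(sprintf("  gene mean 5'SS ratio  median %.4f [IQR %.4f-%.4f], n=%d\n",
              x$gene_5p["median"], x$gene_5p["q25"], x$gene_5p["q75"], x$gene_5p["n"]))
  cat(sprintf("  gene mean 3'SS ratio  median %.4f [IQR %.4f-%.4f], n=%d\n",
              x$gene_3p["median"], x$gene_3p["q25"], x$gene_3p["q75"], x$gene_3p["n"]))
  cat(sprintf("  intron/exon ratio     median %.4f, n=%d\n",
              x$intron_exon["median"], x$intron_exon["n"]))
  invisible(x)
}

#' Boxplot of gene-level splice-site ratios
#'
#' @param x a `splice_ratios` fit.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.splice_ratios <- function(x, ...) {
  e <- filter_expressed(x)
  graphics::boxplot(list(`5'SS` = e$mean_5p[!is.na(e$mean_5p)],
                         `3'SS` = e$mean_3p[!is.na(e$mean_3p)]),
                    ylab = "gene mean SS ratio (intron retention)", ...)
  invisible(x)
}

#' Write the per-intron and per-gene tables of a fit
#'
#' @param sr a `splice_ratios` fit.
#' @param intron_path,gene_path output TSV paths (either may be NULL).
#' @export
write_splice_tables <- function(sr, intron_path = NULL, gene_path = NULL) {
  if (!is.null(intron_path))
    utils::write.table(sr$introns, intron_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(gene_path))
    utils::write.table(sr$genes, gene_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(sr)
}
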