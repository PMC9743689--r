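# Windowed, library-size-scaled coverage tracks and scaled gene-body
# (TSS -> PAS) metagene profiles. A 5' to 3' declining profile is the coverage
# hallmark of chromatin-bound (nascent) RNA; mRNA-seq profiles are flat or
# mildly 3'-biased.

#' TPM-scaled windowed coverage track
#'
#' Tiles each chromosome into `window_size`-bp windows (stride = window size)
#' and records the mean per-base read coverage in each window, scaled by
#' `1e6 / n_reads` so that the genome-wide sum of `value * window_length`
#' equals `1e6 *` (mean read length) — i.e. one million read-length
#' equivalents, making tracks comparable across library sizes (doubling every
#' read leaves the track unchanged).
#'
#' @param aln an `alignments` object.
#' @param chrom_lengths named vector of chromosome lengths; defaults to the
#'   lengths recorded in `aln`'s header.
#' @param window_size window width in bp (default 5).
#' @return Object of class `windowed_track`: list of per-chromosome value
#'   vectors plus `window_size`, `scale` and `chrom_lengths`.
#' @export
windowed_tpm <- function(aln, chrom_lengths = NULL, window_size = 5L) {
  window_size <- as.integer(window_size)
  stopifnot(window_size >= 1L)
  if (is.null(chrom_lengths)) chrom_lengths <- attr(aln, "chrom_lengths")
  if (is.null(chrom_lengths) || !length(chrom_lengths))
    stop("chromosome lengths are required (none recorded in the alignments)")
  n_reads <- attr(aln, "n_reads")
  scale <- if (n_reads > 0) 1e6 / n_reads else 0
  values <- lapply(names(chrom_lengths), function(ch) {
    len <- as.integer(chrom_lengths[[ch]])
    nwin <- ceiling(len / window_size)
    bl <- aln[aln$chrom == ch, , drop = FALSE]
    if (nrow(bl) == 0L) return(numeric(nwin))
    ir <- IRanges::IRanges(bl$start + 1L, pmin(bl$end, len))
    cov <- IRanges::coverage(ir, width = len)
    starts <- seq.int(1L, len, by = window_size)
    v <- IRanges::Views(cov, start = starts,
                        end = pmin(starts + window_size - 1L, len))
    IRanges::viewMeans(v) * scale
  })
  names(values) <- names(chrom_lengths)
  structure(list(values = values, window_size = window_size, scale = scale,
                 chrom_lengths = chrom_lengths, n_reads = n_reads),
            class = "windowed_track")
}

#' @export
print.windowed_track <- function(x, ...) {
  cat(sprintf("windowed_track: %d chromosome(s), %d-bp windows, scale %.4g per read\n",
              length(x$values), x$window_size, x$scale))
  invisible(x)
}

#' Export a windowed track as bedGraph
#'
#' The normalization dialect (scaling constant) is documented in the header
#' comment line.
#'
#' @param track a `windowed_track`.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# ctsplice windowed coverage; window=%dbp; value = mean per-base coverage * 1e6 / %d reads",
            track$window_size, track$n_reads),
    'track type=bedGraph name="ctsplice_windowed_tpm"'), con)
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    len <- track$chrom_lengths[[ch]]
    starts <- seq.int(0L, by = track$window_size, length.out = length(v))
    ends <- pmin(starts + track$window_size, len)
    keep <- v != 0
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%.6g", ch, starts[keep], ends[keep], v[keep]), con)
  }
  invisible(path)
}

#' Scaled gene-body metagene profile (TSS to PAS)
#'
#' Each qualifying gene's genomic span (representative transcript, TSS to PAS
#' in transcription direction) is rescaled to `n_bins` bins; every base takes
#' the value of its covering window and each bin averages its bases, then bins
#' are averaged across genes. Gene-body scaling only — no flanking regions.
#'
#' @param track a `windowed_track` from [windowed_tpm()].
#' @param gene_set a [gene_set].
#' @param n_bins number of bins across the gene body (default 100).
#' @param min_gene_length minimum genomic span; defaults to
#'   `max(n_bins, 10 * window_size)` so every bin receives at least one base.
#' @param exclude_overlapping drop genes whose span overlaps another gene's
#'   span (default keeps them).
#' @return Object of class `metagene_profile`: `bin_means`, `n_genes`,
#'   `n_bins`, `anchors = c("TSS", "PAS")`.
#' @export
metagene_profile <- function(track, gene_set, n_bins = 100L,
                             min_gene_length = NULL,
                             exclude_overlapping = FALSE) {
  stopifnot(inherits(track, "windowed_track"), inherits(gene_set, "gene_set"))
  n_bins <- as.integer(n_bins)
  if (is.null(min_gene_length))
    min_gene_length <- max(n_bins, 10L * track$window_size)
  g <- gene_set$genes
  spans <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    ex <- .tx_exons(gene_set, g$representative[i])
    if (nrow(ex) == 0L) return(NULL)
    data.frame(gene_id = g$gene_id[i], chrom = g$chrom[i], strand = g$strand[i],
               start = min(ex$start), end = max(ex$end), stringsAsFactors = FALSE)
  }))
  if (is.null(spans)) stop("no genes with exons")
  if (exclude_overlapping) {
    keep <- rep(TRUE, nrow(spans))
    for (ch in unique(spans$chrom)) {
      ii <- which(spans$chrom == ch)
      ir <- IRanges::IRanges(spans$start[ii] + 1L, spans$end[ii])
      keep[ii] <- IRanges::countOverlaps(ir, ir) == 1L
    }
    spans <- spans[keep, , drop = FALSE]
  }
  spans <- spans[spans$end - spans$start >= max(min_gene_length, n_bins), , drop = FALSE]
  if (nrow(spans) == 0L) stop("no genes pass the minimum-length requirement")

  w <- track$window_size
  acc <- matrix(0, nrow = nrow(spans), ncol = n_bins)
  for (i in seq_len(nrow(spans))) {
    ch <- spans$chrom[i]
    v <- track$values[[ch]]
    if (is.null(v)) stop("chromosome absent from track: ", ch)
    pos <- spans$start[i]:(spans$end[i] - 1L)
    vals <- v[(pos %/% w) + 1L]
    len <- length(pos)
    rel <- seq_len(len) - 1L
    if (spans$strand[i] == "-") rel <- rev(rel)
    bins <- as.integer(floor(rel * (n_bins / len))) + 1L
    acc[i, ] <- rowsum(vals, bins)[, 1] / tabulate(bins, n_bins)
  }
  structure(list(bin_means = colMeans(acc), n_bins = n_bins,
                 n_genes = nrow(spans), anchors = c("TSS", "PAS")),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf("metagene_profile: %d bins (%s -> %s), %d gene(s); slope %.3f\n",
              x$n_bins, x$anchors[1], x$anchors[2], x$n_genes,
              profile_slope(x)))
  invisible(x)
}

#' @export
plot.metagene_profile <- function(x, ...) {
  graphics::plot(seq_len(x$n_bins), x$bin_means, type = "l",
                 xlab = sprintf("scaled gene body (%s -> %s)",
                                x$anchors[1], x$anchors[2]),
                 ylab = "mean scaled coverage", xaxt = "n", ...)
  graphics::axis(1, at = c(1, x$n_bins), labels = x$anchors)
  invisible(x)
}

#' Spearman slope of a metagene profile
#'
#' Rank correlation between bin index and bin mean; negative values indicate
#' the 5' to 3' decline characteristic of nascent (chromatin-bound) RNA. A
#' constant profile is degenerate: the slope is reported as 0 with attribute
#' `flagged = TRUE`.
#'
#' @param profile a `metagene_profile` (needs at least 3 bins).
#' @return Spearman correlation in `[-1, 1]`.
#' @export
profile_slope <- function(profile) {
  stopifnot(inherits(profile, "metagene_profile"), profile$n_bins >= 3L)
  y <- profile$bin_means
  if (stats::sd(y) == 0)
    return(structure(0, flagged = TRUE))
  stats::cor(seq_along(y), y, method = "spearman")
}

#' Write a metagene profile as TSV
#'
#' @param profile a `metagene_profile`.
#' @param path output path (columns `bin`, `mean`).
#' @export
write_profile <- function(profile, path) {
  utils::write.table(
    data.frame(bin = seq_len(profile$n_bins), mean = profile$bin_means),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
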