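# Alignment ingest: read filtering, CIGAR-resolved blocks, coverage.
#
# A read's "blocks" are the half-open genomic intervals its alignment covers on
# the reference: M/=/X and D operations consume reference into blocks (deletions
# are sequenced through), N splice skips open a new block, I/S/H consume no
# reference. Blocks are stored 0-based half-open, one row per block.

#' Read filter configuration
#'
#' The default configuration reproduces the filtering used for CB-RNA-seq:
#' uniquely mapped reads only (multi-mappers excluded), unstranded counting
#' (antisense reads kept), no mapping-quality floor, duplicates kept (no
#' deduplication step is applied to these libraries).
#'
#' @param unique_only drop reads flagged secondary/supplementary or whose
#'   alignment-hit-count tag (`NH`) exceeds 1.
#' @param min_mapq minimum mapping quality (0 = no filter).
#' @param strand_policy `"unstranded"`, `"sense"` or `"antisense"`; applied by
#'   the counting functions relative to each gene's strand (fragment
#'   orientation, i.e. read2 of a pair counts on its mate's strand).
#' @param exclude_duplicates also drop reads flagged as PCR/optical duplicates.
#' @return An object of class `read_filters`.
#' @export
read_filters <- function(unique_only = TRUE, min_mapq = 0L,
                         strand_policy = c("unstranded", "sense", "antisense"),
                         exclude_duplicates = FALSE) {
  structure(list(
    unique_only = isTRUE(unique_only),
    min_mapq = as.integer(min_mapq),
    strand_policy = match.arg(strand_policy),
    exclude_duplicates = isTRUE(exclude_duplicates)
  ), class = "read_filters")
}

.FLAG_UNMAPPED <- 4L
.FLAG_SECONDARY <- 256L
.FLAG_DUP <- 1024L
.FLAG_SUPPLEMENTARY <- 2048L

.as_alignments <- function(blocks, n_reads, n_fragments, chrom_lengths = NULL,
                           read_length = NA_real_) {
  rownames(blocks) <- NULL
  structure(blocks,
            n_reads = n_reads,
            n_fragments = n_fragments,
            chrom_lengths = chrom_lengths,
            read_length = read_length,
            class = c("alignments", "data.frame"))
}

#' @export
print.alignments <- function(x, ...) {
  cat(sprintf("alignments: %d read(s), %d fragment(s), %d block row(s)\n",
              attr(x, "n_reads"), attr(x, "n_fragments"), nrow(x)))
  invisible(x)
}

#' Load filtered alignments from SAM/BAM
#'
#' Reads aligned records, applies the filter set, and decodes every CIGAR into
#' reference-space blocks. SAM input is converted through [Rsamtools::asBam()].
#' A record whose CIGAR query width disagrees with its sequence length is an
#' error naming the record.
#'
#' @param path SAM or BAM file.
#' @param filters a [read_filters] configuration.
#' @return An `alignments` object: a data.frame with one row per aligned block
#'   (`read_id`, `frag_id`, `chrom`, `strand` (alignment), `fstrand` (fragment
#'   orientation), `mate_role`, `start`, `end`; 0-based half-open) carrying
#'   attributes `n_reads`, `n_fragments`, `chrom_lengths`, `read_length`.
#' @export
read_alignments <- function(path, filters = read_filters()) {
  stopifnot(inherits(filters, "read_filters"))
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (tolower(tools::file_ext(path)) == "sam") {
    dest <- tempfile(fileext = ".bam")
    path <- Rsamtools::asBam(path, sub("\\.bam$", "", dest),
                             overwrite = TRUE, indexDestination = FALSE)
  }
  hdr <- Rsamtools::scanBamHeader(path)[[1]]
  chrom_lengths <- hdr$targets
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar", "qwidth"),
    tag = "NH"
  )
  b <- Rsamtools::scanBam(path, param = param)[[1]]
  flag <- b$flag
  keep <- !is.na(b$pos) & bitwAnd(flag, .FLAG_UNMAPPED) == 0L
  mask <- .FLAG_SECONDARY + .FLAG_SUPPLEMENTARY
  if (filters$unique_only) {
    keep <- keep & bitwAnd(flag, mask) == 0L
    nh <- b$tag$NH
    if (!is.null(nh)) keep <- keep & (is.na(nh) | nh == 1L)
  }
  if (filters$exclude_duplicates)
    keep <- keep & bitwAnd(flag, .FLAG_DUP) == 0L
  if (filters$min_mapq > 0L)
    keep <- keep & !is.na(b$mapq) & b$mapq >= filters$min_mapq

  qname <- b$qname[keep]
  flag <- flag[keep]
  cigar <- b$cigar[keep]
  pos <- b$pos[keep]
  chrom <- as.character(b$rname[keep])
  strand <- as.character(b$strand[keep])
  qwidth <- b$qwidth[keep]

  qw_cigar <- GenomicAlignments::cigarWidthAlongQuerySpace(cigar)
  bad <- !is.na(qwidth) & qwidth > 0L & qw_cigar != qwidth
  if (any(bad))
    stop(sprintf("CIGAR/sequence length mismatch for record '%s'",
                 qname[which(bad)[1]]))

  paired <- bitwAnd(flag, 1L) != 0L
  read2 <- paired & bitwAnd(flag, 128L) != 0L
  mate_role <- ifelse(!paired, "unpaired", ifelse(read2, "read2", "read1"))
  fstrand <- ifelse(read2, ifelse(strand == "+", "-", "+"), strand)
  frag_id <- match(qname, unique(qname))

  rl <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cigar, pos = pos, ops = c("M", "=", "X", "D"), reduce.ranges = TRUE)
  nb <- S4Vectors::elementNROWS(rl)
  fl <- unlist(rl, use.names = FALSE)
  idx <- rep.int(seq_along(cigar), nb)
  blocks <- data.frame(
    read_id = idx,
    frag_id = frag_id[idx],
    chrom = chrom[idx],
    strand = strand[idx],
    fstrand = fstrand[idx],
    mate_role = mate_role[idx],
    start = BiocGenerics::start(fl) - 1L,
    end = BiocGenerics::end(fl),
    stringsAsFactors = FALSE
  )
  .as_alignments(blocks,
                 n_reads = length(cigar),
                 n_fragments = length(unique(frag_id)),
                 chrom_lengths = chrom_lengths,
                 read_length = stats::median(qw_cigar))
}

.blocks_by_chrom <- function(aln, chrom, strand = NULL) {
  sel <- aln$chrom == chrom
  if (!is.null(strand)) sel <- sel & aln$fstrand == strand
  aln[sel, , drop = FALSE]
}

#' Count reads covering single genomic positions
#'
#' A read covers a position when one of its aligned blocks contains it
#' (half-open: a block `[s, e)` covers `s` up to `e - 1`; splice skips are not
#' covered). Vectorised over `pos`.
#'
#' @param aln an `alignments` object.
#' @param chrom chromosome name (scalar).
#' @param pos 0-based genomic position(s).
#' @param strand optional fragment strand to restrict to (`"+"`/`"-"`).
#' @return Integer vector of read counts, one per position.
#' @export
coverage_at <- function(aln, chrom, pos, strand = NULL) {
  stopifnot(all(pos >= 0))
  bl <- .blocks_by_chrom(aln, chrom, strand)
  if (nrow(bl) == 0L) return(integer(length(pos)))
  IRanges::countOverlaps(
    IRanges::IRanges(start = as.integer(pos) + 1L, width = 1L),
    IRanges::IRanges(start = bl$start + 1L, end = bl$end)
  )
}

#' Per-base pileup over a region
#'
#' @param aln an `alignments` object.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open region bounds (`start < end`).
#' @param strand optional fragment strand restriction.
#' @return Integer vector of length `end - start`; element `i` is the number of
#'   reads covering position `start + i - 1`.
#' @export
region_pileup <- function(aln, chrom, start, end, strand = NULL) {
  stopifnot(start < end, start >= 0)
  bl <- .blocks_by_chrom(aln, chrom, strand)
  if (nrow(bl) == 0L) return(integer(end - start))
  ir <- IRanges::IRanges(start = bl$start + 1L, end = bl$end)
  cov <- IRanges::coverage(ir, width = max(end, max(bl$end)) + 1L)
  as.integer(cov[(start + 1L):end])
}
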