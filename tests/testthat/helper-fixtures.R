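# Fixtures are built in code; oracles here are deliberately naive and
# independent of the package's implementation paths.

# -- gene-set builders ---------------------------------------------------------

one_gene_set <- function(exon_starts, exon_ends, strand = "+", chrom = "chr1",
                         gene_id = "g1") {
  gene_set(
    genes = data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                       stringsAsFactors = FALSE),
    transcripts = data.frame(transcript_id = paste0(gene_id, ".1"),
                             gene_id = gene_id, stringsAsFactors = FALSE),
    exons = data.frame(transcript_id = paste0(gene_id, ".1"),
                       start = exon_starts, end = exon_ends,
                       stringsAsFactors = FALSE)
  )
}

# -- in-memory alignments builder ---------------------------------------------

# blocks: data.frame(read_id, start, end) in 0-based half-open coords;
# one row per block, shared read_id = one (possibly spliced) read
make_alignments <- function(blocks, chrom = "chr1", strand = "+",
                            chrom_lengths = NULL, read_length = NA_real_) {
  n_reads <- length(unique(blocks$read_id))
  n <- nrow(blocks)
  bl <- data.frame(
    read_id = blocks$read_id,
    frag_id = blocks$read_id,
    chrom = rep_len(chrom, n),
    strand = rep_len(strand, n),
    fstrand = rep_len(strand, n),
    mate_role = rep_len("unpaired", n),
    start = as.integer(blocks$start),
    end = as.integer(blocks$end),
    stringsAsFactors = FALSE
  )
  ctsplice:::.as_alignments(bl, n_reads = n_reads, n_fragments = n_reads,
                            chrom_lengths = chrom_lengths,
                            read_length = read_length)
}

# -- SAM text writer -----------------------------------------------------------

write_test_sam <- function(path, records, chrom_lengths = c(chr1 = 100000L)) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*%s",
                  records$qname, records$flag, records$chrom, records$pos,
                  records$mapq, records$cigar,
                  ifelse(is.na(records$nh), "", sprintf("\tNH:i:%d", records$nh)))
  ord <- order(records$chrom, records$pos)
  writeLines(c(hdr, body[ord]), path)
  path
}

random_sam_records <- function(n, max_pos = 5000L) {
  pos <- sample.int(max_pos, n, replace = TRUE)
  kind <- sample(3, n, replace = TRUE)
  m1 <- sample(10:60, n, replace = TRUE)
  gap <- sample(30:300, n, replace = TRUE)
  m2 <- sample(10:60, n, replace = TRUE)
  cigar <- ifelse(kind == 1, sprintf("%dM", m1),
           ifelse(kind == 2, sprintf("%dM%dN%dM", m1, gap, m2),
                  sprintf("%dM%dD%dM", m1, pmin(gap, 20L), m2)))
  data.frame(qname = sprintf("r%04d", seq_len(n)), flag = 0L, chrom = "chr1",
             pos = pos, mapq = 60L, cigar = cigar, nh = 1L,
             stringsAsFactors = FALSE)
}

# reference bases consumed by a CIGAR, by direct token walk
cigar_ref_width <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  n <- as.integer(sub("[A-Z=]", "", ops))
  op <- sub("[0-9]+", "", ops)
  sum(n[op %in% c("M", "D", "N", "=", "X")])
}

# -- naive oracles -------------------------------------------------------------

# per-read, per-base accumulation pileup
naive_pileup <- function(aln, chrom, start, end) {
  v <- integer(end - start)
  bl <- aln[aln$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(bl))) {
    for (p in seq(bl$start[i], bl$end[i] - 1L)) {
      if (p >= start && p < end) v[p - start + 1L] <- v[p - start + 1L] + 1L
    }
  }
  v
}

# exact Wilcoxon rank-sum p by enumeration over all assignments of the pooled
# values themselves (recomputes ranks per assignment; independent of the
# package's midrank shortcut)
brute_wilcoxon_p <- function(a, b, alternative = "two.sided") {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  r <- rank(pooled)
  stat <- function(idx) sum(r[idx]) - na * (na + 1) / 2
  obs <- stat(seq_len(na))
  mu <- na * length(b) / 2
  all_idx <- utils::combn(n, na)
  Us <- apply(all_idx, 2, stat)
  eps <- 1e-9
  switch(alternative,
    two.sided = mean(abs(Us - mu) >= abs(obs - mu) - eps),
    less = mean(Us <= obs + eps),
    greater = mean(Us >= obs - eps))
}

# naive metagene: raw per-base pileup, scaled, per-gene base-level rebinning
naive_metagene <- function(aln, gs, chrom_lengths, window = 5L, n_bins = 100L) {
  scale <- 1e6 / attr(aln, "n_reads")
  g <- gs$genes
  prof <- matrix(NA_real_, nrow(g), n_bins)
  for (i in seq_len(nrow(g))) {
    ex <- gs$exons[gs$exons$transcript_id == g$representative[i], , drop = FALSE]
    span <- c(min(ex$start), max(ex$end))
    len <- span[2] - span[1]
    pb <- naive_pileup(aln, g$chrom[i], 0L, chrom_lengths[[g$chrom[i]]])
    # per-base value = mean coverage of the tiling window containing the base
    base_vals <- numeric(len)
    for (k in seq_len(len)) {
      p <- span[1] + k - 1L
      w0 <- (p %/% window) * window
      w1 <- min(w0 + window, chrom_lengths[[g$chrom[i]]])
      base_vals[k] <- mean(pb[(w0 + 1L):w1]) * scale
    }
    rel <- seq_len(len) - 1L
    if (g$strand[i] == "-") rel <- rev(rel)
    bins <- floor(rel * n_bins / len) + 1L
    for (bq in seq_len(n_bins)) prof[i, bq] <- mean(base_vals[bins == bq])
  }
  colMeans(prof)
}

# map a read's genomic blocks back through its source molecule's splice state;
# returns the molecule-coordinate interval(s) covered
liftback_to_molecule <- function(blocks_df, seg, states_row, pol) {
  kept <- pmax(0L, pmin(pol, seg$pend) - seg$pstart)
  iord <- seg$intron_order
  kept[seg$type == "I" & states_row[pmax(iord, 1L)] == 0L & iord > 0L] <- 0L
  moff <- cumsum(kept) - kept  # molecule offset of each segment's kept part
  res <- NULL
  for (r in seq_len(nrow(blocks_df))) {
    gs0 <- blocks_df$start[r]
    ge0 <- blocks_df$end[r]
    for (s in seq_len(nrow(seg))) {
      if (kept[s] == 0L) next
      # genomic interval of the kept part of segment s
      if (attr(seg, "strand") == "+") {
        ka <- seg$gstart[s]; kb <- seg$gstart[s] + kept[s]
      } else {
        ka <- seg$gend[s] - kept[s]; kb <- seg$gend[s]
      }
      a <- max(gs0, ka); b <- min(ge0, kb)
      if (b <= a) next
      if (attr(seg, "strand") == "+") {
        res <- rbind(res, c(moff[s] + (a - ka), moff[s] + (b - ka)))
      } else {
        res <- rbind(res, c(moff[s] + (kb - b), moff[s] + (kb - a)))
      }
    }
  }
  res <- res[order(res[, 1]), , drop = FALSE]
  res
}
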