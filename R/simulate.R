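# Mechanistic simulator of the three chromatin RNA populations.
#
# A locus's chromatin-bound RNA is modelled as a mixture of:
#   RNAe - elongating transcripts truncated at the polymerase position (drawn
#          uniformly along the pre-mRNA); an intron whose 3'SS lies d bases
#          upstream of the polymerase has been spliced with probability
#          1 - exp(-d / lambda) ("first come, first serve" maturation).
#   RNAf - full-length, polyadenylated but still chromatin-associated RNA;
#          each intron retained independently with probability r.
#   mRNA - mature message, fully spliced, optional 3' fragment-position bias.
# Cooperativity c > 1 multiplies the splicing rate of an intron per
# already-spliced adjacent intron (two-stage draw; c = 1 is independence).
# Reads are uniform-start fragments of the (possibly truncated, possibly
# spliced) molecule, lifted back to genome coordinates as multi-block
# alignments with N skips across spliced introns, with exact per-junction
# ground truth recomputable from the emitted molecules.

#' Simulator configuration
#'
#' Defaults describe a compact plant-like genome: short exons and introns
#' (log-normal, median 150 bp), genes of 2-10 exons on a single synthetic
#' chromosome with >= 500 bp spacing, 75-bp reads, and a chromatin RNA mixture
#' dominated by elongating transcripts with a small polyadenylated fraction
#' (RNAe 0.9 / RNAf 0.1), maturation length lambda = 2000 bp (about one mean
#' gene length), RNAf per-intron retention 0.05, no cooperativity, no mRNA
#' 3' bias. Identical seed and config give identical output.
#'
#' @param n_genes number of genes.
#' @param exon_count_range inclusive integer range of exons per transcript.
#' @param exon_length,intron_length `c(meanlog, sdlog)` of the log-normal
#'   length distributions (bp; lengths are floored at `min_exon`/`min_intron`).
#' @param min_exon,min_intron minimum feature lengths (bp).
#' @param read_length read length (bp).
#' @param depth target mean boundary coverage: the expected read coverage of a
#'   base present in every molecule of a gene.
#' @param n_molecules molecules simulated per gene (the pool reads sample
#'   from; keep well above the junction coverage target so reads are a light
#'   sample of the population).
#' @param fraction_mix named weights for `mRNA`, `RNAe`, `RNAf` (sum to 1).
#' @param maturation_length lambda (bp): splicing probability of a fully
#'   transcribed intron at polymerase distance d is `1 - exp(-d / lambda)`.
#' @param rnaf_retention per-intron retention probability r for RNAf.
#' @param cooperativity multiplier c (>= 1) on the splicing rate per
#'   already-spliced neighbouring intron.
#' @param three_prime_bias beta >= 0: mRNA fragment-start density is
#'   proportional to `1 + beta * x` with x the relative molecule position.
#' @param gene_spacing minimum intergenic distance (bp).
#' @param chrom synthetic chromosome name.
#' @param seed integer RNG seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 50L,
                       exon_count_range = c(2L, 10L),
                       exon_length = c(meanlog = log(150), sdlog = 0.45),
                       intron_length = c(meanlog = log(150), sdlog = 0.45),
                       min_exon = 25L, min_intron = 60L,
                       read_length = 75L,
                       depth = 100,
                       n_molecules = 2000L,
                       fraction_mix = c(mRNA = 0, RNAe = 0.9, RNAf = 0.1),
                       maturation_length = 2000,
                       rnaf_retention = 0.05,
                       cooperativity = 1,
                       three_prime_bias = 0,
                       gene_spacing = 500L,
                       chrom = "chrS",
                       seed = 1L) {
  mix <- fraction_mix[c("mRNA", "RNAe", "RNAf")]
  if (anyNA(mix)) stop("fraction_mix needs named weights mRNA, RNAe, RNAf")
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8)
    stop("fraction_mix weights must be nonnegative and sum to 1")
  if (maturation_length <= 0) stop("maturation_length must be > 0")
  if (rnaf_retention < 0 || rnaf_retention > 1)
    stop("rnaf_retention must be in [0, 1]")
  if (cooperativity <= 0) stop("cooperativity must be > 0")
  if (three_prime_bias < 0) stop("three_prime_bias must be >= 0")
  stopifnot(length(exon_count_range) == 2L,
            exon_count_range[1] >= 1L,
            exon_count_range[2] >= exon_count_range[1])
  structure(list(
    n_genes = as.integer(n_genes),
    exon_count_range = as.integer(exon_count_range),
    exon_length = exon_length, intron_length = intron_length,
    min_exon = as.integer(min_exon), min_intron = as.integer(min_intron),
    read_length = as.integer(read_length),
    depth = depth,
    n_molecules = as.integer(n_molecules),
    fraction_mix = mix,
    maturation_length = maturation_length,
    rnaf_retention = rnaf_retention,
    cooperativity = cooperativity,
    three_prime_bias = three_prime_bias,
    gene_spacing = as.integer(gene_spacing),
    chrom = chrom,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a synthetic genome and gene models
#'
#' Places `n_genes` non-overlapping genes with sampled exon/intron structure on
#' both strands of one synthetic chromosome and draws a random nucleotide
#' sequence. Deterministic under the config seed.
#'
#' @param config a [sim_config].
#' @return list with `genome` (named character vector of sequence),
#'   `gene_set` (a [gene_set]) and `chrom_lengths`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  margin <- 200L
  cursor <- margin
  genes <- transcripts <- exons <- NULL
  if (n > 0L) {
    glist <- vector("list", n)
    for (i in seq_len(n)) {
      ne <- if (config$exon_count_range[1] == config$exon_count_range[2])
        config$exon_count_range[1]
      else sample(config$exon_count_range[1]:config$exon_count_range[2], 1L)
      el <- pmax(config$min_exon,
                 round(stats::rlnorm(ne, config$exon_length["meanlog"],
                                     config$exon_length["sdlog"])))
      il <- if (ne > 1L)
        pmax(config$min_intron,
             round(stats::rlnorm(ne - 1L, config$intron_length["meanlog"],
                                 config$intron_length["sdlog"])))
      else integer(0)
      seg <- integer(2L * ne - 1L)
      seg[seq(1L, 2L * ne - 1L, by = 2L)] <- el
      if (ne > 1L) seg[seq(2L, 2L * ne - 2L, by = 2L)] <- il
      bounds <- cursor + c(0L, cumsum(seg))
      ex_start <- bounds[seq(1L, 2L * ne - 1L, by = 2L)]
      ex_end <- bounds[seq(2L, 2L * ne, by = 2L)]
      strand <- sample(c("+", "-"), 1L)
      gid <- sprintf("SYNG%04d", i)
      glist[[i]] <- list(
        gene = data.frame(gene_id = gid, chrom = config$chrom, strand = strand,
                          stringsAsFactors = FALSE),
        tx = data.frame(transcript_id = paste0(gid, ".1"), gene_id = gid,
                        stringsAsFactors = FALSE),
        ex = data.frame(transcript_id = paste0(gid, ".1"),
                        start = ex_start, end = ex_end,
                        stringsAsFactors = FALSE)
      )
      cursor <- bounds[length(bounds)] + config$gene_spacing
    }
    genes <- do.call(rbind, lapply(glist, `[[`, "gene"))
    transcripts <- do.call(rbind, lapply(glist, `[[`, "tx"))
    exons <- do.call(rbind, lapply(glist, `[[`, "ex"))
  } else {
    genes <- data.frame(gene_id = character(), chrom = character(),
                        strand = character(), stringsAsFactors = FALSE)
    transcripts <- data.frame(transcript_id = character(), gene_id = character(),
                              stringsAsFactors = FALSE)
    exons <- data.frame(transcript_id = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE)
  }
  chrom_length <- cursor + margin
  genome <- paste(sample(c("A", "C", "G", "T"), chrom_length, replace = TRUE),
                  collapse = "")
  names(genome) <- config$chrom
  gs <- gene_set(genes, transcripts, exons, dialect = "GTF")
  list(genome = genome, gene_set = gs,
       chrom_lengths = stats::setNames(chrom_length, config$chrom))
}

# segment map of one gene in transcription order: exons and introns with
# genomic interval [gstart, gend) and pre-mRNA offsets [pstart, pend)
.gene_segments <- function(gene_set, gene_id) {
  g <- gene_set$genes[gene_set$genes$gene_id == gene_id, , drop = FALSE]
  if (nrow(g) == 0L) stop("unknown gene: ", gene_id)
  ex <- .tx_exons(gene_set, g$representative)
  n <- nrow(ex)
  seg <- data.frame(
    type = rep(c("E", "I"), length.out = 2L * n - 1L),
    gstart = integer(2L * n - 1L), gend = integer(2L * n - 1L)
  )
  seg$gstart[seq(1L, 2L * n - 1L, 2L)] <- ex$start
  seg$gend[seq(1L, 2L * n - 1L, 2L)] <- ex$end
  if (n > 1L) {
    seg$gstart[seq(2L, 2L * n - 2L, 2L)] <- ex$end[-n]
    seg$gend[seq(2L, 2L * n - 2L, 2L)] <- ex$start[-1]
  }
  if (g$strand == "-") seg <- seg[rev(seq_len(nrow(seg))), , drop = FALSE]
  seg$len <- seg$gend - seg$gstart
  seg$pend <- cumsum(seg$len)
  seg$pstart <- seg$pend - seg$len
  seg$intron_order <- cumsum(seg$type == "I") * (seg$type == "I")
  rownames(seg) <- NULL
  seg
}

.draw_splice_states <- function(n_introns, pol, fraction, seg, config) {
  # states: 0 spliced, 1 retained, 2 not yet (fully) transcribed
  N <- length(pol)
  states <- matrix(0L, nrow = N, ncol = max(n_introns, 1L))
  if (n_introns == 0L) return(states[, 0, drop = FALSE])
  lam <- config$maturation_length
  r <- config$rnaf_retention
  cc <- config$cooperativity
  iseg <- seg[seg$type == "I", , drop = FALSE]
  is_e <- fraction == "RNAe"
  is_f <- fraction == "RNAf"
  d <- matrix(0, N, n_introns)
  for (j in seq_len(n_introns)) {
    pe <- iseg$pend[j]
    d[, j] <- pmax(pol - pe, 0)
    full <- pol >= pe
    st <- integer(N)                       # mRNA default: spliced
    # RNAe: fully transcribed introns splice with 1 - exp(-d/lambda)
    idx <- which(is_e & full)
    if (length(idx)) {
      p <- 1 - exp(-d[idx, j] / lam)
      st[idx] <- ifelse(stats::runif(length(idx)) < p, 0L, 1L)
    }
    st[is_e & !full] <- 2L
    idx <- which(is_f)
    if (length(idx))
      st[idx] <- ifelse(stats::runif(length(idx)) < r, 1L, 0L)
    states[, j] <- st
  }
  if (cc != 1) {
    # stage 2: still-unspliced introns re-drawn with the rate multiplied by
    # c per stage-1-spliced adjacent intron
    s1 <- states == 0L
    for (j in seq_len(n_introns)) {
      nb <- integer(N)
      if (j > 1L) nb <- nb + s1[, j - 1L]
      if (j < n_introns) nb <- nb + s1[, j + 1L]
      idx <- which(is_e & states[, j] == 1L & nb > 0L)
      if (length(idx)) {
        p2 <- pmax(0, 1 - exp(-d[idx, j] * (cc^nb[idx] - 1) / lam))
        states[idx, j] <- ifelse(stats::runif(length(idx)) < p2, 0L, 1L)
      }
      idx <- which(is_f & states[, j] == 1L & nb > 0L)
      if (length(idx)) {
        keep <- pmin(1, cc^(-nb[idx]))
        states[idx, j] <- ifelse(stats::runif(length(idx)) < keep, 1L, 0L)
      }
    }
  }
  states
}

#' Simulate transcript molecules
#'
#' Draws, per gene, `n_molecules` molecules from the configured fraction mix:
#' mRNA fully spliced; RNAe truncated at a uniform polymerase position with
#' maturation-length splicing of fully transcribed introns; RNAf full length
#' with per-intron retention. Per-junction ground truth (the unspliced fraction
#' among boundary-covering molecules, per splice-site side) is tabulated by
#' exhaustive enumeration of the emitted molecules.
#'
#' @param sim output of [simulate_genome()] (or a [gene_set]).
#' @param config a [sim_config].
#' @return Object of class `sim_molecules`: per-gene molecule records
#'   (`fraction`, `pol`, `states`, segment map), the `truth` table
#'   (`gene_id`, `order`, `side`, `n_covering`, `n_unspliced`, `u`) and
#'   realized fraction counts.
#' @export
simulate_molecules <- function(sim, config) {
  stopifnot(inherits(config, "sim_config"))
  gs <- if (inherits(sim, "gene_set")) sim else sim$gene_set
  set.seed(config$seed + 1L)
  fr_levels <- c("mRNA", "RNAe", "RNAf")
  per_gene <- list()
  truth <- list()
  fraction_counts <- stats::setNames(numeric(3), fr_levels)
  for (gid in gs$genes$gene_id) {
    seg <- .gene_segments(gs, gid)
    plen <- sum(seg$len)
    N <- config$n_molecules
    fraction <- fr_levels[sample.int(3L, N, replace = TRUE,
                                     prob = config$fraction_mix)]
    fraction_counts <- fraction_counts + table(factor(fraction, fr_levels))
    pol <- rep(plen, N)
    is_e <- fraction == "RNAe"
    pol[is_e] <- sample.int(plen, sum(is_e), replace = TRUE)
    n_introns <- sum(seg$type == "I")
    states <- .draw_splice_states(n_introns, pol, fraction, seg, config)
    per_gene[[gid]] <- list(segments = seg, fraction = fraction, pol = pol,
                            states = states)
    if (n_introns > 0L) {
      iseg <- seg[seg$type == "I", , drop = FALSE]
      for (j in seq_len(n_introns)) {
        for (side in c("5p", "3p")) {
          cov <- if (side == "5p") pol >= iseg$pstart[j] + 1L
                 else pol >= iseg$pend[j]
          nc <- sum(cov)
          nu <- sum(cov & states[, j] != 0L)
          truth[[length(truth) + 1L]] <- data.frame(
            gene_id = gid, order = j, side = side,
            n_covering = nc, n_unspliced = nu,
            u = if (nc > 0) nu / nc else NA_real_,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(gene_id = character(), order = integer(), side = character(),
               n_covering = integer(), n_unspliced = integer(), u = numeric(),
               stringsAsFactors = FALSE)
  structure(list(per_gene = per_gene, truth = truth,
                 fraction_counts = fraction_counts, config = config,
                 gene_set = gs),
            class = "sim_molecules")
}

#' @export
print.sim_molecules <- function(x, ...) {
  cat(sprintf("sim_molecules: %d gene(s) x %d molecules; mix mRNA/RNAe/RNAf = %s\n",
              length(x$per_gene), x$config$n_molecules,
              paste(round(x$fraction_counts), collapse = "/")))
  invisible(x)
}

#' True per-junction retention from simulated molecules
#'
#' The exact fraction of boundary-covering molecules in which the intron is
#' retained or not yet spliced, by enumeration of the emitted molecules — the
#' oracle the splice-site ratio estimates.
#'
#' @param truth a `sim_molecules` object or its `truth` table.
#' @param gene_id,order junction identity.
#' @param side `"5p"` or `"3p"`.
#' @return The true unspliced fraction (scalar).
#' @export
true_retention <- function(truth, gene_id, order, side = c("5p", "3p")) {
  side <- match.arg(side)
  tab <- if (inherits(truth, "sim_molecules")) truth$truth else truth
  row <- tab[tab$gene_id == gene_id & tab$order == order & tab$side == side, ]
  if (nrow(row) == 0L) stop("unknown junction: ", gene_id, " intron ", order)
  row$u[1]
}

.rowcumsum <- function(m) {
  if (ncol(m) > 1L)
    for (j in 2:ncol(m)) m[, j] <- m[, j - 1L] + m[, j]
  m
}

#' Simulate reads from molecules
#'
#' Fragments of `read_length` start uniformly on each molecule (molecules
#' sampled proportionally to their number of possible start positions; mRNA
#' starts optionally skewed 3' by `three_prime_bias`), and read coordinates are
#' lifted from molecule to genome space, producing multi-block alignments whose
#' N skips equal the spliced introns. Molecules shorter than the read length
#' are skipped (count recorded in attribute `n_too_short`).
#'
#' @param mol a `sim_molecules` object.
#' @param config a [sim_config] (defaults to the one stored in `mol`).
#' @param chrom_lengths chromosome lengths recorded on the output (optional).
#' @return An `alignments` object (as from [read_alignments()]), with the
#'   per-gene read counts in attribute `reads_per_gene`.
#' @export
simulate_reads <- function(mol, config = mol$config, chrom_lengths = NULL) {
  stopifnot(inherits(mol, "sim_molecules"))
  set.seed(config$seed + 2L)
  L <- config$read_length
  beta <- config$three_prime_bias
  gs <- mol$gene_set
  blocks <- list()
  read_mol <- list()
  read_offset <- 0L
  n_too_short <- 0L
  reads_per_gene <- stats::setNames(integer(length(mol$per_gene)),
                                    names(mol$per_gene))
  for (gid in names(mol$per_gene)) {
    pg <- mol$per_gene[[gid]]
    seg <- pg$segments
    S <- nrow(seg)
    N <- length(pg$pol)
    strand <- gs$genes$strand[gs$genes$gene_id == gid]
    chrom <- gs$genes$chrom[gs$genes$gene_id == gid]
    # kept length of each segment per molecule: truncation at pol, spliced
    # introns removed entirely (an intron can only be spliced once fully
    # transcribed)
    K <- matrix(0L, N, S)
    for (s in seq_len(S)) {
      kept <- pmax(0L, pmin(pg$pol, seg$pend[s]) - seg$pstart[s])
      if (seg$type[s] == "I") {
        j <- seg$intron_order[s]
        kept[pg$states[, j] == 0L] <- 0L
      }
      K[, s] <- kept
    }
    M <- rowSums(K)
    wts <- pmax(M - L + 1, 0)
    n_too_short <- n_too_short + sum(wts == 0 & M > 0)
    if (all(wts == 0)) next
    n_reads <- as.integer(round(config$depth * sum(M) / (L * N)))
    if (n_reads <= 0L) next
    reads_per_gene[gid] <- n_reads
    mi <- sample.int(N, n_reads, replace = TRUE, prob = wts)
    read_mol[[gid]] <- data.frame(read_id = read_offset + seq_len(n_reads),
                                  gene_id = gid, molecule = mi,
                                  stringsAsFactors = FALSE)
    u <- stats::runif(n_reads)
    if (beta > 0) {
      is_m <- pg$fraction[mi] == "mRNA"
      if (any(is_m)) {
        q <- u[is_m] * (1 + beta / 2)
        u[is_m] <- (-1 + sqrt(1 + 2 * beta * q)) / beta
      }
    }
    s0 <- floor(u * (M[mi] - L + 1))          # molecule-coordinate start
    s1 <- s0 + L
    Kc <- .rowcumsum(K)
    Cend <- Kc[mi, , drop = FALSE]
    Cstart <- Cend - K[mi, , drop = FALSE]
    pieces <- vector("list", S)
    for (s in seq_len(S)) {
      a <- pmax(s0, Cstart[, s])
      b <- pmin(s1, Cend[, s])
      hit <- which(b > a)
      if (!length(hit)) next
      loc <- a[hit] - Cstart[hit, s]
      len <- b[hit] - a[hit]
      if (strand == "+") {
        gstart <- seg$gstart[s] + loc
      } else {
        gstart <- seg$gend[s] - loc - len
      }
      pieces[[s]] <- data.frame(read_id = read_offset + hit,
                                gstart = gstart, gend = gstart + len)
    }
    pc <- do.call(rbind, pieces)
    pc <- pc[order(pc$read_id, pc$gstart), , drop = FALSE]
    # merge genomically abutting pieces (contiguous kept segments)
    nb <- c(TRUE, pc$read_id[-1] != pc$read_id[-nrow(pc)] |
                  pc$gstart[-1] != pc$gend[-nrow(pc)])
    grp <- cumsum(nb)
    start <- pc$gstart[nb]
    end <- pc$gend[c(which(nb)[-1] - 1L, nrow(pc))]
    blocks[[gid]] <- data.frame(
      read_id = pc$read_id[nb],
      frag_id = pc$read_id[nb],
      chrom = chrom,
      strand = strand,
      fstrand = strand,
      mate_role = "unpaired",
      start = as.integer(start),
      end = as.integer(end),
      stringsAsFactors = FALSE
    )
    read_offset <- read_offset + n_reads
  }
  bl <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(read_id = integer(), frag_id = integer(), chrom = character(),
               strand = character(), fstrand = character(),
               mate_role = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)
  out <- .as_alignments(bl, n_reads = read_offset, n_fragments = read_offset,
                        chrom_lengths = chrom_lengths,
                        read_length = as.numeric(L))
  attr(out, "n_too_short") <- n_too_short
  attr(out, "reads_per_gene") <- reads_per_gene
  attr(out, "read_molecule") <- if (length(read_mol))
    do.call(rbind, read_mol) else NULL
  out
}

#' Write alignments as a coordinate-sorted SAM file
#'
#' CIGARs are reconstructed from the block structure (M runs separated by N
#' skips). If `genome` is supplied, read sequences are taken from it and a
#' constant high base quality is emitted; otherwise SEQ/QUAL are `*`.
#'
#' @param aln an `alignments` object.
#' @param chrom_lengths named chromosome lengths for the header.
#' @param path output SAM path.
#' @param genome optional named character vector of chromosome sequences.
#' @export
write_sam <- function(aln, chrom_lengths, path, genome = NULL) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  if (nrow(aln) == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  bl <- aln[order(aln$chrom, aln$read_id, aln$start), , drop = FALSE]
  first <- !duplicated(bl$read_id)
  widths <- bl$end - bl$start
  reads <- data.frame(read_id = bl$read_id[first], chrom = bl$chrom[first],
                      strand = bl$strand[first], pos = bl$start[first] + 1L,
                      stringsAsFactors = FALSE)
  cig <- vapply(split(seq_len(nrow(bl)), match(bl$read_id, reads$read_id)),
                function(ii) {
                  w <- widths[ii]
                  if (length(ii) == 1L) return(sprintf("%dM", w))
                  gaps <- bl$start[ii][-1] - bl$end[ii][-length(ii)]
                  paste0(paste0(w[-length(w)], "M", gaps, "N", collapse = ""),
                         w[length(w)], "M")
                }, character(1))
  if (!is.null(genome)) {
    seqs <- vapply(split(seq_len(nrow(bl)), match(bl$read_id, reads$read_id)),
                   function(ii) {
                     paste(substring(genome[[bl$chrom[ii][1]]],
                                     bl$start[ii] + 1L, bl$end[ii]),
                           collapse = "")
                   }, character(1))
    quals <- strrep("I", nchar(seqs))
  } else {
    seqs <- rep("*", nrow(reads))
    quals <- seqs
  }
  flag <- ifelse(reads$strand == "-", 16L, 0L)
  lines <- sprintf("simread%07d\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s\tNH:i:1",
                   reads$read_id, flag, reads$chrom, reads$pos, cig, seqs, quals)
  ord <- order(reads$chrom, reads$pos)
  writeLines(c(hdr, lines[ord]), path)
  invisible(path)
}

#' Run the full simulator and optionally write its outputs
#'
#' Genome + gene models + molecules + reads in one call. With `out_dir` set,
#' writes `genome.fa`, `genes.gtf`, `reads.sam`, `truth.tsv` and `config.yaml`.
#'
#' @param config a [sim_config].
#' @param out_dir optional output directory.
#' @return list with `genome`, `gene_set`, `chrom_lengths`, `molecules`,
#'   `truth`, `alignments`.
#' @export
simulate_cbrna <- function(config = sim_config(), out_dir = NULL) {
  gen <- simulate_genome(config)
  mol <- simulate_molecules(gen, config)
  aln <- simulate_reads(mol, config, chrom_lengths = gen$chrom_lengths)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    dna <- Biostrings::DNAStringSet(gen$genome)
    Biostrings::writeXStringSet(dna, file.path(out_dir, "genome.fa"))
    write_gtf(gen$gene_set, file.path(out_dir, "genes.gtf"))
    write_sam(aln, gen$chrom_lengths, file.path(out_dir, "reads.sam"),
              genome = gen$genome)
    utils::write.table(mol$truth, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cfg <- unclass(config)
    cfg$fraction_mix <- as.list(cfg$fraction_mix)
    cfg$exon_length <- as.list(cfg$exon_length)
    cfg$intron_length <- as.list(cfg$intron_length)
    yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  }
  list(genome = gen$genome, gene_set = gen$gene_set,
       chrom_lengths = gen$chrom_lengths, molecules = mol,
       truth = mol$truth, alignments = aln)
}

#' Read a simulator configuration from YAML
#'
#' @param path YAML file whose keys are [sim_config()] arguments.
#' @param seed optional seed overriding the file's.
#' @return A [sim_config].
#' @export
read_sim_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$fraction_mix)) y$fraction_mix <- unlist(y$fraction_mix)
  if (!is.null(y$exon_length)) y$exon_length <- unlist(y$exon_length)
  if (!is.null(y$intron_length)) y$intron_length <- unlist(y$intron_length)
  if (!is.null(seed)) y$seed <- seed
  do.call(sim_config, y[intersect(names(y), names(formals(sim_config)))])
}
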