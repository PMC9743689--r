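# Annotation model: genes, transcripts, exons and derived introns.
#
# All coordinates inside the package are 0-based, half-open intervals [start, end).
# GTF/GFF3 files are read as 1-based inclusive and converted on the way in; BED is
# written 0-based half-open. This keeps boundary arithmetic (adjacent exonic base,
# first/last intronic base) unambiguous.

#' Build a gene set from annotation tables
#'
#' Constructs the internal annotation model used throughout the package: a set of
#' genes, their transcripts and exons, with one representative transcript chosen
#' per gene (the transcript with the largest spliced length, i.e. summed exon
#' length; ties broken by the lexicographically smallest transcript id).
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand` ("+"/"-").
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`.
#' @param exons data.frame with columns `transcript_id`, `start`, `end`; 0-based
#'   half-open genomic intervals.
#' @param dialect annotation source dialect, `"GTF"` or `"GFF3"` (informational).
#' @return An object of class `gene_set`: a list with elements `genes`
#'   (including the `representative` transcript id per gene), `transcripts`
#'   (including `spliced_length`) and `exons` (sorted within transcript).
#' @examples
#' gs <- gene_set(
#'   genes = data.frame(gene_id = "g1", chrom = "chr1", strand = "+"),
#'   transcripts = data.frame(transcript_id = "g1.1", gene_id = "g1"),
#'   exons = data.frame(transcript_id = "g1.1", start = c(0, 200), end = c(100, 300))
#' )
#' introns(gs)
#' @export
gene_set <- function(genes, transcripts, exons, dialect = "GTF") {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  transcripts <- as.data.frame(transcripts, stringsAsFactors = FALSE)
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(sprintf("%s table lacks column(s): %s", what, paste(miss, collapse = ", ")))
  }
  need(genes, c("gene_id", "chrom", "strand"), "genes")
  need(transcripts, c("transcript_id", "gene_id"), "transcripts")
  need(exons, c("transcript_id", "start", "end"), "exons")

  if (anyDuplicated(genes$gene_id))
    stop("duplicated gene ids in gene set")
  if (anyDuplicated(transcripts$transcript_id))
    stop("duplicated transcript ids in gene set")
  if (!all(genes$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  if (!all(transcripts$gene_id %in% genes$gene_id))
    stop("transcript references unknown gene id")
  if (!all(exons$transcript_id %in% transcripts$transcript_id))
    stop("exon without parent transcript")
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (any(exons$start >= exons$end))
    stop("exon intervals must satisfy start < end")

  exons <- exons[order(match(exons$transcript_id, transcripts$transcript_id),
                       exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  # overlapping exons within a transcript are rejected, not merged
  same_tx <- exons$transcript_id[-1] == exons$transcript_id[-nrow(exons)]
  if (nrow(exons) > 1 && any(same_tx & exons$start[-1] < exons$end[-nrow(exons)]))
    stop("overlapping exons within a transcript")

  lens <- exons$end - exons$start
  spl <- rowsum(lens, exons$transcript_id)
  transcripts$spliced_length <-
    as.integer(spl[match(transcripts$transcript_id, rownames(spl)), 1])
  transcripts$spliced_length[is.na(transcripts$spliced_length)] <- 0L

  genes$representative <- vapply(genes$gene_id, function(g) {
    tx <- transcripts[transcripts$gene_id == g, , drop = FALSE]
    if (nrow(tx) == 0L) return(NA_character_)
    select_representative_transcript(tx)
  }, character(1))

  structure(
    list(genes = genes, transcripts = transcripts, exons = exons),
    dialect = dialect,
    class = "gene_set"
  )
}

#' Select a gene's representative transcript
#'
#' The representative structure is the longest transcript, with "longest"
#' measured as spliced length (summed exon length) so that the same length
#' notion underlies FPKM. Ties go to the lexicographically smallest id.
#'
#' @param transcripts data.frame with columns `transcript_id`, `spliced_length`
#'   (the transcripts of one gene).
#' @return The representative transcript id.
#' @export
select_representative_transcript <- function(transcripts) {
  if (nrow(transcripts) == 0L) stop("gene has no transcripts")
  best <- transcripts$spliced_length == max(transcripts$spliced_length)
  sort(transcripts$transcript_id[best])[1L]
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set: %d gene(s), %d transcript(s), %d exon(s) [%s]\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$exons),
              attr(x, "dialect")))
  invisible(x)
}

.tx_exons <- function(gs, transcript_id) {
  gs$exons[gs$exons$transcript_id == transcript_id, , drop = FALSE]
}

#' Derive introns of the representative transcripts
#'
#' Introns are exactly the gaps between consecutive exons. Intron `order` is
#' 1-based and runs 5' to 3' in the direction of transcription regardless of
#' strand; `five_ss_pos` is the genomic position of the first intronic base in
#' transcription direction and `three_ss_pos` the last (so on "+" strand
#' `five_ss_pos = start`, `three_ss_pos = end - 1`, mirrored on "-").
#'
#' @param gene_set a [gene_set] object.
#' @param genes optional character vector restricting to these gene ids.
#' @return data.frame with one row per intron: `gene_id`, `transcript_id`,
#'   `chrom`, `strand`, `order`, `start`, `end`, `five_ss_pos`, `three_ss_pos`.
#' @export
introns <- function(gene_set, genes = NULL) {
  stopifnot(inherits(gene_set, "gene_set"))
  g <- gene_set$genes
  if (!is.null(genes)) g <- g[g$gene_id %in% genes, , drop = FALSE]
  out <- vector("list", nrow(g))
  for (i in seq_len(nrow(g))) {
    ex <- .tx_exons(gene_set, g$representative[i])
    n <- nrow(ex)
    if (n < 2L) {
      out[[i]] <- NULL
      next
    }
    istart <- ex$end[-n]
    iend <- ex$start[-1]
    ord <- if (g$strand[i] == "+") seq_len(n - 1L) else rev(seq_len(n - 1L))
    out[[i]] <- data.frame(
      gene_id = g$gene_id[i],
      transcript_id = g$representative[i],
      chrom = g$chrom[i],
      strand = g$strand[i],
      order = ord,
      start = istart,
      end = iend,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(gene_id = character(), transcript_id = character(),
                      chrom = character(), strand = character(),
                      order = integer(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  out$five_ss_pos <- ifelse(out$strand == "+", out$start, out$end - 1L)
  out$three_ss_pos <- ifelse(out$strand == "+", out$end - 1L, out$start)
  out <- out[order(out$gene_id, out$order), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# structural pre-scan so malformed records are reported with their line number;
# the actual parsing is delegated to rtracklayer
.scan_annotation_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^\\s*(#|$)", lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L)
      stop(sprintf("malformed annotation record at line %d: expected >= 8 tab-separated fields", i))
    if (is.na(suppressWarnings(as.integer(f[4]))) ||
        is.na(suppressWarnings(as.integer(f[5]))))
      stop(sprintf("malformed annotation record at line %d: non-numeric coordinates", i))
  }
  length(body)
}

#' Read gene models from GTF or GFF3
#'
#' Parses an annotation file into a [gene_set]. GTF records are resolved through
#' their `gene_id`/`transcript_id` attributes, GFF3 through `ID`/`Parent`
#' chains (exon -> transcript -> gene). Source coordinates (1-based inclusive)
#' are converted to the package's internal 0-based half-open convention.
#'
#' @param path annotation file.
#' @param dialect `"auto"` (sniffed from extension/content), `"GTF"` or `"GFF3"`.
#' @return A [gene_set].
#' @export
read_gene_models <- function(path, dialect = c("auto", "GTF", "GFF3")) {
  dialect <- match.arg(toupper(dialect[1]), c("AUTO", "GTF", "GFF3"))
  if (!file.exists(path)) stop("annotation file not found: ", path)
  n_records <- .scan_annotation_lines(path)
  if (dialect == "AUTO") {
    ext <- tolower(tools::file_ext(path))
    dialect <- if (ext %in% c("gff", "gff3")) "GFF3"
      else if (ext == "gtf") "GTF"
      else {
        head <- readLines(path, n = 50L, warn = FALSE)
        if (any(grepl("\tgene_id \"", head, fixed = TRUE))) "GTF" else "GFF3"
      }
  }
  empty <- gene_set(
    genes = data.frame(gene_id = character(), chrom = character(),
                       strand = character(), stringsAsFactors = FALSE),
    transcripts = data.frame(transcript_id = character(), gene_id = character(),
                             stringsAsFactors = FALSE),
    exons = data.frame(transcript_id = character(), start = integer(),
                       end = integer(), stringsAsFactors = FALSE),
    dialect = dialect
  )
  if (n_records == 0L) return(empty)

  gr <- rtracklayer::import(path, format = if (dialect == "GTF") "gtf" else "gff3")
  md <- S4Vectors::mcols(gr)
  is_exon <- !is.na(md$type) & tolower(as.character(md$type)) == "exon"
  if (!any(is_exon)) return(empty)

  ex_gr <- gr[is_exon]
  ex_md <- S4Vectors::mcols(ex_gr)
  if (dialect == "GTF") {
    tx_id <- as.character(ex_md$transcript_id)
    gn_id <- as.character(ex_md$gene_id)
    if (anyNA(tx_id)) stop("exon without parent transcript (missing transcript_id)")
    if (anyNA(gn_id)) gn_id[is.na(gn_id)] <- tx_id[is.na(gn_id)]
  } else {
    parents <- ex_md$Parent
    if (any(lengths(parents) == 0L))
      stop("exon without parent transcript (missing Parent)")
    tx_id <- vapply(parents, function(p) as.character(p)[1], character(1))
    # transcript -> gene via the Parent of the feature whose ID matches
    ids <- as.character(md$ID)
    par1 <- vapply(md$Parent, function(p)
      if (length(p)) as.character(p)[1] else NA_character_, character(1))
    gn_id <- par1[match(tx_id, ids)]
    gn_id[is.na(gn_id)] <- tx_id[is.na(gn_id)]  # transcript directly under no gene
  }

  exons <- data.frame(
    transcript_id = tx_id,
    start = BiocGenerics::start(ex_gr) - 1L,
    end = BiocGenerics::end(ex_gr),
    stringsAsFactors = FALSE
  )
  tx_first <- !duplicated(tx_id)
  transcripts <- data.frame(
    transcript_id = tx_id[tx_first],
    gene_id = gn_id[tx_first],
    stringsAsFactors = FALSE
  )
  gn_first <- !duplicated(transcripts$gene_id)
  chrom <- as.character(GenomicRanges::seqnames(ex_gr))[tx_first]
  strand <- as.character(BiocGenerics::strand(ex_gr))[tx_first]
  strand[!strand %in% c("+", "-")] <- "+"
  genes <- data.frame(
    gene_id = transcripts$gene_id[gn_first],
    chrom = chrom[gn_first],
    strand = strand[gn_first],
    stringsAsFactors = FALSE
  )
  gene_set(genes, transcripts, exons, dialect = dialect)
}

#' Write a gene set as GTF
#'
#' Emits gene, transcript and exon records with `gene_id`/`transcript_id`
#' attributes, converting the internal 0-based half-open coordinates back to
#' GTF's 1-based inclusive convention. `read_gene_models()` on the output
#' reproduces the interval sets exactly.
#'
#' @param gene_set a [gene_set].
#' @param path output file.
#' @export
write_gtf <- function(gene_set, path) {
  stopifnot(inherits(gene_set, "gene_set"))
  lines <- character(0)
  g <- gene_set$genes
  for (i in seq_len(nrow(g))) {
    txs <- gene_set$transcripts[gene_set$transcripts$gene_id == g$gene_id[i], , drop = FALSE]
    gex <- gene_set$exons[gene_set$exons$transcript_id %in% txs$transcript_id, , drop = FALSE]
    if (nrow(gex) == 0L) next
    gl <- sprintf('%s\tctsplice\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
                  g$chrom[i], min(gex$start) + 1L, max(gex$end), g$strand[i], g$gene_id[i])
    tl <- character(0)
    for (j in seq_len(nrow(txs))) {
      ex <- gene_set$exons[gene_set$exons$transcript_id == txs$transcript_id[j], , drop = FALSE]
      tl <- c(tl,
        sprintf('%s\tctsplice\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
                g$chrom[i], min(ex$start) + 1L, max(ex$end), g$strand[i],
                g$gene_id[i], txs$transcript_id[j]),
        sprintf('%s\tctsplice\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
                g$chrom[i], ex$start + 1L, ex$end, g$strand[i],
                g$gene_id[i], txs$transcript_id[j]))
    }
    lines <- c(lines, gl, tl)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write the junction (intron) table of a gene set
#'
#' One row per intron of each representative transcript, in the internal
#' 0-based half-open convention; optionally also a BED6 export
#' (name `gene_id:order`, the intron's genomic interval, gene strand).
#'
#' @param gene_set a [gene_set].
#' @param path output TSV.
#' @param bed optional BED6 output path.
#' @return The intron table, invisibly.
#' @export
write_junction_table <- function(gene_set, path, bed = NULL) {
  tab <- introns(gene_set)
  out <- tab[, c("gene_id", "chrom", "strand", "order", "start", "end",
                 "five_ss_pos", "three_ss_pos")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bed)) {
    bedtab <- data.frame(tab$chrom, tab$start, tab$end,
                         paste0(tab$gene_id, ":", tab$order), 0L, tab$strand)
    utils::write.table(bedtab, bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(out)
}
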