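# junction fixture used repeatedly: '+' strand gene, exons (50,100) and
# (200,260), one intron (100,200)
junction_gene <- function(strand = "+") {
  one_gene_set(c(50L, 200L), c(100L, 260L), strand = strand)
}

test_that("boundary counts separate unspliced, spliced and absent reads", {
  gs <- junction_gene()
  it <- introns(gs)
  # 3 unspliced reads spanning the whole intron (cover both boundaries),
  # 1 spliced read with an N skip exactly over the intron
  aln <- make_alignments(data.frame(
    read_id = c(1L, 2L, 3L, 4L, 4L),
    start = c(80L, 80L, 80L, 80L, 200L),
    end = c(220L, 220L, 220L, 100L, 220L)))
  cb <- count_boundary_reads(aln, it)
  expect_equal(cb$intronic_5p, 3)
  expect_equal(cb$exonic_5p, 4)
  expect_equal(cb$intronic_3p, 3)
  expect_equal(cb$exonic_3p, 4)
  expect_equal(ss_ratio(cb, "5p"), 0.75)
  expect_equal(ss_ratio(cb, "3p"), 0.75)

  none <- make_alignments(data.frame(read_id = integer(), start = integer(),
                                     end = integer()))
  cb0 <- count_boundary_reads(none, it)
  expect_equal(unlist(cb0[, c("intronic_5p", "exonic_5p",
                              "intronic_3p", "exonic_3p")]),
               c(intronic_5p = 0, exonic_5p = 0, intronic_3p = 0, exonic_3p = 0))

  only_spliced <- make_alignments(data.frame(
    read_id = c(1L, 1L, 2L, 2L), start = c(90L, 200L, 95L, 200L),
    end = c(100L, 210L, 100L, 215L)))
  cbs <- count_boundary_reads(only_spliced, it)
  expect_equal(cbs$intronic_5p, 0)
  expect_equal(cbs$exonic_5p, 2)
  expect_equal(ss_ratio(cbs, "5p"), 0)
})

test_that("boundary counting mirrors correctly on the minus strand", {
  gs <- junction_gene(strand = "-")
  it <- introns(gs)
  # 5'SS of a '-' intron sits at the genomic right edge (end - 1), the 3'SS at
  # the genomic left edge (start); adjacent exonic bases lie just outside
  aln <- make_alignments(data.frame(
    read_id = c(1L, 2L, 3L),
    start = c(190L, 150L, 90L),
    end = c(210L, 190L, 110L)),
    strand = "-")
  cb <- count_boundary_reads(aln, it)
  expect_equal(cb$intronic_5p, 1)  # read 1 covers base 199
  expect_equal(cb$exonic_5p, 1)    # read 1 covers base 200
  expect_equal(cb$intronic_3p, 1)  # read 3 covers base 100
  expect_equal(cb$exonic_3p, 1)    # read 3 covers base 99
})

test_that("windowed boundary counting averages flanking coverage", {
  gs <- junction_gene()
  it <- introns(gs)
  # one read covering 95..104 -> in a 10-bp window at the 5'SS, 5 of 10
  # intronic bases and 5 of 10 exonic bases are covered
  aln <- make_alignments(data.frame(read_id = 1L, start = 95L, end = 105L))
  cb <- count_boundary_reads(aln, it, window = 10L)
  expect_equal(cb$intronic_5p, 0.5)
  expect_equal(cb$exonic_5p, 0.5)
})

test_that("ss_ratio arithmetic and undefined case", {
  counts <- data.frame(intronic_5p = c(0, 25, 10), exonic_5p = c(50, 100, 0),
                       intronic_3p = 0, exonic_3p = 1)
  expect_equal(ss_ratio(counts, "5p"), c(0, 0.25, NA))
})

test_that("FPKM formula and guards", {
  expect_equal(compute_fpkm(100, 1000, 1e6), 100)
  expect_equal(compute_fpkm(0, 1000, 1e6), 0)
  expect_equal(compute_fpkm(50, 2000, 1e7), 2.5)
  expect_error(compute_fpkm(1, 0, 1e6), "exonic_length")
  expect_error(compute_fpkm(1, 100, 0), "total_mapped_fragments")
})

test_that("expression filter is boundary-inclusive and order-preserving", {
  genes <- data.frame(gene_id = c("a", "b", "c"), fpkm = c(0.5, 1.0, 3.2))
  expect_equal(filter_expressed(genes)$gene_id, c("b", "c"))
  expect_equal(nrow(filter_expressed(genes, fpkm_min = 10)), 0L)
  expect_equal(filter_expressed(genes, fpkm_min = 0)$gene_id, genes$gene_id)
})

test_that("gene mean skips undefined ratios and is reorder/scale invariant", {
  expect_equal(gene_ss_ratio(c(0.2, 0.4), c(0.2, 0.4))["mean_5p"],
               c(mean_5p = 0.3))
  expect_equal(gene_ss_ratio(c(0.1, NA, 0.3), c(NA, NA, NA)),
               c(mean_5p = 0.2, mean_3p = NA_real_))
  expect_equal(gene_ss_ratio(0.7, 0.7), c(mean_5p = 0.7, mean_3p = 0.7))
  # reordering introns leaves the mean unchanged
  r <- c(0.05, 0.3, NA, 0.8)
  expect_equal(gene_ss_ratio(r, r), gene_ss_ratio(rev(r), rev(r)))
  # scaling all counts at every junction leaves every ratio unchanged
  counts <- data.frame(intronic_5p = c(3, 7), exonic_5p = c(9, 11),
                       intronic_3p = c(2, 5), exonic_3p = c(8, 10))
  scaled <- counts * 17
  expect_equal(ss_ratio(counts, "5p"), ss_ratio(scaled, "5p"))
  expect_equal(ss_ratio(counts, "3p"), ss_ratio(scaled, "3p"))
})

test_that("intron/exon ratio: uniform, mature-mRNA and mixed depths", {
  gs <- one_gene_set(c(0L, 200L), c(100L, 300L))
  # uniform depth 10 across the whole gene body
  uni <- make_alignments(data.frame(read_id = 1:10, start = 0L, end = 300L))
  expect_equal(unname(intron_exon_ratio(gs, uni)["g1"]), 1.0)
  # coverage only on exons (spliced reads)
  mat <- make_alignments(data.frame(read_id = rep(1:5, each = 2),
                                    start = rep(c(0L, 200L), 5),
                                    end = rep(c(100L, 300L), 5)))
  expect_equal(unname(intron_exon_ratio(gs, mat)["g1"]), 0.0)
  # intron depth 2, exon depth 8, intron length 100 vs exon length 200:
  # (2) / (8) = 0.25 after length normalization
  mix <- make_alignments(data.frame(
    read_id = c(rep(1:8, each = 2), 9:10),
    start = c(rep(c(0L, 200L), 8), 100L, 100L),
    end = c(rep(c(100L, 300L), 8), 200L, 200L)))
  expect_equal(unname(intron_exon_ratio(gs, mix)["g1"]), 0.25)
})

test_that("stratification by intron order and by intron number", {
  fake_fit <- function(introns, genes) {
    structure(list(introns = introns, genes = genes, fpkm_min = 1),
              class = "splice_ratios")
  }
  it <- data.frame(
    gene_id = rep(c("A", "B"), each = 2), order = c(1L, 2L, 1L, 2L),
    ratio_5p = c(0.1, 0.3, 0.2, 0.4), ratio_3p = c(0.1, 0.3, 0.2, 0.4))
  ge <- data.frame(gene_id = c("A", "B"), fpkm = c(5, 5),
                   n_introns = c(2L, 2L), mean_5p = c(0.2, 0.3),
                   mean_3p = c(0.2, 0.3), expressed = TRUE)
  fit <- fake_fit(it, ge)
  st <- stratify_by_intron_order(fit, k = 2)
  s5 <- st$summary[st$summary$side == "5p", ]
  expect_equal(s5$median[s5$order == 1], 0.15)
  expect_equal(s5$median[s5$order == 2], 0.35)

  # single qualifying gene: per-order values equal that gene's ratios
  ge1 <- ge[1, , drop = FALSE]
  st1 <- stratify_by_intron_order(fake_fit(it[it$gene_id == "A", ], ge1), k = 2)
  expect_equal(st1$summary$median[st1$summary$side == "5p"], c(0.1, 0.3))

  # intron-number classes with an empty class
  ge2 <- data.frame(gene_id = c("A", "B", "C", "D"), fpkm = 5,
                    n_introns = c(1L, 1L, 2L, 2L),
                    mean_5p = c(0.2, 0.4, 0.1, 0.1),
                    mean_3p = c(0.2, 0.4, 0.1, 0.1), expressed = TRUE)
  sn <- stratify_by_intron_number(fake_fit(it[0, ], ge2), k_range = 1:3)
  s5n <- sn[sn$side == "5p", ]
  expect_equal(s5n$median[s5n$n_introns == 1], 0.3)
  expect_equal(s5n$median[s5n$n_introns == 2], 0.1)
  expect_equal(s5n$n[s5n$n_introns == 3], 0)
  expect_true(is.na(s5n$median[s5n$n_introns == 3]))
})

test_that("splice_ratios integrates counting, FPKM and gene summaries", {
  gs <- junction_gene()
  aln <- make_alignments(data.frame(
    read_id = c(1L, 2L, 3L, 4L, 4L),
    start = c(80L, 80L, 80L, 80L, 200L),
    end = c(220L, 220L, 220L, 100L, 220L)),
    chrom_lengths = c(chr1 = 1000L))
  fit <- splice_ratios(gs, aln, fpkm_min = 0)
  expect_s3_class(fit, "splice_ratios")
  expect_equal(fit$introns$ratio_5p, 0.75)
  expect_equal(fit$genes$mean_5p, 0.75)
  expect_equal(fit$genes$n_introns, 1L)
  # 4 fragments all overlap the exon model; exonic length 110 bp
  expect_equal(fit$genes$fpkm, compute_fpkm(4, 110, 4))
  expect_output(print(fit), "splice_ratios fit")
  expect_output(print(summary(fit)), "gene mean 5'SS")
})

test_that("sense strand policy counts only matching fragments", {
  gs <- junction_gene()
  it <- introns(gs)
  aln <- make_alignments(
    data.frame(read_id = 1:2, start = 80L, end = 220L),
    strand = c("+", "-"))
  unstranded <- count_boundary_reads(aln, it)
  sense <- count_boundary_reads(aln, it, strand_policy = "sense")
  anti <- count_boundary_reads(aln, it, strand_policy = "antisense")
  expect_equal(unstranded$intronic_5p, 2)
  expect_equal(sense$intronic_5p, 1)
  expect_equal(anti$intronic_5p, 1)
})
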