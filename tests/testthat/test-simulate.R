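test_that("identical seed and config give byte-identical outputs", {
  cfg <- sim_config(n_genes = 5, depth = 30, n_molecules = 200, seed = 77)
  d1 <- file.path(tempdir(), "sim_a")
  d2 <- file.path(tempdir(), "sim_b")
  s1 <- simulate_cbrna(cfg, out_dir = d1)
  s2 <- simulate_cbrna(cfg, out_dir = d2)
  expect_identical(readLines(file.path(d1, "genes.gtf")),
                   readLines(file.path(d2, "genes.gtf")))
  expect_identical(readLines(file.path(d1, "reads.sam")),
                   readLines(file.path(d2, "reads.sam")))
  expect_identical(s1$truth, s2$truth)
})

test_that("degenerate and structural bounds of the genome generator", {
  empty <- simulate_genome(sim_config(n_genes = 0, seed = 1))
  expect_equal(nrow(empty$gene_set$genes), 0L)
  expect_gt(nchar(empty$genome), 0L)

  cfg <- sim_config(n_genes = 30, exon_count_range = c(2, 10), seed = 3)
  gs <- simulate_genome(cfg)$gene_set
  ni <- table(introns(gs)$gene_id)
  expect_true(all(ni >= 1 & ni <= 9))
  # genes do not overlap and respect the spacing
  g <- gs$genes
  spans <- t(vapply(g$representative, function(tx) {
    ex <- gs$exons[gs$exons$transcript_id == tx, ]
    c(min(ex$start), max(ex$end))
  }, numeric(2)))
  ord <- order(spans[, 1])
  expect_true(all(spans[ord[-1], 1] - spans[ord[-length(ord)], 2] >=
                    cfg$gene_spacing))
})

test_that("pure mRNA molecules are fully spliced and give zero SS ratios", {
  cfg <- sim_config(n_genes = 4, depth = 60, n_molecules = 300,
                    fraction_mix = c(mRNA = 1, RNAe = 0, RNAf = 0), seed = 5)
  sim <- simulate_cbrna(cfg)
  for (pg in sim$molecules$per_gene)
    expect_true(all(pg$states == 0L))
  fit <- splice_ratios(sim$gene_set, sim$alignments, fpkm_min = 0)
  r <- c(fit$introns$ratio_5p, fit$introns$ratio_3p)
  expect_true(all(r[!is.na(r)] == 0))
})

test_that("instant maturation (lambda -> 0) splices every transcribed intron", {
  cfg <- sim_config(n_genes = 4, n_molecules = 300, maturation_length = 1e-9,
                    fraction_mix = c(mRNA = 0, RNAe = 1, RNAf = 0), seed = 6)
  sim <- simulate_molecules(simulate_genome(cfg), cfg)
  for (pg in sim$per_gene) {
    iseg <- pg$segments[pg$segments$type == "I", , drop = FALSE]
    for (j in seq_len(nrow(iseg))) {
      # any transcription past the 3'SS suffices at instant maturation
      past <- pg$pol > iseg$pend[j]
      expect_true(all(pg$states[past, j] == 0L))
      expect_true(all(pg$states[pg$pol < iseg$pend[j], j] == 2L))
    }
  }
})

test_that("slow maturation matches the numerical-integration oracle", {
  # single-intron genes, RNAe only, lambda comparable to gene length:
  # at the 3'SS the retention among covering molecules (pol >= intron end)
  # is E[exp(-(pol - pe)/lambda)] with pol uniform on {pe..plen}
  cfg <- sim_config(n_genes = 3, exon_count_range = c(2, 2),
                    n_molecules = 20000, maturation_length = 1500,
                    fraction_mix = c(mRNA = 0, RNAe = 1, RNAf = 0), seed = 8)
  sim <- simulate_molecules(simulate_genome(cfg), cfg)
  for (gid in names(sim$per_gene)) {
    pg <- sim$per_gene[[gid]]
    iseg <- pg$segments[pg$segments$type == "I", , drop = FALSE]
    plen <- sum(pg$segments$len)
    pe <- iseg$pend[1]
    expected <- mean(exp(-(seq(pe, plen) - pe) / cfg$maturation_length))
    u <- true_retention(sim, gid, 1, "3p")
    n_cov <- sim$truth$n_covering[sim$truth$gene_id == gid &
                                    sim$truth$order == 1 &
                                    sim$truth$side == "3p"]
    se <- sqrt(expected * (1 - expected) / n_cov)
    expect_lt(abs(u - expected), 4 * se + 1e-12)
  }
})

test_that("true_retention is the enumeration oracle and errors on unknowns", {
  cfg <- sim_config(n_genes = 2, n_molecules = 50, seed = 9)
  sim <- simulate_molecules(simulate_genome(cfg), cfg)
  gid <- names(sim$per_gene)[1]
  pg <- sim$per_gene[[gid]]
  iseg <- pg$segments[pg$segments$type == "I", , drop = FALSE]
  cov <- pg$pol >= iseg$pstart[1] + 1L
  expect_equal(true_retention(sim, gid, 1, "5p"),
               sum(cov & pg$states[, 1] != 0L) / sum(cov))
  expect_error(true_retention(sim, "nope", 1, "5p"), "unknown junction")
})

test_that("emitted reads lift back to one contiguous molecule interval", {
  cfg <- sim_config(n_genes = 3, depth = 20, n_molecules = 150, seed = 12)
  gen <- simulate_genome(cfg)
  mol <- simulate_molecules(gen, cfg)
  aln <- simulate_reads(mol, cfg, chrom_lengths = gen$chrom_lengths)
  rm <- attr(aln, "read_molecule")
  expect_false(is.null(rm))
  set.seed(1)
  pick <- sample(unique(aln$read_id), 40)
  for (rid in pick) {
    info <- rm[rm$read_id == rid, ]
    pg <- mol$per_gene[[info$gene_id]]
    seg <- pg$segments
    attr(seg, "strand") <-
      gen$gene_set$genes$strand[gen$gene_set$genes$gene_id == info$gene_id]
    bl <- aln[aln$read_id == rid, c("start", "end"), drop = FALSE]
    iv <- liftback_to_molecule(bl, seg, pg$states[info$molecule, , drop = TRUE],
                               pg$pol[info$molecule])
    # contiguous: pieces abut in molecule coordinates and total the read length
    expect_equal(sum(iv[, 2] - iv[, 1]), cfg$read_length)
    if (nrow(iv) > 1)
      expect_true(all(iv[-1, 1] == iv[-nrow(iv), 2]))
  }
})

test_that("SAM round trip preserves block structure and splice skips", {
  cfg <- sim_config(n_genes = 4, depth = 25, n_molecules = 200, seed = 14)
  sim <- simulate_cbrna(cfg, out_dir = file.path(tempdir(), "sim_rt"))
  back <- read_alignments(file.path(tempdir(), "sim_rt", "reads.sam"))
  sig <- function(a) sort(vapply(split(paste(a$start, a$end), a$read_id),
                                 paste, character(1), collapse = ";"))
  expect_equal(unname(sig(back)), unname(sig(sim$alignments)))
  expect_equal(attr(back, "n_reads"), attr(sim$alignments, "n_reads"))

  # a spliced read's skip equals the intron it crosses
  it <- introns(sim$gene_set)
  spliced <- split(back, back$read_id)
  spliced <- Filter(function(b) nrow(b) > 1, spliced)
  expect_gt(length(spliced), 0)
  gaps <- unlist(lapply(spliced, function(b) b$start[-1] - b$end[-nrow(b)]))
  expect_true(all(gaps %in% (it$end - it$start)))
})

test_that("config validation rejects inconsistent mixtures and parameters", {
  expect_error(sim_config(fraction_mix = c(mRNA = 0.5, RNAe = 0.2, RNAf = 0.2)),
               "sum to 1")
  expect_error(sim_config(fraction_mix = c(a = 1)), "named weights")
  expect_error(sim_config(maturation_length = 0), "maturation_length")
  expect_error(sim_config(rnaf_retention = 1.5), "rnaf_retention")
  cfg <- sim_config(seed = 2)
  f <- tempfile(fileext = ".yaml")
  sim <- simulate_cbrna(sim_config(n_genes = 1, n_molecules = 10, depth = 5,
                                   seed = 2),
                        out_dir = file.path(tempdir(), "cfg_echo"))
  cfg2 <- read_sim_config(file.path(tempdir(), "cfg_echo", "config.yaml"),
                          seed = 4)
  expect_equal(cfg2$seed, 4L)
  expect_equal(cfg2$fraction_mix, cfg$fraction_mix)
})
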