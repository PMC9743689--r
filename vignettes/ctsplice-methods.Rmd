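---
title: "Quantifying co-transcriptional splicing from chromatin-bound RNA-seq"
author: "ctsplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying co-transcriptional splicing from chromatin-bound RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctsplice)
```

## Background and model

Chromatin-bound RNA (CB-RNA) co-purifies with the stable Pol II–DNA ternary
complex after stringent urea washes of isolated nuclei. It is dominated by
nascent transcripts and is therefore the most direct substrate for measuring
co-transcriptional splicing (CTS) in plants. At a given locus the chromatin
RNA pool is a mixture of three molecule populations:

* **RNAe** — elongating transcripts, truncated at the current polymerase
  position; introns behind the polymerase may or may not have been spliced yet.
* **RNAf** — full-length transcripts that are already polyadenylated but still
  chromatin-associated; largely but not completely spliced (on-chromatin
  processing intermediates).
* **mRNA** — mature message; fully spliced; only a contaminant of chromatin
  fractions, but sequenced as the reference library.

Two sequencing signatures separate these populations. First, coverage: because
synthesis runs 5'→3', an elongating population has more molecules covering a
gene's 5' end than its 3' end, so CB-RNA coverage declines along the gene body
while mRNA-seq coverage is flat or mildly 3'-biased. Second, intron signal:
nascent molecules carry unspliced introns, so intronic coverage is high
relative to mRNA-seq.

### The splice-site ratio

For each intron of a gene's representative transcript, the package counts reads
covering the **first intronic base** and the **adjacent exonic base** at the 5'
splice site, and their mirror images at the 3' splice site:

\[
\mathrm{SS}_{5'} = \frac{\text{cov(first intronic base)}}{\text{cov(last exonic base upstream)}},
\qquad
\mathrm{SS}_{3'} = \frac{\text{cov(last intronic base)}}{\text{cov(first exonic base downstream)}} .
\]

A junction-spanning spliced read (an alignment with an N skip across the
intron) covers the exonic base but no intronic base, so it enters the
denominator only. The ratio therefore estimates the **unspliced (retained)
fraction** among molecules covering that junction: 0 for complete
co-transcriptional splicing, 1 for full retention, and it is negatively
correlated with splicing efficiency. Gene-level values are the unweighted mean
over the gene's introns with defined ratios (zero-denominator introns carry no
information and are skipped, not imputed), restricted to genes passing an
expression filter of FPKM ≥ 1.

Single-base adjacency is the minimal reading of "intronic reads over the
adjacent exonic reads" with exact semantics; a `window` argument averages
coverage over N flanking bases per side for robustness (the intronic window
never extends past the intron).

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `fpkm_min` | 1 | FPKM | expression filter for gene-level summaries |
| `window` | 1 | bp | flanking bases averaged per boundary side |
| `strand_policy` | unstranded | — | antisense reads kept (antisense transcription is rare in Arabidopsis; stranded and unstranded profiles are nearly identical); `sense` mode available |
| `unique_only` | TRUE | — | drop secondary/supplementary records and NH > 1 |
| `window_size` (tracks) | 5 | bp | coverage window for metagene tracks |
| `n_bins` | 100 | — | bins across the scaled gene body (TSS→PAS) |

FPKM here is a self-contained dialect: fragments (paired mates = 1 fragment,
an unpaired read = 1 fragment) with ≥ 1 bp overlap of the representative
transcript's exon model, scaled by `1e9 / (exonic_length ×
total_mapped_fragments)` with the total taken over all filtered fragments in
the library. Published pipelines delegate this to an assembler; the formula
above is exact and reproducible. Duplicates are kept by default since no
deduplication step is part of the protocol's analysis. The expression filter
is applied per library.

The windowed coverage track is likewise a declared dialect: each tiled window
(stride = window size) stores the mean per-base coverage times
`1e6 / n_reads`, so the genome-wide sum of value × window length equals one
million read-length equivalents, and doubling every read leaves the track
unchanged. Metagene profiles rescale each qualifying gene span (TSS→PAS,
strand-aware; no flanks, matching how such profiles are anchored) to
`n_bins` bins by per-base averaging, then average bins across genes. The
profile slope is the Spearman correlation of bin index with bin mean; a
constant profile is degenerate and reported as 0 with a `flagged` attribute.

"Longest transcript" for the representative structure means the largest
**spliced** (summed exon) length, not genomic span, so that one length notion
underlies both the representative choice and FPKM; ties break to the
lexicographically smallest transcript id. Transcripts with overlapping
annotated exons are rejected rather than merged, as no merging rule is part of
the method. All internal coordinates are 0-based half-open; GTF/GFF3 are read
as 1-based inclusive and BED is written 0-based half-open.

## The simulator

`simulate_cbrna()` generates a synthetic genome, gene models, molecules and
aligned reads under an explicit mechanism, with exact per-junction ground
truth, so every stage of the estimator is testable without external data.

* **Genome**: one synthetic chromosome; genes spaced ≥ 500 bp to avoid overlap
  ambiguity; exon and intron lengths log-normal with median 150 bp (floors of
  25/60 bp), 2–10 exons per gene — a compact, Arabidopsis-like architecture.
* **RNAe**: polymerase position uniform on the pre-mRNA (no promoter-proximal
  pausing is simulated; chromatin libraries with a ≥ 200 nt size cut-off do
  not resolve pausing). A fully transcribed intron whose 3'SS lies `d` bases
  behind the polymerase has been spliced with probability
  \(1 - e^{-d/\lambda}\). This "maturation length" λ (default 2000 bp, about
  one mean gene length) is the minimal mechanism producing the observed
  first-come-first-serve order trend; the trend, not the functional form, is
  the constrained observable.
* **RNAf**: full-length; each intron retained with probability `r`
  (default 0.05).
* **Cooperativity** `c` (default 1 = off): a two-stage draw; still-unspliced
  introns are re-drawn with their rate multiplied by `c` per adjacent intron
  spliced in stage one. With `c > 1`, genes with more introns splice each
  intron faster, reproducing the negative correlation between intron number
  and mean SS ratio.
* **Mixture**: default mRNA/RNAe/RNAf = 0/0.9/0.1. The polyadenylated
  chromatin fraction is known to be small but unquantified; 0.1 is a free
  parameter, chosen once.
* **Reads**: single-end fragments of fixed length (default 75 bp) starting
  uniformly over each molecule's valid start positions, with molecules sampled
  proportionally to their number of start positions (equivalently: fragments
  uniform over the pooled molecule bases). The `depth` parameter is the
  expected coverage of a base present in every molecule of a gene. mRNA
  fragment starts can be skewed 3' with density ∝ 1 + βx to mimic oligo-d(T)
  bias. Coordinates are lifted from molecule to genome space, yielding
  multi-block alignments whose N skips equal the spliced introns. Sequencing
  error, quality variation and PCR duplicates are not simulated — every
  statistic in scope depends only on alignment coordinates. Reads are emitted
  unpaired; all ratio statistics are per-read coverage ratios for which mates
  contribute independently, and fragment-level FPKM counting is exercised
  through the same grouping path.

`true_retention()` recomputes, by exhaustive enumeration of the emitted
molecules, the unspliced fraction among molecules covering each junction side —
the oracle against which the SS ratio is validated.

### What the simulator does and does not emulate

It reproduces the statistical structure that the estimators consume: 5'→3'
declining coverage from truncated elongating molecules, order-dependent intron
retention, a small polyadenylated-but-incompletely-spliced fraction, spliced
junction reads, and mature mRNA with optional 3' bias. It does **not** emulate
sequence-dependent mappability, multi-mapping, rRNA contamination, alternative
isoforms, overlapping genes, expression heterogeneity across genes, or
paired-end fragment-size distributions. Tests passing on simulated data
therefore validate the counting and estimation machinery and the mechanistic
trends, not robustness to alignment artefacts on real libraries.

## Numerical and statistical choices

* **Wilcoxon rank-sum comparisons** between fractions use exact enumeration of
  all rank assignments (with midranks, so ties are exact) for combined
  n ≤ 20, and the tie-corrected normal approximation without continuity
  correction otherwise. If all pooled values are identical the p-value is 1.
* **Undefined ratios** (zero exonic denominator) are values, not errors; they
  are skipped by gene means and stratifications.
* **Degenerate metagene profiles** (constant) report slope 0 with a flag
  rather than NA, so downstream comparisons remain total.
* **Determinism**: a seed plus configuration yields byte-identical simulator
  output; the genome, molecule and read stages draw from separated seeds
  derived from the configured one.

### Estimator accuracy and its limits

On simulated elongating-fraction libraries with ≥ 2000 covering reads per
junction, the SS ratio tracks the enumerated truth with a mean absolute error
below 0.01 and roughly binomial sampling noise. Two finite-read-length edge
effects bound its accuracy, and neither shrinks with sequencing depth:

1. **Short terminal exons.** When a junction lies within one read length of a
   molecule's end — e.g. a first exon shorter than the read — spliced and
   retained molecules offer different numbers of read-start positions covering
   the exonic base, biasing that junction's ratio by up to ~0.1 in extreme
   cases (a 42-bp first exon). This affects real libraries identically.
2. **Truncation near the junction.** Elongating molecules whose polymerase sits
   within one read length past a junction are under-sampled relative to an
   unweighted molecule census, deflating estimates at near-fully-retained
   junctions by ~0.01–0.02.

Consequently a strict binomial 3σ recovery band holds for about 97% of
junctions at high depth rather than the nominal ≥ 99%: at 2000–3000 covering
reads the band is ±0.01–0.03 while these biases are depth-independent. Users
comparing distributions across fractions (the intended use) are unaffected;
users interpreting single junctions with terminal exons shorter than the read
length should use the `window` option or discount those junctions.

## Problem sizes

The test-suite simulations use 8–40 genes with 800–60 000 molecules per gene
and junction coverages of 150–3000; recovery experiments keep the molecule
pool ≥ 20× the junction coverage target so that reads are a light,
with-replacement sample of the molecule population, as in a real library where
molecules per expressed gene vastly exceed junction coverage. The acceptance
script re-runs the same designs at 20–30 genes per condition.

## Worked example

```{r example, fig.width = 6, fig.height = 4}
cfg <- sim_config(n_genes = 12, depth = 120, n_molecules = 1200, seed = 7)
sim <- simulate_cbrna(cfg)
fit <- splice_ratios(sim$gene_set, sim$alignments)
summary(fit)
plot(fit)

track <- windowed_tpm(sim$alignments, sim$chrom_lengths)
prof <- metagene_profile(track, sim$gene_set)
profile_slope(prof)
plot(prof)
```

## Known limitations

* Gene-level FPKM and ratio computation assume one representative transcript;
  alternative isoforms and overlapping genes are flagged
  (`exclude_overlaps`, `exclude_overlapping`) but not modelled.
* No differential-splicing inference, PSI estimation, or isoform
  quantification is attempted.
* qPCR ratios assume a single amplification efficiency for both amplicons.
* The exact-enumeration Wilcoxon is quadratic in `choose(n, n_a)` and is
  capped at combined n = 20.
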