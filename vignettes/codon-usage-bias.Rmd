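---
title: "Scanning genomes for codon usage bias with cubscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning genomes for codon usage bias with cubscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cubscan)
library(dplyr)
```

## The problem

Synonymous codons are not used interchangeably: within a genome, some genes
draw their codons far from the uniform expectation over each amino acid's
synonym set. Such codon usage bias (CUB) is of interest in molecular
evolution because biased genes concentrate in pathways under lineage-specific
selection on translation efficiency — a hypothesis-free, genome-wide CUB
ranking therefore works as a screen for functions that a lineage has been
"rewiring". `cubscan` implements that screen end to end: per-gene CUB
scoring, ranked-list functional enrichment, an independent validation
statistic, between-genome comparison of orthologs, regional GC controls, and
a complementary pseudogene lesion screen for hypothesis-driven candidate
genes.

## The differential-entropy statistic

For a gene with codons $c_1,\dots,c_n$ (stop codons and codons containing N
excluded), the observed entropy is the Shannon entropy of its empirical
codon distribution,

$$H_{obs} = -\sum_c f_c \log_2 f_c \quad \text{(bits/codon)},$$

where $f_c$ is the frequency of codon $c$ in the gene. $H_{obs}$ alone
confounds amino-acid composition with synonymous choice, so it is compared
with re-encodings of the *same protein*: each codon is replaced by a random
synonym, preserving the translation codon-for-codon. With $H^{(1)},\dots,
H^{(R)}$ the entropies of $R$ such re-encodings (default $R = 20$), the
score is the differential entropy

$$D = H_{obs} - \frac{1}{R}\sum_r H^{(r)}.$$

$D \approx 0$ means the gene looks like a random synonymous encoding of its
own protein; $D < 0$ means its codon choices are more regular than chance,
i.e. biased. Because the null term is built from the gene's own amino-acid
sequence and length, the small-sample bias of the entropy estimator appears
in both terms and cancels in the subtraction — this is what makes $D$
usable across genes of very different lengths, and the package tests verify
$|r(D, \text{length})| < 0.1$ on unbiased synthetic genomes.

Two design points were genuinely open and are resolved as follows:

* **Estimator.** The default estimator is the codon-distribution Shannon
  entropy (`codon_shannon`): proportion-sensitive, and exactly checkable
  against enumeration oracles. An order-sensitive alternative, normalised
  Lempel–Ziv-76 complexity (`lz76`), is provided for users who want
  regularity of codon *order* to count as well. Every result table carries
  an `estimator` column, and cross-genome comparison refuses to mix
  estimators.
* **Null model.** The default null draws each synonym uniformly
  (`uniform_synonymous`) — the literal reading of "codons selected at
  random". A `genome_frequency` option draws synonyms proportionally to a
  genome-wide usage table instead; this changes the meaning of $D$ from
  "bias relative to uniform" to "bias relative to the genome norm", so it
  is an explicit option, never a silent default.

Reproducibility: every gene's RNG stream is seeded by a 31-bit hash of
`(master_seed, gene_id)`, so scores are independent of gene order and of
parallel scheduling, and identical master seeds give bit-identical tables.

## ENC as the independent validation

Wright's effective number of codons is the cross-check statistic. For each
amino-acid family the homozygosity estimator is
$\hat F = (n\sum_i \hat p_i^2 - 1)/(n-1)$, and

$$ENC = 2 + \frac{9}{\bar F_2} + \frac{1}{\bar F_3} + \frac{5}{\bar F_4} +
\frac{3}{\bar F_6},$$

with $\bar F_k$ the mean over $k$-fold families observed at least twice.
ENC runs from 20 (one codon used exclusively per amino acid) to 61 (fully
even synonymous usage); the finite-sample estimator can stray outside, so
results are capped to $[20, 61]$. Wright's original class structure is used
(Leu/Ser/Arg as one 6-fold class each, no splitting); a missing 3-fold class
(Ile rare) is imputed as the mean of $\bar F_2$ and $\bar F_4$, while any
other empty class flags the gene as unscorable rather than imputing.
Since both $D$ and ENC decrease with bias, their correlation across a genome
should be positive; `enc_vs_entropy()` computes it and `autoplot()` draws
the scatter.

## Ranked-list enrichment

The within-genome ranking (ascending $D$, most biased first) feeds a
flexible-threshold enrichment. After collapsing duplicate symbols to their
best rank and restricting the universe to ranked genes with at least one
annotation, each term is scored by the minimum hypergeometric tail over all
prefixes,

$$mHG = \min_{n} \; P\big(X \ge b(n)\big), \qquad
X \sim \mathrm{HG}(N, B, n),$$

and the optimisation over thresholds is corrected *exactly*: a dynamic
program over the $N \times B$ lattice counts the label arrangements whose
prefix path never enters the rejection region, giving the exact probability
that a random ranking would achieve an equally small minimum. The Bonferroni
bound $p \le N \cdot mHG$ holds by construction and is asserted in tests;
for universes up to $N = 8$ the DP is verified against brute-force
enumeration of all $\binom{N}{B}$ label placements. Benjamini–Hochberg
q-values are computed across all terms tested in one run. Term-size bounds
(default $3 \le B \le 2000$) avoid degenerate scans.

## Between-genome comparison

Orthologs scored in both genomes (shared symbols, or an explicit two-column
map) are compared by $\delta = D_A - D_B$; the scatter-plot distance from
the identity diagonal is $|\delta|/\sqrt{2}$. The asymmetry summary counts
pairs beyond a threshold on $|\delta|$ in each direction and tests symmetry
with an exact sign test — a deliberately assumption-free choice, since the
underlying claim is a count asymmetry, not a location shift. The default
threshold is $2\times\mathrm{MAD}(\delta)$, a robust "clearly off the
diagonal" cut.

## Pseudogene lesion screen

The hypothesis-driven arm takes pairwise alignments of an intact reference
CDS against candidate loci (it does not run the alignment tools itself) and
calls two lesion classes: frameshifts — target indels whose length is not a
multiple of 3, with cumulative frame tracked so compensating indels restore
frame downstream — and premature stops — stop codons in the target's running
reading frame mapping strictly before the reference terminal stop. Three
artifact filters mirror standard practice: lesions reproduced in the
reference self-alignment, lesions within 10 nt (configurable) of an exon
boundary, and lesions at sites with read depth below 5 or an
alternate-allele fraction inside [0.2, 0.8] (heterozygous). The thresholds
are explicit configuration with documented defaults, not literature facts;
they are echoed in output. A gene keeping at least one unfiltered lesion is
reported as a candidate pseudogene.

## What the simulator emulates — and what it does not

`simulate_genome()` draws gene lengths log-normally (median 250 codons,
log-sd 0.6, clipped to 50–3000 — a realistic mammalian CDS length profile),
uniform amino-acid composition, and encodes each amino acid by its
preferred codon with probability $\beta + (1-\beta)/k$ ($k$ = family
degeneracy). The mixture form maps directly onto the preferred/nonpreferred
framing of genome-wide usage tables and makes $\beta$ monotonic in every
CUB statistic; $\beta = 0$ reproduces the uniform null *exactly*, which is
what makes the calibration tests meaningful. Study conditions planted by
default: a 20-gene term at $\beta = 0.6$ over a 300-gene background at
$\beta = 0.05$, plus random decoy terms. `simulate_ortholog_pair()` holds
amino-acid sequences identical across species and shifts $\beta$ in a
subset of species-A genes; `simulate_lesion_pair()` plants single indels or
stop substitutions with exact truth records.

The simulator deliberately omits several features of real genomes: regional
GC gradients, non-uniform amino-acid composition, intron structure,
expression-correlated bias, and mutation–selection population dynamics.
Passing tests therefore demonstrate that the statistics recover planted
synonymous-choice signal under controlled conditions — not that every
biological confounder is handled; regional GC in particular is addressed
retrospectively with `flank_gc()` rather than corrected in $D$.

## Numerical choices and degenerate inputs

* Codons containing N are excluded from all counts; genes with more than
  10% N-codons are flagged ineligible (masked assembly gaps would otherwise
  masquerade as low entropy). Internal stops make a gene ineligible for CUB
  and route it to the pseudogene screen; terminal stops are trimmed before
  per-gene statistics but retained for genome-wide usage tables when
  validation is run with `trim_stop = FALSE`.
* Genes without synonymous freedom (all Met/Trp) have $H^{(r)} = H_{obs}$
  for every re-encoding, so $D = 0$ and the null sd is 0 — by construction,
  not by special-casing.
* Ties in ranking are broken lexicographically by `gene_id` and flagged;
  preferred-codon ties likewise.
* The exact mHG p-value is floored at machine epsilon (the DP computes
  $1 - s$, which cannot resolve below that), keeping it a valid probability.
* Coordinates are 0-based half-open internally, converted only at the BED
  boundary; flank windows are clipped at contig edges with achieved lengths
  reported, and a fully clipped window yields `NA` rather than an error.

## Problem sizes used in the test suite

The packaged checks run the simulator at the default study conditions:
null calibration on a 200-gene unbiased genome spanning 100–3000 codons;
monotonicity across $\beta \in \{0, 0.25, 0.5, 0.75, 1\}$ with 50 genes of
500 codons per level; enrichment power over 50 seeded 300-gene genomes and
calibration over 500 random terms; ortholog symmetry over 100 seeds and
planted-shift recovery over 50; and 100 planted-lesion alignments plus 100
lesion-free controls. Exhaustive enumeration oracles are used wherever the
synonymous space is small enough (up to a few hundred variants), and the
Monte-Carlo machinery is required to agree with them within three standard
errors at $R = 10{,}000$.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_genome(seed = 7)
cds <- validate_cds(sim$cds)
res <- run_within_genome(cds, sim$gene_sets, master_seed = 7)
head(res$enrichment[, c("term_id", "N", "B", "p_value", "q_value")])

val <- run_validation(cds, res$scores)
glance(val$validation)
```

The planted term should surface with a q-value far below 0.05 while decoy
terms stay near 1, and the ENC–entropy correlation should be strongly
positive; the README shows the actual numbers printed by this code.

## Known limitations

* $D$ is not corrected for background GC; strongly skewed regional GC can
  mimic bias (inspect with `flank_gc()`).
* The enrichment machinery works on flat gene-set collections (GMT); it
  does not propagate terms over an ontology graph or de-duplicate nested
  terms.
* The pseudogene screen trusts the supplied alignments; alignment errors
  surface only through the three filters.
* The LZ76 estimator is provided for order-sensitivity but has no
  enumeration oracle; its tests are comparative (regular vs. shuffled
  sequences) rather than exact.
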