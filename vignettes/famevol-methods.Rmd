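---
title: "famevol: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{famevol: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`famevol` packages, as a tested and reusable pipeline, the analyses that go
into a genome-wide survey of a large plant receptor-kinase gene family —
the worked system being the soybean LRR-RLK family, whose hundreds of
members arose largely through two whole-genome duplications (roughly 13 and
59 million years ago) plus tandem duplication, and a fraction of which
shows allele-frequency signatures of domestication. This vignette explains
the models and procedures each module implements, the parameters that
matter, what the synthetic-data generator does and does not emulate, and
the design choices made where the underlying methodology is conventionally
under-specified.

## Family identification

Membership in the family is definitional: a candidate protein is a member
exactly when its domain annotation table carries **at least one
leucine-rich-repeat (LRR) interval and at least one kinase interval**
(`filter_by_domains()`). Domain annotations are ingested as a TSV
emulating SMART/PFAM output; re-running those HMM scans is out of scope.
Redundant entries (identical id or identical sequence) collapse to the
lexicographically smallest id — the original study removed redundancy
"manually", so a deterministic rule had to be chosen.

Upstream of the domain criterion sits an optional similarity prescreen
(`prescreen_by_similarity()`): Smith–Waterman local alignment against a
reference query set (BLOSUM62, gap open 11 / extend 1, via Biostrings) with
a Karlin–Altschul E-value `E = K·m·n·exp(-λS)` using the published gapped
BLOSUM62 parameters (λ = 0.267, K = 0.041) and the default cutoff `1e-6`.
A full BLAST heuristic is deliberately not reproduced: the prescreen only
thins candidates, and the domain filter is the decisive criterion.

For annotation-free inputs, `scan_lrr_motif()` provides a fallback scanner:
a 24-column position-weight matrix built from the canonical plant LRR
consensus (`LxxLxxLxLxxNxLSGxIPxxLGx`), conserved columns holding 60% of
the probability mass, scored as log2-odds against a uniform background.
The default threshold is 60% of the maximum attainable score; hits are
selected greedily without overlap, by descending score, ties leftmost.

## Phylogeny of kinase domains

Trees are built from the aligned kinase domains only, as is conventional
for this family. Distances are p-distances by default (the common choice
for protein NJ trees), with a Poisson correction `-ln(1-p)` available;
columns gapped in either row are ignored pairwise, and a pair with no
comparable columns is an error rather than a guess. A Poisson distance is
refused (flagged as saturated) when `1-p ≤ 1e-9`.

`neighbor_joining()` is the standard Saitou–Nei agglomeration with the
Q-criterion `Q(i,j) = (r-2)d(i,j) − R_i − R_j`. Ties in Q are resolved by
the lexicographically smallest pair of cluster labels (a cluster is
labelled by its smallest member), which makes the output a pure function of
the input matrix. Negative branch lengths are retained internally — they
carry information about noise — and `clamp_branch_lengths()` produces the
conventional clamped view for display and Newick export. On additive
inputs NJ is exact; the test suite verifies recovery of random additive
trees, branch lengths included, to 1e-9, and cross-checks topology and
path lengths against `ape::nj`.

Bootstrap support (`bootstrap_support()`) resamples alignment columns with
replacement, rebuilds the tree per replicate, and counts each internal
bipartition of the full-data tree among replicates; 1000 replicates is the
default in the pipeline. Group labels transfer from reference leaves by
minimal patristic distance (`assign_groups()`), ties to the
lexicographically smallest reference, together with a per-group monophyly
report. Subgroup boundaries that the original analysis read off a figure
are not reproduced; nearest-reference assignment plus the monophyly
diagnostics are the package's answer to that gap.

## Genome organization

Tandem clusters are chains: per chromosome, genes sorted by start join one
cluster when consecutive **start-to-start** distances are at most the
window (200 kb default), applied transitively, so a cluster's span can
exceed one window — matching reports of ten-gene clusters. Start-to-start
was chosen because "within 200 kb" is ambiguous (start-to-start, midpoint,
or gap); it is the common convention in the plant gene-family literature
and is monotone under chaining. The measure is a parameter, not a
constant, for anyone preferring another convention.

Paralog pairs are `tandem` when co-clustered; otherwise `segmental` when an
external collinearity-evidence flag marks them (mirroring a duplication
database), and `segmental-candidate` under the no-evidence fallback — the
package does not assert collinearity it has not seen. Chromosome
distribution ratios are percentages of *placed* genes, with unplaced
scaffold genes reported separately.

## Molecular evolution

Ka/Ks follows Nei–Gojobori (1986) with Jukes–Cantor correction. Per codon,
the synonymous site count is the fraction of the nine single-nucleotide
changes that preserve the amino acid; **changes into stop codons count as
nonsynonymous**, so `S + N = 3` holds exactly for every codon (the
originally published convention excludes stop mutations from the
denominator, which breaks that conservation; exact site conservation was
preferred here because it is testable to machine precision). Codons
differing at several sites are counted by averaging over all orderings of
the single-site steps, excluding orderings that pass through an
intermediate stop; if every ordering is blocked, all are averaged equally.
The test suite checks these counts against an independent exhaustive
enumerator over all 3,721 ordered sense-codon pairs.

Proportions convert to distances by `Ks = -(3/4)·ln(1 - (4/3)·pS)` (Ka
analogous); `pS ≥ 3/4` is reported as saturated with no numeric value.
Duplication ages are `T = Ks / (2λ)` with the soybean synonymous clock
λ = 6.1e-9 substitutions/synonymous site/year, reported in million years
to one decimal. The Ks histogram uses bins of width 0.06 anchored at 0 —
exactly the layout under which the two whole-genome-duplication peaks fall
in [0.12, 0.18) and [0.54, 0.60) — and peaks are bins strictly exceeding
both neighbors. The omega partition uses a strict lower bin
(`omega < 0.3` vs `≥ 0.3`), with undefined omega (Ks = 0 or saturation)
reported separately.

Codon alignments come from `backtranslate_align()`: proteins are aligned
(globally, BLOSUM62) and each protein gap expands to a codon triple-gap;
every CDS must translate exactly to its ungapped protein row. Equal-length
proteins are aligned positionally, which is exact for the simulator's
substitution-only pairs.

## Expression profiling

The atlas is gene-wise z-normalized with the population (divide-by-n)
standard deviation; constant rows map to zero vectors and are placed at
distance 1 from everything, keeping the clustering total and
deterministic. Clustering is average-linkage (UPGMA merge rule) on
`1 - Pearson r`, with the same lexicographic tie-break as the tree builder;
the result is a standard `hclust` object, cross-checked against
`stats::hclust` heights on tie-free data.

Two thresholds the original study leaves unstated are exposed as
parameters with documented defaults:

* *tissue preference*: a gene is called preferential in a tissue when its
  value there is at least `fold = 2` times the gene's median across
  tissues and at least `floor = 1`. The rule deliberately permits
  multi-tissue calls, because published per-tissue counts for this family
  sum to more than the number of genes.
* *duplicate divergence*: a pair is "similar" when the Pearson correlation
  of its two rows is at least `r = 0.8`; a tandem cluster is similar only
  if all member pairs are.

qPCR relative expression is the exact `2^(-ΔΔCt)` arithmetic.

## Selection scan

Per locus and population, gene diversity is `H = 1 - Σp_i²` over observed
allele frequencies (the unbiased `n/(n-1)` variant is available; plain H is
the default since the original tooling's choice is not documented).
Fst offers two estimators: Nei's GST `(Ht - Hs)/Ht` with Ht at the
unweighted mean frequency vector — the closed-form testable route — and
the Weir & Cockerham (1984) variance-components θ̂ from allele counts and
sample sizes (the default, since it is what standard population-genetics
software reports). θ̂ is slightly negative for undifferentiated samples;
it is reported as-is rather than floored, and both estimators give exactly
1 for fixed differences.

Classification uses the study's strict boundaries: `selected` means
`Fst > 0.45`, `non-selected` means `Fst < 0.15`, between is
`intermediate`. Coding effects map each SNP through its gene's CDS spans
respecting strand (alleles complemented on minus-strand genes), substitute
the alternate allele into the affected codon and translate; intron and
non-coding positions are labelled as such. The mapping is verified against
a translate-the-whole-CDS oracle and all 576 single-nucleotide codon
substitutions.

## The synthetic-data generator

Every pipeline input can be generated with planted ground truth
(`simulate_inputs()`), making the full analysis testable offline. The
generator's defaults are the package's standing study conditions, chosen
once to echo the real system:

* family protein lengths uniform in 423–1563 residues (the family's
  reported range); three kinase-ancestor groups with ~3% within-group and
  essentially random between-group divergence, so group recovery is
  unambiguous;
* tandem layout of four clusters (10+3+2+2 genes at 80–150 kb spacings) in
  an 80-gene family — about a fifth of the family clustered, echoing
  94/464 with a ten-gene largest cluster; dispersed genes placed strictly
  more than one window apart;
* thirty 300-codon paralog pairs with synonymous targets on the two
  whole-genome-duplication peaks (Ks ≈ 0.15 and ≈ 0.57) plus a recent
  fraction, and Ka targets putting roughly three quarters of pairs under
  omega 0.3. Edits are planted one per codon (synonymous and
  nonsynonymous edits in distinct codons, never creating a stop, rejection
  with a bounded retry), so the Nei–Gojobori counts recover the planted
  numbers exactly;
* a nine-tissue atlas with 80% of genes given one dominant tissue at 8–12×
  a background drawn in a narrow band (0.8–1.2× its mean), so the planted
  tissue is provably the row maximum and preference calls are exactly
  recoverable; duplicate pairs planted as shared (rescaled copies) or
  contrasting (dominant tissues forced to differ);
* a 21-wild / 35-cultivated diploid panel (the study's sample sizes) of
  biallelic loci: 96 "neutral" loci whose frequencies are tuned so
  expected gene diversities are 0.36 (wild) and 0.25 (cultivated), plus 4
  strongly differentiated loci (population GST ≈ 0.87) giving a ~4%
  selected fraction. Genotypes are drawn binomially per individual; loci
  are positioned inside generated gene models, alternating exonic and
  intronic placements, with exonic reference alleles consistent with the
  gene's CDS.

Every generator is a pure function of (config, seed): private RNG streams
are derived from the seed at fixed offsets and the caller's RNG state is
restored, so outputs are byte-identical across runs and independent of
call order.

What the generator does **not** emulate — and hence what green tests do not
demonstrate about real data: realistic amino-acid/codon composition and
transition/transversion bias; indels (alignments are substitution-only);
linkage disequilibrium between loci or within-genome spatial structure of
allele frequencies; read-level expression noise (the atlas is an abundance
matrix, not counts); and annotation error in the domain tables. The
pipeline's correctness on such inputs rests on the component algorithms,
not on end-to-end simulation.

## Numerical and reporting conventions

Percentages and fold ratios round **half away from zero** at one decimal
(82.35% → 82.4%), matching the reporting style of the family literature;
`round_half_away()` implements this against R's banker's rounding, with a
1e-9 guard for rationals whose decimal image sits a few ulp under the half.
Diversity histogram bin edges are built as exact decimals `(0:10)/10` to
avoid floating-point drift at the boundaries. NJ and UPGMA tie-breaks are
lexicographic as described above; all stochastic steps (bootstrap,
generators) take explicit seeds.

## Problem sizes

The shipped test suite exercises the package at small scale (tens of genes,
hundreds of loci, 20–100 bootstrap replicates) so the whole suite runs in
about a minute and a half. The acceptance script
(`scripts/acceptance.R`) runs the pipeline at the package's full reference
scale — about 1,000 genes (667 family + 333 decoys), 329 paralog pairs,
2,000 SNP loci, and a 1,000-replicate bootstrap on a 60-leaf subtree — in
a couple of minutes on one CPU. Bootstrapping is performed on a subtree
once the family exceeds `bootstrap_max_leaves` (default 60) because NJ
bootstrap cost grows cubically with leaf count while support estimates on
a representative subtree answer the same question.

## Interface

The package's interface is its exported functions plus the two drivers:
`simulate_inputs()` writes a complete input bundle (FASTA, GFF3, TSV, VCF
4.2, truth JSON), and `run_pipeline()` chains
identify → phylo → duplication → kaks → express → select over a YAML or
list config, skipping stages whose inputs are absent and writing every
artifact with a manifest of parameters and input checksums. As an analysis
library meant to be driven from R, no shell entry point is shipped; the
config-file driver fills that role for scripted use.

## Known limitations

* The prescreen's E-values use ungapped-theory parameters with gapped
  alignments, as BLAST does, but without composition-based corrections;
  they are a filter, not a statistic to publish.
* Progressive multiple alignment is not implemented; the phylogeny stage
  expects aligned (or fixed-length) kinase domains, which the simulator
  provides and which real use can obtain from any standard aligner.
* The Weir–Cockerham estimator is the haploid (allele-count) form; the
  within-individual (heterozygosity) component of the full genotypic
  estimator is not used, which matters only for strongly inbred or
  Wahlund-structured samples.
* Cluster-level expression similarity requires *all* member pairs to pass
  the correlation threshold; with large clusters this is conservative.
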