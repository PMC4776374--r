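# famevol

Genome-wide gene-family expansion and molecular-evolution analysis in R,
built around the leucine-rich repeat receptor-like kinase (LRR-RLK) family
of soybean — the largest receptor-kinase family described in plants, shaped
by two whole-genome duplications (~13 and ~59 million years ago), tandem
duplication, and domestication-era selection.

The package is for researchers who run this kind of family survey: starting
from protein/CDS sequences, gene models, domain annotations, an expression
atlas and a two-population SNP panel, it produces the family roster, the
kinase-domain phylogeny with group assignments, the duplication landscape,
Ka/Ks-based dating, expression-divergence calls and a selection scan — each
step exposed as a tested function, and the whole chain drivable from one
config. A synthetic-data module generates every input with planted ground
truth, so the full pipeline runs and is verifiable without any external
download.

## The statistics at its core

* **Membership criterion** — a protein belongs to the family iff its domain
  table has ≥ 1 LRR and ≥ 1 kinase interval; an optional Smith–Waterman
  prescreen (BLOSUM62, Karlin–Altschul E-value < 10⁻⁶) thins candidates.
* **Neighbor joining** on kinase-domain p-distances, with
  Q(i,j) = (r−2)d(i,j) − Rᵢ − Rⱼ, column-bootstrap supports, and
  nearest-patristic-reference group transfer.
* **Tandem duplication** — single-linkage chaining of genes whose
  start-to-start distance ≤ 200 kb; non-tandem paralog pairs are segmental
  (with evidence) or segmental-candidate.
* **Nei–Gojobori Ka/Ks** with Jukes–Cantor correction,
  Ks = −(3/4)·ln(1 − (4/3)·pS), pathway-averaged multi-hit codons, and
  duplication ages T = Ks/(2λ) with λ = 6.1×10⁻⁹
  substitutions·synonymous-site⁻¹·year⁻¹.
* **Expression** — gene-wise z-scores, UPGMA clustering on 1 − Pearson r,
  fold-over-median tissue-preference calls, r ≥ 0.8 duplicate similarity,
  and qPCR 2^(−ΔΔCt).
* **Selection scan** — per-locus gene diversity H = 1 − Σpᵢ², Fst (Weir &
  Cockerham 1984 θ̂, or Nei GST), strict thresholds Fst > 0.45 (selected) /
  Fst < 0.15 (non-selected), and codon-level SNP effect annotation.

## Worked example

Simulate a complete input bundle (80-gene family + 40 decoys, 4 planted
tandem clusters, 30 paralog pairs on the two WGD Ks peaks, a 9-tissue
atlas, and a 21-wild/35-cultivated SNP panel), then run every stage:

```r
library(famevol)

cfg    <- sim_config(seed = 7)
bundle <- simulate_inputs(cfg, "demo")
report <- run_pipeline(list(
  inputs = c(bundle$paths[names(bundle$paths) != "truth"],
             list(queries = bundle$paths$reference)),
  params = list(bootstrap = 200, seed = 7),
  outdir = "demo/out"))
#> [famevol] identify: done (80 family members)
#> [famevol] phylo: done (86 leaves)
#> [famevol] duplication: done (4 tandem clusters)
#> [famevol] kaks: done (30 pairs)
#> [famevol] express: done (80 genes)
#> [famevol] select: done (100 loci)
```

The report echoes the planted structure back:

```r
report$duplication$n_clustered_genes   # 17 genes (21.3% of the family)
report$kaks$peaks
#>    bin_low bin_high count
#> 1     0.00     0.06     3
#> 3     0.12     0.18    18
#> 10    0.54     0.60     9
report$select$mean_H
#> wild cult
#> 0.35 0.25
report$select$summary
#>          class  n pct
#> 1     selected  4   4
#> 2 intermediate  2   2
#> 3 non-selected 94  94
```

The Ks histogram peaks sit exactly in the [0.12, 0.18) and [0.54, 0.60)
bins that correspond to the two whole-genome duplications, and the
selection scan recovers the four planted high-Fst loci. Individual
statistics work standalone:

```r
nei_gojobori(codon_alignment(strrep("TTT", 10),
                             paste0("TTC", strrep("TTT", 9))))
#> Nei-Gojobori: 10 codons | S=3.333 N=26.667 | Sd=1.00 Nd=0.00 |
#>   Ks=0.3831 Ka=0 omega=0
date_duplication(0.732)                   # 60 MY
fst(c(900, 100), c(100, 900), "gst")      # 0.64
percentage(340, 464)                      # 73.3
fold_ratio(467, 213)                      # 2.2
```

`Sd = 1` on `S = 10/3` synonymous sites gives pS = 0.3 and the
Jukes–Cantor-corrected Ks above; a Ks of 0.732 under the soybean clock
dates a duplication to 60 million years — the older WGD era.

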