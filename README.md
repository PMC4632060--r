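# notchopa

Genotyping and phenotype scoring for the *opa* triplet repeats of
*Drosophila* *Notch*.

## The problem

Exon 8 of *Notch* carries the *opa* repeats: a run of ~23–38 5′-CAX codons
encoding two polyglutamine (pQ) tracts separated by a single histidine
(wild type: Q₁₃HQ₁₇, the *opa31* allele). The locus is invisible to
short-read assembly — a read must span the whole repeat plus flanking
anchor sequence (3 bp × 40 codons + 10 bp × 2 anchors = 140 bp), so it is
genotyped by Sanger sequencing of multiple independent plasmid clones per
fly. That protocol brings its own error model: PCR slippage (stutter)
produces single-codon contractions at ~5%/clone (expansions ~0.6%), and
clone libraries pick up contamination from bottle mates (intraculture) or
from other stocks handled alongside (interculture).

`notchopa` is for researchers genotyping unstable triplet repeats from
clone libraries. It implements:

* **Nomenclature** — pQ configurations Q_l[H]Q_r, allele names
  `opa{N}` with letter suffixes for same-length alleles with a different
  histidine position (`opa33a` = Q₁₄HQ₁₈ vs `opa33b` = Q₁₅HQ₁₇), numeric
  suffixes for identical pQ isoforms with independent codon histories
  (`opa35a1`/`opa35a2`), and `L`/`R` names for slippage derivatives
  (`opa30L` = Q₁₂HQ₁₇ from *opa31*).
* **Repeat extraction** — anchor-based location of the in-frame CAX run on
  either strand of FASTA clone sequences, with mismatch-tolerant anchor
  matching and hard errors instead of guessing on ambiguity.
* **Genotype calling** — per-individual calls from clone tallies. Alleles
  with ≥ 2 clones and ≥ 20% support are candidates; candidates explainable
  as stutter of a better-supported candidate (below a 30% ceiling) or as
  listed foreign contaminants are demoted; remaining minor clones are
  classified as slippage, interculture contaminant, intraculture
  contaminant (singleton among ≥ 8 clones), or ambiguous. Error rates are
  estimated as class counts over clones.
* **Population QC** — allele distributions with heterozygous haplotypes
  weighted 0.5, non-wild-type fractions, mean |length − 31| deviation, and
  X-linked Hardy–Weinberg expectations
  (A-only = M·p + F·p², het females = F·2p(1−p), with the female count
  rounded before expectation).
* **Macrochaete scoring** — the 13-position hemi-notum scoring system
  (1.0 normal, 0.0 missing, 2.0 ectopic/split, 1.5 shared-mid, fractional
  slender, −1.0/−2.0 compound defects) with the rarer-defect masking rule,
  plus embryonic-failure and fecundity summaries.
* **Synthetic data** — a seeded generator of Sanger clone libraries
  (X-linkage, 5–13 clones/individual, configurable slippage and
  contamination rates) with per-clone ground truth, so the whole pipeline
  is testable end to end.

## Worked example

Simulate a 4-line study (10 individuals/line, 10 clones each) at the
default error rates, extract the repeats, and call genotypes:

```r
library(notchopa)

cfg   <- sim_config(clones_range = 10L, seed = 7L)
study <- simulate_study(cfg)
ex    <- extract_repeats(study$sequences, cfg$anchors)
calls <- call_genotypes(ex, study$samples, foreign_alleles = cfg$foreign_pool)
calls
#> opa genotype calls: 40 individuals in 4 lines
#> line simA: opa31  [10 individuals]
#> line simB: opa32  [10 individuals]
#> line simC: opa33a  [10 individuals]
#> line simD: opa23  [10 individuals]
calls$error_rates
#> clone error rates (400 clones):
#>   original genotype             92.0%  (368/400)
#>   original (excl. intercult.)   96.1%  (368/383)
#>   slippage contraction           3.0%  (12/400)
#>   slippage expansion             0.8%  (3/400)
#>   intraculture contamination     0.0%  (0/400)
#>   interculture contamination     4.3%  (17/400)
#>   ambiguous                      0.0%  (0/400)
```

All 40 individuals are recovered correctly: every line is called
homozygous for its generating allele, the stutter clones are explained as
`opa{N}L`-type contractions rather than spurious heterozygosity, and the
estimated contamination sits near the generating 3.6%/5.7% rates (the
intraculture contaminants of a homozygous line carry the line's own allele
and are therefore invisible to the caller — see the vignette).

Hardy–Weinberg expectations for a polymorphic X-linked stock:

```r
xlinked_hw_expected(39, 53.7, 0.5)
#> X-linked Hardy-Weinberg expectation: n = 39 (21F/18M), p = 0.5
#>   A_only       14.25  (rounded 14)
#>   B_only       14.25  (rounded 14)
#>   het_female   10.50  (rounded 11)
```

## Package layout

* `R/pq-config.R`, `R/registry.R`, `R/slippage.R` — allele model.
* `R/extract.R` — anchor-based extraction, spanning-read criterion.
* `R/genotype.R` — tally / call / error-rate estimation.
* `R/popqc.R`, `R/data.R` — population summaries, published survey tables.
* `R/phenotype.R` — bristle scoring, hatch and fecundity summaries.
* `R/simulate.R` — seeded synthetic clone libraries and phenotype tables.
* `vignettes/opa-genotyping.Rmd` — methods and design notes.
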