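---
title: "Genotyping the Notch opa repeats from Sanger clone libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping the Notch opa repeats from Sanger clone libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(notchopa)
```

## The locus and its error model

The *opa* repeats of *Drosophila* *Notch* are a run of 5′-CAX codons in
exon 8: CAA/CAG (CAR) encode glutamine, CAC/CAT (CAY) encode histidine.
Functionally the region is two polyglutamine tracts separated by a single
histidine — wild type Q₁₃HQ₁₇, 31 codons — and natural alleles range from
an uninterrupted Q₂₃ to Q₁₃HQ₂₃. Because a sequencing read must span the
entire repeat plus non-repetitive anchor sequence on both sides before an
alignment can even be anchored, short reads cannot genotype the locus;
the data model here is therefore a Sanger *clone library*: for each fly,
several independent plasmid clones of a PCR amplicon are sequenced.

Three error processes stand between clone sequences and genotypes:

* **PCR slippage (stutter).** Replication slippage inside a run of
  identical glutamine codons deletes (commonly) or inserts (rarely) whole
  codons. Observed per-clone rates are ~5–6% for contractions and ~0.6%
  for expansions, nearly always single-codon events; the observed extremes
  are a 4-codon contraction and a 2-codon expansion, which set the default
  reachability limits (`max_del = 4`, `max_ins = 2`).
* **Intraculture contamination.** DNA of bottle mates of another genotype
  from the same culture (relevant for polymorphic stocks), at ~5.7% per
  clone in the one affected experiment.
* **Interculture contamination.** Clones matching a different stock
  handled alongside, at ~3.6% per clone in the one affected experiment.

## Nomenclature

Alleles are named `opa{N}` by total residue count. A lowercase letter
separates same-length alleles whose histidine sits elsewhere (`opa33a` =
Q₁₄HQ₁₈, `opa33b` = Q₁₅HQ₁₇); letters are assigned in discovery
(registry) order, and an unlettered name occupies "a". A trailing number
separates identical pQ configurations with different codon strings
(`opa35a1`/`opa35a2`), i.e. independent indel histories; `*n` tags for
synonymous substitutions are stored as opaque registry tags. Slippage
derivatives are named `opa{N}L` or `opa{N}R` by the side of the histidine
on which the changed run lies. For histidine-less alleles (the `opa23`
family) the side is taken from the position the histidine occupies in the
ancestral wild-type pattern (codon 14), which is how an `opa22L`
contraction of *opa23* gets its "L" despite *opa23* lacking the His.

When a configuration is resolved against a registry that lacks it, a name
is minted by these rules and added to the registry. One consequence of
treating an unlettered name as occupying "a": a nucleotide-level variant
of plain `opa31` would mint `opa31a2`. The alternative — guessing whether
the variant arose by substitution (`*n`) or by independent indels (`a2`)
— needs history information a registry does not have, so the indel-style
suffix is used and the `*n` tag is left to the curator.

`default_registry()` ships the ten RAL survey alleles. Their published pQ
configurations are exact; their codon strings are **synthetic
placeholders** (the published per-allele third-position strings are not
machine-readable). The placeholder layout puts a 7-codon CAG run at the
3′ end of the left tract and keeps right-tract CAG runs at ≤ 6, so the
longest run — the stutter hotspot — lies left of the histidine and
simulated contractions are predominantly "L", matching the dominance of
`opa30L`-type variants in every quality-control experiment. The registry
TSV round-trips losslessly, so real strings can be dropped in.

## Repeat extraction

`locate_and_extract()` matches a left and right anchor (default 10 bp,
≤ 1 substitution, no indels — Sanger clone flanks are high quality) on
both strands and takes the in-frame CAX codon run between them. Two
refusals are deliberate: several candidate loci raise an ambiguity error
listing all of them (a genotyper must not silently pick a locus), and a
non-CAX codon between matched anchors raises a malformed-repeat error
rather than returning a truncated run. The spanning criterion
`can_span()` is a strict inequality — a read exactly as long as
3·codons + 2·anchor is judged insufficient, consistent with calling a
75-nt read unable to span 23 codons with 3-bp anchors (exactly 75 bases).
The 3′ hypervariable (GGGGA)ₙ region downstream of the repeats is treated
as outside the locus.

## Genotype calling

`call_individual()` works on the clone tally of one individual, keyed by
codon string so nucleotide-level variants stay separate:

1. Alleles with at least `het_min_support = 2` clones **and** at least
   `het_min_frac = 20%` of clones are provisional candidates. Singletons
   never support heterozygosity, mirroring the singleton-contaminant
   rule.
2. Candidates are demoted, weakest first, while any is *explainable*:
   as stutter, when a better-supported candidate can produce it by
   slippage and it holds at most `slip_max_frac = 30%` of clones; or as
   an interculture contaminant, when it matches a listed foreign allele
   and a non-foreign candidate remains.
3. Every minor allele is then classified against the surviving
   candidates, in order of biological precedence: slippage derivative
   (contraction or expansion; ties between possible parents break toward
   the higher-count parent, then lexicographically), listed foreign
   contaminant, intraculture contaminant (a singleton among at least
   `singleton_contaminant_min_clones = 8` clones; below 8 such
   singletons stay ambiguous), else ambiguous. An allele that is both
   slippage-derivable and foreign-matching is classed as slippage — PCR
   error is the dominant observed process.
4. Zygosity: heterozygous with exactly two surviving candidates,
   single-allele (hemizygous/homozygous — the X gives no way to tell in
   males) with one, ambiguous otherwise; zero candidates give an
   ambiguous call with a diagnostic, not an exception.

Step 2 is the one place the procedure goes beyond a literal
support-threshold rule, and it is forced by the arithmetic of stutter: at
10 clones/individual and a 5%/clone contraction rate, the probability of
two or more identical contraction clones in one individual is ~9%, and
contraction products of a given parent are a *single* codon string (any
deletion within a run yields the same sequence). A support-only rule
would therefore call several percent of homozygotes heterozygous for
their own stutter product. The 30% ceiling separates the stutter regime
(~5%) from a true heterozygous allele (~50% of clones): at 10 clones, a
true het minor allele falls at or below 3 clones only ~17% of the time
binomially, and such individuals are under-called as single-allele — a
known cost, visible in the simulator, which is why polymorphic stocks
are genotyped with more clones or more individuals.

`estimate_error_rates()` turns pooled classifications into rates with
numerators and denominators retained. The original-genotype fraction is
reported both over all clones and after removing interculture
contaminants from the denominator — the convention used when summarizing
a contaminated culture. One bookkeeping note: in the reference
somatic-variation clone set (`qc_reference_clone_sets()$somatic`), the
published totals (218 clones, 94.0% original) imply 13 variant clones
while the per-class enumeration lists 12; the set reconstructed here
assigns the unenumerated clone to the dominant `opa30L` class so that
the totals, not the enumeration, are authoritative. Similarly, the
contaminated-stock summary uses the 345-clone denominator implied by
333 original + 12 contractions after removing 13 contaminants.

## Population summaries

`allele_distribution()` weights each homozygous line 1 and each haplotype
of a segregating line 0.5, so weights sum to the line count.
`mean_abs_deviation()` gives a heterozygous line the average of its two
haplotype deviations, consistent with the 0.5-weight convention.
`dgrp_line_genotypes()` ships the printed survey groups; the
radiation-resistant group reproduces 58.3% non-*opa31* (10.5/18) and a
mean deviation of 1.8 residues.

`xlinked_hw_expected()` computes, for an X-linked biallelic locus among
`n` individuals with female fraction `f` and allele frequency `p`:
A-only = M·p + F·p², B-only = M·(1−p) + F·(1−p)², heterozygous females =
F·2p(1−p). Two rounding choices matter and are fixed: the **female count
is rounded to an integer before** expectations are computed (21 F/18 M
from 39 at 53.7%), and reported counts are rounded **half away from
zero** (10.5 → 11). This is the only rounding order that reproduces the
published 14/14/11 expectation; raw counts always sum to `n` exactly.
All displayed percentages across the package use the same half-away
rounding (`round_half_away()`, `percent1()`), because base R's
round-half-to-even gives 4.7% where the published tables print 4.8%.

`goodness_of_fit()` computes Pearson's Σ(O−E)²/E with k−1 degrees of
freedom directly, because the expected counts are externally supplied
rather than estimated from the observations; the statistic is
cross-checked against `chisq.test()` in the tests.

## Macrochaete scoring

Each of the 13 hemi-notum positions gets a score: 1.0 normal, 0.0
missing, 2.0 ectopic or split, 1.5 to each member of a DC/SC pair
sharing a mid-positioned bristle, a fraction (default 0.5) for slender
bristles, −1.0 for an empty socket with a nearby ectopic, −2.0 for two
empty sockets replacing one bristle. Because opposite defects would
cancel in a mean, within each genotype × sex × position group only the
more frequent defect class (ectopic, score > 1, or missing, score < 1)
is kept; the rarer class is masked to 1.0. Two decisions the scoring
rules leave open are fixed here: ties keep the ectopic class, and
masking is stratified by sex (all published frequency panels separate
sexes). The negative compound-defect scores enter the means and are also
counted separately, since the published treatment is not stated.
Hemi-nota (two per fly) are the unit for frequency means; flies are the
unit for `ectopic_rate()`, which counts flies with any score > 1 at the
duplication-prone DC/SC/pPA positions.

## The synthetic generator

`simulate_study()` emulates the genotyping study design: inbred lines on
the X (males hemizygous, one allele; females two draws from the line
frequencies), clones per individual uniform on [5, 13] (the reported
range, whose mean 9.2 is consistent with uniform), per-clone contraction
0.05, expansion 0.006, intraculture contamination 0.057 and interculture
contamination 0.036 — the observed rates as generating conditions.
Slippage events are single-codon, drawn from the longest glutamine run
(ties at random); multi-codon events arise only as compound
probabilities. Intraculture contaminants are drawn from the line's own
allele set (bottle mates), interculture contaminants from a configured
foreign pool. One global seed governs all draws in a fixed stream order
(lines → individuals → clones), so identical seeds give byte-identical
studies; every emitted clone appears exactly once in the truth tables.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: chromatogram quality and base-calling error,
primer-proximal artifacts, per-cycle stutter accumulation (the rate is a
flat per-clone probability, not a likelihood model over cycles),
real flank sequences (placeholders), and real codon strings (the
registry placeholders fix the run structure, not the published
sequences). In particular, intraculture contamination of a *homozygous*
line produces clones carrying the line's own allele: the truth tables
record them, but no caller can detect them, so parameter-recovery checks
target the contraction and interculture rates.

## Problem sizes and verification

The end-to-end property exercised in the tests: a 4-line × 10-individual
× 10-clone study (400 clones) at the default rates is simulated,
extracted and called; genotype accuracy must reach 99% and the estimated
contraction and interculture rates must lie within two binomial standard
errors of the generating rates. At these sizes the whole suite runs in
well under a minute. The deterministic published numbers (QC error
rates, Hardy–Weinberg 14/14/11, survey group statistics, the nine
distinct pQ isoforms, the 140-bp spanning length) are asserted exactly
at their printed precision; nothing in this vignette states a number the
tests or `scripts/acceptance.R` do not themselves compute.

## Known limitations

* Heterozygotes whose minor allele drifts to ≤ 30% of clones are called
  single-allele; genotype more clones for polymorphic stocks.
* The caller is rule-based by design; it assigns classes, not
  probabilities, and does not model per-cycle stutter.
* Same-allele (intraculture) contamination of homozygous lines is
  undetectable in principle from clone sequences alone.
* Registry codon strings are placeholders; analyses that depend on exact
  third-position strings (e.g. distinguishing `opa35a1` from `opa35a2`
  in real data) require a curated registry file.
* No mutational phylogeny among alleles is inferred; gene conversion
  makes simple relationships unreliable at this locus.
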