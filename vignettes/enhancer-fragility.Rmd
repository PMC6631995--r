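---
title: "Enhancer fragility from predicted deactivating mutations: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enhancer fragility from predicted deactivating mutations: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the model and its
assumptions, the parameters that matter and why they default where they do,
what the synthetic world emulates and what it deliberately does not, and
the numerical policies applied at the edges. Nothing stated here goes
beyond what the test suite and `scripts/acceptance.R` compute.

## The question

A point mutation inside an enhancer can abolish a transcription-factor
binding event and with it the enhancer's activity — or it can be silently
absorbed because a redundant site compensates. The pipeline asks, for every
position of every enhancer, whether at least one of the three possible
substitutions is predicted to deactivate the enhancer (a *deMP*,
deactivating-mutation position), and then studies enhancers at the two ends
of the deMP-density spectrum: *fragile* (top 20% by density) versus
*stable* (bottom 20%), with the middle 20% as *regular*. Enhancers without
any deMP are left unclassified; all class sizes are `floor(0.2 n)` of the
deMP-containing enhancers.

## The scoring model

**Vocabularies.** For each chromatin signal track (and pooled over all
enhancers), canonical k-mers — a word and its reverse complement count as
one, giving 32,896 classes at k = 8 — are tested for enrichment in
enhancers versus matched controls with a one-sided Fisher exact test on the
2×2 table (this k-mer vs all others) × (enhancer windows vs control
windows). A k-mer is *top* when its Bonferroni-corrected p ≤ 1e−3 and its
enhancer window density exceeds its control density; *background* when its
raw p > 1e−3 (strict inequality); *neutral* otherwise. Windows containing
`N` or repeat-masked (lowercase) bases are never counted. Top k-mers carry
weight `log2((d_e + 1/N_e) / (d_c + 1/N_c))` with `d` the window densities
and one pseudo-window as a continuity guard; all other k-mers weigh exactly
zero. The one-sided p-value is computed as a hypergeometric tail
(`phyper`); the test suite checks it against direct summation of the
hypergeometric point masses and against `fisher.test`.

**Candidates.** Only substitutions that flip a top 8-mer into a background
8-mer in at least one covering window are scored; every other substitution
is a non-deM by definition. This keeps the scored set on the
motif-disruption side of the score's dynamic range, which is the regime the
deM concept addresses.

**Features.** For every k in {4, 6, 8, 10, 12} and every track:

* `Δ_kj` — the maximum over the k windows covering the variant of
  (weight of reference window − weight of alternate window), floored at 0.
* `S_kj` — the summed weight of top-k-mer windows lying fully inside
  ±100 bp of the variant that do **not** cover the variant position.

The exclusion of covering windows from S is a design choice: it keeps Δ
and S non-redundant, so the decomposition separates "what the mutation
breaks" from "what the neighborhood still offers". The 100-bp half-width
is the typical scale of clustered co-binding within an enhancer and is
configurable (`feature_schema(flank_window = ...)`).

**Weights and decomposition.** A linear maximum-margin classifier
(`e1071::svm`, linear kernel) is fitted to labeled variants, with the cost
parameter chosen by 5-fold cross-validated AUC over {0.01, 0.1, 1, 10}. A
logistic probability map is then fitted on the held-out decision values
and *folded into the weight set* (weights scaled by the logistic slope,
intercept absorbing the offset), so that the published invariant

    score = plogis(WS(Δ) + WS(S) + b),   margin = WS(Δ) + WS(S) + b

holds exactly rather than approximately: the decomposition is asserted to
1e−9 on every scored variant. If the logistic slope is non-positive
(degenerate folds), the map falls back to identity, preserving the
invariant.

**Threshold.** The deM threshold is the empirical upper (1 − FPR)-quantile
of negative-control scores: the smallest score t such that the fraction of
negatives ≥ t is at most FPR (0.01 by default). Ties at the threshold
count as deMs. With fewer than 1/FPR negatives the function warns: the
order statistic is then unstable. The held-out false-positive rate of this
rule is the first acceptance quantity (`t5` in `scripts/acceptance.R`).

## The synthetic world

The generator's defaults are the package's study conditions; they were
fixed once and are stated here with their rationale.

* **Genome** — one 5-Mb chromosome, i.i.d. background at GC 0.45, 10%
  repeat masking in 800-bp lowercase blocks placed outside enhancers.
  These are round numbers in the range of mammalian euchromatin; the
  single-chromosome choice only simplifies bookkeeping.
* **Enhancers** — 200 per architecture, 300–600 bp, ≥ 200 bp apart.
  *Homotypic* enhancers carry 3–5 copies of one pioneer-like 8-bp motif;
  *heterotypic* enhancers one copy each of 3–5 distinct tissue-specific
  motifs. This is the billboard-vs-enhanceosome contrast the classifier
  must recover. Each planted copy is degenerate with probability 0.2 (one
  position switched to its designated second-best base) so vocabularies
  must learn motif families, not single strings.
* **Tracks** — negative-binomial bin counts (10-bp bins, background mean
  5, dispersion 0.3), 5× elevated over target sites: an accessibility
  track over all sites, a pioneer-factor ChIP analog over homotypic sites,
  a tissue-specific-factor analog over heterotypic sites. Overdispersed
  counts, not Gaussians, because sequencing coverage is overdispersed.
* **Labels** — 500 positives and 500 negatives by default. Positives
  substitute a base of a heterotypic planted site, where no redundant copy
  buffers the loss. Negatives sit inside enhancers: half at homotypic
  planted sites (buffered), half at non-site positions. This is the
  generator's ground truth about buffering — the biological claim that
  losing one of several identical sites is survivable while losing a
  unique site in a cooperative arrangement is not. Both classes are at
  distance 0 from an enhancer and draw their simulated minor-allele
  frequency from one Beta(1, 3)/2, so the matched covariates are
  exchangeable by construction (checked by a KS test in the suite).
* **LD panel** — 2,000 genome-wide SNPs plus 400 inside enhancers, fixed
  50-kb blocks, all within-block pairs at r² = 0.9, nothing across blocks.
  Trait tags (30 per disease type) are biased 0.8 toward one architecture
  (immune → heterotypic, metabolic → homotypic), giving the GWAS stage a
  plantable contrast.
* **Evolution** — substitution indicators at rate 0.002 over planted sites
  and conserved elements versus 0.01 elsewhere (a ~5× constraint typical
  of functional elements), restricted to a 95% alignability mask; SNP
  indicators use the same two-rate scheme scaled by 0.8. Conserved
  elements are centered segments covering 50% of homotypic but only 15% of
  heterotypic enhancers, so sequence constraint correlates with the stable
  architecture. Ortholog activity is 0.6 vs 0.3 by architecture at a 30%
  ortholog rate.
* **Seeds** — a mandatory master seed; every artifact consumes a sub-seed
  from a fixed affine splitting rule (`derive_seed`), so adding one output
  never perturbs another and two runs under one seed are byte-identical.

**What the world does not emulate.** Nucleosome positioning, 3D contacts,
realistic demographic LD, indels, motif spacing grammar, transcription
units (the control matching therefore uses distance-to-enhancer where the
original design matched distance-to-TSS). Passing tests on this world show
that the pipeline recovers a planted redundancy-vs-cooperativity signal
under realistic noise; they do not show that real HepG2 enhancers follow
the same effect sizes.

## Matched controls

For each enhancer, candidate windows of identical length are drawn
uniformly from the genome and accepted when |ΔGC| ≤ 0.005,
|Δrepeat| ≤ 0.01, the window is N-free and overlaps neither an enhancer
nor a previously accepted control. The draw budget is 10,000 tries per
needed control; any deficit is filled by mononucleotide shuffles of the
enhancer itself (case travelling with its letter, so both matched
statistics are preserved exactly) and flagged as such. The mononucleotide
shuffle is the minimal reading of "reshuffling"; a dinucleotide-preserving
shuffle is deliberately out of scope. Controls never overlap each other —
otherwise enrichment denominators would double-count sequence.

## PSSM scanning and clusters

PSSMs are log2-odds against a uniform background. The consensus-based
builder varies the consensus-base probability across positions in a fixed
cyclic gradient (±0.03 around 0.85): with identical columns, all
single-mismatch words tie at one score and the threshold can only move in
coarse jumps, which makes density calibration needlessly lumpy; real motif
columns are heterogeneous. The calibrated threshold is the smallest score
whose hit density on background sequence (both strands) is at most 5 per
10 kb; a score distribution with no spread (an all-zero matrix) is
rejected. Scanning skips windows containing N or lowercase, returns both
strands, and never merges overlapping same-factor hits.

Clusters follow the ≥ 3 sites / ≤ 1 kb rule: homotypic for one factor,
heterotypic for ≥ 3 *distinct* factors (the strict reading of "different
TFs"; `min_distinct = 2` gives the lax reading). Spans are measured
max(end) − min(start) over member hits. Typing is disjoint: a single-factor
run can never satisfy the distinct-factor requirement. Per-enhancer
`has_homotypic`/`has_heterotypic` flags — not cluster counts — feed the
class-level statistics, since a window count per enhancer would depend on
an arbitrary tiling convention.

## Evolutionary and GWAS statistics

Divergence is the fraction of alignable, non-repeat-masked interval
positions that differ from the outgroup; undefined (NA with a warning)
when nothing is alignable. Conserved-element coverage excludes
repeat-masked bases from the denominator; groups are compared by rank-sum
test. Ortholog activity uses a two-sided Fisher exact test between the
stable and fragile classes among enhancers with orthologs.

LD expansion is one round — tags plus partners at r² strictly greater than
0.8 within 500 kb — with no transitive chaining. Disease-type enrichment
uses the union of the two LD-expanded class SNP sets as the hypergeometric
universe; this universe choice is a documented decision (the natural
population is not otherwise defined for a two-set contrast) and is the
quantity reported as −log10 p in both directions.

## Numerical policies

* All internal coordinates are 0-based half-open; VCF is converted at the
  boundary. One convention everywhere prevents off-by-one drift.
* Repeat masking travels only as lowercase; every analysis window touching
  lowercase or N is skipped, and GC denominators exclude N.
* Quintile ties are broken by enhancer id, making the partition a pure
  function of the (density, id) ranking; rescaling densities cannot change
  labels.
* The middle quintile is anchored at offset `floor(0.4 n)`.
* Enrichment ratios use a 0.5 continuity guard only when the control count
  is zero.
* Hypergeometric p-values are floored at the smallest positive double
  before −log10.
* deMP density denominators use full enhancer length including masked
  bases — the simpler reading of "enhancer positions"; the alternative
  (non-repetitive length) would only rescale densities within an enhancer
  set whose repeat content is balanced by construction.

## Problem sizes

The default study conditions (200 enhancers per architecture on 5 Mb, 500
positive and 500 negative training variants, 2,000 calibration negatives)
run end to end in a few minutes on one CPU; the unit-test world uses 30
enhancers per architecture on 600 kb, which preserves every qualitative
contrast. The acceptance quantities use 10,000 + 10,000 negatives (FPR
check) and 200 enhancers × 5 controls (matching check), the sizes at which
the order statistics concerned are stable.

## Known limitations

* The weight fit is only as identifiable as the track set is informative;
  with a single flat track the Δ/S features of the two architectures
  coincide and the classifier cannot separate buffered from unbuffered
  site disruptions.
* Calibration negatives are drawn by the same generator as training
  negatives (different sub-seed); with very small enhancer sets the two
  samples can overlap in positions, which leaves the threshold honest on
  average but correlated with training.
* The canonical-k-mer convention counts palindromic words once per window;
  a strand-by-strand counting convention would double them.
* `fit_weights` assumes both classes are present and at least two examples
  per class; it refuses degenerate inputs rather than guessing.
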