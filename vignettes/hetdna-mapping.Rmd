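---
title: "Mapping heteroduplex DNA in crossover products: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping heteroduplex DNA in crossover products}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetmapr)
library(dplyr)
```

## The problem

Homologous recombination repairs a broken DNA duplex using an intact
homologue as template. While strands are exchanged, regions form in which the
two strands of one duplex derive from *different* parental molecules —
heteroduplex DNA (hetDNA). In a mismatch-repair-deficient background the
hetDNA footprint survives until the first post-recombination replication,
when the two strands segregate into different daughter cells. A colony grown
from the recombinant cell therefore contains *two* sequence species for a
product that carried hetDNA, and sequencing a barcoded amplicon pool of the
colony reveals, marker by marker, where both parental alleles are present.

The disposition of hetDNA in the two reciprocal crossover (CO) products
discriminates initiation mechanisms:

* a **double-strand break (DSB)** repaired through the canonical
  double-Holliday-junction route leaves one asymmetric hetDNA tract on each
  side of the break, one tract per product (*two-sided* hetDNA);
* a **nick** (Meselson–Radding initiation) leaves a single asymmetric tract,
  in what was originally donor sequence, adjacent to the crossover point;
* a **single-strand gap** leaves a *symmetric* tract (hetDNA at the same
  position in both products) flanked by an asymmetric extension in exactly
  one product.

hetmapr implements the full path from barcoded consensus reads to these
classifications, together with a strand-resolved simulator of the mechanisms
that serves as ground truth for every stage.

## The assay geometry

Two truncated alleles of a reporter gene share a homology region (~4.1 kb in
the engineered system) carrying 82 silent SNPs at ~50-bp spacing. The
*recipient* allele carries an I-SceI recognition site; the *donor* allele has
the same site inactivated by a 6-bp insertion, so only the recipient is cut.
The SNPs nearest the break sit 8 bp from each 3' end left by the nuclease
(which cleaves to leave a 4-nt 3' overhang). A crossover anywhere in the
homology region fuses the two alleles into a selectable full-length gene; the
two reciprocal products — the doubly-truncated product (recipient arm
upstream, donor arm downstream of the crossover) and the full-length product
(the reverse) — are amplified separately with product-specific primer pairs
and sorted by colony barcode.

The real substrate sequences are not redistributed with the package.
`synthetic_substrates()` generates a stand-in pair that reproduces every
structural property the analysis depends on: homology length, marker count
and spacing, the recognition site with its overhang geometry, the flanking
markers at 8 bp, and the inactivating donor insertion. All coordinates are
0-based, half-open, in the recipient homology frame.

```{r assay}
assay <- synthetic_assay()
assay$pair
assay$break_site
head(tibble::as_tibble(assay$map), 3)
```

## From reads to genotypes

`demultiplex()` assigns reads to recombinants by their 16-nt barcode (unique
hit within Hamming distance 2, both orientations tried; both amplicon ends
carry the barcode, so the adjacent universal primer decides product identity
and reading direction). `call_read_profiles()` aligns each read globally to
both parental references, frames the marker columns with the higher-scoring
alignment, and calls each marker `R`, `D`, or `N` (non-parental base or
deletion). `cluster_species()` groups read profiles by exact equality on
non-`N` calls, with `N` matching anything and ties broken toward the larger,
earlier cluster. A species is *major* when it has at least 2 reads and at
least 10% of the product's reads; recombinants with more than two major
species in a product fail QC. With two major species, a marker where they
disagree `R`-vs-`D` is diagnostic of hetDNA and is called `H`.

The thresholds (2 reads, 10%, 80% alignment identity, barcode distance 2)
are package defaults, all configurable; they are the package's own
operating points. Base qualities are parsed but unused:
consensus reads are treated as flat-quality.

## Tracts and lengths

`segment_product()` collapses a genotype vector into maximal runs; an `N`
marker is absorbed when its informative neighbours agree and excluded
otherwise. `event_tracts()` interprets segments against the product's fixed
flank structure (the truncated product inherits the recipient arm upstream
of the anchor and the donor arm downstream; the full-length product the
reverse): `H` runs become hetDNA tracts, donor alleles in recipient context
become conversions, recipient alleles in donor context are donor
alterations, and parental runs sandwiched inside hetDNA are restoration
patches. An `H` run whose markers are heteroduplex in *both* products is
symmetric hetDNA; it is *terminal* when it closes the break-distal end of
the partner's longer asymmetric tract (the junction-migration signature) and
interstitial otherwise.

Tract length is measured to the **most break-distal transition** from
heteroduplex to homoduplex DNA or between donor and recipient sequence. The
true transition lies between two markers; the package places it at the
inter-marker midpoint, an unbiased and reproducible convention. When the
outermost non-parental marker is the last before the homology border, the
tract extends to the border. The midpoint convention is the
package's choice over the marker-to-marker alternative; the two conventions differ by at most half a marker
interval (~25 bp).

Medians, not means, summarise tract lengths, because many tracts run to the
homology border and the distribution is censored there.

## Classification

For induced events (`classify_induced()`, break known) the decision order
is: conversion-only (no hetDNA), donor-only (hetDNA exclusively in
donor-derived context), displaced transition (adjacent inter-product tract
boundary shifted from the break by at least one marker), two-sided
(asymmetric hetDNA on both sides in opposite products), one-sided
left/right, else uninterpretable. The order makes the classes disjoint: a
two-sided event with donor alterations stays two-sided and records the
alterations as features. "Adjacent to the break" for gap-expansion features
means the conversion run includes the break-flanking marker.

For spontaneous events (`infer_initiation()`, break unknown) the hetDNA
pattern itself is matched: a DSB pattern (asymmetric tracts in both products
meeting at a transition) yields the inferred break at the transition
midpoint — or at the centre of an interstitial conversion tract separating
the tracts, acknowledging that the true break likely sat at one of its ends
— and the broken allele as the minor-contribution parent; nick and gap
patterns require their diagnostic tract to touch the crossover point within
one inter-marker interval. These labels are descriptive, not causal: the
same patterns occur among DSB-induced events, which is why induced events
never receive nick/gap labels.

## The simulator

`simulate_dsbr()`, `simulate_mr_nick()`, `simulate_gap()` and
`simulate_dloop_cleavage()` operate at strand-of-markers resolution with
bp-valued interval endpoints; sequences are realised only by
`emit_reads()`. Each product duplex is two strands of parental alleles;
`observe_colony()` replicates them into the one or two colony species
(daughter loss optionally hides hetDNA), and `emit_reads()` adds barcodes,
primers, and uniform substitution errors. Every sampled quantity is stored
in the truth record, and `replay_audit()` verifies that each event's
duplexes are re-derivable from that record.

Key parameters (`mechanism_params()`), with defaults:

* `resection_mean = 1000` bp — geometric hetDNA extent per side, floored at
  `extent_min = 60` bp (one marker interval; shorter pairing is invisible at
  marker resolution). The mean is chosen so simulated total hetDNA is
  commensurate with the multi-kb scale of the assay.
* `p_end_loss = 0.15`, `end_loss_mean = 150` bp — 3'-end loss expanding the
  break into a gap, producing break-adjacent conversion.
* `p_single_snp_loss_upstream = 0.49`, `..._downstream = 0.94` — removal of
  the break-flanking marker by polymerase proofreading of the terminal
  mismatch; the defaults are the efficiencies observed in the CO assay.
* `p_back_migration = 0` — D-loop back-end migration to the break, erasing
  invasion-side hetDNA (one-sided events).
* `hj_migration_bp` (with `p_hj_migration`) — signed junction migration:
  positive values convert the distal end of one tract to terminal symmetric
  hetDNA; negative values displace the inter-product transition upstream of
  the break. No quantitative migration model exists for
  this step; the signed-bp formalisation is the package's own.
* `p_template_switch = 0`, `switch_extent_mean = 200` bp — one
  sister-template excursion per event during fill-in synthesis, yielding an
  interstitial donor-context tract (modelled as a single switch-out/switch-
  back, per the established depiction).
* `resolution_mode` — `NICK_DIRECTED` fixes hetDNA upstream in the truncated
  product and downstream in the full-length product; `RANDOM_LIGATED` flips
  the orientation with probability 0.5. Back-migration and junction
  migration are applied after second-end capture and before resolution (the
  mechanisms themselves do not fix an order).
* `p_patch_repair = 0` with `p_restoration_given_repair = 26/37` — MMR-
  independent mismatch removal with the observed restoration bias.

What the simulator does *not* emulate: thermodynamics of strand exchange,
break-induced replication and multi-invasion events, meiotic recombination,
PCR chimeras, and CCS consensus construction from subreads (the pipeline
starts from consensus reads). Passing round-trip tests therefore shows the
analysis correctly inverts this generative model, not that real colonies
contain no artefacts beyond it.

`simulate_fluctuation()` draws Luria–Delbrück mutant counts (Poisson number
of mutations, clone sizes from the reciprocal-uniform law, capped at the
culture size), and `lea_coulson_rate()` estimates the event rate by the
method of the median, solving `r/m − ln m = 1.24` by bracketed root finding
(tolerance 1e-12). For the confidence interval
the package uses a Stewart-type dispersion on
`ln m` (`1.225 · m^-0.315 / √C`), documented and swappable. A zero median
with non-zero counts falls back to the flagged `P0` estimator `m = −ln P0`;
all-zero cultures yield only a flagged upper bound (the largest `m`
consistent at the 5% level with no mutants in `C` cultures).

## Numerical and degenerate-case choices

* Coordinates: 0-based half-open, recipient frame; `dist_to_break` is
  measured to the nearer 3'-end coordinate, so the flanking markers report
  8 bp on the engineered design.
* The donor's 6-bp insertion is a product-identity feature, never a
  genotyping marker; reads carry it when the strand they derive from is
  donor-derived at the cut-site region, and the global aligner absorbs it as
  a gap.
* Alignment scoring is fixed (match 1, mismatch −2, gap open 12, extend 3)
  so isolated SNPs are never represented as indels; the short donor
  insertion remains affordable. The insertion's placement within the
  cut-site region is alignment-ambiguous by one or two bases, which is
  immaterial because no marker logic depends on its exact offset.
* All-`N` genotype vectors are rejected; an `N` at a tract boundary is
  excluded from segments and reported.
* A displaced transition requires at least one marker strictly between the
  break and the transition midpoint — displacements below marker resolution
  are not claimable.
* A single product carrying hetDNA on both sides of the break (with none in
  the partner) matches no model prediction and is uninterpretable, the precedence
  order above is one consistent formalisation of that "patchy" exclusion.
* The 3'-half flag for inferred initiation sites uses the homology midpoint
  as a strict boundary.

## Problem sizes used in the shipped checks

The test-suite and acceptance script sizes are chosen to exercise the
claimed properties at cohort scale while staying quick on a laptop:
orientation law at 10,000 nick-directed and 1,000 random-ligated events;
noiseless round trips at 500 events per mechanism at full marker density;
read-level round trips with 1% substitution error at depth 20 on a
scaled-down substrate (600 bp, 10 markers, identical geometry — full-length
4.1-kb alignments add nothing to the logic being checked and two orders of
magnitude of runtime); 100 fluctuation experiments of 24 cultures;
brute-force oracle comparisons at 1,000 random instances each.

## Known limitations

* Real CCS data contain chimeric reads, heteroduplex PCR artefacts and
  barcode hopping that the simulator does not model; QC (major-species
  limits) is the only line of defence the package offers against them.
* Breakpoint positions are only resolvable to the inter-marker interval;
  all bp-valued outputs inherit that granularity.
* Donor-only and conversion-only events are recorded but treated as
  mechanistically uninformative.
* The confidence interval on fluctuation rates assumes the median-method
  estimator's asymptotic dispersion; for very small culture counts it is
  approximate.
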