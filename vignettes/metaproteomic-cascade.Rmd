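---
title: "The iterative metaproteomic cascade: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The iterative metaproteomic cascade: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metacascade)
```

## The problem and the model

Shotgun metaproteomics of a holobiont — a host animal together with its
microbial community — assigns tandem-MS spectra to peptides by searching a
protein database. When the host genome is unsequenced, no tailored database
exists, so the search must start from a generalist database covering
hundreds of thousands of taxa. That first pass is statistically weak (a
huge search space inflates score thresholds) but taxonomically informative:
the peptides it does validate reveal which organisms are present. The
cascade strategy exploits this: taxa supported in round one define small
sub-databases (host plus other metazoa; food plants; unicellular organisms)
that make the follow-up searches far more sensitive, and the union of
round-two identifications forms the final database for protein-level
quantification.

`metacascade` implements everything downstream of the search engine. Its
evidence unit is the **taxon-to-spectrum match (TSM)**: an accepted PSM
whose peptide maps, via its protein accessions, to a taxon. Peptides
shared across taxa are handled by rank projection: a peptide is *specific*
to a taxon at a canonical rank (superkingdom, phylum, class, order,
family, genus, species) when every taxid in its set projects to that same
taxon at that rank. A peptide ambiguous between two sibling species is
therefore still genus-specific — ambiguity rises to the nearest rank that
absorbs it, which is the same collation idea as lowest-common-ancestor
assignment, but bookkept per rank so that every level carries four
counters (TSMs, distinct peptides, specific peptides, specific TSMs).

Relative biomass at a reporting rank is the share of specific TSMs:

share(t) = specificTSM(t) / Σ_t' specificTSM(t').

Specific TSMs are used rather than all TSMs so that no spectrum is counted
for two taxa at the same rank; this makes shares sum to one by
construction and matches the unit used for the FDR estimate.

## Assumptions

* Spectral counts are proportional to protein biomass. No correction is
  applied for proteome size, peptide detectability or protein length; the
  shares are relative, not absolute, abundances.
* Leucine and isoleucine are indistinguishable by the instrument, so
  peptides are canonicalized with I → L before any taxonomic use, and
  duplicate peptides collapse to one key.
* Decoy peptides (from reversed sequences) inherit the taxonomy of their
  source protein, so the decoy pool has the same per-taxon composition as
  the target pool and decoy genus calls estimate the rate at which random
  matches produce apparently specific evidence.
* The input tables (taxonomy, accession map, PSM tables, GO annotation)
  are mutually consistent; consistency is enforced at load time, and
  accessions or GO identifiers that cannot be resolved are surfaced in
  orphan/skipped reports rather than silently dropped.

## Tunable parameters

| parameter | default | where | rationale |
|---|---|---|---|
| expectation cutoff | 0.05 (strict <) | `validate_psms` | standard PSM validation level; engine-specific homology thresholds are deliberately not modelled |
| multi-PSM fraction | 0.98 | `select_spectrum_psms` | within a spectrum, co-accepted PSMs must exceed 98% of the top ion score; the top match is always kept |
| retention thresholds | eukaryota (9, 109), bacteria (7, 74), archaea (1, 6) | `retention_policy` | species enter the sub-databases when they exceed (strictly) either the specific-peptide or the TSM threshold for their superkingdom |
| representatives | max 10, ≥ 2 added TSMs | `select_representatives` | caps database growth; "added" is marginal spectrum coverage over prior picks |
| genus-call support | 3 distinct specific peptides | `call_genera` | the smallest evidence level at which a genus is reported |
| PSM-level FDR | 0.01 | `filter_psm_fdr` | cumulative decoy/target ratio on the expectation ordering |
| reporting rank | genus | `biomass_shares`, `call_genera` | the rank at which community composition is quantified |
| fold change / alpha | 1.5 / 0.05 (both strict) | `wilcoxon_bh` | a feature is significant only when both fire |

All thresholds quoted as "more than n" are strict inequalities: a
bacterium with 8 specific peptides is retained (8 > 7), a eukaryote with
exactly 9 is not (9 > 9 is false). The same reading applies to the 98%
rule — a PSM scoring exactly 0.98 × top is dropped.

## Design choices where the procedure was open

* **TSM clause of retention** uses *total* TSMs at species rank, not
  specific TSMs. Both counters are exposed and the policy is an argument;
  the permissive reading was chosen as the default because retention is a
  recall-oriented step (the FDR control happens later, at genus calling).
* **Taxonomic FDR formula** is the plain ratio #decoy calls / #target
  calls, the minimal reading of a target/decoy hit comparison; the
  (2d)/(t+d) variant can be computed from the reported counts.
* **Parsimony inference** is realized as connected components on the
  shared-peptide graph, subset-collapse inside each component (a protein
  whose peptide set is contained in another member's is subsumed), then
  razor assignment of multi-group PSMs to the group with the larger
  provisional count. Ties break to the smaller group id, and the anchor
  of a group is the member covering the most distinct peptides
  (lexicographic on ties), so the whole pipeline is deterministic and
  permutation-invariant.
* **GOslim counts are duplicated, not split**: a group annotated to terms
  reaching two incomparable slim ancestors contributes its full spectral
  count to each. Slim profiles are therefore *not* a partition of the
  spectral counts and should not be renormalized across terms; within one
  term, counts remain comparable across samples.
* **Group-level GO annotation** uses the anchor accession first and falls
  back to the union over members, because annotation is per protein while
  quantification is per group.
* **Technical replicates are averaged** into their biological replicate
  before testing (configurable), avoiding pseudoreplication with tiny n.
* **Exact Wilcoxon** p-values are used rather than the normal
  approximation: with three biological replicates per tissue the exact
  null has only 20 arrangements, and the approximation is meaningless at
  that size.
* **Fold change** is the ratio of group medians, larger over smaller, with
  direction recorded separately; a zero lesser-median yields an infinite
  fold change, which is reported rather than masked (a pseudo-count
  argument exists for users who prefer shrinkage).
* Bray–Curtis distances are delegated to `vegan::vegdist`; the
  closed-form value on a two-feature example is asserted independently in
  the tests.

## The synthetic generator

`simulate_world()` emulates exactly the statistical structure the cascade
consumes, nothing more:

* a small multi-superkingdom taxonomy with complete canonical lineages
  (plus Metazoa / Streptophyta / Fungi clade nodes so partitioning has
  real lineages to inspect);
* per-species proteomes of random tryptic-like peptides (length 7–25,
  ending in K/R, no isoleucine); peptide *identity*, not chemistry, is all
  the cascade uses, so masses, retention times and spectra are not
  simulated;
* controlled peptide sharing: a configurable fraction of each species'
  peptides is copied into a sibling species, producing peptides that are
  genus- but not species-specific;
* a planted community (default shares 0.5/0.3/0.2 over three bacterial
  genera) from which target PSMs are drawn multinomially, and decoy PSMs
  from reversed sequences with lower scores and higher expectation values
  (default 10% of the target count), so the PSM-FDR filter has a
  realistic operating point;
* a six-term GO DAG with a diamond (one leaf under two incomparable slim
  terms) so the antichain behaviour of slim mapping is always exercised.

Ground truth (planted genera, realized multinomial shares, protein-group
memberships by construction) is recorded alongside, and identical seeds
give byte-identical worlds.

Because peptide sharing never crosses genus boundaries, genus-level share
recovery is exact up to multinomial sampling noise; the tests verify
recovery within ±3 points at 5,000 PSMs and exact round-tripping against
the realized draw. What the generator does **not** emulate — homologous
peptides shared across distant taxa, database incompleteness, chimeric
spectra, intensity-dependent detectability — means a green test suite
demonstrates the bookkeeping is correct, not that real-data biomass
estimates are unbiased.

For the differential layer, `simulate_abundance_matrix()` draws
negative-binomial counts (size 20, the moderate extra-Poisson spread
typical of spectral-count replicates) with a four-fold shift planted in a
subset of features. Note that total-sum scaling propagates planted shifts
into the unshifted features (the classic compositionality artifact); the
fold-change filter suppresses most, but not necessarily all, of these.

## Numerical and degenerate-input conventions

* Within-spectrum score ties at the top are all kept.
* Representative-selection ties on TSM count break by ascending taxid.
* Constant features get p = 1 and a flag instead of a test.
* Empty inputs produce empty, well-typed outputs (empty profile, empty
  FASTA with a warning); undefined quantities (biomass with zero specific
  TSMs, FDR with zero target calls, Bray–Curtis between all-zero samples)
  raise errors naming the offending object.
* All randomness flows through a single integer seed; sampling is
  integer-based where feasible for cross-platform stability.

## Problem sizes

The test suite and the acceptance script run entirely on simulated worlds
chosen at desk scale: oracle cross-checks use ≤ 30 taxa / ≤ 200 PSMs
(collation), ≤ 8 candidate sets (greedy selection), ≤ 12 proteins
(parsimony vs exhaustive minimal cover) and ≤ 20-term DAGs (slim mapping);
recovery studies use 200–5,000 PSMs and 100–200 Monte-Carlo replicates.
These sizes were picked so every brute-force oracle is exhaustive and the
whole suite completes in about a minute.

## Known limitations

* Biomass shares ignore proteome size and detectability; two genera with
  equal cell counts but different proteome sizes will not report equal
  shares.
* The genus-level decoy FDR estimate is coarse in very small communities:
  with a handful of genera, a few validated decoy PSMs suffice to call
  every genus on the decoy side, and the ratio saturates above 1. In
  realistic communities (tens to hundreds of genera) decoy evidence
  dilutes and the estimate is informative.
* Strain-level resolution, entrapment databases, per-genus q-values,
  intensity-based quantification and ordination plotting are out of
  scope; the package exports tables for external tools instead.
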