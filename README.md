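# metacascade

Metaproteomics of a host-associated microbiome when the host has no
sequenced genome: `metacascade` implements the bookkeeping behind an
iterative ("cascade") database-search strategy for tandem-MS data. A first
search against a generalist protein database yields peptide-to-spectrum
matches (PSMs); taxa supported by those matches define small,
sample-specific sub-databases (host, food-derived plants, unicellular
organisms) for follow-up searches; the final merged search supports protein
inference and functional profiling of both host and microbiome. The package
is aimed at microbial ecologists and proteomics bioinformaticians working
on non-model holobionts (gut tissues of invertebrates, for instance), and
consumes search-engine-agnostic PSM tables rather than raw spectra.

## What it computes

* **PSM validation** — expectation value < 0.05 (strict), and a
  per-spectrum multiple-match rule: within a spectrum the top-scoring PSM
  is kept along with any PSM whose ion score exceeds 98% of the top score.
* **Taxon-to-spectrum matches (TSMs)** — each accepted PSM's peptide is
  mapped through protein accessions to taxa and collated up the seven
  canonical ranks (superkingdom … species). A peptide is *specific* to a
  taxon at a rank when its whole taxon set projects to that single taxon;
  specific TSMs at the reporting rank (genus by default) give **relative
  biomass** shares: share(g) = specificTSM(g) / Σ specificTSM.
* **Taxonomic FDR** — genera are called from ≥ 3 distinct genus-specific
  peptides, independently for target and reversed-decoy peptides;
  FDR = #decoy calls / #target calls.
* **Database tailoring** — species are retained when they exceed
  superkingdom-specific thresholds (> 9/7/1 specific peptides or
  > 109/74/6 TSMs for eukaryota/bacteria/archaea); up to ten representative
  taxa per species are picked greedily by TSM count with ≥ 2 newly covered
  spectra each; retained taxa partition into host-metazoa / streptophyta /
  unicellular FASTA sub-databases with reversed `DECOY_` companions.
* **Protein inference** — proteins sharing a peptide form groups
  (connected components), subset proteins are collapsed under the maximal
  member, and each accepted PSM contributes exactly one spectral count to
  one group (razor assignment). Counts are conserved exactly.
* **Functional rollup** — microbial group counts are summed onto the
  minimal GOslim ancestors of their GO annotations (Map2Slim semantics
  over is_a/part_of; a group contributes its full count to every slim term
  it reaches).
* **Differential layer** — total-sum scaling, exact two-sided Wilcoxon
  tests with Benjamini–Hochberg correction, fold change on group medians
  (significant when FC > 1.5 and adjusted p < 0.05), Bray–Curtis
  dissimilarities, and a heat-tree-ready export table.

A synthetic-fixture generator (`simulate_world()`) builds complete toy
worlds — taxonomy, proteomes, planted communities, PSM tables with decoys,
GO annotations — with recorded ground truth, so every stage is testable
without raw mass-spectrometry data.

## Worked example

`make_worked_example()` builds a hand-written three-genus world (two
*Escherichia* species, one *Pseudomonas*, one *Saccharomyces*; six
proteins, eight peptides, thirty PSM rows). Every number below is
documented step by step in
`inst/extdata/worked_example/COMPANION.md`.

```r
library(metacascade)
r <- run_cascade(make_worked_example())
r$biomass
#>   taxid          name specific_tsm_count     share
#> 1    25   Escherichia                 16 0.5714286
#> 2    35   Pseudomonas                  8 0.2857143
#> 3    45 Saccharomyces                  4 0.1428571
r$fdr
#> $fdr
#> [1] 0
#> $n_target
#> [1] 1
#> $n_decoy
#> [1] 0
r$groups[, c("anchor", "n_peptides", "spectral_count", "bin")]
#>   anchor n_peptides spectral_count        bin
#> 1 P251_1          3             13 microbiome
#> 2 P251_2          1              3 microbiome
#> 3 P351_1          2              8 microbiome
#> 4 P451_1          2              4 microbiome
r$goslim
#>      slim_id               name          namespace spectral_count
#> 1 GO:0008152  metabolic process biological_process             20
#> 2 GO:0006950 response to stress biological_process             12
```

Of the 30 PSM rows, 28 target PSMs survive validation (one candidate fails
the 98%-of-top-score rule on its spectrum; the decoy is excluded from
profiles). *Escherichia* carries 16 of the 28 genus-specific TSMs, hence
57.1% of the biomass. Only *Escherichia* reaches the three
genus-specific-peptide threshold, and with no decoy genus call the
estimated taxonomic FDR is 0. The 28 spectral counts distribute over four
protein groups without loss, and the two GOslim totals (20 and 12) sum
whole group counts, with the group annotated to a diamond GO term counted
under both slim ancestors.

There is also a small command-line front end:

```sh
Rscript inst/cli/metacascade.R simulate --seed 1 --n-psms 2000 --out world/
Rscript inst/cli/metacascade.R profile --dir world/ --out world/
```

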