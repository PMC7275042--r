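# Worked example: hand-derived numbers

World: `make_worked_example()`. Three genera — Escherichia (species 251, 252),
Pseudomonas (351), Saccharomyces (451) — six proteins, eight peptides, thirty
PSM rows.

## Peptide map

| peptide | proteins | taxa | species-specific | genus-specific |
|---|---|---|---|---|
| AAAAAAK | P251_1 | {251} | 251 | 25 |
| CCCCCCK | P251_1, P252_1 | {251,252} | — | 25 |
| DDDDDDK | P251_2 | {251} | 251 | 25 |
| EEEEEEK | P252_1 | {252} | 252 | 25 |
| FFFFFFK | P351_1 | {351} | 351 | 35 |
| GGGGGGK | P351_1, P351_2 | {351} | 351 | 35 |
| HHHHHHK | P451_1 | {451} | 451 | 45 |
| MMMMMMK | P451_1 | {451} | 451 | 45 |

## PSM acceptance

30 rows. All expectation values < 0.05 pass validation. Spectrum S06 carries
three candidates: AAAAAAK (ion score 100, top — kept), CCCCCCK (98.5 > 0.98
x 100 = 98 — kept), FFFFFFK (97 <= 98 — dropped). One decoy PSM (S28,
KAAAAAA, DECOY_P251_1) passes validation but is excluded from profiles.
Accepted target PSMs: 28.

Accepted target PSMs per peptide: AAAAAAK 6, CCCCCCK 4, DDDDDDK 3,
EEEEEEK 3, FFFFFFK 5, GGGGGGK 3, HHHHHHK 2, MMMMMMK 2 (sum 28).

## Taxon profile (expected_profile.tsv)

Species rank: 251 touches AAAAAAK+CCCCCCK+DDDDDDK -> tsm 6+4+3=13, 3
peptides; specific = AAAAAAK, DDDDDDK -> 2 peptides, 9 TSMs. 252: CCCCCCK +
EEEEEEK -> 7 TSMs, 2 peptides; specific EEEEEEK -> 1, 3. 351: 8 TSMs, both
specific. 451: 4 TSMs, both specific.

Genus rank: Escherichia gets all four bacterial-Enterobacteriaceae peptides
(CCCCCCK becomes genus-specific): 16 TSMs / 4 peptides, all specific.
Pseudomonas 8/2, Saccharomyces 4/2. Higher ranks aggregate accordingly
(Proteobacteria = Escherichia + Pseudomonas = 24 TSMs / 6 peptides).

## Biomass at genus rank (expected_biomass.tsv)

Total genus-specific TSMs = 16 + 8 + 4 = 28.
Shares: 16/28 = 0.571428..., 8/28 = 0.285714..., 4/28 = 0.142857...

## Genus calls and taxonomic FDR (expected_genus_calls.tsv)

Target genus-specific distinct peptides: Escherichia 4 (>= 3, called),
Pseudomonas 2, Saccharomyces 2 (not called). Decoy pool has one peptide ->
no decoy call. FDR = 0 / 1 = 0.

## Protein groups (expected_groups.tsv)

Components by shared peptides: {P251_1, P252_1} via CCCCCCK; {P251_2};
{P351_1, P351_2} with P351_2 subsumed (its peptide set is a subset);
{P451_1}. Razor counts: group 1 = 6 + 4 + 3 (EEEEEEK hits P252_1, a member)
= 13; group 2 = 3; group 3 = 5 + 3 = 8; group 4 = 4. Sum 28 = accepted
target PSMs. All species are unicellular -> microbiome bin.

## GOslim rollup (expected_goslim.tsv)

Annotations (anchors): P251_1, P251_2 -> GO:0006508 (proteolysis, slim
ancestor GO:0008152); P351_1 -> GO:0042026 (protein refolding, slim ancestor
GO:0006950); P451_1 -> GO:0019538 (diamond: both GO:0008152 and GO:0006950
are minimal slim ancestors — the full count goes to each).
GO:0008152 = 13 + 3 + 4 = 20. GO:0006950 = 8 + 4 = 12.
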