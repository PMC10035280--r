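# primercover

In silico coverage evaluation of degenerate 16S rRNA gene primers and
primer pairs against species-annotated amplicon sequence variant (ASV)
databases.

## The problem

Amplicon sequencing of the 16S rRNA gene depends on "universal" primers
that anneal in conserved regions flanking a hypervariable target. Primers
mismatch some taxa, and a mismatched taxon silently disappears from the
community profile. `primercover` quantifies that risk for ecosystem-specific
databases — e.g. oral bacteria and archaea — where each species is
represented by one to many genomic sequence variants:

- a variant is **covered** by a primer when every primer position matches
  the sequence with **zero mismatches**, IUPAC ambiguity codes in the
  primer expanding to their base sets (R = A/G, ...); ambiguous or gap
  characters in the database never satisfy a primer position;
- **variant-level coverage** `VC = 100 · (matched variants) / (all variants)`;
- **species-level coverage** `SC = 100 · (species with ≥ 1 matched variant)
  / (all species)` — robust to variants truncated at the sequence ends,
  which depress VC but not SC.

Primer pairs are formed from all forward × reverse combinations of
candidates (SC ≥ 75.00%) whose mean positions satisfy
`mean(F first) < mean(R last)` and `mean(R last) − mean(F first) ≥ 100`,
binned by mean amplicon length (100–300, 301–600, > 600 bp), labelled by
the 16S region they amplify in the *E. coli* J01859.1 coordinate frame,
and classified **bacteria-specific** / **archaea-specific** /
**non-specific** by whether their SC in the other domain is exactly 0.00%.

All positions live in a 1-based frame where position 1 is the first
nucleotide of *E. coli* J01859.1 and sequences are trimmed at position
2000. The package bundles a clearly labelled **synthetic** 1542-nt
stand-in reference (`inst/extdata/synthetic_reference_16S.fasta`) so it is
fully self-contained offline; pass the real J01859.1 FASTA to
`reference_frame()` for production work.

## Worked example

```r
library(primercover)

fx <- generate_fixture(fixture_spec(seed = 3))   # synthetic primers + databases
p  <- fx$primers[1, ]                            # "OP_F001"

primer_coverage(p, fx$bacteria)
#> OP_F001 vs bacteria: VC = 60.53% (23 variants), SC = 90.00% (9/10 species)

position_stats(p, fx$bacteria)
#>   primer_id direction mean_first mean_last mode_first mode_last n_observations
#> 1   OP_F001   forward         40        57         40        57             23

res <- run_eval_pairs(fx$primers, fx$bacteria, fx$archaea)
res$pairs[, c("forward_id", "reverse_id", "mean_amplicon_length",
              "length_category", "region", "bacterial_sc", "archaeal_sc",
              "specificity")]
#>   forward_id reverse_id mean_amplicon_length length_category region
#> 1    OP_F001    OP_R001                  398         301-600    1-3
#>   bacterial_sc archaeal_sc  specificity
#> 1           70          80 non_specific
```

The primer matches 23 of 38 bacterial variants (VC 60.53%) but 9 of 10
species (SC 90.00%): truncated variants lower VC while their full-length
siblings keep the species covered. The single admitted pair spans mean
positions 40–437 (mean amplicon 398 bp, category 301–600), amplifies
regions 1–3, and covers both domains, so it is non-specific.

Every fixture carries a ground-truth table computed by a brute-force
oracle (`oracle_coverage()`, `oracle_pair_coverage()`) that expands
degenerate primers into all concrete sequences and compares every window —
independent of the regex-based engine it validates.

## Acceptance script

`scripts/acceptance.R` regenerates the synthetic world at a given seed and
runs the complete pipeline (primer evaluation, candidate selection, pair
enumeration, dual-domain pair coverage, specificity):

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
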