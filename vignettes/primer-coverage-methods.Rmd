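---
title: "Methods: coverage evaluation of degenerate 16S primers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coverage evaluation of degenerate 16S primers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The matching model

A primer is a short 5'→3' oligonucleotide over the 15-letter IUPAC
alphabet. Canonicalization uppercases, maps U→T and inosine I→N (inosine
pairs promiscuously; N is the most permissive stand-in, and the transform
is logged as lossy), and rejects anything else with the offending
position. Matching is **zero-mismatch**: primer letter *p* matches
database letter *s* iff *s* is a concrete base contained in the IUPAC set
of *p*. Two asymmetries are deliberate:

* degeneracy in the **primer** widens matching (a pool of synthesized
  oligos really contains every expansion);
* ambiguity in the **database** (N and friends) never matches — an
  uncertain base call is not evidence of annealing — and gap characters
  never match.

Databases store sense-strand sequences; reverse primers are
reverse-complemented once at load time (IUPAC-aware complement) and then
searched like forward primers, which reproduces the annealing geometry
with a single search path. All overlapping occurrences are reported,
because position statistics are computed over the whole match population.

The engine compiles a primer into a character-class regular expression
wrapped in a lookahead (overlaps included). Its independent check is a
brute-force oracle that expands the primer into all concrete A/C/G/T
strings and compares every window by string equality; engine and oracle
are held equal on 100 seeded random fixtures in the test suite.

## The two coverage statistics

`VC` (variant level) is the percentage of database sequences with at
least one match; `SC` (species level) is the percentage of species with
at least one matched variant. Public sequence deposits are frequently
truncated at the gene ends, so a primer annealing near an end loses VC
for reasons that have nothing to do with its biology. SC absorbs this: a
species whose full-length variant matches stays covered even when its
truncated variants do not. Percentages are reported at two decimals with
halves rounded **away from zero** (base R rounds half to even, which is
not byte-stable against tabulated values); raw fractions are retained on
every result object, and specificity classification uses the raw count —
"0.00%" in a specificity decision means literally zero covered species.

## Positions, modes and gene regions

For each primer the first/last positions of every match across all
variants form a multiset; the mean and mode are reported. With several
modes, the one **closest to the mean** wins; an equidistant residual tie
resolves to the smaller position. An empty match population yields
undefined (`NA`) statistics, not an error — "undefined" propagates into
pair labels.

Region assignment uses a configurable table tiling the 1542-nt reference
into 10 conserved (C1–C10) and 9 hypervariable (V1–V9) intervals
(closed intervals, boundary position belongs to the region whose interval
starts there). The bundled boundaries follow the commonly cited *E. coli*
coordinates, but they are configuration, not ground truth. A primer whose
mode lands in a conserved region is named by the hypervariable region on
its amplicon-interior side (forward → next V downstream, reverse → next V
upstream): universal primers anneal in conserved flanks yet are
conventionally named by the V region they amplify. Modes beyond the
reference end (possible up to frame position 2000) are "beyond-reference"
and render as "undefined" in labels.

## Primer pairs

Candidates are primers with SC ≥ 75.00% (inclusive, on the rounded
percentage) on the relevant database. All forward × reverse combinations
are admitted when (1) the mean first position of F is below the mean last
position of R and (2) the distance between the two means is ≥ 100 nt.
Mean amplicon length uses the inclusive span `mean(R last) − mean(F
first) + 1`, and the three categories (100–300, 301–600, > 600 bp — the
short-read, long-read and near-full-length regimes) are applied to the
integer-rounded mean. Pairs admitted on both domains are merged by
(forward, reverse) and evaluated once.

Pair coverage demands **same-variant co-matching with geometry**: a
variant counts only when both primers hit it and some F site starts
before some R site ends — amplification requires one template molecule.
This is the stricter of the two readings (the alternative being
"both primers cover the species somewhere") and is the biologically
coherent one; the admission thresholds and category edges are all
configurable should a user want the sensitivity analysis.

## The reference frame and normalization

Coverage positions are meaningful only if all sequences share a
coordinate frame: 1-based positions anchored at the first nucleotide of
*E. coli* J01859.1 with a hard stop at 2000. Imposing the frame never
needed a multiple sequence alignment — each record is aligned **pairwise**
to the reference (ends-free global alignment; match +1, mismatch −1, gap
open 5, gap extend 1 — stated here because no canonical values exist),
alignment-internal gaps are discarded, and the record is stored as
`leading_offset` gap characters followed by its own bases. Consequences:

* a pure reference subsequence recovers its true offset exactly (tested);
* bases 5' of the reference start map below position 1 and are trimmed;
  bases whose frame position exceeds 2000 are trimmed;
* normalization is idempotent: leading padding is stripped and re-derived
  on re-entry.

A record is dropped as "unalignable" when its aligned span falls under
60% identity **or** covers less than 30% of the record's length. The
second condition is this package's addition: an ends-free alignment of an
unrelated sequence can degenerate to a tiny high-identity window and slip
past a pure identity filter. Records whose total length exceeds 120% of
the reference span they cover are flagged "redundant" (duplicated-segment
heuristic, e.g. a deposit carrying two copies of regions 4–6) but are
**never auto-deleted** — no principled removal criterion exists, so the
flag is for human review.

The bundled reference is a deterministic **synthetic** 1542-nt stand-in,
not the real J01859.1 sequence; every fixture derives from it, so no test
result depends on the real gene. `reference_frame()` accepts any
single-record FASTA replacement.

## The synthetic world

`generate_fixture()` builds, from a seed and a declarative spec, a primer
set plus one database per domain with oracle-computed truth:

* species drawn from the reference with ~5% divergence, variants with a
  further ~1% (defaults; both configurable) — enough structure for
  non-trivial matching without emulating real phylogeny;
* 1 to many variants per species (default range 1–6);
* primer sites implanted exactly where declared, as concrete realizations
  of degenerate primers built from the reference window; non-selected
  variants get the window actively broken by one out-of-set base, and an
  implant restricted to one domain is broken everywhere in the other, so
  domain-specific truth SC is exactly zero;
* a truncation fraction (default 0.3) clips variants at the 5' end
  (leading-gap padding keeps the frame) or the 3' end — this is what makes
  VC < SC, the phenomenon SC exists for;
* a small N rate (default 0.01) emulates ambiguous base calls.

Truth tables are computed by the brute-force oracle on the *final*
sequences, so accidental matches and sites destroyed by noise are
reflected exactly. What the generator does **not** emulate: phylogenetic
correlation between species, chimeras, length heterogeneity of real 16S
genes, or realistic primer thermodynamics. A green engine-vs-oracle test
therefore establishes the combinatorics and arithmetic of coverage, not
field performance of any real primer.

## Numerical and degenerate-input choices

* rounding: half away from zero, 2 dp for percentages, 0 dp for mean
  amplicon lengths before categorization;
* deduplication keeps the first-seen primer identifier, making the
  distinct set reproducible under file order;
* empty databases error on coverage; empty match populations do not;
* mode ties: nearest the mean, then smaller position;
* region table must tile contiguously from position 1 (validated on
  read).

## Limitations

Paper-scale figures (hundreds of primers against databases with hundreds
of species and up to thousands of variants per species) depend on the
original supplementary primer list and databases, which this package does
not redistribute; the `eval-pairs` command applied to those files is the
intended integration run. The pure-R matcher favors clarity over
throughput — at desk scale every suite runs in seconds; at paper scale
expect minutes, not hours.
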