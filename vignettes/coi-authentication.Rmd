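---
title: "Methods: COI barcoding authentication and misdescription calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: COI barcoding authentication and misdescription calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coiauth)
```

## The problem

Processed seafood — sushi in particular — loses the morphological traits that
let an inspector recognize a species, which makes species substitution easy
and common. The standard molecular remedy is DNA barcoding: a ~650 nt
fragment of the mitochondrial Cytochrome Oxidase I (COI) gene is amplified
from the product, sequenced, and assigned to a species by percent identity
against reference sequences. A product is then *misdescribed* when no match
exists among three things: the name on the menu, the taxa that name lawfully
declares under the applicable trade-name list (in the packaged survey, the
Italian ministerial decree n.19105 of 22 September 2017), and the species the
barcode identifies.

`coiauth` implements that workflow as four composable stages — amplicon QC
with NUMT screening, percent-identity assignment against a local reference
panel, trade-name compliance calling, and stratified survey statistics — plus
a seeded generator that fabricates panels, reads and whole surveys with known
ground truth, so every stage is testable without touching GenBank or BOLD.

## Amplicon QC and NUMT screening

Nuclear copies of mitochondrial genes (NUMTs) co-amplify with true mtDNA and
would corrupt species assignment. Because COI is protein-coding and the
amplicon sits mid-gene, a genuine mitochondrial sequence must translate
without stop codons in some reading frame; NUMTs accumulate frameshifts and
premature stops, and vertebrate NUMTs are typically shorter than 600 bp.
`screen_numt()` therefore:

1. translates the read in all six frame/strand combinations under the
   vertebrate mitochondrial code (NCBI table 2: AGA/AGG are stops, TGA is
   Trp, ATA is Met — using the standard nuclear code here would miss
   AGA/AGG and mistranslate TGA);
2. selects the combination with the fewest internal stops, breaking ties
   deterministically (forward strand before reverse, frame 0 before 1
   before 2);
3. flags the read as a putative NUMT if the best combination still has an
   internal stop (`stops_in_all_frames`) or the read is shorter than 600 nt
   (`too_short`).

A stop codon counts as *internal* when it occurs before the final codon of
the translated frame; for a mid-gene amplicon any stop is anomalous, and the
terminal-codon exemption only matters for adversarial inputs. Codons
containing N translate to `X` and never count as stops, so Sanger ambiguity
cannot masquerade as a pseudogene signature; reads with more than 1%
ambiguous bases fail QC separately (`ambiguous_bases`), as do reads over
700 nt (`too_long`), neither with the NUMT flag. Lengths inside the hard
bounds [600, 700] but outside the expected amplicon window 636–655 nt pass
with a warning: the window is the range actually observed in the packaged
survey and is treated as an observation, not a filter.

Primer trimming is available but off by default: the assay's primer
sequences (the VF2_t1/FishR2_t1 cocktail) are not part of the packaged
survey's record, so primers are a configuration item with no hard-coded
default, and trimming is skipped when unset.

## Species assignment

The original survey assigned species with megablast against GenBank and
BOLD. This package substitutes optimal global (Needleman–Wunsch) alignment
against a curated, taxonomy-annotated local panel: all query/reference pairs
are near-full-length COI amplicons of similar length, for which end-to-end
alignment is the natural comparison, and a local panel removes network
dependence and database version drift. The aligner is implemented in C++
(linear gap penalty; default scores +1 match, −1 mismatch, −2 per gap
column). Near-identical sequences are insensitive to this choice, which the
test suite verifies by brute-force enumeration on small strings.

Percent identity is defined as 100 × matches / alignment columns, gap
columns included — the common pairwise convention; coverage is 100% by
construction for a global alignment, matching the survey's "100% coverage"
reporting. A column containing N counts in the denominator but never as a
match (conservative under ambiguity). Identities are reported rounded
half-up to two decimals, the precision of the survey tables. Among
co-optimal alignments the traceback prefers diagonal over vertical over
horizontal moves, so reported match counts are deterministic.

Assignment then follows the survey's decision rule: hits at or above
`min_identity_pct` (default 97; the survey observed 98.17–99.85 and states
no threshold) are ranked by identity with deterministic accession
tie-breaking, and the read is assigned only if every hit tied at the top
(tie tolerance 0 on the rounded identities, matching "identical percent
identity values") belongs to one species; otherwise it is `ambiguous`.
Products are sampled with up to three replicate DNA extractions precisely to
detect mixed-species products: unanimous replicates give one consensus call,
disagreeing assigned replicates give `multi_species`, and an ambiguous
replicate is recorded but does not overrule an otherwise unanimous species.

## Compliance calling

`call_compliance()` evaluates the identified species against the union of
two constraint sources: the printed declared scientific name(s) of the
product, and the taxa its menu label lawfully declares under the rule table.
Constraints carry an explicit rank: species-rank constraints require an
exact binomial match, genus-rank constraints match the genus component, and
family-rank constraints are resolved through the taxonomy table (an error
names any species the taxonomy cannot place). Satisfying any one constraint
makes the product compliant; an assigned species satisfying none makes it
misdescribed; a missing species call gives `unresolved`; and a product with
no derivable constraint at all gives `unlisted_name`.

Two details matter for reproducing the packaged survey:

- The printed declared-name column is authoritative where present. Table
  rows such as MIL3B ("sea bream" declared as *Sparus aurata/Dicentrarchus
  labrax*) show the survey's declared sets do not follow mechanically from
  the label, so label resolution alone would miscall them.
- Umbrella names are evaluated at genus rank: "tobiko"/"flying fish egg"
  declare the flying-fish genera *Hirundichthys* and *Cheilopogon* (so
  capelin roe, *Mallotus villosus*, is misdescribed while congeneric flying
  fish are compliant), "ikura"/"salmon eggs" declare *Oncorhynchus*, and
  "Anago" declares *Anguilla*. These names are footnoted in the source
  survey as absent from the decree list; they are carried with
  `listed = FALSE` and still evaluated.

Label lookup is normalization-invariant (case folding, accent
transliteration, whitespace collapsing), and compound labels — parts joined
by "or", "/" or parentheses, e.g. "maguro Yaki (red tuna)" — resolve to the
union of their resolvable parts.

Economic direction of a substitution (up- versus down-grading) is reported
only in the free-text rationale; the survey discusses it but defines no
computation.

## Survey statistics and the packaged fixture

`stratified_rates()` computes per-product misdescription rates over every
stratum of region × retail type × category, including `all` wildcards on
each axis, with unresolved products excluded from numerator and denominator
(the original survey likewise excluded its 17 failed extractions). Each
table row is one product; rates are per-product, not per-venue or
per-replicate. Raw rates are always kept alongside half-up integer-rounded
ones, the rounding used in the survey's prose (67, 11, 33).

The three fixture TSVs under `inst/extdata/` transcribe the survey's
tables — 19 + 20 + 21 products with menu label, declared and identified
species, percent identity, bracketed replicate counts (summing to 163
sequences) and bold misdescription marking — with md5 checksums verified at
load. Feeding the declared and identified columns through the compliance
engine reproduces the marking for all 60 products and the published rates:
Central overall 40% (8/20), Northern tuna 67% (4/6), Central and Southern
tuna 100%, overall tuna 87.5% (14/16, with exactly 2 compliant red-tuna
products), Northern white fish 11% (1/9), Northern roe 33% (1/3), Northern
takeaway 25% (2/8), Central restaurant 50% (5/10).

A handful of the survey's printed figures do **not** reconcile per-product
with its own tables; they are excluded from the package's acceptance checks
and recorded here with the reconciliation attempt:

| printed figure | per-product value from the tables |
|---|---|
| Northern overall 31.8% | 6/19 = 31.6% |
| Southern takeaway 50% | 2/6 = 33.3% |
| Southern restaurant 33.3% | 6/15 = 40.0% |
| Central roe 20% | 1/6 = 16.7% |
| "61 sushi samples ... 45 fish samples" | the tables hold 60 rows, 44 non-roe |
| "17 species expected, 29 found" | neither count is reconstructible; the 16 *identified* species are |

The Southern retail figures reconcile only partially under per-venue
counting and not at all per-product; the one-sample discrepancy (61 vs 60)
is surfaced, not resolved.

## The synthetic-data generator

`simulate_survey()` fabricates the whole input side of the pipeline with
known ground truth. Its defaults are the packaged survey's conditions: a
16-species panel of 650 nt amplicons (the survey identified 16 species from
~650-base amplicons), ≥10% interspecies divergence, three replicates per
product, 60 products, query reads at 98.5% identity to their generating
reference (the middle of the observed 98.17–99.85% band), a mislabel rate
of 0.35 (the survey's regional rates span roughly 32–40%), and no NUMT
reads (none was observed; decoys are opt-in via `numt_fraction`).

Design choices worth stating explicitly:

- **Stop-free construction.** Panel sequences are drawn codon-wise from the
  non-stop codon set of the vertebrate mitochondrial code and truncated to
  the exact requested length; a trailing partial codon cannot introduce a
  frame-0 stop, so any length ≥ 30 nt is supported and generated sequences
  pass `screen_numt()` by construction.
- **Substitution-only mutation.** `mutate_to_identity()` applies exactly
  `round(L × (1 − identity))` substitutions at distinct positions, with no
  indels, because accepted survey sequences showed no insertions, deletions
  or stops; indels live in the decoys. With `preserve_frame = TRUE` a
  substitution that would create an in-frame stop is resampled. Substituted
  bases are drawn uniformly from the three alternatives — no
  transition/transversion bias, which is irrelevant at the identity levels
  tested but is a stated realism limitation.
- **Calibrated mislabeling.** Exactly `round(n_products × mislabel_rate)`
  products are mislabeled (uniformly chosen; the marginal probability per
  product is still the rate), and a mislabel swaps the declared label to the
  species-rank trade name of a different species, so the intended verdict is
  unambiguous. Calibration makes parameter-recovery error measure pipeline
  error rather than binomial sampling noise; a Bernoulli draw at n = 200
  would alone contribute ~2.4 percentage points of mean absolute error.
- **Decoys.** `make_numt_decoy()` produces three failure modes:
  `stop_insert` writes stop codons into all six frame/strand combinations
  (reverse-strand stops are written as TTA, the reverse complement of TAA,
  at positions the target frame reads in-frame; write regions are spaced so
  they cannot clobber each other, and the post-condition is verified by
  six-frame translation), `frameshift` deletes one mid-sequence nucleotide
  and then guarantees the remaining frames stop, and `truncate` returns a
  fragment below the 600 nt heuristic (at most 550 nt and at most 85% of
  the reference).
- **Trade-name universe.** One species-rank name per species plus a
  configurable number of genus-rank umbrella names covering two species
  each, to exercise the genus-rank rule path.

What the generator does *not* emulate: phylogenetically realistic sequence
evolution, chromatogram/quality artifacts, PCR and sequencing error, or
heterogeneous amplicon lengths. Passing the simulation-based tests therefore
demonstrates correctness of the decision logic and the alignment arithmetic
under controlled divergence — not robustness to real Sanger noise.

## Numerical and degenerate-input conventions

- Rounding is half-up everywhere a value is displayed (identities to two
  decimals, percentages to integers); raw values are retained in every
  result table. Base R's round-half-to-even would turn 66.5 into 66.
- Coordinates are 0-based only in `frame_offset` (skipped leading bases);
  all string positions in code are 1-based R conventions.
- Empty hit lists, empty rule sets, empty fixtures and single-replicate
  products are all defined cases, tested explicitly, and never errors;
  genuinely unusable inputs (non-IUPAC characters, trimming below 50 nt,
  an accession missing from the taxonomy) fail fast with the offending
  identifier in the message.
- Determinism: every ranking and tie-break is total, so repeated runs are
  byte-identical; all stochastic code flows through a single integer seed.

## Problem sizes in the test suite

The packaged tests run the fixture end to end (60 products), verify the
aligner against brute-force enumeration on 1,000 random pairs of length
≤ 8, screen 8 synthetic panels' worth of clean and decoy reads, and measure
parameter recovery over 20 seeded surveys of 200 single-replicate products
against a 6-species panel — sizes chosen so the whole suite completes in a
few minutes on one core while still exercising every decision branch at
survey scale.

## Known limitations

- The compliance engine encodes only the trade-name subset needed for the
  packaged survey plus a documented extension format; it is not a full
  transcription of the decree's species list.
- Global alignment presumes near-full-length queries; heavily truncated
  queries would be better served by semi-global alignment, which is out of
  scope (such reads fail QC first).
- The identity threshold and tie tolerance are exposed but their defaults
  are conventions, not fitted values; surveys targeting taxa with
  barcode-sharing species (e.g. some *Thunnus*) may need stricter panels
  rather than stricter thresholds.
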