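---
title: "Models and methods behind mirduplex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mirduplex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirduplex)
```

mirduplex implements the computational machinery of a classic question in
plant small-RNA biology: how the *architecture* of a miRNA:target duplex —
in particular the single unpaired nucleotide ("bulge") found between
positions 7 and 8 of miR396 when it binds *GROWTH-REGULATING FACTOR* (GRF)
transcripts — modulates regulatory strength, and how sequence variation
within miRNA families redistributes that strength across targets.  This
vignette explains the models, the defaults and the design choices; the
README shows the worked example.

## The duplex alignment model

A plant miRNA recognizes its target by near-complete antiparallel base
pairing.  `align_duplex()` computes a *global* alignment of the full miRNA
(5'→3') against a candidate target window (read 3'→5') by dynamic
programming over three column types:

* a column consuming one base of each strand — a Watson–Crick pair, a G:U
  wobble, or a mismatch;
* a bulged miRNA base (consumes miRNA only);
* a bulged target base (consumes target only).

Bulge runs are capped at `max_bulge` (default 3 nt per side), matching the
short asymmetric loops seen in validated plant target sites, and the window
length may differ from the miRNA length by at most the same amount, which
bounds the search band.

Two objectives are supported over the *same* alignment space:

* **score** (default) — the empirical plant complementarity penalty:
  `mismatch` (1.0) per mismatched column, `wobble` (0.5) per G:U, and
  `bulge_per_nt` (1.0) per bulged nucleotide, all configurable through
  `scoring_params()`.  A window is a candidate target site when its optimal
  penalty is at most `max_score` (default 5), the conventional cap for
  plant target prediction ("5 mismatches and gaps", with G:U counted half).
  Whether a wobble should instead count fully is genuinely open; setting
  `wobble = 1` reproduces the stricter reading.
* **energy** — the nearest-neighbor free energy described below, minimized
  over the same moves.

**The 10–11 anchor.**  AGO-catalyzed cleavage cuts the target opposite
miRNA positions 10–11, so by default (`require_paired_10_11 = TRUE`)
alignments are rejected when position 10 or 11 is mismatched or bulged, or
when a bulge intervenes between them.  A window admitting no such alignment
yields a sentinel result with infinite score ("no site").  The constraint is
only meaningful for miRNAs of at least 11 nt and is skipped below that.

**Determinism and ties.**  Among equal-penalty alignments the package
prefers fewer gap columns, and then places gaps at their 5'-most equivalent
position.  The second rule is a rendering convention with real consequences
for degenerate sites: the GRF2 site carries two adjacent Cs around the
bulge, so "which C is bulged" is chemically meaningless, and the 5'-most
placement reproduces the conventional depiction of the miR396:GRF bulge
*between positions 7 and 8* rather than 8 and 9.

## The nearest-neighbor energy model

`duplex_delta_g()` evaluates an alignment with the additive Turner 2004
parameter set embedded in `energy_params()` (units: kcal/mol at 37 °C):

* one intermolecular initiation term (+4.10);
* a stacking term for each adjacent pair of paired columns (Watson–Crick
  and G:U stacks; the stack is retained across a single-nucleotide bulge,
  per the standard single-bulge rule);
* a length-dependent bulge or internal-loop initiation term for each
  maximal internal run of unpaired columns (tabulated to 30 nt,
  log-extrapolated beyond);
* a +0.50 penalty for each terminal AU or GU closing pair.

Unpaired bases outside the outermost pairs are free single-stranded ends.
Deliberately omitted: coaxial stacking, dangling ends, loop-asymmetry
(NINIO) terms and sequence-specific loop bonuses.  These refinements cancel
in the ΔΔG comparisons the package is built for — the same target window
bound by two miRNA variants — and leaving them out keeps the model exactly
additive and order-independent, which the test suite exploits (a perfect
helix evaluates to initiation + stacks + terminal penalties, checkable
against an independent implementation to the last digit).

Removing a 1-nt bulge next to a G–C pair is then a transparent sum: the
duplex gains the `GG/CC` stack (−3.30) and sheds the 1-nt bulge initiation
(+3.80).  This additivity — not any fitted constant — is what produces the
≈7 kcal/mol strengthening of the miR396:GRF2 interaction when the
monocot-specific insertion variant eliminates the bulge.

One caveat is recorded honestly rather than hidden: for the position-7
A→G substitution variant, the minimum-energy duplex relocates the bulge so
that the new G pairs the formerly bulged C (replacing an A–U pair with
G–C), and the additive model prices that rearrangement at ≈1.5 kcal/mol —
in the strengthening direction, but smaller than the >2 kcal/mol sometimes
quoted from folding programs whose parameterization differs.  The
corresponding acceptance test is intentionally left failing rather than
loosened.

## Target search, junctions and cleavage coordinates

`search_targets()` scans every window of length `|miRNA| ± 3` at every
offset of each spliced transcript and reports windows at or under the score
cap.  Overlapping reportable windows describe one biological site, so each
overlap chain is merged to its best-scoring window (ties: leftmost, then
shortest).  Transcript models built by `build_transcript()` or
`read_gff3_exons()` carry exon junctions as spliced coordinates; a site
*spans* a junction when a boundary falls strictly inside it — the situation
of the bHLH74 site, which only exists after the first two exons are
spliced together.  Searching a spliced sequence is by construction
identical to searching its concatenated exons; the junction only adds
bookkeeping.

The predicted cleavage coordinate is the spliced position of the target
base opposite miRNA position 10 in the cognate register: bulged target
bases 5' of it shift the coordinate by their length, bulged miRNA bases
(which consume no target sequence) do not.  Sites whose alignment does not
pair positions 10–11 contiguously have no cleavage coordinate and
`map_cleavage_site()` refuses them.

## The expression funnel

`filter_by_expression()` is a deterministic threshold rule, not a
hypothesis test: a candidate gene passes when its linear-scale
mutant/wild-type fold change is at least `min_fold` (default 1.30, the
closed reading of "at least 30% up-regulated") in *every* required genotype
(default `hyl1`, `se`, `dcl1`, the three miRNA-biogenesis mutants;
`mode = "any"` relaxes to at least one).  Whether the historical filter
was applied per mutant or to a summary is not documented; the concordant
(`all`) reading is the default because it is the stricter and the one a
three-way intersection diagram implies.  Genes with sites missing from the
matrix are reported with `NA`, never dropped, and no multiple-testing
correction is applied — there is no test statistic to correct.

## Family variation profiles

`variation_profile()` implements the equal-contribution variation
statistic: for each family, members are 5'-anchored, the per-position
consensus is the majority base (ties broken A < C < G < U; positions where
fewer than half the members have a base are trimmed from the reported
consensus), and the deviation count `d_p` is the number of members whose
base at `p` differs — a base missing through length differences counts as
a deviation.  Normalizing by family size (`v_p = d_p / n`) caps each
family's contribution at 1 per position, so no large family dominates the
summary `V_p = Σ_f v_p,f`.  Families can be pooled before computation with
`merge_families()` (e.g. miR159 with miR319, which are conventionally
treated as one family); pooling recomputes the consensus on the merged
membership rather than averaging profiles.

Two documented ambiguities are resolved as flags:

* `count = "position"` (default) charges a member at every deviating
  position; `count = "sequence"` charges it once, at its 5'-most deviation.
* `gapped = FALSE` (default) compares strictly by position, so a length
  variant (the monocot 7-8insG insertion) shifts every downstream position;
  `gapped = TRUE` re-aligns length-discordant members to the consensus with
  a single-gap allowance, choosing the placement with the fewest deviation
  events (ties 5'-most), which charges the insertion once, at position 8.

`consensus_shared_positions()` applies the same single-gap logic between
two family consensuses; it is how the package expresses the classic
observation that the six Arabidopsis miR159/miR319 sequences, offset by one
base at their 5' ends, share 17 of 21 positions.

## Variant abundance in sequencing libraries

`count_variant_reads()` assigns a read to a variant when the 5' ends
coincide, the overlapping prefix is identical, and the 3' length difference
is at most `trim_tol` (default 2 nt).  The asymmetry mirrors miRNA biology:
the 5' region defines targeting and is precisely processed, while 3' ends
are ragged in real libraries.  Reads consistent with several variants are
split fractionally by default (`ambiguous = "strict"` discards them), and
unmatched reads are counted and reported, never silently assigned, so
per-library counts can only under- not over-run the read total.  Variant
panels that are mutually indistinguishable under the rule (prefix-identical
with lengths within the tolerance) are rejected before counting.
`relative_abundance()` normalizes within one library; an empty library
yields zero abundances with a warning rather than NaN.

## What the synthetic data emulate — and what they do not

The generators exist so that every stage is testable without downloads,
with ground truth recorded alongside:

* `gen_transcriptome()` plants target sites of controlled architecture
  (mismatch/wobble counts, bulge side and length, optional exon junction,
  decoys placed one penalty unit above the cap to stress the threshold)
  into uniform-composition random background.  Planted mutations are kept
  away from the ends, the 10–11 anchor and the bulge, and spaced at least
  two apart; because random draws can still interact through register
  shifts, each planted site is verified against a scan of its
  neighbourhood and redrawn until the intended record is exactly what the
  scan reports.  Transcript lengths in the test suite are 120–300 nt with
  up to ~20 transcripts per experiment — sizes chosen so a full scan stays
  a sub-second desk computation while still exercising merging, junctions
  and decoys.
* `gen_expression()` draws one true fold per target gene uniformly from
  `fold_range` (default 1.3–2.0) and multiplies per-genotype lognormal
  noise (`noise_sd`, default 0.05); non-targets are pure noise around 1.
  A consequence worth stating plainly: with the default range touching the
  1.30 threshold, a true target drawn near the boundary fails a genotype
  with appreciable probability, so exact recovery of all true targets
  holds in roughly four of five replicates, not almost surely; it becomes
  exact as `noise_sd → 0` or when folds clear the threshold.
* `gen_library()` draws read identities multinomially and perturbs 3' ends
  by a length-offset profile (default 80% exact, 20% within ±2 nt).

All seeds are explicit arguments and the generators restore the session
RNG, so identical seeds give byte-identical outputs.  None of this imitates
real data's hard parts: transcriptome-scale composition, expression
correlation structure, sequencing error inside reads, or adapter artifacts.
Passing recovery tests therefore demonstrates that the *algorithms* invert
the generative model they were given, not that the model captures every
property of a real library or microarray.

## Numerical and degenerate-input choices

* Penalty ties are resolved on exact floating-point equality; the default
  weights (multiples of 0.5) make this well defined.
* Energy minimization breaks ties by fixed scan order; equal-energy
  structures (e.g. which of two identical adjacent bases is "the" bulge)
  are reported deterministically.
* DNA input is accepted anywhere RNA is expected and normalized T→U;
  anything outside ACGU after normalization is an error, not a warning.
* Empty FASTA files are valid (empty results); empty sequences, duplicate
  ids, mixed-strand transcripts and out-of-bounds exons are errors that
  name the offender.
* Single-member families return their member as consensus with a warning —
  the statistic is undefined rather than zero.

## Known limitations

* The energy model is a duplex model: target-site accessibility and
  competing secondary structure are out of scope, as is any model of
  translational repression.
* Printed interaction energies in the literature come from heterogeneous
  programs; absolute ΔG values here are comparable only within the
  package's own parameter set, which is why all headline quantities are
  energy *differences*.
* The family statistic anchors at the 5' end; 3'-end length variation
  inflates terminal positions unless `gapped = TRUE` is used.
* The target scan is exhaustive over windows and intended for
  transcript-scale inputs (the compiled kernel scans roughly a
  thousand-nucleotide transcript per second per miRNA); genome-scale
  seeding/indexing is deliberately not provided.
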