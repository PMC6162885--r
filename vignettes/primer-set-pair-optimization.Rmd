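---
title: "Multi-objective optimization of 16S primer-set-pairs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-objective optimization of 16S primer-set-pairs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primeropt)
```

## The optimization problem

A *primer-set-pair* is a non-empty set of forward plus a non-empty set of
reverse non-degenerate primers used together in one PCR. Any degenerate
primer pair expands into one (`expand_pair()`), but the converse does not
hold: freeing the sets from the degeneracy constraint gives the search
direct control over which oligonucleotides are actually synthesized, which
matters both for amplification efficiency (every degenerate position
multiplies mismatching variants into the mix) and for batch-to-batch
reproducibility of the mixture.

Candidate set-pairs are scored on three objectives against a reference set
of 16S sequences:

* efficiency `E` (maximize, 0–10),
* coverage `C` (maximize, fraction of sequences covered),
* matching-bias `M` (minimize, coefficient of variation of per-sequence
  combination counts).

Set-pair `p` dominates `p'` iff the objective vectors differ,
`E(p) ≥ E(p')`, `C(p) ≥ C(p')` and `M(p) ≤ M(p')`. The package
approximates the Pareto front of this tri-objective problem.

## Efficiency: ten fuzzy terms

Hard constraints are impractical — most published 16S primers violate at
least one design rule — so each rule is encoded as a fuzzy score in
`[0, 1]`: 1 when satisfied with margin, 0 when clearly violated, linear in
between. Seven single-primer terms are averaged over all primers of the
set-pair; three more score the set-pair as a whole. The total is the sum of
the ten terms. Defaults (all exposed in `po_config()`, units in
parentheses):

| term | rule | ramp |
|---|---|---|
| `tm` | melting temperature (°C) | 0 at ≤50, 1 at ≥52 |
| `gc` | GC fraction | 1 on [0.5, 0.7]; 0 above 0.7 or below 0.4; linear on [0.4, 0.5) |
| `end3_at` | last 3 bases not all A/T | binary |
| `end3_gc` | at most 3 G/C in last 5 bases | binary |
| `homopolymer` | longest run (nt) | 1 at ≤4, 0.5 at 5, 0 at ≥6 |
| `self_dimer` | max gap-free matches vs own reverse complement | 1 at ≤8, 0 at ≥11 |
| `hairpin` | 3′-terminal 5-mer folding back onto the primer | binary |
| `tm_range` | ΔT_m across all primers (°C) | 1 at ≤3, 0 at ≥5 |
| `cross_dimer` | max matches over forward × reverse pairs | 1 at ≤8, 0 at ≥11 |
| `amplicon_range` | median − 1st percentile of amplicon lengths (nt) | 1 at ≤50, 0 at ≥100 |

Two conventions deserve comment. The GC ramp on the low side is
implemented as `(f_GC − 0.4)/0.1`, the continuous monotone interpolation
that is 0 at 0.4 and 1 at the 0.5 plateau edge; the alternative descending
form would contradict the plateau and introduce a discontinuity. And a
set-pair that produces *no* amplicon on the reference set scores 0 on
`amplicon_range`: a pair that amplifies nothing cannot be maximally
efficient, and its coverage is 0 as well.

Dimer and hairpin screens are pure match-counting (`max_gapfree_matches()`
over every offset with at least one overlapping position, no
end-anchoring), not free-energy models: this matches how the score
thresholds (8 and 11 matches) are defined. A useful structural fact:
against its own reverse complement a primer can only realize an *even*
number of matches (matching positions pair up symmetrically, and no base
is its own complement), so the interior of the 8/11 self-dimer ramp is
reachable only at 10 — the odd values arise for cross-dimers between
distinct primers.

The hairpin screen folds the reverse complement of the 3′-terminal
`hairpin_seed` (5) bases back onto the primer at every full-window offset
that does not overlap the fragment's own source positions (a palindromic
3′ end aligned onto itself is physically meaningless); it fires when the
terminal base pairs and at least 3 of the 4 preceding bases pair.

### Melting temperature

No installed R package provides an oligonucleotide T_m, so the package
implements the standard two-state nearest-neighbour model: unified
SantaLucia-1998 enthalpy/entropy sums with terminal initiation terms, the
entropic salt correction `0.368 (n−1) ln[Na+]`, and
`T_m = ΔH / (ΔS + R ln x) − 273.15` with `x = C_T/4` (for
self-complementary oligos, `x = C_T/2` plus the −1.4 cal/(mol K) symmetry
term). Defaults: 50 mM monovalent cation, 500 nM total oligonucleotide.
The implementation was cross-checked against an independent one
(Biopython's `Tm_NN` under identical parameters); the test suite freezes
those oracle values and requires agreement within 1.5 °C (observed
agreement is within 0.02 °C, the residual coming from the gas-constant
rounding).

T_m enters two terms (`tm` and `tm_range`), which makes the efficiency
total sensitive to the parameter table and reaction conditions. This is
not hypothetical: for the three published V3–V7 set-pairs bundled in
`inst/extdata/setpairs_v3v7.tsv`, every efficiency term that does not
depend on a reference collection sits at its ceiling *except* the
melting-temperature range — ΔT_m is 3.6–5.3 °C under the SantaLucia-1998
defaults, and remains above 3 °C under the Breslauer-1986,
Sugimoto-1996 and SantaLucia-2004 tables across a broad range of salt and
concentration conditions. Published efficiency totals for these pairs at
or near 10 therefore imply a T_m parameterization that compresses the
spread below 3 °C; with standard published thermodynamics the
desk-computable upper bound on their totals (nine refset-independent terms
plus one) is 9.62, 9.00 and 9.49. The corresponding acceptance check
asserts the published row as printed and is expected to fail until a
parameter set reproducing it is identified; `scripts/acceptance.R` reports
the computed bounds.

## Coverage and matching-bias

A primer matches a sequence where its 3′-terminal 5-nt *seed* pairs
exactly and the 5′ remainder carries at most 2 mismatches — the polymerase
extends only from a clamped 3′ end, while 5′ mismatches are tolerated.
Reverse primers are matched against the reverse complement of the
sequence, with sites reported in 1-based inclusive sense-strand
coordinates. Reference letters outside A/C/G/T (ambiguity codes, N runs)
count as mismatches everywhere, including the seed: coverage is never
claimed through ambiguity.

For every (forward, reverse, sequence) triple the amplicon is the span
from the forward site start to the reverse site end, over pairings where
the reverse site starts strictly downstream of the forward site end. When
a primer binds multiply, the *shortest* valid product is taken — PCR
kinetics favour the shortest template, and this choice is deterministic.
The *target amplicon length* is the nearest-rank median of all such
lengths; a sequence is *covered* when at least one combination yields an
amplicon within ±100 nt (`length_tolerance`) of the target. All order
statistics are nearest-rank (`ceil(q·n)`-th order statistic; median of an
even-sized sample is the mean of the two central order statistics), so
scoring is exactly reproducible across platforms.

Matching-bias is the population coefficient of variation of the
per-sequence combination counts, computed **over covered sequences only**:
uncovered sequences are already penalized by `C`, and including their
zeros would double-count the same defect in two objectives. The ±100 nt
filter is applied to the counts entering the statistic, for consistency
with the coverage definition. When nothing is covered, `M` is reported as
a configured large sentinel (`bias_sentinel`, 10^6) rather than NaN, which
keeps Pareto dominance well-defined and makes such solutions dominated by
anything that amplifies at all.

## The search

`multi_objective_search()` follows the iterated scalarized local-search
template: keep an archive of every solution evaluated; at each of
`restarts` restarts, compute the Pareto front of the archive, sample one
front member uniformly, sample weights `α = (α_E, α_C, α_M)` uniformly
from the unit simplex (exponential-spacings construction), maximize the
scalarization `α_E·E/10 + α_C·C + α_M·max(0, 1 − M)` by local search, and
archive the resulting local optimum.

Normalization: `E/10` and `C` have natural fixed maxima; `M` (a CV) is
unbounded, so it is remapped by `max(0, 1 − M)`. Fixed normalizers keep
the scalarized landscape stationary across restarts; the alternative —
normalizing by the current archive maximum — would make earlier and later
restarts optimize different functions and break reproducibility of
individual local searches.

Local search is best-improvement: for the addressed primer the *entire*
single-edit neighbourhood (3 substitutions per position, 4 bases prepended
or appended, removal of either terminal base, within the
`[move_len_min, move_len_max]` = [15, 25] bounds) is evaluated and the
best strictly-improving neighbour is accepted, repeatedly, until that
primer admits no improvement; the outer loop cycles over all primers until
a full pass is quiescent. Ties among equally-best neighbours resolve to
the first in a fixed enumeration order (positions ascending, bases
A/C/G/T, substitutions before additions before removals), making every
run fully deterministic given the seed. The stricter 17–21 nt bound is a
*candidate-selection* filter only; the search itself may leave that box,
which is how published set-pairs containing 16-mers arise from 17–21 nt
seeds.

Initial solutions come from `select_initial()`: candidates (possibly
degenerate, probeBase-style TSV) are kept when the expected amplicon
length (metadata if present, otherwise the computed median on the
reference set) lies in the requested range, every expanded primer is
17–21 nt, and the annotated target domain is Bacteria or Universal —
unannotated candidates are kept, since user lists often lack domain tags
and exclusion should be opt-in.

Multiple independent `runs` execute sequentially with per-run seeds
derived from the base seed; archives are merged before the final front, so
a parallel implementation would have to reproduce the sequential result
exactly. Heterogeneity between runs is quantified by the mean pairwise
Jaccard index of the run fronts (`run_heterogeneity()`), with solutions
identified by their primer sets.

## The synthetic study

`generate_synthetic_refset()` emulates the 16S layout that matters to this
method: conserved primer-binding blocks flanking variable regions. Each
sequence is uniform-random background (the "variable region" null) with a
forward site and a reverse-complemented reverse site planted at fixed
positions; each site is present with a carrier fraction and, when present,
mutated per-base at a configurable rate, with every mutation recorded.
Defaults are the study conditions used throughout the tests and the
acceptance script: 50 sequences of 1500 nt, sites at positions 340 and
1041 (a ~719 nt product, matching the V3–V6 span of the canonical 16S
coordinate system), carrier fractions 1.0, and a 5 % per-base site
mutation rate — the order of within-conserved-block variation that makes
the 2-mismatch tolerance decisive without washing out the planted signal.

Because every mutation is recorded, the expected coverage is known
*exactly* (a sequence is covered iff both sites are present, their seeds
intact, and each carries at most 2 non-seed mutations), and the tests
require exact agreement between generator ground truth and the matching
engine — not statistical closeness — at both zero and positive mutation
rates. What the generator does **not** emulate: phylogenetic correlation
between sequences, compositional bias, length variation, chimeras, and
secondary binding sites in real 16S backgrounds. Passing recovery tests
therefore demonstrate the correctness of the scoring and search machinery
under known truth, not field performance of any particular primer set on
real databases — benchmark coverage/bias values on curated external
collections additionally depend on the exact database version and on
taxonomy filtering steps that are outside this package's scope.

## Degenerate inputs, errors, determinism

The full 15-code IUPAC alphabet is accepted in degenerate inputs and in
reference sequences (published primer collections use codes beyond the
common R/Y/H). Parsers reject rather than coerce: duplicate FASTA ids,
empty files, non-IUPAC characters (named by record and position),
malformed candidate fields (named by row) are all errors classed as user
errors — the command-line tool maps them to exit code 1, internal errors
to 2. Every stochastic component (weight sampling, front sampling,
generator) is governed by explicit integer seeds; identical inputs, seeds
and configuration produce byte-identical archives, which the test suite
asserts.

## Problem sizes used in validation

The test suite and acceptance script run entirely on generated data:
matching is cross-validated against a naive sliding-window oracle on 10^4
random primer/sequence instances; Pareto-front maintenance against an
all-pairs oracle on 1000 random archives of up to 200 entries; search
guarantees (verified local optimality, monotone scalarized score,
byte-determinism, planted-optimum recovery within three edits) on
reference sets of 8–60 sequences and on the 50 × 1500 nt default study
conditions, with restart budgets of 2–10. These sizes were chosen so the
whole validation cycle stays interactive while each property is exercised
at a scale where violations would be visible.
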