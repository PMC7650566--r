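---
title: "DNA-based traceability of canned tuna: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DNA-based traceability of canned tuna: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cantrace)
```

## The problem

Canning transforms tuna through a chain of processing levels — frozen (L1),
defrosted (L2), cooked (L3), canned in oil (L4O) or brine (L4B) — that
progressively degrade and fragment DNA. Morphological species identification
is impossible after filleting, so traceability of the four tropical tunas
that dominate the canned market (yellowfin *Thunnus albacares*, bigeye
*T. obesus*, skipjack *Katsuwonus pelamis*, longtail *T. tonggol*) rests on
DNA barcoding: a short mitochondrial cytochrome b region is amplified,
sequenced, and assigned to a species by percent identity against a reference
panel. `cantrace` implements that analysis end to end, together with a
simulator that emulates the degradation process, so that the behaviour of
the identification rule under increasing damage can be studied on data with
known truth.

The package quantifies two distinct phenomena:

* **fragmentation** — at later levels the full 236-bp barcode (`AB`) no
  longer amplifies and only mini-barcodes survive (`A`, 117 bp, or `B`,
  109 bp), shrinking the information available; and
* **nucleotide substitution (NS)** — the sequence obtained from a processed
  specimen differs from the frozen baseline of the *same individual*,
  which erodes the diagnostic positions that discriminate the species.

## Data model

All coordinates live in a fixed 236-column cytochrome b alignment anchored
to the *T. thynnus* mitogenome (NC_004901, positions 14665–14901). The
central container is the S4 class `ReferencePanel`: a
`Biostrings::DNAStringSet` of equal-width aligned sequences, one species
label (and optional FAO-area label) per record, and a named `IRanges` of
fragment coordinates. The published fragment lengths (AB 236, A 117, B 109)
do not pin down where A and B sit inside AB (117 + 109 < 236); this package
adopts A = columns 1–117 and B = columns 128–236, leaving a 10-column
inter-primer region, and makes both configurable through
`defaultFragments()`. Coordinates are 1-based and inclusive throughout.

Gap characters are tolerated in a panel, but any column containing a gap or
an `N` in a sequence involved in a comparison is excluded from that
comparison: ambiguity never counts as a match, a mismatch, or support for a
diagnosis.

## Core statistics

**p-distance.** `pDistance()` is the proportion of differing bases over
comparable columns (both bases in A/C/G/T), i.e. pairwise deletion of
ambiguous sites. No model correction is applied — the identification rule
and the barcode-gap analysis are both defined on raw p-distance.

**Barcode gap.** `barcodeGapSummary()` partitions all pairwise distances
into intra- and inter-specific sets using the known species labels and
reports a gap when `min(inter) > max(intra)` and
`min(inter) − max(intra) > (X − 1) · max(intra)` with relative gap width
`X = 1.5`. This is a deliberate single-pass simplification of the recursive
ABGD procedure: the labels are known and the question is confirmatory (does
a gap exist that licenses threshold identification?), not de novo species
delimitation.

**Diagnostic positions.** A column is diagnostic for a focal species when
the focal species is fixed for one base, every contrasted species is fixed,
and the focal base differs from all contrasted bases
(`diagnosticPositions()`). Both a one-vs-all mode and a pairwise mode are
exposed, since "diagnostic" is used in both senses in the barcoding
literature. Columns are returned in ascending coordinate order.

**NS statistic.** For a specimen sequenced at level `k` with fragment `f`,
`countSubstitutions()` counts the comparable columns of `f` at which the
sequence differs from the same individual's L1 sequence, and
`nsPercent()` reports `100 · nNS / length(f)` to 2 decimals. The
denominator is the length of the fragment actually obtained at that level:
the printed group means of the study are reproduced exactly by `k/109` and
`k/117` arithmetic (e.g. 7/109 = 6.42%), which is how that inference was
made; a full-alignment denominator can be supplied instead. Group averages
(`groupMeanNS()`) are unweighted arithmetic means of the *unrounded*
per-specimen percentages, displayed to 2 decimals.

**Identification.** `identifySpecies()` computes percent identity
(`100 · matches / comparable columns`, the exact complement of p-distance on
fully comparable columns) of the query fragment against the matching
fragment slice of every panel record. The best identity decides the status:
`ASSIGNED` to the unique best species at ≥ 98% identity; `TIE` when several
species attain the same best identity at the reported 2-decimal precision
(matching how multi-species rows are printed with a single similarity
value); `AMBIGUOUS` below 98%; `FAILED` when nothing amplified.
`classifyOutcome()` compares the genetic result with the morphological
label. In the default strict mode any multi-species tie counts as
`MISIDENTIFIED` — that is the bookkeeping of the published
misidentification table, which lists ties among the misidentified samples
even when the set contains the true species; a lenient mode that credits
such ties as concordant is available. `AMBIGUOUS` records are excluded from
the concordant numerator but kept in the denominator, which is what makes
the "34 of 64" style of accounting add up.

**Rounding.** All displayed percentages use 2 decimals with halves rounded
away from zero. The published figures are not perfectly self-consistent at
that precision (86/90 = 95.556 is printed as 95.55%), so counts, not
percentages, are treated as ground truth wherever the two disagree.

## The degradation simulator

The simulator is first-class, tested code, not a test fixture. It emulates
the study conditions in three layers.

**Panel synthesis** (`synthesizePanel()`). A random background sequence is
drawn and each species receives a disjoint set of *private columns* carrying
a base that differs from the background — at least 7 of them inside fragment
B, the published count of diagnostic positions there. Private columns are
diagnostic by construction. The number of private columns per species `m`
is sized so that consensus-to-consensus distances `2m/236` sit at the middle
of the target inter-specific range (0.09–0.14), and per-record intra-specific
noise (at non-private columns only, so diagnostics stay fixed) is budgeted
so intra-specific distances stay inside 0–0.05. Realized distances are
verified post hoc and the panel is regenerated under a bounded retry count;
an unreachable specification raises a feasibility error. The defaults
reproduce the distance structure reported for the real 372-sequence
reference dataset: a clear barcode gap between intra (0–0.05) and inter
(0.09–0.14) p-distances.

**Study design** (`studyDesign()`, `buildDesign()`). The default layout is
the study's: yellowfin and skipjack from four FAO areas, bigeye from two,
longtail from one, three individuals per species × area cell, each tracked
through the five levels — 33 individuals, 165 specimen records.

**Degradation** (`degradationParams()`, `applyDegradation()`,
`simulateStudy()`). Each individual receives an L1 haplotype (a panel
sequence of its species plus 0–2 intra-specific mutations at non-diagnostic
columns, kept small so the baseline is unambiguously identifiable). At each
level the number of new substitutions is Poisson with a level-specific mean
λ, applied within the columns of the fragment amplified at that level; a
fraction `w` of the substitution mass (default 0.7) is directed at
diagnostic columns, the rest uniformly at other columns, and each hit base
is replaced by one of its three alternatives uniformly. Mass aimed at an
exhausted pool is dropped, never redirected, so `w = 1` guarantees purely
diagnostic damage. Degradation is cumulative along levels — the same
individuals were followed through the chain, so a specimen's L3 sequence
builds on its L2 state — with an option for independent-per-level damage.
The λ defaults (0, 0.3, 1.5, 2.5, 5 for L1…L4B) were chosen once so that
group-mean NS% is ordered L1 = 0 < L2 < L3 < L4O < L4B with magnitudes in
the few-percent range reported for canned levels; they parameterize a
phenomenological substitution process, not damage chemistry. Fragment
availability is drawn per record from a per-level categorical table whose
default reproduces the observed pattern (AB through L1–L2; AB or A with
rare failure at L3; B, rarely A, at L4O; B, rarely failure, at L4B),
independent of the substitution count — the study reports fragmentation and
substitution separately, and nothing in a count table identifies a coupling.
Seeds are explicit arguments; the caller's RNG state is saved and restored.

What the simulator does *not* model: deamination spectra, strand breaks or
any damage chemistry (only substitution counts and amplifiability),
chromatogram noise, and the distinction between true in-vitro base
modification and sequencing artifacts on degraded templates — the NS
statistic itself cannot distinguish these on real data either. Passing
end-to-end tests on simulated data therefore show that the *pipeline logic*
behaves correctly under the planted degradation model, not that real canned
specimens will show these exact rates.

A note on misidentification in the simulator: with substituted bases drawn
uniformly from the three alternatives, heavy damage to diagnostic columns
usually drives the best identity *below* the 98% threshold (an `AMBIGUOUS`
outcome) rather than converging on a wrong species at ≥ 98%. Real canned
specimens often matched a wrong species at high identity, which suggests
damage that is convergent toward other haplotypes; the simulator does not
bias substitutions toward other species' bases. End-to-end checks therefore
measure *loss of traceability* — the non-concordant fraction, misidentified
plus ambiguous — which is the quantity the processing chain degrades.

## The Poisson mixed model

Substitution counts are modelled as
`nNS ~ Level * Species + (1 | Individual/Species)` with a log link,
fitted by maximum likelihood under the Laplace approximation
(`fitPoissonGLMM()`, delegating the optimization to `lme4::glmer`). Two
modelling notes:

* The nested random term is implemented literally, expanding to intercepts
  for `individual` and `individual:species`. Because every individual
  belongs to exactly one species the two terms are confounded and only
  their sum is identifiable; both estimated components are reported, and a
  `species/individual` alternative plus a single-intercept form are
  exposed.
* L1 records (nNS = 0 by construction) stay in the model: the
  interaction-vs-additive likelihood-ratio test needs all five level
  categories to have its (5−1)(4−1) = 12 degrees of freedom. Treatment
  coding uses L1 and the alphabetically first species as references.

`likelihoodRatioTest()` computes `2Δlogℓ` with df equal to the parameter
count difference (identical models are allowed and return statistic 0,
p = 1; a negative df is a nesting error). `overdispersion()` is the ratio
of the Pearson residual sum of squares to `n − p` (fixed effects plus
variance components), with an upper-tail chi-square p-value — the standard
GLMM overdispersion point estimate. The study's own χ²(12) = 60.549 is not
reproducible without its unreleased sequence data; the package targets the
structural df and calibrates the machinery by simulation instead.

`fitPoissonGLMM()` exposes `nAGQ`: 1 (default) is the Laplace fit; 0 uses
lme4's penalized-IRLS approximation, which is an order of magnitude faster
and is what the package's large repeated-simulation studies use.

## Numerical and testing choices

* Degenerate inputs: an all-constant response cannot be fitted by `glmer`;
  the fit falls back to the fixed-effects-only model with the convergence
  flag honestly set to `FALSE`. Singular designs are reported through the
  flag, not by crashing.
* Identity ties are resolved at the displayed 2-decimal precision.
* `p_distance` with no comparable columns is an error, not 0 — silence here
  would fabricate certainty from pure ambiguity.
* Problem sizes in the test suite: parameter recovery runs 200 replicates
  at 500 individuals (nAGQ = 0); the zero-variance oracle check compares
  boundary Laplace fits against plain Poisson regression; LRT power and
  overdispersion calibration use 15–25 replicates at 200–300 individuals;
  end-to-end traceability contrasts use 100 replicates of the full
  33-individual design. These sizes are the package's choice of a
  simulation budget that keeps each property sharply resolved.

## Limitations

* The reference panel is consumed pre-aligned; multiple alignment and live
  GenBank/BLAST queries are out of scope (identification is in-panel).
* The single-pass gap criterion is confirmatory; it does not perform
  recursive ABGD partition refinement.
* The simulator's substitution process is phenomenological; its defaults
  encode the *ordering and rough magnitude* of NS accumulation across
  levels, not mechanistic damage rates.
* With one species per individual the nested random-effect variance
  decomposition is arbitrary; only the total is interpretable.
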