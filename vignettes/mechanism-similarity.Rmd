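---
title: "Measuring similarity of enzyme reactions and catalytic mechanisms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring similarity of enzyme reactions and catalytic mechanisms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechsim)
```

## The model

`mechsim` treats an enzyme reaction at two resolutions, both built from the
same primitive: the **bond change**, an elementary chemical event identified
by a kind — bond formed (`f`), cleaved (`c`), increased (`i`) or decreased
(`d`) in order — and an unordered pair of element symbols. Atom types are
deliberately not differentiated beyond the element: an aromatic and an
aliphatic carbon are the same `C`, so a `c:C-Cl` in two different scaffolds
is the same event. Bond-change collections are *sets*: a repeated identical
change within one step or one overall reaction is counted once (duplicates
are merged at construction with a warning), which is the semantics under
which the Tanimoto coefficient below is defined.

**Overall similarity.** The net transformation from substrates to products
is a set of bond changes $A$; two overall reactions are compared with the
Tanimoto coefficient $T_c = |A \cap B| / |A \cup B|$.

**Mechanistic similarity.** A catalytic mechanism is an ordered sequence of
steps, each with its own bond-change set. All pairwise step Tanimoto
coefficients form an $n_1 \times n_2$ similarity matrix; Needleman–Wunsch
dynamic programming with *unpenalised* gaps finds the maximum-match pathway,

$$H(i,j) = \max\{H(i-1,j-1) + M(i,j),\; H(i-1,j),\; H(i,j-1)\},$$

and the alignment score $S = H(n_1, n_2)$ is converted into a Tanimoto-style
similarity $S / (n_1 + n_2 - S)$. Gaps are free because there is no credible
model for how insertion or deletion of mechanistic steps should be priced;
a mechanism embellished with extra steps pays only through the denominator.

**Reversibility.** Catalysis is microscopically reversible: the enzyme
stabilises the same transition states in both directions, and curated
databases store reactions in whatever direction the source literature used.
Every comparison is therefore run forward and with the second entry
inverted — bond changes swapped ($f \leftrightarrow c$,
$i \leftrightarrow d$) and, for mechanisms, step order reversed — and the
larger score is reported. The overall and mechanistic directions are
searched independently and both winners recorded, so direction agreement
between the two levels can itself be studied.

**Circular permutation.** Some mechanisms begin or end with proton
transfers that could equally well sit at the other end of the sequence
without changing the catalytic outcome. Because deciding that requires
chemical judgement, rotation is *curated input metadata*: each entry carries
a `permutation_allowed` flag and `compare_pair(rotations =)` selects the
policy — `"whitelist"` (default: rotate only flagged entries), `"none"`, or
`"all"` (exhaustive, for exploration). Enabling rotations maximises over a
superset of configurations and therefore can never lower a score (a tested
invariant).

**Normalization.** Two sets of sizes 3 and 5 can reach a Tanimoto
coefficient of at most $3/(3+5-3) = 0.6$; two mechanisms of $n_1$ and $n_2$
steps at most $m/(n_1+n_2-m)$ with $m = \min(n_1, n_2)$. Dividing a raw
score by this bound yields a normalized score that is 1 exactly when the
smaller set (or shorter mechanism) is perfectly contained in the larger,
separating "different chemistry" from "same chemistry, different
bookkeeping granularity".

## Preprocessing rules

* **Spontaneous steps** (non-enzymatic formation of the substrate or the
  final product) are removed before comparison, and the overall reaction is
  re-annotated by subtracting the union of their bond changes. A change
  occurring in both a spontaneous and a catalysed step is still subtracted —
  the conservative reading — and flagged in the log. An entry whose steps
  are all spontaneous has no mechanism to compare and is an error.
* **Stereochemistry records** ("bonds involved") are dropped on input with a
  warning: a stereochemistry change is always the net result of elementary
  changes, and curated inputs are expected to already contain the
  replacements. The replacement itself is chemical curation and out of scope
  here.
* **Change-free reactions** (empty overall set) are flagged at parse time;
  the similarity of two empty sets is an *error*, not 1, matching the
  practice of excluding change-free reactions from background statistics.

## Significance machinery

Dataset pairs (functional analogs: same EC sub-subclass, no shared
structural superfamily) are the positive class; all pairs of a
**non-redundant background** — assembled by iterative random selection,
each pick removing everything sharing its sub-subclass or any superfamily —
are the negative class. Any similarity left in the background comes only
from the limited repertoire of bond types in catalysis. At every candidate
cutoff (the union of observed scores; Tanimoto values are rationals with
small denominators, so observed scores are the only places the confusion
matrix can change) the package computes tp/fp/tn/fn with the "equal or
higher is positive" convention, precision, recall, F-measure, Matthews
correlation, enrichment (TPR/FPR), and ROC points; AUC uses the trapezium
rule. Two cutoffs matter:

* the **F-optimal cutoff**, maximising the F-measure (ties broken toward
  the lowest cutoff, i.e. maximal recall at equal F) — pairs at or above it
  are *highly similar*;
* the **5% significance cutoff**, the smallest observed score that fewer
  than 5% of background pairs reach — pairs between the two cutoffs are
  *distantly similar*.

The repeated-random-selection helper quantifies how many repetitions a
randomised minimisation needs: $x \approx -\ln(p)/f$, e.g. 461 repetitions
for a 1% miss probability when 1% of selection orders are optimal; the
minimum-domain-combination estimate uses 500 by default.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `rotations` | `"whitelist"` | circular-permutation policy per entry |
| `alpha` | 0.05 | empirical significance level |
| `mismatch_offset` (local alignment) | 0.5 | step-pair Tc below which a local block terminates |
| `gap_penalty` (local alignment) | 0 | consistent with free gaps globally |
| report precision | 4 decimals | printed scores; full precision kept internally |

The local-alignment parameterisation is genuinely open — no published
values exist — so identical-step detection does **not** depend on it:
`find_identical_steps()` enumerates all step pairs with $T_c = 1$ directly,
forward and reversed, and `compare_pair()` separately reports which of them
lie on the winning global alignment. `local_align()` is provided for
exploratory block-finding with its defaults documented above.

## Numerical choices

* Traceback ties in the global alignment are broken diagonal, then up, then
  left; the optimal *score* is unique, the reported path is made
  deterministic by this rule. Matched cells with similarity 0 are dropped
  from the path: aligning two steps that share nothing conveys nothing.
* Direction ties report `"forward"`; rotation ties report the smallest
  offsets. Floating-point comparisons use an absolute guard of 1e-12; all
  scores are small rationals, so this is far below the spacing of distinct
  values.
* `significance_cutoff(bg, alpha = 1)` is accepted as the limiting case and
  returns the smallest observed score (the strict "< alpha" rule, read
  literally at `alpha = 1`, would skip it).
* Degenerate inputs fail loudly: empty mechanisms, all-spontaneous entries,
  both-empty overall sets, zero cardinalities in normalization, and
  backgrounds whose every score is identical (no significance cutoff
  exists) are all errors with informative messages.

## The synthetic generator

`generator_config()` states a small world resembling curated catalytic
mechanisms: a bond repertoire weighted toward the bond types most common in
enzyme catalysis (O-H, C-O, N-H, C-C, C-N, C-H, P-O in decreasing weight,
plus a tail of rarer bonds), formations/cleavages four times as likely as
order changes, mechanisms of 2–8 steps with 1–5 changes per step, and
default perturbation rates of 0.1 per step (insertion, deletion,
within-step swap). The step-count and changes-per-step ranges bracket the
bulk of curated mechanisms; the perturbation default is half the 0.2 used
in the separation calibration, representing a mild analog.

The overall reaction of a generated entry is *derived* from its mechanism
by net-change cancellation: a formation and a cleavage of the same bond
(or an order increase and decrease) annihilate, so transient intermediates
leave no net change, mimicking how curated overall reactions relate to
their mechanisms. Entries whose changes fully cancel are flagged
change-free; the ensemble generators resample them, mirroring the removal
of change-free reactions from empirical backgrounds.

What the generator does **not** emulate: valence or mass balance, chemical
plausibility of step order, correlated step content within a mechanism
(real mechanisms reuse proton-transfer motifs), realistic EC/superfamily
co-occurrence structure, or stereochemistry records. A green separation
test therefore establishes that the statistics recover an *injected*
signal at the stated perturbation rate — not that the method's published
cutoffs are reproduced; that requires the curated dataset, which is not
redistributable with this package (the full pipeline for it ships and is
exercised by the acceptance suite the moment the transcribed tables are
supplied under `extdata/reference/`).

## Known limitations

* Bond-change sets ignore multiplicity; if a source database ever recorded
  the same change twice in one step, it collapses to one (warned).
* Element-pair bond identity cannot distinguish, e.g., which of several
  C-O bonds in a substrate is cleaved; similarity is chemistry-typed, not
  atom-mapped.
* The curated circular-permutation whitelist and the reference analog and
  background datasets are metadata of a non-redistributable database; this
  package ships the machinery and schema, not those data.
* Runtime is interpreted R: all-vs-all comparison of a few thousand pairs
  takes seconds, not milliseconds; no compiled code is used because the
  matrices involved are tiny (steps per mechanism, not residues).
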