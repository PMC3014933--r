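---
title: "Methods: detecting nested retroposons and fitting activity chronologies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting nested retroposons and fitting activity chronologies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tintr)
```

# The problem

Retroposons (SINEs such as the primate Alu family, LINEs, LTR elements)
amplify in waves: a subfamily arises, produces copies for a while, and falls
silent. A new insertion lands wherever the integration machinery puts it, and
when it lands inside an existing element it fragments that host into two
annotated pieces. Since insertion into an element requires that element to
already exist, the direction of nesting carries time information: counting
who-inserted-into-whom across a genome constrains the relative order of
subfamily activity periods, independently of sequence divergence and its
well-known pathologies (rate variation, saturation, CpG hypermutability).

`tintr` implements the full path from RepeatMasker annotation to a fitted
relative chronology. This vignette documents the method, its assumptions,
the tunable parameters, and the numerical and design choices.

# Input and element reconstruction

The input is the standard RepeatMasker `.out` report (15 whitespace-delimited
columns plus an optional `*`). Three points matter:

* **Consensus coordinates are strand-dependent.** RepeatMasker prints
  complement-strand consensus coordinates in reversed order,
  `(left) end begin`. `read_rm_out()` normalizes every row to
  `cons_begin <= cons_end`; `write_rm_out()` restores the dialect. All
  coordinates are 1-based inclusive throughout — no half-open conversion
  anywhere, so the consensus-overlap arithmetic below matches the thresholds
  literally.
* **The ID column is mandatory.** Fragments of one interrupted element share
  an ID, and identity is always the pair (query sequence, ID): RepeatMasker
  restarts IDs across query sequences, so the ID alone is not an element key.
  Files without IDs are rejected with instructions to rerun RepeatMasker.
* **Fragment naming is unreliable.** Interrupted elements are occasionally
  annotated with different subfamily names on their two sides. After grouping
  rows into element instances, `group_elements()` adopts the name of the
  largest fragment (by query span; ties go to the first fragment in query
  order).

The `*` (overlap) flag is parsed and stored but plays no role in detection.

# The five unambiguity criteria

Real annotation is noisy, so only *unambiguously* nested insertions are
counted. A candidate consists of two host fragments `f1`, `f2` (in query
order) and an inserted element instance lying strictly between them.
`detect_nested()` accepts it iff:

1. everything lies on the same query sequence;
2. *(stringent mode)* `f1` and `f2` carry the same element index and the
   inserted element's index is higher — RepeatMasker assigns IDs in query
   order, so a nested element necessarily received a later ID than its host;
3. every fragment — both host fragments and each fragment of the inserted
   instance — spans at least `min_query_length` = 20 nt on the query;
4. both host fragments have the same orientation;
5. the host's consensus is continuous across the break. With the consensus
   overlap defined as `ov = f1.cons_end − f2.cons_begin + 1` for plus-strand
   hosts (mirrored in consensus orientation for complement-strand hosts,
   where the downstream-on-query fragment carries the upstream consensus
   segment), and non-overlapping spans `span − max(0, ov)`, the pair passes
   if both non-overlapping spans are at least `min_repeat_extension` = 50 nt,
   **or** both are at least `min_repeat_extension_overlay` = 18 nt and
   `ov ≤ max_repeat_overlay` = 35 nt.

Choices worth making explicit:

* The 50-nt branch carries no overlap bound. Under hard thresholds this is
  the only reading in which the "preferably ≥ 50 nt" level has any logical
  force: two long rediscovered host halves are accepted even when a
  low-complexity region inflates the apparent overlap, while short fragments
  must show a believable target-site-duplication-scale overlap (TSDs of the
  L1 machinery are ~5–15 nt, safely under 35). For elements integrating
  without TSDs (e.g. avian CR1), lower `max_repeat_overlay` and raise
  `min_repeat_extension_overlay` — both are run parameters.
* The overlay fallback default is 18 nt; descriptions of this rule vary
  between 18 and 19 nt, and the parameter reproduces either convention.
* A negative `ov` (a consensus gap between the halves, e.g. an internal host
  deletion) is allowed by the rule as stated — the criterion only bounds the
  overlap from above.
* Criterion 3's 20-nt minimum is applied per fragment ("all elements"
  read distributively), including each fragment of the inserted instance.
* Single elements — neither fragmented nor inserted into anything — produce
  no events and are visible only in the copy numbers.

**Relaxed mode** (`use_element_index = FALSE`) is for scarce data (trace
archives, low-copy-number elements): element indices are ignored and a host
pair is each fragment together with the *next* fragment of the same subtype
(or the same class/family with `class_level_match`; `class_only` compares
only the part before the `/`). Two consequences are documented rather than
hidden: a same-subtype element nested inside a host gap captures the pairing
and can mask the outer event (the test suite checks the stringent ⊆ relaxed
containment on exactly the events without such interlopers), and class-level
matching on data dominated by a single class pairs mostly adjacent fragments
and accepts very little — it is useful only for mixed-class, sparse
annotation.

**Innermost attribution.** In multi-level nests (A inside B inside C),
criteria (1)–(5) accept A against both enclosing contexts. `detect_tints()`
attributes each inserted instance to the smallest *accepted* enclosing gap,
so the chain yields A→B and B→C, never A→C — with one deliberate refinement:
if the inner host pair fails criteria (3)/(5), the element is attributed to
the next enclosing context that passes. Whether deep nests should count once
per level or only innermost is a genuinely open choice; innermost is used
because each physical insertion event is then counted exactly once.

Rejected candidate pairs are tallied per query and per criterion in a
diagnostics report attached to every detection result.

# The count matrix

`build_tint_matrix()` tallies events into K×K counts with **rows = inserted,
columns = host** (every serialization states this orientation in a header
line to prevent silent transposition). Copy numbers count element instances
(fragments merged by ID) of each subtype among all detected elements — not
annotation rows, and not only elements participating in nestings.

Self-insertions (inserted subtype = host subtype) are excluded from the
tally by default and retained only for calibration studies
(`include_self = TRUE`); see the model section for why they still matter.

`merge_types()` pools related subtypes whose individual resolution is too
low (e.g. closely related AluYR variants); counts between group members move
to the merged diagonal, and totals and copy numbers are conserved exactly.
`filter_types()` removes subtypes interacting with fewer than
`min_partner_types` = 2 other subtypes (the minimum for the model to place a
type *between* others), iterating to a fixed point since a removal can
strand another type's last partner.

# The Gaussian activity model

Assumptions, in the package's terms:

1. each subtype j has a single activity period; its copies insert at times
   drawn from a Normal(t_j, σ_j) density, so the number of type-j elements
   existing at time t is η_j(t) = n_j Φ((t − t_j)/σ_j), with the activity
   maximum at t_j;
2. an inserting element lands in any preexisting element with equal
   probability per element — including elements of its own type;
3. the spread is tied to abundance, σ_j ∝ n_j: prolific subtypes are modeled
   as active longer.

For a type-i copy inserting at a random moment τ of its own activity period,
the expected number of type-j targets is E[η_j(τ)] with τ ~ N(t_i, σ_i²).
Using the identity E[Φ((τ − a)/b)] = Φ((μ − a)/√(b² + s²)) for τ ~ N(μ, s²),
this marginalizes in closed form:

> w_ij = n_j Φ((t_i − t_j) / √(σ_i² + σ_j²)),  q_ij = w_ij / Σ_k w_ik.

No numerical integration is needed anywhere in the fit; the test suite
verifies the closed form against adaptive quadrature of the defining
integral to ~1e-15.

**The self-target stays in the denominator.** Insertion into one's own type
is physically possible (assumption 2), contributing w_ii = n_i Φ(0) = n_i/2.
Observed self-insertion *counts* are excluded from the likelihood — a nested
AluY in an AluY says nothing about order — but the self-target's probability
mass must remain in the normalization: it is precisely what makes empty
cells informative. With only two types and the self-target dropped, every
insertion would have a single allowed target, q ≡ 1, and the likelihood
would be flat; with the self-target retained, ten A-into-B events against
zero B-into-A force t_A > t_B, as they should. The strict k ≠ i
normalization is available (`exclude_self_target = TRUE`) but is not the
default.

The log-likelihood is the product-multinomial Σ_ij N_ij log q_ij over
tallied cells. The global per-element insertion probability cancels in this
conditional form and is not a parameter.

## Identifiability, gauge and spreads

The likelihood is invariant under a common shift of all peaks (only time
*differences* enter). The gauge is fixed after optimization by the
copy-number-weighted centering Σ n_j t_j = 0. The overall time *unit* is set
by the spreads: `sigma_mode = "scaled"` (default) uses σ_j = n_j / max(n) —
identical to the prescribed σ_j = n_j up to the unit gauge, but
numerically well-scaled when copy numbers reach 10⁵–10⁶.
`sigma_mode = "copy_number"` uses σ_j = n_j literally;
`sigma_mode = "free"` additionally estimates per-type spreads
(log-parameterized) and is exploratory only — with K(K−1) observed cells and
2K parameters it is weakly constrained on small matrices. Whether the
original model estimated the spreads or fixed them at n_j exactly is not
recoverable; fixing them is the conservative choice and is what the
recovery tests validate.

## Optimization

`fit_activity()` maximizes over the K peaks with derivative-free
Nelder-Mead from multiple starts — one heuristic start ranking types by
host/inserted asymmetry (types that mostly host are old), plus seeded random
restarts (default 10 in total) — each polished twice and finished with BFGS;
the best optimum wins. Convergence tolerance is `tol = 1e-8` (relative). On
three-type problems the fitted optimum matches a 160×160 dense grid search
in the gauge plane to better than 1e-6 log-likelihood units. All randomness
flows from the `seed` argument, which is recorded in the output.

## Intervals and display

The reported intervals are central intervals of the Gaussian *activity
density*: t_j ± z σ_j with z = 1.150349 (75 %), 1.959964 (95 %), 2.575829
(99 %). They describe the activity period, not estimation uncertainty of
t_j (for a Gaussian the central interval and the highest-density interval
coincide, so the distinction between the two possible readings of the
"probable activity period range" is immaterial). The chart draws one row per
subtype, sorted by peak: the oval body spans 75 %, vertical ticks mark 95 %,
whisker caps end at 99 %; a relative axis below maps the union of 99 %
intervals to [0, 1]. Colors are assigned deterministically from a hash of
the subtype name so charts are comparable across runs. SVG is generated by
a purpose-built writer so that glyph geometry is exact and testable; PNG and
PostScript come from the corresponding R graphics devices over the same
geometry (PostScript honoring the classic print-to-file export path).

No absolute time calibration is attempted, and the activity density is
deliberately symmetric single-peak: asymmetric activity and
divergence-based calibration are out of scope.

# The simulator

`simulate_tints()` is the package's ground-truth generator and embodies the
model assumptions generatively:

* per-subtype insertion times drawn from Normal(peak, sigma), processed in
  time order;
* each insertion lands uniformly per nucleotide over the current genome
  (background plus accumulated elements). Landing in an element fragments
  the host into two records sharing its ID, with consensus coordinates
  overlapping by `tsd_length`; strand conventions are mirrored for
  complement-strand hosts. This reproduces the size bias of insertion —
  longer subtypes attract proportionally more hits — which is why mixing
  300-nt SINEs with 6-kb LINEs in one analysis is inadvisable, and why the
  analytic twin `expected_matrix()` weights targets by copy number ×
  consensus length;
* the genome is emitted as many short query sequences (trace-style), which
  also gives subsampling tests a natural unit;
* optional annotation noise: subtype misannotation within a class
  (exercises largest-fragment renaming) and ID loss on fragmented hosts
  (defeats stringent pairing but not relaxed).

Default scenario (the study condition used throughout the tests): six
Alu-like subfamilies of 800 copies each, 300-nt consensus, peaks at
0, 2, …, 10 with spread 1 (well-separated but overlapping neighbors),
120 kb of background over 400 loci, `tsd_length` 12 nt (typical
L1-machinery TSD scale, safely below the 35-nt overlay threshold) and
`min_fragment` 15 nt (small enough that criterion 5 genuinely rejects some
true events, keeping the closure tests non-trivial). This yields ~8,500
annotation records, ~3,700 true nestings and ~2,600 tallied non-self events
per run — large enough for stable ordering recovery, small enough that the
full 20-replicate recovery study runs in under two minutes.

What the simulator does **not** emulate: sequence-level mutation and
divergence (the divergence columns carry plausible constants; detection
never reads them), element deletion or recombination, target-site sequence
preferences, and misassembly. Passing tests therefore demonstrate
correctness of the algorithmic chain under the model's own assumptions —
not robustness to every pathology of real annotation, where the stringent
criteria are the main safeguard.

# Numerical choices and degenerate inputs

* All target probabilities are computed in log space
  (`pnorm(log.p = TRUE)` + log-sum-exp), so even astronomically separated
  peaks stay normalized; a row whose every target weight is identically
  zero (possible only with non-finite input or an empty target set) raises
  a numerical-guard error suggesting rescaled time units.
* Host fragment pairs overlapping on the query (annotation artifacts) are
  skipped and counted in the diagnostics, not errors.
* `filter_types()` reports removed subtypes; removing everything is an
  error that advises relaxed conditions — recommended only when the amount
  of data is genuinely small.
* Tie-breaks are deterministic everywhere (first-in-query-order), so equal
  inputs give byte-identical outputs; the simulator restores the caller's
  RNG state.

# Known limitations

* Relaxed mode's next-same-subtype pairing can be captured by same-subtype
  interlopers (see above); stringent mode does not have this failure.
* Copy-number-proportional spreads are an assumption, not an estimate; a
  subtype with many copies but a genuinely short, intense activity burst
  will be drawn too wide.
* The model places every subtype on one axis with a single symmetric
  activity period; bimodal reactivations (known for some L1 lineages) are
  averaged into one interval.
* Counts are treated as independent given the peaks (product-multinomial);
  in reality deep nests share hosts, a weak dependence ignored here.
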