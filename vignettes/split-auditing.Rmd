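---
title: "Auditing dataset splits for surgical workflow recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing dataset splits for surgical workflow recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splitaudit)
```

## The problem

Benchmarks for surgical phase and instrument recognition annotate endoscopic
video frame by frame: every frame carries exactly one *phase* label (a coarse,
conceptually ordered segment of the procedure, e.g. *Calot triangle
dissection*), and, at a lower sampling rate, a binary presence vector over the
*instrument* vocabulary. Machine-learning evaluation partitions whole
surgeries into training, validation and test sets. Three properties of
surgical workflows make such splits fragile:

* **Duration imbalance.** Phases differ in length by orders of magnitude, and
  so do whole surgeries; a per-surgery split can concentrate a short phase's
  few frames in one set.
* **Erratic workflows.** Phases can be skipped, repeated, or visited out of
  order. The interesting attribute is often not the phase itself but a
  *phase transition* — and rare transitions (a surgery skipping the first
  phase, an unusual ending) can easily land entirely in one set.
* **Multi-label instrument usage.** Instruments co-occur, and the *exact
  combination* visible in a frame is a much sparser attribute than any
  individual instrument.

When an attribute occurs in the data but has zero frames (or zero
occurrences) in one set, the model is never trained on it, never validated on
it, or never tested on it — and the evaluation silently stops being
representative. This package makes those cases mechanical to find.

## Derived attributes

From the aligned frame streams of each surgery the package derives:

| attribute | unit | notes |
|---|---|---|
| phase occurrence | frames | per phase, per set; plus #surgeries containing the phase |
| phase transition | occurrences | boundaries between consecutive distinct runs |
| surgery duration | frames | per surgery; per-set means |
| individual instrument | frames | visibility regardless of co-visible instruments |
| instrument combination | frames | the exact set of >= 2 co-visible instruments |
| idle frames | frames | no instrument visible |

Transitions are counted in occurrences, not frames, because a boundary has no
temporal extent. Every surgery contributes two *sentinel* transitions,
`START -> first phase` and `last phase -> END`, so that skipped first phases
and unusual endings are first-class, auditable attributes. A transition is
*forward* when its target comes later in the configured conceptual order than
its source, *backward* otherwise; sentinels are *boundary*.

### Combination semantics

A frame showing instruments $\{A,B,C\}$ could count toward $\{A,B\}$ or not.
The default here is **exact-set** semantics: the frame's full visible set
determines its single class, so idle frames, singletons and combinations
partition the instrument-annotated frames of each set, and two identities
hold that the test suite checks on every synthetic dataset:

$$\mathrm{idle} + \sum_i \mathrm{singleton}(i) + \sum_{|S|\ge 2} c(S) = \#\text{annotated frames},$$
$$f(i) = \mathrm{singleton}(i) + \sum_{S \ni i} c(S).$$

This matches a Radial-Sets-style display whose combination nodes are
disjoint, and per-node pie charts only make sense over a partition. Because
published frame counts for specific combinations could conceivably follow the
superset-inclusive reading instead, `aggregate_combination_counts()` exposes
a `semantics = "subset"` switch under which a combination $S$ counts every
frame whose visible set contains $S$; the exact-set route remains the
default and the two are never conflated.

## Auditing

`audit_splits()` computes all families over a split and flags every
attribute with positive global count and zero count in at least one
*non-empty* set — a 40/-/40 split (no validation set) is audited over train
and test only, and an attribute that never occurs at all is never flagged
(vacuous absence). The summary is a kind-by-set matrix whose columns are
explicitly labelled *absent-in-set*; sentinel transitions get their own row
(`sentinel_transition`) so a summary with or without them is recoverable.
`NA` marks empty sets and families the dataset has no data for (a
phase-only dataset has no instrument rows, and vice versa).

## Re-assignment and the greedy improver

`reassign()` is pure: it returns a new assignment (set membership is kept in
sorted id order, which makes a move followed by its inverse restore the
original split bit-exactly) plus a diff that recomputes the audit de novo on
the moved split — there is no incremental bookkeeping to drift. The diff
lists newly covered and newly lost attributes explicitly, because
re-partitions can trade one flag for another.

`greedy_improve()` is a deliberately simple first-improvement hill climb:
candidates (pairwise swaps when set sizes must be preserved; single moves
additionally when not) are scanned in lexicographic surgery-id order and a
candidate is accepted only on a strict decrease of the objective (the number
of (attribute, absent-set) flag pairs by default). Ties keep the incumbent,
so the default path is deterministic without any seed; an optional seed
deterministically shuffles the scan order. The objective never increases and
the climb stops at a local optimum or `max_iter`. This is an exploratory
tool, not an optimal splitter: with two carrier surgeries and three sets no
single swap can cover all sets, and finding globally optimal stratifications
is out of scope.

## The synthetic generator

`generator_spec()` describes surgeries as a Markov chain over phases with
geometric run lengths — the simplest memoryless model that produces variable
durations and re-occurring phases. Instrument vectors are drawn per frame
conditioned on the active phase; an optional `persistence` probability
copies the previous frame's vector to emulate bursty tool usage. The
defaults state a heavily imbalanced but plausible world:

* mostly-forward chain (forward 0.7, skip-one 0.1, backward 0.15, small
  early-END mass), ending mostly from the final phase;
* per-phase mean run lengths recycled from `c(4, 40, 12, 3, 8)` frames — a
  more than tenfold spread, which produces the heavy-tailed phase totals the
  audit is designed for;
* one signature instrument per phase at 0.8 visibility, a secondary at 0.4,
  a 0.05 base rate;
* a quarter of surgeries skipping the first phase, assigned to the
  lexicographically first ids so tests can name them.

What the generator does **not** emulate: visual content of any kind,
annotation noise, temporal correlation beyond the one-step persistence, and
surgeon- or center-level effects. A green test therefore establishes that
the counting, auditing and re-assignment machinery is correct on data with
the right *combinatorial* structure — it says nothing about any real
dataset's numbers, which require the external annotation downloads.

`dense_generator_spec()` states the opposite regime for closed-loop tests:
uniform transitions, a single start phase, END reachable only from the last
phase (`end_prob = 0.08`, which keeps the probability of hitting the
`max_frames = 2000` cutoff — and thereby ending mid-phase — around
$10^{-18}$), short runs, and 0.5 visibility for every instrument. Under this
spec every attribute occurs in every set with overwhelming probability, so
after `plant_unrepresented()` suppresses one attribute (zeroing a transition
probability, or deflecting chance occurrences of a combination) and injects
it into the first surgery of every non-victim set, the audit must flag
exactly the planted attribute — which the acceptance suite verifies for 50
random plants.

## Numerical and design choices

* **Frame indexing** is 0-based in source-video units; Cholec80-style tool
  files sample frames $0, s, 2s, \dots$ and stride-downsampling of the phase
  stream keeps exactly those indices, so the two streams align by position.
* **Length mismatches** between the streams (real Cholec80 videos differ by
  a few frames) are truncated to the shorter stream with a warning carrying
  the dropped-frame count; no rule for this case is standard.
* **Idle steps** (CATARACTS) are excluded at load time, before any
  statistics; runs separated only by idle frames merge, so exclusion never
  creates a self-transition.
* **Config files** are JSON (phases in conceptual order, instruments, the
  two frame rates, the split); set colors are fixed red/green/blue for
  train/val/test across all views.
* **Rendering** is split into pure model-building (positions, proportions,
  linearly scaled arc widths with a positive floor — the sources do not
  specify a scaling function) and drawing; tests assert on the models.
  Combination nodes use a force-directed layout with a fixed seed.
* **Degenerate inputs**: empty phase sequences, unknown labels, non-monotone
  frame indices, non-divisible frame rates, cells outside {0, 1}, surgeries
  missing from the split, and generator chains that cannot reach END all
  raise errors naming the offending entity.

## Known limitations

The package audits *which* attributes are covered, not *how well* — it
reports raw counts and absence flags, no imbalance indices. Workflow
patterns longer than a single transition are invisible to the audit.
The greedy improver finds local optima only. Published numeric results for
the five real datasets can be reproduced only after downloading their
annotation archives; the shipped `inst/extdata` configurations carry the
published split assignments and proposed re-assignment moves so that doing
so is a one-liner with `load_dataset()` + `audit_splits()`.
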