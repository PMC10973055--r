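# splitaudit

Auditing train/validation/test splits of frame-wise surgical workflow
annotations.

## Why

Surgical phase and instrument recognition datasets (Cholec80, CATARACTS,
CaDIS, the M2CAI challenge sets, ...) annotate video frame by frame: one
phase label per frame at the video rate, one binary instrument-presence
vector per sampled frame at a lower rate. Evaluation splits whole surgeries
into train/val/test sets — but phase durations are imbalanced by orders of
magnitude, phases get skipped and repeated, and instruments co-occur in
sparse combinations. The result: attributes that occur in the data but have
**zero frames in one set**. A phase transition seen only in training is never
evaluated; an instrument combination missing from validation distorts model
selection. This package finds those cases mechanically, for machine-learning
practitioners and challenge organizers preparing such datasets.

## What it computes

For every surgery it derives, and per set aggregates:

* **phase occurrence** (frames per phase) and the number of surgeries
  containing each phase;
* **phase transitions** (occurrences, not frames), including `START ->` and
  `-> END` sentinels so skipped first phases and odd endings are auditable,
  classified forward/backward against the configured conceptual phase order;
* **surgery durations** (frames) with per-set means;
* **individual instrument occurrence** (frames visible, regardless of
  co-visible instruments) and **idle frames**;
* **instrument combinations** under exact-set semantics — the frame's full
  visible set of >= 2 instruments is its single class, so idle + singletons +
  combinations partition the instrument-annotated frames (a
  `semantics = "subset"` switch provides the superset-inclusive reading).

`audit_splits()` flags every attribute with positive global count and zero
count in some non-empty set, summarized in a kind-by-absent-in-set matrix.
`reassign()` applies surgery moves purely and diffs the audit before/after;
`greedy_improve()` hill-climbs over swaps to reduce the flag count.
`generator_spec()` + `generate_dataset()` simulate workflow-structured
annotation data (Markov phase chain, geometric run lengths, phase-conditioned
instrument visibility, skip/early-end quirks) so everything is testable
without downloads. `render_phase_view()`, `render_instrument_view()` and
`render_supplementary()` draw static arc-diagram, radial-sets and totals
views (SVG/PNG/PDF) with the fixed red/green/blue = train/val/test coding.

## Worked example

```r
library(splitaudit)

ds <- generate_dataset(generator_spec(n_surgeries = 10), seed = 2024)
report <- audit_splits(ds$surgeries, ds$config$split, ds$config)
print(report)
```

```
<audit_report> synthetic (exact combination semantics)
sets: train/val/test 
unrepresented attributes per (kind, absent set):
                     absent_in
kind                  train val test
  phase                   0   0    0
  transition              2   6    5
  sentinel_transition     0   0    2
  instrument              0   0    0
  combination             0   3    2
13 flagged attribute(s); first few:
        kind      key train val test  absent_in
1 transition P1 -> P3     1   0    0  val, test
2 transition P2 -> P1     0   1    2      train
3 transition P2 -> P4     0   0    1 train, val
4 transition P3 -> P2     1   0    0  val, test
5 transition P3 -> P5     1   1    0       test
```

Reading: every phase and every individual instrument is represented in all
three sets, but 13 rarer attributes are not — e.g. the backward transition
`P2 -> P1` occurs once in validation and twice in test yet never in
training, and two surgeries end in unusual phases (`sentinel_transition`,
absent from test). The per-set totals show the duration skew behind this:

```r
per_set_totals(ds$surgeries, ds$config$split)
#     set surgeries frames mean_frames
# 1 train         5    465    93.00000
# 2   val         3    214    71.33333
# 3  test         2    404   202.00000
```

A greedy pass reduces the flag count while preserving the 5/3/2 shape:

```r
gi <- greedy_improve(ds$surgeries, ds$config$split, ds$config, max_iter = 10)
print(gi)
# <greedy_improvement> objective 20 -> 17 in 2 step(s) (local optimum)
gi$trace
#   iter objective      move
# 1    1        19 s01<->s07
# 2    2        17 s02<->s04
```

(The objective counts (attribute, absent-set) pairs; 20 pairs over the 13
flagged attributes.)

Real datasets load from their published annotation files (external
downloads). Configuration skeletons with the published splits and proposed
re-assignment moves for Cholec80 (40/-/40) and M2CAI-tool (10/-/5) ship in
`inst/extdata/`:

```r
cfg <- read_dataset_config(system.file("extdata", "cholec80_40_40.json",
                                       package = "splitaudit"))
ds  <- load_dataset(cfg, dir = "path/to/cholec80/annotations")  # videoNN-phase.txt / videoNN-tool.txt
audit_splits(ds$surgeries, cfg$split, cfg)
```

## Command line

```sh
splitaudit simulate --out demo/ --seed 4 --surgeries 8
splitaudit audit    --config demo/config.json --data demo --out report.json
splitaudit improve  --config demo/config.json --data demo --out improved.json
splitaudit plot     --config demo/config.json --data demo --view phase --out phase.svg
```

(`exec/splitaudit` is installed with the package; equivalently
`Rscript -e 'splitaudit::splitaudit_cli()' audit --config ...`.)

## Further reading

`vignettes/split-auditing.Rmd` documents the model, the exact-vs-subset
combination semantics, what the synthetic generator does and does not
emulate, and the numerical/design choices.
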