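---
title: "Methods: saturation sampling, circuit thresholds and the bouton-share null"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: saturation sampling, circuit thresholds and the bouton-share null}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`consat` packages the analysis workflow of a sparse EM-reconstruction survey
of the fly thermo- and hygrosensory system. This vignette documents the
models and procedures, the parameters that matter, the synthetic-data
generator the tests rely on, and the numerical and design choices made where
the procedures left room.

## The data model

Neurons are rooted trees of 3-D treenodes with radii (`skeleton()`, SWC I/O
via `read_swc()`/`write_swc()`). All internal coordinates are nanometres;
SWC files default to micrometres (`unit_scale = 1000`). Synapses are stored
connector-centrically: one presynaptic site — a continuous synaptic cleft
scored once — with one or more postsynaptic links, one per opposing membrane
(`synapse_table()`). A *connection* is always one postsynaptic link, so a
polyadic connector contributes once per link to any count; per-edge synapse
numbers are derived, never stored. Neuropil volumes are axis-aligned boxes
or closed triangle meshes with a point-membership test; the boundary counts
as inside. Cable length inside a volume sums parent–child edges whose *both*
endpoints lie inside — no clipping — matching the node-resolution
bookkeeping of traced skeletons.

## Saturation sampling

`enumerate_postsynapses()` lists every (connector, postsynaptic link) pair
downstream of the query neurons, optionally restricted to a volume, in a
deterministic sort order. `sample_to_saturation()` draws uniformly without
replacement over those links — matching a workflow that first annotates all
postsynapses and then samples them — and tracks *novel hits*, first
occurrences of an unseen partner. After each novel hit, once at least
`window` (default 10) novel hits exist, sampling stops if the most recent
`window` of them each have fewer than `weak_threshold` (default 5)
connections to the query: when recent discoveries are all weak partners, the
strong ones are presumed found.

Two choices are deliberate:

* The per-partner connection count the rule inspects is the partner's *true*
  total within the sampled scope. In the original workflow each hit was
  reconstructed to identification, making that total known; the synthetic
  generator supplies it as ground truth, and `partner_truth_from_pool()`
  recomputes it live from a connectome. The scope is volume-restricted by
  default, mirroring the accessory-calyx workflow; passing `volume = NULL`
  gives brain-wide counts. Whether the original counts were volume-restricted
  is not documented; both modes are provided and only the default is ours.
* The window is evaluated only once `window` novel hits exist; the rule can
  never fire earlier.

One property worth stating precisely: for a fixed draw order, raising
`weak_threshold` makes *more* partners count as weak, so the all-weak window
fires no later and the sampled fraction is non-increasing. The paired test
over 200 seeds pins this direction. Intuitively a stricter notion of
"strong" makes the sampler give up sooner, not later.

The rule trades completeness for effort, and the trade depends on the
degree distribution. With a long singleton tail (the default generator
profile: 3 partners × 20 connections, 2 × 8, 200 × 1 per query) the window
often fills with singletons after a handful of draws, so sampling halts at a
small fraction of the pool and partners of moderate degree can be missed.
The acceptance script measures and reports the per-partner discovery rate
over 500 seeded runs rather than assuming it is high; treat the stopping
rule as an effort heuristic, not a completeness guarantee.

## Circuit extraction

`build_adjacency()` counts links source-by-target with optional volume and
per-neuron compartment restrictions (e.g. only a target's dendritic nodes,
from `split_dendrites()`). Threshold semantics are pinned by tests because
they are asymmetric on purpose: `circuit_members()` is inclusive (summed
input **≥ 5** designates membership), `strong_targets()` is strict
(**> 150**), and `input_budget()` drops raw cells of **≤ 2** synapses before
renormalizing — thresholds apply to raw counts, normalization to what
remains. Budgets come in two modes: over total VP-PN input, or over
identified input categories supplied as a user-editable mapping.

`vp_census()` implements the survey's bookkeeping arithmetic, including the
sacculus triad rule: VP4, VP5 and VP1d receptor neurons cohabit triad
sensilla in chamber II, so a hemisphere's chamber-II VP4 count equals its
VP5 count, the remaining VP4 RNs sit in chamber I, and the VP1d total equals
the VP5 count. The underlying survey reports both 88 and 89 reconstructed VP
PNs in different places; the census implements the per-side sum (52 + 36 =
88) and leaves the discrepancy to the reader.

## Morphology similarity and typing

`to_dotprops()` resamples each unbranched segment at `spacing` (default
1000 nm) and takes the tangent at each point as the first principal axis of
its `k` (default 5) nearest resampled neighbours; tangent sign is
meaningless downstream. `nblast_similarity()` sums, over query points, a
kernel of nearest-target distance `d` and absolute tangent dot `a`. The
kernel is `exp(-d/σ)·a` with `σ = 3000` nm — chosen for smoothness and for
having a closed-form oracle the tests verify against — and a tabulated
(distance-bin × dot-bin) score table can be supplied instead for
compatibility with published score matrices. Nearest-neighbour ties break to
the lowest target index, deterministically.

Mean normalized scores divide by self-similarity and average forward and
reverse, so identical clouds score exactly 1. Typing clusters on `1 − score`
(clipped at 0) with Ward linkage (`hclust(method = "ward.D2")`) and cuts at
height 0.8. Ward on this non-Euclidean dissimilarity is accepted as-is; it
is what the field's typing pipelines do. Contralateral matching reflects one
hemisphere rigidly about a single sagittal plane — no nonrigid registration —
which suffices for synthetic mirrored data; real-brain asymmetry is out of
scope.

## The Kenyon-cell bouton-share null

`observed_inputs()` builds the binary claw-input table: for each KC dendritic
claw, a PN class is an observed input if it contributes at least `min_syn`
(default 5) synapses; inputs are weighted equally above threshold. Inputs
from accessory-calyx-associated PNs *inside* that volume are excluded — the
claw analysis concerns calyx bouton inputs, not the accessory-calyx circuit
itself.

The null model asks what input composition a claw population would show if
every input were drawn independently with probability proportional to each
class's calyx bouton share (`bouton_shares()`). One *draw* is one
(claw, class) event — the simplest reading of equally weighted per-branch
inputs — and draws within a claw are independent, with no
without-replacement correction. `expected_inputs()` realises the virtual
population `reps = 1000` times; because rows draw i.i.d., the per-class
population total in one replicate is exactly multinomial, which is both the
implementation and the analytic check (means within Monte Carlo error of
`n·p`). Per-row input counts may be held at the observed totals (the
default, honouring "same number of KCs and inputs") or set to a constant;
whether the original procedure resampled them is not documented, so both
modes exist.

`enrichment_report()` adds observed/expected ratios and empirical two-sided
Monte Carlo p-values, plus a valence roll-up after summing classes within
valence groups. The p-values use the **mid-p** convention — add-one
corrected, doubling the smaller tail with ties counted at half weight —
because the replicate distribution is discrete and plain tail-doubling is
conservative, which would bias the calibration the tests check (the
fraction of null data flagged at p < 0.05 should be near 0.05). Expected
bars alone are what the original analysis reported; the p-value layer is an
addition of this package and is labelled as such.

## The synthetic generator

`generate_connectome()` builds, from a single master seed, a connectome with
the statistical structure the analyses assume: seven VP glomeruli with
per-hemisphere RN counts at the survey's scale (e.g. 14 VP4, 9 VP5, 9
VP1d); PN types whose axons span several neuropil boxes; an accessory-calyx
volume in which the two query PNs supply at least `laca_dominance` (default
0.92) of PN presynapses; a long-tailed downstream degree multiset matched
*exactly* per query PN; and KCs whose claw inputs are drawn from
(bias-adjustable, renormalised) bouton shares and realised at 6 synapses per
input so the 5-synapse observation threshold retains them, with optional
sub-threshold contamination. RN→PN counts are Poisson with mean proportional
to the PN's dendritic cable in the glomerulus (1.5 inputs/µm by default),
giving the regression stage real signal; dendritic segment sizes vary
between instances so cable spans a useful range. Every stage draws from its
own stream derived from the master seed, so stages are independently
reproducible and output is byte-identical across runs.

Ground truth (partner degrees, claw draws, share vectors, cable/input
samples, type labels) is always emitted, because every downstream test is
parameter recovery. What the generator does **not** emulate: realistic
neurite geometry (skeletons are folded random walks, with type archetypes
jittered per instance only in `generate_type_population()`), electrical
properties, development, tracing error, and real-brain left–right
asymmetry. Passing tests therefore demonstrate correctness of the
*procedures* under their stated assumptions, not robustness to the noise
structure of real reconstructions.

Default problem sizes keep the full suite in tens of seconds: the standard
connectome has ~500 skeletons and ~2000 connectors; the exhaustive-sampling
identity is checked on a ~10⁴-connector instance; stopping-rule coverage
uses 500 seeded runs; null calibration uses 200 simulations of 1000
replicates; typing recovery uses 10 seeds of 3 × 3 neurons.

## Degenerate inputs and numerical conventions

* Boundary points are inside volumes; mesh membership uses ray parity along
  a fixed irrational direction with deterministic fallback directions when a
  ray grazes an edge, and on-surface points count as inside.
* Single-node skeletons have zero cable and cannot become dotprops
  (`degenerate_morphology` error); zero self-similarity likewise.
* Empty pools, missing truth entries, all-zero bouton counts, constant
  predictors and infeasible generator configurations raise classed errors
  (`consat_error_*`) rather than propagating NaNs.
* `cutree` at height 0 separates any neurons whose merge height is positive;
  exact duplicates (merge height 0) stay together, which is the correct
  limit for a dissimilarity of zero.
* All identifiers are opaque strings; nothing assumes numeric skeleton ids.

## Limitations

The stopping rule's completeness depends strongly on the tail of the degree
distribution (measured, not assumed — see the acceptance script's discovery
rate). The Ward/0.8 typing convention is inherited, not optimised; score
tables other than the default kernel shift the dendrogram scale, and the cut
height is only meaningful relative to the default normalization. The null
model treats claws as exchangeable and inputs as independent; any claw-level
correlation structure (e.g. one bouton feeding several claws of one KC) is
outside the model.
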