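---
title: "Delay-aware signaling dynamics and Temporal Sequences on geometric networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delay-aware signaling dynamics and Temporal Sequences on geometric networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tseqnet)
```

## The model

`tseqnet` simulates the simplest signaling model that still takes the
spatial embedding of a neuronal network seriously. A network is a directed
graph whose nodes (neurons) carry 3-D soma positions in micrometres and a
polarity (excitatory or inhibitory); edges are chemical (axonal)
connections. A quantum of signal emitted by a node travels along every
outgoing edge at a fixed conduction velocity, so each edge has an integer
signal delay

    delay_ij = max(1, round(||p_i - p_j|| / v / dt))

in simulation steps, where `||p_i - p_j||` is the straight-line distance
between somata. Node dynamics are threshold-1 and refractory: an inactive
node activates the moment any single signal arrives, emits one signal per
outgoing edge (carrying the *emitting* node's polarity), and is then
refractory for a fixed period during which all arrivals are discarded. An
activation triggered by an inhibitory arrival is identical except that no
outgoing signals are generated. Activity is initialized to quiescence and
seeded by a single excitatory pulse at one node.

The point of the model is not biophysical realism — there is no membrane
integration, no synaptic weighting, no attenuation — but the interaction
of three ingredients: connectivity, geometry-derived delays, and
refractoriness. Because every activation has well-defined causal parents
(the signals that arrived at its trigger step), the full causal structure
of a run is recoverable, which is what the Temporal Sequence analysis
exploits.

The motivating instance is the *C. elegans* connectome (chemical
connections only, somata with known positions, GABAergic neurons
inhibitory), but nothing in the package is specific to it: any directed
edge list plus node table in the documented CSV formats works.

## Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| conduction velocity `v` | 80 | mm/s | within the theoretical range for small organisms of this type |
| refractory period | 4 | ms | biologically plausible neuronal refractoriness |
| time step `dt` | 25 | µs | 0.15 s of activity split into 6000 steps |
| steps `n_steps` | 6000 | — | long enough for transient and periodic phases |
| activation threshold | 1 | signal | fixed by the model; not configurable |

At these defaults one simulation step corresponds to 2 µm of axonal
travel, so somata hundreds of micrometres apart interact with delays of
hundreds of steps while the refractory period is 160 steps. That ordering
(heterogeneous delays straddling the refractory scale) is what gives
spatially embedded networks their large dynamic repertoire.

## Numerical and semantic choices

Several details are deliberate decisions where the model description
leaves room; they are all encoded in one place each and covered by tests.

* **Delay rounding** is half-away-from-zero, clamped to ≥ 1 step. The
  clamp prevents zero-delay edges between near-coincident somata, which
  would create same-step causal cycles.
* **Simultaneous mixed arrivals**: if any arrival at the trigger step is
  inhibitory, the activation is non-emitting ("suppression wins"). This
  tie-break is conservative and makes the update rule deterministic.
* **Inhibited activations** start a refractory window like any other
  activation, but are excluded from the binary raster `y(t)` (the state
  vector describes signal *output*). The flag is kept in the event log so
  the opposite convention is recomputable. Inhibited activations may
  terminate a Temporal Sequence but never continue one, because no signal
  is emitted past them.
* **Multi-parent events**: all sources whose signals arrive at the
  trigger step are recorded as parents. A diamond of equal total delay
  therefore yields one activation with two parents — and two distinct
  causal walks.
* **Refractory accounting**: a node activating at step `f` is next
  eligible at `f + refractory_steps`.
* **Window truncation**: signals still in flight at `n_steps` are
  dropped.
* **Self-loops** are rejected at construction; the model gives them no
  meaning (a node is refractory exactly when its own signal would
  return).
* **Nodes without positions** are dropped (with their incident edges, and
  reported) rather than imputed — the same reduction that takes the
  302-neuron connectome to the 277 neurons with known soma positions.
* **Lattice variant**: the spatially-unaware control sets every delay to
  one time unit and the refractory period to 0.9 time units (a locally
  near-optimal refraction ratio). One time unit is realized as 10 steps
  so that the 0.9 ratio is exact in integers (delay 10, refractory 9).
* **Unique network states** are counted as distinct binary column
  vectors, the quiescent all-zero vector included; no further
  equivalence (e.g., of permuted consecutive states) is applied.

## Temporal Sequences

A Temporal Sequence (TSeq) is a causal walk of one signal from the
stimulated start node to an end-node activation: consecutive entries are
network edges, and step differences equal the edge delays. Extraction is
a depth-first enumeration of root-to-end paths in the causal event DAG; a
path that continues past an end node contributes additional, longer
sequences ending at later end events. Path counts are exponential in the
worst case, so enumeration carries a hard cap (default 10^6) and fails
loudly rather than truncating silently.

**Sequence identity** defaults to the pair (label sequence, step
sequence): two signals tracing the same nodes at different times are
different sequences. Label-only deduplication is available as a switch
(`dedupe_labels`) because either counting granularity is defensible.

**The similarity measure** between a reference sequence `x` and a
comparison sequence `y` is greedy in-order label matching: a cursor scans
`y` left to right, each successive label of `x` advances the cursor past
its first later occurrence (if any), and the fraction of matched labels
is returned. The set-level count `c_alpha` is the number of reference
sequences whose best fraction against the comparison set meets the
threshold. The greedy scan (not longest-common-subsequence) is the
normative semantics here; the two differ on adversarial inputs. One
consequence worth knowing: the fraction is *not* monotone under appending
labels to `y` — a previously unmatched label can match inside the
extension and push the cursor past later matches. The documented
properties (reflexivity, bounds, completeness on supersequences) are the
ones tested.

**Basis decomposition** groups sequences by the canonical form of their
labels: every maximal tandem repeat (k ≥ 2 contiguous copies of a block,
smallest period preferred, leftmost first) is collapsed, iterating to a
fixed point so nested repetition also collapses. Groups of two or more
members — sequences differing only in how many times a signal circulated
a cycle — are Repeating; singletons are One-Time. A single sequence
containing repeats but matching no other sequence stays One-Time
(repetition is defined relative to *another* observed sequence). The
single-pass compression units retain exact expansion counts, so every
member reconstructs exactly from its group's primitive blocks; the basis
is the One-Time set plus one compressed representative (the shortest
member) per Repeating group. Timing is ignored for grouping: repetition
is a property of node sub-sequences.

## Null models

Three randomizations support structural controls:

* **Gilbert**: every ordered pair becomes an edge independently with
  `p = e / (N (N - 1))` — edge density preserved in expectation,
  everything else destroyed. The diagonal is excluded, consistent with
  the `N (N - 1)` denominator. Positions, polarities and class labels are
  retained; delays must be recomputed from positions.
* **Degree-preserving edge swap**: target exchange between two random
  edges, rejected if it would duplicate an edge or create a self-loop,
  reverted if it breaks weak connectedness; `|E|` attempts per iteration,
  10 iterations by default. Weak (not strong) connectivity is checked
  because strong connectivity is not guaranteed even for the original
  connectome. A `check_connectedness = FALSE` switch exposes the bare
  swap rule for disconnected inputs.
* **Embedded substitution**: the member-by-member block of the full
  network is replaced by a randomized subnetwork's edges while every edge
  with an endpoint outside the member set is preserved — the control that
  isolates a subcircuit's internal wiring while keeping its context. The
  "replace rows and columns" description taken literally would also erase
  member-to-outside edges; block substitution is used because preserving
  outside connectivity is the construction's stated purpose.

All randomness flows through a per-call seed; the caller's RNG state is
saved and restored, and reports record the seed and edge counts.

## Synthetic fixtures and what they do (and do not) show

The generator family in `make_fixture()` provides the study conditions
for every test: chains and diamonds pin down delay arithmetic and
multi-parent causality; the tapped two-node cycle is the smallest network
whose sequence set grows by one lap per period, exercising repetition;
the two-population fixture drives two labeled groups from one oscillator
through staggered taps, reproducing the alternating class-histogram motif
at toy scale; and seeded random geometric networks in a 50 × 1000 × 50 µm
worm-like box give heterogeneous position-derived delays. Deterministic
fixtures carry closed-form expected event tables, so the simulator is
checked against ground truth that is *derived*, never recorded from the
implementation. Brute-force oracles (backward path enumeration, naive
distinct-column counting) provide independent second routes for the
extraction and state-counting code.

What passing these tests does **not** show: that the model captures real
*C. elegans* physiology (graded potentials, gap junctions, synaptic
weights and attenuation are all absent by design), or that results at toy
scale transfer quantitatively to the 277-node connectome. Running the
workflow at connectome scale additionally requires the public
wiring/position compilations as an external input bundle, and the
resulting counts depend on conventions (delay rounding, counting
granularity, tie-breaks) that the package exposes as switches precisely
so discrepancies between runs are diagnosable.

## Problem sizes

Test and acceptance runs use sizes chosen to keep every property check
exhaustive: toy logs of 8–10 nodes over 40–60 steps for oracle
equivalence (100 seeds), 300-case compression fuzzing, 1000 Gilbert
draws at N = 50 for the density check, and a 50-node geometric network
at the full 6000-step horizon for the end-to-end workflow, with sequence
analysis over a 2000-step window (stepping down automatically if the
enumeration cap would be exceeded). These are the package's own choices
of scale; all are regenerated from seeds at run time.

## Limitations

* The engine is a plain R implementation; it is comfortable up to a few
  hundred nodes and tens of thousands of events, which covers the
  connectome use case but not large-scale surrogates.
* Sequence enumeration is exact, not sampled; on densely recurrent
  networks the cap will trigger and a shorter analysis window (or a
  tighter end-node set) is the intended response.
* The feed-circuit membership for subnetwork analyses is an input (a
  member list), not something the package infers.
* Determining a *sufficient* node set that reproduces a sequence set —
  as opposed to counting the necessary nodes observed in it — is out of
  scope.
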