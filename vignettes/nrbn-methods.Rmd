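---
title: "Modelling cell differentiation with noisy random Boolean networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cell differentiation with noisy random Boolean networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrbnkit)
```

## The model and its assumptions

`nrbnkit` implements the classical synchronous Boolean abstraction of a
gene regulatory network. Genes are binary (expressed / silent); each
gene has a Boolean function over an ordered list of regulators; all
genes update simultaneously at discrete time steps. The assumptions this
buys and costs are the standard ones: regulation is qualitative,
kinetics and time scales are collapsed into one clock, and intermediate
expression levels are invisible. What the abstraction keeps is exactly
what ensemble studies need — a finite state space of $2^N$
configurations whose deterministic dynamics must end in a state cycle
(an *attractor*), interpretable as a stable gene activation pattern.

Truth tables are stored with a fixed row convention: the row index for
regulator values $v$ is the integer with binary digits $v$ in input
order, first-listed regulator most significant. The same convention
orders state encodings (first gene = most significant bit), which gives
attractors a canonical form: the rotation starting at the
lexicographically smallest state. Zero-input genes are legal constants
(a one-row table); augmentation and knockouts can strand genes without
regulators, so refusing them would make those operations partial.
Self-regulation is accepted.

Knockouts and knock-ins are *clamp overrides*, not function rewrites:
a clamped gene ignores its function and holds its forced value, and the
wild-type function is recoverable by releasing the clamp. This makes a
40-gene knockout screen 40 reversible experiments on one object.

Noise enters as transient single-gene *flips*. The semantics is pinned
by a worked example in the test suite: a flip applied in state $s$
takes effect together with one synchronous update — the flipped gene is
forced to $1 - s_i$ while every other gene updates from $s$ normally —
and the forced value is held for `duration` updates (default 1); the
dynamics then relaxes freely from the release state. Holding (rather
than re-inverting) is the only reading under which `duration > 1`
differs from repeated length-1 flips.

## From flips to differentiation trees

For every attractor $a$, every cycle state (phase), and every target
gene, a flip experiment is run and its destination attractor recorded.
Row-normalizing the counts gives the attractor transition matrix; its
rows sum to one whenever at least one experiment in the row resolved,
and counts plus unresolved experiments always equal phases × targets —
both identities are enforced exactly in the tests.

A sampled atlas can be incomplete, so a relaxation may land in a cycle
the atlas does not contain. The default policy extends the atlas (with
a warning) and runs flip experiments for the appended attractors too, so
the matrix stays square and row-stochastic; a strict mode instead counts
such experiments as unresolved. Silently assigning them to the nearest
known attractor would bias the matrix, which is why that option does not
exist.

Threshold ergodic sets are formalized as the **terminal strongly
connected components** of the ATM after removing transitions with
probability strictly below $\delta$ — sets the dynamics can wander
within but not leave. The strict inequality makes $\delta = 0$ keep
every transition (one stem-like TES containing all attractors, when the
ATM is connected), and $\delta = 1$ keep only certain transitions.
Attractors in non-terminal components are transient at that threshold.
Self-loops are pruned by the same rule but never affect component
membership.

Sweeping an increasing threshold sequence yields one TES partition per
level; TESs of consecutive levels are connected by attractor-set
inclusion into a rooted tree. Two choices needed pinning:

* a TES identical at consecutive levels persists as the same tree node
  (no unary chains), so tree depth reflects actual splits;
* a TES with no containing parent — possible when a transient attractor
  becomes its own TES at a higher threshold — is attached to the parent
  of maximal overlap, or opens a new root when it overlaps nothing;
  multi-root results are joined under a flagged virtual root. Both cases
  are logged in the tree's `notes` attribute rather than hidden, because
  they violate the clean refinement picture and a user matching trees
  should know.

Trees are compared only through their shape table $n_x(k, l)$ — the
number of nodes at depth $l$ with $k$ children — summed as an $L_1$
distance over all $(k, l)$ up to the maxima of both trees. Labels never
enter the distance; attractor sets are carried as annotations for
inspection only. Because it is a sum of coordinate-wise absolute
differences, the distance is symmetric, zero exactly on equal shape
tables, and satisfies the triangle inequality; the tests verify this and
equality with a naive two-pass reimplementation on 1000 random pairs.

The *representative tree* of a network is the modal shape over sampled
threshold combinations of a given depth, with ties broken by smaller
node count and then lexicographic shape key — an arbitrary but
deterministic rule, chosen so reruns are reproducible.

## Generators and the study conditions

Five topology schemes are provided. Erdos-Renyi places exactly the
requested number of ordered pairs uniformly; fixed-in-degree gives every
gene exactly $K$ regulators; preferential attachment builds the
undirected scale-free skeleton and orients each edge uniformly at
random; the power-law scheme samples each gene's in-degree from a
discrete power law truncated to $[1, N-1]$ (total edge count therefore
stochastic under this mode); the small-world scheme is generated
directly as a *directed* ring lattice (each gene receives edges from its
$K$ ring predecessors) with per-edge source rewiring, so that rewiring
probability 0 returns the lattice exactly — a deliberate departure from
orienting an undirected skeleton, which could not satisfy that
degeneracy. Multi-edges are forbidden throughout (a regulator appears
once per function); self-loops are off by default.

Function schemes: *bias-random* draws each table bit independently with
probability `bias` of being 1; *canalyzing* designates one input/value
pair that alone forces the output (the canalyzing-inhibitor pattern,
forcing output 0 when the input is 1, is the standard Boolean reading of
a miRNA silencing its target) and fills other rows bias-randomly;
*logic* builds a random AND/OR/NOT expression in which every regulator
appears once, leaves negated with probability 0.3, compiled to a table.
Named regime presets pair connectivity and bias: ordered ($K=2, b=0.3$),
critical ($K=2, b=0.5$), chaotic ($K=3, b=0.5$), plus a lower-bias
chaotic variant ($K=3, b=0.3$).

Augmentation extends a core of $n$ genes / $m$ interactions to target
sizes $N, M$ by adding exactly $N-n$ genes and $M-m$ interactions. New
edges may run new–new, new–core or core–new, but never core–core, so
restricting the result to the core reproduces the core edge set exactly
(a `protect_core` flag additionally forbids new in-edges on core genes).
When a core gene gains $j$ new inputs its table is extended by the
*duplicate-then-bias* policy: replicate across the $2^j$ new-input
combinations, then resample every row in which at least one new input is
active — new edges are functional, yet the behaviour with all new inputs
off equals the original function exactly. A *silent* policy (pure
duplication, new inputs non-functional) is selectable. Small-world
placement is refused for augmentation: a ring lattice over added genes
has no principled reading that hits an arbitrary target edge count.

The bundled 40-gene / 51-interaction core is **synthetic**: an
Erdos-Renyi wiring with bias-0.5 functions from a fixed seed, standing
in for a curated signalling core of that size whose published wiring is
not redistributed here. It fixes the problem shape (40 genes, 51
interactions, ER augmentation to 200 genes / 400 edges at bias 0.5,
average connectivity 2) without claiming biological identity.

## Numerical choices and budgets

* Attractor search: exhaustive mode enumerates all $2^N$ states and is
  refused above a 20-gene cap; sampled mode draws initial states
  uniformly **with replacement** (the only scalable reading at large
  $N$), without-replacement being available below the cap. Sampling is
  sequential, so a longer run's sample extends a shorter run's under the
  same seed and discovered attractors can only accumulate.
* Per-trajectory update budget `max_steps = 1000`. Trajectories that do
  not close are counted as unresolved — never dropped, never assigned.
* Cycle detection is an exact per-trajectory hash of visited states
  (recovering the full cycle and entry point in one pass), with a
  global state-to-attractor memo shared within a search call; the memo
  is capped at $2 \times 10^6$ states to bound memory.
* Flip experiments enumerate all phases × all genes by default; for
  large networks a per-attractor phase cap (sampled without replacement,
  seeded) is the budget knob, and it is what batch sessions use
  (default cap 8).
* Threshold combinations for representative trees and matching are
  enumerated exhaustively when few, otherwise sampled (seeded); batch
  sessions default to 50 samples at depth 4.
* Batch problem sizes used by the package's own acceptance tests:
  20-network and 60-network ensembles of 200 genes / 400 edges, 500
  sampled initial states each — sizes at which a full
  augment–simulate–ATM–match chain completes in a few minutes on one
  CPU while still exercising every stage.

Avalanches compare the attractor reached by the wild type with the
attractor reached by the perturbed network from the same initial state.
When both cycles have equal length they are aligned at the cyclic
rotation minimizing total Hamming mismatch and a gene is affected iff
its column mismatches anywhere; when lengths differ, every gene is
affected unless it is frozen at the same value in both. The alignment
rule is arbitrary in the literature's verbal definition and is pinned
here for determinism. Sensitivity is the per-gene count of experiments
affecting it, so summed sensitivities equal summed avalanche sizes — an
exact identity used as a test.

## What the synthetic generator does and does not show

The generators emulate the *structural* conditions of ensemble GRN
studies: sizes, degree distributions, function biases, a preserved core.
They do not emulate real regulatory logic (no curated truth tables), no
transcriptional time scales, and no spatial or signalling context.
Passing tests therefore certify the machinery — exact counts, exact
conservation identities, oracle-equal dynamics, reproducible pipelines —
not any biological claim about a particular organism's differentiation.
Findings about which augmented networks match a target tree are
statements about random realizations under the configured conditions;
match counts vary with the seed and are deliberately not asserted.

## Known limitations

Synchronous deterministic updating only (no asynchronous or probabilistic
schedules, no multi-valued logic, no ODE semantics); single-gene flips
only; tree comparison is shape-based (no edit distance, no mapping of
TESs to named cell types); SBML-qual files are detected and refused
rather than parsed; sampled atlases are incomplete by construction, and
everything downstream (ATM, TESs, trees) inherits that sampling error —
the atlas-extension warning is the visible symptom, not a defect.
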