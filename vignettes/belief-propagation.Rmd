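---
title: "Qualitative belief propagation on signed interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Qualitative belief propagation on signed interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beliefnet)
```

## The modelling problem

Ecologists and environmental managers often know the *structure* of a system
— which species, habitats, human activities and revenue streams affect which
others, and in what direction — long before anyone can parameterise a
quantitative model of it. `beliefnet` works at that qualitative level. A
system is a directed network whose edges carry integer strengths from −4 to
4: the sign says whether the child node moves with or against the parent, and
the magnitude encodes how strong and how well-supported the interaction is. A
*scenario* assigns integer prior changes, on the same −4..4 scale, to the
nodes that are directly manipulated (a culled predator, a fishing ban); every
other node starts with no prior knowledge. The package then predicts the
direction and relative magnitude of change of every node.

The output is ordinal, not interval: a prediction of 3.1 for one node and
1.5 for another means the first is expected to change more, and in the
indicated directions — not that it changes twice as much. Scenarios can be
ranked against each other; their values cannot be subtracted meaningfully.

## The propagation model

All computation happens on the probability that a node *increases*. Integer
values map linearly to probabilities, `p = 0.5 + 0.1 v`, so −4 becomes 0.1,
0 becomes 0.5 and +4 becomes 0.9. The extremes are deliberately 0.1/0.9
rather than 0/1: in complex systems no change, and no interaction, is ever
certain. The probability of a decrease is always the complement `1 − p`, and
every stored probability is clamped to [0.1, 0.9] throughout.

One iteration updates every node synchronously from the previous state:

1. **Per-parent conditionals.** For each *informative* parent Y of node X —
   one whose current probability differs from 0.5 by more than 10⁻⁹ — the
   probability of X increasing given Y alone is
   `P(X⁺|Y) = e·q + (1 − e)(1 − q)`, where `e` is the edge probability and
   `q` the parent's current probability. The complement `1 − e` serves as
   the conditional given the parent decreases; this choice makes the entire
   pipeline odd-symmetric about 0.5, so negating a scenario exactly negates
   every prediction — the behaviour the ordinal interpretation requires.
   Parents at 0.5 contribute nothing and are excluded entirely (they may
   join in later iterations once they acquire a value).

2. **Two candidate posteriors.** With `c₁..cₙ` the conditionals of the n
   informative parents and `p` the node's current probability:
   a *prior-bearing* candidate `p + (1 − p) · mean(p·(cⱼ − 0.5))`, which
   lets evidence sharpen an existing prior, and an *interactions-only*
   candidate `mean(cⱼ)`, which lets strong evidence override an
   uninformative prior. Both are clamped to [0.1, 0.9]. Note that n counts
   informative parents only, never all inbound edges.

3. **Max-certainty selection.** The node takes whichever candidate lies
   further from 0.5. This selection is the package's defence against signal
   loss: a long chain fed only through the prior-bearing route would
   attenuate geometrically, whereas the interactions-only route lets a
   strong signal hop undiminished. Ties (within 10⁻⁹, so that mirror values
   like 0.3 and 0.7 tie regardless of floating-point representation) keep
   the prior-bearing candidate, preserving prior information when the
   evidence is equivocal.

4. **Pinning.** Nodes with nonzero scenario priors never become *less*
   certain than their initial prior: if an update moves a pinned node closer
   to 0.5 than its pin, the pin value is restored. A consequence users must
   know: feedback onto a directly manipulated node is invisible. To study,
   say, how a fishing ban's effect on lobster feeds back into illegal
   fishing pressure, represent the ban as an explicit policy node with a
   strong edge into the fishery node, rather than pinning the fishery node
   itself.

`bbn_predict()` runs four iterations by default. Because the update is
synchronous — every node reads only the previous iteration's state —
information travels exactly one edge per iteration, so four iterations reach
four hops from every manipulated node. The synchronous order also makes
results independent of the order nodes appear in the input file. Finally the
state maps back to the reporting scale by `change = 10 (p − 0.5)`; these
values are continuous, not integers.

A worked trace on the two-node chain A→B (edge +4, scenario A = +4): the
conditional is `0.9·0.9 + 0.1·0.1 = 0.82`; iteration 1 selects the
interactions-only 0.82 over the prior-bearing 0.58; iteration 2 the
prior-bearing route wins with `0.82 + 0.18·(0.82·0.32) = 0.8672`; two more
iterations hit the 0.9 ceiling, so both nodes report +4.

```{r chain-trace}
toys <- toy_fixtures()
bbn_predict(toys$chain2$network, toys$chain2$scenario)[[1]]$change
```

## Numerical choices

* The integer-to-probability map is computed as `(5 + v)/10`, algebraically
  identical to `0.5 + 0.1 v` but exact in floating point at all nine table
  values (`0.5 + 0.1·(−4)` lands one ulp below 0.1, outside the clamp).
* Clamping to [0.1, 0.9] is applied after every candidate-posterior
  computation; the prior-bearing formula can otherwise exceed 0.9 (e.g.
  prior 0.9, conditional 0.82 gives a raw 0.9288).
* "Informative" means `|p − 0.5| > 10⁻⁹`; the same tolerance breaks
  max-certainty ties.
* The prior-bearing formula multiplies the prior *inside* the evidence sum,
  exactly as the method defines it.
* Self-edges are rejected at parse time: the update semantics never read
  them, and silently accepting one would mislead model builders. Likewise a
  literal 0 cell in a network matrix is accepted as "no edge" but with a
  warning, since absence is the intended encoding. Decimal edge strengths
  are a hard validation error naming the offending cell, rather than
  undefined behaviour downstream.

## Bootstrap confidence intervals

Edge strengths are judgement calls, so `bbn_bootstrap()` quantifies how much
predictions depend on them. Each replicate perturbs `⌈10%⌉` of the edges —
selected uniformly without replacement — by an independent
Uniform(−0.1, +0.1) delta *on the probability scale*, clamps to [0.1, 0.9],
and reruns the prediction. Deltas may cross 0.5, flipping the sign of a weak
edge: that is the literal reading of "up to ±0.1" and is allowed. The point
estimate is always the unperturbed run, never a replicate mean. Per node,
the 95% interval trims 2.5% of replicate values from each tail by nearest
rank — the reported bounds are the extreme *surviving* replicates (with
1000 replicates, ranks 26 and 975). The bounds are raw empirical percentiles
of the replicate distribution; the alternative reading (offsets re-centred
on the point estimate) is not used. The default `boot_max = 1` runs no
replicates at all — fast exploration with no intervals. Perturbation happens
once per replicate, not once per iteration.

Near the ±4 saturation boundary the replicate distribution is one-sided
(perturbations can only weaken a clamped response), so intervals there
hug the point estimate from below; this is a property of the clamp, not an
error.

## Edge sensitivity

`bbn_sensitivity()` asks which edge strengths most affect chosen outcome
nodes (at most three is recommended; labels must match the network's
spelling exactly, and a misspelling fails with a nearest-label suggestion).
Each of `boot_max` replicates (default 1000) perturbs edges exactly as the
bootstrap does and additionally perturbs `⌈10%⌉` of node priors by
Uniform(−0.1, +0.1) on the probability scale — without this the replicates
of a neutral scenario would not differ at all, since perturbing an edge
whose parent sits at 0.5 changes nothing. Pinning still applies only to
nodes the driving scenario manipulates, at their perturbed values. A
replicate's impact is the summed absolute deviation of the outcome nodes'
changes from the unperturbed baseline (absolute, so increases and decreases
count alike). Every edge modified in a top-25% replicate (ties at the
cutoff included) scores one count; high-count edges are the ones whose
parameterisation deserves scrutiny. Edges with no directed path to any
outcome node can only score through ranking noise and sit far below on-path
edges.

## Stepwise dynamics (press and pulse)

`bbn_timeseries()` trades predictive robustness for a readable *order of
events*. It deliberately drops the signal-loss machinery — no prior-bearing
candidate, no max-certainty selection: at each timestep a node with
informative parents takes the plain mean of its per-parent conditionals,
and a node without any keeps its value. Its values therefore do **not**
match `bbn_predict()` and should not be used as predictions; timesteps are
ordinal ("before/after"), not units of time.

Column 1 of the output is the scenario itself. Under a **press**
disturbance each manipulated node is re-imposed after every step (restored
to the more certain of its computed value and its prior — the manipulation
is maintained; we do not additionally reinforce it, the more aggressive
reading of a sustained press). Under a **pulse** the injected prior acts as
a pin at timestep 1 only. From timestep 2 a manipulated node evolves like
any other node; in particular, a manipulated node with no informative
parents relaxes to neutral rather than keeping its injected value — the
injection, not the node's own dynamics, was holding it there, and without
this release a pulse at a source node would be indistinguishable from a
press. Downstream of the release, peaks travel one hop per step.

```{r pulse}
ts <- bbn_timeseries(toys$chain6$network, toys$chain6$scenario,
                     disturbance = "pulse")
round(ts$values, 2)
```

## Figures

Three renderers share igraph layouts ("grid" preserves input node order;
sphere, circle, random and Fruchterman–Reingold are igraph's):

* `bbn_visualise()` draws one network snapshot per timestep. Node shading is
  *ordinal by rank*, never value-scaled: the biggest increase is black, the
  smallest white, intermediate ranks interpolate linearly, ties share a
  shade, and an all-tied network is mid-grey. A node draws its outgoing
  edges only when its absolute change exceeds `threshold` (default 0.2 on
  the −4..4 scale; 4 suppresses every edge).
* `bbn_network_diagram()` draws the full network from the diagram dialect:
  node fill by colour class 1–4 (an Okabe–Ito colour-blind-safe palette:
  orange, sky blue, green, yellow), red arrows for negative interactions,
  black for positive, width proportional to `|strength| × arrow_scale`.
* `plot_predictions()` lays up to 12 scenarios out column-major (scenario 2
  below scenario 1), points at the unperturbed estimates with error bars
  when intervals are present.

Every drawing decision is computed by the pure functions `flow_frame()` and
`diagram_frame()`, which is where the semantics are tested; file output
overwrites silently by default, with `overwrite = FALSE` available because
silent overwriting is a known footgun.

## The synthetic generator and what the tests do (and do not) show

`random_network()` draws each ordered non-self node pair as an edge with
probability `density` (default 0.3, a typical connectance for small
qualitative webs) and uniform strengths from the full ±1..±4 set;
`random_scenario()` manipulates one node by default. Defaults of 5–10 nodes
keep enumeration and property tests fast; the engine itself has no size
limit. The generator emulates the *shape* of real model files — sparse
signed matrices, sparse scenarios — but none of the structure of real
ecosystems (no trophic ordering, no guilds, no reciprocity bias, no
correlation between edge sign and position). Passing tests therefore
certify the propagation algebra and its invariants (bounds, odd symmetry,
locality, oracle agreement on the full enumeration of ≤3-node networks with
strengths {−4, −2, 2, 4} and single ±4 priors), not ecological validity of
any particular model. The bundled `web8` fixture is an explicitly synthetic
web that only mimics structural motifs (top-down trophic edges, reciprocal
competition, a policy input and a revenue output); it stands in for no real
dataset.

Problem sizes used by the test-suite property loops — 1000 seeded
random-web cases for the bounds invariant, 200 for odd symmetry, the full
15,650-network small-web enumeration for oracle agreement, 500 replicates
for the sensitivity structure check — were chosen to make the sampling
arguments meaningful at interactive runtimes.

## Known limitations

* Outputs are ordinal; treating them as measured effect sizes is a misuse.
* Each edge acts independently on its child; there are no conditional
  probability tables, so interactions between parents (synergy, redundancy)
  cannot be expressed — structure the network to compensate.
* Feedback onto pinned nodes is invisible by design (see pinning above).
* The iteration count bounds the influence horizon: with the default 4,
  nodes more than four directed hops from every manipulated node report
  exactly 0.
* Edge strengths are integers by contract; continuous strengths enter only
  through the bootstrap's internal perturbation.
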