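# beliefnet

Qualitative belief-network prediction for signed interaction webs.

Many ecological and social-ecological questions arrive as a *structure*
without numbers: which species, habitats, human activities and revenue
streams affect which others, in what direction, and roughly how strongly.
`beliefnet` turns that structure into predictions. A system is a directed
network whose edges carry integer strengths in −4..4 (sign = direction of
the interaction, magnitude = strength and confidence); a *scenario* assigns
integer prior changes, on the same scale, only to the nodes directly
manipulated. The package propagates those changes through the network and
reports, for every node, an ordinal change value in [−4, 4].

It is aimed at ecologists, environmental managers and students who want
rapid hypothesis generation and scenario ranking from expert-elicited
networks — not at replacing parameterised quantitative models.

## The model in brief

Integer values map to probabilities of increase, `p = 0.5 + 0.1v` (so −4 →
0.1, 0 → 0.5, +4 → 0.9; bounds are 0.1/0.9 because nothing in a complex
system is certain). Each iteration, synchronously for every node X with
informative parents (parent probability ≠ 0.5):

* per parent Y: `P(X⁺|Y) = e·q + (1 − e)(1 − q)`, with `e` the edge
  probability and `q` the parent's probability;
* two candidate posteriors over the n informative parents:
  `p + (1 − p)·mean(p(cⱼ − 0.5))` (prior-bearing) and `mean(cⱼ)`
  (interactions-only), both clamped to [0.1, 0.9];
* the node takes whichever lies further from 0.5 (signal-loss prevention);
  nodes with nonzero scenario priors are additionally pinned — they never
  become less certain than their prior.

After four iterations (default; one hop of propagation each) the state maps
back to the reporting scale by `change = 10(p − 0.5)`. See
`vignette("belief-propagation")` for the full account, including the
bootstrap, sensitivity and press/pulse time-series procedures.

## Worked example

The bundled `synthetic_web8` fixture is a small invented web with a policy
node, a predator, two competing grazers, two algae, a filter feeder and a
revenue node. The scenario removes the predator (prior −4):

```r
library(beliefnet)
net <- read_network(system.file("extdata", "synthetic_web8_network.csv",
                                package = "beliefnet"))
sc  <- read_scenario(system.file("extdata",
                                 "synthetic_web8_scenario_predator_removal.csv",
                                 package = "beliefnet"),
                     net, name = "predator_removal")
bbn_bootstrap(net, sc, bootstrap_settings(boot_max = 1000, seed = 42))
```

```
Scenario: predator_removal 
         node change ci_low ci_high
       Policy  0.000  0.000   0.000
     Predator -4.000 -4.000  -4.000
      GrazerA  2.878  2.184   3.432
      GrazerB  1.791  1.181   2.540
    AlgaeTurf -1.821 -2.110  -1.506
  AlgaeCanopy  0.336  0.115   0.549
 FilterFeeder  0.051  0.007   0.094
      Revenue -3.609 -4.000  -2.900
```

Reading it: removing the predator (pinned at −4) releases both grazers
(+2.9 and +1.8 — ordinally, GrazerA responds more), grazing pressure drives
the turf algae down (−1.8), the canopy alga is weakly released (+0.3), and
revenue falls (−3.6) because the model ties it strongly to the predator
fishery. The `ci_*` columns are 95% bootstrap intervals from 1000 replicates
that each perturb 10% of edge probabilities by up to ±0.1: the point
estimates are the unperturbed run. `Policy` has no incoming edges and no
prior, so it stays exactly 0.

Which edge values deserve the most scrutiny if revenue is what we care
about?

```r
bbn_sensitivity(net, "Revenue", scenario = sc,
                settings = bootstrap_settings(boot_max = 1000, seed = 42))
```

```
Edge sensitivity over 1000 replicates; outcome node(s): Revenue 
       parent        child strength count
     Predator      Revenue        3    70
  AlgaeCanopy    AlgaeTurf       -2    47
      GrazerA      GrazerB       -2    43
```

(top rows shown) — the direct Predator→Revenue edge dominates, as it
should: replicates that perturbed it ended up in the top quartile of
outcome deviation far more often than any other edge.

## Command line

A thin executable wraps the same functions (installed under `exec/`):

```sh
beliefnet predict --network net.csv --scenario s1.csv --scenario s2.csv \
          --boot-max 1000 --seed 7 --values
beliefnet timeseries --network net.csv --scenario s1.csv --disturbance pulse
beliefnet visualise  --network net.csv --scenario s1.csv --threshold 0.05
beliefnet sensitivity --network net.csv --nodes "Limpet" --nodes "Green Algae"
beliefnet diagram --network diagram.csv --layout grid
beliefnet fixtures --dir toys
```

Defaults mirror the analysis functions: 4 iterations, `boot_max` 1 for
predict and 1000 for sensitivity, 5 timesteps, threshold 0.2, font scale
0.7, arrow scale 4.

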