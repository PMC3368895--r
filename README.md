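# swnet

Small-world network analysis of block-design working-memory fMRI.

`swnet` compares the topology of task-state functional brain networks
between a patient and a control group across the load levels of a blocked
working-memory task (Sternberg-style: 2 s prompt, 6 s encode, 38 s probe,
loads of 1/3/5 digits, three 6-minute runs). It is aimed at researchers who
have node-level BOLD time series (e.g. region or component averages) and
want the complete load-wise pipeline: band-pass filtering, block
truncation and load-wise concatenation, partial-correlation connectivity,
degree-uniform thresholding in a verified small-world regime, graph
metrics with rewiring-null small-worldness, and the group-by-load
statistics. Because patient recordings of this kind are rarely shareable,
the package also ships a synthetic cohort generator with a planted ground
truth, so the entire pipeline is testable end to end.

## The method in brief

Per subject and load, the concatenated encode+probe series (132 TRs over
105 nodes by default) yields a partial-correlation matrix: each pair of
nodes conditioned on all others via the (shrinkage-regularized) inverse
covariance, then Fisher-transformed, `z = atanh(r)`. Networks are
binarized at a *uniform degree*: the `E = round(K N / 2)` strongest edges
are kept, so every network in the cohort has the same density
(cost `= K/(N−1)`). On a binary network `G` with `N` nodes the measures are

- degree `K_i` and mean degree `K_net`; cost `K_net/(N−1)`;
- clustering `C_i = E_i / (K_i(K_i−1)/2)` (edges among neighbours), mean `C_net`;
- shortest path lengths `min{L_ij}` (infinite when disconnected),
  characteristic path length `L_net`;
- global efficiency `E_global = mean(1/L_ij)`;
- local efficiency `E_local` = mean global efficiency of each node's
  neighbour subgraph (node removed);
- small-worldness `sigma = (C_net/C_rand)/(L_net/L_rand)` averaged over 25
  degree-preserving Markov-chain rewired null networks; `sigma > 1` is
  small-world.

The analysis runs on a 16-degree observation grid inside the regime where
*every* network of the cohort is fully connected and has mean `sigma > 1`;
the regime is found by search and every grid point is verified. Statistics:
site-mean removal, two-way group-by-load ANOVA per measure, two-sample
t-tests per observation with Benjamini–Hochberg FDR across the 16
observations, one-tailed load-contrast tests, Pearson correlations with
mean correct-trial reaction time, and head-motion summaries.

## Worked example

```r
library(swnet)
cfg <- pipeline_config(n_per_group = 8)   # default study size is 35 per group
report <- run_pipeline(cfg, seed = 1)
print(report)
```

```
Small-world network analysis report
  16 subjects; observation grid 4.2..11.7 (16 degrees)
  regime degrees 4.2-11.8, verified min sigma 1.035
  group x load interaction p-values:
    C_net     3.163e-07
    L_net     0.001022
    E_local   5.196e-07
    E_global  6.63e-05
  load with the strongest averaged C_net group difference: L3
```

Reading this output: the regime search certified that at every degree of
the 16-point grid all 48 networks (16 subjects x 3 loads) are connected
and small-world (the worst mean sigma over the 25 rewired nulls is 1.035).
The two-way ANOVA finds a group-by-load interaction in every measure, and
the group differences concentrate at the medium load — the planted pattern
of the default synthetic cohort: the patient group's networks are rewired
(less clustered) at load 3 only, and reaction times are negatively coupled
to each subject's planted clustering. `summary(report)` makes the load
localisation explicit (averaged group-difference p-values of ~1e-8 at L3
against 0.02–0.63 at the unplanted loads in this draw);
`plot(report, measure = "C_net", load = "L3")` draws both groups' means
along the grid degrees.

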