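# lpamni — deterministic community detection by modularity-seeded label propagation

`lpamni` detects communities in undirected networks with **LPA-MNI**, a
deterministic variant of label propagation, and provides the stochastic
classical LPA as a baseline, the evaluation metrics needed to compare them
(modularity, NMI, AMI, community count, run-to-run entropy), and
planted-partition / LFR-style benchmark generators.

## The problem

Label propagation (LPA) is attractive for community detection because it is
near linear time and needs no preset community count, but it is randomized
three ways — visiting order, tie-breaking, and the label dynamics that
follow — so repeated runs on the same network return different partitions.
On small or weakly modular graphs it can collapse everything into one
community. LPA-MNI removes the randomness:

1. **Seeding.** A greedy modularity local-moving pass (nodes visited in
   descending degree centrality $DC(i) = k_i/(n-1)$, ties by first-seen
   order) produces rough communities. Each candidate move is scored by the
   incremental modularity gain
   $\Delta Q(i \to C) = k_{i,in}/m - \Sigma_{tot}\,k_i/(2m^2)$,
   which the test suite pins to the exact definition
   $Q_{\text{after}} - Q_{\text{before}}$ to $10^{-12}$.
2. **Propagation.** Each rough community contributes one shared label; nodes
   then adopt their neighbors' most frequent label asynchronously, in the
   same fixed order. Frequency ties are broken by the label held by the most
   important (highest-$DC$) neighbor, residual ties by the smallest label.

No step draws a random number, so the output is identical on every run.
See the vignette (`vignettes/lpa-mni-method.Rmd`) for the full method
description, parameter rationale, and numerical edge cases.

Intended audience: anyone analyzing modular structure in biological or
social networks who needs reproducible partitions, and methods developers
who want a tested, oracle-checked reference implementation of the
modularity-gain and chance-corrected agreement machinery.

## Worked example

Zachary's karate club (34 nodes, 78 edges, bundled as a fixture) against its
observed two-faction split:

```r
library(lpamni)

fx  <- load_fixture("karate")
res <- run_lpa_mni(fx$network)
res
#> <lpa_mni_result> 2 communities (rough seed: 9); 3 sweep(s)

community_count(res$membership)          # 2
modularity_q(fx$network, res$membership) # 0.3714661
nmi(res$membership, fx$truth)            # 1
ami(res$membership, fx$truth)            # 1
```

The detected partition matches the observed split exactly. And it is stable:
100 repeated runs give a constant metric sequence,

```r
s <- stability_run(fx$network, "lpa-mni", runs = 100, truth = fx$truth)
sequence_entropy(s$Q)   # 0 bits
```

whereas the classical baseline scatters (on this machine,
`sequence_entropy` of the 100-run LPA modularity sequence is about 3.9
bits, and on the bundled two-clique bridge graph `fig2_sample` a few
percent of LPA seeds merge everything into a single community, while
`run_lpa_mni` always returns the two cliques).

Benchmark sweep (planted partition, 128 nodes, 4 blocks of 32, expected
degree 16, `mixing` = fraction of a node's links going outside its block):

```r
sw <- sweep_benchmark("gn", mixing = seq(0.1, 0.6, 0.1),
                      replicates = 5, seed = 1)
aggregate(nmi ~ algorithm + mixing, sw, mean)
```

LPA-MNI holds NMI = 1.0 at mixing 0.1 and stays high through 0.4; the
stochastic baseline collapses around 0.4–0.5.

## Command line

`exec/lpamni` exposes the same operations without writing R:

```sh
exec/lpamni detect --input network.edgelist --algorithm lpa-mni \
    --truth truth.tsv --out-membership memb.tsv --out-metrics metrics.json
exec/lpamni stability --input network.edgelist --runs 100 --seed 1
exec/lpamni eval --a memb_a.tsv --b memb_b.tsv
exec/lpamni benchmark --type gn --mixing 0.1,0.3,0.5 --replicates 5
exec/lpamni fixtures --name karate --dir ./out
```

Inputs are whitespace edge lists or GML (`--format gml` or a `.gml`
extension); memberships are two-column TSV; metrics are written as JSON.

## Layout

| Path | Contents |
|---|---|
| `R/network.R`, `R/fixtures.R` | graph container, I/O (edge list, GML), degree centrality, bundled fixtures |
| `R/metrics.R` | modularity, NMI, AMI (exact hypergeometric E[MI]), community count, sequence entropy |
| `R/lpa.R` | stochastic LPA baseline and `stability_run()` |
| `R/lpa_mni.R` | incremental modularity aggregates, `delta_q()`, rough phase, deterministic propagation |
| `R/benchmarks.R` | planted-partition and LFR-style generators, `sweep_benchmark()` |
| `R/cli.R`, `exec/lpamni` | command-line entry points |
| `tests/testthat/` | per-module tests, independent oracles, acceptance blocks |
| `vignettes/lpa-mni-method.Rmd` | methods description and design rationale |
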