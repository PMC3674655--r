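---
title: "Shortest-path betweenness for disease gene prioritization: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shortest-path betweenness for disease gene prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathbetween)
library(dplyr)
```

## The method

`pathbetween` implements a shortest-path approach to prioritizing disease
genes in a confidence-weighted protein–protein interaction (PPI) network.
The inputs are a STRING-style edge list — protein pairs with an integer
combined confidence score $s \in [1, 999]$ — and a set of disease *seed
genes* (typically members of curated disease pathways), mapped to their
protein identifiers.

The procedure is:

1. **Network construction.** Each interaction becomes an undirected edge
   with traversal cost $c = 1000 - s$, so stronger interactions are cheaper
   to traverse. The score-to-cost transform is configurable; the linear
   default maps the score scale onto strictly positive integer costs with
   "smaller weight = stronger interaction" semantics.
2. **Seed resolution.** Seed gene symbols are mapped (one-to-many) to
   protein identifiers and restricted to network nodes. Pair enumeration
   downstream runs over *resolved proteins*, so $m$ resolved proteins give
   $\binom{m}{2}$ pairs — e.g. 54 seed genes resolving to 59 proteins give
   1711 pairs.
3. **Path mining.** For every unordered pair of seed proteins, one
   minimum-cost path is computed with Dijkstra's algorithm. Among equal-cost
   optima the lexicographically smallest node sequence (under sorted protein
   identifiers) is returned, making results fully deterministic.
   Unreachable pairs are recorded and skipped, not errors: genome-scale
   networks can be disconnected.
4. **Path-occurrence betweenness.** Every gene is scored by the number of
   mined paths on whose *interior* it lies (endpoints excluded). This is a
   path-occurrence tally over seed pairs only — not classical normalized
   betweenness centrality. Seed genes are dropped from the candidate table
   by default (`include_seeds = FALSE`), so it lists non-seed "path genes".
5. **Permutation significance.** For each of `n_perm` replicates (2000 by
   default) a random seed set of the same size is drawn uniformly without
   replacement from the network's nodes, paths are re-mined, and counts
   re-tallied. A candidate's p-value is the fraction of replicates whose
   count **strictly exceeds** the observed count. Candidates with raw
   $p < \alpha$ (default 0.05, no multiplicity correction — a
   Benjamini–Hochberg column is emitted as supplementary output only) are
   selected.
6. **Evaluation statistics.** Candidate sets are benchmarked by (a) the
   hypergeometric overlap test against a reference cancer-gene list, (b)
   Fisher's exact comparison of two candidate sets' reference overlaps, and
   (c) similarity of Gene Ontology *functional profiles* — vectors of
   $-\log_{10}$ per-term enrichment p-values — compared by Pearson
   correlation.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_score` | 0 | minimum STRING score kept at load (no filtering by default) |
| `cost_transform` | $1000 - s$ | score-to-cost map; must be strictly positive and decreasing |
| `n_perm` | 2000 | permutation replicates; p-values are multiples of `1/n_perm` |
| `alpha` | 0.05 | raw selection threshold, strict inequality |
| `background_n` | 20000 | background gene count for the overlap test (protein-coding genome) |
| reference size | 742 | size of the curated cancer-gene list used in the worked comparisons |
| profile cap | 300 | ceiling on $-\log_{10} p$ values (the magnitude of the smallest positive normal double) |

## Statistical conventions

**Overlap tail.** The hypergeometric overlap test uses the *strictly
greater* upper tail $P(X > k)$ by default. This convention reproduces all
four published candidate-versus-reference p-values from their printed
inputs ($n$, $k$, $K = 742$, $N = 20000$); the inclusive tail
$P(X \ge k)$ does not, and is exposed as an option.

**Fisher cells.** `compare_sets_fisher()` builds its default $2\times 2$
table from the per-set *(overlap, set size)* cells — the construction that
reproduces the published comparison p-values from the printed table
columns. Note this double-counts the overlap inside the set-size column;
the statistically orthodox *(overlap, non-overlap)* construction is
available via `cells = "complement"` and gives somewhat smaller p-values
(e.g. 1.56e-3 versus 3.86e-3 on the worked NSCLC comparison). Both are
two-sided by the minimum-likelihood convention of `stats::fisher.test`.

**Enrichment tail.** Per-term enrichment for functional profiles uses the
inclusive tail $P(X \ge k)$: a term fully contained in the query set then
has a finite $-\log_{10} p$, which a strict tail would send to infinity.

**Strict-exceedance permutation p.** Following the selection rule, no
pseudocount is added, so $p = 0$ is attainable and should be read as
$< 1/\texttt{n\_perm}$. Two consequences worth knowing:

- *Discreteness.* $p = S(\text{obs})$ with $S(x) = P(B > x)$ estimated
  from replicates. Where the null count distribution has large atoms —
  in particular $P(B = 0)$ for peripheral genes — the p-value is far from
  uniform under the null: a gene that appears on even one observed path
  may receive $p \le P(B > 1)$, which can sit below $\alpha$. The p-value
  is approximately uniform only where the count distribution is rich
  (well-connected genes). The package's calibration experiment therefore
  evaluates uniformity at high-degree candidates, with the candidate
  excluded from both the observed and the replicate seed draws so the two
  are identically conditioned; mixing the two conditionings (candidate
  never a seed when observed, but sampleable as a seed in replicates)
  installs an artificial atom of size `seed_size / n_nodes` in the null.
- *Selection effect.* The pipeline tests only genes already observed on at
  least one path, which tilts raw p-values anti-conservative for marginal
  genes. The emitted BH column does not repair this; it is a
  multiplicity adjustment, not a selection adjustment.

## The synthetic generator

`generate_network()` draws a connected preferential-attachment topology
(PPI degree distributions are heavy-tailed; an Erdős–Rényi alternative is
included for null experiments) and assigns integer scores, by default
uniform on 150–999 — STRING's practical range above its common 150 floor.
`plant_connectors()` wires each of `n_connectors` nodes to
$\lceil \text{attach\_fraction} \cdot n_\text{seeds} \rceil$ random seeds
at score 999 (cost 1), so planted connectors lie on many seed-pair shortest
paths; it also emits a gene–protein map in which seed genes may map to two
proteins each, exercising one-to-many resolution.
`generate_annotation()` plants enriched term blocks for designated gene
sets, and `generate_reference_list()` draws reference lists with an exact,
controlled overlap. Every generator is a pure function of its parameters
and `rng_seed`.

What the generator does *not* emulate: evidence-channel structure in
STRING scores, correlated annotations along the GO graph, protein
complexes/cliques, and literature bias in reference lists. Passing the
recovery experiments therefore demonstrates the machinery and the
statistic's behaviour under a clean planted model, not performance on real
interactomes.

## Behaviour under planted signal: two honest caveats

Simulation at the package's default planted settings (500 nodes, 20 seeds,
3 connectors at `attach_fraction = 0.5`, 500 replicates) shows two
systematic effects that temper idealised expectations:

- *Tie concentration among overlapping connectors.* A seed pair covered by
  two planted connectors has two equal-cost routes; the deterministic
  single-path tie-break awards all such pairs to one of them (the
  lexicographically smallest). Competing connectors therefore split
  observed counts unevenly, and the disadvantaged connector — whose
  permutation null is simultaneously *inflated* by its own planted cost-1
  edges, which stay in the network during permutation — can miss the 0.05
  cutoff. Measured recovery at these settings is roughly three quarters of
  planted connectors rather than all of them.
- *Seed-gateway genes.* Each seed's cheapest edge into the network core
  places its neighbour on nearly all of that seed's pairs' paths
  (counts near $n_\text{seeds} - 1$), while random replicate seeds have
  different gateways — so gateway genes earn small p-values. Against
  planted-connector ground truth they count as false positives (about a
  third of non-planted path genes at the default settings), but they are
  genuinely *seed-specific* path genes: the statistic is answering exactly
  the question it was designed to answer.

Both effects are properties of the method as specified (single path per
pair; permutation over seeds with the network fixed), not implementation
artifacts; the acceptance suite reports them as measured.

## Numerical and degenerate-input choices

- Costs from the default transform are integers, so path-cost comparisons
  are exact; under custom real-valued transforms, co-optimality in path
  reconstruction is judged with a relative tolerance of $10^{-9}$.
- Empty edge lists build an empty network with a warning; malformed rows
  and out-of-range scores fail with the offending line number; duplicate
  edges keep the maximum score; self-loops are dropped with a message.
- A gene resolving to zero in-network proteins is reported; a seed *list*
  resolving to zero proteins is an error.
- Zero-variance functional profiles make Pearson correlation undefined and
  raise an error rather than returning `NA`.
- All hypergeometric tails are computed by `stats::phyper`, which is
  stable in the parameter ranges used here (no underflow to zero for the
  worked examples).

## Problem sizes used by the test and acceptance suites

Unit tests run on graphs of 4–800 nodes with exhaustive-enumeration
oracles confined to at most 8 nodes. The calibration experiment uses a
300-node network, seed size 54, 200 trials of 200 replicates; the recovery
experiment uses 20 scenarios of 500 nodes with 500 replicates each. These
sizes give stable statistics for the stochastic checks while keeping a
full run of the suite inside a few minutes on one core; the pipeline
itself scales to STRING-sized networks since mining is
$O(m \cdot E \log V)$ for $m$ seeds plus one walk per pair.

## Known limitations

- One path per pair: co-optimal path multiplicity is collapsed by the
  lexicographic tie-break (reproducible, but arbitrary as biology).
- The permutation null fixes the network and randomizes seeds only; hub
  genes and planted high-confidence structure shape the null.
- No correction for testing only observed path genes (see above).
- GO aspects are pooled unless the annotation table carries an aspect
  column and a filter is requested; no semantic-similarity measure over
  the GO graph is attempted.
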