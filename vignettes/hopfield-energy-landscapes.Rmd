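---
title: "Hopfield energy landscapes of differentiation potency: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hopfield energy landscapes of differentiation potency: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hopscape)
```

## The model

A differentiating cell population can be pictured as marbles rolling down a
Waddington landscape: totipotent cells sit high, lineage-committed cells sit
in low valleys. `hopscape` makes that elevation quantitative with a Hopfield
network built on gene states.

Each cell is reduced to a binary vector over $M$ highly variable genes
(HVGs): gene $i$ is in state $g_i = 1$ when its expression is at or above
its own mean across cells, $0$ otherwise. A set of observed states
$\{g^\mu\}_{\mu=1..p}$ is stored as attractors through the Hebbian rule

$$ w_{ij} = \sum_{\mu=1}^{p} g_i^\mu\, g_j^\mu \quad (i \ne j), \qquad
   w_{ii} = 0, $$

and a state $s$ is scored by the Hopfield energy

$$ E(s) = -\tfrac{1}{2} \sum_{i \ne j} w_{ij}\, s_i s_j . $$

For the single-cell protocol each cell is its own attractor ($p = 1$,
`grouping = "self"`); for bulk samples, all samples sharing a phenotype
label form the attractor set (`grouping = "phenotype"`, with optional
division of $w$ by $p$ so group size does not inflate $|E|$). In the
`"zero-one"` convention and $p = 1$, the self-energy collapses to the
closed form $E = -k(k-1)/2$ with $k$ the number of active genes — a cell
expressing many of its HVGs above their means sits deep in its own
attractor. Under the generator below, and in staged expression data with
progressive module activation, $k$ grows along the differentiation path,
so energy falls monotonically with stage and rises along reprogramming:
energy is the elevation proxy.

### Two state conventions

Two encodings of a binary state coexist deliberately:

* **zero-one** (`0/1`, the default for scoring): the literal gene-state
  encoding. Energies are integers and reproduce the magnitude regime one
  obtains when the stored pattern is the scored state itself.
* **spin** (`-1/+1`, the default for dynamics): with `0/1` states the local
  field $h_i = \sum_j w_{ij} s_j$ is a sum of nonnegative terms, so the
  threshold update $s_i \leftarrow \mathrm{sgn}(h_i)$ would fix every gene
  at 1 — the dynamics are degenerate. The classic spin encoding removes the
  degeneracy and gives the textbook guarantees: stored patterns (and their
  global complements) are fixed points, and asynchronous updates never
  increase the energy.

`sgn(0)` maps to the up-state 1 everywhere, mirroring the "$\ge 0$" branch
of the binarization rule, so ties are resolved identically at every layer.
Asynchronous sweeps visit genes in a seeded random permutation; the seed is
a required, logged argument, making every trajectory reproducible.
Synchronous updates may enter period-2 cycles; `converge()` detects the
cycle and reports both states with `converged = FALSE` instead of erroring.

## Preprocessing choices

* **Z-scores** use the population standard deviation (denominator $N$).
  Binarization only consumes the sign, so the $N$ vs $N-1$ choice is
  immaterial to the states; fixing one makes byte-level reproducibility
  possible. Z-scores are not clipped to $[-1, 1]$: the sign is all that is
  used downstream.
* **Constant genes** ($\sigma = 0$) become all-zero z-rows and are flagged.
  Dimensions are preserved; under "$\ge 0 \to 1$" such genes binarize to
  the up-state, and the flag lets users drop them explicitly.
* **HVG ranking** is computed on the variance of `log1p(expression)`.
  Ranking genes *after* per-gene z-scoring would be degenerate — every
  non-constant gene then has variance exactly 1 — so variance must be taken
  on a pre-standardization scale. The log1p scale is the field's standard
  compromise between mean-variance coupling and outlier sensitivity; a
  `scale = "raw"` option is provided. The selection size is
  $\lceil \text{fraction} \times M_1 \rceil$ (0.05 is typical for bulk,
  0.10 for single-cell data), and ties at the cutoff break by ascending
  gene ID so selection is deterministic.

## State transitions

A transition from an old state $A$ to a new state $B$ is not a property of
either attractor alone; it uses the asymmetric coupling

$$ w'_{ij} = \sum_\mu g_i^{\mu B}\, g_j^{\mu A} \quad (i \ne j), $$

with the target state on the row (output) index and the source state on
the column (input) index. Iterating
$g_i \leftarrow \mathrm{sgn}(\sum_j w'_{ij} g_j)$ from $A$ under the spin
convention pulls the network toward $B$; every gene flip is logged with its
position in the update order.

### The mixing ladder

The energy profile *along* the transition is traced by decomposing it into
`steps` mixing steps (default 100): at step $s$, a random subset of
$\mathrm{round}(s/\text{steps} \times M)$ gene positions takes its state
from $B$, the rest stay at $A$. Which positions switch is random, so each
step's energy is averaged over `repeats` seeded node assignments (default
20) and reported as mean ± sd; an `exhaustive` flag enumerates all
$\binom{M}{n}$ assignments when $M$ is small. Step 0 is pure $A$ and step
$S$ pure $B$ by construction, for every seed.

The coupling evaluated at an intermediate step is a genuinely open design
point: the step energy uses $w'$ built, by default, from the mixed state
itself in both roles (`coupling_policy = "self"`). This choice makes each
step's energy the self-energy of the mixed network, which reduces
*exactly* to the symmetric attractor energy at both endpoints — a testable
identity that anchors the whole ladder. The alternative
(`"endpoint"`: target role fixed at $B$, source role the mixed state) is
available for sensitivity analysis.

### Importance scores

To rank genes by how much their flip drives the network toward a stable
state, gene $i$'s "connection pattern" in a network state is the signed
difference vector $a_{ij} = g_i - g_j$ over all partners $j$ (values in
$\{-1, 0, 1\}$, computed on 0/1 states). With $A_i^0$ the pattern in the
stable state and $A_i^1, A_i^2$ the patterns immediately before and after
gene $i$'s own flip,

$$ \mathrm{IS}_i = \frac{|A_i^2 \cap A_i^0| - |A_i^1 \cap A_i^0|}{M}, $$

where $|X \cap Y|$ counts positions where the two patterns agree (simple
matching). Three small ambiguities had to be fixed: the self position
$j = i$ (which always agrees) is excluded from the agreement counts by
default (`include_self = FALSE`) while the denominator stays $M$; genes
that never flip score 0; and a gene flipping several times is scored at
its last flip. Genes with $\mathrm{IS} > 0.1$ are flagged as retained
drivers. On planted transitions where $d$ genes separate $A$ from $B$, the
$d$ true drivers occupy the top-$d$ IS ranks and pass the filter
essentially always (20/20 seeded instances at $M = 50$, $d = 5$ in the
acceptance checks).

## Robustness and the landscape fit

Two perturbation protocols probe whether the stage-energy ordering is an
artifact of the exact gene set:

* **gene-subset** (default): rebuild the network from a random
  $\mathrm{round}(f \times M)$-gene subset of the HVGs;
* **expression-permutation**: permute a random $f$-fraction of genes'
  expression values across cells before the whole pipeline.

Both protocols appear in the literature this package serves, described
once by the perturbed quantity and once by the selected gene set; making
each a mode keeps both readings reproducible. Within each (fraction, seed)
run the per-stage mean energies are standardized — z-scored across stages
— so runs with very different gene counts (and hence energy magnitudes)
share one axis; `rank_preserved` records whether the stage ordering by
mean energy survived. The default fraction list
$\{0.1, 0.2, 0.4, 0.6, 0.8, 0.9\}$ spans mild to 90% disturbance.

`landscape_fit()` runs centred PCA on the z-scored HVG matrix (cells as
observations), orients PC1 to correlate positively with the stage index
when labels exist (PCA signs are arbitrary; $|R|$ is unaffected), and
reports the Pearson correlation between PC1 and per-cell energy plus a
least-squares polynomial fit of energy on PC1. Degree 3 is the default —
the lowest degree that can express the sigmoidal dip of a staged descent —
and is configurable. Constant energies raise an explicit
`undefined_correlation` flag rather than returning a silent `NaN`.

## The synthetic generator

`synthetic_spec()` describes stage-structured data with a known potency
ordering: the gene pool splits into `n_stages` activation modules of
`module_size` genes plus constant background; a cell at stage $t$ expresses
modules $1..t$ (differentiation) or $1..(n_\text{stages}-t+1)$
(reprogramming) at `active_level`, everything else at `base_level`, with
multiplicative lognormal noise (`sdlog = noise_sd`) and optional Bernoulli
dropout (off by default). Defaults — 5 stages × 40 cells, 2000 genes,
40-gene modules, levels 1 and 10, `noise_sd = 0.3` — are sized so that
top-10% HVG selection captures exactly the stage modules and the
above-mean HVG count grows by roughly one module per stage; these are the
conditions under which all simulation-based checks run.

What the generator emulates is the single property the energy model
consumes: a progressively growing (or shrinking) set of above-mean HVGs
along a staged process. What it does **not** emulate: library-size
variation, UMI/count sampling noise, zero inflation, batch effects,
partially overlapping or transient modules, or the mean-variance
relationship of real scRNA-seq counts. Passing tests therefore certify the
machinery — preprocessing, energy, ladders, drivers, robustness — under a
clean staged signal, not performance on any particular real dataset.

Two boundary behaviours of the generator are worth knowing. Module-1 genes
are active in *every* stage, so their binarization threshold sits at the
centre of their noise distribution and their states are near-Bernoulli(½);
similarly background genes never change level. Both are exactly the genes
with the lowest log1p variance, so an HVG fraction that matches the
informative module count excludes them — mirroring the role HVG selection
plays on real data. The driver-transition fixtures in the test suite pick
fractions that way on purpose.

## Numerical and interface choices

* All randomness (update orders, ladder assignments, subsets, generator
  noise) flows through explicit seeds; seeded helpers restore the caller's
  RNG state.
* Stage archetypes for the ladder workflow are per-gene majority votes over
  the stage's binarized cells, ties resolved to 1 (the `sgn(0)` rule again).
* Energies are computed by the quadratic form of the zero-diagonal weight
  matrix; integer inputs give exact integer energies, and per-flip energies
  during asynchronous sweeps are maintained by an exact incremental update
  (row plus column terms, so it also holds for asymmetric couplings).
* Dense TSV output formats values with `%.17g`, so a write/read round trip
  is bit-exact.
* Problem sizes in the checks: energies and recall at $M \le 200$;
  descent over 1,000 trials at $M = 50$; recall over 500 probes at
  $M = 100$; direction/robustness on the default 2000 × 200 generator
  output with 100 perturbation seeds; exhaustive ladder enumeration at
  $M \le 12$.

## Known limitations

* Asymmetric-coupling dynamics between states differing in more than about
  half of the network's genes can oscillate (the source-state overlap term
  changes sign mid-trajectory); `converge()` bounds the sweep count and
  reports non-convergence, but importance scores from such trajectories
  should not be trusted. In staged data this regime signals that the two
  states are too distant for a single-step transition model.
* Per-cell self-attractor energies depend on the cell only through its
  active-gene count $k$; cells with equal $k$ are indistinguishable. The
  phenotype grouping, which scores each cell against its group's pooled
  attractors, is the finer instrument when labels exist.
* Hopfield energy is a scalar stability proxy, not a physical energy, and
  the landscape is defined relative to the chosen HVG set; changing the
  HVG fraction rescales energies (the robustness scan quantifies how much
  the *ordering* survives such changes).
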