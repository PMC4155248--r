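---
title: "Gradient-basin coarse graining and exact macro-state kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gradient-basin coarse graining and exact macro-state kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(basinflood)
```

## The model

An RNA molecule of sequence length $n$ folds through a discrete space of
secondary structures: sets of base pairs $(i, j)$ that are admissible
(A-U, G-C, G-U), pairwise disjoint, nested, and separated by a hairpin
loop of at least `min_loop = 3` unpaired bases.  `basinflood` treats this
space as a discrete energy landscape $(X, E, M)$: the micro-states $X$
are all structures of the sequence, $E$ is an energy function, and the
move set $M$ connects structures differing by exactly one base pair.
Dynamics are a discrete-time Metropolis chain at inverse temperature
$\beta$,

$$p_{x \to y} \;=\; \Delta^{-1}\,
  \min\bigl\{e^{-\beta\,[E(y) - E(x)]},\, 1\bigr\},
  \qquad y \in M(x),$$

normalized by $\Delta$, the largest neighborhood size in the landscape
(attained by the open chain: the number of admissible pairs).

Because $|X|$ grows exponentially with $n$, kinetics are studied on a
coarse-grained level.  The package uses the standard *gradient basin*
partition: every micro-state is assigned, by a steepest-descent walk, to
the local minimum it drains into, and each basin becomes one macro-state
$b$ with partition function $Z_b = \sum_{x \in F^{-1}(b)} w(x)$, where
$w(x) = e^{-\beta E(x)}$.  Macro-state transition probabilities follow
from summing all micro-transitions crossing a basin boundary: each
boundary edge contributes $\Delta^{-1} w(\text{higher endpoint})$ to the
symmetric transition-state partition function $Z_{\{b,c\}}$, and

$$q_{b \to c} \;=\; Z_{\{b,c\}} / Z_b .$$

This *exact* chain satisfies macro detailed balance
$Z_b\, q_{b\to c} = Z_c\, q_{c \to b}$ by construction.

### Degeneracy and the total order

Energy functions over discrete structures are heavily degenerate, so
"steepest descent" is ill-defined by energy alone.  All comparisons in
this package use a strict total order: energy first, ties broken by
byte-wise comparison of the dot-bracket encoding (`'('` < `')'` <
`'.'`).  This makes the descent map single-valued on plateaus, every
flood deterministic, and all outputs reproducible bit for bit.  The
comparator is a design choice; any fixed tie-break yields a valid
partition, but results on degenerate landscapes depend on it, so it is
fixed once and documented here.

## Three routes to the same decomposition

1. **Brute force** (`brute_force_macromodel`): enumerate $X$, gradient-walk
   every state, accumulate $Z_b$ and $Z_{\{b,c\}}$.  Transparent and
   general; the package's internal oracle.
2. **Energy-sorted global flooding** (`barriers_flood`): process states in
   ascending total order; a state's basin is a single lookup of its
   steepest-descent neighbor's basin, because that neighbor has always
   been processed already.  A state adjacent to two or more previously
   disconnected basin components records its energy as their *saddle*;
   the union-find merge history is the **barrier tree**.
3. **Local flooding** (`local_flood`, `discover_landscape`): the
   memory-frugal route.  One basin is enumerated at a time from its
   minimum, holding only the member set `D` and the sorted candidate set
   `T`; all $Z_{\{b,\cdot\}}$ contributions are collected on the fly, and
   foreign states are assigned by explicit gradient walks.  Whole
   landscapes are discovered by a worklist over newly seen adjacent
   minima.  Per-basin memory is `members + contacts` against $|X|$ for
   global hashing (`memory_ratio`); each transition partition function is
   obtained independently from both sides and cross-checked at
   $10^{-6}$ relative tolerance before assembly.

The three routes are algorithmically independent in their assignment
logic; the test suite requires them to agree exactly (within $10^{-9}$
relative on partition functions) on every fixture landscape.  One
subtlety in the local flood deserves note: the membership test and the
handling of transitions leaving the basin are both driven by the total
order, so that when a candidate $x$ is popped, every basin member below
$x$ is provably already in `D`.  The published description of this
algorithm prints the leaving-transition condition with an extra
membership requirement that would produce self-transitions; the
implementation uses the only reading consistent with the transition-state
definition, and the oracle-equivalence tests arbitrate.

### Memory accounting

`contacts_count` counts the distinct foreign states a flood ever holds:
candidates that entered `T` plus the lower endpoints of transitions
leaving the basin.  (Counting only `T` entries would miss foreign states
reached downhill and make the canonical two-basin worked example
inconsistent.)  Member states that pass through `T` are not double
counted.

## Kinetic models and their comparison

Three row-stochastic chains over the basins are built:

* **exact** — $q_{b\to c} = Z_{\{b,c\}}/Z_b$ (zero for non-adjacent basins);
* **barrier** — an Arrhenius-type model from the barrier tree,
  $a_{b \to c} = A\, e^{-\beta\,(E(b,c) - E(\min_b))}$ with $E(b,c)$ the
  saddle energy; *every* pair of basins is connected, whether or not a
  direct boundary exists;
* **merged** — Arrhenius values masked to the exact adjacency topology,
  separating the barrier model's loss of *precision* from its loss of
  *topology*.

The pre-exponential factor $A$ is physically unknown.  With
`A = "auto"` it is set to $0.99 / \max_b \sum_{c \ne b} e^{-\beta(E(b,c)-E_b)}$
so every diagonal stays positive.  The choice is immaterial for model
comparison: scaling $A$ makes the chain uniformly lazier, multiplying
every first-passage time by the same constant, so FPT *ranks* are
invariant (a tested property).

Model quality is measured through mean first-passage times
$\tau(b, t) = 1 + \sum_c q_{b\to c}\, \tau(c, t)$, $\tau(t,t) = 0$, from
the basin of the unfolded (open-chain) state to every other basin, and
summarized as the Spearman rank correlation of approximate against exact
FPTs.  `first_passage_times` solves the absorbing linear system per
target; `compare_models` needs *all* targets from one start and instead
uses one fundamental-matrix solve per chain,
$Z = (I - P + \mathbf{1}\pi')^{-1}$ and
$\tau(s, t) = (Z_{tt} - Z_{st})/\pi_t$, with the stationary vector known
in closed form for all three chains by detailed balance ($\pi_b \propto
Z_b$ exact; $\pi_b \propto e^{-\beta E_b}$ barrier/merged).  The two
routes agree to $10^{-7}$ on the test fixtures.  Targets with
non-finite FPT under either chain of a pair are excluded from the
correlation and counted in the report.

## Energy backends

The built-in backend (`simple_energy_backend`) is a deliberately minimal
additive model — each G-C pair $-3$, A-U $-2$, G-U $-1$, open chain $0$,
in arbitrary units with default $\beta = 1$.  It is *not* the Turner
nearest-neighbor model: it has no stacking, loop or entropic terms.  Its
virtues are determinism, dependency-freedom and hand-checkable energies.
Two behavioral consequences matter when interpreting results:

* every structure to which no pair can be added is a local minimum, so
  basin counts are far higher than under a physical model
  (roughly 13% of $|X|$ for uniform random 22-mers);
* the open chain is an energy *maximum*, so the "unfolded" start basin
  is the basin its gradient walk drains into, and the open-chain basin
  is small — in contrast to nearest-neighbor landscapes, where the
  unstructured state is itself a large, highly connected minimum.

The full nearest-neighbor model is available through
`vienna_energy_backend()` / `external_energy()`, which drive the
ViennaRNA `RNAeval` program (kcal/mol, 37 °C default,
$\beta = 1/kT \approx 1.62\ \mathrm{mol\,kcal^{-1}}$) and record the
program version in all outputs.  Absence of the program is a hard error,
never a silent fallback.

## Synthetic data

Toy landscapes (`chain_landscape`, `random_toy_landscape`, the TSV
reader) make every downstream number hand-checkable and are the oracle
substrate for the flooding algorithms.  Two canonical chains are used
throughout the documentation and tests: `c(0, 2, 1)` (two basins,
$Z_{B_0} = 1 + e^{-2}$, $Z_{\{B_0,B_2\}} = \tfrac12 e^{-2}$,
$q_{B_0 \to B_2} \approx 0.0596$, $\tau \approx 16.78$ steps) and
`c(0, 3, 1, 2, 0.5)` (three basins, saddles at 2 and 3).  Random toy
landscapes are connected (spanning tree plus uniform extra edges to a
target mean degree) with distinct uniform energies; exact ties are
generated separately where the tie-break logic itself is under test.
`random_rna_set` draws sequences with i.i.d. uniform base composition —
the defaults regenerate a 110-sequence set, 10 per length 25–35 nt.
These generators emulate the *distributional* properties of the
evaluation data (composition, connectivity, energy spread), not the
correlated energy surfaces of physical RNA; conclusions from passing
tests transfer to real data only at the level of algorithmic
correctness, not of biophysical numbers.

## Problem sizes and numerical choices

The package's own verification runs at desk scale, chosen so the whole
suite completes in minutes on one core:

* oracle equivalence on all structures of sequences up to 20 nt
  (hundreds to a few thousand states each) and on 50 random toy
  landscapes of 50–2000 states;
* the kinetic-model comparison on 10 random 22-nt sequences (1.8k–15k
  states, 500–2700 basins each).  22 nt is the largest length at which
  the worst-case basin count keeps the three dense fundamental-matrix
  solves (the $O(|B|^3)$ step) within a few GB of memory and seconds of
  time per sequence; under the built-in additive model, random 25-mers
  can already exceed 17000 basins, for which a single dense solve needs
  several gigabytes.
* memory-ratio statistics from full local-flooding discovery at lengths
  12, 16 and 20.

Further numerical choices: state enumeration is capped (default $10^6$
states, `basinflood.cap` option) with an explicit overflow error quoting
the count; gradient walks of foreign states during local flooding use a
bounded memoization cache (speed only, never results); chain rows must
sum to 1 within $10^{-12}$ and any negative diagonal is an internal
consistency error; saddle ties at one flood level are resolved by
processing order, i.e. by the total order of the merging states.

## Worked example

```{r example}
L <- rna_landscape("GGGAAACCC")      # built-in backend, beta = 1
fl <- barriers_flood(L)
fl$model
head(summary(fl$model), 3)
local_flood(L, "(((...)))")
```

The hairpin `(((...)))` at $-9$ anchors the dominant basin; the model
has 9 basins over 20 structures.  On a three-state toy chain the full
kinetic pipeline is visible at a glance:

```{r toy}
L2 <- chain_landscape(c(0, 3, 1, 2, 0.5))
compare_models(L2, start = "s0")
```

## Known limitations

* The built-in energy model is a stand-in with the caveats above;
  quantitative comparisons with nearest-neighbor results require the
  ViennaRNA backend and, for published-scale landscapes (30+ million
  states), hours of compute and the local-flooding route.
* Only the single base-pair add/remove move set is implemented; no
  shift moves, lonely-pair prohibition, dangling ends, pseudoknots or
  circular RNA.
* Kinetics are discrete-time with self-loops; continuous-time
  master-equation integration and spectral analysis are out of scope.
* The Arrhenius prefactor is not estimated; only rank-based comparisons
  are meaningful across models.
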