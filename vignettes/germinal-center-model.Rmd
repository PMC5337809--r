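---
title: "The gcrsim germinal-center model: mechanics, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The gcrsim germinal-center model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`gcrsim` simulates affinity maturation in a single germinal center (GC) as a
hybrid system: a deterministic set of ordinary differential equations, four
per subclone, interleaved every six hours with a stochastic somatic
hypermutation (SHM) step that creates and kills subclones. This vignette
explains the model and, more importantly, the choices made where the design
was genuinely open, so a user can judge what a given output does and does
not establish.

## The deterministic core

Each subclone $i$ has a fixed absolute affinity $\sigma_i$ (a µM-scaled
binding score; higher = stronger — it is *not* a dissociation constant) and
four continuous compartments: centroblasts $CB_i$ (dark zone,
proliferating), centrocytes $CC_i$ (light zone, under selection), memory
$M_i$ and plasma cells $P_i$:

$$\frac{dCB_i}{dt} = \rho_{CB}\,\frac{A^h}{CB_{tot}^h + A^h}\,CB_i
  + \eta_{CC\to CB}\,CC_i - (1 - S_d(\sigma_{rel,i}))\,\eta_{CB\to CC}\,CB_i$$

$$\frac{dCC_i}{dt} = (1 - S_d)\,\eta_{CB\to CC}\,CB_i - \eta_{CC\to CB}\,CC_i
  - (1 - S_a)\,\mu_{CC}\,CC_i - \eta_{CC\to M}\,CC_i - \eta_{CC\to P}\,\sigma_i\,CC_i$$

$$\frac{dM_i}{dt} = \eta_{CC\to M}\,CC_i - \mu_M M_i, \qquad
  \frac{dP_i}{dt} = \eta_{CC\to P}\,\sigma_i\,CC_i - \mu_P P_i$$

Antigen capture and T-cell help are not modeled as agents; both are folded
into sigmoidal survival signals of the *relative* affinity
$\sigma_{rel,i} = \sigma_i / \max_j \sigma_j$ over the living population:

$$S(\sigma_{rel}) = \frac{\sigma_{rel}^{\,n}}{k^n + \sigma_{rel}^{\,n}}$$

with $(k_d, n_d) = (0.06, 1)$ for differentiation and
$(k_a, n_a) = (0.1, 4)$ for apoptosis. Multiplying the CB→CC rate and the
CC apoptosis rate by $(1-S)$ lets strong binders linger in the dark zone
and protects their centrocytes. Because the scaling is by the population
maximum, the arrival of a better binder *lowers* everyone else's signals —
this is the competitive engine of the model. Plasma-cell output scales with
the absolute affinity, keeping plasma production low early.

Defaults (per day): $\rho_{CB} = 4$, $\eta_{CB\to CC} = 6$,
$\eta_{CC\to CB} = 1$, $\eta_{CC\to M} = 1$, $\eta_{CC\to P} = 0.1$ per µM,
$\mu_{CC} = 4$, $\mu_P = 0.25$, $\mu_M = 0.01$; capacity $A = 8000$ cells
with Hill exponent $h = 20$. The density factor is evaluated in log space
(`plogis(-h log(CB_tot/A))`): $8000^{20}$ is representable, but the
stable form costs nothing and holds for any configuration.

## Schedule

The reaction starts at day 0 with three founder centroblasts of distinct
low affinities (0.1, 0.3, 0.5 µM — chosen distinct to seed competition) and
ends at day 21; GC shutdown is not modeled. For the first four days both
signals are clamped at 0.9, producing the monoclonal expansion to roughly
10⁴ cells. SHM begins at the first step starting at day 4; the same
boundary removes the clamp. Each step integrates the ODEs over 0.25 day
(one CB division) with signals frozen at their interval-start values —
affinities only change at discrete SHM events, so freezing the scaling
maximum within an interval is the natural operator splitting. After SHM,
any subclone with $CB + CC < 0.1$ cells is removed together with its
equations; its memory and plasma tallies are accumulated as GC output
rather than deleted, since those cells have already been exported.

## The mutation engine

At each division a daughter cell draws $m \sim \mathrm{Poisson}(0.6)$
mutations (a 600-nt receptor at $10^{-3}$ per bp per division). Each
mutation takes one path through a fate tree: framework region (FWR) with
probability `p_fwr`, else CDR; replacement with `p_repl_fwr` / `p_repl_cdr`;
an FWR replacement is lethal with `p_lethal_fwr`; a CDR replacement changes
affinity with `p_affinity_cdr`, else is neutral. Any lethal outcome kills
the cell (parent CB − 1). Otherwise, at the *nucleotide* tracking level any
mutated daughter founds a new subclone (CB = 1, parent CB − 1); at the
*peptide* level only daughters with a CDR replacement do. The tree
probabilities are **not** established quantities: the defaults
(0.75, 0.75, 0.75, 0.5, 0.5) are plausibility choices in the style of
classic clonal-selection simulations and should be treated as tunable
configuration, which is why the package exposes all five.

**Which cells mutate (the key structural choice).** Mapping continuous ODE
counts onto discrete mutating cells admits several readings, and the
package implements three (`shm$mode`):

* `"per_division"` (default): SHM is replication-coupled. The integrator
  accumulates the births $\int \rho_{CB} f(CB_{tot})\, CB_i\, dt$ over the
  interval, and the daughters at risk of mutation in subclone $i$ are
  $\min(\mathrm{Poisson}(\text{births}_i), \lfloor CB_i\rfloor)$. Near
  carrying capacity only a small fraction of cells divides per six hours,
  so mutation pressure scales down with crowding exactly as replication
  does.
* `"per_cell"`: all $\lfloor CB_i \rfloor$ standing cells are treated as
  newborn daughters each step. At $\lambda = 0.6$ this makes ~45% of every
  subclone's cells leave (spawn or die) per step. Near capacity, where the
  density factor throttles proliferation far below this fixed drain, **no
  subclone can sustain an observable centrocyte count** — the population
  shatters into tens of thousands of sub-cell fragments. The mode is kept
  because it is the literal reading of "each cell acquires 0, 1, or more
  mutations after each cell division", but it cannot produce the regime
  the model is meant to study.
* `"per_subclone"`: one representative daughter per subclone per division;
  diversity then grows far too slowly (tens of subclones in 21 days).

Subclones with $CB < 1$ are exempt from SHM (sub-unit continuous counts
must not generate cells), and a cell with several affinity-changing
mutations draws a single affinity change.

**The affinity-change distribution.** An affinity-changing mutation sets
$\sigma_{new} = \max(\sigma_{parent} + \Delta\sigma,\ \sigma_{min})$ with

$$\Delta\sigma = X - \mathbb{E}[X] - 0.1\,\sigma_{parent}, \qquad
  X \sim \mathrm{InvGamma}(s = 3,\ r = 0.3).$$

Centering by the analytic mean gives near-even odds of improvement; the
right skew leaves a small chance of large gains (key mutations); the parent
term makes improvement harder the better the parent already binds. Two
conventions exist for $r$: as the inverse-gamma **scale**
($\mathbb{E}[X] = r/(s-1) = 0.15$, the default) or as the reciprocal scale
($\mathbb{E}[X] = 1/(r(s-1)) \approx 1.67$), selectable via
`affinity$parameterization`. The choice matters more than any rate
constant: with the scale reading, affinities mature slowly (population
maxima of a few µM by day 21) and the GC dynamics stay in the stable regime
(flat late totals, CB/CC between roughly 1.4 and 2); with the reciprocal
reading, µM-scale jumps drive a runaway ratchet — affinities reach tens of
µM, the $\eta_{CC\to P}\sigma CC$ term drains the light zone, and diversity
collapses. The default preserves the dynamics. A consequence the user
should know: statistics tied to the *absolute* affinity scale (the 75th
percentile of all subclones ever produced, quartile mixtures among
expanded/unexpanded subclones, the abundance–affinity rank correlation) are
sensitive to this convention and to the unpublished tree probabilities, and
should be read as qualitative under either setting.

$\sigma_{min} = 0.001$ µM clamps the rare draw that would push affinity to
zero or below, keeping the relative-affinity scaling and the plasma term
defined.

## Repertoire statistics

* **Expansion threshold.** From integer counts (final-step centrocyte
  counts rounded to the nearest integer for simulations — sequencing is
  assumed to sample centrocytes, and counts rounding to zero are
  unobservable), build the frequency histogram $F(c)$ and set $T$ to the
  lowest count with $F(c) < p$ ($p = 1$ by default: the lowest unobserved
  count). Counts strictly above $T$ are expanded. Gap-free count vectors
  yield $T = \max(c) + 1$ and no expansion calls. The rounding rule and the
  exclusion of zeros are package decisions; the threshold statistic itself
  is defined on integer counts.
* **Affinity classes.** "High affinity" means above the 75th percentile
  (linear interpolation between order statistics — the method is a package
  decision) of the affinities of *every subclone ever created*, pruned ones
  included, each counted once.
* **Correlation.** Spearman with average-rank ties, over subclones with a
  rounded final centrocyte count of at least 1, reported as undefined below
  three observations.
* **Trajectories.** Per-step totals, the number of observable subclones
  (centrocyte count ≥ 1 — the continuous equations keep a long tail of
  sub-unit subclones alive that sequencing would never see), the maximum
  mutation load among them, and the cell-weighted mean affinity.

## Lineage clustering and the synthetic repertoire

Annotated reads are grouped by V–J assignment (families ranked by read
count, ties broken lexicographically), and each family is clustered by
connecting every pair of reads at most `max_diff = 2` differences apart;
lineages are the *connected components*, so members may differ by more than
2 through chains of intermediates. Equal-length reads use the positional
(Hamming) count with positions carrying `N` in either read excluded;
unequal-length reads fall back to Levenshtein edit distance — the original
variable-length pyrosequencing reads carry indels, and the alignment scheme
used upstream of such data is not recoverable, so edit distance is a
documented stand-in. Pairwise clustering is $O(n^2)$ and intended for the
observed scale of hundreds of reads per family.

The synthetic generator plants known structure: a few V–J families, each
with independent random founders (two random 300-nt sequences differ at
~75% of positions, far beyond any clustering radius), lineage members
within `max_mutations = 2` substitutions of their founder (so recovery of
the planted partition is guaranteed by construction, and tests assert it
exactly), the unmutated founder emitted as the lineage's expanded subclone,
and a heavy-tailed read-count distribution (count $1 + \mathrm{Geom}(0.8)$
backgrounds, a planted count-40 peak). It emulates the *shape* of a
lymph-node repertoire — it does not emulate sequencing error, PCR
amplification bias, varying read lengths, or allele-level V–J ambiguity, so
a green clustering test establishes correctness of the algorithm, not
robustness to instrument noise.

## Numerical choices

* Integrator: adaptive Dormand–Prince RK45, relative tolerance $10^{-6}$,
  absolute $10^{-8}$; the contract is the tolerance, not the algorithm.
  Verified in tests against matrix-exponential solutions of the
  frozen-signal linear limit ($10^{-5}$ relative).
* Compartments are clipped at zero after each accepted integrator step;
  undershoot at these tolerances is below $10^{-8}$ cells.
* Signals (and the scaling maximum) are piecewise-constant per 6-h
  interval; the day-4 boundaries (clamp off, SHM on) act on interval start
  times.
* With SHM disabled, total CB equilibrates ~12–15% *above* the nominal
  capacity $A$: inverting the Hill-20 density factor against the net
  outflow puts the fixed point at $CB_{tot}/A \approx 1.12$, so overshoot
  of this size is a property of the equations, not an integrator artifact.
* Determinism: a run is fully determined by `(params, seed)`; replicates
  use one seeded stream each, and every output records its seed.

## Known limitations

* No GC shutdown, no spatial dark/light zones, no explicit antigen, FDC or
  Tfh agents, no B-cell egress, and no explicit receptor sequence — hence
  no back-mutations, hotspots, or CDR1/2/3 distinction (peptide-level
  subclone counts are correspondingly optimistic).
* The fate-tree probabilities and the affinity-change convention are
  under-determined by published information; absolute-affinity statistics
  inherit that uncertainty (see above).
* The simulated total rises to a plateau rather than a sharp day-8 peak;
  argmax-based "peak day" statistics therefore have high variance across
  replicates.
* Observable-subclone diversity (centrocyte count ≥ 1) sits in the
  100–200 range with defaults; pushing it higher requires a faster
  affinity ratchet, which destabilizes the late-phase dynamics under the
  printed rate constants.
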