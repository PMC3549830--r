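---
title: "Solvent-aware Markov state models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Solvent-aware Markov state models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(solvmsm)
```

## The model

A Markov state model (MSM) replaces a molecular-dynamics trajectory by a
discrete-time Markov chain on a partition of configuration space. With a
column-stochastic transition matrix $T(\tau)$ estimated at lag time $\tau$,
state populations evolve as $P(n\tau) = T(\tau)^n P(0)$. Building the model
has two stages: a geometric *split* of the $N$ frames into $K$ microstates,
and a kinetic *lump* of those microstates into $L$ metastable macrostates.

This package's contribution is to keep the solvent in the split stage.
Solvent molecules are numerous and exchangeable, so naive coordinate
distances are useless: permuting two waters produces a formally different
but physically identical configuration. We summarize the solvent seen from
each solute atom $x_i$ by a Gaussian-kernel density,
$$f(x_i, Y) = \sum_{j=1}^{n} \exp\!\left(-\frac{\|x_i - y_j\|^2}{2\sigma^2}\right),$$
where $Y$ holds one point per water (its oxygen). The signature vector
$f(X, Y) = (f(x_1, Y), \dots, f(x_m, Y))$ is:

1. *continuous* — a perturbation of magnitude $\delta$ moves each entry by
   at most $n\,(\delta/\sigma)e^{-1/2}$, the kernel's maximal gradient;
2. *symmetric* — any permutation of the solvent leaves it unchanged;
3. *local* — waters beyond a few $\sigma$ contribute exponentially little.

Configurations are compared by the Euclidean distance between signature
vectors (solvent metric) or by Kabsch-aligned heavy-atom RMSD (solute
metric), and the two clusterings can be *combined*: $K_1$ solute clusters
crossed with $K_2$ solvent clusters, a microstate being an occupied
(solute, solvent) pair. Setting $K_1 = K_2 = \lceil\sqrt{K}\rceil$ cuts the
split cost from $O(KN)$ to $O(\sqrt{K}\,N)$ metric evaluations. The solute-
and solvent-only models are the special cases $K_2 = 1$ and $K_1 = 1$.

Lumping maximizes the metastability $Q = \sum_i T_{ii}(\tau)$ by simulated
annealing: per step, one microstate is reassigned to a uniformly random
macrostate (rejected if a macrostate would empty), accepted when $Q$ does
not decrease and otherwise with probability $\exp((Q' - Q)/\text{temp})$,
temp $= 1/\text{step}$. Uniform random assignments give $E[Q/K] = 1/K$,
which we report as the baseline beside every fitted model.

For concave solutes the *water number* integrates the normalized kernel
density over a cylindrical region $V$:
$\int_V f(x, Y)\,dx = \sum_i \int_V K(x, y_i)\,dx$, a continuous count of
the waters inside $V$. As $\sigma \to 0$ the kernel tends to a Dirac delta
and the integral to the indicator $I(y_i \in V)$; a molecule exactly on the
boundary contributes $1/2$.

## Parameters that matter

- **Kernel width σ** (coordinate units, Å for PDB input). The resolution at
  which solvent structure is compared. Rule of thumb used throughout the
  package's examples: match σ to the length scale of the solvent
  rearrangement of interest — of order 1 Å for density changes at a pore
  mouth (we use σ = 1/3–1/2 for the channel model, whose site spacing is 1),
  and of order the basin-to-basin solvent displacement for conformational
  hopping (σ = 5 for the two-basin model, whose mean solvent shift has
  magnitude 5). Too-small σ makes signatures noisy step functions of single
  near-contacts; too-large σ blurs all structure into the total water count.
  σ is a free parameter everywhere; signatures computed at different σ are
  deliberately incomparable.
- **Normalization.** Signatures use the *unnormalized* kernel (entries in
  [0, n], dimensionless); the water number uses the kernel normalized by
  $(2\pi\sigma^2)^{-3/2}$ so it integrates to one per molecule. The printed
  form of that constant in the source literature, $1/(2\pi\sigma)^3$, does
  not integrate to one; we use the unique normalizing constant, which the
  δ-function limit requires.
- **K, K₁, K₂, L.** As in any MSM, K trades resolution against statistics.
  `product_split()` increments K₁, K₂ (up to 5 times) when fewer than K
  product states are occupied, then merges the smallest states down to
  exactly K.
- **Lag.** Transition counting uses integer frame lags with a sliding
  window, stride 1, no reversibility enforcement; `lag_time` is carried as
  metadata only.
- **Annealing budget.** Defaults: 10000 steps, 100 restarts, temperature
  1/step reset per restart. On every benchmark with $K \le 8$ the budget of
  10000 steps × 20 restarts already attains the exhaustive optimum (see the
  acceptance suite); the full default is conservative.

## Numerical choices

- *Water-number evaluation.* The normalized 3-D Gaussian is separable along
  and across the cylinder axis, so each molecule contributes (axial 1-D
  Gaussian mass between the faces, a difference of error functions) ×
  (2-D Gaussian mass in the disk). The disk factor — equivalently a Marcum-Q
  function — is evaluated by adaptive quadrature of the Rice density to
  $10^{-8}$ absolute tolerance, with an exponentially scaled Bessel $I_0$
  (asymptotic series beyond its stable range) so that σ may be orders of
  magnitude smaller than the geometry.
- *Order-canonical summation.* Kernel contributions are summed in sorted
  order, making every signature-derived quantity bit-identical — not merely
  equal to rounding — under solvent permutation.
- *Kabsch degeneracies.* The SVD construction with the determinant
  correction (reflections excluded) is used for all m; for collinear or
  m < 3 point sets the null-space singular vectors are arbitrary but the
  attained RMSD is still optimal, which is what the numerical oracle in the
  test suite checks.
- *Tie-breaks.* k-center assigns ties to the earlier (lower-index) center;
  the farthest-point step takes the lowest qualifying index; merging picks
  the smallest-population state (ties: lower id) and its nearest neighbor
  under the combined distance d_solute/D_solute + d_solvent/D_solvent
  (diameters D from the cluster centers; a zero diameter drops its term).
  The exhaustive lumping oracle breaks Q-ties toward the lexicographically
  smallest canonical assignment.
- *Zero-count states.* A state never observed as a transition source gets a
  self-loop column and a loud warning rather than silent deletion, keeping
  label ids stable; such states contribute 1 to Q and are flagged.
- *Annealer objective.* Q of a candidate lumping is computed from the
  aggregated macro *count* matrix, column-normalized — weighting microstates
  by observed occupancy, as a macro-level estimator would. The annealer
  updates the macro counts incrementally per move; the tests verify exact
  agreement with the from-scratch aggregate → normalize → trace route.
- *Periodic boundaries.* Off by default. An optional orthorhombic box
  applies the minimum-image convention inside signature evaluation only;
  RMSD alignment and the cylinder integral assume an unwrapped, whole
  solute.

## What the synthetic generators emulate

The **channel model** is a single-file lattice stand-in for nanopore
hydration: `n_sites` axial sites inside a rigid tube of carbon-like rings;
occupancy is always empty, full, or a contiguous block anchored at one end,
because molecules enter and leave only at the ends. Its hidden state chain
(2·`n_sites` states on a ring) has a closed-form transition matrix, so MSM
estimates can be checked against exact values. The four-way structure —
empty / full / left-filling / right-filling — is exactly representable: a
left-filling state cannot become right-filling without passing through
empty or full. The filled-site waters sit exactly at their sites and the
region faces pass through the end sites, so a full channel's water number is
`n_sites − 1` (interior sites count 1, the two boundary molecules ½ each) in
the small-σ limit. Bath waters keep the total solvent count constant and
exercise permutation invariance and locality at realistic n. Defaults
(`n_sites = 6`, `p_enter = p_exit = 0.02` per frame) give sharp, rare
transitions between the hydration states with at most six waters inside,
and were fixed before any downstream fitting.

The **two-basin model** emulates a small solute hopping between two
conformations, each with its own mean solvent arrangement: a hidden
symmetric 2-state chain (`hop_probability = 0.02`), solute = basin reference
± isotropic noise, solvent = a fixed cloud shifted by ±`solvent_shift`/2
per basin plus noise. The default shift magnitude 5 at noise 1 (a 5:1
separation) is the regime in which solvent signatures alone should recover
the basins almost perfectly.

Neither generator is physical: there are no forces, energies, water
geometry, or realistic diffusion, and the channel's hidden chain is a
uniform ring walk rather than an energy landscape. Passing tests therefore
demonstrate the *estimators* — signatures separate states the solvent
distinguishes, counting recovers known transition probabilities, lumping
finds planted structure — not that real MD systems will present such clean
separations.

## Problem sizes

The test and acceptance workloads are sized for interactive runs on one
core: 20000-frame trajectories for parameter recovery, 2000 frames ×
K = 16 for the three-model comparison, 10⁶ Monte-Carlo samples for the
water-number integral, 50 brute-force k-center instances with N ≤ 14, and
20 annealer-vs-oracle instances with K ≤ 8. These choices reflect where the
brute-force oracles stay exact and cheap; the library itself has no such
limits.

## Open choices made here

- The split/lump literature leaves the transition-count estimator
  unspecified; we use sliding-window counts at stride 1 and do not enforce
  detailed balance.
- The destination of a merged smallest state is not specified by the
  combination scheme; we send it to the nearest surviving state under the
  normalized combined center distance, preferring geometric coherence over
  arbitrary absorption, and allow merges across solute-cluster boundaries.
- The first k-center seed is a seeded-random frame, recorded in the output
  for reproducibility.
- The per-solute-cluster (nested) solvent clustering variant is available
  behind `mode = "nested"`; the global product is the default.
- Annealing initial assignments are drawn uniformly over all maps and
  rejected until surjective.

## Known limitations

- No binary trajectory formats (DCD/XTC); XYZ and multi-model PDB only.
- No Markovianity diagnostics (implied timescales, Chapman–Kolmogorov) and
  no reversible or Bayesian estimators; the transition matrix is the plain
  column-normalized count estimate.
- The region V for the water number is always user-supplied; the package
  does not infer pore geometry.
- k-center's greedy 2-approximation chooses outliers as centers by design;
  for heavy-tailed data k-medoid refinement (`k_medoid()`) gives more
  central prototypes at higher cost.
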