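---
title: "Superiorized feasibility-seeking for linearly constrained inverse planning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Superiorized feasibility-seeking for linearly constrained inverse planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amsplan)
```

## The planning problem

Inverse planning for intensity-modulated radiotherapy (IMRT) discretizes the
patient into $n$ voxels and the radiation fluence into $m$ beamlets. A
precomputed nonnegative dose influence matrix $A \in \mathbb{R}^{n \times m}$
maps beamlet intensities $x \ge 0$ to voxel doses $d = Ax$. Clinical
prescriptions are grouped per volume of interest (VOI): each voxel $i$ of a
VOI carries a dose hyperslab

$$\ell_i \le \langle a_i, x \rangle \le u_i,$$

with $a_i$ the $i$-th row of $A$. Organs at risk get $\ell_i = 0$ and a
tolerance dose as $u_i$; the target gets a window around the prescribed
dose. Finding *any* nonnegative $x$ satisfying all slabs is a convex
feasibility problem; `amsplan` solves it with a row-action projection
method and, optionally, *superiorizes* that method so the feasible point it
returns also has a reduced value of a weighted-sum dose objective

$$f(x) = \sum_p w_p f_p(d(x)),$$

without claiming constrained optimality. Superiorization sits between bare
feasibility-seeking (no objective at all) and full constrained
minimization: it keeps the per-iteration cost of projections plus plain
gradient steps and needs no second derivatives, Lagrange multipliers or
slack variables, which matters when every voxel contributes two inequality
constraints.

## The feasibility-seeking sweep

The basic algorithm is the sequential AMS (Agmon–Motzkin–Schoenberg)
relaxation method for linear inequalities. One *sweep* visits every active
voxel (those carrying a nontrivial slab) in a control-sequence order; at
each voxel the violated half-space, if any, is handled by a relaxed
projection

$$x \leftarrow x \mp \lambda \nu_i \,
  \frac{|\langle a_i, x\rangle - b|}{\lVert a_i \rVert_2^2}\, a_i,$$

where $b$ is the violated bound, $\lambda \in (0, 2]$ the relaxation
parameter and $\nu_i \in (0, 1]$ a per-voxel importance weight derived
from the prescription's relative weights (rescaled so the most important
VOI has $\nu = 1$). After the full pass the iterate is clamped onto the
nonnegative orthant. With $\lambda\nu_i = 1$ the step lands exactly on the
half-space boundary; for $\lambda \in (0,2)$ each sweep is Fejér monotone
with respect to every feasible point, which is the property the test suite
checks against constructed witnesses.

Decisions this package fixes where the method description leaves freedom:

* **within-voxel order** — the upper bound is handled before the lower
  bound, the second check using the already-updated inner product. With
  $\lambda\nu_i \le 1$ and $\ell_i \le u_i$ at most one side can fire per
  visit, so the order only matters for over-relaxed runs;
* **orthant projection** — applied once per sweep after the full pass, not
  after every row;
* **control sequences** — `cyclic` (ascending voxel index, the default),
  `random` (seeded shuffle, redrawn every sweep), `weight_ascending` and
  `weight_descending` (stable sorts by $\nu_i$);
* **default $\lambda = 1$** — the admissible range is $(0, 2]$; exact
  projections are the common practical choice and make the
  residual-closing property testable to machine precision.

Progress is tracked by two metrics: the proximity function

$$V(x) = \frac{1}{n_{\text{act}}} \sum_{i \in \text{act}}
  \frac{(\ell_i - \langle a_i,x\rangle)_+^2 +
        (\langle a_i,x\rangle - u_i)_+^2}{\lVert a_i \rVert_2^2},$$

and the maximum violation $\max_i \max(\ell_i - \langle a_i,x\rangle,
\langle a_i,x\rangle - u_i, 0)$ in Gy. $V$ is averaged over the *active*
voxels only: voxels whose slab is the trivial $[0, \infty)$ belong to no
prescribed structure, and counting them would silently dilute the metric
with zeros. Rows that are identically zero cannot define a half-space and
are excluded (and logged) as well.

## Objectives

Six per-VOI objective kinds are provided, all using the per-structure mean
convention $\frac{1}{|S|}\sum_{i \in S}(\cdot)$ so values are comparable
across structures of different sizes (absolute values are therefore *not*
comparable with software using sum conventions): squared deviation,
one-sided squared overdose/underdose, mean dose, and two dose-volume
histogram (DVH) objectives. The DVH objectives penalize squared deviation
from the reference dose $\hat d$ only on the voxel band between $\hat d$
and the quantile dose $d_V$, the dose received by the hottest $V$-fraction
of the structure. $d_V$ uses the nearest-rank convention on the descending
sort (index $\max(1, \operatorname{round}(V |S|))$), and is treated as
locally constant during differentiation — the selection set changes
discontinuously with the dose, and freezing it is the conventional
subgradient-style choice. All gradients are analytic and are verified
against central finite differences; the composite chains them to intensity
space through $\nabla_x f = A^\top \sum_p w_p \nabla_d f_p$ with a single
dose computation per evaluation.

The squared-underdose kind is included for completeness of the family even
though the packaged prescriptions do not use it.

## The superiorized algorithm

Iteration $k = 0, 1, \dots$ interlaces two phases:

1. **Perturbation phase** — $N$ objective-reducing steps. Each records the
   phase-start value $f_{\text{start}} = f(x)$ and proposes
   $z = x + \beta v$ with $v = -\nabla f(x)/\lVert\nabla f(x)\rVert_2$ and
   $\beta = \alpha^s$, $0 < \alpha < 1$; after every proposal the global
   exponent $s$ increments, so rejected proposals retry with geometrically
   smaller steps until $f(z) \le f_{\text{start}}$. The exponent never
   resets: the total step length over the whole run is bounded by the
   geometric series $\alpha^{s_0}/(1-\alpha)$, which is what makes the
   perturbations *bounded* and the feasibility-seeking resilient to them.
   Normalizing $v$ makes $\beta$ the actual Euclidean step length.
2. **Feasibility phase** — one AMS sweep with weights decayed to
   $\eta^k \nu$, $0 < \eta \le 1$.

A *warm start* increments $s$ by 25 (configurable) after the run's very
first proposal instead of by 1. The proposal-then-increment order follows
the algorithm's step contract (the first proposal of the run is taken at
$\beta = \alpha^{s_0}$); the warm-start jump then tames every subsequent
step. With a zero gradient the perturbation is skipped entirely, which
makes the superiorized run with zero objective weights *bitwise* identical
to the bare solver under the same seed — a reduction the tests assert.

**Stopping.** The run terminates on an iteration budget (default 500), a
wall-clock budget (default 3000 s), or when for three consecutive
iteration pairs both relative changes

$$\frac{|f_{k+1}-f_k|}{\max(1, f_k)} < \text{tol}_f = 10^{-4}
  \quad\text{and}\quad
  \frac{|V_{k+1}-V_k|}{\max(1, V_k)} < \text{tol}_V = 10^{-3}$$

hold. A *negative* tolerance disables that part of the conjunction
(vacuously satisfied); a tolerance of exactly 0 makes the part
unsatisfiable and thereby disables criterion-based stopping altogether,
since the absolute change is never strictly below zero. Both switches are
useful: the bare solver reuses the same evaluator with
$\text{tol}_f = -1$ so only proximity stagnation decides, and long
benchmark runs use $\text{tol}_V = 0$ to exhaust the sweep budget. Note
that the $\max(1,\cdot)$ denominator makes the rule weak when $V \ll 1$:
on problems whose row norms are large the stagnation rule can fire while
violations are still clinically relevant, which is visible in the packaged
phantom when the bare solver runs with default tolerances.

Defaults the algorithm description leaves open and this package fixes:
$\alpha = 0.99$ and $N = 5$ (stable at desk scale across the packaged
problems; both exposed in `superiorization_config()`), $\eta = 1$ (no
decay unless requested), start vector $x_0 = 0$ (nonnegative and
objective-neutral), and the random control sequence is redrawn every sweep
from a per-sweep seed derived as `seed + sweep`.

## What the synthetic generators emulate

**Phantom.** `build_phantom()` reproduces the classic TG119-like horseshoe
benchmark geometry on a 2D slab: a C-shaped target annulus (inner/outer
radii 15/37 mm, 90° opening) wrapping a 10 mm core organ-at-risk inside an
80 mm circular body. The benchmark's exact dimensions are not standardized
in this package's sources; the radii are config parameters, not claims.
The default grid is a 64×64×1 slab at 3 mm spacing — 2D for speed, with
the identical code path supporting nz > 1 by extrusion.

**Dose engine.** `generate_dose_influence()` stands in for a clinical
pencil-beam engine with a transparent analytic model: five equidistant
coplanar fields, beamlets every 5 mm across the body's lateral extent,
and per-beamlet deposition $\propto e^{-\mu\,\text{depth}} \cdot
e^{-\text{lat}^2/2\sigma^2}$ inside the body ($\mu = 0.005$/mm, in the
megavoltage-photon range for water; $\sigma = 3$ mm). Entries below
$10^{-4}$ of the beamlet's maximum are dropped to control sparsity. The
default phantom yields 155 beamlets and ~5.6 × 10⁴ nonzeros — deliberately
desk scale rather than the thousands of beamlets and ~10⁸ nonzeros of
clinical matrices. The model has no scatter, no heterogeneity, no divergence, and
2D symmetry; passing tests demonstrate algorithmic correctness on
realistic *structure*, not clinical dosimetric accuracy.

**Feasible-by-construction problems.** Toy problems draw a sparse
nonnegative system and a nonnegative witness $x^\*$, then place each slab
symmetrically around $\langle a_i, x^\*\rangle$ with a chosen slack — the
witness certifies feasibility exactly. Infeasible instances duplicate one
row and give the two copies disjoint intervals, so infeasibility is
provable without an external certificate (tests nevertheless cross-check
with an independent bound-constrained solver). The packaged phantom
problem derives its witness from a bound-constrained least-squares fit to
the ideal dose (60 Gy in the target) and widens each VOI's nominal
tolerance (Target 59–61 Gy, Core < 20 Gy, Body < 30 Gy, weights
1000/100/30) just far enough — plus a 0.5 Gy interior margin — to contain
the witness dose. The synthetic engine cannot reach a clinical ±1 Gy
target homogeneity with 155 beamlets, so the effective target window is
wider (about 53–65 Gy); the nominal and widened prescriptions are both
stored in the problem metadata.

## Numerical choices and conventions

* Voxel linear indices run x-fastest and are 1-based in memory (the R
  convention) and 0-based in every file format; the conversion happens
  only at the I/O boundary.
* MatrixMarket files are written with 17 significant digits and all CSV
  bound/intensity columns through the same formatter, so
  `read_problem(write_problem(p))` is exact to the bit. The history CSV's
  `elapsed_s` column is wall-clock time and is the one column that varies
  between otherwise identical runs.
* Squared row norms are cached at matrix construction and validated in
  tests against recomputation at 1e-12 relative tolerance.
* Ties in the weight-sorted control sequences are broken by the stable
  radix sort, i.e. by ascending voxel index.
* The per-iteration history records one row per full iteration
  (perturbations plus sweep) plus a row 0 for the starting point, so
  "objective after iteration 1 versus at the start" is directly readable
  from the first two rows.

## Problem sizes used in the packaged studies

The test-suite and acceptance studies run: ten paired toy problems with
$n = 200$, $m = 30$, 30% density and 0.5 Gy slack; infeasible variants at
$n = 50$; and the 64×64 phantom (2244 in-body voxels, 155 beamlets) with
a 500-sweep/iteration budget. These sizes keep a full paired study in the
low seconds while preserving the structural features — wide slabs,
correlated rows, heterogeneous weights — the algorithms are sensitive to.

## Known limitations

* Linear per-voxel dose bounds only: no dose-volume *constraints*, no
  nonlinear constraint sets, no EUD/NTCP-type objectives.
* One basic algorithm (sequential AMS); no simultaneous, block-iterative
  or string-averaging variants.
* The bare solver's stagnation rule inherits the $\max(1, V)$ weakness
  discussed above; for hard-feasibility studies disable it
  (`tol_V = 0`) and rely on the sweep budget.
* The synthetic dose engine is a stand-in; conclusions about clinical
  dosimetry require a validated engine and patient data, which are out of
  scope here.
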