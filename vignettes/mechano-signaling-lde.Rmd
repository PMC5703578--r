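---
title: "Logic-based differential equation modeling of mechano-signaling networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Logic-based differential equation modeling of mechano-signaling networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechnet)
```

## The model

`mechnet` simulates signaling networks with logic-based differential
equations (LDEs), the formalism behind the Netflux family of models. Each
node $c$ — a receptor, kinase, transcription factor, mRNA, or phenotype —
carries a normalized activity $Y_c \in [0, Y_{max,c}]$ obeying

$$\frac{dY_c}{dt} = \frac{1}{\tau_c}\left(Y_{max,c}\, g_c(Y) - Y_c\right),$$

where the drive $g_c$ aggregates the reactions targeting $c$. A reaction
with weight $w$ and operands $x_1, \dots, x_k$ contributes

$$a = w \prod_{i \in \text{activators}} f(x_i)
      \prod_{j \in \text{inhibitors}} \left(1 - f(x_j)\right),$$

so operands inside one rule combine as a continuous AND (each is
necessary), with inhibition entering as the complement $1 - f$. Input
reactions (no operands) contribute their weight directly — the weight *is*
the input level, e.g. mechanical stretch at 0.7. Multiple reactions on one
target OR-combine pairwise via $a \lor b = a + b - ab$, equivalently
$1 - \prod_r (1 - a_r)$, which makes the fold order-independent (a tested
property). Species with no incoming reactions decay to zero; the model
check warns about them.

The transfer function is the *normalized Hill function*

$$f(x) = \frac{B\,x^n}{K^n + x^n}, \qquad
B = \frac{EC_{50}^n - 1}{2\,EC_{50}^n - 1}, \quad K^n = B - 1,$$

the unique member of the Hill family with $f(0)=0$, $f(EC_{50})=0.5$,
$f(1)=1$ (the Kraeutler/Netflux convention). When $2\,EC_{50}^n = 1$ the
closed form is singular and the constrained family degenerates to the
identity $f(x) = x$, which `normalize_hill()` returns as the limit case.
The test suite cross-checks $B$ and $K$ against a root-finder solving the
three constraints directly.

```{r hill}
f <- normalize_hill(1.4, 0.5)
f
f$fn(c(0, 0.5, 0.7, 1))
```

### Parameters and defaults

All parameters are dimensionless except $\tau$ (arbitrary time units):

| parameter | meaning                         | default |
|-----------|---------------------------------|---------|
| $Y_{init}$ | initial activity               | 0       |
| $Y_{max}$  | maximal activity               | 1       |
| $\tau$     | relaxation time constant       | 1       |
| $w$        | reaction weight                | 0.9 (non-input) |
| $n$        | Hill coefficient               | 1.4     |
| $EC_{50}$  | half-activation input          | 0.5     |
| input      | stretch input weight           | 0.7     |

Uniform defaults are the established practice for large literature-curated
logic networks, where per-reaction kinetics are unknown; the default
reaction weight 0.9 and input 0.7 keep most of the cascade activated
between 50 and 95% of maximum (see `activation_band()`), avoiding both
undersaturation and saturation so perturbations remain informative.
Missing cells in model tables fall back to these defaults in the parser —
not in the math core — so explicit per-reaction overrides in a model file
are always honored.

### Numerical choices

* Integration uses `deSolve::ode` with `lsoda` (stiff-safe), absolute and
  relative tolerances $10^{-8}$. Trajectory boundedness
  $0 \le Y_c \le Y_{max,c}$ is asserted to within $10^{-6}$.
* `steady_state()` integrates until $\max_c |dY_c/dt| < 10^{-8}$, checking
  at eight intervals up to a time cap of 40 (plenty for $\tau = 1$
  transients); hitting the cap raises an explicit error naming possible
  oscillation or multistability rather than silently returning the last
  state.
* `fixed_point_state()` solves $Y = Y_{max} g(Y)$ by damped iteration
  ($\alpha = 0.5$). Plain iteration can cycle on feedback loops; the
  damping mitigates that. It is kept as an independent route to the same
  fixed point: every steady state in the test suite must agree with it
  (and with a third, helper-level reimplementation) to $10^{-6}$.
* Activities are clipped to $[0,1]$ before entering $f$, and $f$'s output
  is clipped to $[0,1]$. This matters only when a perturbation raises
  $Y_{max}$ above 1 (the +50% arm of the pairwise screen): the raw
  normalized-Hill form exceeds 1 there, which would push gate operands out
  of range. Saturating the transfer at 1 keeps the gate algebra closed and
  the boundedness invariant intact.
* Exactly-at-threshold deltas in validation classify as *no change*
  (strict inequalities) — the conservative reading of a claimed change.

## Perturbations, validation, and robustness

A `perturbation()` bundles input changes (`set_input`), knockdowns or
overexpression (`scale_ymax`, `set_ymax`), and hard clamps. Applying one
never mutates the input model. Validation compares classified steady-state
changes against literature-style observation tables in three categories:
input–output and input–intermediate changes are measured relative to the
unstretched state, inhibition changes relative to steady-state stretch.
The change threshold defaults to 0.05 *absolute*; a relative mode is
available (`threshold_mode = "relative"`) since both readings appear in
the literature on this threshold.

The depth of a simulated inhibitor is genuinely underdetermined: network
sensitivity analyses conventionally use 50% knockdown, but pharmacological
blockade is typically stronger. `validation_config()` therefore defaults
to `inhibition_depth = 0` (full block) and exposes the knob; reports of
inhibition-category accuracy should state the depth used, and
`robustness_scan()` can quantify the sensitivity of that accuracy.

Disagreements are classified into four mechanistic classes —
below-threshold (right direction, too small), missing connection
(observed change, exact zero predicted), spurious prediction, and sign
flip — because each points to a different kind of model revision.

`robustness_scan()` resamples every instance of one parameter uniformly
within a relative half-width, clips to validity, and revalidates;
`tau` and `y_init` scans are steady-state no-ops by construction and serve
as self-checks. Input-reaction weights are excluded from the `w` scan
because validation contexts overwrite them through `set_input`.

## Sensitivity analysis and the combination screen

`knockdown_matrix()` halves one node's $Y_{max}$ at a time under the
stretch context and records every node's steady-state change.
`influence_ranking()` aggregates a column's mean absolute delta over a row
subset (transcription factors, outputs); mean signed delta is available as
an option — the aggregation is a design choice, as "greatest activity
change" admits both readings. `cluster_hubs()` groups hub columns by
Euclidean distance with unweighted-average (UPGMA) linkage, cut at a
distance criterion of 0.3; raw deltas are used by default since row
standardization is a separate, optional choice.

`pairwise_screen()` perturbs every unordered pair of nodes in both
directions ($Y_{max} \times 0.5$ and $\times 1.5$) and scores *additional
benefit*: the combined output change minus the larger-magnitude change of
either node alone in the same direction. Negative additional benefit on an
output one wants to suppress means super-additive inhibition. Two fixture
geometries bracket the behavior: independent branches converging through
an AND gate are super-additive (both necessary factors are weakened),
while a node paired with its sole descendant is redundant — at full block
the additional benefit is exactly zero, and at partial knockdown it equals
a small residual that the tests pin against the fixed-point oracle.

## What the synthetic fixtures emulate — and what they do not

`random_network()` generates seeded random signed logic networks at the
framework defaults (inhibitory operands at 15%, two-operand AND rules at
20% — a minority of gates, echoing the composition of curated signaling
topologies; one input source driven at 0.7). They exercise the solver,
gate algebra, and screen machinery at desk scale.

`mini_mechano_network()` is a ~30-node, text-derived subnetwork of
cardiomyocyte stretch signaling: stretch fans out to AT1R, the
stretch-sensitive calcium channels (LTCC, TRP), integrin, dystroglycan and
gp130; G$\alpha_{q/11}$ couples AT1R to Ras and PI3K/Akt; Ras–Raf1–MEK1/2–
ERK1/2 drives cFos; calcium runs through calmodulin and calcineurin to
NFAT; gp130 drives JAK/STAT; and an sGC–cGMP–PKG1 axis inhibits the
calcium channels and the calcineurin step. BNP is the AND of five
transcription factors (NFAT, CREB, GATA4, STAT, cFos), encoding that each
is necessary but none sufficient. Convergence points other than BNP
default to OR, and FAK→Ras closes the cytoskeletal branch onto the Ras
hub; both are fixture choices where the qualitative literature does not
pin a gate. The fixture reproduces the qualitative pharmacology — stretch
raises BNP, full AT1R blockade reduces it only partially, raising cGMP
suppresses the calcineurin/NFAT drive, and the AT1R+cGMP combination
suppresses BNP at lower per-axis doses than either arm alone.

What passing tests on these fixtures do **not** show: the fixture is not
the full published 94-node / 125-reaction curation, so quantitative
accuracy percentages, hub identities, and cluster memberships obtained on
it are properties of the fixture, not reproductions of the published
figures. Pipelines that require the released model and observation
workbooks detect them under `inst/extdata/supplementary/` and run the
full-network checks only when those files are present.

## Problem sizes used in the shipped checks

The bundled test suite and the acceptance script run entirely at desk
scale: toy motifs of 2–5 nodes, 50 seeded random networks of 5–15 nodes
for oracle equivalence, the 30-node mini network for validation (10
fixture observations), a 100-set $\pm 20\%$ $Y_{max}$ robustness scan, and
pairwise screens over explicit small candidate sets. These sizes were
chosen so each property is exercised with independent oracles while a full
run stays comfortably interactive.

## Known limitations

* No stochastic simulation, bifurcation analysis, or spatial/biophysical
  mechanisms (force propagation, diffusion, electrophysiology).
* "Dose" in the dose-response functions is an abstract fraction, not a
  concentration; no pharmacokinetics.
* Non-convergent steady states error out rather than being continued or
  annealed; genuinely oscillatory models are out of scope.
* Workbooks are read (via readxl) but written only in the paired-CSV
  dialect.
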