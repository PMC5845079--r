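---
title: "Mechanics, stochastic events and immune infiltration in a tumor-islet model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanics, stochastic events and immune infiltration in a tumor-islet model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isletsim)
```

`isletsim` simulates a two-dimensional pancreatic tumor islet as an
off-lattice, center-based population of circular cells: epithelial cells
that can mutate into cancer cells, and T lymphocytes that infiltrate the
islet to engulf them, all wrapped in an annulus of aligned stromal collagen
that selectively damps radial motion. This vignette is the package's
account of the model itself: the governing relations, the parameters and
their defaults, the numerical choices, and — importantly — the places where
the published constants are mutually inconsistent and a design decision had
to be made. Everything quantitative shown here is computed by the package
at build time; nothing is transcribed from elsewhere.

## Mechanotactic communication between epithelial and cancer cells

Every viable epithelial or cancer cell of radius $R$ exerts a traction
force $F$ on the substrate and injects a strain-energy density

$$M^0 = \frac{F^2}{2\pi^2 E_s R^4},$$

with $E_s$ the substrate modulus. The signal decays exponentially with the
attenuation ratio $\lambda = E_s/E_c$ ($E_c$ the cell modulus):

$$M(d) = M^0 e^{-\lambda d / R}.$$

A cell $i$ senses the sum of all neighbours' signals; its migration
direction $\hat z_i$ is the normalized energy-weighted resultant of the
unit vectors pointing **toward** its neighbours, and the drift speed is
$\alpha \hat M_i$ with mobility $\alpha = \beta R^3 / (\mu F)$. Two cells
in physical contact additionally exchange an invagination (contact)
strain-energy density

$$M^{ij} = \frac{4}{15\sqrt 2}\,\frac{E_c}{\pi}\left(\frac hR\right)^{5/2},
\qquad h = \max(R_a + R_b - d,\, 0),$$

and the net energy $\hat M_i = M_i^{\mathrm{remote}} - \sum_j M^{ij}$
switches the motion between attraction ($\hat M_i > 0$, along $\hat z_i$)
and repulsion ($\hat M_i < 0$, along the contact-weighted away direction).
With this sign convention — and only with it — the two-cell configuration
has a stationary separation where remote attraction balances contact
repulsion, which is the equilibrium the model's event gates are anchored
to. A formulation with the repulsion added as a second, independent
displacement on top of the drift would instead be stationary where the
remote signal equals *twice* the contact energy, contradicting the stated
balance; the package therefore treats the repulsion as the negative branch
of the same net-energy drift for the large cells, and keeps the separate
per-pair repulsion term only in the T-cell update, whose displacement law
is written that way.

### The traction-force ambiguity and the calibrated default

The published constants for $F$ are mutually inconsistent: the parameter
table lists $F = (10\text{–}25)\cdot 10^2$, the two-cell energy figure uses
$F = 10$, and neither reproduces the printed detection threshold. The
package's `model_params()` default is therefore the *calibrated* value
$F^* \approx 3.16\times 10^{-2}$, defined so that
$M^0 = 2.596\times10^{-2}\ \mathrm{kg\,\mu m/min^2}$ reproduces the printed
threshold exactly:

```{r}
p <- model_params()
p$F_traction
p$M0
detection_threshold(p$M0, p$lambda_att, d_hat = 30, R = p$R)
```

which matches the quoted $\epsilon \approx 1.99\times10^{-54}$ at the
30-µm maximum detection distance. (At runtime the cutoff actually applied
to remote signals is 0; $\epsilon$ is fifty orders of magnitude below
anything representable as a meaningful energy here, and the 30-µm radius
is kept as a neighbour-list optimization.) Solving the two-cell balance by
bracketed bisection gives the equilibrium overlap and the total sensed
stimulus there:

```{r}
h_star <- equilibrium_overlap(p)
h_star
p$M0 + pairwise_energy(p$M0, p$lambda_att, 2 * p$R - h_star, p$R)
```

— about 2.0 µm and 0.026 kg·µm/min², against the published "approximately
2.35 µm" and "approximately 0.03". Both sit within the rounding and the
$F$-ambiguity of the source values. Two technical notes. First, the balance
curve crosses zero twice on $(0, 2R)$; the solver deliberately returns the
*upper* crossing, the "maximum equilibrium overlap" the literature quotes.
Second, because the exponential remote term outgrows the $h^{5/2}$ contact
term, overlaps beyond that root re-enter net attraction; the engine's hard
quarter-diameter overlap constraint (below) is what keeps configurations
out of that unphysical regime.

## Stochastic division, anoikis and mutation

Division, death and mutation are memoryless events at rate
$\lambda = 10\ \mathrm{min}^{-1}$, drawn per step with probability
$1 - e^{-\lambda\,\Delta t}$ (0.6321 at the default 0.1-min step). An event
is *eligible* only when the gating energy $\|\hat M_i\|$ (the total
stimulus including the cell's own $M^0$, minus the contact sum) and the
cell's growth clock pass fixed gates: epithelial cells divide below 0.03
(cancer below 0.04) after 5 min of growth, mutate at or above 0.05 after
10 min, and undergo anoikis at or above 0.1 after 10 min. Epithelial
lineages stop dividing after a configurable cap (default 50 divisions);
cancer lineages are immortal and die only by engulfment.

These gates are the model's second internal inconsistency, and the most
consequential one. With any of the published traction forces, the gating
energy is essentially $M^0$ for every cell — contact energies are of order
$10^{-7}$ and remote signals of order $10^{-9} M^0$ at touching distance —
so the gates cannot respond to crowding at all:

* with the calibrated $F^*$ ($M^0 = 0.026$), every cell is *always* free to
  divide and can never mutate or die, and a whole-islet run grows
  exponentially without bound;
* with $F = 10$ ($M^0 \approx 2594$), no cell can ever divide, and every
  epithelial cell becomes eligible to mutate (or die by anoikis) the moment
  its growth clock passes 10 min.

No parameter choice makes the gates crowding-sensitive, because the
contact-energy scale $E_c$ also fixes the decay ratio $\lambda$; the
printed six-neighbour steady-state value cannot be derived from the stated
relations. The package keeps the gates verbatim and resolves the dilemma by
using each regime where it is meaningful: `model_params()` defaults to
$F^*$ for the desk-scale mechanics (thresholds, equilibria), while
`scenario_config()` runs whole-islet simulations at $F = 10$ — the value
the source itself singles out as "the best reasonable choice" for the
islet simulations. Under $F = 10$ the simulated natural history is: a
synchronized mutation/anoikis wave converts the monolayer at
$t \approx 10$ min (mirroring the published snapshot in which the first
tumor cells appear at $t = 10$ min), about 73% of cells emerging as cancer
and the rest dying; the tumor does not proliferate further; and the
outcome is decided by the race between the fixed tumor burden and the
T-cell engulfment capacity. A deterministic `seed_cancer_at` switch is
also provided for single-initial-tumor experiments.

## Chemokine field and T-cell infiltration

Live cancer cells secrete one chemokine at rate $\gamma$; the field is the
steady-state free-space solution of the secretion–diffusion balance, a sum
of logarithmic kernels

$$c(\mathbf x) = -\sum_j \frac{\gamma}{2\pi D_c}\,
  \log\|\mathbf x - \mathbf r_j\|,$$

evaluated analytically (concentration and gradient) with distances clamped
below $r_{\min} = R_t$ to regularize the singularity. The field is
harmonic away from sources, which the tests verify with a five-point
Laplacian. T cells move by

$$\Delta\mathbf r_j = \Psi\left[\beta\nabla c\,\Delta t +
  \sqrt{2D}\,\Delta\mathbf W\right] - \sum_l \alpha_t M^{jl}\,
  \hat{\mathbf u}_{jl}\,\Delta t,$$

with $\Psi$ the stromal orientation tensor. With the published $\beta$,
$\gamma$ and $D_c$, the chemotactic speed $\beta|\nabla c|$ is of order
$10^3\ \mathrm{\mu m/min}$ near the islet; the quarter-diameter
displacement cap (below) regularizes this to at most
$R_t/2 = 1\ \mathrm{\mu m}$ per step, making the T cells effective
unit-step gradient ascenders at up to 10 µm/min.

Two consequences of the clamped log-kernel sum required engine-level
decisions, both reached by observing stalled immune dynamics in early runs
and both encoded as model features with biological readings:

* **Near-field homing / synapse arrest.** The bulk gradient points at the
  tumor's center of mass, so a T cell that reaches the rim is dragged
  *past* its targets; and a T cell surrounded by sources (inside an
  eaten-out pocket) feels no net gradient at all — in two dimensions the
  log-potential of an enclosing shell of sources is constant. Within
  `tcell_homing_radius` (default 10 µm, two cell diameters — the range in
  which the nearest source dominates the true, unclamped kernel) a T cell
  therefore steers toward its nearest cancer cell directly. This is also
  where the immunological reading sits: an engaged T cell stops migrating
  and holds its target.
* **Per-T-cell contact clocks.** Engulfment requires sustained proximity:
  distance at most 3.5 µm held for 5 min in the strong immune system,
  at most 2.5 µm for 10 min in the weak one, then removal at rate
  $\lambda = 10$ with a `tcell_death_prob` (default 0.1) chance of the
  T cell dying in the act. The dwell clock is kept per T cell against its
  *current nearest* target rather than per (T, cancer) pair: contacting
  cells exchange nearest partners every few steps as they advect, so a
  pair-keyed clock resets perpetually and the published "in contact for
  some time" rule would never fire.

The geometry of the overlap constraint interacts with the two kill
distances in a way worth stating plainly: a T cell pressed against a large
cell sits at center distance $R_t + R - R_t/2 = 3.5\ \mathrm{\mu m}$ —
exactly the strong-immunity kill distance, while the weak-immunity 2.5 µm
requires a transient deeper excursion that the constraint almost always
undoes within the step. Strong immunity therefore kills steadily at the
contact surface, while weak immunity kills only in rare aligned fluctuations.
That asymmetry, together with the doubled T-cell count
($N_s = 2N_w$, default $N_w = 10$), is what separates the two regimes.

`tcell_death_prob` defaults to 0.1 by a capacity argument made before any
ensemble was run: the expected number of engulfments per T cell is $1/p$,
so the strong system's capacity is $N_s/p = 200$ against a mutation-wave
burden of roughly 140–160 cells (of ~190 initial epithelial cells at the
default 0.9 packing), while the weak system's 100 falls short — matching
the published dichotomy in which the strong immune system clears the islet
and the weak one is overrun.

## Stromal collagen annulus

The stroma is the annulus between the islet radius (35 µm) and the outer
radius (50 µm), with fibers parallel to the islet boundary. At penetration
depth $s$ (clamped to the 15-µm thickness) the orientation tensor

$$\Psi = v^0 e^{-ks}\lambda_1\,\mathbf w_1\mathbf w_1^\top +
  v^0\lambda_2\,\mathbf w_2\mathbf w_2^\top$$

damps the radial component ($\mathbf w_1$) by $e^{-ks}$ and leaves the
tangential one untouched. The eigen-weights $\lambda_1 = \lambda_2 = 1$
and $v^0 = 1$ are never assigned numbers in the source; these defaults
make $\Psi$ collapse to the identity exactly when $k = 0$, as the
isotropic control requires. Inside the islet proper the fibers do not
exist and isotropy is restored (the alternative — letting the saturated
attenuation persist inside — would damp T cells after they have already
crossed the barrier, which the model's narrative contradicts). At
$k = 0.3$ a full crossing is attenuated by $e^{-4.5} \approx 0.011$ at the
inner edge; integrating the crossing time over the annulus gives roughly
30 extra minutes at $k = 0.3$ and makes $k = 0.6$ effectively impassable
within the 200-min horizon, which is exactly how the ensembles behave.

## Numerical scheme

Positions advance by explicit Euler–Maruyama with all nonlinear terms
lagged one step; the contact law's $h^{5/2}$ kink at $h = 0$ is why no
higher-order scheme is attempted. The step is
$\Delta t = \min(0.1, R / (2\max_i\|\mathbf v_i\|))$ over the
epithelial/cancer drift speeds; T-cell speeds are governed by their own
per-step cap $R_t/2$ rather than by shrinking $\Delta t$, since their
clamped chemotactic speeds would otherwise drive $\Delta t$ to
$\sim 10^{-4}$ min and make every run intractable without changing any
trajectory beyond the cap already imposed. Wiener increments have variance
$\Delta t$ per component and enter as $\sqrt{2D}\,\Delta W$. Each step
ends with a Gauss–Seidel projection enforcing the hard maximum-overlap
rule — no pair may indent deeper than a quarter of the smaller cell's
diameter — resolved symmetrically so pairwise pushes are equal and
opposite; residuals converge below $10^{-2}$ µm. Cells leaving the
computational disk (outer stroma radius + 10 µm) are reflected radially.
One seeded generator drives each replicate, consuming draws in a fixed
order (large-cell noise, T-cell noise, mutation, anoikis, division,
engulfment), so replicates are bit-reproducible.

The per-step pairwise kernel (remote stimuli, direction resultants,
contacts, repulsion resultants) and the overlap projection are implemented
in C++; a 200-min replicate of ~200 cells takes a few seconds.

## Replicate statistics and derived metrics

`run_simulation()` records per-step phenotype counts and the cancer
fraction, whose denominator by default counts all live cells including
T cells (`totals_include_tcells = FALSE` restricts it to epithelial +
cancer; the source never defines "total cells"). Two derived metrics
summarise a replicate: the **immune response time** (first time after
tumor initiation at which the cancer count returns to zero; reported as
the horizon and flagged when never reached) and the **maximum cancer
fraction**. Ensembles are summarised with the plain normal-approximation
interval $\bar x \pm 1.96\,\sigma/\sqrt n$ — kept deliberately instead of
a t-interval because that is the formula the methodology states — and
replicate series are aligned by previous-value interpolation.

## What the shipped ensembles do and do not show

The package's acceptance-level ensembles (10 replicates, 200-min horizon,
~190 initial cells — sizes chosen to characterise the model at desk scale)
reproduce two of the three published ensemble patterns:

* strong immunity clears the tumor in the large majority of replicates
  (mean response time ≈ 110–120 min at $k = 0$) while weak immunity ends
  overrun at a cancer fraction near 0.94;
* the mean immune response time is monotonically non-decreasing in the
  anisotropy constant $k$ over $\{0, 0.3, 0.6\}$, with $k = 0.6$ censored
  at the horizon in every replicate.

The third pattern — maximum cancer fraction increasing with $k$ — has no
driving mechanism under these conditions and the corresponding test is
deliberately left failing rather than loosened: with the published gates
the tumor cannot proliferate during the stromal delay (no division is
possible at $F = 10$), so the peak burden is fixed by the mutation wave,
identical across $k$ up to noise; the measured ensemble means are flat to
about 1% and actually *decrease* slightly, because at low $k$ T-cell
attrition late in the clearance shrinks the fraction's denominator. In the
source, that pattern is produced by delay-enabled tumor growth, which the
printed constants rule out.

More generally, the synthetic scenario emulates the published geometry,
counts and event rules, but not: tumor proliferation under contact
inhibition (see the gate discussion above), heterogeneous stromal density,
chemokine decay, or any 3D effect. Passing ensembles therefore validate
the implemented mechanics, field solutions, event model and their
coupling — not the biology of a real islet.

## Degenerate inputs and edge conventions

Zero-horizon runs return the initial census. A population with a single
cell has zero remote stimulus and a null migration direction (directions
are nulled whenever the resultant cancels below $10^{-12}$ of the remote
stimulus, so symmetric rings report no preferred direction). The
orientation tensor is undefined at the islet center. Chemokine distances
clamp at $r_{\min}$; contact indentations clamp at
$R_a + R_b - 0.1\ \mathrm{\mu m}$ so coincident centres cannot arise; a
single-replicate confidence band has zero width and one-sample intervals
warn. The equilibrium solver reports an explicit error when the balance
has no sign change in $(0, 2R)$.
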