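---
title: "Models and estimators in shoaldyn"
author: "shoaldyn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and estimators in shoaldyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shoaldyn)
```

shoaldyn studies the collective states of small fish shoals — schooling,
milling and swarming — with the toolkit of many-body statistical physics:
dynamical order parameters, two-body correlation functions in the comoving
frame of a focal fish, and three-body correlations compared against their
Kirkwood-superposition prediction. It contains a minimal agent-based
simulator that reproduces the intermittent multistate dynamics of groups of
a few zebrafish, and the full observable stack needed to analyze either
simulated or tracked trajectories.

## Units

Lengths are measured in body lengths $L$ (default 30 mm). Times are
measured in units of $T = L / v_f$ with $v_f = 100$ mm/s a typical cruising
speed, so $T = 0.3$ s and a cruising fish moves at speed $1$. Trajectory
files store a `frame_interval` in seconds; all velocities are reported in
$L/T$.

## Order parameters and state classification

For a frame with $N$ fish with positions $\mathbf r_i$ and velocities
$\mathbf v_i$, the polarization and rotation order parameters are

$$O_p = \frac{1}{N}\left|\sum_i \frac{\mathbf v_i}{|\mathbf v_i|}\right|,
\qquad
O_r = \frac{1}{N}\left|\sum_i \hat{\mathbf v}_i \times
\frac{\mathbf r_i - \mathbf r_{cm}}{|\mathbf r_i - \mathbf r_{cm}|}\right|,$$

with $\mathbf r_{cm}$ the group center of mass. In 2D the cross product is
its scalar $z$ component; for 3D data the norm of the vector sum is used.
A frame is *schooling* when $O_p > 0.65$, *milling* when $O_r > 0.65$,
*swarming* when both are below $0.35$, and *unclassified* otherwise. The
thresholds are the conventional ones for this system and are configurable
(`state_thresholds()`). Two conventions had to be fixed where the
thresholds alone are ambiguous:

* if both order parameters exceed the high threshold (rare), the larger one
  wins; an exact tie is unclassified;
* fish with undefined headings (speed below $10^{-6}\,L/T$, or a missing
  tracking sample) are excluded from the sums for that frame rather than
  imputed, and $N$ counts only the participating fish.

Nearest-neighbor subgroups (`subgroup_series()`) treat the focal fish plus
its $n-1$ nearest neighbors as a group of $n$: both order parameters,
including the center of mass in $O_r$, are evaluated within the subgroup.
Distance ties are broken by fish id so results are deterministic.

## The simulator

Fish are overdamped constant-speed agents in a circular arena of radius
$R = 66.7\,L$. Fish $i$ moves at speed $v_0$ along its heading $\phi_i$:

$$\dot x_i = v_0\cos\phi_i,\quad \dot y_i = v_0\sin\phi_i,\quad
\dot\phi_i = \frac{1}{v_0}\left(\mathbf F^{wall}_i + \mathbf F^{att}_i\right)
\cdot \mathbf e_{i,\phi} + T^{al}_i + T^{hyd}_i + \eta_i,$$

where $\mathbf e_{i,\phi} = (-\sin\phi_i, \cos\phi_i)$ projects forces onto
the turning direction and $\eta_i$ is zero-mean Gaussian white noise with
$\langle\eta_i(t)\eta_j(t')\rangle = 2 D_\phi \delta_{ij}\delta(t - t')$,
$D_\phi = 0.015$. Integration is Euler–Maruyama with $\Delta t = 0.05\,T$;
$10^4$ burn-in steps are discarded.

The interaction channels are:

* **Wall avoidance** — soft exponential repulsion
  $k_w e^{-(R - |\mathbf r_i|)/\lambda_w}$ toward the arena center
  ($k_w = 5$, $\lambda_w = 2\,L$).
* **Repulsion–attraction** — a linear spring toward each visible neighbor,
  $f = k_{att}(r - r_{eq})$ for $r \le r_{cut}$, capped at $f_{max}$; the
  sign change at $r_{eq} = 1\,L$ provides short-range repulsion.
* **Alignment** — a weak heading torque
  $k_{al}\sin(\phi_j - \phi_i)e^{-r/r_{al}}$ applied directly in the
  heading equation.
* **Hydrodynamics** — each fish sheds a far-field 2D dipole of strength
  $S_h v_j$ aligned with its heading. Neighbors are advected by the summed
  dipolar flow ($\propto 1/r^2$, regularized below $1\,L$) and reorient at
  the slender-body (Jeffery) rotation rate
  $\dot\phi = \mathbf p_\perp^{\mathsf T} \nabla\mathbf u\, \mathbf p$ in
  the local velocity gradient. A pure vorticity coupling would vanish
  identically for a potential dipole flow, which is why the full
  slender-body rate (vorticity/2 plus strain alignment) is used.
* **Field of view** — attraction and alignment act only on neighbors within
  150° of the heading (a 60° rear blind zone); the hydrodynamic channel is
  not masked, because flow is felt regardless of vision.

### Default parameters

The exact social-force expressions for real zebrafish are not identifiable
from first principles; the shipped defaults are a calibrated model choice
with strong attraction, weak alignment and moderate hydrodynamic coupling
— the regime in which a group of three is *tristable*, i.e. intermittently
occupies all three states. With
`k_att = 1, r_cut = 20, f_max = 3, k_align = 0.15, r_align = 3, s_hydro = 0.25`
a $5\times10^5$-frame run of three fish spends roughly 55% of its frames
schooling, 10–12% milling and 12–14% swarming (the rest unclassified),
stable across seeds. Two calibration notes:

* the attraction cutoff must be an appreciable fraction of the arena radius
  (here $20\,L$): with a short cutoff the group fragments, each fish
  circulates along the wall, and the arena-scale rotation masquerades as
  milling with pair distances of tens of body lengths;
* strong hydrodynamic coupling ($S_h \gtrsim 1$) locks the group into
  permanent tight milling; weak coupling ($S_h \lesssim 0.1$) makes milling
  too rare to sample.

Growing the group at fixed parameters shifts weight into the swarming
state (about 13% at $N = 3$, dominant by $N = 20$), reproducing the
qualitative size dependence expected for this system.

### Variable speed

In variable-speed mode the speed obeys
$\dot v_i = (v_0 - v_i)/\tau_v + \mathbf F_i \cdot \hat{\mathbf e}_i$,
floored at $0.1\,v_0$. The relaxation time defaults to $\tau_v = 0.1\,T$
(30 ms): with substantially slower relaxation the force coupling lets
sustained attraction drive speeds to several $v_0$ and the group collapses
into near-permanent schooling. At the default, speeds stay within about
30% of $v_0$ and state occupancies move by at most ~0.2 relative to the
fixed-speed run, with all three states still occupied — the package's
operational reading of "speed variability leaves the observables broadly
unchanged". (The shift statistic itself carries run-to-run noise of a few
percent: the long-run dynamics is chaotic, so even compiler-level
floating-point differences select different trajectories.)

### Reproducibility

All randomness flows through R's RNG: `simulate_shoal()` seeds from
`config$seed`, so identical configs give bit-identical trajectories. The
compiled core is mirrored by a pure-R reference step (`sim_step()`,
`pair_interactions()`) and the two are cross-checked to $10^{-12}$ in the
test suite; the update rule is exactly rotation-equivariant, which is also
tested.

## Synthetic fixtures

`perfect_school()`, `perfect_mill()`, `random_swarm()` and
`ideal_gas_frames()` generate idealized configurations with closed-form
observables ($O_p \equiv 1$; $O_r \equiv 1$; mean polarization
$\sqrt{\pi/4n}$; flat correlations). They carry analytic velocity sidecars
so order-parameter tests are exact rather than limited by
finite-difference error; the finite-difference path
(`estimate_velocities()`, central differences, one-sided and flagged at the
edges) is tested separately. Fixtures emulate geometry only — they contain
no tracking noise, missing samples, or realistic dynamics (that is the
simulator's role), so tests passing on fixtures validate the estimators,
not the biology.

## Pair and triplet correlation estimators

`g2_map()` histograms neighbor positions in the focal fish's comoving frame
($x'$ along the heading, $y'$ 90° counter-clockwise), over all ordered
pairs or focal→nearest-neighbor pairs, optionally restricted to frames in
one state; maps are normalized by their maximum, with the 0.1…0.9 contour
levels available downstream. `detect_peaks()` labels local maxima as the
front peak ($\beta$) or side peaks ($\alpha$ left, $\gamma$ right) using a
relative height floor of 0.5 and a lateral tolerance of $0.5\,L$, chosen so
the three lobes of fixture data separate cleanly. Defaults: $0.2\,L$ bins
on $[-5, 5]^2$.

`radial_g2()` divides the pair-distance histogram by the shell measure
($2\pi r\,\Delta r$ in 2D, $4\pi r^2 \Delta r$ in 3D) and reports the
principal-peak location $r_{max}$. Bond angles (`bond_angles()`) take, for
each vertex of the three-fish triangle, the angle between the two incident
bonds when both lie in a separation window around the per-state $r_{max}$;
the window half-width for bond angles is $0.5\,L$ (the peak has finite
width, and the narrower $0.25\,L$ window used for the $g_3$ reference pair
leaves too few triple-bond coincidences).

`g3_map()` conditions one pair to $|r_{12}|$ in a window of half-width
$0.25\,L$ around $r_{max}$, then histograms the third fish in the frame
with origin at the pair midpoint and $\tilde x$ along $\mathbf r_{12}$.
Unconditioned maps are symmetrized over the two pair orderings and the
$\tilde x$-mirror; orientation-conditioned maps (`orientation_condition()`:
side-by-side or head-to-tail, heading and separation tolerances 30°) orient
$\tilde x$ from follower to leader. `kirkwood_map()` predicts the same map
from the radial $g_2$ via
$g_3(\tilde x,\tilde y) \propto g_2(r_{13})\,g_2(r_{23})$ (the $g_2(r_{12})$
factor is constant over the map and removed by max-normalization), with
linear interpolation between radial bins and NA flags where $g_2$ was not
estimated.

### Boundary corrections and the ideal-gas null

For points sampled in a finite region, the raw estimators measure the
region as much as the correlations: for an ideal gas in a disc of radius 5,
the uncorrected $g_3$ map shows a central deficit of about $-0.25$ relative
to the Kirkwood product — pure geometry, no interactions. Both estimators
therefore accept a `domain_radius`: `radial_g2()` divides by the analytic
disc–disc overlap factor, and `g3_map()` divides each bin by the fraction
of the observed reference-pair geometries for which that bin, mapped back
to the lab frame, lands inside the disc. With these corrections an ideal
gas gives flat profiles and the Kirkwood identity holds exactly in
expectation. Simulator and experimental-style data keep the uncorrected
default, since the shoal is far from the walls.

### The discrepancy statistic

`kirkwood_discrepancy()` reports the per-bin difference of the two
max-normalized maps and its maximum over interior bins (≥ 2 bins from the
edge). Because max-normalizing a *noisy* histogram biases every other bin
downward, a per-bin binomial envelope understates the sampling spread of
this statistic; the function therefore also simulates the full statistic
under the binomial null implied by the Kirkwood side (parametric bootstrap,
default 100 replicates, honoring the factor-2 duplication introduced by the
ordering symmetrization) and reports the null mean `null_max_abs`. On
$10^5$ ideal-gas frames the observed maximum sits at 0.6–1.0 times the null
mean, far below the 3× band used in the tests; a genuine central excess
(the experimental signature of three-body effects in schooling) is flagged
through `central_excess`.

## Numerical choices and degenerate inputs

* Coincident fish: the pairwise separation is jittered to $10^{-6}\,L$ and
  the repulsion cap applies; events are counted and reported.
* A fish exactly at the subgroup center is excluded from $O_r$.
* Angles are wrapped to $(-\pi, \pi]$; headings are recovered exactly from
  the simulator (recorded alongside positions), not by differencing.
* Histogram bins are left-closed with the top edge included in the last
  bin; values at 1.0 of either order parameter land in the last density
  bin.
* Frames with all headings undefined yield NA order parameters and are
  excluded from occupancy denominators.

## Problem sizes in the shipped checks

The test suite uses a $5\times10^5$-frame, $N = 3$ run (about 6 s of
compute) for the tristability and milling bond-angle checks, a
$10^5$-frame $N = 20$ run for the swarming size trend, $10^5$ ideal-gas
frames for the Kirkwood null, and $2\times10^4$ heading increments for the
rotational-diffusion check; these sizes give sampling errors comfortably
below the tested tolerances while keeping the whole suite around a minute.

## Known limitations

* The simulator is 2D with a circular wall; the real observation tank is a
  3D paraboloid. The analysis stack accepts 3D trajectories (the comoving
  frame uses the horizontal heading; the vertical separation is
  marginalized), but the simulator does not generate them.
* The social-force forms are minimal stand-ins constrained by qualitative
  requirements (strong attraction, weak alignment, short-range repulsion,
  rear blind zone, dipolar hydrodynamics); none are fitted to data.
* Frame-by-frame thresholding means classification flickers near state
  boundaries; no temporal smoothing is applied, and occupancy counts
  frames, not episodes.
* The bootstrap envelope treats the symmetrized map counts as a
  multinomial draw at the deduplicated sample size; residual frame-to-frame
  autocorrelation in simulator data makes it mildly anti-conservative
  there, which is why the null check is run on independent ideal-gas
  frames.
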