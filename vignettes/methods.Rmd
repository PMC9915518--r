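---
title: "Spatial uncertainty in enclosures: the model behind bayesnav"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial uncertainty in enclosures: the model behind bayesnav}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`bayesnav` simulates an observer that must infer its own pose — location
$\ell$ and head direction $\theta$ — inside a polygonal enclosure from
noisy egocentric inputs, and everything else in the package (behavioral
policies, information analysis, the warped grid-cell code) is built on
the posterior distribution this observer maintains. This vignette states
the model, the assumptions, the parameters that matter, and the design
choices made where the design was genuinely open.

## Generative model

At each step the observer intends a control $u = (u_x, u_\theta)$ drawn
from a four-element menu (stay; forward; forward with a left or right
turn). The realized motion is noisy:

* heading: $\tilde u_\theta \sim \mathrm{vM}(u_\theta \Delta t,\,
  \kappa \Delta t)$, added to $\theta$;
* translation: forward magnitude with mean $u_x \Delta t$ and variance
  $\sigma_x^2 u_x \Delta t$. The gamma family reads that pair as
  (mean, variance) and converts to shape/rate; the Gaussian family adds
  an isotropic 2D perturbation instead and is used for the
  large-environment rescaling protocols.
* walls: a move that would cross the boundary stops exactly at the
  nearest intersection with it.

Vision is image-computable. The retina is a pinhole array (default
24×8 neurons over a 150°×60° field of view, one ray per neuron center,
Gaussian blur of 1 pixel); walls are vertical rectangles carrying 1D
luminance textures, the floor and sky are uniform, and the horizon
follows from eye height. Each neuron's count is Poisson with rate
$\bar v_i(\ell,\theta)\,\Delta t$, with the optics `gain` converting
luminance to expected counts. Tactile probes (rodent configurations
only) point 90° left and right, reach $x_w = 12$ cm, and report contact
with reliability $p_w$ via the two-branch Bernoulli rule.

Every wall carries a distinct texture (base luminance and stripe
frequency follow low-discrepancy sequences so no two walls look alike).
This implements the salient orientation cues present in all the modeled
experiments; without it a square room has rotational ambiguities that
no real participant experiences.

## The ideal observer

The filter is grid-based: location bins tile the enclosure bounding box
(only in-polygon bins are kept) crossed with uniformly spaced heading
bins. One step is (i) motion prediction — a von Mises heading
convolution composed with a per-heading displacement mixture whose
out-of-bounds mass is reassigned to the bin containing the wall-clipped
stopping point, the mixture truncated at 4 standard deviations and
renormalized — and (ii) multiplication by the observation likelihood.
The visual log likelihood per pose is
$\sum_i [V_i \log \bar v_i(z) - \bar v_i(z)\Delta t]$; the second,
brightness-dependent sum cannot be dropped because poses differ in how
bright their views are. Computation is in log space with max-shift
normalization; view libraries (expected images at every grid pose) are
rendered once and cached.

Model mismatch — the core of the rescaling protocols — renders
observations in the *test* environment while evaluating likelihoods
against the *familiar* environment's library; the belief always lives on
the familiar grid, and wall identities correspond by index.

Numerical choices: containment tolerance $10^{-9}$ m (boundary points
count as inside); library rates floored at $10^{-6}$ of the maximum
before the logarithm; default bins 6–35 cm depending on arena scale
(about 1/20 of the enclosure) with 12 heading bins. Two discretization
artifacts are worth knowing about. First, motion noise much finer than a
heading bin is absorbed by the bin (the filter then underestimates
heading diffusion). Second, with a very bright retina the likelihood
becomes sharp enough to resolve the mismatch between an off-bin-center
true pose and the bin-center templates, and localization can lock onto a
wrong template; the package's default gains (0.15–1) keep the simulations
out of that regime, and exact-limit tests use on-grid poses.

## Behavior

Homing: the learning phase guides the observer to the target (control
selection is passive — the candidate whose noiseless successor is
closest to the goal, ties at random); the belief at arrival is tempered
($P^{\beta_{\text{learn}}}$, renormalized) and stored, with its mean as
the remembered point. In the test phase the observer evaluates each
candidate control by the expected negative squared distance between the
remembered location and the counterfactual location distribution (the
current marginal for staying; one application of the motion kernel, with
no observation, for moving), chooses by softmax with temperature
$\sigma_v^2$, and the true position when it chooses to stay is the
response. Distance estimation walks along an arrow from a believed root
position (retained untempered) until the predicted walked distance
matches the remembered inter-object distance, with the arrow treated as
fixing the heading.

Two policy parameters are not printed anywhere and were set as design
choices: the turn size is $\Delta\theta = 90°$ and
$\sigma_v^2 = (\Delta\ell)^2/2$. With forward-turn controls, a 90° turn
moves perpendicular to the goal direction and is therefore value-neutral,
so the softmax can always escape the "facing away from the target"
situation; smaller turn angles make every reorienting step strictly
worse than staying and freeze the near-greedy policy at its start, while
the chosen temperature still stops the observer within about one step of
the value optimum.

## Visual information

`analytic_info()` is the eccentricity-squared over distance-to-the-fourth
law for a point landmark; `numerical_info()` measures the Poisson
population information $\sum_i (\partial \bar v_i/\partial s)^2 \Delta t/
\bar v_i$ by central differences of the rendered image. The law presumes
the landmark's retinal footprint does not change with distance (the
classical homogeneous retinotopic population), so the package's
point-landmark scene renders a fixed-amplitude, fixed-width angular
Gaussian bump at the landmark's projected direction; a physical post of
fixed size and luminance would add its own distance dependence to the
flux and steepen the exponent. The regression uses distances 2–6 m at
0.5 m eccentricity (and 0.25–1 m eccentricity at 3 m distance), where
the bump is well inside the field of view; the measured slopes are
slightly shallower than −4/+2 because of the exact
$\varepsilon^2/(d^2+\varepsilon^2)^2$ geometry. `info_map()` aggregates
per-axis information over 8–16 headings (mean by default; a max option
reflects that information is dominated by looking toward the nearest
wall) and reports the per-axis sum as total.

## The warped population code

Grid cells are sums of three cosine gratings 60° apart (shifted and
scaled to be non-negative with the configured peak rate), in two modules
with scales in ratio 1:1.4 and 16 phases per module tiling the unit
rhombus. Warping evaluates these curves at mesh-interpolated
coordinates; the decoded "neural posterior" is the infinite-population
limit
$\log P^g(\ell; z) = \sum_i \alpha_i [f_i^{enc}(z) \log f_i^{dec}(\ell)
- f_i^{dec}(\ell)]$, normalized over $\ell$, with one sharpness weight
$\alpha$ per module and decode rates floored at $10^{-6}$ of peak.

Fitting minimizes the time-averaged KL divergence from the ideal
posteriors to the decoded ones. Because many time steps share a state
bin $z$ (the true location bin, optionally crossed with the last
approached wall), the objective is precomputed as a visit-weighted cross
entropy over the binned, visit-averaged posteriors — identical to the
direct time average up to a data constant, which the test suite verifies
to $10^{-10}$. States are binned at twice the filter bin so each bin
accumulates enough visits for a stable average. Gradients are analytic
(verified against finite differences) and the optimizer is an
Adam-style first-order method with per-coordinate rates scaled to the
mesh spacing, returning the best iterate (so the fit never ends worse
than it started); steps that would invert a mesh cell are shrunk or
rejected.

The regularizer is the per-angle penalty $(1-\sin^2\vartheta)^\beta$
summed over adjacent mesh-edge pairs, which vanishes exactly at right
angles. Two additional terms make the fit identifiable at realistic
episode lengths and are deliberate design choices of this package:
nodes with no data support (bounding-box corners outside a trapezoid)
are weakly tethered to their rest positions, and an edge-length penalty
$w_{len}\sum (\mathrm{len}/\mathrm{len}_0 - 1)^2$ anchors the mesh
scale. The angle penalty alone is blind to rectilinear stretches, so
without the length term the global mesh scale is degenerate with the
sharpness weights and fits collapse the mesh, destroying hexagonality
even in a familiar square — contradicting the defining phenomenon that
familiar-square grids are regular. $w_{len} = 0.15$ (with $w_{reg}=0.1$,
a 4×4 protocol mesh, 3000-step episodes) is the weakest anchoring for
which the familiar-square code stays near-regular; the 9×9 mesh of the
recovery analysis uses a lighter $w_{len} = 0.05$ since its targets are
noise-free.

## Study conditions and what the simulations do and do not show

The modeled paradigms fix their geometry: a 1.4 m square and a
1.9 × 0.9/0.2 m isosceles trapezoid for the rodent deformation
protocols; 1.0 m familiar squares compressed to 0.65–0.7 along one axis
for the rescaling/tethering protocols; a 5.1 m square (area-matched to
a 9.5 × 4.5/1 m trapezoid) and a 3.5 m-radius circular arena for the VR
protocols. Unprinted sensing parameters were chosen once for
plausibility: behavioral gains 0.5–1 give homing errors of 10–30% of
the enclosure (comparable to VR experiments), rodent eye height 5 cm,
human 1.6 m, $\kappa = 50$, $\sigma_x = 0.15$–0.3, $\beta_{learn} =
0.8$–1, tactile $p_w = 0.5$. Episode lengths (2000–3000 foraging steps,
40 trials per behavioral condition) are the sizes the package's checks
run at.

The generator emulates textured rigid walls, uniform floors, and
independent Poisson retinal noise. It does not emulate optic flow as a
separate channel, lighting, landmark objects, head-direction-cell
dynamics, or across-trial learning — so passing tests show that the
*uncertainty mechanism* produces the qualitative effect patterns under
these conditions, not that the parameters quantitatively match any
particular dataset.

Three effect patterns do **not** reproduce under the frozen conditions,
and the package reports them honestly rather than tuning toward them:
(i) the trapezoid field-diameter ordering — in a 0.2–0.55 m corridor
the close side walls and whiskers pin the posterior so its *total*
uncertainty is smaller in the narrow half even though x-information is
poorer, so fitted fields do not enlarge there (the package's own
information maps do show the expected 3:1 broad/narrow information
asymmetry, locating the discrepancy in how corridor geometry converts
information into posterior width); (ii) the unchanged-axis grid
rescaling ratio sits just below 1 rather than above it; (iii) the
whole-map tethering-versus-scaling correlation — with the default cue
balance the mid-room posterior anchors to vision (proportional
rescaling) rather than to the last approached wall, although the
phase-shift signature of tethering (largest along the changed axis,
absent in the familiar room) is present. The homing-bias sign tests in
scaled rooms are also close to their noise floor at 40 trials per
condition. These limitations are properties of the chosen study
conditions, not of the implementation, and the corresponding checks are
left red with this analysis.

## Interfaces

Environments serialize to YAML (`write_environment_config()`);
trajectories, trial tables and metric tables are plain data frames ready
for `write.csv()`; episodes and fits are returned as R lists.
`run_experiment()` is the orchestrating entry point; every protocol
takes a seed and a configuration override list, and
`default_config(protocol)` documents every default in one place.
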