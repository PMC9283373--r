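---
title: "Homeostatic Langevin dynamics of adherent cell morphology and motility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homeostatic Langevin dynamics of adherent cell morphology and motility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlecell)
```

## The model

An adherent cell on a flat substrate is treated as a two-dimensional
incompressible body of resting radius $R_0$ and thickness $b_0$, with a
concentric nucleus of radius $R_N$. A *morphological microstate* is a smooth
displacement field applied to the resting disc, parameterised by a $4\times4$
grid of control points of a bicubic tensor-product spline (open knot vectors,
unit weights — a single Bezier patch). The 32 control displacements
$\hat r_q$ are the only configurational degrees of freedom; features finer
than the patch resolution (filopodium-scale wiggles) are deliberately not
representable.

Each microstate is scored by a Gibbs free energy with two ingredients:

* **Stress-fibre chemo-mechanics.** At every material point, contractile
  stress-fibres at orientation $\phi$ (measured from the stripe axis $x_2$ in
  the reference configuration) equilibrate chemically with a well-mixed pool
  of unbound protein packets. The functional-unit count per fibre scales
  linearly with the fibre stretch, $\hat n^{ss} = \lambda(\phi)/(1 +
  \tilde\varepsilon^{ss}_{nom})$, and the bound enthalpy per packet is
  lowered by the isometric tension work $\sigma_{max}\Omega(1 +
  \tilde\varepsilon^{ss}_{nom})$. Chemical equilibrium gives a closed-form
  angular concentration $\hat\eta(\lambda)$, saturating at $\hat\eta_{max}$,
  and a single scalar unbound fraction $\hat N_u$ fixed by protein
  conservation over the cytoplasm. At equilibrium the entire cytoskeletal
  contribution collapses to $\rho_0 V_C \chi_u$ with $\chi_u = \mu_u + k_BT
  \ln \hat N_u$ per packet.
* **Passive elasticity.** Cytoplasm and nucleus follow a two-dimensional
  Ogden-type energy in the principal stretches, plus a quadratic in-plane
  area term and a compression penalty $\bar\kappa\,H(J_c - J)(J - J_c)^2$.
  The nucleus is an order of magnitude more nonlinear (shear exponent
  $m_N = 20$ vs $m_C = 5$), which is what ultimately limits cell elongation.

The substrate is rigid and uniformly adhesive (or adhesive only on a stripe
of normalised width $\hat W = W/2R_0$); the adhesion energy is
configuration-independent and dropped.

All lengths are in units of $R_0$ and stresses in kPa, so energies carry
kPa·$R_0^3$; $\rho_0 k_B T \approx 12.8$ kPa sets the cytoskeletal scale
against the moduli. The reference constants $\mu_u$ and $\pi N_L$ only shift
or rescale the energy; both default to 0 and 1.

### The suspension reference

A cell in suspension must be self-equilibrated. For the default
(myofibroblast) parameters the package solves the one-variable traction-free
condition $\sigma^A(\lambda) + \sigma^p(\lambda) = 0$ for a uniform
equibiaxial stretch with the nucleus left undeformed:

```{r}
susp <- suspension_state(cell_parameters())
susp
```

The solved radius is `r round(suspension_state()$radius_ratio, 4)` $R_0$
(the literature value for this parameter family is quoted as $0.92\,R_0$;
the difference is below one percent and traces to the unit reading of the
functional-unit volume $\Omega$, which is stated in the parameter
documentation). The energy of this state, $G_S < 0$, normalises every other
energy: $\hat G = G/|G_S|$.

## The homeostatic ensemble and its temperature

Over times long compared to its internal biochemistry the cell fluctuates
over microstates with stationary probability $P_{eq} \propto
\exp(-\hat\zeta \hat G)$, where the *homeostatic temperature* $1/\hat\zeta$
is not a free parameter: it is calibrated so that the ensemble mean energy
equals the suspension value, $\langle\hat G\rangle = \hat G_S$. The package
samples the ensemble by single-coordinate random-walk Metropolis over the 32
control displacements, with hard rejection of folded meshes and of
configurations protruding beyond the stripe, and solves
$\langle\hat G\rangle(\hat\zeta) = \hat G_S$ by a bracketed bisection on
chain averages run with common random numbers.

### Sampling locality

The discretised free-energy landscape is not globally bounded in any useful
sense: beyond the physical basin of spread morphologies there exist strongly
distorted "needle" states in which a thin region of cytoplasm is stretched
many-fold, paying a modest local Ogden cost against a global logarithmic
cytoskeletal reward. An unbounded-step sampler eventually drifts there, but
nothing in the observed biology (or in the stationary statistics this model
family is known for) lives in that region. The package therefore adopts an
explicitly *basin-local* sampling protocol: chains start from the seeded
suspension configuration and the adapted Metropolis step is capped at
$0.1\,R_0$, i.e. microstate moves stay below the spline feature wavelength.
The homeostatic average — and hence the calibrated $1/\hat\zeta$ — is defined
over this protocol. Admissibility also imposes $J = \lambda_I\lambda_{II} >
0.02$ per element (a fifty-fold in-plane compression, far beyond the penalty
threshold $J_c = 0.6$), which keeps the chain away from numerically stiff
near-fold states. Both choices are stated here once and used everywhere;
passing tests demonstrate properties of this protocol, not of an
(ill-defined) global ensemble.

## The Langevin extension

Temporal evolution follows overdamped Langevin dynamics on the control
displacements,
$$\partial_{\hat t}\hat r_q = -\partial\hat G/\partial\hat r_q +
\sqrt{2/(\hat\zeta\,\Delta\hat t)}\;\mathcal N(0,1),$$
whose Fokker–Planck stationary law is exactly the homeostatic ensemble. Time
is normalised by $\gamma R_0^2/|G_S|$ (about 10 minutes for fibroblasts; a
pure relabelling of the axis). Integration is forward Euler–Maruyama.

Numerical policies, stated once:

* **Gradients** are finite differences of $\hat G$: adaptive
  Richardson-extrapolated differences are available for verification
  (`scheme = "richardson"`), and plain central or forward differences
  (`h = 10^{-6}`) run in the compiled core. The forward scheme halves the
  energy evaluations per step; its $O(h)$ bias is orders of magnitude below
  the per-step noise at the step sizes used and is the default for ensemble
  production runs.
* **Stiff events.** A proposal that folds the mesh is retried with fresh
  noise; persistent folding means the drift itself is stiff, so the local
  step is halved (noise rescaling with it, keeping the discretisation
  consistent) down to a floor, after which the move is rejected in the
  Monte-Carlo sense (time advances, state stays). An energy jump with
  $\hat\zeta\,\Delta\hat G > 50$ — Boltzmann weight below $10^{-21}$ — is
  treated the same way: it can only be an Euler overshoot of a penalty or
  barrier wall.
* **Stripes** enter the dynamics as a smooth quartic barrier
  $\kappa_w \sum \max(0, |x_1| - \hat W)^4$ over the nodes
  ($\kappa_w = 250$, chosen so an order-one driving force equilibrates at a
  protrusion depth below half an element edge), because the integrator needs
  a differentiable forcing where the sampler can simply reject.

## The reduced elliptical cell

To expose why cell area and cell shape evolve on different timescales the
package also implements the two-variable reduced model: the cell is a
spatially uniform ellipse with principal stretches $(\lambda_1, \lambda_2)$
and fixed axes. The same chemistry and elasticity are evaluated for
$F = \mathrm{diag}(\lambda_1,\lambda_2)$, with the nucleus co-deforming
affinely — its nonlinearity is precisely what bounds the equilibrium aspect
ratio. The nucleus energy is measured relative to the equibiaxial suspension
stretch so that the reduced energy at $(\lambda_s, \lambda_s)$ equals
$\hat G_S$ exactly (a constant shift; gradients are untouched).

The noise-free gradient flow $\dot\lambda_i = -\partial\hat G/
\partial\lambda_i$ from the suspension state shows three regimes: fast
isotropic spreading at $A_S \approx 1$, then elongation at nearly constant
area, then a final minor drift of both. Because pure gradient flow from an
exactly symmetric point stays symmetric forever, the default start carries an
infinitesimal ($10^{-6}$) asymmetric perturbation; any real noise breaks the
symmetry the same way. With the default parameters the fitted exponential
timescales are $\tau_{\hat A} \approx 0.4$ and $\tau_{A_S} \approx 12$ — a
thirty-fold separation arising purely from the topology of the landscape:

```{r, eval = FALSE}
fl <- gradient_flow(cell_parameters())
plot(fl$t_hat, fl$A_over_AR, type = "l", xlab = "t_hat", ylab = "A / A_R")
lines(fl$t_hat, fl$AS, lty = 2)
```

## Observables

Per frame the package records the boundary polygon's area, perimeter and
form factor $FF = p^2/(4\pi A)$, and the best-fit ellipse (equal area and
equal central second moments — the standard image-analysis construction)
giving the aspect ratio and the orientation $\varphi$ of the major axis
relative to the stripe. Ensemble metrics follow the standard definitions:
normalised area $\hat A = (\bar A - A_R)/(A_\infty - A_R)$; squared centroid
displacements and their ensemble mean $\widehat{MSD}$; the stripe-direction
$\widehat{MSD}_y$ and the motility dimensionality $\hat\Lambda =
2(\widehat{MSD} - \widehat{MSD}_y)/\widehat{MSD}$ (1 for isotropic 2D
motion, 0 for motion confined to the stripe axis); the nematic order
parameter $\Theta = \sqrt{\langle\cos2\varphi\rangle^2 +
\langle\sin2\varphi\rangle^2}$ over trajectories; and its cytoskeletal
analogue $\Theta_{cyto}$, computed per configuration from the
volume-centred dominant-fibre direction field and then averaged over the
ensemble (the centring makes it rotation-invariant). Timescales are
extracted by fitting $x(\hat t) = x_\infty - (x_\infty - x_R)
e^{-\hat t/\tau_x}$ with the endpoints fixed from the data, so $\tau_x$ is
the only fitted parameter.

Axial quantities use the doubled-angle convention throughout; `phi_max` ties
are broken toward the smallest $|\phi|$ for deterministic rendering; MSD
slopes are fitted over the final 90% of the time window (the transient is
skipped) and the window is recorded. $\hat\Lambda$ can formally reach 2 if
motion concentrates across the stripe; the $[0,1]$ reading applies to
stripe-aligned patterns.

## Problem sizes and what the tests show

The package's own study scale — used by its validation suite and chosen once
— is: element edge $R_0/5$ (about 165 constant-strain triangles), 12 angular
bins, $\Delta\hat t = 0.01$ (checked by step-halving on short ensembles),
forward-difference gradients, $n = 20$ trajectories to $\hat T = 200$, and
Metropolis chains of 40,000 proposals for calibration. At this scale the
qualitative physics is reproduced: the suspension radius; Boltzmann
stationarity and equipartition of the samplers on closed-form toys; the
reduced model's timescale separation; area equilibrating faster than aspect
ratio on unpatterned substrates; the collapse of $\hat\Lambda$ and the rise
of $\Theta$ under narrow-stripe confinement; and centroid motility much more
sluggish than the bare homeostatic diffusivity $1/\hat\zeta$ (coordinated
morphological motion is required for displacement). The quantitative
full-scale numbers of the framework (e.g. a normalised MSD slope of order
0.06 with $\hat D \approx 0.23$) require the fine mesh, $\Delta\hat t =
10^{-3}$ and hundreds of trajectories to $\hat t = 4000$ — cluster-scale
computations outside the scope of the test suite, whose chain-mean
estimators at desk scale also carry appreciable Monte-Carlo spread (the
tests state their error bars accordingly).

The synthetic toy systems (quadratic wells, a double well, a two-level
system) emulate only the statistical mechanics of the machinery — they have
exact Boltzmann measures, stationary variances and visit ratios — and say
nothing about cell biology; conversely the cell-scale ensembles inherit
every modelling idealisation above (2D, rigid substrate, constant adhesion
energy, no fibre kinetics below steady state, no ballistic motility below
the correlation time).

## Known limitations

* Observables of the stochastic cell model at desk scale are
  protocol-dependent through the basin-local sampling policy; the global
  landscape of the printed energy is deeper than the physical basin.
* The orientation of the best-fit ellipse is numerically arbitrary for
  near-circular cells; order parameters at early times average over such
  angles, exactly as experimental image analysis would.
* Euler–Maruyama with substepping is first order; no higher-order stochastic
  integrators are provided.
* The stripe barrier stiffness and the admissibility floor are numerical
  regularisations; results insensitive to them at the tested scales, but
  they are not part of the physical model.
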