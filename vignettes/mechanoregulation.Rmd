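---
title: "Mechano-regulated peri-implant healing: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechano-regulated peri-implant healing: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`osseoheal` simulates the first 35 days of tissue differentiation in the
healing chamber (the void between implant threads) after dental implant
insertion. The modelling chain per healing day is:

1. **Poroelastic load step.** The bone-implant system is a 2D axisymmetric
   Biot consolidation problem: drained linear elasticity for the solid
   skeleton coupled to Darcy flow of the interstitial fluid. An average
   axial displacement of 8 µm — the displacement a ~100 N bite force
   produces — is prescribed on the implant top surface and ramped over 1 s
   in 10 implicit (backward Euler) steps. The implant (Ti-6Al-4V) is an
   elastic solid without pore pressure; callus, cortical and cancellous
   bone are poroelastic with Biot coefficient 1 and incompressible
   constituents.
2. **Stimulus and phenotype.** At peak load each callus element's
   octahedral shear strain $\gamma$ and interstitial fluid speed
   $\nu = \lVert -k \nabla p \rVert$ (µm/s) combine into the scalar
   stimulus
   $$S = \frac{\gamma}{a} + \frac{\nu}{b}, \qquad a = 0.0375,\;
   b = 3\ \mu\text{m/s},$$
   which sets the element's tissue phenotype for the next day: fibrous
   tissue ($S > 3$), cartilage ($3 \ge S > 1$), immature bone
   ($1 \ge S > 0.266$), mature bone ($0.266 \ge S > 0.010$) and resorption
   ($0.010 \ge S$). Upper ends are closed; $S = 0$ (zero load) classifies
   as resorption.
3. **Stem-cell invasion.** Mesenchymal stem cells diffuse into the callus,
   $\partial n / \partial t = D \nabla^2 n$, from the callus outer boundary
   (the cells origin, held at the maximal concentration); all other callus
   boundaries are no-flux. One implicit step per day. The diffusivity D is
   calibrated (bisection, 1 % relative) as the smallest value for which
   the callus-wide minimum concentration reaches 99 % of the maximum by
   day 35 — "maximal concentration" is read numerically as a 0.99
   threshold since the exact maximum is only reached asymptotically.
4. **Property mixing.** Each element's material properties interpolate
   linearly between granulation tissue ($X_g$) and its differentiated
   phenotype ($X_d$) by local concentration:
   $X_{mix} = \frac{n_{max}-n_i}{n_{max}} X_g + \frac{n_i}{n_{max}} X_d$.
5. **Temporal smoothing.** To avoid abrupt stiffness jumps, the properties
   driving the next day's solve average the fresh $X_{mix}$ with the
   smoothed values of up to the nine previous days
   ($X_i = \tfrac1N (X_{mix} + X_{i-1} + \dots + X_{i-(N-1)})$, $N = 10$);
   for $i < N$ the window truncates to the available history and the
   denominator is the number of summed terms, so early averages are
   well defined.

Material properties (drained Young's modulus in MPa, Poisson ratio,
hydraulic mobility in m⁴/(N·s)): granulation 1 / 0.17 / 1e-14, fibrous
2 / 0.17 / 1e-14, cartilage 10 / 0.17 / 5e-15, immature bone
1000 / 0.30 / 1e-13, mature bone 6000 / 0.30 / 3.7e-13, cortical
20000 / 0.30 / 1e-17, cancellous 6000 / 0.30 / 3.7e-13, implant
113000 / 0.30 (solid). Resorption has no tabulated entry: resorbed
elements take granulation properties (the softest state) and count as
non-bone in the morphometry.

Histomorphometry scores a design by **BIC** (per cent of the thread
flank-and-root interface length adjoining mature/immature bone; crest
faces, collar, apex and tip are excluded) and **BA** (per cent of the
inter-thread area occupied by bone elements). Area weighting uses
in-plane element areas, mimicking a 2D histology section; a volume
(2πr) weighting would emphasize the outer callus instead.

## Geometry and meshing

Implants are parametric: a thread unit is a crest, an upper flank at
angle φ to the load direction (90° = flat, smaller = steeper; axial flank
extent $d/\tan\varphi$), a root, and a lower flank, repeated `n_threads`
times between a collar and an apex. Beak-shaped styles split the chamber
into a shallow and a deep half (`eagle_beak` deepens the lower half,
`inverse_eagle_beak` the upper). The eight catalogued designs A–H encode
only the published ordering relations (φ_A > φ_E > φ_F; r_B < r_G,
c_B < c_G; d_C < d_H; D/H beak variants of C); absolute dimensions are
package choices (4 mm diameter, 0.8 mm pitch, 8 mm embedded length,
0.5 mm callus band, 1.5 mm cortical stratum) exposed as parameters.

The outline is kept single-valued in the axial coordinate, r = f(z).
The mesher places a horizontal mesh line at every geometric breakpoint
and grades each row's radial nodes in three bands (implant interior,
callus band, outer bone) whose limits follow f(z). Every element is a
trapezoid with two horizontal edges — positive Jacobians by
construction — and every region boundary lies on mesh lines, so region
areas are conserved exactly at any resolution. This boundary-fitted
structured mesher replaces a general unstructured quad mesher: it is
deterministic, dependency-free and exact for this geometry family, at
the cost of not supporting overhanging (truly undercut) profiles; beak
chambers are therefore approximated by their non-overhanging outline.

## Interface mechanics

The implant-bone interface is frictional (µ = 0.3). Two modes are
implemented. `tied` shares mesh nodes across the interface — cheap, and
the right limit for a fully osseointegrated interface. The default,
`coulomb_penalty`, duplicates the interface nodes, couples them with
bilateral normal penalty springs, and imposes Coulomb friction by a
projected-Newton return mapping on tangential pair forces, using
per-pair compliances probed from the single factorized operator
(loading within a day is monotone, so total slip stands in for the slip
rate). The frictional default matters scientifically: with a tied
interface, collar shear drags the crestal callus with the implant and
the stimulus there never falls into the resorption range, so the
characteristic crestal bone loss at the implant neck cannot emerge;
with sliding, the smooth collar unloads and resorption initiates at the
top callus surface. The penalty stiffness (1e7 N/mm³) and iteration
budget are configurable.

## Numerical choices

* Bilinear 4-node quadrilaterals for displacement and pressure, 2×2
  Gauss integration, axisymmetric weight r (the common 2π is dropped
  consistently). Strains, pressure gradients and stimuli are evaluated
  at element centroids — one phenotype per element.
* Zero storativity makes pore pressure instantaneous in the
  displacement history: each daily solve restarts from the unloaded
  state, which represents discrete daily loading episodes rather than a
  sustained bite force.
* The fluid speed is the Euclidean norm of the Darcy flux components;
  the stimulus uses it in µm/s (catalog permeabilities in m⁴/(N·s) are
  converted internally to mm⁴/(N·s)).
* Backward Euler with a lumped mass matrix keeps the diffusion step
  monotone; bilinear quads are not strictly M-matrices, so
  concentration excursions up to 1e-4 of the maximum are clamped and
  anything larger raises an error (it signals a genuine mesh/step
  misconfiguration).
* Classification uses exact threshold comparisons, so boundary stimuli
  (3, 1, 0.266, 0.010) classify per the closed upper ends.
* Within a day the order of operations is solve → classify → diffuse →
  mix → smooth; the phenotype recorded for day d is the one in effect
  during day d (granulation on day 1, thereafter the previous day's
  classification).

## What the fixtures emulate — and what they do not

The verification fixtures carry their own oracles: a Terzaghi
consolidation column (series solution), a pressurized thick-walled
cylinder (Lamé closed form), a 1D diffusion strip (half-space erfc
solution and a first-mode slab estimate of the calibrated diffusivity),
and a single-chamber implant toy. The toy's crestal band is a
collar-depth region (0.8 mm collar and cortical stratum, over a 1.2 mm
apex shank so the collar is about a quarter of the callus height, close
to the proportion of a real implant) — deep enough for the crestal
shielding mechanism to be resolved in a one-thread geometry. Because
that single thread carries the entire 8 µm load, its chamber sees
several times the per-thread stimulus of an eight-thread implant and
stays soft-tissue dominated; the toy therefore demonstrates crestal
resorption, not realistic BIC/BA levels, and its callus-mean stimulus
stays essentially flat over the healing period (the chamber never
unloads) even though the full eight-thread geometries all show the
expected decrease of the mean stimulus between day 4 and day 35.
Design comparisons (the A–H catalog) use the full eight-thread
geometries at 0.1 mm element size — twice the reference 0.05 mm — which
keeps a 35-day run around two minutes. At this scale, with the
calibrated cell invasion, all catalog analogs finish with saturated
(100 %) BIC and BA: the stimulus stays in the bone-forming range across
the thread interface, so published design orderings hold only as ties
and the resorption-driven BIC contrasts between real designs are not
reproduced. None of the synthetic geometries reproduces the proprietary
commercial thread forms; only ordering relations between designs are
meaningful, never absolute BIC/BA values.

## Known limitations

* 2D axisymmetry admits vertical loading only; thread helix angle,
  lateral and oblique loads are out of scope.
* Small-strain, quasi-static mechanics; no separation at the interface
  (the normal penalty is bilateral).
* Single cell species, pure diffusion — no proliferation, haptotaxis or
  angiogenesis.
* Deformation-theory friction within a day (no cyclic slip history).
* Concentration is nodal; element values are corner averages when fed
  into the mixing rule.
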