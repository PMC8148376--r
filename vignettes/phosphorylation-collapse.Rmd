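---
title: "Charge-driven conformational response of IDPs to multisite phosphorylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Charge-driven conformational response of IDPs to multisite phosphorylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosflex)
```

## The question

Multisite phosphorylation adds up to two negative elementary charges per
modified Ser/Thr/Tyr.  For an intrinsically disordered protein (IDP),
whose conformational ensemble sits on a nearly flat free-energy
landscape, such a perturbation can shift the whole ensemble: simple
electrostatics predicts that phosphorylating a positively charged chain
reduces internal repulsion and lets it contract, while phosphorylating a
neutral or negatively charged chain adds repulsion and swells it.
`phosflex` packages the machinery to study this quantitatively on
coarse-grained ensembles: sequence charge descriptors, a Monte Carlo
ensemble generator with screened electrostatics, radius-of-gyration and
SAXS/Guinier observables, salt-bridge and binding-site-shielding
analyses, and the "V-shape" regression of normalized Rg on net charge
per residue (NCPR).

The package ships four ~66-83-residue fragments known to undergo
multisite phosphorylation in vivo (`idp_fragments()`): yeast Ash1
(420-500, net charge +15, 10 Ser/Thr sites), the RNA polymerase II
CTD2' repeat region (1659-1741, net 0, 10 Ser sites), the E-Cadherin
cytosolic domain (735-800, net -9, 8 sites) and a p130Cas fragment
(631-696, net -4, 6 Tyr/Ser sites).  With a fully deprotonated
phosphate (charge -2, the prevalent species at pH ~7.5 given
phosphoester pKa of 5.5-6) the fully phosphorylated net charges are
-5, -20, -25 and -16 respectively.

```{r descriptors}
sequence_descriptors(idp_fragments()$Ash1)[, 1:7]
```

## Charge model

`charge_model()` assigns fixed formal charges at pH ~7.5: Asp/Glu -1,
Lys/Arg +1, His 0 (configurable: its solution pKa ~6 leaves it mostly
neutral at 7.5).  Chain termini are acetyl/amide capped and contribute
no charge; a free-termini mode (+1/-1) exists but is off by default.
Phosphosites take -2 (default) or -1 (mono-protonated regime,
2.2 < pH < 6), and a phosphomimetic mode rewrites sites to Glu with -1.
Protonation is a discrete mode switch; no pKa prediction or titration is
attempted.

Two descriptors beyond net charge and NCPR summarize charge patterning
along the sequence: the sequence Coulomb potential
$\sum_{i<j} Q_i Q_j / |j-i|$ and force $\sum_{i<j} Q_i Q_j / |j-i|^2$,
dimensionless sums over residue index separation.  We fix the exponents
at 1 and 2 (the natural reading of "potential" and "force") and sum over
unordered pairs; a global sign flip leaves both invariant.

## The coarse-grained ensemble generator

The generator stands in for all-atom molecular dynamics, which is out of
reach at desk scale.  It aims to reproduce *directions and orderings* of
the phosphorylation response, never Angstrom magnitudes.

One bead per residue on rigid virtual bonds of 3.8 Å (the Cα-Cα
spacing).  The pair energy, in units of kT, contains:

* **WCA excluded volume** between beads at least two positions apart,
  with contact distance $r_i + r_j$ (default bead radius 3.0 Å, an
  effective residue size);
* a **uniform square-well attraction** (default 0.1 kT within 9 Å), a
  generic solvent-mediated stickiness that keeps neutral chains slightly
  below athermal-coil dimensions;
* a **Debye–Hückel screened Coulomb term**
  $q_i q_j \, \ell_B \, e^{-r/\lambda_D} / r$ with Bjerrum length
  $\ell_B = 7.1$ Å (water, 300 K).  The screening length
  $\lambda_D$ comes from the 1:1-salt closed form
  (`debye_length()`; 9.6 Å at 100 mM, 5.1 Å at 350 mM, 2.5 Å at
  1.5 M), so ionic strength is the single knob that attenuates all
  charge effects;
* a **phosphate radius increment** on beads carrying a phosphate,
  entering both the excluded volume and the surface readout.  This
  models the bulky, strongly hydrated PO₄ moiety, and it is
  residue-typed: +0.3 Å on phospho-Ser/Thr, whose compact phosphate
  barely enlarges the residue envelope, and +1.4 Å on phospho-Tyr,
  where the phosphate extends an already long aromatic side arm.  The
  distinction matters twice over.  For the binding-site exposure
  analysis, point-like phosphates get it qualitatively wrong: the extra
  negative charge *attracts* nearby Lys/Arg segments and increases,
  rather than decreases, the shielding of the (tyrosine) sites of
  E-Cadherin and p130Cas — the pTyr steric term restores the
  unshielding.  Conversely, a comparably large increment on the ten
  Ser/Thr phosphates of Ash1 or CTD2' would add a salt-independent
  swelling of several Å that overwhelms the screened electrostatic
  response and destroys the salt attenuation of |ΔRg|, so the Ser/Thr
  value must stay small.  Both values were calibrated once, jointly,
  against the qualitative directions (Ash1 collapse at 100 mM and its
  attenuation to 1.5 M; unshielding of the two-site states at 350 mM)
  and then frozen.

Sampling is Metropolis Monte Carlo from an extended linear start, with
three bond-preserving move classes (pivot about a random bead,
crankshaft rotation of an internal segment, single-bead rotation; all
are rigid rotations, so bond lengths are exact to machine precision and
proposal distributions are symmetric).  One sweep is N trial moves; the
leading 25% of sweeps is discarded as equilibration (the Monte Carlo
analog of discarding the leading segment of an MD trajectory) and frames
are saved every `save_stride` sweeps.  Seeds are mandatory and recorded
in the ensemble provenance; the same seed regenerates an ensemble
bit-for-bit.  Acceptance ratios are logged per move class, and a run in
which nothing is ever accepted warns about a stalled sampler.

Two analytic reference generators support validation:
`generate_gaussian_chain_ensemble()` (ideal random walks, with
$\langle R_g^2\rangle = b^2(N^2-1)/(6N)$ exactly) and
`uniform_ball_points()` (uniform solid-ball clouds, with
$R_g = \sqrt{3/5}\,R$), used as oracles for the Guinier and SASA
machinery.  A 3-bead chain with terminal charges provides a
detailed-balance smoke test: its single internal angle has a closed-form
Boltzmann density that long runs must reproduce.

### What the generator does and does not emulate

It reproduces: the sign of the Rg change upon multisite phosphorylation
as a function of initial net charge; the attenuation of that change with
salt; the salt-bridge bookkeeping; and the relative exposure of binding
sites.  It does not attempt: secondary-structure propensities, proline
rigidity, specific ion effects, polarization, hydrodynamics, or the
absolute ΔRg magnitudes of atomistic simulations (of order 10 Å at low
salt for an 81-mer), which depend on microsecond all-atom sampling.
Passing directional tests here says the charge logic is implemented
correctly, not that real ensembles were reached.

## Observables

**Rg statistics.** `radius_of_gyration()` is mass-weighted (standard
residue masses by default; the coarse-grained validation tests use
uniform masses).  Ensemble standard errors use block averaging with
block size $\approx\sqrt{n_\text{frames}}$ by default, a standard
compromise against Monte Carlo autocorrelation; `convergence_profile()`
reports cumulative means over growing frame windows.  For cross-sequence
comparison Rg is normalized by the excluded-volume-coil reference
$R_c = R_0 N^{0.588}$.  $R_0$ defaults to 2.0 Å; its value scales all
normalized Rg equally and cancels from every cross-state comparison at
equal N, so no conclusion here depends on it.

**SAXS.** `debye_intensity()` evaluates the Debye formula
$I(q) = \sum_{ij} f_i f_j \sin(qr_{ij})/(qr_{ij})$ (per-bead form
factors default to 1; the $q\to0$ and $i=j$ limits are analytic), and
`ensemble_average_intensity()` averages it over frames.  Because the
low-q intensity weights conformations by their squared size, ensemble
curves must average enough frames for the z-average to stabilize; the
pipeline uses at least ~150 frames per curve.  The hydration shell is a
deliberately parametric contrast model (`hydration_model()`): every
bead whose SASA fraction exceeds a threshold (0.3) receives one extra
scatterer of weight 0.5 placed 5 Å outward from the chain centroid,
and phosphosite shells are boosted by a factor 5 — this single term
lumps the dense first hydration layers and the condensed counterion
cloud of the doubly charged phosphate.  The weights were calibrated
once so that the hydration term masks a substantial fraction (~10–30%
at these ensemble sizes) of the Ash1 collapse in Guinier terms, the
qualitative signature seen when comparing solvation-aware scattering
with bare-chain dimensions; they were then frozen.  This replaces
explicit-solvent scattering calculations, which are out of scope.

**Guinier analysis.** `guinier_fit()` fits ln I against q² by weighted
least squares over the largest low-q window with $q R_g$ below a limit,
iterating window selection to a fixed point ($R_g$ change < 10⁻⁶ Å,
at most 50 iterations).  The standard mode uses $qR_g \le 1.0$, the
conservative textbook Guinier region: on an exact uniform-sphere form
factor the truncation bias is then +0.9%, whereas a 1.1 limit already
exceeds 1%.  The extended mode for disordered chains widens the window
to $qR_g \le 1.9$; the wider window trades accuracy (a coil fit at 1.9
underestimates Rg by ~13%) for stability on flat disordered-chain
curves, which is acceptable because it is used comparatively, on pairs
of states analyzed identically.  For an ensemble curve, Guinier Rg
estimates the intensity-weighted (z-average) size; at the standard
window this nearly coincides with the arithmetic mean per-frame Rg for
coil ensembles (the −3% truncation bias and the +3% z-average-vs-mean
offset almost cancel), which is the convention used when comparing
against the direct ensemble Rg.

**χ².** `chi_square()` interpolates the calculated curve linearly onto
the reference grid, absorbs a single multiplicative scale in closed form
(no additive background — whether one should be fitted is left open),
and reports $\chi^2 = \frac{1}{N-1}\sum_q [(cI_\text{calc}-I_\text{ref})/\sigma]^2$.

**Salt bridges.** A bridge is an unordered pair of opposite-sign beads
at sequence separation ≥ 2 within a cutoff.  The default cutoff is
9.0 Å — 1.5× the 6 Å contact diameter of two standard beads, i.e. the
first coordination shell.  Atomistic N–O criteria (~4 Å) do not
transfer to single-bead residues, and a 6.5 Å cutoff would sit inside
this model's excluded-volume wall and count essentially nothing.
Bridges are classified as D/E–R/K (both partners unmodified charged
residues) or phosphate-mediated (at least one active phosphosite), the
latter also normalized per active site.

**SASA and shielding.** `shrake_rupley_sasa()` uses a deterministic
golden-spiral quadrature (512 points by default; 1% accuracy on
analytic sphere tests), making every surface number bit-reproducible.
The shielded area of a binding site is the SASA of the site-only
sub-conformation (same internal coordinates) minus the same residues'
SASA within the full chain — the part of the interaction surface
occluded by the rest of the IDP.  The 10-residue binding windows are
configurable inputs; the defaults center on E-Cadherin Y753/Y754 (the
p120-binding juxtamembrane region) and p130Cas Y664/Y666 (the Src
SH2-binding EDYDYVHL motif), the two most functionally documented sites
of each fragment.

## The study pipeline

`study_config()` fixes sequences, states (unphosphorylated / two-site /
full), the salt series (100, 350, 1500 mM), seeds, and Monte Carlo
controls; `run_state()` produces one summary row per (sequence, state,
salt, seed) cell and `run_study()` the full grid.  Phosphorylation
deltas pair states at matched seeds, which cancels a large share of the
sampling noise.  `vshape_fit()` regresses normalized Rg on NCPR or
|NCPR| with weights 1/SE² and reports the slope's t-test p-value
(n − 2 degrees of freedom, two-sided; per-fit p-values only, no
multiple-testing correction).  Fits are done per salt condition.  A
null simulation (`vshape_null_rejection_rate()`) checks that the test
keeps its nominal 5% size.

Two conventions follow the study design: the V-shape and ΔRg sign
comparisons are evaluated at 100 mM-equivalent screening, where charge
effects are strongest; salt-bridge and shielding comparisons use
350 mM, the regime where atomistic ensembles best matched experimental
SAXS/NMR data and where the exposure analysis is defined.

## Problem sizes and numerical choices

Desk-scale defaults: 2000 sweeps per ensemble (one sweep = N moves;
25% equilibration discard, stride 5, i.e. 300 saved frames), three
replicate chains per state, chains of 66-83 beads.  These sizes give
per-state Rg standard errors of ~0.2-0.4 Å, small against the 2-5 Å
directional signals tested; the SAXS stage averages every other saved
frame and the shielding stage every third, since their per-frame cost
dominates.  Degenerate
inputs are handled explicitly: single-bead chains have Rg 0 and unit
form-factor intensity; Guinier fitting refuses windows of fewer than 5
points and curves without a decaying low-q regime; the block-error
estimator refuses fewer than two blocks; χ² requires overlapping q
ranges and positive reference uncertainties.

## Known limitations

* The generator's parameters are effective, not transferable; only
  directions and orderings are meaningful.
* The shielding signal for the 2-site states is a few Å² against
  seed-to-seed scatter of similar size — it is a directional statement
  over replicate chains, not a per-chain effect.
* The extended-Guinier window is a stand-in for published extended
  Guinier schemes whose exact formulation differs; divergence from the
  standard window grows with the window limit.
* Sequence Coulomb descriptors ignore dielectric screening and chain
  geometry by construction; they are sequence-only covariates.
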