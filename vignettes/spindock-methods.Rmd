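---
title: "Integrative docking from PELDOR and cross-linking restraints: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative docking from PELDOR and cross-linking restraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`spindock` reconstructs the architecture of a two-component protein complex
from sparse distance information: nanometre-range distances between
nitroxide spin labels measured by pulsed electron-electron double resonance
(PELDOR, also called DEER), and residue-pair proximities inferred from
chemical cross-linking read out by mass spectrometry. The motivating use
case is a histone chaperone assembly — a Vps75 dimer docked against an
Asf1-capped H3–H4 dimer — but every stage is generic: two rigid bodies, a
handful of restraints, a restrained rigid-body search.

The pipeline has five computational stages, each usable on its own:

1. **Spin-label simulation** (`attach_r1_ensemble`, `attach_rx2_label`) —
   the unpaired electron of a nitroxide label is not at a backbone
   position; its accessible positions are simulated as a weighted point
   cloud.
2. **PELDOR inversion** (`correct_background`, `invert_tikhonov`) — the
   dipolar time trace is converted to a distance distribution P(r).
3. **Cross-link identification** (`digest`, `xl_search`, `estimate_fdr`) —
   isotope-coded cross-linked peptide pairs are identified from MS/MS peak
   lists with decoy-based error control, then converted to distance
   restraints (`crosslinks_to_restraints`).
4. **Restrained docking** (`run_docking`, `average_models`,
   `validate_model`, `extrapolate_tetramer`) — rigid-body search from
   random orientations against all restraints, with acceptance, ensemble
   averaging and validation.
5. **Synthetic data** (`make_toy_bodies`, `simulate_restraints`,
   `simulate_dipolar_dataset`, `simulate_xl_spectra`) — generators with
   known ground truth for every input above, so the whole pipeline is
   testable without any external data.

# Models and assumptions

## Spin-label ensembles

The monofunctional nitroxide side chain (R1) is modelled by an
accessible-volume construction: candidate electron positions are drawn on
shells `r_min`–`r_max` (defaults 4–12 Å) from the anchor C-beta, restricted
to a cone away from the backbone, and rejected within `clash_cutoff`
(default 3 Å) of any host heavy atom; survivors are uniformly weighted.
This is deliberately a geometric model — no rotamer energies, no label
atoms added to the structure. The electron is represented by a single
point per conformer (the N–O midpoint proxy).

The bifunctional label (Rx2) bridges two engineered cysteines, typically
across a dimer two-fold, and is conformationally restricted. It is modelled
by sampling near the perpendicular bisector plane of the two anchor
C-betas at tether-consistent distances from both (defaults: anchors must be
5–14 Å apart; electron 4–10 Å from each anchor; distance asymmetry below
1.5 Å), with the same clash filter. Both constructions sample in a
residue-local frame, so labeling commutes exactly with rigid motion of the
host body — a property the test suite asserts to 1e-8 Å.

Sampling parameters of the published accessible-volume tools are not
standardized; all defaults here are package choices, exposed in
`r1_params()` / `rx2_params()`.

## The dipolar signal and its inversion

Two unpaired electrons at distance $r$ couple with dipolar frequency
$\nu_{dd} = D / r^3$, $D = 52.041$ MHz·nm³ (computed from $\mu_0$, the
electron g-value and Bohr magneton; asserted against that derivation in the
tests). For an isotropic powder the kernel is

$$K(t, r) = \int_0^1 \cos\left[(1 - 3x^2)\, 2\pi \nu_{dd}(r)\, t\right] dx,$$

evaluated by Gauss–Legendre quadrature (200 nodes; checked against a
100,000-point brute-force rule to 1e-6). The intermolecular background is
modelled as a three-dimensional homogeneous exponential
$V_{bg} = (1-\lambda)e^{-kt}$, fitted on the final 75% of the trace and
divided out. Inversion solves

$$\min_{p \ge 0} \|K p - V\|^2 + \alpha^2 \|L_2 p\|^2$$

with $L_2$ the second-difference operator, by Lawson–Hanson non-negative
least squares on the stacked system — non-negativity by construction, not
by clipping, which would bias P(r). When $\alpha$ is not given it is chosen
at the point of maximum curvature of the L-curve over a 40-point log grid
spanning 1e-3–1e3. The r grid defaults to 1.5–10 nm with 256 points, wide
enough to bracket the 5.5–6.7 nm modal distances of the motivating system.
The reference analysis software's background model and regularization
settings are not published; these defaults are stated package choices.

## Cross-link search

In-silico tryptic digestion cleaves after K/R except before proline, with
up to 3 missed cleavages by default — a cross-linked lysine itself blocks
cleavage, so missed cleavages are the norm for linked peptides. The
isotope-coded linker (BS2G-d0/d4) leaves a glutaryl bridge of composition
C5H4O2, 96.02113 Da monoisotopic; the heavy form carries four deuteriums,
shifting precursors by 4 × (²H − ¹H) = 4.02511 Da. Precursor doublet
detection requires equal charge in 3+–6+, co-elution, and the neutral-mass
difference within 10 ppm (inclusive).

Candidates are all peptide pairs whose masses plus bridge match the
precursor within the MS1 tolerance (default 1 ppm), with both peptides of
at least 5 residues and a linkable site: an internal lysine or the protein
N-terminus; a C-terminal lysine is excluded because trypsin would have
cleaved an unmodified one. Scoring sums `1 + log10(relative intensity)`
over matched b/y ions of both peptides (the linked residue carries partner
plus bridge as a fixed shift); a theoretical ion matches the most intense
peak within the MS2 tolerance. The score is a package definition — the
original search engine's exact score is unpublished — and the decoy layer
makes downstream results robust to it: q-values are computed from a
reversed-sequence decoy database as (decoys ≥ s)/(targets ≥ s), monotonized.
Acceptance requires q ≤ 0.05 and the same residue pair observed more than
twice (d0 and d4 forms pooled).

Accepted lysine–lysine links become flat-bottom restraints between NZ
atoms with bounds [0, 20 Å]: the 7.7 Å spacer plus two lysine side chains
and backbone mobility. The upper bound is configurable because the
published restraint width is not stated.

## Docking

Body A is fixed; body B's pose is a rotation plus translation. Restraint
distances are the weighted mean over all conformer pairs for ensemble
(PELDOR) sites — a differentiable, well-defined quantity; the modal
distance of the extracted P(r) is available as an alternative target — and
plain atom–atom distances for cross-link sites. Energies:

* `e_noe` — flat-bottom quadratic: per restraint, violation
  $v = \max(0, d - u, l - d)$ and $e = \sum w v^2$;
* `e_clash` — soft quadratic repulsion $\sum k_{rep}(d_c - d_{ij})^2$ over
  inter-body atom pairs closer than $d_c = 3$ Å (on a configurable atom
  subset for speed);
* optionally a weak smooth contact attraction (`k_attract`, default **off**)
  that stands in for the attractive nonbonded term of a full force field;
  it enters only the minimization objective and is reported separately, so
  `e_total = e_noe + e_clash` always.

Each start draws a uniformly random orientation (normalized quaternions —
exactly Haar-uniform), then places the body so one randomly chosen
restraint is exactly satisfied along a random direction, refined by a
translation-only Gauss–Newton fit to all restraint targets. The original
protocol randomizes orientations but does not describe translation
initialization; this choice keeps starts in the feasible basin without
biasing orientation. Minimization is BFGS over six degrees of freedom with
an exact analytic gradient (rotation updates through the SO(3) exponential
map and left Jacobian; the gradient is verified against central differences
in development). A first pass with the repulsion softened by 50× lets poses
slide along restraint-satisfying directions through mild steric overlap — a
cheap stand-in for the rigid-body dynamics of the original protocol — and a
second pass refines with the full repulsion.

The published acceptance thresholds (an NOE energy below 170 kcal/mol, a
total energy below 6900 kcal/mol) are in the original force field's units
and are not portable. Acceptance here is violation-based: maximum restraint
violation at most `d_acc` (default 3 Å, matching the criterion by which the
published model's restraints were called satisfied) and clash energy at
most `clash_max`. Accepted solutions are aligned on body A's backbone,
averaged coordinate-wise, and the mean backbone / heavy-atom RMSD of
members to the average is reported. The average is output raw — whether the
published averaged model was geometrically regularized afterwards is not
stated.

`extrapolate_tetramer` superposes a copy of the complex onto each
histone-fold dimer of a tetramer template via shared backbone atoms, drops
the capping-chaperone chains, and counts inter-copy contacts below a clash
cutoff — the operation used to extend the dimer-level model to the
tetramer-level assembly.

**Identifiability.** Five scalar distance restraints cannot uniquely pin
six pose degrees of freedom: the exact-solution set is generically a
one-dimensional manifold, and any restrained-docking ensemble (including
the published one, whose 62 accepted models spread 4.68 Å around their
mean) samples it. What localizes the answer in practice is steric
exclusion at a snug interface plus the bounded reach of the restraints.
The package therefore reports ensembles, not single structures, and the
synthetic recovery test asks whether the accepted set *contains* the truth
pose, not whether every member equals it.

# The synthetic world

The generators state one fixed world; their defaults are not tuned per
test.

* **Bodies**: two ~190-atom two-helix bundles (backbone N/CA/C/O plus
  C-beta, NZ pseudo-atoms on six lysines each). The two helices have
  unequal lengths (20 + 16 residues) to avoid an adventitious internal
  two-fold that would create near-degenerate docking twins. The truth pose
  has a random orientation and sits at the smallest clash-free separation
  along the most contact-rich of 24 candidate directions — a snug,
  interlocking interface, as for real docked complexes.
* **Restraints**: 3 label-ensemble restraints plus 2 NZ–NZ cross-link
  restraints, chosen among interface-proximal sites (only
  interface-spanning measurements inform a docking experiment). Labels use
  a compact accessible volume (3.5–6.5 Å, narrow cone), emulating the
  conformationally restricted bifunctional-label strategy. Targets are the
  true model distances plus Gaussian noise of stated `noise_sd`;
  flat-bottom half-widths default to the noise level, so the noiseless
  world gives harmonic pulls to exact targets.
* **Dipolar traces**: form factor × 3D exponential background + white
  Gaussian noise, from a stated Gaussian (mixture) P(r).
* **Spectra**: each planted lysine–lysine link emits d0 and d4 precursors
  (charges 3–6) with a configurable fraction of theoretical b/y ions,
  uniform-random noise peaks, and noise-only background spectra at
  plausible cross-link masses as false-positive bait. Planted links are
  restricted to lysines whose shortest covering tryptic peptide offers a
  single link site, so the planted identity is resolvable from fragments —
  mirroring the restriction of published restraints to links resolved in
  the structures.

What a green synthetic test does **not** establish: performance on real
EPR instrument artifacts (phase error, multi-spin effects, orientation
selection), chromatographic co-elution structure, real fragmentation
chemistry, or flexible-backbone docking. The real-structure validation
path (PDB downloads) exercises none of the generators and is the
appropriate end-to-end check where network access exists.

# Numerical choices

* Lengths are Å everywhere internally; nm appears only at the PELDOR
  boundary.
* Kabsch superposition corrects the sign of the smallest singular value,
  so reflections are never returned; collinear point sets are flagged.
* The NNLS active-set solver iterates to machine-level feasibility;
  distribution normalization is exact by construction.
* The L-curve corner is the discrete maximum-curvature point, with corner
  candidates restricted to the lower half of the log-residual range — a
  guard against spurious curvature maxima deep in the over-regularized
  limb, which otherwise capture noiseless synthetic traces whose classic
  corner is undefined.
* `modal_distance` breaks ties toward smaller r (documented argmax rule).
* Mass arithmetic: adduct counts use `floor`, which reproduces both
  printed counts in the motivating study (2.7 kDa / 174 Da = 15.5 →
  "approximately 15"); the monoisotopic residue masses are standard
  values to 1e-5 Da.
* Minimization tolerance is `reltol = 1e-10` with a 60-iteration default
  cap per stage; divergent minimizations (non-finite energy) are returned
  as failed solutions, not errors.

# Known limitations

* Bodies are strictly rigid; the original protocol's internal-coordinate
  dynamics (flexible label side chains during minimization) is replaced by
  pre-computed label ensembles.
* Only two bodies are docked; no ensemble reweighting; no
  orientation-selective PELDOR; no multi-spin corrections.
* The published acceptance counts (62/500) and ensemble RMSDs
  (4.68/5.05 Å) depend on unpublished energy units and well widths and are
  treated as qualitative references only.
* The real-structure acceptance checks require PDB downloads and fail,
  by design loudly rather than silently, in offline environments.
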