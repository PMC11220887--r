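---
title: "Determining SAD substructures by modified RAAR phase retrieval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining SAD substructures by modified RAAR phase retrieval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Single-wavelength anomalous diffraction (SAD) phasing starts from the
intensity differences between Bijvoet mates F(hkl) and F(-h-k-l) caused by
anomalous scatterers ("heavy atoms") in a macromolecular crystal.  The
absolute Bijvoet difference |dF| = ||F+| - |F-|| approximates the amplitude
|F_A| of the substructure -- the few heavy atoms alone -- so locating the
substructure is a small, point-atom phase problem.  Once those sites are
known they seed the phase determination of the whole structure; solving the
substructure reliably and automatically is therefore the critical first
step of the SAD pipeline.

`sadret` solves this problem with an *ab initio* dual-space phase-retrieval
iteration: no Patterson interpretation, no prior composition knowledge,
only the normalized anomalous difference magnitudes.

## The iteration

Each trial starts from a random electron-density map synthesized from the
symmetry-expanded observed amplitudes with random phases obeying Friedel's
law (unobserved coefficients zero, F(000) = 0).  One Fourier cycle then:

1. inverse-transforms the current map and reduces the coefficients to the
   Laue asymmetric unit;
2. replaces calculated moduli with observed ones, keeping phases.  Three
   classes of reflections are distinguished: observed (modulus replaced),
   unobserved inside the resolution sphere (left free), and
   beyond-the-limit or systematically absent (forced to zero), with F(000)
   pinned at zero throughout;
3. shifts the phases of the weakest observed reflections by +90 degrees
   (the pi-half perturbation), the weak set being the fraction `w_best` of
   observed reflections with smallest E, fixed for the whole run;
4. on schedule, refines the phases of the `n_tf` strongest reflections with
   the tangent formula.  For a strong reflection h the triplet sum
   G(h) = sum_k E(k) E(h-k) runs over the symmetry-expanded strong set
   (computed as the Fourier coefficients of the squared strong-set E-map);
   with T = Im G and B = Re G the tangent phase is atan2(T, B), and the
   new phase is the argument of
   (1 - alpha) exp(i phi_c) + alpha exp(i phi_tf), where
   alpha = M / max(M) and M = E_h |G(h)| weights the tangent phase by its
   reliability;
5. expands back to the full sphere, synthesizes the new map, and applies
   the real-space constraint.  For the modified RAAR scheme this is, with
   a = |rho~| (positivity is enforced by taking absolute values before and
   after the update):

   - a(x) >= delta: keep a(x);
   - a(x) <  delta: beta * rho_last(x) + (1 - 2 beta) * a(x),

   followed by a final absolute value.  `rho_last` is the constrained map
   of the previous cycle, and delta is chosen each cycle so that exactly
   `perturb_fraction` of the grid points fall in the relaxed branch.

The Pearson correlation between observed and calculated amplitudes over
the observed set, evaluated on the map after the real-space constraint, is
recorded every cycle; an abrupt, persistent CC gain is the signature of a
successful trial.  Because trials start from random phases, a search runs
hundreds of independent trials and keeps the one with the highest CC --
subject to a map-skewness plausibility screen.  Roughly one trial in
twenty converges to an enantiomorph-superposition artifact whose CC can
slightly exceed that of genuine solutions but whose density histogram is
diagnostically flat: its skewness falls far below the ensemble maximum
(20 vs 29-45 on the noise-free eight-atom reference problem).  Trials
below 0.6 x the maximum skewness are therefore set aside before the CC
ranking (`skew_screen`, 0 disables); skewness is one of the standard
phasing figures of merit alongside R and CC.

Two baselines are built in for comparison: plain RAAR (no reciprocal-space
perturbations) and classical charge flipping (densities below delta are
sign-flipped; no positivity).

## Parameters

| parameter | default | meaning |
|---|---|---|
| `beta` | 0.82 | RAAR relaxation; the empirical sweet spot for SAD substructures |
| `perturb_fraction` | 0.13 | share of grid points in the relaxed (low-density) branch |
| `w_best` | auto | weak fraction; automatic mode spreads trials over 0.20/0.30/0.40/0.50 |
| `n_tf` | rule | 1000 below 5000 observed reflections, 1300 up to 8000, 1500 above |
| `tf_start`, `tf_stride` | 100, 20 | tangent refinement every 20 cycles once 100 cycles have passed, compensating its strong perturbation |
| `n_iter` | 500 | Fourier cycles per trial (750 for hard data) |
| `n_trials` | 400 | random starts per dataset |
| `grid_factor` | 2 | grid spacing <= d_min / grid_factor |

Defining delta through a fixed proportion of low-density grid points
admits two readings -- the proportion may count the perturbed points or
the retained ones; the default takes 13% of points as *perturbed*, and
`delta_mode = "pass"` exposes the complementary reading.  The sign of the 90-degree shift is likewise convention
(`pihalf_sign`), as is whether weak reflections keep their calculated
moduli (`weak_keep_calc`) and whether the weak set is fixed from the
observed E ranking or re-ranked each cycle from calculated moduli
(`weak_mode = "dynamic"`); defaults follow the pi-half variant
literature.

## Data preparation

`prep_anomalous()` mirrors the standard preparation chain:

* |dF| = |F+ - F-| with sigma = sqrt(sigF+^2 + sigF-^2); records with a
  missing mate or non-positive sigma are dropped, as are centric
  reflections (phase-restricted, hence without Bijvoet signal) and
  systematic absences.  An optional `k_reject` sigma-cutoff is off by
  default -- the proprietary intensity-statistics rejection of standard
  preparation programs is deliberately *not* imitated, only documented
  simple filters.
* The anomalous resolution limit uses the mean |dF|/sigma(dF) = 1.2 shell
  criterion: scanning from low to high resolution over equal-volume shells
  (uniform in 1/d^3, ten by default), the data are truncated at the
  low-resolution edge of the first shell whose mean falls below 1.2; if no
  shell falls below, nothing is truncated.
* E values are dF / sqrt(<dF^2>) with the shell mean-square smoothed by
  linear interpolation in 1/d^2 between shell centres (linear, not
  constant, extrapolation beyond the end centres -- constant extrapolation
  biases the edge shells), an epsilon-factor (Laue-stabilizer multiplicity)
  correction, and a final global rescale to <E^2> = 1 exactly.

## Symmetry conventions

Operators are "x,y,z" strings acting on column fractional coordinates;
reflections transform as F(hR) = F(h) exp(-2 pi i h.t).  The Laue-orbit
representative is the lexicographically greatest equivalent triple.
Internally the engine carries the full-sphere coefficients on the FFT grid
and maps them to unique reflections through precomputed member tables;
scattering back with per-index averaging is the orthogonal projection onto
the symmetry-consistent subspace, so symmetry (including Friedel reality
and the phase restriction of centric reflections) is enforced in
reciprocal space at every cycle without special cases.  Permissible origin
shifts are found by brute force on a 1/12 fractional grid (all t with
R t - t integral for every rotation), with continuous polar directions
reported separately.

## Peak search and site comparison

`find_peaks()` takes periodic 26-neighbourhood maxima, refines them with
separable three-point parabolic interpolation, suppresses peaks within
`min_sep` (1 A) of a higher peak including symmetry images, and reports
heights in map-sigma units; the conventional list length is two more than
the expected site count.  `match_sites()` searches the full ambiguity
group of phase retrieval -- space-group rotations x permissible origin
shifts x enantiomorph inversion -- scoring each transform by greedy
nearest-neighbour matching under minimum-image Cartesian distance
(threshold 1.5 A by default; the reference threshold of the standard
comparison tools is unpublished, so it is config-exposed).  Shift
components along polar axes are seeded from ref-minus-calc difference
vectors and refined by coordinate-wise line search.  A determination
counts as successful when more than half the reference sites match.

## The synthetic-data generator

`make_dataset()` fabricates ground-truth fixtures in two modes.
`direct_fa` hands the engine |F_A| of a random, minimum-separation-packed
point-atom substructure plus optional Gaussian noise -- the idealized
input.  `bijvoet` adds a light-atom background and gives heavy atoms a
complex scattering factor f0 + f' + i f''; the resulting |F+|, |F-| pairs
carry a realistic anomalous signal in which ||F+|-|F-|| tracks |F_A| only
through the modulation |sin(phiT - phiA)|.  That modulation caps the
correlation between extracted differences and true |F_A| near 0.7 no
matter how small the noise -- an intrinsic property of the SAD
approximation, visible in the tests.  Sigmas follow a simple
shell-mean-amplitude noise model rather than counting statistics.

The generator does **not** emulate form-factor resolution dependence,
anisotropic displacement, absorption, radiation damage, twinning, or
merging statistics.  A green end-to-end test therefore establishes that
the algorithm recovers substructures from data with the stated noise and
modulation structure, not that it reproduces any particular published
success rate on deposited experimental data.

## Numerical choices

* **Grid.** Dimensions are the smallest even 5-smooth integers giving
  spacing at most d_min/3 per axis (and at least 2 hmax + 2 indices).
  Half-d sampling would represent every reflection in the sphere exactly,
  but the positivity (absolute-value) step broadens the density spectrum
  and on a d/2 grid the aliased tails fold back inside the sphere: in
  testing this bred centrosymmetric "ghost" maps -- superpositions of both
  enantiomorphs -- that could even win the CC ranking.  At d/3 the ghosts
  vanish; `grid_factor` remains exposed.  The FFT is a self-contained
  mixed-radix (2/3/5) implementation in C++ with a real-to-Hermitian
  half-spectrum path, verified against R's `fft` in the suite.
* **Tangent grid.** Triplet index sums reach 2 hmax, so the squared-E-map
  convolution runs on a separate grid of at least 3 hmax + 2 per axis;
  on the working grid the sums would alias back onto the strong set.
  Triplet sums at FFT-roundoff level are treated as zero and leave phases
  untouched.
* **Threshold.** delta is the k-th order statistic of |rho~| with
  k = floor(perturb_fraction * N): the perturbed count is exact, not a
  quantile approximation.
* **Convergence flag.** "Abrupt CC increase" is operationalized as a gain
  of more than 0.05 over at most 50 cycles, followed by a plateau (the
  final 25-cycle mean within 0.05 of the trace maximum).  Thresholds are
  arguments of `detect_convergence()`.
* **Determinism.** One master seed; trial i uses seed + i; the trial core
  uses its own compiled generator so traces are bit-reproducible across
  sessions, and the best trial is reproduced (not cached) when its map is
  requested.
* **Degenerate inputs.** Flat maps yield empty peak lists; zero-variance
  CC is defined as 0; all-zero triplet sums leave phases unchanged;
  shape-mismatched grids and non-group operator sets are hard errors.

## Known limitations

* On synthetic data the CC gap between converged-correct and
  converged-wrong trials can be a few hundredths; ranking by best CC picks
  the right trial in the tested worlds, but with marginal data more trials
  (the 400-trial default rather than the scaled-down test counts) are the
  remedy.  Maps that superimpose both enantiomorphs fit the amplitudes
  almost as well as a single-handed solution and occasionally rank high;
  symmetry-aware matching with the inversion flag is the diagnostic.
* The enantiomorph is not determined (inherent to the method); matching
  reports the inversion flag instead.
* Heavy-atom parameter refinement against the data (occupancies, B
  factors) is out of scope; peak heights are the only occupancy proxy.
* Space-group symbols beyond the small built-in table must be supplied as
  explicit operator lists.
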