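# sadret — SAD substructure determination by modified RAAR phase retrieval

`sadret` locates heavy-atom (anomalous scatterer) substructures from
single-wavelength anomalous diffraction (SAD) data. The input is the set of
Bijvoet differences |ΔF| = ||F⁺| − |F⁻|| — the standard approximation to the
substructure amplitudes |F_A| — and the output is a list of fractional
heavy-atom coordinates, the starting point for experimental phasing of the
full macromolecule.

The core is an *ab initio* dual-space iteration built on the relaxed
averaged alternating reflections (RAAR) scheme with two reciprocal-space
perturbations borrowed from charge-flipping practice:

* **π-half perturbation** — each cycle, the phases of the weakest fraction
  *w*<sub>best</sub> of observed reflections are shifted by 90°, which
  widens the convergence radius;
* **tangent-formula refinement** — on a schedule (every 20 cycles after
  cycle 100), the phases of the *N*<sub>TF</sub> strongest normalized
  reflections are pulled toward the direct-methods triplet estimate
  φ<sub>TF</sub>(**h**) = atan2(T, B), with T + iB = Σ<sub>k</sub>
  E(**k**)E(**h**−**k**), blended with weight α = M/M<sub>max</sub>,
  M = E<sub>h</sub>|G(**h**)|.

In real space the modified RAAR update keeps |ρ̃(x)| where it exceeds a
threshold δ (set each cycle so that 13% of grid points fall below) and
relaxes the rest to β·ρ<sub>last</sub>(x) + (1−2β)·|ρ̃(x)| with β = 0.82,
taking absolute values before and after to enforce positivity. Convergence
of a trial is monitored through the Pearson correlation between observed
and calculated E values; searches run many random-start trials and keep the
best.

The package also provides: Bijvoet-pair preparation (|ΔF|, σ propagation,
the |ΔF|/σ = 1.2 anomalous resolution cutoff, shell-wise E normalization
with ε-factors), explicit space-group symmetry handling (expansion, Laue
reduction, systematic absences, permissible origin shifts), peak search and
symmetry/origin/enantiomorph-aware site matching with the >50% success
rule, a synthetic SAD data simulator with ground truth, and a JSON-driven
CLI pipeline.

## Worked example

Simulate a 6-atom substructure in P1, prepare, solve with the modified
algorithm, pick peaks, and compare to the ground truth:

```r
library(sadret)

cell <- unit_cell(30, 32, 34)
sg   <- space_group("P1")
spec <- synthetic_spec(cell, sg, n_atoms = 6, d_min = 2.4,
                       noise_frac = 0.02, min_sep = 4, seed = 7)
ds   <- make_dataset(spec, "direct_fa")

refl <- normalize_to_E(estimate_resolution_cutoff(ds$refl), sg = sg)
prob <- build_problem(refl, cell, sg)
print(prob)
#> phase-retrieval problem: 4955 unique reflections (4955 observed), d_min 2.40 A, grid 40 x 40 x 48

cfg <- engine_config(n_iter = 250, n_trials = 4, seed = 1)
mr  <- run_multi(prob, cfg)
print(mr)
#> 4 trials, 4 converged; best CC 0.643 (seed 5, w_best 0.50)

peaks <- find_peaks(mr$best$density, cell, n_peaks = 8, sg = sg)
head(peaks, 3)
#>       x       y     z height rank
#> 1 0.181 0.87917 0.694   55.1    1
#> 2 0.612 0.00152 0.984   23.0    2
#> 3 0.827 0.30390 0.648   22.1    3

report <- match_sites(peaks[1:6, ], ds$sites, sg, cell, tol = 1.5)
print(report)
#> matched 6 / 6 reference sites (100%), rmsd 0.097 A [success]
```

What the numbers mean: each trial's CC trace jumps abruptly when the
iteration escapes the random start and locks onto a substructure; the best
trial's map shows peaks in units of the map standard deviation (genuine
sites typically stand several σ above the noise peaks), and the match
report aligns the found sites with the reference over all permissible
origin shifts and the enantiomorph flip — here all 6 sites are recovered
to better than 0.1 Å. Rare trials converge onto the centrosymmetric
superposition of both enantiomorphs (inherent to phase retrieval from
|F_A| data); those maps are screened out of the winner selection by their
diagnostically low skewness.

The same run as a shell pipeline:

```sh
cat > cfg.json <<'EOF'
{"cell": [30, 32, 34, 90, 90, 90], "symops": "x,y,z", "seed": 7,
 "simulate": {"mode": "direct_fa", "n_atoms": 6, "d_min": 2.4,
              "noise_frac": 0.02, "min_sep": 4},
 "solve": {"iters": 250, "trials": 4}}
EOF
Rscript inst/cli/sadret run --config cfg.json --out run1 --verbose
```

`run1/manifest.json` records the config echo, file digests, timings and
outcome; re-running reproduces the best CC bit-for-bit.

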