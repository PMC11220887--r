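# Shared fixtures: tiny cells, groups, and canned synthetic problems.
# Everything is generated in code; nothing is read from disk.

fix_cell_small <- function() unit_cell(30, 32, 34)
fix_cell_ortho <- function() unit_cell(42, 46, 50)

fix_p1 <- function() space_group("P1")
fix_p1bar <- function() space_group("P-1")
fix_p21 <- function() space_group("P21")
fix_p212121 <- function() space_group("P212121")

# small noise-free direct-FA problem in P1; solved in a couple of seconds
fix_direct_fa_small <- function(seed = 7, n_atoms = 6, noise = 0,
                                d_min = 2.2) {
  cell <- fix_cell_small()
  sg <- fix_p1()
  spec <- synthetic_spec(cell, sg, n_atoms = n_atoms, d_min = d_min,
                         noise_frac = noise, min_sep = 4, seed = seed)
  ds <- make_dataset(spec, "direct_fa")
  refl <- normalize_to_E(ds$refl, sg = sg)
  list(cell = cell, sg = sg, spec = spec, ds = ds, refl = refl)
}

# allowed phase of a centric reflection: phi = pi * h.t (mod pi) for the
# operator mapping h to -h
centric_phase <- function(hkl, sg) {
  phase <- rep(NA_real_, nrow(hkl))
  for (op in sg$ops) {
    hr <- hkl %*% op$rot
    self <- rowSums(abs(hr + hkl)) == 0 & is.na(phase)
    if (any(self))
      phase[self] <- pi * as.vector(hkl[self, , drop = FALSE] %*% op$trans)
  }
  phase
}

# random phased Laue-unique reflection set, symmetry-consistent (centric
# phases restricted to their allowed values)
fix_random_phased_set <- function(sg, cell, d_min = 3.5, seed = 1) {
  hkl <- sadret:::unique_hkl(cell, sg, d_min)
  hkl <- hkl[!is_systematically_absent(hkl, sg), , drop = FALSE]
  withr::with_seed(seed, {
    cen <- is_centric(hkl, sg)
    phase <- runif(nrow(hkl), -pi, pi)
    if (any(cen)) phase[cen] <- centric_phase(hkl, sg)[cen]
    data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
               amp = rexp(nrow(hkl)) + 0.1, phase = phase)
  })
}

expect_close <- function(x, y, tol = 1e-10) {
  expect_lt(max(abs(x - y)), tol)
}
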