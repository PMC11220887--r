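make_pairs <- function(hkl, Fp, sp, Fm, sm) {
  data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3], Fplus = Fp,
             sigFplus = sp, Fminus = Fm, sigFminus = sm)
}

test_that("anomalous differences: arithmetic, drops and filters", {
  cell <- fix_cell_small(); sg <- fix_p1()
  hkl <- rbind(c(1, 2, 3), c(2, 1, 1), c(3, 1, 2))
  pairs <- make_pairs(hkl, c(105, 50, NA), c(2, 1, 1), c(100, 47, 40),
                      c(2, 1, 1))
  refl <- compute_anomalous_differences(pairs, cell, sg)
  expect_equal(nrow(refl), 2)
  r <- refl[refl$h == 1 | refl$k == 1, ] # rep of (1,2,3) may be negated copy
  i <- which(refl$dF == 5)
  expect_length(i, 1)
  expect_equal(refl$sig_dF[i], sqrt(8))
  log <- attr(refl, "filter_log")
  expect_equal(unname(log["unpaired"]), 1)
  # sigma <= 0 dropped
  p2 <- make_pairs(hkl[1:2, ], c(10, 10), c(0, 1), c(9, 9), c(1, 1))
  r2 <- compute_anomalous_differences(p2, cell, sg)
  expect_equal(nrow(r2), 1)
  # k_reject is monotone: tightening never increases the count
  withr::with_seed(4, {
    n <- 200
    hkl_n <- cbind(1:n, rep(1, n), rep(2, n))
    pn <- make_pairs(hkl_n, 100 + rnorm(n, sd = 5), 2, 100 + rnorm(n, sd = 5), 2)
  })
  counts <- vapply(c(Inf, 3, 2, 1, 0.5), function(k)
    nrow(compute_anomalous_differences(pn, cell, sg, k_reject = k)),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(compute_anomalous_differences(pn, cell, sg, k_reject = 0),
               "no reflections")
})

test_that("centric reflections carry no Bijvoet difference and are dropped", {
  cell <- fix_cell_ortho(); sg <- fix_p212121()
  spec <- synthetic_spec(cell, sg, n_atoms = 4, d_min = 3.0, noise_frac = 0,
                         n_background = 60, min_sep = 4, seed = 5)
  ds <- make_dataset(spec, "bijvoet")
  cen <- is_centric(as.matrix(ds$pairs[, c("h", "k", "l")]), sg)
  expect_gt(sum(cen), 0)
  # noise-free: centric dF identically ~0, acentric not
  dF <- abs(ds$pairs$Fplus - ds$pairs$Fminus)
  expect_lt(max(dF[cen]) / max(dF), 1e-9)
  refl <- compute_anomalous_differences(ds$pairs, cell, sg)
  expect_equal(unname(attr(refl, "filter_log")["centric"]), sum(cen))
  expect_false(any(is_centric(as.matrix(refl[, c("h", "k", "l")]), sg)))
})

test_that("resolution cutoff follows the 1.2 crossing rule", {
  cell <- fix_cell_small(); sg <- fix_p1()
  # plant shell mean ratios (low -> high res) 3.0, 1.5, 1.1, 0.9
  withr::with_seed(9, {
    hkl <- sadret:::unique_hkl(cell, sg, 2.2)
    d <- d_spacing(cell, hkl)
    b2 <- sadret:::.shell_bounds(d, 4)
    shell <- findInterval((1 / d)^2, b2, rightmost.closed = TRUE)
    shell[shell < 1] <- 1; shell[shell > 4] <- 4
    ratio <- c(3.0, 1.5, 1.1, 0.9)[shell]
    refl <- reflection_set(hkl, dF = ratio, sig_dF = rep(1, nrow(hkl)),
                           cell = cell)
  })
  st <- shell_table(refl, 4)
  expect_equal(st$mean_ratio, c(3.0, 1.5, 1.1, 0.9), tolerance = 1e-9)
  out <- estimate_resolution_cutoff(refl, st)
  d_cut <- attr(out, "d_cut")
  expect_equal(d_cut, 1 / sqrt(st$s2_lo[3]), tolerance = 1e-12)
  expect_true(all(out$beyond_limit == (out$d < d_cut)))
  # all shells above the criterion: no truncation
  refl2 <- refl; refl2$dF <- rep(2, nrow(refl2))
  out2 <- estimate_resolution_cutoff(refl2, shell_table(refl2, 4))
  expect_true(is.na(attr(out2, "d_cut")))
  expect_false(any(out2$beyond_limit))
  expect_error(estimate_resolution_cutoff(refl, shell_table(refl, 4)[1:2, ]),
               "3 populated shells")
})

test_that("planted sigma crossover at d* = 2.6 A is recovered within one shell", {
  cell <- unit_cell(40, 50, 60); sg <- fix_p1()
  withr::with_seed(12, {
    hkl <- sadret:::unique_hkl(cell, sg, 2.0)
    d <- d_spacing(cell, hkl)
    dF <- rexp(nrow(hkl), rate = 1) + 0.5
    sig <- dF / 2.5            # strong signal ...
    sig[d < 2.6] <- dF[d < 2.6] / 0.6 # ... drowned beyond 2.6 A
    refl <- reflection_set(hkl, dF = dF, sig_dF = sig, cell = cell)
  })
  n_shells <- 12
  st <- shell_table(refl, n_shells)
  out <- estimate_resolution_cutoff(refl, st)
  d_cut <- attr(out, "d_cut")
  shell_width <- diff((1 / d_cut)^3 + c(0, diff(st$s2_lo^(3 / 2))[1]))
  # within one shell of the planted d*: compare in 1/d^3 (shell metric)
  planted <- (1 / 2.6)^3
  got <- (1 / d_cut)^3
  one_shell <- diff(range(sadret:::.shell_bounds(refl$d, n_shells)^(3 / 2))) /
    n_shells
  expect_lt(abs(got - planted), one_shell * 1.5)
})

test_that("E normalization: unit mean square per shell, scale invariance", {
  cell <- unit_cell(40, 50, 60); sg <- fix_p1()
  withr::with_seed(3, {
    hkl <- sadret:::unique_hkl(cell, sg, 2.2)
    d <- d_spacing(cell, hkl)
    # Wilson-like falloff plus noise
    dF <- exp(-8 / d^2) * (rexp(nrow(hkl)) + 0.2)
    refl <- reflection_set(hkl, dF = dF, sig_dF = pmax(dF / 3, 1e-3),
                           cell = cell)
  })
  expect_gt(nrow(refl), 5000)
  norm <- normalize_to_E(refl, n_shells = 10, sg = sg)
  expect_equal(mean(norm$E^2), 1, tolerance = 1e-12)
  b2 <- sadret:::.shell_bounds(norm$d, 10)
  shell <- findInterval((1 / norm$d)^2, b2, rightmost.closed = TRUE)
  shell[shell < 1] <- 1; shell[shell > 10] <- 10
  per_shell <- tapply(norm$E^2, shell, mean)
  expect_true(all(per_shell > 0.95 & per_shell < 1.05))
  expect_true(all(tapply(rep(1, nrow(norm)), shell, sum) >= 200))
  # doubling all amplitudes (and sigmas) leaves E bit-identical, flags too
  refl2 <- refl; refl2$dF <- 2 * refl$dF; refl2$sig_dF <- 2 * refl$sig_dF
  norm2 <- normalize_to_E(refl2, n_shells = 10, sg = sg)
  expect_lt(max(abs(norm2$E - norm$E)), 1e-12)
  expect_identical(norm2$beyond_limit, norm$beyond_limit)
  # constant dF in effect: single shell -> all E equal 1
  refl3 <- refl; refl3$dF <- rep(3.3, nrow(refl3))
  norm3 <- normalize_to_E(refl3, n_shells = 1, sg = NULL)
  expect_close(norm3$E, rep(1, nrow(norm3)), tol = 1e-12)
})

test_that("full prep keeps scale invariance across the whole chain", {
  cell <- fix_cell_ortho(); sg <- fix_p212121()
  spec <- synthetic_spec(cell, sg, n_atoms = 4, d_min = 2.8,
                         noise_frac = 0.05, n_background = 80, min_sep = 4,
                         seed = 8)
  ds <- make_dataset(spec, "bijvoet")
  r1 <- prep_anomalous(ds$pairs, cell, sg)
  p2 <- ds$pairs
  for (cn in c("Fplus", "sigFplus", "Fminus", "sigFminus"))
    p2[[cn]] <- p2[[cn]] * 7.3
  r2 <- prep_anomalous(p2, cell, sg)
  expect_identical(r1$beyond_limit, r2$beyond_limit)
  expect_lt(max(abs(r1$E - r2$E), na.rm = TRUE), 1e-12)
  dc1 <- attr(r1, "d_cut"); dc2 <- attr(r2, "d_cut")
  expect_true(identical(dc1, dc2) || abs(dc1 - dc2) < 1e-12)
})

test_that("HKL and pair files round-trip", {
  cell <- fix_cell_small()
  withr::with_seed(2, {
    hkl <- rbind(c(1, 2, 3), c(-2, 5, 1), c(10, -4, 7))
    refl <- reflection_set(hkl, dF = c(12.25, 0.5, 103.72),
                           sig_dF = c(1.25, 0.33, 9.1), cell = cell)
  })
  f <- withr::local_tempfile(fileext = ".hkl")
  write_hkl(refl, f)
  back <- read_hkl(f, cell)
  expect_equal(back$h, refl$h)
  expect_equal(back$dF, refl$dF, tolerance = 1e-9) # 2 decimals preserved
  pairs <- data.frame(h = c(1, 2), k = c(0, 1), l = c(3, -2),
                      Fplus = c(10.5, NA), sigFplus = c(0.1, NA),
                      Fminus = c(9.75, 8), sigFminus = c(0.1, 0.2))
  fp <- withr::local_tempfile(fileext = ".hkl")
  write_pairs(pairs, fp)
  back2 <- read_pairs(fp)
  expect_equal(back2$Fplus, pairs$Fplus, tolerance = 1e-6)
  expect_true(is.na(back2$sigFplus[2]))
})
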