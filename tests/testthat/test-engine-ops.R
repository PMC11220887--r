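test_that("compiled 3D FFT matches R's fft in both directions", {
  withr::with_seed(1, {
    for (dims in list(c(8, 9, 10), c(12, 15, 20), c(24, 24, 24))) {
      z <- array(complex(real = rnorm(prod(dims)),
                         imaginary = rnorm(prod(dims))), dims)
      a <- sadret:::fft3_cpp(as.vector(z), as.integer(dims), -1L)
      expect_lt(max(Mod(a - fft(z))) / max(Mod(a)), 1e-12)
      b <- sadret:::fft3_cpp(as.vector(z), as.integer(dims), 1L)
      expect_lt(max(Mod(b - fft(z, inverse = TRUE))) / max(Mod(b)), 1e-12)
    }
  })
})

test_that("amplitude projection follows the three-class rule", {
  cell <- fix_cell_small()
  obs <- reflection_set(rbind(c(1, 0, 0), c(2, 0, 0), c(3, 0, 0)),
                        dF = c(1, 1, 1), sig_dF = c(1, 1, 1), cell = cell,
                        E = c(2.0, 1.0, 0.7))
  obs$beyond_limit[3] <- TRUE
  calc <- data.frame(h = c(1, 2, 3, 4, 0), k = 0, l = 0,
                     amp = c(1.0, 0.5, 0.7, 0.9, 3.0),
                     phase = c(40, 10, 20, 30, 0) * pi / 180)
  out <- amplitude_projection(calc, obs)
  expect_equal(out$amp, c(2.0, 1.0, 0, 0.9, 0))
  expect_identical(out$phase, calc$phase)            # phases always kept
  expect_identical(out[4, ], calc[4, ])              # free: bit-for-bit
  # absent forced to zero
  obs2 <- obs; obs2$absent[2] <- TRUE; obs2$observed[2] <- FALSE
  out2 <- amplitude_projection(calc, obs2)
  expect_equal(out2$amp[2], 0)
})

test_that("pi-half perturbation shifts exactly the weakest fraction", {
  cell <- fix_cell_small()
  refl <- reflection_set(cbind(1:10, 1, 1), dF = 1:10, sig_dF = 1,
                         cell = cell, E = as.numeric(10:1), phase = 0.1)
  expect_identical(pi_half_perturb(refl, 0)$phase, refl$phase)
  p <- pi_half_perturb(refl, 0.5)
  expect_equal(sum(p$weak), 5)
  expect_true(all(p$weak == (refl$E <= 5)))          # the 5 smallest E
  expect_close(p$phase[p$weak], rep(0.1 + pi / 2, 5), tol = 1e-12)
  expect_close(p$phase[!p$weak], rep(0.1, 5), tol = 1e-12)
  # four applications = identity mod 2 pi
  q <- refl
  for (i in 1:4) q <- pi_half_perturb(q, 0.5)
  expect_close(sin(q$phase - refl$phase), rep(0, 10), tol = 1e-12)
  expect_close(cos(q$phase - refl$phase), rep(1, 10), tol = 1e-12)
})

test_that("tangent refinement: FFT path equals brute force", {
  withr::with_seed(6, {
    hkl <- unique(matrix(sample(-6:6, 3 * 120, replace = TRUE), ncol = 3))
    hkl <- hkl[rowSums(abs(hkl)) > 0, ][1:100, ]
    refl <- data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                       E = rexp(100) + 0.1, phase = runif(100, -pi, pi))
  })
  a <- tangent_refine(refl, n_tf = 100, method = "fft")
  b <- tangent_refine(refl, n_tf = 100, method = "brute")
  expect_close(sin(a$phase - b$phase), rep(0, 100), tol = 1e-8)
  # raw sums agree to 1e-6 relative
  Ga <- sadret:::.triplet_fft(hkl, complex(modulus = refl$E,
                                           argument = refl$phase))
  Gb <- sadret:::.triplet_brute(hkl, complex(modulus = refl$E,
                                             argument = refl$phase))
  expect_lt(max(Mod(Ga - Gb)) / max(Mod(Gb)), 1e-6)
})

test_that("tangent refinement: no-triplet identity and single-triplet toy", {
  # no closed triplets -> all G = 0 -> phases untouched
  refl0 <- data.frame(h = c(1, 5, 9), k = 0, l = 0, E = c(3, 2, 1),
                      phase = c(0.3, 0.7, -0.2))
  out0 <- tangent_refine(refl0, 3)
  expect_identical(out0$phase, refl0$phase)
  # single triplet {h, k, h-k}: phi_tf(h) = phi_k + phi_{h-k} = 60 deg
  refl1 <- data.frame(h = c(5, 3, 2), k = c(4, 1, 3), l = c(2, 1, 1),
                      E = c(1, 2, 2),
                      phase = c(2.5, 40 * pi / 180, 20 * pi / 180))
  out1 <- tangent_refine(refl1, 3)
  expect_close(out1$phase[1], 60 * pi / 180, tol = 1e-9)
  expect_equal(out1$phase[2:3], refl1$phase[2:3])
})

test_that("in-loop (C++) tangent equals an independent expanded-set brute force", {
  fx <- fix_direct_fa_small(seed = 13, n_atoms = 4, d_min = 3.2)
  prob <- build_problem(fx$refl, fx$cell, fx$sg)
  n_u <- nrow(prob$hkl)
  withr::with_seed(3, phase <- runif(n_u, -pi, pi))
  F <- complex(modulus = prob$E_obs, argument = phase)
  strong <- order(-prob$E_obs)[1:60]
  out <- sadret:::tangent_apply_cpp(
    F, as.integer(prob$tf_dims), prob$member_off, prob$tf_member_idx,
    prob$member_ph, prob$member_conj, prob$tf_member_wt, prob$E_obs,
    as.integer(strong - 1L))
  # oracle: double loop over the Friedel-expanded strong set (P1 members)
  hs <- rbind(prob$hkl[strong, ], -prob$hkl[strong, ])
  Es <- c(F[strong], Conj(F[strong]))
  key <- paste(hs[, 1], hs[, 2], hs[, 3])
  lut <- setNames(seq_len(nrow(hs)), key)
  G <- complex(real = numeric(length(strong)))
  for (i in seq_along(strong)) {
    for (j in seq_len(nrow(hs))) {
      rem <- prob$hkl[strong[i], ] - hs[j, ]
      kk <- lut[paste(rem[1], rem[2], rem[3])]
      if (!is.na(kk)) G[i] <- G[i] + Es[j] * Es[kk]
    }
  }
  M <- prob$E_obs[strong] * Mod(G)
  alpha <- M / max(M)
  blend <- (1 - alpha) * complex(argument = phase[strong]) +
    alpha * complex(argument = Arg(G))
  want <- Arg(blend)
  got <- Arg(out[strong])
  upd <- Mod(G) > 1e-12
  expect_close(sin(got[upd] - want[upd]), rep(0, sum(upd)), tol = 1e-6)
  # non-strong reflections untouched
  expect_close(Mod(out[-strong] - F[-strong]), rep(0, n_u - 60), tol = 1e-12)
})

test_that("RAAR real-space constraint: algebraic limits", {
  withr::with_seed(2, {
    rho_t <- array(rnorm(6 * 5 * 4), c(6, 5, 4))
    rho_l <- array(abs(rnorm(6 * 5 * 4)), c(6, 5, 4))
  })
  # perturb_fraction -> 0: pure modulus pass-through
  expect_identical(raar_real_space(rho_t, rho_l, 0.82, 1e-9), abs(rho_t))
  # beta = 0.5: perturbed branch = |0.5 rho_last| exactly
  out <- raar_real_space(rho_t, rho_l, 0.5, 0.4)
  delta <- sadret:::.density_threshold(abs(rho_t), 0.4)
  low <- abs(rho_t) < delta
  expect_equal(sum(low), floor(0.4 * length(rho_t)))
  expect_close(out[low], abs(0.5 * rho_l[low]), tol = 1e-14)
  expect_close(out[!low], abs(rho_t)[!low], tol = 1e-14)
  # beta = 1 with rho_last = |rho_tilde|: perturbed branch annihilates
  out2 <- raar_real_space(rho_t, abs(rho_t), 1, 0.4)
  expect_close(out2[low], rep(0, sum(low)), tol = 1e-14)
  expect_error(raar_real_space(rho_t, array(0, c(2, 2, 2)), 0.8, 0.1),
               "mismatch")
  # delta_mode "pass": the fraction is read as the pass-through share
  out3 <- raar_real_space(rho_t, rho_l, 0.82, 0.4, delta_mode = "pass")
  d3 <- sadret:::.density_threshold(abs(rho_t), 0.4, "pass")
  expect_equal(sum(abs(rho_t) >= d3), floor(0.4 * length(rho_t)))
})

test_that("charge flipping: identity, negation and double-flip behaviour", {
  withr::with_seed(3, rho <- array(rnorm(5 * 4 * 6), c(5, 4, 6)))
  expect_identical(cf_real_space(rho, 0), rho)
  neg <- -abs(rho)
  expect_identical(cf_real_space(neg, 1), -neg)
  # double application with a fixed threshold: identity on the band
  # |rho| < delta and on rho >= delta; rho <= -delta is flipped once and
  # then retained (the signed flip rule is not a global involution)
  delta <- sadret:::.density_threshold(abs(rho), 0.3)
  once <- cf_real_space(rho, 0.3, delta = delta)
  twice <- cf_real_space(once, 0.3, delta = delta)
  inv_region <- abs(rho) < delta | rho >= delta
  expect_identical(twice[inv_region], rho[inv_region])
  expect_identical(twice[!inv_region], -rho[!inv_region])
})

test_that("Pearson CC definition and edge cases", {
  withr::with_seed(8, {
    x <- rexp(1000)
    y <- rnorm(1000)
  })
  expect_equal(cc_pearson(x, 3 * x + 2), 1, tolerance = 1e-12)
  expect_equal(cc_pearson(x, -x), -1, tolerance = 1e-12)
  expect_lt(abs(cc_pearson(x, y) - cor(x, y)), 1e-12)
  expect_equal(cc_pearson(x, rep(1, 1000)), 0)
})

test_that("figures of merit behave", {
  withr::with_seed(5, {
    E <- rexp(500)
    gauss <- array(rnorm(32^3), c(32, 32, 32))
  })
  fom <- monitor_fom(gauss, E, E)
  expect_equal(fom$r_factor, 0)
  expect_equal(fom$cc, 1)
  expect_lt(abs(fom$skewness), 0.05)
  spike <- array(0.01 * runif(8000), c(20, 20, 20))
  spike[3, 4, 5] <- 50
  expect_gt(monitor_fom(spike, E, E)$skewness, 1)
  # scaled E_calc still gives R = 0 thanks to the least-squares scale
  expect_equal(monitor_fom(gauss, E, E * 4.2)$r_factor, 0, tolerance = 1e-12)
})

test_that("random starting density is real, zero-mean and seed-deterministic", {
  fx <- fix_direct_fa_small(seed = 4, n_atoms = 3, d_min = 3.5)
  prob <- build_problem(fx$refl, fx$cell, fx$sg)
  r1 <- init_random_density(prob, seed = 42)
  r2 <- init_random_density(prob, seed = 42)
  r3 <- init_random_density(prob, seed = 43)
  expect_identical(r1, r2)
  expect_false(identical(r1, r3))
  expect_lt(abs(mean(r1)), 1e-12 * max(abs(r1)))
})

test_that("scatter/reduce round trip is the identity on consistent sets", {
  cell <- fix_cell_ortho(); sg <- fix_p212121()
  spec <- synthetic_spec(cell, sg, n_atoms = 3, d_min = 3.2, noise_frac = 0,
                         min_sep = 5, seed = 2)
  ds <- make_dataset(spec, "direct_fa")
  refl <- normalize_to_E(ds$refl, sg = sg)
  prob <- build_problem(refl, cell, sg)
  withr::with_seed(7, phase <- runif(nrow(prob$hkl), -pi, pi))
  cen <- is_centric(prob$hkl, sg)
  phase[cen] <- centric_phase(prob$hkl, sg)[cen]
  F <- complex(modulus = ifelse(prob$obs, prob$E_obs, 0.5),
               argument = phase)
  G <- sadret:::.scatter_R(prob, F)
  back <- sadret:::.reduce_R(prob, G)
  expect_lt(max(Mod(back - F)), 1e-10)
  # and the grid is Hermitian: synthesized map real
  rho <- sadret:::fft3_cpp(as.vector(G), as.integer(prob$dims), -1L)
  expect_lt(max(abs(Im(rho))), 1e-8 * max(abs(Re(rho))))
})
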