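test_that("symop parsing and printing round-trip", {
  strs <- c("x,y,z", "-x,y+1/2,-z", "-x+1/2,-y,z+1/2", "x-y,x,z+1/3",
            "x+1/2,y+1/2,z")
  for (s in strs) {
    op <- parse_symop(s)
    op2 <- parse_symop(symop_to_string(op))
    expect_equal(op$rot, op2$rot, info = s)
    expect_close(op$trans, op2$trans)
  }
  expect_error(parse_symop("x,y"), "3 components")
  expect_error(parse_symop("x,y,q"), "cannot parse")
})

test_that("space_group validates group structure", {
  expect_error(space_group(c("-x,y+1/2,-z")), "identity")
  expect_error(space_group(c("x,y,z", "-x,y+1/4,-z")), "not closed")
  sg <- fix_p212121()
  expect_equal(sg$n_ops, 4)
  expect_length(sg$laue_ops, 8) # mmm Laue group
  # every group in the built-in table is a group
  for (sym in c("P1", "P-1", "P2", "P21", "C2", "P222", "P21212"))
    expect_s3_class(space_group(sym), "space_group")
})

test_that("Friedel expansion in P1", {
  asu <- data.frame(h = 1, k = 0, l = 0, amp = 2, phase = 30 * pi / 180)
  full <- expand_reflections(asu, fix_p1())
  expect_equal(nrow(full), 2)
  mate <- full[full$h == -1, ]
  expect_equal(mate$amp, 2)
  expect_equal(mate$phase, -30 * pi / 180)
})

test_that("P21 expansion carries the -2 pi h.t phase shift", {
  sg <- fix_p21()
  # (0,1,0) maps onto itself under (-x, y+1/2, -z) with shift
  # -2 pi (0,1,0).(0,1/2,0) = -pi: systematically absent
  expect_true(is_systematically_absent(c(0, 1, 0), sg))
  # (1,1,0): operator image is (-1,1,0) with phase phi - pi
  asu <- data.frame(h = 1, k = 1, l = 0, amp = 1, phase = 0.3)
  full <- expand_reflections(asu, sg)
  img <- full[full$h == -1 & full$k == 1 & full$l == 0, ]
  expect_equal(nrow(img), 1)
  expect_close(img$phase, 0.3 - pi, tol = 1e-12)
  # Friedel mate of the image
  img2 <- full[full$h == 1 & full$k == -1 & full$l == 0, ]
  expect_close(img2$phase, pi - 0.3, tol = 1e-12)
})

test_that("expand -> reduce round trip is the identity (P212121, P-1, P21)", {
  cell <- fix_cell_small()
  for (sym in c("P212121", "P-1", "P21")) {
    sg <- space_group(sym)
    asu <- fix_random_phased_set(sg, cell, d_min = 4.5, seed = 11)
    full <- expand_reflections(asu, sg)
    back <- reduce_to_asu(full, sg)
    key <- function(d) paste(d$h, d$k, d$l)
    pos <- match(key(asu), key(back))
    expect_false(anyNA(pos), info = sym)
    z0 <- complex(modulus = asu$amp, argument = asu$phase)
    z1 <- complex(modulus = back$amp[pos], argument = back$phase[pos])
    expect_lt(max(Mod(z0 - z1)) / max(Mod(z0)), 1e-10)
  }
})

test_that("reduction averages inconsistent duplicates and is idempotent", {
  sg <- fix_p1bar()
  # two members of one orbit carrying inconsistent values -> mean
  full <- data.frame(h = c(1, -1), k = c(2, -2), l = c(3, -3),
                     amp = c(1, 2), phase = c(0.2, -0.5))
  red <- reduce_to_asu(full, sg)
  expect_equal(nrow(red), 1)
  zm <- mean(c(complex(modulus = 1, argument = 0.2),
               Conj(complex(modulus = 2, argument = -0.5))))
  expect_close(c(red$amp, red$phase), c(Mod(zm), Arg(zm)), tol = 1e-12)
  # idempotent: reducing the reduction changes nothing
  red2 <- reduce_to_asu(red, sg)
  expect_equal(red[order(red$h), ], red2[order(red2$h), ],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("expansion flags inconsistent duplicate input", {
  sg <- fix_p1bar()
  asu <- data.frame(h = c(1, -1), k = c(0, 0), l = c(0, 0),
                    amp = c(1, 5), phase = c(0, 0))
  expect_error(expand_reflections(asu, sg), "inconsistent duplicate")
})

test_that("systematic absences match the brute-force phase-shift rule", {
  brute_absent <- function(h, sg) {
    for (op in sg$ops) {
      if (all(h %*% op$rot == h)) {
        ph <- sum(h * op$trans) %% 1
        if (abs(ph - round(ph)) > 1e-9) return(TRUE)
      }
    }
    FALSE
  }
  grid <- as.matrix(expand.grid(h = -4:4, k = -4:4, l = -4:4))
  grid <- grid[rowSums(abs(grid)) > 0, ]
  for (sym in c("P1", "P21", "P212121", "C2")) {
    sg <- space_group(sym)
    got <- is_systematically_absent(grid, sg)
    want <- apply(grid, 1, brute_absent, sg = sg)
    expect_equal(got, want, info = sym)
  }
  # textbook cases
  expect_false(any(is_systematically_absent(grid, fix_p1())))
  expect_true(is_systematically_absent(c(3, 0, 0), fix_p212121()))
  expect_false(is_systematically_absent(c(2, 0, 0), fix_p212121()))
})

test_that("permissible origin shifts and polar axes", {
  p1 <- permissible_origin_shifts(fix_p1())
  expect_true(all(p1$polar_axes))
  p1b <- permissible_origin_shifts(fix_p1bar())
  expect_false(any(p1b$polar_axes))
  expect_equal(nrow(p1b$shifts), 8) # the half-integer translations
  expect_true(all(p1b$shifts %in% c(0, 0.5)))
  p212121 <- permissible_origin_shifts(fix_p212121())
  expect_equal(nrow(p212121$shifts), 8)
  expect_false(any(p212121$polar_axes))
  # invariant: R t - t integral for every rotation and every shift
  for (sym in c("P-1", "P21", "C2", "P212121")) {
    sg <- space_group(sym)
    for (i in seq_len(nrow(sg$allowed_shifts))) {
      t <- sg$allowed_shifts[i, ]
      for (r in sg$rotations) {
        d <- as.vector(r %*% t) - t
        expect_close(d - round(d), c(0, 0, 0), tol = 1e-9)
      }
    }
  }
  # P21: y polar, discrete shifts on x/z only
  p21 <- permissible_origin_shifts(fix_p21())
  expect_equal(p21$polar_axes, c(FALSE, TRUE, FALSE))
  expect_true(all(p21$shifts[, 2] == 0))
})

test_that("centricity and epsilon factors follow the point group", {
  sg <- fix_p212121()
  expect_true(all(is_centric(rbind(c(0, 1, 2), c(1, 0, 2), c(1, 2, 0)), sg)))
  expect_false(any(is_centric(rbind(c(1, 2, 3), c(-1, 2, 3)), sg)))
  expect_true(all(is_centric(rbind(c(1, 2, 3), c(0, 1, 0)), fix_p1bar())))
  eps <- sadret:::epsilon_factor(rbind(c(1, 0, 0), c(1, 2, 3)), sg)
  expect_equal(eps, c(2L, 1L)) # axial reflection fixed by one 2-fold
})

test_that("unit cell geometry is consistent", {
  cl <- unit_cell(40, 50, 60)
  expect_equal(d_spacing(cl, c(1, 0, 0)), 40)
  expect_equal(d_spacing(cl, c(0, 2, 0)), 25)
  mono <- unit_cell(30, 40, 50, beta = 110)
  x <- matrix(c(0.1, 0.2, 0.3), 1, 3)
  expect_close(cart_to_frac(mono, frac_to_cart(mono, x)), x, tol = 1e-12)
  expect_error(unit_cell(-1, 2, 3), "positive")
  expect_error(unit_cell(1, 2, 3, alpha = 181), "angles")
})
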