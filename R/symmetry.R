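#' Parse a symmetry operator string
#'
#' Parses "x,y,z"-style operator triplets (e.g. `"-x,y+1/2,-z"`) into a
#' rotation matrix and a translation vector.  The rotation acts on column
#' fractional coordinates, `x' = R x + t`; translations are reduced mod 1.
#'
#' @param s operator string, three comma-separated components
#' @return a list with integer 3 x 3 `rot` and numeric length-3 `trans`
#' @examples
#' parse_symop("-x,y+1/2,-z")
#' @export
parse_symop <- function(s) {
  parts <- strsplit(gsub("[[:space:]]", "", tolower(s)), ",")[[1]]
  if (length(parts) != 3) stop("symmetry operator must have 3 components: ", s)
  rot <- matrix(0L, 3, 3)
  trans <- numeric(3)
  for (i in 1:3) {
    terms <- regmatches(parts[i],
                        gregexpr("[+-]?[0-9./]*[xyz]|[+-]?[0-9.]+(/[0-9.]+)?",
                                 parts[i]))[[1]]
    if (!nzchar(paste(terms, collapse = "")) ||
        nchar(paste(terms, collapse = "")) != nchar(parts[i]))
      stop("cannot parse symmetry operator component: ", parts[i])
    for (term in terms) {
      sign <- if (startsWith(term, "-")) -1 else 1
      body <- sub("^[+-]", "", term)
      if (grepl("[xyz]", body)) {
        axis <- match(substring(body, nchar(body)), c("x", "y", "z"))
        coef <- sub("[xyz]$", "", body)
        val <- if (nzchar(coef)) eval(parse(text = coef)) else 1
        rot[i, axis] <- rot[i, axis] + as.integer(sign * val)
      } else {
        trans[i] <- trans[i] + sign * eval(parse(text = body))
      }
    }
  }
  list(rot = rot, trans = trans %% 1)
}

#' @rdname parse_symop
#' @param op a symop list as returned by `parse_symop`
#' @export
symop_to_string <- function(op) {
  comp <- character(3)
  ax <- c("x", "y", "z")
  for (i in 1:3) {
    s <- ""
    for (j in 1:3) {
      r <- op$rot[i, j]
      if (r != 0) {
        pre <- if (r > 0) (if (nzchar(s)) "+" else "") else "-"
        mag <- if (abs(r) == 1) "" else as.character(abs(r))
        s <- paste0(s, pre, mag, ax[j])
      }
    }
    tr <- op$trans[i] %% 1
    if (abs(tr) > 1e-9) {
      fr <- .as_fraction(tr)
      s <- paste0(s, "+", fr)
    }
    comp[i] <- s
  }
  paste(comp, collapse = ",")
}

.as_fraction <- function(x, denoms = c(2, 3, 4, 6, 12)) {
  for (d in denoms) {
    n <- round(x * d)
    if (abs(x - n / d) < 1e-9) return(paste0(n, "/", d))
  }
  format(x)
}

symop_compose <- function(op1, op2) {
  list(rot = op1$rot %*% op2$rot,
       trans = (op1$rot %*% op2$trans + op1$trans) %% 1)
}

symop_equal <- function(op1, op2, tol = 1e-9) {
  all(op1$rot == op2$rot) &&
    all(abs((op1$trans - op2$trans + 0.5) %% 1 - 0.5) < tol)
}

#' Space-group operator set
#'
#' Builds a space group from explicit operator strings (or parsed operator
#' lists).  Checks that the set forms a group (identity present, closed
#' under composition mod lattice translations) and derives the Laue
#' rotation set, polar (continuous-origin) axes and the discrete
#' permissible origin shifts.  Centring is handled by listing the centring
#' translations as ordinary operators.
#'
#' @param symops character vector of "x,y,z"-style operators, or a space
#'   group symbol known to [sg_ops()], or a list of parsed operators
#' @return an object of class `space_group`
#' @examples
#' sg <- space_group(c("x,y,z", "-x,y+1/2,-z"))   # P2_1
#' sg$polar_axes
#' @export
space_group <- function(symops) {
  if (is.character(symops) && length(symops) == 1 && !grepl(",", symops))
    symops <- sg_ops(symops)
  ops <- if (is.list(symops) && !is.null(symops$rot)) list(symops)
         else if (is.list(symops)) symops
         else lapply(symops, parse_symop)
  for (op in ops) {
    if (abs(det(op$rot)) != 1)
      stop("symmetry rotation must have determinant +/-1")
  }
  has_id <- any(vapply(ops, function(o)
    symop_equal(o, list(rot = diag(3), trans = c(0, 0, 0))), logical(1)))
  if (!has_id) stop("operator set must contain the identity x,y,z")
  # closure
  for (o1 in ops) for (o2 in ops) {
    comp <- symop_compose(o1, o2)
    if (!any(vapply(ops, symop_equal, logical(1), comp)))
      stop("operator set is not closed under composition: ",
           symop_to_string(o1), " o ", symop_to_string(o2))
  }
  rots <- unique(lapply(ops, `[[`, "rot"))
  laue <- rots
  for (r in rots) {
    neg <- -r
    if (!any(vapply(laue, function(x) all(x == neg), logical(1))))
      laue <- c(laue, list(neg))
  }
  polar <- .polar_axes(rots)
  shifts <- .origin_shifts(rots, polar)
  obj <- list(ops = ops, rotations = rots, laue_ops = laue,
              polar_axes = polar, allowed_shifts = shifts,
              centrosymmetric = any(vapply(rots, function(r)
                all(r == -diag(3)), logical(1))),
              n_ops = length(ops))
  class(obj) <- "space_group"
  obj
}

#' @export
print.space_group <- function(x, ...) {
  cat("space group with", x$n_ops, "operators:\n")
  for (op in x$ops) cat("  ", symop_to_string(op), "\n")
  cat("polar axes:", if (any(x$polar_axes)) paste(c("x", "y", "z")[x$polar_axes],
                                                  collapse = " ") else "none",
      "| discrete origin shifts:", nrow(x$allowed_shifts), "\n")
  invisible(x)
}

# axis i has continuous origin freedom iff every rotation fixes e_i
.polar_axes <- function(rots) {
  vapply(1:3, function(i) {
    e <- diag(3)[, i]
    all(vapply(rots, function(r) all(r %*% e == e), logical(1)))
  }, logical(1))
}

# discrete permissible origin shifts: brute force over the 1/12 fractional
# grid, t allowed iff R t - t == 0 (mod 1) for every rotation; components
# along polar axes are zeroed (continuous freedom reported separately)
.origin_shifts <- function(rots, polar) {
  g <- (0:11) / 12
  cand <- as.matrix(expand.grid(x = g, y = g, z = g))
  ok <- rep(TRUE, nrow(cand))
  for (r in rots) {
    d <- cand %*% t(r) - cand
    ok <- ok & apply(abs((d + 0.5) %% 1 - 0.5) < 1e-9, 1, all)
  }
  sh <- cand[ok, , drop = FALSE]
  sh[, polar] <- 0
  sh <- unique(round(sh, 9))
  rownames(sh) <- NULL
  sh
}

#' Built-in operator lists for a few common space groups
#'
#' A hand-written convenience table so that tests and examples never need an
#' external symmetry database; any other group can be supplied as explicit
#' operator strings.
#'
#' @param symbol one of P1, P-1, P2, P21, C2, P222, P21212, P212121
#' @return character vector of operator strings
#' @export
sg_ops <- function(symbol) {
  tab <- list(
    "P1"      = c("x,y,z"),
    "P-1"     = c("x,y,z", "-x,-y,-z"),
    "P2"      = c("x,y,z", "-x,y,-z"),
    "P21"     = c("x,y,z", "-x,y+1/2,-z"),
    "C2"      = c("x,y,z", "-x,y,-z", "x+1/2,y+1/2,z", "-x+1/2,y+1/2,-z"),
    "P222"    = c("x,y,z", "-x,-y,z", "-x,y,-z", "x,-y,-z"),
    "P21212"  = c("x,y,z", "-x,-y,z", "-x+1/2,y+1/2,-z", "x+1/2,-y+1/2,-z"),
    "P212121" = c("x,y,z", "-x+1/2,-y,z+1/2", "-x,y+1/2,-z+1/2",
                  "x+1/2,-y+1/2,-z"))
  key <- toupper(gsub("[[:space:]()]", "", symbol))
  if (is.null(tab[[key]])) stop("unknown space-group symbol: ", symbol,
                                " (supply explicit operators instead)")
  tab[[key]]
}

# ---- reflection symmetry -------------------------------------------------

# apply rotations to rows of hkl: returns n x 3 matrix h' = h R (row conv.)
.hkl_transform <- function(hkl, rot) hkl %*% rot

#' Laue-unique representative of reflections
#'
#' Maps each index triple to its orbit representative under the Laue group
#' (space-group rotations plus inversion/Friedel): the lexicographically
#' greatest equivalent triple (h compared first, then k, then l).
#'
#' @param hkl n x 3 integer matrix (or length-3 vector)
#' @param sg a [space_group()]
#' @return list with `hkl` (n x 3 representative indices), and for
#'   bookkeeping `op` (index of the generating rotation), `friedel`
#'   (logical: representative reached through Friedel inversion) and
#'   `phase_shift` (radians to add to the member phase to obtain the
#'   representative phase, before any conjugation)
#' @export
asu_representative <- function(hkl, sg) {
  m <- if (is.matrix(hkl)) hkl else matrix(hkl, ncol = 3, byrow = TRUE)
  n <- nrow(m)
  best <- m
  best_op <- rep(1L, n)
  best_friedel <- rep(FALSE, n)
  lex_greater <- function(a, b) {
    (a[, 1] > b[, 1]) |
      (a[, 1] == b[, 1] & a[, 2] > b[, 2]) |
      (a[, 1] == b[, 1] & a[, 2] == b[, 2] & a[, 3] > b[, 3])
  }
  for (oi in seq_along(sg$rotations)) {
    hr <- .hkl_transform(m, sg$rotations[[oi]])
    for (fr in c(FALSE, TRUE)) {
      cand <- if (fr) -hr else hr
      better <- lex_greater(cand, best)
      if (any(better)) {
        best[better, ] <- cand[better, , drop = FALSE]
        best_op[better] <- oi
        best_friedel[better] <- fr
      }
    }
  }
  list(hkl = best, op = best_op, friedel = best_friedel)
}

#' Systematic absence test
#'
#' A reflection is systematically absent iff some operator maps its index
#' onto itself with a non-integral translation phase (brute-force rule over
#' the full operator list, centring included).
#'
#' @param hkl length-3 vector or n x 3 matrix
#' @param sg a [space_group()]
#' @return logical vector
#' @export
is_systematically_absent <- function(hkl, sg) {
  m <- if (is.matrix(hkl)) hkl else matrix(hkl, ncol = 3, byrow = TRUE)
  absent <- rep(FALSE, nrow(m))
  for (op in sg$ops) {
    hr <- .hkl_transform(m, op$rot)
    selfmap <- rowSums(abs(hr - m)) == 0
    ph <- as.vector(m %*% op$trans) %% 1
    absent <- absent | (selfmap & abs(ph - round(ph)) > 1e-9)
  }
  absent
}

#' Centric reflection test (phase-restricted under the point group)
#' @inheritParams is_systematically_absent
#' @return logical vector: TRUE where some rotation maps h to -h
#' @export
is_centric <- function(hkl, sg) {
  m <- if (is.matrix(hkl)) hkl else matrix(hkl, ncol = 3, byrow = TRUE)
  cen <- rep(FALSE, nrow(m))
  for (r in sg$rotations)
    cen <- cen | rowSums(abs(.hkl_transform(m, r) + m)) == 0
  cen
}

# symmetry-enhancement (epsilon) factor: order of the stabilizer of h in
# the rotation group
epsilon_factor <- function(hkl, sg) {
  m <- if (is.matrix(hkl)) hkl else matrix(hkl, ncol = 3, byrow = TRUE)
  eps <- rep(0L, nrow(m))
  for (r in sg$rotations)
    eps <- eps + (rowSums(abs(.hkl_transform(m, r) - m)) == 0)
  eps
}

#' Permissible origin shifts
#'
#' @param sg a [space_group()]
#' @return list with `shifts` (matrix of discrete fractional shifts on the
#'   1/12 search grid, polar components zeroed) and `polar_axes` (logical
#'   length 3)
#' @export
permissible_origin_shifts <- function(sg) {
  list(shifts = sg$allowed_shifts, polar_axes = sg$polar_axes)
}

# ---- expansion / reduction of reflection data ---------------------------

#' Symmetry-expand an asymmetric-unit reflection set to the full sphere
#'
#' Each record (amplitude, phase) is propagated to all symmetry images,
#' `F(hR) = F(h) exp(-2 pi i h.t)`, and to their Friedel mates (conjugate
#' phase).  Images that coincide are checked for consistency.
#'
#' @param asu data frame with columns h, k, l, amp, phase (radians), one
#'   row per Laue-unique reflection
#' @param sg a [space_group()]
#' @param tol relative amplitude tolerance for duplicate consistency
#' @return data frame h, k, l, amp, phase covering the full sphere
#' @export
expand_reflections <- function(asu, sg, tol = 1e-8) {
  stopifnot(all(c("h", "k", "l", "amp", "phase") %in% names(asu)))
  m <- as.matrix(asu[, c("h", "k", "l")])
  out <- vector("list", 2 * length(sg$ops))
  i <- 0
  for (op in sg$ops) {
    hr <- .hkl_transform(m, op$rot)
    ph <- asu$phase - 2 * pi * as.vector(m %*% op$trans)
    i <- i + 1
    out[[i]] <- data.frame(h = hr[, 1], k = hr[, 2], l = hr[, 3],
                           amp = asu$amp, phase = ph)
    i <- i + 1
    out[[i]] <- data.frame(h = -hr[, 1], k = -hr[, 2], l = -hr[, 3],
                           amp = asu$amp, phase = -ph)
  }
  full <- do.call(rbind, out)
  full$phase <- atan2(sin(full$phase), cos(full$phase))
  key <- paste(full$h, full$k, full$l)
  dup <- duplicated(key)
  if (any(dup)) {
    z <- complex(modulus = full$amp, argument = full$phase)
    ref <- tapply(z, key, function(v) v[1])
    scale <- max(abs(z), 1e-300)
    bad <- abs(z - ref[key]) > tol * scale + 1e-12
    if (any(bad)) {
      b <- which(bad)[1]
      stop(sprintf("inconsistent duplicate amplitudes/phases at (%d %d %d)",
                   full$h[b], full$k[b], full$l[b]))
    }
  }
  res <- full[!dup, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Reduce full-sphere reflections to Laue-unique representatives
#'
#' Groups reflections into Laue orbits, back-transforms every member to the
#' representative index (lexicographically greatest triple) and averages the
#' complex values (phase-aligned average, which silently absorbs any
#' symmetry inconsistency).
#'
#' @param full data frame with columns h, k, l, amp, phase
#' @param sg a [space_group()]
#' @return data frame with one row per orbit
#' @export
reduce_to_asu <- function(full, sg) {
  stopifnot(all(c("h", "k", "l", "amp", "phase") %in% names(full)))
  m <- as.matrix(full[, c("h", "k", "l")])
  rep_info <- asu_representative(m, sg)
  # back-transform member value to the representative: the recorded op has
  # h_rep = (+/-)(h_m R), and F(h_m R) = F(h_m) exp(-2 pi i h_m.t), so
  # F_rep = z_m exp(-2 pi i h_m.t), conjugated afterwards on the Friedel leg
  z <- complex(modulus = full$amp, argument = full$phase)
  tshift <- numeric(nrow(m))
  for (oi in seq_along(sg$rotations)) {
    sel <- rep_info$op == oi
    if (!any(sel)) next
    # rotation oi may come from several ops; their translations differ by a
    # centring vector whose phase is integral on non-absent reflections
    opi <- Find(function(o) all(o$rot == sg$rotations[[oi]]), sg$ops)
    tshift[sel] <- as.vector(m[sel, , drop = FALSE] %*% opi$trans)
  }
  zback <- z * exp(-2i * pi * tshift)
  zback <- ifelse(rep_info$friedel, Conj(zback), zback)
  key <- paste(rep_info$hkl[, 1], rep_info$hkl[, 2], rep_info$hkl[, 3])
  agg <- tapply(zback, key, mean)
  first <- !duplicated(key)
  ord <- key[first]
  hkl_rep <- rep_info$hkl[first, , drop = FALSE]
  zrep <- as.complex(agg[ord])
  data.frame(h = hkl_rep[, 1], k = hkl_rep[, 2], l = hkl_rep[, 3],
             amp = Mod(zrep), phase = Arg(zrep))
}
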