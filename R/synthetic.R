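# Synthetic fixtures: open curves of known topology, idealized backbones,
# toy native structures with contact maps, and in-silico mutants.  All
# generators are seed-deterministic and self-verify their declared topology.

torus_curve <- function(n, p, q, cut_phase = 0, tube = 1) {
  t <- cut_phase + 2 * pi * (seq_len(n) - 1) / n
  cbind((2 + tube * cos(q * t)) * cos(p * t),
        (2 + tube * cos(q * t)) * sin(p * t),
        tube * sin(q * t))
}

rescale_bonds <- function(x, b0 = 3.8) {
  b <- sqrt(rowSums((x[-1, , drop = FALSE] - x[-nrow(x), , drop = FALSE])^2))
  x * (b0 / mean(b))
}

# n beads spaced uniformly in arc length along a densely sampled open curve,
# scaled to b0 bonds; keeps consecutive-bead distances essentially constant
# even where the parametrization speeds up
resample_uniform <- function(dense, n, b0 = 3.8) {
  seg <- sqrt(rowSums((dense[-1, , drop = FALSE] -
                       dense[-nrow(dense), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  targets <- seq(0, cum[length(cum)] * (n - 1) / n, length.out = n)
  x <- cbind(stats::approx(cum, dense[, 1], targets)$y,
             stats::approx(cum, dense[, 2], targets)$y,
             stats::approx(cum, dense[, 3], targets)$y)
  rescale_bonds(x, b0)
}

# arc-length-uniform open torus curve (the workhorse of the knot fixtures)
torus_polygon <- function(n, p, q, cut_phase = 0, tube = 1, b0 = 3.8) {
  resample_uniform(torus_curve(40 * n, p, q, cut_phase, tube), n, b0)
}

#' Closed torus-knot ring with uniform bonds
#'
#' @param n_beads ring vertices.
#' @param p,q torus winding numbers ((2,3) gives the trefoil).
#' @param b0 bond length (Angstrom).
#' @return N x 3 ring vertex matrix (first and last vertex are adjacent).
#' @export
make_closed_torus_knot <- function(n_beads = 120, p = 2, q = 3, b0 = 3.8) {
  dense <- torus_curve(40 * n_beads, p, q)
  dense <- rbind(dense, dense[1, ])
  seg <- sqrt(rowSums((dense[-1, , drop = FALSE] -
                       dense[-nrow(dense), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  targets <- cum[length(cum)] * (seq_len(n_beads) - 1) / n_beads
  x <- cbind(stats::approx(cum, dense[, 1], targets)$y,
             stats::approx(cum, dense[, 2], targets)$y,
             stats::approx(cum, dense[, 3], targets)$y)
  b <- sqrt(sum((x[1, ] - x[2, ])^2))
  x * (b0 / b)
}

# straight radial prolongations of both termini (deepens an embedded knot)
add_straight_tails <- function(x, n_head, n_tail, b0 = 3.8) {
  ctr <- colMeans(x)
  out <- x
  if (n_head > 0) {
    u <- x[1, ] - ctr; u <- u / sqrt(sum(u^2))
    head_pts <- t(sapply(n_head:1, function(k) x[1, ] + k * b0 * u))
    out <- rbind(head_pts, out)
  }
  if (n_tail > 0) {
    u <- x[nrow(x), ] - ctr; u <- u / sqrt(sum(u^2))
    tail_pts <- t(sapply(1:n_tail, function(k) x[nrow(x), ] + k * b0 * u))
    out <- rbind(out, tail_pts)
  }
  out
}

#' Open trefoil curve of prescribed handedness
#'
#' Parametric (2,3) torus-knot polygon opened at `cut_phase`, rescaled to
#' 3.8 Angstrom bonds.  With `tail_beads > 0` both termini are prolonged
#' radially outward, burying the knot core deep inside the chain so that
#' every sound closure scheme classifies the curve as a proper trefoil.
#'
#' @param n_beads number of vertices on the knotted body (>= 30).
#' @param handedness `"right"` (positive writhe) or `"left"`.
#' @param cut_phase phase (radians) at which the ring is opened.
#' @param tail_beads straight beads appended at each terminus (default 0).
#' @return N x 3 coordinate matrix.
#' @export
make_open_trefoil <- function(n_beads = 48, handedness = c("right", "left"),
                              cut_phase = 0, tail_beads = 0) {
  handedness <- match.arg(handedness)
  stopifnot(n_beads >= 30)
  x <- torus_polygon(n_beads, 2, 3, cut_phase)
  w <- .writhe_cpp(x, TRUE)
  if ((handedness == "right") != (w > 0)) x[, 3] <- -x[, 3]
  if (tail_beads > 0) x <- add_straight_tails(x, tail_beads, tail_beads)
  x
}

#' Open figure-eight curve
#'
#' 4_1 parametrization opened at `cut_phase`, 3.8 Angstrom bonds.  The
#' figure-eight knot is amphichiral, so no handedness is offered.
#'
#' @inheritParams make_open_trefoil
#' @return N x 3 coordinate matrix.
#' @export
make_figure_eight <- function(n_beads = 60, cut_phase = 0, tail_beads = 0) {
  stopifnot(n_beads >= 30)
  t <- cut_phase + 2 * pi * (seq_len(40 * n_beads) - 1) / (40 * n_beads)
  dense <- cbind((2 + cos(2 * t)) * cos(3 * t),
                 (2 + cos(2 * t)) * sin(3 * t),
                 sin(4 * t))
  x <- resample_uniform(dense, n_beads)
  if (tail_beads > 0) x <- add_straight_tails(x, tail_beads, tail_beads)
  x
}

#' Unknotted open curve
#'
#' `"helix"` builds an ideal C-alpha helix (trivially unknotted);
#' `"random_coil"` grows a self-avoiding walk with 3.8 Angstrom steps and a
#' 4 Angstrom exclusion distance, restarting on dead ends.
#'
#' @param n_beads number of beads (>= 3).
#' @param style `"helix"` or `"random_coil"`.
#' @param seed RNG seed (random_coil only).
#' @return N x 3 coordinate matrix.
#' @export
make_unknot <- function(n_beads = 48, style = c("helix", "random_coil"), seed = 1) {
  style <- match.arg(style)
  stopifnot(n_beads >= 3)
  if (style == "helix") return(helix_ca(n_beads))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  b0 <- 3.8; dmin2 <- 16
  for (restart in 1:100) {
    x <- matrix(0, n_beads, 3)
    x[2, ] <- c(b0, 0, 0)
    ok <- TRUE
    for (i in 3:n_beads) {
      placed <- FALSE
      for (try in 1:200) {
        z <- stats::rnorm(3); z <- z / sqrt(sum(z^2))
        # bias forward to keep the walk open
        dirp <- x[i - 1, ] - x[i - 2, ]
        z <- z + 0.5 * dirp / b0
        z <- z / sqrt(sum(z^2))
        cand <- x[i - 1, ] + b0 * z
        prev <- x[seq_len(i - 2), , drop = FALSE]
        if (all(rowSums((prev - matrix(cand, nrow(prev), 3, byrow = TRUE))^2) > dmin2)) {
          x[i, ] <- cand; placed <- TRUE; break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(x)
  }
  stop("self-avoiding growth failed repeatedly")
}

# ideal C-alpha helix: radius 2.3 A, rise 1.5 A, 100 degrees per residue
helix_ca <- function(n, radius = 2.3, rise = 1.5, turn = 100 * pi / 180) {
  i <- seq_len(n) - 1
  cbind(radius * cos(i * turn), radius * sin(i * turn), rise * i)
}

# C-alpha chain from internal coordinates (NeRF construction)
place_next <- function(a, b, c, bond, angle, dihedral) {
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  nv <- pracma_cross(b - a, bc)
  nn <- sqrt(sum(nv^2))
  if (nn < 1e-10) nv <- pick_orthogonal(bc) else nv <- nv / nn
  m2 <- pracma_cross(nv, bc)
  d2 <- c(-bond * cos(angle), bond * sin(angle) * cos(dihedral),
          bond * sin(angle) * sin(dihedral))
  c + d2[1] * bc + d2[2] * m2 + d2[3] * nv
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' C-alpha chain from pseudo-bond internal coordinates
#'
#' @param angles pseudo-angles (radians, length N-2).
#' @param dihedrals pseudo-dihedrals (radians, length N-3).
#' @param b0 bond length (Angstrom).
#' @return N x 3 coordinate matrix.
#' @export
ca_chain_from_internal <- function(angles, dihedrals, b0 = 3.8) {
  n <- length(angles) + 2
  stopifnot(length(dihedrals) == n - 3)
  x <- matrix(0, n, 3)
  x[2, ] <- c(b0, 0, 0)
  x[3, ] <- x[2, ] + b0 * c(-cos(angles[1]), sin(angles[1]), 0)
  for (i in seq_len(n - 3))
    x[i + 3, ] <- place_next(x[i, ], x[i + 1, ], x[i + 2, ], b0,
                             angles[i + 1], dihedrals[i])
  x
}

# ---------------------------------------------------------------------------
# Idealized full-backbone fixtures (for hydrogen-bond / secondary-structure
# machinery): standard peptide geometry propagated by NeRF.

#' Idealized peptide backbone from repeated (phi, psi)
#'
#' Builds N, CA, C, O (plus a CB pseudo-side-chain for non-glycine) with
#' standard bond lengths and angles and omega = 180 degrees; returns a
#' `residue_set` compatible with the contact-map and secondary-structure
#' machinery.  phi = -57, psi = -47 gives an ideal alpha-helix; phi = -139,
#' psi = 135 an extended strand.
#'
#' @param n_res number of residues.
#' @param phi,psi backbone dihedrals in degrees (recycled).
#' @param sequence residue one- or three-letter codes (recycled; default ALA).
#' @return a `residue_set`.
#' @export
make_ideal_backbone <- function(n_res, phi = -57, psi = -47, sequence = "A") {
  phi <- rep(phi * pi / 180, length.out = n_res)
  psi <- rep(psi * pi / 180, length.out = n_res)
  seq1 <- rep(if (all(nchar(sequence) == 3)) aa_3to1(sequence) else toupper(sequence),
              length.out = n_res)
  deg <- function(x) x * pi / 180
  N <- matrix(0, n_res, 3); CA <- N; C <- N
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  C[1, ] <- CA[1, ] + 1.525 * c(cos(pi - deg(111.2)), sin(pi - deg(111.2)), 0)
  for (i in seq_len(n_res - 1)) {
    N[i + 1, ] <- place_next(N[i, ], CA[i, ], C[i, ], 1.329, deg(116.2), psi[i])
    CA[i + 1, ] <- place_next(CA[i, ], C[i, ], N[i + 1, ], 1.458, deg(121.7), pi)
    C[i + 1, ] <- place_next(C[i, ], N[i + 1, ], CA[i + 1, ], 1.525, deg(111.2), phi[i + 1])
  }
  residues <- vector("list", n_res)
  for (i in seq_len(n_res)) {
    # carbonyl O on the bisector opposite N(i+1) (virtual for the last residue)
    nref <- if (i < n_res) N[i + 1, ]
            else C[i, ] + 1.3 * (C[i, ] - N[i, ]) / sqrt(sum((C[i, ] - N[i, ])^2))
    d1 <- C[i, ] - nref; d1 <- d1 / sqrt(sum(d1^2))
    d2 <- C[i, ] - CA[i, ]; d2 <- d2 / sqrt(sum(d2^2))
    ov <- d1 + d2; ov <- ov / sqrt(sum(ov^2))
    O <- C[i, ] + 1.231 * ov
    bb <- list(N = N[i, ], CA = CA[i, ], C = C[i, ], O = O)
    sc <- matrix(0, 0, 3)
    if (seq1[i] != "G") {
      u1 <- N[i, ] - CA[i, ]; u1 <- u1 / sqrt(sum(u1^2))
      u2 <- C[i, ] - CA[i, ]; u2 <- u2 / sqrt(sum(u2^2))
      bis <- -(u1 + u2); bis <- bis / sqrt(sum(bis^2))
      pp <- pracma_cross(u2, u1); pp <- pp / sqrt(sum(pp^2))
      cb <- CA[i, ] + 1.53 * (cos(deg(54)) * bis + sin(deg(54)) * pp)
      sc <- matrix(cb, 1, 3)
    }
    residues[[i]] <- list(seq_index = i, insert = "", aa = aa_1to3(seq1[i]),
                          ca = CA[i, ], backbone = bb, sidechain = sc)
  }
  for (i in seq(2, n_res)) {
    if (residues[[i]]$aa != "PRO") {
      d <- residues[[i - 1]]$backbone$C - residues[[i - 1]]$backbone$O
      residues[[i]]$backbone$H <- residues[[i]]$backbone$N + d / sqrt(sum(d^2))
    }
  }
  structure(residues, class = "residue_set")
}

#' Idealized antiparallel beta-hairpin
#'
#' Two extended strands related by the two-fold rotation about the sheet
#' normal that generates antiparallel beta-sheets; the inter-strand offset
#' and registry shift are scanned (then polished) to maximize the
#' cross-strand hydrogen-bond network.  Used as the sheet fixture for the
#' secondary-structure assignment.
#'
#' @param n_per_strand residues per strand.
#' @return a `residue_set` of `2 * n_per_strand + 2` residues.
#' @export
make_beta_hairpin <- function(n_per_strand = 6) {
  n <- n_per_strand
  s1 <- make_ideal_backbone(n, phi = -139, psi = 135)
  ca1 <- t(vapply(s1, function(r) r$ca, numeric(3)))
  ctr <- colMeans(ca1)
  u <- ca1[n, ] - ca1[1, ]; u <- u / sqrt(sum(u^2))      # strand direction
  resid <- ca1 - matrix(ctr, n, 3, byrow = TRUE)
  resid <- resid - outer(as.numeric(resid %*% u), u)
  v <- svd(resid)$v[, 1]                                  # pleat direction
  w <- pracma_cross(u, v); w <- w / sqrt(sum(w^2))        # sheet normal

  transform_res <- function(res, rot, shift) {
    tr <- function(p) if (is.null(p)) NULL else as.numeric(rot %*% (p - ctr) + ctr + shift)
    res$ca <- tr(res$ca)
    res$backbone <- lapply(res$backbone, tr)
    if (nrow(res$sidechain)) res$sidechain <- t(apply(res$sidechain, 1, tr))
    res
  }
  bond_score <- function(s2t) {
    e <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      e <- e + min(hbond_energy(s2t[[j]], s1[[i]]), 0) +
           min(hbond_energy(s1[[i]], s2t[[j]]), 0)
    }
    ca2 <- t(vapply(s2t, function(r) r$ca, numeric(3)))
    dmin <- min(as.matrix(stats::dist(rbind(ca1, ca2)))[seq_len(n), n + seq_len(n)])
    e + if (dmin < 3.8) 100 * (3.8 - dmin) else 0
  }
  # NH/CO point along +/-w, so the partner strand sits along w and the
  # antiparallel two-fold axis is the out-of-plane pleat direction v
  R2 <- rotmat(pi * v)
  best <- NULL; best_val <- Inf
  for (sh in seq(-6, 6, by = 0.25)) for (off in seq(-5.6, 5.6, by = 0.4)) {
    if (abs(off) < 4) next
    s2t <- lapply(s1, transform_res, rot = R2, shift = off * w + sh * u)
    val <- bond_score(s2t)
    if (val < best_val) { best_val <- val; best <- c(off, sh) }
  }
  score_t <- function(par) {
    s2t <- lapply(s1, transform_res, rot = R2,
                  shift = par[1] * w + par[2] * u + par[3] * v)
    bond_score(s2t)
  }
  opt <- stats::optim(c(best, 0), score_t, method = "Nelder-Mead",
                      control = list(maxit = 1000, reltol = 1e-9))
  s2t <- lapply(s1, transform_res, rot = R2,
                shift = opt$par[1] * w + opt$par[2] * u + opt$par[3] * v)
  # index order: the two-fold flip makes s2 antiparallel already; keep order
  p1 <- s1[[n]]$ca; p2 <- s2t[[1]]$ca
  turn <- lapply(1:2, function(k) {
    f <- k / 3
    ca <- (1 - f) * p1 + f * p2 + 2.5 * w
    list(seq_index = 0, insert = "", aa = "GLY", ca = ca,
         backbone = list(N = ca + c(-0.5, 0, 0), CA = ca, C = ca + c(0.5, 0, 0),
                         O = ca + c(0.5, 1.2, 0)),
         sidechain = matrix(0, 0, 3))
  })
  out <- c(s1, turn, s2t)
  for (i in seq_along(out)) out[[i]]$seq_index <- i
  structure(out, class = "residue_set")
}

rotmat <- function(rv) {
  th <- sqrt(sum(rv^2))
  if (th < 1e-12) return(diag(3))
  k <- rv / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# ---------------------------------------------------------------------------
# Toy native structures

toy_contact_map <- function(coords, cutoff = 6, strength = 3) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  idx <- which(upper.tri(d) & d < cutoff &
               abs(row(d) - col(d)) >= 3, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("toy structure produced no contacts")
  data.frame(i = idx[, 1], j = idx[, 2], class = "sidechain",
             strength = strength, r0 = d[idx])
}

#' Toy native structure with a verified topology
#'
#' Desk-scale analogue of a natively knotted / unknotted protein pair.  A
#' parametric scaffold fixes the topology: the knotted kind opens a (2,3)
#' torus knot (right-handed trefoil) at the phase whose knot core touches
#' the C-terminal end, so the chain's last strand -- continued by a short
#' C-terminal helix -- is the knot-completing thread; the unknotted kind
#' winds the same tube as a topologically trivial (1,3) coil.  Both carry
#' the same polar body sequence; the terminal helix is hydrophobic
#' (LEU/ILE/VAL/ALA) in the knotted toy and neutral hydrophilic
#' (GLU/GLN/ASN) in the unknotted one, mirroring the C-terminal chemistry
#' that distinguishes the natively knotted protein from its unknotted
#' homolog.  A short packing stage (crossing-audited local Monte Carlo
#' under a strengthened quasi-chemical attraction, pivots disabled so the
#' embedded topology is provably conserved) settles the terminal helix
#' against the body, which places native contacts between the tail and the
#' knot loop: during folding these reward the correctly threaded -- hence
#' correctly handed -- knot.  The contact map uses the geometric C-alpha
#' rule (< 6 A, |i-j| >= 3, uniform strength).  The declared topology (and
#' right-handed chirality for the knotted kind) is verified after packing
#' and again on the final structure; failures retry with a shifted seed, a
#' bounded number of times.
#'
#' @param kind `"knotted"` or `"unknotted"`.
#' @param n_beads total length (default 60).
#' @param tail_length residues in the terminal helix (default 12).
#' @param seed generator seed (the result is a deterministic function of it).
#' @param contact_strength uniform native strength, kT (default 3, the
#'   hydrogen-bond scale).
#' @param pack_units MC time of the packing stage; the hydrophilic terminal
#'   helix of the unknotted kind packs more slowly, so it gets a longer
#'   default, which also matches the two kinds' contact counts.
#' @return a `toy_native`: list with `sequence` (one-letter), `coords`,
#'   `contact_map`, `topology` (`label`, `chirality`), `kind`, `seed`.
#' @export
make_toy_native <- function(kind = c("knotted", "unknotted"), n_beads = 60,
                            tail_length = 12, seed = 1, contact_strength = 3,
                            pack_units = if (match.arg(kind) == "knotted") 30 else 50) {
  kind <- match.arg(kind)
  nb <- n_beads - tail_length
  stopifnot(nb >= 30, tail_length >= 4)
  expected <- if (kind == "knotted") "trefoil_3_1" else "unknot"

  for (attempt in 0:3) {
    coords <- toy_scaffold(kind, nb, tail_length)
    seqv <- toy_sequence(kind, nb, tail_length)
    x <- pack_toy(coords, seqv, expected, seed = seed + 101L * attempt,
                  pack_units = pack_units, strength = contact_strength)
    if (is.null(x)) next
    cm <- toy_contact_map(x, strength = contact_strength)
    assess <- classify_topology(x, n_closures = 50, seed = 7)
    ok <- identical(assess$label, expected) &&
      (kind == "unknotted" || identical(assess$chirality, "right"))
    b <- sqrt(rowSums((x[-1, ] - x[-nrow(x), ])^2))
    if (ok && all(b > 2.5 & b < 4.5)) {
      chir <- if (kind == "knotted") assess$chirality else "n/a"
      return(structure(list(sequence = seqv, coords = x, contact_map = cm,
                            topology = list(label = expected, chirality = chir),
                            kind = kind, seed = seed),
                       class = "toy_native"))
    }
  }
  stop("toy native generation failed after bounded retries (kind = ", kind, ")")
}

# parametric scaffold: knot body plus a terminal helix placed with at least
# 4.2 A clearance from every non-adjacent bead.  The knotted body is opened
# at the phase whose knot core touches the C-terminal end, so the terminal
# helix continues the knot-completing strand: re-forming the knot during
# folding is a C-terminal threading event, as in the natively-knotted
# protein the toy emulates.
toy_scaffold <- function(kind, nb, tail_length, cut_phase = pi / 2) {
  body <- if (kind == "knotted") make_open_trefoil(nb, "right", cut_phase = cut_phase)
          else torus_polygon(nb, 1, 3, cut_phase = cut_phase)
  ctr <- colMeans(body)
  tangent <- body[nb, ] - body[nb - 1, ]; tangent <- tangent / sqrt(sum(tangent^2))
  outward <- body[nb, ] - ctr; outward <- outward / sqrt(sum(outward^2))
  hx <- helix_ca(tail_length + 1)
  best <- NULL; best_clear <- -Inf
  for (w in seq(0, 1, by = 0.1)) {
    axis <- (1 - w) * tangent + w * outward
    axis <- axis / sqrt(sum(axis^2))
    e1 <- pick_orthogonal(axis); e2 <- pracma_cross(axis, e1)
    for (ph in seq(0, 2 * pi - 1e-9, by = pi / 4)) {
      rot1 <- cos(ph) * e1 + sin(ph) * e2
      rot2 <- -sin(ph) * e1 + cos(ph) * e2
      tail <- t(vapply(seq_len(tail_length), function(k) {
        h <- hx[k + 1, ] - hx[1, ]
        body[nb, ] + h[3] * axis + h[1] * rot1 + h[2] * rot2
      }, numeric(3)))
      cand <- rbind(body, tail)
      d <- as.matrix(stats::dist(cand))
      clear <- min(d[abs(row(d) - col(d)) > 1 & upper.tri(d)])
      if (clear > best_clear) { best_clear <- clear; best <- cand }
      if (clear >= 4.2) return(cand)
    }
  }
  best  # fall back to the clearest placement found
}

# shared polar body; kind-specific terminal-helix chemistry
toy_sequence <- function(kind, nb, tail_length) {
  body_seq <- rep(c("A", "S", "E", "K", "V", "G", "T", "N", "Q", "L"),
                  length.out = nb)
  tail_seq <- if (kind == "knotted") rep(c("L", "I", "V", "A"), length.out = tail_length)
              else rep(c("E", "Q", "N"), length.out = tail_length)
  c(body_seq, tail_seq)
}

# settle the terminal helix against the body by audited local moves under a
# strengthened quasi-chemical attraction; returns NULL if the topology is
# ever lost
pack_toy <- function(coords, seqv, expected, seed, pack_units, strength) {
  cm0 <- toy_contact_map(coords, strength = strength)
  params <- forcefield_params(nonnative_ratio = 0.4)
  m <- folding_model(coords, seqv, cm0, params, mode = "full",
                     bonded_reference = "native")
  cfg <- mc_config(total_units = pack_units, snapshot_interval = pack_units,
                   seed = seed * 1000 + 555, max_relax_units = 0,
                   p_phase1 = c(0.9, 0.1, 0), p_phase2 = c(0.9, 0.1, 0),
                   audit_fraction = 0.02)
  x <- run_trajectory(m, cfg, start = coords)$final
  lab <- classify_topology(x, n_closures = 30, seed = 11, localize = FALSE)$label
  if (!identical(lab, expected)) return(NULL)
  x
}

#' @export
print.toy_native <- function(x, ...) {
  cat(sprintf("toy_native (%s): %d beads, %d contacts, topology %s %s\n",
              x$kind, nrow(x$coords), nrow(x$contact_map),
              x$topology$label,
              if (x$topology$chirality == "n/a") "" else paste0("(", x$topology$chirality, ")")))
  invisible(x)
}

#' In-silico mutant sequences
#'
#' `"hydrophilic_cterm"` replaces the last `n_res` residues by cycling the
#' neutral hydrophilic triplet GLU/GLN/ASN; `"chimera_cterm"` grafts the
#' last `n_res` residue types of a donor sequence.  Coordinates and the
#' native contact map are left untouched -- only the sequence changes.
#'
#' @param base character vector of residue codes, or a `toy_native`.
#' @param op `"hydrophilic_cterm"` or `"chimera_cterm"`.
#' @param n_res number of C-terminal residues to substitute.
#' @param donor donor sequence for the chimera (character vector or
#'   `toy_native`); must be at least `n_res` long.
#' @return object of the same kind as `base` with the mutated sequence.
#' @export
make_mutant_sequence <- function(base, op = c("hydrophilic_cterm", "chimera_cterm"),
                                 n_res, donor = NULL) {
  op <- match.arg(op)
  seqv <- if (inherits(base, "toy_native")) base$sequence else base
  three <- all(nchar(seqv) == 3)
  seq1 <- if (three) aa_3to1(seqv) else toupper(seqv)
  n <- length(seq1)
  stopifnot(n_res >= 0, n_res <= n)
  if (n_res > 0) {
    tail_idx <- (n - n_res + 1):n
    if (op == "hydrophilic_cterm") {
      seq1[tail_idx] <- rep(c("E", "Q", "N"), length.out = n_res)
    } else {
      if (is.null(donor)) stop("chimera_cterm requires a donor sequence")
      dseq <- if (inherits(donor, "toy_native")) donor$sequence else donor
      dseq <- if (all(nchar(dseq) == 3)) aa_3to1(dseq) else toupper(dseq)
      if (length(dseq) < n_res) stop("donor shorter than n_res")
      seq1[tail_idx] <- dseq[(length(dseq) - n_res + 1):length(dseq)]
    }
  }
  out <- if (three) aa_1to3(seq1) else seq1
  if (inherits(base, "toy_native")) {
    base$sequence <- seq1
    base$mutant_op <- if (n_res > 0) op else NULL
    base
  } else out
}
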