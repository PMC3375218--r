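# Topology classification of open C-alpha chains: KMT-style rectification,
# Alexander determinants of closed rings, two closure schemes with a
# majority rule, knot-core localization and chirality from the Gauss writhe.

#' Rectify a chain while preserving its topology
#'
#' Iteratively removes every vertex whose elementary triangle (formed with
#' its two neighbours) is pierced by no other chain segment, as in the
#' KMT / KNOTFIND rectification step.  Idempotent; endpoints of open chains
#' are never removed.
#'
#' @param coords N x 3 coordinate matrix (open chain or ring).
#' @param closed treat the polygon as closed.
#' @return list with `coords` (reduced vertices) and `orig_index` (1-based
#'   indices of the surviving vertices in the input).
#' @export
simplify_chain <- function(coords, closed = FALSE) {
  coords <- as.matrix(unclass(coords))
  stopifnot(nrow(coords) >= 3, ncol(coords) == 3)
  .kmt_simplify_cpp(coords, closed)
}

#' Alexander determinants of a closed curve
#'
#' Computes `|Delta(-1)|` and `|Delta(-2)|` from the crossing pattern of a
#' generic planar projection of the (rectified) ring; the projection is
#' re-drawn on degenerate crossings.  `|Delta(-2)|` is reported modulo the
#' powers of two inherent to the determinant convention, making both values
#' projection-invariant integers: unknot (1, 1), trefoil (3, 7),
#' figure-eight (5, 11).
#'
#' @param ring closed polygon: N x 3 matrix or a [closed_curve] object.
#' @param max_retries projection retries before failing.
#' @param proj_seed seed of the deterministic projection-direction stream.
#' @return integer vector `c(det_minus1, det_minus2)`.
#' @export
alexander_determinants <- function(ring, max_retries = 50, proj_seed = 12345) {
  .alexander_cpp(as.matrix(unclass(ring)), max_retries, proj_seed)
}

# determinant pair -> knot label
knot_label_from_dets <- function(d) {
  if (d[1] == 1) "unknot"
  else if (d[1] == 3) "trefoil_3_1"
  else if (d[1] == 5 && d[2] == 11) "figure_eight_4_1"
  else "other"
}

#' Closed curve with provenance
#'
#' @param coords ring vertices (consecutive, last connects to first).
#' @param is_original logical per vertex: chain vertex or closure-arc vertex.
#' @return a `closed_curve`: the matrix with a `provenance` attribute.
#' @export
closed_curve <- function(coords, is_original) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == length(is_original))
  if (any(sqrt(rowSums((coords - coords[c(2:nrow(coords), 1), ])^2)) < 1e-9))
    stop("closed curve has coincident consecutive vertices")
  structure(coords, provenance = as.logical(is_original),
            class = c("closed_curve", class(coords)))
}

#' Minimally interfering closure of an open chain
#'
#' Deterministic single closure: when both termini sit near the surface of
#' the chain's bounding region, each is prolonged radially outward well
#' beyond the chain and the two exit points are bridged through a distant
#' waypoint; otherwise the termini are bridged directly.  Closure arcs stay
#' outside the chain's bounding sphere except for the two exit rays.
#'
#' @param chain N x 3 C-alpha coordinates (N >= 3).
#' @param surface_fraction termini farther than this fraction of the maximal
#'   centroid distance count as surface-exposed.
#' @return a [closed_curve()]; added vertices carry `provenance = FALSE`.
#' @export
minimally_interfering_closure <- function(chain, surface_fraction = 0.55) {
  x <- as.matrix(unclass(chain))
  n <- nrow(x)
  stopifnot(n >= 3)
  ctr <- colMeans(x)
  rad <- sqrt(rowSums((x - matrix(ctr, n, 3, byrow = TRUE))^2))
  R <- max(rad, 1e-6)
  t1 <- x[1, ]; tn <- x[n, ]
  if (rad[1] > surface_fraction * R && rad[n] > surface_fraction * R) {
    u1 <- (t1 - ctr) / max(rad[1], 1e-9)
    un <- (tn - ctr) / max(rad[n], 1e-9)
    o1 <- ctr + 3 * R * u1
    on <- ctr + 3 * R * un
    mid <- u1 + un
    if (sqrt(sum(mid^2)) < 1e-6) mid <- pick_orthogonal(u1)
    w <- ctr + 4 * R * mid / sqrt(sum(mid^2))
    closed_curve(rbind(x, on, w, o1),
                 c(rep(TRUE, n), FALSE, FALSE, FALSE))
  } else {
    closed_curve(x, rep(TRUE, n))  # direct bridge: implicit last-first segment
  }
}

pick_orthogonal <- function(v) {
  a <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  w <- a - sum(a * v) * v
  w / sqrt(sum(w^2))
}

#' Stochastic closure poll
#'
#' Prolongs each terminus far out of the chain along a random direction
#' constrained to form an angle of more than 90 degrees with the oriented
#' segment from that terminus to the C-alpha at sequence distance 10, closes
#' the prolonged ends through a distant waypoint, and computes the Alexander
#' determinants; repeated `n_closures` times.  A chain is called entangled
#' when the majority (strictly more than half) of closures return
#' non-trivial determinants.
#'
#' @param chain N x 3 coordinates, N > 10.
#' @param n_closures number of stochastic closures (default 100).
#' @param seed RNG seed for the closure directions.
#' @return list with `consensus` (fraction non-trivial), `majority`
#'   (logical), `label` (majority knot type among non-trivial closures, or
#'   `"unknot"`), and `dets` (n x 2 matrix of determinant pairs).
#' @export
stochastic_closure_poll <- function(chain, n_closures = 100, seed = 1) {
  x <- as.matrix(unclass(chain))
  n <- nrow(x)
  stopifnot(n > 10)
  ctr <- colMeans(x)
  R <- max(sqrt(rowSums((x - matrix(ctr, n, 3, byrow = TRUE))^2)), 1e-6)
  L <- 4 * R  # at least twice the chain diameter for any bead cloud
  v1 <- x[11, ] - x[1, ]; v1 <- v1 / sqrt(sum(v1^2))
  vn <- x[n - 10, ] - x[n, ]; vn <- vn / sqrt(sum(vn^2))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  draw_dir <- function(vref) {
    repeat {
      z <- stats::rnorm(3)
      z <- z / sqrt(sum(z^2))
      if (sum(z * vref) < 0) return(z)  # > 90 degrees away from the inward segment
    }
  }
  dets <- matrix(0L, n_closures, 2)
  for (k in seq_len(n_closures)) {
    d1 <- draw_dir(v1)
    dn <- draw_dir(vn)
    o1 <- x[1, ] + L * d1
    on <- x[n, ] + L * dn
    mid <- (o1 - ctr) + (on - ctr)
    if (sqrt(sum(mid^2)) < 1e-6) mid <- pick_orthogonal(d1)
    w <- ctr + 2 * L * mid / sqrt(sum(mid^2))
    ring <- rbind(x, on, w, o1)
    dets[k, ] <- alexander_determinants(ring, proj_seed = seed + 7L * k)
  }
  nontrivial <- dets[, 1] != 1L | dets[, 2] != 1L
  lab <- "unknot"
  if (any(nontrivial)) {
    labs <- apply(dets[nontrivial, , drop = FALSE], 1, knot_label_from_dets)
    lab <- names(sort(table(labs), decreasing = TRUE))[1]
  }
  list(consensus = mean(nontrivial),
       majority = mean(nontrivial) > 0.5,
       label = lab,
       dets = dets)
}

#' Classify the topology of an open chain
#'
#' Two-stage scheme: the deterministic minimally interfering closure is
#' evaluated first; on a non-trivial result the stochastic closure poll
#' validates it by majority rule.  For entangled chains the knot core is
#' localized and, for trefoils, the chirality determined from the writhe of
#' the core.
#'
#' @param chain N x 3 C-alpha coordinates.
#' @param n_closures closures in the validation poll.
#' @param seed RNG seed (closure directions).
#' @param localize also locate the knot core and chirality (default TRUE).
#' @return a `knot_assessment`: list with `label`, `consensus`, `proper`,
#'   `core` (first/last residue indices or NULL), `chirality`, `dets`.
#' @export
classify_topology <- function(chain, n_closures = 100, seed = 1, localize = TRUE) {
  x <- as.matrix(unclass(chain))
  n <- nrow(x)
  out <- list(label = "unknot", consensus = 0, proper = FALSE, core = NULL,
              chirality = "n/a", dets = c(1L, 1L), n = n)
  class(out) <- "knot_assessment"
  if (n < 3) return(out)
  d0 <- alexander_determinants(minimally_interfering_closure(x), proj_seed = seed)
  out$dets <- d0
  if (d0[1] == 1 && d0[2] == 1) return(out)
  if (n > 10 && n_closures > 0) {
    poll <- stochastic_closure_poll(x, n_closures, seed)
    out$consensus <- poll$consensus
    if (!poll$majority) { out$dets <- c(1L, 1L); return(out) }
    out$label <- poll$label
  } else {
    out$consensus <- 1
    out$label <- knot_label_from_dets(d0)
  }
  if (localize) {
    loc <- locate_knot_core(x)
    out$core <- loc$core
    out$proper <- loc$proper
    if (identical(out$label, "trefoil_3_1") && !is.null(loc$core)) {
      out$chirality <- knot_chirality(x, loc$core)
    } else if (!is.null(loc$core)) {
      w <- core_writhe(x, loc$core)
      out$chirality <- if (abs(w) < 0.5) "indeterminate" else if (w > 0) "right" else "left"
    }
  }
  out
}

# knottedness of a subchain under the deterministic closure
subchain_knotted <- function(x, lo, hi, proj_seed = 12345) {
  if (hi - lo + 1 < 5) return(FALSE)
  d <- alexander_determinants(minimally_interfering_closure(x[lo:hi, , drop = FALSE]),
                              proj_seed = proj_seed)
  d[1] != 1L || d[2] != 1L
}

#' Locate the knot core of an entangled chain
#'
#' Finds the smallest contiguous subchain that remains knotted under the
#' minimally interfering closure, by trimming residues from either end while
#' the trimmed subchain stays knotted (two-sided search, then a tightening
#' re-pass).  A knot whose core reaches a chain terminus -- or that vanishes
#' for every subchain even though the closed full chain is knotted -- spans
#' the closure arcs and is flagged improper.
#'
#' @param chain N x 3 coordinates of a chain classified as entangled.
#' @return list with `core` (`c(first, last)` 1-based indices, or NULL) and
#'   `proper` flag.
#' @export
locate_knot_core <- function(chain) {
  x <- as.matrix(unclass(chain))
  n <- nrow(x)
  if (!subchain_knotted(x, 1, n))
    return(list(core = NULL, proper = FALSE))
  lo <- 1; hi <- n
  while (lo < hi && subchain_knotted(x, lo + 1, hi)) lo <- lo + 1
  while (hi > lo && subchain_knotted(x, lo, hi - 1)) hi <- hi - 1
  # tightening re-pass from the left after the right end settled
  while (lo < hi && subchain_knotted(x, lo + 1, hi)) lo <- lo + 1
  proper <- lo > 1 && hi < n
  list(core = c(lo, hi), proper = proper)
}

core_writhe <- function(chain, core) {
  x <- as.matrix(unclass(chain))[core[1]:core[2], , drop = FALSE]
  ring <- minimally_interfering_closure(x)
  s <- simplify_chain(ring, closed = TRUE)
  .writhe_cpp(s$coords, TRUE)
}

#' Knot chirality from the Gauss writhe
#'
#' Sign of the writhe of the rectified, closed knot core: positive means a
#' right-handed knot, negative left-handed.
#'
#' @param chain N x 3 coordinates (full chain).
#' @param core `c(first, last)` core bounds from [locate_knot_core()].
#' @return `"right"` or `"left"`; `"indeterminate"` when `|writhe| < 0.5`.
#' @export
knot_chirality <- function(chain, core) {
  stopifnot(length(core) == 2, core[1] >= 1, core[2] <= nrow(chain))
  if (!subchain_knotted(as.matrix(unclass(chain)), core[1], core[2]))
    stop("knot_chirality requires an entangled core (classify the chain first)")
  w <- core_writhe(chain, core)
  if (abs(w) < 0.5) return("indeterminate")
  if (w > 0) "right" else "left"
}

#' Persistence of a knotting event
#'
#' A detected knot counts as persistent (fully developed) when the stochastic
#' closure consensus reaches `consensus_threshold`, or the knot core sits at
#' a depth of at least `depth_threshold` residues from both termini.
#'
#' @param assessment a `knot_assessment`.
#' @param consensus_threshold closure-consensus fraction (default 0.9).
#' @param depth_threshold minimal sequence distance of the core from the
#'   nearest terminus (default 20 residues).
#' @return logical.
#' @export
is_persistent_knot <- function(assessment, consensus_threshold = 0.9,
                               depth_threshold = 20) {
  if (identical(assessment$label, "unknot")) return(FALSE)
  if (assessment$consensus >= consensus_threshold) return(TRUE)
  if (is.null(assessment$core)) return(FALSE)
  depth <- min(assessment$core[1] - 1, assessment$n - assessment$core[2])
  depth >= depth_threshold
}

#' @export
print.knot_assessment <- function(x, ...) {
  cat(sprintf("Knot assessment: %s (|Delta(-1)|, |Delta(-2)| = %d, %d)\n",
              x$label, x$dets[1], x$dets[2]))
  cat(sprintf("  closure consensus: %.2f;  %s\n", x$consensus,
              if (identical(x$label, "unknot")) "untangled"
              else if (x$proper) "proper knot" else "improper knot"))
  if (!is.null(x$core))
    cat(sprintf("  core: residues %d-%d;  chirality: %s\n",
                x$core[1], x$core[2], x$chirality))
  invisible(x)
}
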