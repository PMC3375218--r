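# Chain geometry and the assembled folding model.

#' Chain geometry: ordered C-alpha coordinates
#'
#' @param coords numeric N x 3 matrix of C-alpha positions in Angstrom.
#' @param check_bonds if `TRUE`, require consecutive-bead distances in
#'   (2.5, 4.5) Angstrom, as native C-alpha traces must satisfy.
#' @return the coordinate matrix with class `chain_geometry`.
#' @export
chain_geometry <- function(coords, check_bonds = TRUE) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3) stop("coords must have 3 columns")
  if (nrow(coords) < 3) stop("a chain needs at least 3 beads")
  if (anyNA(coords)) stop("coords contain missing values")
  if (check_bonds) {
    b <- sqrt(rowSums((coords[-1, , drop = FALSE] - coords[-nrow(coords), , drop = FALSE])^2))
    bad <- which(b <= 2.5 | b >= 4.5)
    if (length(bad))
      stop("consecutive-bead distance outside (2.5, 4.5) A at bond(s) ",
           paste(utils::head(bad, 5), collapse = ", "),
           " (first offending length ", sprintf("%.2f", b[bad[1]]), " A)")
  }
  class(coords) <- c("chain_geometry", class(coords))
  coords
}

#' Assemble a coarse-grained folding model
#'
#' Binds together the native C-alpha trace, the sequence, the native contact
#' map and the force-field parameters, and (by default) calibrates the
#' non-native scale so the mean non-native strength is the configured
#' fraction of the mean native strength.
#'
#' @param coords native C-alpha coordinates (N x 3, Angstrom).
#' @param sequence residue types (one- or three-letter codes, length N).
#' @param contact_map data frame with columns `i`, `j`, `class`, `strength`
#'   (and optionally `r0`, recomputed from `coords` when absent).
#' @param params a [forcefield_params()] object.
#' @param mode `"native_only"` (purely native-centric potential) or `"full"`
#'   (adds quasi-chemical non-native and screened electrostatic terms).
#' @param calibrate run [calibrate_nonnative_scale()] on the parameters.
#' @param bonded_reference `"statistical"` uses the transferable double-well
#'   angle and residue-class torsion terms; `"native"` uses harmonic angle
#'   and 1+3-cosine torsion terms centred on the native geometry (the
#'   classic native-centric choice, used for the toy structures whose
#'   geometry is not protein-like).
#' @return an object of class `folding_model`.
#' @export
folding_model <- function(coords, sequence, contact_map, params = forcefield_params(),
                          mode = c("full", "native_only"), calibrate = TRUE,
                          bonded_reference = c("statistical", "native")) {
  mode <- match.arg(mode)
  bonded_reference <- match.arg(bonded_reference)
  coords <- chain_geometry(unclass(coords))
  seq1 <- if (all(nchar(sequence) == 3)) aa_3to1(sequence) else toupper(sequence)
  if (length(seq1) != nrow(coords)) stop("sequence length must match chain length")
  if (!all(seq1 %in% AA1)) stop("non-canonical residue in sequence")
  contact_map <- validate_contact_map(contact_map, nrow(coords))
  if (is.null(contact_map$r0)) {
    d <- coords[contact_map$i, , drop = FALSE] - coords[contact_map$j, , drop = FALSE]
    contact_map$r0 <- sqrt(rowSums(d^2))
  }
  if (calibrate) params <- calibrate_nonnative_scale(params, contact_map, seq1)
  m <- list(coords = coords, sequence = seq1, contact_map = contact_map,
            params = params, mode = mode, bonded_reference = bonded_reference)
  if (bonded_reference == "native") {
    ic <- chain_internal_coords(coords)
    m$theta0 <- ic$angles
    m$phi0 <- ic$dihedrals
  }
  class(m) <- "folding_model"
  m
}

#' Pseudo-angles and pseudo-dihedrals of a C-alpha chain
#'
#' @param coords N x 3 coordinate matrix.
#' @return list with `angles` (radians, length N-2) and `dihedrals`
#'   (radians, length N-3).
#' @export
chain_internal_coords <- function(coords) {
  x <- as.matrix(unclass(coords))
  n <- nrow(x)
  ang <- vapply(2:(n - 1), function(i) {
    u <- x[i - 1, ] - x[i, ]; v <- x[i + 1, ] - x[i, ]
    acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
  }, numeric(1))
  dih <- vapply(seq_len(n - 3), function(k) {
    b1 <- x[k + 1, ] - x[k, ]; b2 <- x[k + 2, ] - x[k + 1, ]; b3 <- x[k + 3, ] - x[k + 2, ]
    n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
    y <- sum(pracma_cross(n1, n2) * b2 / sqrt(sum(b2^2)))
    atan2(y, sum(n1 * n2))
  }, numeric(1))
  list(angles = ang, dihedrals = dih)
}

# shared sanity checks on a native contact map
validate_contact_map <- function(cm, n) {
  cm <- as.data.frame(cm)
  if (nrow(cm) == 0) stop("empty contact map: degenerate model")
  stopifnot(all(c("i", "j", "strength") %in% names(cm)))
  swap <- cm$i > cm$j
  if (any(swap)) { tmp <- cm$i[swap]; cm$i[swap] <- cm$j[swap]; cm$j[swap] <- tmp }
  if (any(cm$j - cm$i < 3)) stop("contact map contains |i - j| < 3 pairs")
  if (any(cm$i < 1 | cm$j > n)) stop("contact indices out of range")
  if (any(cm$strength <= 0)) stop("contact strengths must be positive attraction magnitudes")
  if (anyDuplicated(cm[c("i", "j")])) stop("duplicate contact pairs")
  if (is.null(cm$class)) cm$class <- "sidechain"
  cm[order(cm$i, cm$j), , drop = FALSE]
}

# list consumed by the compiled backend
model_cpp_list <- function(model, mode = model$mode) {
  p <- model$params
  bonded <- p$bonded
  if (identical(model$bonded_reference, "native")) {
    bonded$theta0 <- model$theta0
    bonded$phi0 <- model$phi0
    bonded$nat_k_ang <- p$nat_k_ang %||% 20
    bonded$nat_k_dih1 <- p$nat_k_dih1 %||% 1
    bonded$nat_k_dih3 <- p$nat_k_dih3 %||% 0.5
  }
  list(sequence_int = aa_index(model$sequence),
       contact_pairs = cbind(model$contact_map$i, model$contact_map$j),
       contact_r0 = model$contact_map$r0,
       contact_eps = model$contact_map$strength,
       nonnative_eps = unname(nonnative_eps_matrix(p)),
       sigma = unname(p$diameters),
       charge = unname(p$charges[model$sequence]),
       bonded = bonded,
       dh_prefactor = p$dh_prefactor,
       debye_length = p$debye_length,
       ev_eps = p$ev_eps,
       ev_sigma = p$ev_sigma %||% 4,
       nn_cut_factor = p$nn_cut_factor,
       temperature = p$temperature,
       native_only = identical(mode, "native_only"))
}

#' Total potential energy with component breakdown
#'
#' @param model a [folding_model()].
#' @param coords coordinates to evaluate (defaults to the native trace).
#' @param mode override of the model's potential mode.
#' @return an `energy_breakdown`: named vector with components `bonded`,
#'   `native`, `nonnative`, `electrostatic` and their `total`, thermal units.
#' @export
total_energy <- function(model, coords = model$coords, mode = model$mode) {
  e <- .total_energy_cpp(as.matrix(unclass(coords)), model_cpp_list(model, mode))
  if (isTRUE(attr(e, "degenerate_torsions") > 0))
    warning(attr(e, "degenerate_torsions"),
            " collinear pseudo-torsion(s) set to zero energy")
  structure(e, class = "energy_breakdown", mode = mode)
}

#' Bonded energy (bonds, pseudo-angles, pseudo-torsions)
#'
#' @inheritParams total_energy
#' @return named vector with `bond`, `angle`, `torsion`, `total` (kT).
#' @export
bonded_energy <- function(model, coords = model$coords) {
  e <- .bonded_energy_cpp(as.matrix(unclass(coords)), model_cpp_list(model))
  if (isTRUE(attr(e, "degenerate_torsions") > 0))
    warning(attr(e, "degenerate_torsions"),
            " collinear pseudo-torsion(s) set to zero energy")
  e
}

#' Native-contact pair potential (12-10-6 well)
#'
#' Minimum of exactly `-eps` at `r = r_native`, a desolvation-style shoulder
#' beyond it and strong excluded-volume repulsion below.
#'
#' @param r distances (Angstrom).
#' @param r_native native-state separation of the pair.
#' @param eps attraction strength (kT), positive.
#' @return energies in kT.
#' @export
native_pair_energy <- function(r, r_native, eps) {
  stopifnot(all(r > 0), r_native > 0, eps > 0)
  .native_pair_energy_cpp(r, r_native, eps)
}

#' Quasi-chemical non-native pair potential
#'
#' Effective strength `eps = lambda * (e_ab - e0)`: attractive pairs
#' (`eps < 0`) get a Lennard-Jones well of depth `|eps|` at the contact
#' distance `sigma_ab` (arithmetic mean of the residue diameters); repulsive
#' pairs (`eps > 0`) a monotone repulsion of scale `eps` at `sigma_ab`.
#'
#' @param r distances (Angstrom).
#' @param type_a,type_b residue types (one- or three-letter).
#' @param params a [forcefield_params()].
#' @return energies in kT.
#' @export
nonnative_pair_energy <- function(r, type_a, type_b, params = forcefield_params()) {
  a <- if (nchar(type_a[1]) == 3) aa_3to1(type_a) else toupper(type_a)
  b <- if (nchar(type_b[1]) == 3) aa_3to1(type_b) else toupper(type_b)
  eps <- nonnative_eps_matrix(params)[a, b]
  sig <- (params$diameters[a] + params$diameters[b]) / 2
  .nonnative_pair_energy_cpp(r, sig, eps)
}

#' Screened (Debye-Hueckel) electrostatic pair potential
#'
#' @param r distances (Angstrom).
#' @param q_a,q_b charges in elementary units.
#' @param params a [forcefield_params()].
#' @return energies in kT; zero for uncharged pairs, sign of `q_a * q_b`.
#' @export
electrostatic_pair_energy <- function(r, q_a, q_b, params = forcefield_params()) {
  stopifnot(all(r > 0))
  params$dh_prefactor * q_a * q_b * exp(-r / params$debye_length) / r
}

#' Incremental energy difference for a contiguous window move
#'
#' Returns the energy change produced by replacing the positions of beads
#' `from..to` with `new_window`, computed from the affected terms only;
#' agrees with a full before/after recomputation to well below 1e-8 kT.
#'
#' @param model a [folding_model()].
#' @param coords current coordinates.
#' @param new_window matrix of new positions for beads `from..to`.
#' @param from,to 1-based bead range (single bead: `from == to`).
#' @return named vector of component deltas and `total` (kT).
#' @export
local_energy_delta <- function(model, coords, new_window, from, to) {
  stopifnot(from >= 1, to <= nrow(coords), from <= to)
  new_window <- matrix(as.numeric(new_window), ncol = 3)
  stopifnot(nrow(new_window) == to - from + 1)
  .local_delta_cpp(as.matrix(unclass(coords)), new_window, from, to,
                   model_cpp_list(model))
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("Energy breakdown (%s potential, thermal units)\n",
              attr(x, "mode") %||% "?"))
  for (nm in c("bonded", "native", "nonnative", "electrostatic", "total"))
    cat(sprintf("  %-14s %12.4f\n", nm, x[[nm]]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.folding_model <- function(x, ...) {
  cat(sprintf("Coarse-grained folding model: %d residues, %d native contacts (%s potential)\n",
              nrow(x$coords), nrow(x$contact_map), x$mode))
  tab <- table(x$contact_map$class)
  cat("  contact classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  mean native strength %.3f kT; lambda = %.4g\n",
              mean(x$contact_map$strength), x$params$lambda))
  invisible(x)
}

#' @export
summary.folding_model <- function(object, ...) {
  e <- total_energy(object)
  print(object)
  print(e)
  invisible(object)
}
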