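# Force-field parameter assembly.  All energies are in thermal units
# (kT = 1 at the nominal Monte Carlo temperature); `kT_kcal` fixes the
# conversion used when importing hydrogen-bond energies in kcal/mol.

#' Coarse-grained force-field parameters
#'
#' Assembles the parameter set of the C-alpha model: harmonic pseudo-bond
#' constants, the double-well pseudo-angle potential with helical and
#' extended minima, a four-term cosine pseudo-torsion series keyed by the
#' middle residue pair, the quasi-chemical non-native matrix with its scale
#' `lambda` and offset `e0`, per-residue van der Waals diameters and charges,
#' and Debye-Hueckel screened electrostatics.
#'
#' @param qc_matrix symmetric 20x20 quasi-chemical contact matrix (see
#'   [read_qc_matrix()]); entries more negative than `e0` give attractive
#'   non-native pairs, less negative entries repulsive ones.
#' @param lambda dimensionless scale of the non-native interaction strength
#'   `eps_ab = lambda * (e_ab - e0)`; rescaled by [calibrate_nonnative_scale()].
#' @param e0 offset on the quasi-chemical entries (units of the matrix).
#' @param charges,diameters named per-residue vectors (elementary charges,
#'   Angstrom); defaults are the shipped tables.
#' @param debye_length Debye screening length in Angstrom.
#' @param dielectric relative dielectric constant.
#' @param temperature global multiplier on kT (1 = nominal temperature).
#' @param kT_kcal one thermal unit in kcal/mol (0.593 at 298 K).
#' @param k_bond bond spring constant, kT per square Angstrom.
#' @param b0 equilibrium pseudo-bond length, Angstrom.
#' @param theta_helical,theta_extended pseudo-angle minima, radians.
#' @param hb_threshold hydrogen-bond energy threshold (kcal/mol) below which
#'   a backbone pair counts as a native hydrogen-bonded contact.
#' @param weak_hb_factor strength of the weak hydrogen-bond network contacts
#'   relative to their parent pair.
#' @param sidechain_cutoff heavy-atom distance (Angstrom) defining side-chain
#'   native contacts.
#' @param nonnative_ratio target ratio of mean non-native to mean native
#'   strength enforced by [calibrate_nonnative_scale()].
#' @param ev_eps excluded-volume strength (kT) used between non-native pairs
#'   under the purely native-centric potential.
#' @param ev_sigma excluded-volume core diameter (Angstrom) of that
#'   repulsion (the standard 4 A C-alpha hard core).
#' @return an object of class `forcefield_params` (a list).
#' @export
forcefield_params <- function(qc_matrix = read_qc_matrix(),
                              lambda = 0.159,
                              e0 = -2.27,
                              charges = read_residue_table(kf_extdata("residue_charges.tsv"), "charges"),
                              diameters = read_residue_table(kf_extdata("residue_diameters.tsv"), "diameters"),
                              debye_length = 10,
                              dielectric = 80,
                              temperature = 1,
                              kT_kcal = 0.593,
                              k_bond = 20,
                              b0 = 3.8,
                              theta_helical = 1.60,
                              theta_extended = 2.27,
                              hb_threshold = -0.5,
                              weak_hb_factor = 0.25,
                              sidechain_cutoff = 4.5,
                              nonnative_ratio = 0.1,
                              ev_eps = 1.0,
                              ev_sigma = 4.0) {
  stopifnot(debye_length > 0, temperature > 0, all(diameters > 0), kT_kcal > 0)
  tor <- default_torsion_table()
  p <- list(
    qc_matrix = qc_matrix, lambda = lambda, e0 = e0,
    charges = charges, diameters = diameters,
    debye_length = debye_length, dielectric = dielectric,
    temperature = temperature, kT_kcal = kT_kcal,
    bonded = list(
      k_bond = k_bond, b0 = b0,
      # double-well angle term: soft minimum of two quadratic basins
      ang_gamma = 0.1 * kT_kcal,
      ang_k_alpha = 106.4 / kT_kcal, ang_theta_alpha = theta_helical,
      ang_eps_alpha = 4.3 / kT_kcal,
      ang_k_beta = 26.3 / kT_kcal, ang_theta_beta = theta_extended,
      torsion_amp = tor$amp, torsion_phase = tor$phase),
    hb_threshold = hb_threshold,
    weak_hb_factor = weak_hb_factor,
    sidechain_cutoff = sidechain_cutoff,
    nonnative_ratio = nonnative_ratio,
    ev_eps = ev_eps,
    ev_sigma = ev_sigma,
    nn_cut_factor = 3,
    # Coulomb prefactor in kT * Angstrom per unit charge product
    dh_prefactor = 332.06 / (dielectric * kT_kcal))
  class(p) <- "forcefield_params"
  p
}

# Pseudo-torsion coefficients keyed by the middle residue pair.  The cited
# per-pair statistical tables are not redistributable, so the package ships
# a residue-class parameterization: helix formers bias the pseudo-dihedral
# towards ~+50 degrees, sheet formers towards the extended ~180 degrees,
# glycine is left nearly free and proline stiffened.  Amplitudes in kT.
default_torsion_table <- function() {
  helix <- c("A", "L", "M", "E", "Q", "K", "R", "H")
  sheet <- c("V", "I", "F", "Y", "W", "T", "C")
  cls <- ifelse(AA1 %in% helix, "h", ifelse(AA1 %in% sheet, "s",
               ifelse(AA1 == "G", "g", ifelse(AA1 == "P", "p", "m"))))
  prof <- list(  # amplitudes V1..V4 (kT) and preferred dihedral phi0 (rad)
    h = list(v = c(0.60, 0.30, 0.50, 0.10), phi0 = 0.87),
    s = list(v = c(0.60, 0.30, 0.50, 0.10), phi0 = 2.90),
    m = list(v = c(0.30, 0.15, 0.25, 0.05), phi0 = 1.90),
    g = list(v = c(0.10, 0.05, 0.10, 0.02), phi0 = 1.90),
    p = list(v = c(0.80, 0.20, 0.30, 0.10), phi0 = 1.00))
  pair_class <- function(c1, c2) {
    if (c1 == "p" || c2 == "p") return("p")
    if (c1 == "g" || c2 == "g") return("g")
    if (c1 == "h" && c2 == "h") return("h")
    if (c1 == "s" && c2 == "s") return("s")
    "m"
  }
  amp <- matrix(0, 400, 4)
  pha <- matrix(0, 400, 4)
  for (a in 1:20) for (b in 1:20) {
    pr <- prof[[pair_class(cls[a], cls[b])]]
    row <- (a - 1) * 20 + b
    amp[row, ] <- pr$v
    # each harmonic gets a minimum at phi0: delta_n = n * phi0 + pi
    pha[row, ] <- (1:4) * pr$phi0 + pi
  }
  list(amp = amp, phase = pha)
}

#' Calibrate the non-native interaction scale
#'
#' Rescales `lambda` so that the mean absolute non-native strength
#' `|eps_ij| = |lambda * (e_ab - e0)|`, averaged over all non-native pairs
#' `(i, j)` with `|i - j| >= 3` of the given sequence, equals
#' `nonnative_ratio` (default one tenth) times the mean native contact
#' strength -- exactly, since the dependence on `lambda` is linear.
#'
#' @param params a [forcefield_params()] object.
#' @param contact_map a native contact map (see [build_native_contact_map()]).
#' @param sequence residue one-letter codes of the chain.
#' @return `params` with `lambda` updated.
#' @export
calibrate_nonnative_scale <- function(params, contact_map, sequence) {
  stopifnot(inherits(params, "forcefield_params"))
  if (nrow(contact_map) == 0) stop("empty contact map: degenerate model")
  seq1 <- if (all(nchar(sequence) == 3)) aa_3to1(sequence) else toupper(sequence)
  n <- length(seq1)
  idx <- aa_index(seq1) + 1L
  emat <- params$qc_matrix - params$e0
  pr <- which(outer(seq_len(n), seq_len(n), function(i, j) j - i >= 3), arr.ind = TRUE)
  nat <- paste(contact_map$i, contact_map$j)
  keep <- !(paste(pr[, 1], pr[, 2]) %in% nat)
  pr <- pr[keep, , drop = FALSE]
  strengths <- abs(emat[cbind(idx[pr[, 1]], idx[pr[, 2]])])
  if (all(strengths == 0)) stop("all non-native strengths are zero; cannot calibrate")
  target <- params$nonnative_ratio * mean(contact_map$strength)
  params$lambda <- target / mean(strengths)
  params
}

#' Effective non-native strength matrix
#'
#' `eps_ab = lambda * (e_ab - e0)` in thermal units; negative entries are
#' attractive pairs, positive entries repulsive ones.
#'
#' @param params a [forcefield_params()].
#' @return symmetric 20x20 numeric matrix.
#' @export
nonnative_eps_matrix <- function(params) {
  params$lambda * (params$qc_matrix - params$e0)
}

#' @export
print.forcefield_params <- function(x, ...) {
  cat("Coarse-grained force-field parameters (thermal units)\n")
  cat(sprintf("  bonds: k = %.3g kT/A^2, b0 = %.3g A\n", x$bonded$k_bond, x$bonded$b0))
  cat(sprintf("  angle wells at %.2f rad (helical) and %.2f rad (extended)\n",
              x$bonded$ang_theta_alpha, x$bonded$ang_theta_beta))
  cat(sprintf("  non-native: lambda = %.4g, e0 = %.3g (target ratio %.3g)\n",
              x$lambda, x$e0, x$nonnative_ratio))
  cat(sprintf("  electrostatics: Debye length %.3g A, dielectric %.3g\n",
              x$debye_length, x$dielectric))
  invisible(x)
}
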