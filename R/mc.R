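# Kink-jump Metropolis Monte Carlo: move geometry, configuration, the
# trajectory runner and the a-posteriori chain-crossing auditor.

#' Monte Carlo run configuration
#'
#' Phase 1 (relaxation from the stretched coil) attempts crankshaft,
#' cartesian and global pivot moves with probabilities 0.8 / 0.1 / 0.1;
#' when the pivot acceptance over a sliding window drops below the switch
#' threshold the run enters phase 2, where the pivot slot is taken by local
#' end-segment rotations.  One unit of MC time is 100 attempted moves per
#' residue.
#'
#' @param total_units trajectory length in MC time units.
#' @param snapshot_interval MC time between stored snapshots.
#' @param log_interval MC time between observable log rows.
#' @param crankshaft_amplitude rotation amplitude, degrees (+/-).
#' @param pivot_amplitude pivot amplitude, degrees (+/-).
#' @param endpoint_amplitude end-segment amplitude, degrees (+/-).
#' @param cartesian_radius radius of the single-bead displacement sphere, A.
#' @param end_segment_length residues rotated by an end-segment move.
#' @param p_phase1,p_phase2 move probabilities (crankshaft, cartesian,
#'   pivot) and (crankshaft, cartesian, endpoint); each must sum to 1.
#' @param pivot_acc_threshold pivot acceptance rate below which phase 2
#'   starts.
#' @param pivot_window sliding window (pivot attempts) for that rate.
#' @param max_relax_units force the phase switch at this MC time even if the
#'   pivot acceptance never drops below the threshold (default `Inf`); used
#'   for small systems whose open coils keep accepting pivots.
#' @param audit_fraction fraction of accepted local moves checked by the
#'   chain-crossing auditor.
#' @param q_cutoff C-alpha distance (A) under which a native pair counts as
#'   formed when logging the fraction of native contacts.
#' @param seed RNG seed of the trajectory.
#' @return an `mc_config` list.
#' @export
mc_config <- function(total_units = 3000,
                      snapshot_interval = 10,
                      log_interval = 1,
                      crankshaft_amplitude = 15,
                      pivot_amplitude = 180,
                      endpoint_amplitude = 30,
                      cartesian_radius = 0.15,
                      end_segment_length = 10,
                      p_phase1 = c(0.8, 0.1, 0.1),
                      p_phase2 = c(0.8, 0.1, 0.1),
                      pivot_acc_threshold = 0.01,
                      pivot_window = 1000,
                      max_relax_units = Inf,
                      audit_fraction = 0.01,
                      q_cutoff = 7.5,
                      seed = 1) {
  stopifnot(length(p_phase1) == 3, length(p_phase2) == 3,
            all(p_phase1 >= 0), all(p_phase2 >= 0),
            abs(sum(p_phase1) - 1) < 1e-12, abs(sum(p_phase2) - 1) < 1e-12,
            total_units > 0, snapshot_interval > 0, cartesian_radius > 0)
  structure(list(total_units = total_units,
                 snapshot_interval = snapshot_interval,
                 log_interval = log_interval,
                 amp_crank = crankshaft_amplitude * pi / 180,
                 amp_pivot = pivot_amplitude * pi / 180,
                 amp_end = endpoint_amplitude * pi / 180,
                 cart_radius = cartesian_radius,
                 end_seg_len = as.integer(end_segment_length),
                 p_phase1 = as.numeric(p_phase1),
                 p_phase2 = as.numeric(p_phase2),
                 pivot_acc_threshold = pivot_acc_threshold,
                 pivot_window = as.integer(pivot_window),
                 max_relax_units = max_relax_units,
                 audit_frac = audit_fraction,
                 q_cutoff = q_cutoff,
                 seed = as.numeric(seed)),
            class = "mc_config")
}

# ---- deterministic single-move geometry (exposed for inspection/tests) ----

#' Crankshaft rotation of one interior bead
#'
#' Rotates bead `bead` by `angle` about the axis through its two sequence
#' neighbours; both adjacent pseudo-bond lengths are preserved exactly.
#'
#' @param coords N x 3 matrix.
#' @param bead interior bead index (2..N-1).
#' @param angle rotation angle, radians.
#' @return the full coordinate matrix with bead `bead` moved.
#' @export
crankshaft_move <- function(coords, bead, angle) {
  coords <- as.matrix(unclass(coords))
  stopifnot(bead > 1, bead < nrow(coords))
  .crankshaft_once_cpp(coords, bead, angle)
}

#' Cartesian displacement of one bead
#'
#' @param coords N x 3 matrix.
#' @param bead bead index.
#' @param displacement 3-vector, norm at most the configured sphere radius.
#' @return updated coordinate matrix.
#' @export
cartesian_move <- function(coords, bead, displacement) {
  coords <- as.matrix(unclass(coords))
  coords[bead, ] <- coords[bead, ] + displacement
  coords
}

#' Rigid rotation of a chain arm about a pivot residue
#'
#' @param coords N x 3 matrix.
#' @param pivot pivot residue (stays fixed).
#' @param side `"suffix"` rotates beads pivot+1..N, `"prefix"` 1..pivot-1.
#' @param axis rotation axis 3-vector (through the pivot bead).
#' @param angle radians.
#' @return updated coordinate matrix.
#' @export
pivot_move <- function(coords, pivot, side = c("suffix", "prefix"), axis, angle) {
  side <- match.arg(side)
  coords <- as.matrix(unclass(coords))
  n <- nrow(coords)
  rng <- if (side == "suffix") c(pivot + 1, n) else c(1, pivot - 1)
  if (rng[1] > rng[2]) return(coords)
  .segment_rotate_cpp(coords, rng[1], rng[2], pivot, axis, angle)
}

#' Rigid rotation of a terminal segment
#'
#' Rotates the terminal `seg_len` residues about an axis through the most
#' interior bead of the segment (which therefore stays put).
#'
#' @param coords N x 3 matrix (N > seg_len).
#' @param terminus `"C"` or `"N"`.
#' @param axis rotation axis 3-vector.
#' @param angle radians.
#' @param seg_len segment length (default 10).
#' @return updated coordinate matrix.
#' @export
endpoint_move <- function(coords, terminus = c("C", "N"), axis, angle, seg_len = 10) {
  terminus <- match.arg(terminus)
  coords <- as.matrix(unclass(coords))
  n <- nrow(coords)
  stopifnot(n > seg_len)
  if (terminus == "C")
    .segment_rotate_cpp(coords, n - seg_len + 2, n, n - seg_len + 1, axis, angle)
  else
    .segment_rotate_cpp(coords, 1, seg_len - 1, seg_len, axis, angle)
}

#' Empirical Metropolis acceptance rate at fixed energy difference
#'
#' @param delta_e proposal energy difference (kT).
#' @param n number of trials.
#' @param seed RNG seed.
#' @param temperature kT multiplier.
#' @return acceptance frequency.
#' @export
metropolis_acceptance <- function(delta_e, n = 1e5, seed = 1, temperature = 1) {
  .metropolis_trials_cpp(delta_e, as.integer(n), as.integer(seed), temperature)
}

#' A-posteriori chain-crossing detection for local moves
#'
#' Flags a move when the triangle swept between the old and new position of
#' any moved bead and its fixed neighbour is pierced by a non-adjacent chain
#' segment -- the audit that certifies local-move trajectories preserve
#' topology.
#'
#' @param before,after N x 3 coordinate matrices.
#' @param moved indices of beads that moved.
#' @param closed treat the chain as a ring.
#' @return logical: TRUE when a crossing is detected.
#' @export
detect_chain_crossing <- function(before, after, moved, closed = FALSE) {
  .detect_crossing_cpp(as.matrix(unclass(before)), as.matrix(unclass(after)),
                       as.integer(moved), closed)
}

#' Evolve a closed ring by crossing-audited local moves
#'
#' Random single-vertex displacements with bond-length bounds; every move is
#' audited and rejected if it would sweep through another segment, so the
#' ring's knot type is provably conserved.
#'
#' @param coords ring vertices.
#' @param n_moves attempted moves.
#' @param max_disp displacement sphere radius (A).
#' @param bond_range allowed bond-length interval (A).
#' @param seed RNG seed.
#' @return list with final `coords` and acceptance/rejection counters.
#' @export
evolve_ring <- function(coords, n_moves, max_disp = 0.4,
                        bond_range = c(2.0, 5.6), seed = 1) {
  .evolve_ring_cpp(as.matrix(unclass(coords)), as.integer(n_moves), max_disp,
                   bond_range[1], bond_range[2], as.integer(seed))
}

#' Sample the pseudo-angle distribution of a three-bead chain
#'
#' Metropolis sampling (single-bead cartesian moves) of a 3-bead chain under
#' the bond and pseudo-angle terms only; the marginal density of the angle
#' is proportional to `sin(theta) * exp(-V(theta)/kT)`, which makes this the
#' canonical check of Boltzmann correctness against numerical quadrature.
#'
#' @param params force-field parameters (angle double well, bonds).
#' @param n_samples number of recorded angles.
#' @param thin attempted moves between records; the angle decorrelates over
#'   roughly a hundred moves, so meaningful chi-square tests need thinning
#'   of that order.
#' @param seed RNG seed.
#' @param step radius of the cartesian proposal sphere (Angstrom).
#' @param sequence three residue one-letter codes.
#' @return numeric vector of sampled pseudo-angles (radians).
#' @export
sample_angle_distribution <- function(params = forcefield_params(),
                                      n_samples = 1e5, thin = 150, seed = 1,
                                      step = 0.6,
                                      sequence = c("A", "A", "A")) {
  ml <- list(sequence_int = aa_index(sequence),
             contact_pairs = matrix(integer(0), 0, 2),
             contact_r0 = numeric(0), contact_eps = numeric(0),
             nonnative_eps = matrix(0, 20, 20),
             sigma = unname(params$diameters),
             charge = rep(0, 3),
             bonded = params$bonded,
             dh_prefactor = 0, debye_length = params$debye_length,
             ev_eps = 0, nn_cut_factor = 3,
             temperature = params$temperature, native_only = TRUE)
  .sample_angle_chain_cpp(ml, as.integer(n_samples), as.integer(thin),
                          step, as.integer(seed))
}

#' Stretched-coil initial configuration
#'
#' Extended pseudo-angle conformation with pseudo-torsions randomized within
#' +/- 30 degrees of trans; the standard common starting state of all
#' trajectories.
#'
#' @param n number of beads.
#' @param params force-field parameters (extended angle, bond length).
#' @param seed RNG seed for the torsion jitter.
#' @return N x 3 coordinate matrix.
#' @export
stretched_coil <- function(n, params = forcefield_params(), seed = 1) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  ang <- rep(params$bonded$ang_theta_beta, n - 2)
  dih <- pi + stats::runif(n - 3, -pi / 6, pi / 6)
  ca_chain_from_internal(ang, dih, params$bonded$b0)
}

# ---- trajectory runner ----------------------------------------------------

#' Run one Monte Carlo folding trajectory
#'
#' Metropolis kink-jump dynamics under the model's potential, starting from
#' a common stretched-coil state (or `start`), with the two-phase move
#' protocol, periodic snapshots and an observable log.  Identical seeds give
#' bit-identical trajectories.  If the a-posteriori crossing audit flagged
#' any accepted local move the function aborts with a diagnostic.
#'
#' @param model a [folding_model()].
#' @param config an [mc_config()].
#' @param start optional N x 3 starting coordinates.
#' @return an `mc_trajectory`: list with `log` (data frame), `snapshots`
#'   (list of N x 3 matrices), `snapshot_times`, `final`, acceptance
#'   counters, `phase_switch_time`, `energy_drift` and the seed/config.
#' @export
run_trajectory <- function(model, config = mc_config(), start = NULL) {
  stopifnot(inherits(model, "folding_model"), inherits(config, "mc_config"))
  if (is.null(start)) start <- stretched_coil(nrow(model$coords), model$params,
                                              seed = config$seed)
  start <- as.matrix(unclass(start))
  stopifnot(nrow(start) == nrow(model$coords))
  res <- .run_mc_cpp(start, model_cpp_list(model), unclass(config))
  if (res$crossings_flagged > 0)
    stop(sprintf(paste0("trajectory aborted: chain-crossing audit flagged %d of %d",
                        " audited local moves (seed %s)"),
                 as.integer(res$crossings_flagged), as.integer(res$moves_audited),
                 format(config$seed)))
  out <- list(log = as.data.frame(res$log),
              snapshots = res$snapshots,
              snapshot_times = res$snapshot_times,
              final = res$final,
              attempts = res$attempts,
              accepts = res$accepts,
              phase_switch_time = res$phase_switch_time,
              energy_drift = res$energy_drift,
              moves_audited = res$moves_audited,
              final_energy = res$final_energy,
              seed = config$seed,
              mode = model$mode,
              config = config)
  class(out) <- "mc_trajectory"
  out
}

#' @export
print.mc_trajectory <- function(x, ...) {
  n <- nrow(x$log)
  cat(sprintf("MC trajectory: %.0f units (%s potential, seed %s)\n",
              x$log$time[n], x$mode, format(x$seed)))
  acc <- x$accepts / pmax(x$attempts, 1)
  cat("  acceptance:", paste(sprintf("%s %.2f", names(acc), acc), collapse = ", "), "\n")
  cat(sprintf("  phase switch at %s units; energy drift %.2e kT\n",
              ifelse(is.na(x$phase_switch_time), "n/a",
                     sprintf("%.1f", x$phase_switch_time)), x$energy_drift))
  cat(sprintf("  final: Q = %.3f, Rg = %.1f A, E = %.1f kT\n",
              x$log$Q[n], x$log$Rg[n], x$log$total[n]))
  invisible(x)
}

#' @export
plot.mc_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$log$time, x$log$Rg, type = "l", xlab = "MC time (units)",
                 ylab = "Rg (A)", ...)
  if (!is.na(x$phase_switch_time))
    graphics::abline(v = x$phase_switch_time, lty = 2, col = "grey")
  graphics::plot(x$log$time, x$log$Q, type = "l", xlab = "MC time (units)",
                 ylab = "Q", ylim = c(0, 1), ...)
  invisible(x)
}
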