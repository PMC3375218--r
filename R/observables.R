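# Per-frame and ensemble observables: gyration radius, fraction of native
# contacts (overall and split by secondary-structure class), segment
# interaction energies, and windowed knotting probabilities.

#' Gyration radius
#'
#' Root-mean-square distance of the beads from their centroid.
#'
#' @param chain N x 3 coordinate matrix.
#' @return radius of gyration in Angstrom.
#' @export
gyration_radius <- function(chain) {
  .gyration_radius_cpp(as.matrix(unclass(chain)))
}

#' Fraction of formed native contacts
#'
#' A native pair counts as formed when its current C-alpha distance is
#' strictly below `cutoff` (default 7.5 Angstrom).
#'
#' @param chain N x 3 coordinates.
#' @param contact_map native contact map (columns `i`, `j`).
#' @param cutoff contact-formation distance, Angstrom.
#' @return fraction in [0, 1].
#' @export
fraction_native_contacts <- function(chain, contact_map, cutoff = 7.5) {
  x <- as.matrix(unclass(chain))
  if (nrow(contact_map) == 0) stop("empty contact map")
  d <- x[contact_map$i, , drop = FALSE] - x[contact_map$j, , drop = FALSE]
  mean(sqrt(rowSums(d^2)) < cutoff)
}

#' Class-restricted fractions of native contacts
#'
#' Q restricted to native contacts whose both residues are helical
#' (respectively strand) in the native secondary-structure assignment.
#' A class with no native contacts is reported as `NA` (absent), not 0/0.
#'
#' @param chain N x 3 coordinates.
#' @param contact_map native contact map.
#' @param ss per-residue factor with levels helix/strand/coil.
#' @param cutoff contact-formation distance, Angstrom.
#' @return named numeric `c(helix = ..., sheet = ...)`.
#' @export
ss_contact_fractions <- function(chain, contact_map, ss, cutoff = 7.5) {
  x <- as.matrix(unclass(chain))
  ss <- as.character(ss)
  one <- function(lab) {
    sel <- ss[contact_map$i] == lab & ss[contact_map$j] == lab
    if (!any(sel)) return(NA_real_)
    cm <- contact_map[sel, , drop = FALSE]
    d <- x[cm$i, , drop = FALSE] - x[cm$j, , drop = FALSE]
    mean(sqrt(rowSums(d^2)) < cutoff)
  }
  c(helix = one("helix"), sheet = one("strand"))
}

#' Interaction energy between a segment and the rest of the chain
#'
#' Sum of the selected pair energies between residues of the segment and
#' all residues outside it, with the usual `|i - j| >= 3` exclusion; in
#' `"nonnative"` mode native pairs are skipped (the quasi-chemical term does
#' not act on them).
#'
#' @param model a [folding_model()].
#' @param chain coordinates to evaluate.
#' @param segment integer range of residues (e.g. `45:60`).
#' @param mode `"nonnative"` or `"electrostatic"`.
#' @return energy in kT (0 when the segment is the whole chain).
#' @export
segment_interaction_energy <- function(model, chain, segment,
                                       mode = c("nonnative", "electrostatic")) {
  mode <- match.arg(mode)
  segment <- range(as.integer(segment))
  stopifnot(segment[1] >= 1, segment[2] <= nrow(model$coords))
  .segment_energy_cpp(as.matrix(unclass(chain)), model_cpp_list(model),
                      segment[1], segment[2], mode)
}

#' Classify the topology of every snapshot of a trajectory
#'
#' @param traj an `mc_trajectory`.
#' @param n_closures stochastic closures per positive detection.
#' @param seed base seed for the closure directions.
#' @param localize also localize cores / chirality (slower).
#' @return data frame with one row per snapshot: `time`, `label`,
#'   `consensus`, `proper`, `core_first`, `core_last`, `chirality`.
#' @export
analyze_trajectory_knots <- function(traj, n_closures = 100, seed = 1,
                                     localize = TRUE) {
  rows <- lapply(seq_along(traj$snapshots), function(k) {
    a <- classify_topology(traj$snapshots[[k]], n_closures = n_closures,
                           seed = seed + 97L * k, localize = localize)
    data.frame(time = traj$snapshot_times[k], label = a$label,
               consensus = a$consensus, proper = a$proper,
               core_first = if (is.null(a$core)) NA_integer_ else a$core[1],
               core_last = if (is.null(a$core)) NA_integer_ else a$core[2],
               chirality = a$chirality, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Windowed knotting probability over an ensemble of trajectories
#'
#' Pools the per-snapshot topology assessments of all trajectories and
#' reports, per MC-time window, the fraction of snapshots whose label is not
#' the unknot (proper and improper knots both count).
#'
#' @param assessments list of data frames from [analyze_trajectory_knots()]
#'   (one per trajectory), or a single data frame.
#' @param window window width in MC time units (default 100).
#' @return an `observable_series` with columns `time` (window midpoint),
#'   `mean`, `sem`, `n` (snapshots pooled; empty windows are dropped).
#' @export
knotting_probability_series <- function(assessments, window = 100) {
  if (is.data.frame(assessments)) assessments <- list(assessments)
  all <- do.call(rbind, assessments)
  if (nrow(all) == 0) stop("no assessments supplied")
  knotted <- all$label != "unknot"
  win <- floor(all$time / window)
  agg <- stats::aggregate(knotted, by = list(win = win), FUN = function(v)
    c(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)), n = length(v)))
  out <- data.frame(time = (agg$win + 0.5) * window,
                    mean = agg$x[, "mean"], sem = agg$x[, "sem"],
                    n = agg$x[, "n"])
  class(out) <- c("observable_series", class(out))
  attr(out, "observable") <- "knotting probability"
  out
}

#' Ensemble mean and standard error of a logged observable
#'
#' Aligns the observable logs of several trajectories on their common MC
#' time grid and returns per-time ensemble means with standard errors over
#' trajectories.
#'
#' @param trajs list of `mc_trajectory` objects (same config).
#' @param what log column to aggregate (e.g. `"Rg"`, `"Q"`, `"total"`).
#' @return an `observable_series` data frame (`time`, `mean`, `sem`, `n`).
#' @export
ensemble_series <- function(trajs, what = "Rg") {
  stopifnot(length(trajs) >= 1)
  times <- trajs[[1]]$log$time
  vals <- vapply(trajs, function(tr) {
    if (!identical(tr$log$time, times)) stop("trajectories on different time grids")
    tr$log[[what]]
  }, numeric(length(times)))
  vals <- matrix(vals, nrow = length(times))
  n <- ncol(vals)
  out <- data.frame(time = times,
                    mean = rowMeans(vals),
                    sem = if (n > 1) apply(vals, 1, stats::sd) / sqrt(n) else NA_real_,
                    n = n)
  class(out) <- c("observable_series", class(out))
  attr(out, "observable") <- what
  out
}

#' @export
print.observable_series <- function(x, ...) {
  cat(sprintf("observable_series (%s): %d time points, n = %d trajectories/frames\n",
              attr(x, "observable") %||% "?", nrow(x), max(x$n)))
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("  ...\n")
  invisible(x)
}

#' @export
plot.observable_series <- function(x, add = FALSE, col = "black", ...) {
  if (!add)
    graphics::plot(x$time, x$mean, type = "l", col = col,
                   xlab = "MC time (units)",
                   ylab = attr(x, "observable") %||% "value", ...)
  else graphics::lines(x$time, x$mean, col = col, ...)
  ok <- is.finite(x$sem)
  if (any(ok))
    graphics::arrows(x$time[ok], x$mean[ok] - x$sem[ok], x$time[ok],
                     x$mean[ok] + x$sem[ok], length = 0.02, angle = 90,
                     code = 3, col = col)
  invisible(x)
}
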