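# Multi-trajectory campaigns: independent seeded trajectories for each
# condition (structure x potential x optional mutant) and the comparative
# knotting-propensity report.

#' Build a folding model from a toy native
#'
#' @param toy a [make_toy_native()] object (possibly mutated).
#' @param mode `"full"` or `"native_only"`.
#' @param params force-field parameters.
#' @return a [folding_model()].
#' @export
toy_model <- function(toy, mode = c("full", "native_only"),
                      params = forcefield_params()) {
  stopifnot(inherits(toy, "toy_native"))
  # toys use native-derived bonded references: their geometry is designed,
  # not statistical, so the native-centric bonded terms are the consistent
  # choice (see the methods vignette)
  folding_model(toy$coords, toy$sequence, toy$contact_map, params,
                mode = match.arg(mode), bonded_reference = "native")
}

#' Standard configuration of the toy folding campaigns
#'
#' The fixed desk-scale study conditions for the comparative toy
#' experiments: 500 MC time units, snapshots every 10 units, relaxation
#' (pivot) phase capped at 100 units, and a +/- 30 degree crankshaft
#' amplitude (still within the non-crossing displacement bound, and audited).
#'
#' @param total_units trajectory length (default 500).
#' @param seed RNG seed.
#' @param ... further overrides passed to [mc_config()].
#' @return an [mc_config()].
#' @export
toy_campaign_config <- function(total_units = 500, seed = 1, ...) {
  mc_config(total_units = total_units, snapshot_interval = 10,
            max_relax_units = 100, crankshaft_amplitude = 30,
            seed = seed, ...)
}

#' Run a campaign of independent trajectories
#'
#' Runs `n_trajectories` Monte Carlo trajectories of the same model and
#' configuration, trajectory `k` using seed `base_seed + k`.  Trajectories
#' are independent, so results do not depend on execution order.  Aborted
#' trajectories (e.g. a chain-crossing audit failure) are recorded in the
#' manifest and the campaign continues.  With `output_dir` set, per-
#' trajectory logs, snapshot streams and a manifest are written (never
#' overwriting an existing directory unless `overwrite = TRUE`).
#'
#' @param model a [folding_model()].
#' @param config an [mc_config()] template (its seed is replaced per
#'   trajectory).
#' @param n_trajectories number of trajectories (>= 1).
#' @param base_seed seed base.
#' @param label condition label recorded in the manifest.
#' @param output_dir optional directory for TSV/XYZ outputs.
#' @param overwrite allow writing into an existing directory.
#' @return an `mc_campaign`: list with `trajectories` (completed ones),
#'   `manifest` (data frame), `label`, `model`, `config`.
#' @export
run_campaign <- function(model, config = mc_config(), n_trajectories = 10,
                         base_seed = 1, label = model$mode,
                         output_dir = NULL, overwrite = FALSE) {
  stopifnot(n_trajectories >= 1)
  if (!is.null(output_dir)) {
    if (dir.exists(output_dir) && !overwrite)
      stop("output_dir exists; use overwrite = TRUE to replace its contents")
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  }
  trajs <- vector("list", n_trajectories)
  manifest <- data.frame(trajectory = seq_len(n_trajectories),
                         seed = base_seed + seq_len(n_trajectories),
                         status = NA_character_, error = NA_character_,
                         stringsAsFactors = FALSE)
  for (k in seq_len(n_trajectories)) {
    cfg <- config
    cfg$seed <- base_seed + k
    res <- tryCatch(run_trajectory(model, cfg), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$status[k] <- "aborted"
      manifest$error[k] <- conditionMessage(res)
    } else {
      manifest$status[k] <- "completed"
      trajs[[k]] <- res
      if (!is.null(output_dir)) {
        write_trajectory_log(res, file.path(output_dir, sprintf("traj_%03d.tsv", k)))
        write_xyz(res, file.path(output_dir, sprintf("traj_%03d.xyz", k)))
      }
    }
  }
  out <- list(trajectories = Filter(Negate(is.null), trajs),
              manifest = manifest, label = label, model = model,
              config = config, base_seed = base_seed)
  class(out) <- "mc_campaign"
  if (!is.null(output_dir)) {
    utils::write.table(manifest, file.path(output_dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(c(sprintf("label: %s", label),
                 sprintf("base_seed: %s", format(base_seed)),
                 sprintf("n_trajectories: %d", n_trajectories),
                 sprintf("mode: %s", model$mode),
                 sprintf("total_units: %g", config$total_units)),
               file.path(output_dir, "campaign.txt"))
  }
  out
}

#' @export
print.mc_campaign <- function(x, ...) {
  cat(sprintf("MC campaign '%s': %d/%d trajectories completed (%s potential, %g units)\n",
              x$label, length(x$trajectories), nrow(x$manifest),
              x$model$mode, x$config$total_units))
  invisible(x)
}

#' Aggregate ensemble observables of a campaign
#'
#' @param campaign an `mc_campaign` (or list of `mc_trajectory`).
#' @param what log columns to aggregate.
#' @return named list of [ensemble_series()] data frames.
#' @export
aggregate_observables <- function(campaign, what = c("Rg", "Q", "total")) {
  trajs <- if (inherits(campaign, "mc_campaign")) campaign$trajectories else campaign
  if (length(trajs) == 0) stop("no completed trajectories")
  stats::setNames(lapply(what, function(w) ensemble_series(trajs, w)), what)
}

#' Per-snapshot topology assessments for all campaign trajectories
#'
#' @param campaign an `mc_campaign`.
#' @param n_closures stochastic closures per positive detection.
#' @param seed base seed for closure directions.
#' @param localize localize cores and chirality.
#' @return list of per-trajectory assessment data frames.
#' @export
analyze_campaign_knots <- function(campaign, n_closures = 100, seed = 1,
                                   localize = TRUE) {
  lapply(seq_along(campaign$trajectories), function(k)
    analyze_trajectory_knots(campaign$trajectories[[k]], n_closures = n_closures,
                             seed = seed + 1013L * k, localize = localize))
}

#' Comparative knotting-propensity report
#'
#' Side-by-side windowed knotting probabilities and ensemble Rg / Q for a
#' set of campaigns (e.g. knotted vs unknotted native, native-only vs full
#' potential), plus the qualitative contrasts: which campaigns show
#' negligible knotting (windowed probability below `negligible`), and
#' whether all detected knots share one type and chirality.
#'
#' @param campaigns named list of `mc_campaign` objects.
#' @param window knotting-probability window (MC units).
#' @param n_closures closures per positive detection.
#' @param seed base seed for the topology analysis.
#' @param negligible threshold defining negligible knotting (default 0.01).
#' @return a `potential_comparison`: per-campaign summaries and series.
#' @export
compare_potentials_report <- function(campaigns, window = 100, n_closures = 100,
                                      seed = 1, negligible = 0.01) {
  stopifnot(length(campaigns) >= 2)
  if (is.null(names(campaigns)) || any(names(campaigns) == ""))
    names(campaigns) <- paste0("campaign", seq_along(campaigns))
  per <- lapply(names(campaigns), function(nm) {
    cmp <- campaigns[[nm]]
    ass <- analyze_campaign_knots(cmp, n_closures = n_closures, seed = seed)
    kp <- knotting_probability_series(ass, window = window)
    pooled <- do.call(rbind, ass)
    knots <- pooled[pooled$label != "unknot", , drop = FALSE]
    obs <- aggregate_observables(cmp, c("Rg", "Q"))
    list(name = nm, mode = cmp$model$mode,
         knotting = kp,
         overall_knot_fraction = mean(pooled$label != "unknot"),
         max_window_probability = max(kp$mean),
         negligible = max(kp$mean) < negligible,
         knot_labels = table(knots$label),
         chiralities = table(knots$chirality),
         rg = obs$Rg, q = obs$Q,
         assessments = ass)
  })
  names(per) <- names(campaigns)
  structure(list(campaigns = per, window = window, negligible = negligible),
            class = "potential_comparison")
}

#' @export
print.potential_comparison <- function(x, ...) {
  cat("Comparative knotting-propensity report\n")
  cat(sprintf("  (windows of %g MC units; 'negligible' means max windowed probability < %g)\n\n",
              x$window, x$negligible))
  for (p in x$campaigns) {
    cat(sprintf("%-24s [%s]\n", p$name, p$mode))
    cat(sprintf("  knotted snapshot fraction %.3f; max windowed probability %.3f%s\n",
                p$overall_knot_fraction, p$max_window_probability,
                if (p$negligible) " (negligible)" else ""))
    if (length(p$knot_labels))
      cat("  knot types:", paste(sprintf("%s=%d", names(p$knot_labels),
                                         p$knot_labels), collapse = ", "),
          "; chirality:", paste(sprintf("%s=%d", names(p$chiralities),
                                        p$chiralities), collapse = ", "), "\n")
    n <- nrow(p$rg)
    cat(sprintf("  final ensemble Rg %.1f A, Q %.3f\n\n",
                p$rg$mean[n], p$q$mean[n]))
  }
  invisible(x)
}
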