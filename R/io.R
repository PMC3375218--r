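# Plain-text interchange: multi-frame XYZ snapshot streams, TSV observable
# logs, and the self-describing model archive.

#' Write a snapshot stream as multi-frame XYZ
#'
#' One frame per snapshot; the comment line carries the MC time (and is
#' parsed back by [read_xyz()]).
#'
#' @param snapshots list of N x 3 matrices (or an `mc_trajectory`).
#' @param path output file.
#' @param times MC times of the frames.
#' @export
write_xyz <- function(snapshots, path, times = NULL) {
  if (inherits(snapshots, "mc_trajectory")) {
    times <- snapshots$snapshot_times
    snapshots <- snapshots$snapshots
  }
  if (is.null(times)) times <- seq_along(snapshots) - 1
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(snapshots)) {
    x <- snapshots[[k]]
    writeLines(as.character(nrow(x)), con)
    writeLines(sprintf("t= %.6g", times[k]), con)
    writeLines(sprintf("CA %.4f %.4f %.4f", x[, 1], x[, 2], x[, 3]), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ snapshot stream
#'
#' @param path file written by [write_xyz()] (or any standard XYZ).
#' @return list with `snapshots` (list of N x 3 matrices) and `times`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  snaps <- list(); times <- numeric(0); k <- 1; i <- 1
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    cm <- lines[i + 1]
    t <- suppressWarnings(as.numeric(sub(".*t=\\s*([-0-9.eE+]+).*", "\\1", cm)))
    times[k] <- if (is.na(t)) k - 1 else t
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- do.call(rbind, strsplit(trimws(block), "\\s+"))
    snaps[[k]] <- matrix(as.numeric(parts[, 2:4]), ncol = 3)
    i <- i + 2 + n; k <- k + 1
  }
  list(snapshots = snaps, times = times)
}

#' Write the observable log of a trajectory as TSV
#'
#' @param traj an `mc_trajectory`.
#' @param path output file.
#' @export
write_trajectory_log <- function(traj, path) {
  utils::write.table(traj$log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a built model as a self-describing text archive
#'
#' Sections: sequence, C-alpha coordinates, native contact list
#' (i, j, class, strength, r0) and the per-residue charges and diameters.
#' Residue indices are 1-based positions along the chain.
#'
#' @param model a [folding_model()].
#' @param path output file.
#' @export
write_model_archive <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# knotfold model archive v1", con)
  writeLines("@sequence", con)
  writeLines(paste(model$sequence, collapse = ""), con)
  writeLines("@coords", con)
  writeLines(sprintf("%.4f %.4f %.4f", model$coords[, 1], model$coords[, 2],
                     model$coords[, 3]), con)
  writeLines("@contacts", con)
  cm <- model$contact_map
  writeLines("i j class strength r0", con)
  writeLines(sprintf("%d %d %s %.6g %.4f", cm$i, cm$j, cm$class, cm$strength,
                     cm$r0), con)
  writeLines("@residues", con)
  cr <- assign_charges_and_radii(model$sequence, model$params)
  writeLines("index aa charge diameter", con)
  writeLines(sprintf("%d %s %g %.3f", seq_along(model$sequence), cr$aa,
                     cr$charge, cr$diameter), con)
  invisible(path)
}

#' Read a model archive
#'
#' @param path file written by [write_model_archive()].
#' @return list with `sequence`, `coords`, `contact_map`, `residues`;
#'   rebuild a full model with [folding_model()].
#' @export
read_model_archive <- function(path) {
  lines <- readLines(path)
  sec <- function(name) {
    i <- which(lines == paste0("@", name)) + 1
    j <- c(grep("^@", lines), length(lines) + 1)
    j <- min(j[j >= i]) - 1
    lines[i:j]
  }
  seq1 <- strsplit(sec("sequence")[1], "")[[1]]
  co <- do.call(rbind, lapply(strsplit(trimws(sec("coords")), "\\s+"),
                              as.numeric))
  cl <- sec("contacts")
  cm <- utils::read.table(text = paste(cl, collapse = "\n"), header = TRUE,
                          stringsAsFactors = FALSE)
  rl <- sec("residues")
  rs <- utils::read.table(text = paste(rl, collapse = "\n"), header = TRUE,
                          stringsAsFactors = FALSE)
  list(sequence = seq1, coords = co, contact_map = cm, residues = rs)
}
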