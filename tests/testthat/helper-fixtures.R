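# Shared fixtures, built in code and cached per test run.

local_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(local_cache[[name]])) local_cache[[name]] <- force(expr)
  local_cache[[name]]
}

toy_knotted <- function() cached("toy_knotted", make_toy_native("knotted"))
toy_unknotted <- function() cached("toy_unknotted", make_toy_native("unknotted"))

toy_model_cached <- function(kind, mode) {
  cached(paste0("model_", kind, "_", mode),
         toy_model(if (kind == "knotted") toy_knotted() else toy_unknotted(), mode))
}

# a hand-written minimal PDB file; returns its path
write_mini_pdb <- function(path, drop_ca_of = integer(0)) {
  res <- c("MET", "ALA", "GLY")
  atoms <- list(
    MET = list(N = c(0, 0, 0), CA = c(1.46, 0, 0), C = c(2.0, 1.4, 0), O = c(1.4, 2.4, 0),
               CB = c(1.9, -0.8, 1.2)),
    ALA = list(N = c(3.3, 1.5, 0), CA = c(4.2, 2.6, 0), C = c(5.6, 2.2, 0.4),
               O = c(5.9, 1.0, 0.5), CB = c(4.1, 3.5, 1.2)),
    GLY = list(N = c(6.5, 3.2, 0.6), CA = c(7.9, 3.0, 1.0), C = c(8.7, 4.3, 1.1),
               O = c(8.2, 5.4, 1.0)))
  lines <- character(0)
  serial <- 0
  for (i in seq_along(res)) {
    for (an in names(atoms[[res[i]]])) {
      if (an == "CA" && i %in% drop_ca_of) next
      serial <- serial + 1
      xyz <- atoms[[res[i]]][[an]]
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
        serial, an, res[i], i, xyz[1], xyz[2], xyz[3], substr(an, 1, 1)))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

# tiny two-state model used for quick MC runs in tests
quick_config <- function(units = 20, seed = 1, ...) {
  mc_config(total_units = units, snapshot_interval = 10, seed = seed,
            max_relax_units = 10, ...)
}

# expected bin probabilities of the pseudo-angle Boltzmann density,
# sin(theta) * exp(-V(theta)), by trapezoid quadrature of the CDF
angle_bin_probs <- function(params, breaks) {
  grid <- seq(0, pi, length.out = 20001)
  v <- knotfold:::.angle_potential_cpp(grid, params$bonded)
  dens <- sin(grid) * exp(-(v - min(v)))
  cdf <- c(0, cumsum((dens[-1] + dens[-length(dens)]) / 2 * diff(grid)))
  diff(approx(grid, cdf, breaks)$y)
}
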