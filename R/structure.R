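# Structure parsing and construction of the native-centric model inputs.

#' Read residues from a PDB file
#'
#' Parses one chain of a PDB file into a residue list carrying backbone and
#' heavy side-chain atom coordinates.  Alternate locations are resolved to
#' the highest occupancy, hydrogens are dropped, the amide hydrogen is
#' reconstructed from the preceding peptide plane (H = N + unit(C - O) of
#' the previous residue), and selenomethionine (MSE) is mapped to MET.
#'
#' @param path PDB file.
#' @param chain_id chain identifier; default is the first chain in the file.
#' @param residue_map named character vector mapping non-standard residue
#'   names to canonical parents (default `c(MSE = "MET")`); any other
#'   non-standard residue is an error.
#' @return an object of class `residue_set`: a list of residues, each with
#'   `seq_index` (source-file numbering), `aa` (three-letter), `ca`,
#'   `backbone` (named list `N`, `CA`, `C`, `O`, optional `H`), and
#'   `sidechain` (matrix of heavy-atom coordinates).
#' @export
read_structure <- function(path, chain_id = NULL, residue_map = c(MSE = "MET")) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  if (is.null(chain_id)) chain_id <- at$chain[1]
  at <- at[at$chain %in% chain_id & at$resid != "HOH", , drop = FALSE]
  if (nrow(at) == 0) stop("chain ", chain_id, " not present in ", path)
  # drop hydrogens
  elt <- toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "", substr(trimws(at$elety), 1, 1), at$elesy)))
  at <- at[elt != "H" & elt != "D", , drop = FALSE]
  # resolve alternate locations: keep highest occupancy per (residue, atom)
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  key <- paste(at$resno, at$insert, at$elety)
  ord <- order(-at$o, at$alt)
  at <- at[ord, , drop = FALSE][!duplicated(key[ord]), , drop = FALSE]
  at <- at[order(match(paste(at$resno, at$insert), unique(paste(at$resno, at$insert)))), , drop = FALSE]

  rid <- paste(at$resno, at$insert)
  residues <- vector("list", length(unique(rid)))
  prev <- NULL
  k <- 0
  for (r in unique(rid)) {
    rows <- at[rid == r, , drop = FALSE]
    aa <- toupper(rows$resid[1])
    if (!aa %in% AA3) {
      if (aa %in% names(residue_map)) aa <- residue_map[[aa]]
      else stop("non-standard residue ", rows$resid[1], " ", rows$resno[1],
                " (supply a residue_map entry to convert or exclude it)")
    }
    get_atom <- function(name) {
      i <- which(trimws(rows$elety) == name)
      if (!length(i)) return(NULL)
      c(rows$x[i[1]], rows$y[i[1]], rows$z[i[1]])
    }
    ca <- get_atom("CA")
    if (is.null(ca)) stop("residue ", rows$resid[1], " ", rows$resno[1],
                          " has no C-alpha atom")
    bb <- list(N = get_atom("N"), CA = ca, C = get_atom("C"), O = get_atom("O"))
    side <- rows[!trimws(rows$elety) %in% c("N", "CA", "C", "O", "OXT"), , drop = FALSE]
    sc <- if (nrow(side)) cbind(side$x, side$y, side$z) else matrix(0, 0, 3)
    res <- list(seq_index = rows$resno[1], insert = rows$insert[1], aa = aa,
                ca = ca, backbone = bb, sidechain = sc)
    # amide hydrogen from the preceding peptide plane
    if (!is.null(prev) && !is.null(bb$N) && !is.null(prev$backbone$C) &&
        !is.null(prev$backbone$O) && aa != "PRO") {
      d <- prev$backbone$C - prev$backbone$O
      res$backbone$H <- bb$N + d / sqrt(sum(d^2))
    }
    k <- k + 1
    residues[[k]] <- res
    prev <- res
  }
  structure(residues[seq_len(k)], class = "residue_set")
}

#' @export
print.residue_set <- function(x, ...) {
  cat(sprintf("residue_set: %d residues (%s ... %s)\n", length(x),
              paste(x[[1]]$aa, x[[1]]$seq_index),
              paste(x[[length(x)]]$aa, x[[length(x)]]$seq_index)))
  invisible(x)
}

#' Extract the C-alpha trace of a residue set
#'
#' @param residues a [read_structure()] result.
#' @param check_bonds validate consecutive C-alpha distances (see
#'   [chain_geometry()]).
#' @return a [chain_geometry()] with attributes `sequence` (one-letter) and
#'   `seq_index` (source numbering).
#' @export
extract_ca_trace <- function(residues, check_bonds = TRUE) {
  co <- t(vapply(residues, function(r) r$ca, numeric(3)))
  g <- chain_geometry(co, check_bonds = check_bonds)
  attr(g, "sequence") <- aa_3to1(vapply(residues, function(r) r$aa, character(1)))
  attr(g, "seq_index") <- vapply(residues, function(r) r$seq_index, numeric(1))
  g
}

#' Kabsch-Sander backbone hydrogen-bond energy
#'
#' Electrostatic hydrogen-bond model: `E = 0.084 * 332 * (1/r_ON + 1/r_CH -
#' 1/r_OH - 1/r_CN)` kcal/mol between the donor amide (N-H) and the acceptor
#' carbonyl (C=O).  More negative is stronger; proline cannot donate and the
#' first residue of a chain has no reconstructable amide hydrogen.
#'
#' @param donor,acceptor residues from a [read_structure()] result (the donor
#'   provides N-H, the acceptor C=O).
#' @return energy in kcal/mol, or `Inf` when no donor hydrogen exists.
#' @export
hbond_energy <- function(donor, acceptor) {
  if (donor$aa == "PRO") return(Inf)
  H <- donor$backbone$H
  N <- donor$backbone$N
  C <- acceptor$backbone$C
  O <- acceptor$backbone$O
  if (is.null(H) || is.null(N) || is.null(C) || is.null(O)) return(Inf)
  d <- function(a, b) sqrt(sum((a - b)^2))
  rON <- d(O, N); rCH <- d(C, H); rOH <- d(O, H); rCN <- d(C, N)
  if (min(rON, rCH, rOH, rCN) < 0.5) return(-9.9)  # clashing geometry
  0.084 * 332 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
}

#' Build the native contact map
#'
#' Two residues at sequence separation of at least 3 form a native contact
#' when their backbone hydrogen bond is stronger than the threshold
#' (default -0.5 kcal/mol, either donor direction) or any two heavy
#' side-chain atoms are within the side-chain cutoff (default 4.5 A).
#' Hydrogen-bonded pairs take their bond energy (converted to thermal units)
#' as attraction strength; side-chain-only pairs take a strength
#' proportional to the quasi-chemical matrix entry, rescaled so their mean
#' matches the mean hydrogen-bond strength.  Around every pair held by two
#' hydrogen bonds, or by a hydrogen bond plus a side-chain contact, the four
#' neighbouring pairs (i-1, j), (i+1, j), (i, j-1), (i, j+1) are added as a
#' weak hydrogen-bond network (strength `weak_hb_factor` times the parent's)
#' unless already present.
#'
#' @param residues a [read_structure()] result.
#' @param params a [forcefield_params()] (thresholds, matrix, conversion).
#' @return data frame with columns `i`, `j` (1-based positions along the
#'   parsed chain), `class` (`primary_hbond`, `sidechain`, `weak_network`),
#'   `strength` (kT) and `r0` (native C-alpha separation, Angstrom).
#' @export
build_native_contact_map <- function(residues, params = forcefield_params()) {
  n <- length(residues)
  ca <- t(vapply(residues, function(r) r$ca, numeric(3)))
  seq1 <- aa_3to1(vapply(residues, function(r) r$aa, character(1)))
  cad <- as.matrix(stats::dist(ca))

  # per-residue side-chain reach from the C-alpha, for a cheap prefilter
  reach <- vapply(residues, function(r) {
    if (nrow(r$sidechain) == 0) return(0)
    sqrt(max(rowSums((r$sidechain - matrix(r$ca, nrow(r$sidechain), 3,
                                           byrow = TRUE))^2)))
  }, numeric(1))

  pairs <- list(); np <- 0
  for (i in seq_len(n - 3)) {
    for (j in seq((i + 3), n)) {
      sc_possible <- cad[i, j] < reach[i] + reach[j] + params$sidechain_cutoff
      hb_possible <- cad[i, j] < 9  # backbone N-H...O=C never spans further
      if (!sc_possible && !hb_possible) next
      nhb <- 0L; e1 <- Inf
      if (hb_possible) {
        e1 <- hbond_energy(residues[[i]], residues[[j]])
        e2 <- hbond_energy(residues[[j]], residues[[i]])
        nhb <- sum(c(e1, e2) < params$hb_threshold)
        e1 <- min(e1, e2)
      }
      sc <- FALSE
      si <- residues[[i]]$sidechain; sj <- residues[[j]]$sidechain
      if (sc_possible && nrow(si) && nrow(sj)) {
        d2min <- min(outer(rowSums(si^2), rowSums(sj^2), "+") - 2 * si %*% t(sj))
        sc <- d2min < params$sidechain_cutoff^2
      }
      if (nhb > 0 || sc) {
        np <- np + 1
        pairs[[np]] <- list(i = i, j = j, nhb = nhb, sc = sc, ehb = e1)
      }
    }
  }
  if (np == 0) stop("empty contact map: degenerate model")
  pi_ <- vapply(pairs, `[[`, 0, "i"); pj <- vapply(pairs, `[[`, 0, "j")
  nhb <- vapply(pairs, `[[`, 0, "nhb"); sc <- vapply(pairs, `[[`, TRUE, "sc")
  ehb <- vapply(pairs, `[[`, 0, "ehb")

  cls <- ifelse(nhb > 0, "primary_hbond", "sidechain")
  strength <- numeric(np)
  strength[nhb > 0] <- abs(ehb[nhb > 0]) / params$kT_kcal
  if (any(nhb == 0)) {
    q <- abs(params$qc_matrix[cbind(seq1[pi_[nhb == 0]], seq1[pj[nhb == 0]])])
    target <- if (any(nhb > 0)) mean(strength[nhb > 0]) else 1
    q[q == 0] <- min(q[q > 0], 1)
    strength[nhb == 0] <- q * target / mean(q)
  }

  cm <- data.frame(i = pi_, j = pj, class = cls, strength = strength,
                   stringsAsFactors = FALSE)

  # weak hydrogen-bond network around doubly-bonded / mixed pairs
  anchors <- which(nhb >= 2 | (nhb >= 1 & sc))
  have <- paste(cm$i, cm$j)
  for (a in anchors) {
    for (nb in list(c(pi_[a] - 1, pj[a]), c(pi_[a] + 1, pj[a]),
                    c(pi_[a], pj[a] - 1), c(pi_[a], pj[a] + 1))) {
      ii <- min(nb); jj <- max(nb)
      if (ii < 1 || jj > n || jj - ii < 3) next
      if (paste(ii, jj) %in% have) next
      cm <- rbind(cm, data.frame(i = ii, j = jj, class = "weak_network",
                                 strength = params$weak_hb_factor * strength[a],
                                 stringsAsFactors = FALSE))
      have <- c(have, paste(ii, jj))
    }
  }
  d <- ca[cm$i, , drop = FALSE] - ca[cm$j, , drop = FALSE]
  cm$r0 <- sqrt(rowSums(d^2))
  validate_contact_map(cm, n)
}

#' Assign secondary structure from the backbone hydrogen-bond pattern
#'
#' A reduced Kabsch-Sander assignment: an alpha-helix hydrogen bond
#' CO(i) -> NH(i+4) marks residues i+1..i+4 as helical (runs shorter than 4
#' are discarded); antiparallel (i<->j mutual) or parallel
#' ((i-1, j+1) and (j-1, i+1)) bridge patterns mark strand residues;
#' everything else is coil.
#'
#' @param residues a [read_structure()] result.
#' @param params thresholds (see [forcefield_params()]).
#' @return factor of length `length(residues)` with levels helix/strand/coil.
#' @export
assign_secondary_structure <- function(residues, params = forcefield_params()) {
  n <- length(residues)
  ca <- t(vapply(residues, function(r) r$ca, numeric(3)))
  cad <- as.matrix(stats::dist(ca))
  # hb[i, j]: CO of i accepts from NH of j
  hb <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (abs(i - j) < 2 || cad[i, j] > 9) next
    hb[i, j] <- hbond_energy(residues[[j]], residues[[i]]) < params$hb_threshold
  }
  lab <- rep("coil", n)
  helical <- rep(FALSE, n)
  for (i in seq_len(max(0, n - 4)))
    if (hb[i, i + 4]) helical[(i + 1):(i + 4)] <- TRUE
  r <- rle(helical)
  r$values[r$values & r$lengths < 4] <- FALSE
  helical <- inverse.rle(r)
  lab[helical] <- "helix"
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j - i < 3) next
    anti1 <- hb[i, j] && hb[j, i]
    anti2 <- i > 1 && j < n && i + 1 <= n && j - 1 >= 1 &&
      hb[i - 1, j + 1] && hb[j - 1, i + 1]
    par <- (i > 1 && j < n && i + 1 <= n && hb[i - 1, j] && hb[j, i + 1]) ||
           (j > 1 && j < n && i + 1 <= n && hb[j - 1, i] && hb[i, j + 1])
    if (anti1 || anti2 || par) {
      if (lab[i] != "helix") lab[i] <- "strand"
      if (lab[j] != "helix") lab[j] <- "strand"
    }
  }
  factor(lab, levels = c("helix", "strand", "coil"))
}

#' Per-residue charges and diameters
#'
#' @param residues a [read_structure()] result, or a character vector of
#'   residue types.
#' @param params a [forcefield_params()] carrying the lookup tables.
#' @return data frame with `aa`, `charge` (elementary charges: -1 for
#'   ASP/GLU, +1 for LYS/ARG, 0 otherwise) and `diameter` (Angstrom).
#' @export
assign_charges_and_radii <- function(residues, params = forcefield_params()) {
  seq1 <- if (inherits(residues, "residue_set"))
    aa_3to1(vapply(residues, function(r) r$aa, character(1)))
  else if (all(nchar(residues) == 3)) aa_3to1(residues) else toupper(residues)
  if (!all(seq1 %in% AA1)) stop("missing table entry for residue type(s): ",
                                paste(setdiff(seq1, AA1), collapse = ", "))
  data.frame(aa = seq1, charge = unname(params$charges[seq1]),
             diameter = unname(params$diameters[seq1]))
}
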