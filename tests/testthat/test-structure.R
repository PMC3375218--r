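# Structure parsing, hydrogen bonds, contact maps, secondary structure.

test_that("PDB parsing returns residues in order and validates C-alpha presence", {
  pdb <- write_mini_pdb(tempfile(fileext = ".pdb"))
  rs <- read_structure(pdb)
  expect_s3_class(rs, "residue_set")
  expect_length(rs, 3)
  expect_equal(vapply(rs, function(r) r$aa, character(1)), c("MET", "ALA", "GLY"))
  expect_equal(rs[[1]]$seq_index, 1)
  expect_equal(rs[[2]]$ca, c(4.2, 2.6, 0))
  expect_equal(nrow(rs[[3]]$sidechain), 0)  # glycine has no heavy side chain

  bad <- write_mini_pdb(tempfile(fileext = ".pdb"), drop_ca_of = 2)
  expect_error(read_structure(bad), "ALA 2.*C-alpha")
})

test_that("C-alpha trace extraction preserves order and flags geometry breaks", {
  rs <- make_ideal_backbone(10)
  g <- extract_ca_trace(rs)
  expect_equal(nrow(g), 10)
  expect_equal(unname(g[1, ]), rs[[1]]$ca)
  expect_equal(attr(g, "sequence"), rep("A", 10))

  three <- list(
    list(seq_index = 1, aa = "ALA", ca = c(0, 0, 0), backbone = list(), sidechain = matrix(0, 0, 3)),
    list(seq_index = 2, aa = "ALA", ca = c(3.8, 0, 0), backbone = list(), sidechain = matrix(0, 0, 3)),
    list(seq_index = 3, aa = "ALA", ca = c(13.8, 0, 0), backbone = list(), sidechain = matrix(0, 0, 3)))
  class(three) <- "residue_set"
  expect_error(extract_ca_trace(three), "2.5, 4.5")
  expect_silent(extract_ca_trace(three, check_bonds = FALSE))
})

test_that("Kabsch-Sander energies: helix i,i+4 bonds form, distant/proline pairs do not", {
  hel <- make_ideal_backbone(12, phi = -57, psi = -47)
  e <- hbond_energy(hel[[6]], hel[[2]])  # NH(i+4) -> CO(i)
  expect_lt(e, -0.5)

  far <- make_ideal_backbone(3)
  shifted <- lapply(far, function(r) {
    r$ca <- r$ca + c(30, 0, 0)
    r$backbone <- lapply(r$backbone, function(v) v + c(30, 0, 0))
    r
  })
  expect_gt(hbond_energy(shifted[[2]], hel[[2]]), -0.5)
  expect_lt(abs(hbond_energy(shifted[[2]], hel[[2]])), 0.5)

  pro <- hel[[6]]; pro$aa <- "PRO"
  expect_identical(hbond_energy(pro, hel[[2]]), Inf)
})

test_that("contact map applies the hydrogen-bond OR side-chain rule with exclusions", {
  # synthetic residue pair factory: side chains at a controlled distance
  res_at <- function(i, x, sc_offset = 2) {
    list(seq_index = i, aa = "LEU", ca = c(x, 0, 0),
         backbone = list(N = c(x - 0.5, 1, 0), CA = c(x, 0, 0),
                         C = c(x + 0.5, 1, 0), O = c(x + 0.5, 2.2, 0)),
         sidechain = matrix(c(x, -sc_offset, 0), 1, 3))
  }
  # chain of 7; pair (1, 5): closest side-chain atoms 4.4 A apart => contact
  # (the probe side chain reaches down in -y, away from every other residue)
  rs <- lapply(1:7, function(i) res_at(i, (i - 1) * 3.8))
  rs[[5]]$sidechain <- matrix(c(0, -6.4, 0), 1, 3)
  class(rs) <- "residue_set"
  cm <- build_native_contact_map(rs)
  expect_true(any(cm$i == 1 & cm$j == 5 & cm$class == "sidechain"))
  expect_equal(nrow(cm), 1)

  # pair (1, 3) at the same side-chain distance is excluded (|i-j| < 3)
  rs2 <- lapply(1:7, function(i) res_at(i, (i - 1) * 3.8))
  rs2[[3]]$sidechain <- matrix(c(0, -6.4, 0), 1, 3)
  class(rs2) <- "residue_set"
  cm2 <- tryCatch(build_native_contact_map(rs2), error = function(e) NULL)
  if (!is.null(cm2)) expect_false(any(cm2$i == 1 & cm2$j == 3))

  # side chains beyond 4.5 A and no H-bond: no contact
  rs3 <- lapply(1:7, function(i) res_at(i, (i - 1) * 3.8))
  rs3[[5]]$sidechain <- matrix(c(0, -6.6, 0), 1, 3)
  class(rs3) <- "residue_set"
  expect_error(build_native_contact_map(rs3), "empty contact map")
})

test_that("hydrogen-bonded helix pairs enter as primary_hbond with converted strength", {
  hel <- make_ideal_backbone(14, phi = -57, psi = -47)
  params <- forcefield_params()
  cm <- build_native_contact_map(hel, params)
  hb <- cm[cm$class == "primary_hbond", ]
  expect_gt(nrow(hb), 0)
  expect_true(all(hb$j - hb$i >= 3))
  expect_true(all(hb$strength > 0))
  # strengths are |E_hb| / kT with E_hb < -0.5 kcal/mol
  expect_true(all(hb$strength > 0.5 / params$kT_kcal))
})

test_that("contact-map invariants hold on the toy natives", {
  for (toy in list(toy_knotted(), toy_unknotted())) {
    cm <- toy$contact_map
    expect_true(all(cm$j - cm$i >= 3))
    expect_false(anyDuplicated(cm[c("i", "j")]) > 0)
    expect_true(all(cm$strength > 0))
  }
})

test_that("shrinking the side-chain cutoff never adds contacts", {
  hel <- make_ideal_backbone(14, phi = -57, psi = -47)
  p45 <- forcefield_params(sidechain_cutoff = 4.5)
  p35 <- forcefield_params(sidechain_cutoff = 3.5)
  cm45 <- build_native_contact_map(hel, p45)
  cm35 <- build_native_contact_map(hel, p35)
  keys <- function(cm) paste(cm$i, cm$j)
  expect_true(all(keys(cm35) %in% keys(cm45)))
})

test_that("weak-network contacts only appear next to a qualifying anchor pair", {
  hel <- make_ideal_backbone(16, phi = -57, psi = -47)
  cm <- build_native_contact_map(hel)
  expect_gt(nrow(cm), 0)
  wn <- cm[cm$class == "weak_network", ]
  if (nrow(wn)) {
    anchors <- cm[cm$class != "weak_network", c("i", "j")]
    ok <- vapply(seq_len(nrow(wn)), function(k) {
      any((abs(anchors$i - wn$i[k]) + abs(anchors$j - wn$j[k])) == 1)
    }, logical(1))
    expect_true(all(ok))
  }
})

test_that("secondary structure: helix fixture all-helix, extended none, hairpin strands", {
  hel <- make_ideal_backbone(18, phi = -57, psi = -47)
  ss <- assign_secondary_structure(hel)
  expect_true(mean(ss == "helix") > 0.7)  # termini lack H-bond partners

  ext <- make_ideal_backbone(18, phi = -139, psi = 135)
  ss2 <- assign_secondary_structure(ext)
  expect_false(any(ss2 == "helix"))

  hp <- make_beta_hairpin(6)
  ss3 <- assign_secondary_structure(hp)
  expect_gt(sum(ss3[1:6] == "strand"), 1)
  expect_gt(sum(ss3[9:14] == "strand"), 1)
})

test_that("charges and diameters follow the standard ionization table", {
  cr <- assign_charges_and_radii(c("G", "D", "E", "K", "R", "L"))
  expect_equal(cr$charge, c(0, -1, -1, 1, 1, 0))
  expect_true(all(cr$diameter > 4 & cr$diameter < 8))
  # pair contact distance used downstream is the arithmetic mean of diameters
  p <- forcefield_params()
  expect_equal(unname((p$diameters["A"] + p$diameters["W"]) / 2),
               unname(mean(p$diameters[c("A", "W")])))
  expect_error(assign_charges_and_radii(c("A", "XYZ")), "unknown|missing")
})
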