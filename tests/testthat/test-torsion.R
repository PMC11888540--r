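test_that("psi dihedrals are located by backbone connectivity", {
  topo <- make_toy_topology("AQA")
  hits <- find_psi_dihedrals(topo, "GLN")
  expect_equal(nrow(hits), 1)
  a <- topo$molecules$Protein$atoms
  expect_equal(unlist(hits[1, c("ai", "aj", "ak", "al")], use.names = FALSE),
               c(a$index[a$resnr == 2 & a$atomname == "N"],
                 a$index[a$resnr == 2 & a$atomname == "CA"],
                 a$index[a$resnr == 2 & a$atomname == "C"],
                 a$index[a$resnr == 3 & a$atomname == "N"]))

  # C-terminal Gln has no psi
  expect_equal(nrow(find_psi_dihedrals(make_toy_topology("AAQ"), "GLN")), 0)
  # no S/T/Q at all
  expect_equal(nrow(find_psi_dihedrals(make_toy_topology("AGAV"),
                                       c("SER", "THR", "GLN"))), 0)
})

test_that("presets carry the defined force constants", {
  expect_equal(torsion_preset("BASE")$k_map, c(SER = 2, THR = 2, GLN = 2))
  expect_equal(torsion_preset("STQ")$k_map, c(SER = 1, THR = 1, GLN = 1))
  expect_equal(torsion_preset("STQ_PRIME")$k_map, c(SER = 1, THR = 1, GLN = 1.5))
  expect_error(torsion_preset("custom"), "k_map")
  expect_error(torsion_preset("custom", c(GLN = -1)), "> 0")
})

test_that("force constants are rewritten with phase and multiplicity preserved", {
  topo <- make_toy_topology("ASTQA")
  stq <- set_psi_force_constant(topo, torsion_preset("STQ"))
  hits <- find_psi_dihedrals(topo, c("SER", "THR", "GLN"))
  for (i in seq_len(nrow(hits))) {
    row <- hits$dihedral_row[i]
    expect_equal(stq$molecules$Protein$dihedrals$k[row], 1.0)
    expect_equal(stq$molecules$Protein$dihedrals$phase[row],
                 topo$molecules$Protein$dihedrals$phase[row])
    expect_equal(stq$molecules$Protein$dihedrals$mult[row],
                 topo$molecules$Protein$dihedrals$mult[row])
  }
  # untouched: psi of ALA residues
  other <- setdiff(seq_len(nrow(topo$molecules$Protein$dihedrals)),
                   hits$dihedral_row)
  expect_equal(stq$molecules$Protein$dihedrals$k[other],
               topo$molecules$Protein$dihedrals$k[other])

  stqp <- set_psi_force_constant(topo, torsion_preset("STQ_PRIME"))
  gln_row <- hits$dihedral_row[hits$resname == "GLN"]
  expect_equal(stqp$molecules$Protein$dihedrals$k[gln_row], 1.5)
  expect_equal(stqp$molecules$Protein$dihedrals$k[
    hits$dihedral_row[hits$resname %in% c("SER", "THR")]], c(1.0, 1.0))
})

test_that("the refinement is idempotent", {
  topo <- make_toy_topology("AQSA")
  once <- set_psi_force_constant(topo, torsion_preset("STQ"))
  twice <- set_psi_force_constant(once, torsion_preset("STQ"))
  expect_topology_equal(once, twice)
})

test_that("a missing n=1 correction term is a hard error", {
  topo <- make_toy_topology("AQA")
  hit <- find_psi_dihedrals(topo, "GLN")
  topo$molecules$Protein$dihedrals$mult[hit$dihedral_row] <- 2L
  expect_error(set_psi_force_constant(topo, torsion_preset("STQ")), "n=1")
})

test_that("diff_torsions counts exactly the changed Q psi terms", {
  seq15 <- paste(rep("AAQAA", 3), collapse = "")
  topo <- make_toy_topology(seq15)
  stq <- set_psi_force_constant(topo, torsion_preset("STQ"))
  d <- diff_torsions(topo, stq)
  expect_equal(nrow(d), 3)   # three Q residues in (AAQAA)x3
  expect_true(all(d$resname == "GLN"))
  expect_equal(d$k_a - d$k_b, rep(1.0, 3))   # 2.0 -> 1.0

  expect_equal(nrow(diff_torsions(topo, topo)), 0)

  stqp <- set_psi_force_constant(topo, torsion_preset("STQ_PRIME"))
  d2 <- diff_torsions(stq, stqp)
  expect_true(all(d2$resname == "GLN"))
  expect_equal(unique(d2$k_b - d2$k_a), 0.5)  # 1.0 vs 1.5 kJ/mol

  other <- make_toy_topology("AAA")
  expect_error(diff_torsions(topo, other), "differ|molecule")
})

test_that("refinement changes only the psi term energy, by the closed form", {
  topo <- make_toy_topology("AQA")
  stqp <- set_psi_force_constant(topo, torsion_preset("STQ_PRIME"))
  coords <- system_coords(topo, seed = 5)
  cfg_a <- make_configuration(topo, NULL, coords)
  cfg_b <- make_configuration(stqp, NULL, coords)
  ea <- total_energy(topo, cfg_a)
  eb <- total_energy(stqp, cfg_b)
  # LJ and Coulomb identical
  expect_equal(eb["lj"], ea["lj"])
  expect_equal(eb["coulomb"], ea["coulomb"])
  # dihedral delta equals (k_new - k_old)(1 + cos(n psi - delta))
  hit <- find_psi_dihedrals(topo, "GLN")
  q <- unlist(hit[1, c("ai", "aj", "ak", "al")], use.names = FALSE)
  psi <- dihedral_angle(coords[q[1], ], coords[q[2], ], coords[q[3], ], coords[q[4], ])
  dh <- topo$molecules$Protein$dihedrals[hit$dihedral_row, ]
  expected <- (1.5 - 2.0) * (1 + cos((dh$mult * psi - dh$phase) * pi / 180))
  expect_equal(unname(eb["dihedral"] - ea["dihedral"]), expected, tolerance = 1e-10)
})
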