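test_that("atoms classify into backbone, sidechain, water and ions", {
  expect_equal(classify_atom("CA", "ALA"), "BACKBONE")
  expect_equal(classify_atom("CB", "GLN"), "SIDECHAIN")
  expect_equal(classify_atom("OW", "SOL"), "WATER")
  expect_equal(classify_atom("NA", "NA"), "ION")
  expect_equal(classify_atom(c("N", "HA2", "OD1"), c("GLY", "GLY", "ASP")),
               c("BACKBONE", "BACKBONE", "SIDECHAIN"))
  expect_warning(cls <- classify_atom("X1", "XXX"), "unrecognized")
  expect_equal(cls, "OTHER")
})

test_that("every protein atom is backbone xor sidechain", {
  topo <- make_toy_topology("ACDEFGHIKLMNPQRSTVWY")
  a <- topo$molecules$Protein$atoms
  cls <- classify_atom(a$atomname, a$resname)
  expect_true(all(cls %in% c("BACKBONE", "SIDECHAIN")))
})

test_that("scheme target selection follows the mode rules", {
  topo <- make_toy_topology("ADQ")
  a <- topo$molecules$Protein$atoms

  # excluding charged residues: ALA and GLN sidechains only, ASP excluded
  t_unch <- select_scaling_targets(topo, scaling_scheme("SIDECHAIN_UNCHARGED"))
  expect_setequal(unique(t_unch$resname), c("ALA", "GLN"))
  expect_true(all(classify_atom(t_unch$atomname, t_unch$resname) == "SIDECHAIN"))

  # backbone scaling: heavy atoms only, no hydrogens
  t_bb <- select_scaling_targets(topo, scaling_scheme("BACKBONE"))
  expect_true(all(t_bb$atomname %in% c("N", "CA", "C", "O")))
  expect_false(any(grepl("^H", t_bb$atomname)))

  # glycine has no sidechain to scale
  t_gg <- select_scaling_targets(make_toy_topology("GG"),
                                 scaling_scheme("SIDECHAIN_ALL"))
  expect_equal(nrow(t_gg), 0)

  # ALL is a superset of BACKBONE and SIDECHAIN_ALL selections
  t_all <- select_scaling_targets(topo, scaling_scheme("ALL"))
  t_sc <- select_scaling_targets(topo, scaling_scheme("SIDECHAIN_ALL"))
  key <- function(t) paste(t$molecule, t$index)
  expect_true(all(key(t_bb) %in% key(t_all)))
  expect_true(all(key(t_sc) %in% key(t_all)))
})

test_that("combination rules give the standard means", {
  expect_equal(combine_lj(0.3, 0.5, 0.3, 0.5), c(sigma = 0.3, epsilon = 0.5))
  expect_equal(unname(combine_lj(0.3, 0.4, 0.4, 0.9)["epsilon"]), 0.6)
  expect_equal(unname(combine_lj(0.3, 0, 0.4, 0.9)["epsilon"]), 0)
  expect_equal(unname(combine_lj(0.2, 0.4, 0.4, 0.4, "geometric")["sigma"]),
               sqrt(0.08))
  expect_error(combine_lj(-0.1, 0.4, 0.4, 0.9), "negative")
})

test_that("scaled overrides carry exactly gamma times the combination epsilon", {
  topo <- make_toy_topology("ADQ")
  out <- apply_water_scaling(topo, scaling_scheme("SIDECHAIN_UNCHARGED", gamma = 1.10))
  at <- out$atomtypes
  ow <- at[at$name == "OWtoy", ]
  nb <- out$nonbond_params
  a <- out$molecules$Protein$atoms
  targets <- select_scaling_targets(topo, scaling_scheme("SIDECHAIN_UNCHARGED"))
  for (i in targets$index) {
    tp <- a$type[a$index == i]   # possibly cloned type after scaling
    row <- nb[nb$type_a == tp | nb$type_b == tp, ]
    expect_equal(nrow(row), 1)
    trow <- at[at$name == tp, ]
    cmb <- combine_lj(trow$sigma, trow$epsilon, ow$sigma, ow$epsilon)
    expect_equal(row$epsilon, 1.10 * unname(cmb["epsilon"]))
    expect_equal(row$sigma, unname(cmb["sigma"]))
  }
  # ASP sidechain atoms keep unscaled types with no override
  asp <- a[a$resname == "ASP" &
           classify_atom(a$atomname, a$resname) == "SIDECHAIN", ]
  for (tp in unique(asp$type)) {
    expect_false(grepl("_sc$", tp))
    expect_equal(nrow(nb[nb$type_a == tp | nb$type_b == tp, ]), 0)
  }
})

test_that("ALL-mode override count equals the number of distinct protein types", {
  topo <- make_toy_topology("ADQ")
  out <- apply_water_scaling(topo, scaling_scheme("ALL", gamma = 1.10))
  n_types <- length(unique(topo$molecules$Protein$atoms$type))
  expect_equal(nrow(attr(out, "scaling_log")$overrides), n_types)
})

test_that("re-applying to a scaled pair is refused unless forced", {
  topo <- make_toy_topology("AA")
  out <- apply_water_scaling(topo, scaling_scheme("ALL", gamma = 1.10))
  expect_error(apply_water_scaling(out, scaling_scheme("ALL", gamma = 1.10)),
               "pre-existing")
  expect_message(
    out2 <- apply_water_scaling(out, scaling_scheme("ALL", gamma = 1.10),
                                force = TRUE),
    "replaced")
  expect_equal(nrow(out2$nonbond_params), nrow(out$nonbond_params))
})

test_that("scaling preserves molecular mass and net charge", {
  topo <- make_toy_topology("DKQ")
  out <- apply_water_scaling(topo, scaling_scheme("SIDECHAIN_ALL", gamma = 1.10))
  for (mn in names(topo$molecules)) {
    expect_equal(sum(ffbalance:::.atom_masses(out, out$molecules[[mn]])),
                 sum(ffbalance:::.atom_masses(topo, topo$molecules[[mn]])))
    expect_equal(sum(ffbalance:::.atom_charges(out, out$molecules[[mn]])),
                 sum(ffbalance:::.atom_charges(topo, topo$molecules[[mn]])))
  }
  expect_equal(nrow(validate_topology(out)), 0)
})

test_that("hydrogen mass repartitioning conserves total mass exactly", {
  topo <- make_toy_topology("AQ")
  out <- repartition_hydrogen_masses(topo, 1.5)
  a <- out$molecules$Protein$atoms
  m0 <- sum(ffbalance:::.atom_masses(topo, topo$molecules$Protein))
  expect_equal(sum(a$mass), m0, tolerance = 1e-12)
  # every hydrogen now at 1.5 amu
  hs <- grepl("^H", a$atomname)
  expect_true(all(a$mass[hs] == 1.5))
  # methyl carbon of ALA lost 3 x (1.5 - 1.008)
  cb <- a$mass[a$atomname == "CB" & a$resname == "ALA"]
  expect_equal(cb, 12.011 - 3 * (1.5 - 1.008))
  # water untouched
  expect_equal(out$molecules$SOL$atoms$mass, topo$molecules$SOL$atoms$mass)
})

test_that("repartitioning to the current hydrogen mass is the identity", {
  topo <- make_toy_topology("AQ")
  out <- repartition_hydrogen_masses(topo, 1.008)
  expect_equal(ffbalance:::.atom_masses(out, out$molecules$Protein),
               ffbalance:::.atom_masses(topo, topo$molecules$Protein))
})
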