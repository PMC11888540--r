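test_that("the 12-6 potential has its closed-form landmarks", {
  expect_equal(lj_pair_energy(0.3, 0.5, 0.3), 0)
  expect_equal(lj_pair_energy(0.3, 0.5, 2^(1/6) * 0.3), -0.5)
  r <- c(0.2, 0.3, 0.5, 1.0, 2.5)
  expect_equal(lj_pair_energy(0.3, 1.10 * 0.5, r),
               1.10 * lj_pair_energy(0.3, 0.5, r))
  expect_error(lj_pair_energy(0.3, 0.5, 0), "> 0")
})

test_that("the proper-dihedral term has its closed-form landmarks", {
  expect_equal(dihedral_energy(1.5, 1, 0, 0), 3.0)
  expect_equal(dihedral_energy(1.5, 1, 0, 180), 0, tolerance = 1e-12)
  # k 2.0 -> 1.0 at phi = delta changes the energy by -2.0 kJ/mol
  expect_equal(dihedral_energy(1.0, 1, 30, 30) - dihedral_energy(2.0, 1, 30, 30),
               -2.0)
  expect_error(dihedral_energy(1, 0, 0, 0), ">= 1")
})

test_that("a two-particle system reproduces the hand-summed pair energy", {
  txt <- minimal_topology_text()
  topo <- parse_topology(txt)
  # break the bond so the pair actually interacts
  topo$molecules$DIA$bonds <- topo$molecules$DIA$bonds[0, ]
  topo$molecules$DIA$atoms$charge <- c(0.2, -0.2)
  coords <- rbind(c(0, 0, 0), c(0.5, 0, 0))
  cfg <- make_configuration(topo, c(DIA = 1), coords)
  e <- total_energy(topo, cfg)
  cmb <- combine_lj(0.34, 0.36, 0.296, 0.88)
  expect_equal(unname(e["lj"]),
               lj_pair_energy(cmb["sigma"], cmb["epsilon"], 0.5),
               ignore_attr = TRUE)
  expect_equal(unname(e["coulomb"]), 138.935458 * 0.2 * -0.2 / 0.5)
})

test_that("bonded exclusions suppress 1-2/1-3 pairs and scale 1-4", {
  topo <- parse_topology(minimal_topology_text())
  cfg <- make_configuration(topo, c(DIA = 1), rbind(c(0, 0, 0), c(0.15, 0, 0)))
  e <- total_energy(topo, cfg)   # bonded pair: fully excluded
  expect_equal(unname(e["lj"]), 0)
  expect_equal(unname(e["coulomb"]), 0)
})

test_that("energies are invariant under rigid transforms", {
  topo <- make_toy_topology("AQ")
  coords <- system_coords(topo, seed = 3)
  cfg <- make_configuration(topo, NULL, coords)
  e0 <- total_energy(topo, cfg)
  set.seed(42)
  for (k in 1:3) {
    R <- ffbalance:::.random_rotation()
    t <- stats::rnorm(3)
    moved <- sweep(coords %*% t(R), 2, t, "+")
    e1 <- total_energy(topo, make_configuration(topo, NULL, moved))
    expect_equal(e1, e0, tolerance = 1e-9)
  }
})

test_that("distant groups are pairwise additive", {
  topo <- make_toy_topology("AQ", n_water = 1)
  prot_xyz <- toy_coords(topo, "Protein", seed = 2)
  wat_xyz <- toy_coords(topo, "SOL", seed = 3)
  wat_far <- sweep(wat_xyz, 2, c(8, 0, 0), "+")   # >= 5 nm away
  e_both <- total_energy(topo, make_configuration(
    topo, c(Protein = 1, SOL = 1), rbind(prot_xyz, wat_far)))
  e_p <- total_energy(topo, make_configuration(topo, c(Protein = 1), prot_xyz))
  e_w <- total_energy(topo, make_configuration(topo, c(SOL = 1), wat_far))
  expect_lt(abs(e_both["lj"] - e_p["lj"] - e_w["lj"]), 1e-6)
})

test_that("overlapping atoms are a hard error", {
  topo <- parse_topology(minimal_topology_text())
  topo$molecules$DIA$bonds <- topo$molecules$DIA$bonds[0, ]
  expect_error(total_energy(topo, make_configuration(
    topo, c(DIA = 1), rbind(c(0, 0, 0), c(0, 0, 1e-8)))), "overlap")
})

test_that("gamma = 1 scaling is energy-neutral on a full fixture", {
  topo <- make_toy_topology("ADQ", n_water = 2)
  scaled <- apply_water_scaling(topo, scaling_scheme("ALL", gamma = 1.0))
  coords <- system_coords(topo, seed = 1)
  e0 <- total_energy(topo, make_configuration(topo, NULL, coords))
  e1 <- total_energy(scaled, make_configuration(scaled, NULL, coords))
  expect_equal(e1, e0, tolerance = 1e-10)
})

test_that("scaled targeted-atom/water LJ is exactly gamma times unscaled", {
  topo <- make_toy_topology("ADQ")
  scaled <- apply_water_scaling(topo,
    scaling_scheme("SIDECHAIN_UNCHARGED", gamma = 1.10))
  at <- scaled$atomtypes
  ow <- at[at$name == "OWtoy", ]
  a <- scaled$molecules$Protein$atoms
  tgt <- select_scaling_targets(topo, scaling_scheme("SIDECHAIN_UNCHARGED"))
  set.seed(9)
  for (i in sample(tgt$index, 3)) {
    tp <- a$type[a$index == i]
    trow <- at[at$name == tp, ]
    ov <- ffbalance:::.lookup_override(scaled, tp, "OWtoy")
    cmb <- combine_lj(trow$sigma, trow$epsilon, ow$sigma, ow$epsilon)
    for (r in stats::runif(5, 0.25, 1.5)) {
      expect_equal(lj_pair_energy(ov$sigma, ov$epsilon, r),
                   1.10 * lj_pair_energy(cmb["sigma"], cmb["epsilon"], r),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
})

test_that("Coulomb and protein-protein terms are invariant under scaling", {
  topo <- make_toy_topology("DKQ", n_water = 1)
  scaled <- apply_water_scaling(topo, scaling_scheme("SIDECHAIN_ALL", gamma = 1.10))
  coords <- system_coords(topo, seed = 4)
  e0 <- total_energy(topo, make_configuration(topo, NULL, coords))
  e1 <- total_energy(scaled, make_configuration(scaled, NULL, coords))
  expect_identical(unname(e1["coulomb"]), unname(e0["coulomb"]))
  # protein-only configuration: all terms identical
  pc <- toy_coords(topo, "Protein", seed = 4)
  p0 <- total_energy(topo, make_configuration(topo, c(Protein = 1), pc))
  p1 <- total_energy(scaled, make_configuration(scaled, c(Protein = 1), pc))
  expect_equal(p1, p0, tolerance = 1e-12)
})
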