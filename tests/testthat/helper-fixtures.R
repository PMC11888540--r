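# Shared fixtures built in code.

# Minimal hand-written topology text: two atom types, one diatomic
# "molecule", one water-like molecule for scaling tests.
minimal_topology_text <- function(nonbond = FALSE) {
  c("[ defaults ]",
    "1 2 yes 0.5 0.8333",
    "[ atomtypes ]",
    "; name mass charge ptype sigma epsilon",
    "CX 12.011 0.0 A 0.34 0.36",
    "OX 15.999 0.0 A 0.296 0.88",
    if (nonbond) c("[ nonbond_params ]", "CX OX 1 0.31 0.5"),
    "[ moleculetype ]",
    "DIA 3",
    "[ atoms ]",
    "1 CX 1 UNK C1 1 0.0 12.011",
    "2 OX 1 UNK O1 1 0.0 15.999",
    "[ bonds ]",
    "1 2 1")
}

# deep semantic comparison of two topologies
expect_topology_equal <- function(a, b, tol = 1e-6) {
  expect_equal(a$defaults, b$defaults, tolerance = tol)
  expect_equal(a$atomtypes, b$atomtypes, tolerance = tol)
  expect_equal(a$nonbond_params, b$nonbond_params, tolerance = tol)
  expect_equal(names(a$molecules), names(b$molecules))
  for (mn in names(a$molecules)) {
    ma <- a$molecules[[mn]]; mb <- b$molecules[[mn]]
    expect_equal(ma$atoms, mb$atoms, tolerance = tol)
    expect_equal(ma$bonds, mb$bonds, tolerance = tol)
    expect_equal(ma$dihedrals, mb$dihedrals, tolerance = tol)
  }
  expect_equal(a$system_molecules, b$system_molecules)
}

# frame of M residues, each an N atom plus an amide H in a random
# direction: test bed for the iRED generators
make_nh_frame <- function(m, seed = 2) {
  set.seed(seed)
  N <- matrix(stats::rnorm(m * 3), ncol = 3) * 2
  dirs <- t(apply(matrix(stats::rnorm(m * 3), ncol = 3), 1,
                  function(v) v / sqrt(sum(v^2))))
  H <- N + dirs * 0.1
  ord <- as.vector(rbind(seq_len(m), seq_len(m) + m))
  xyz <- rbind(N, H)[ord, ]
  ff_frame(xyz, rep(c("N", "H"), m), rep(seq_len(m), each = 2), "ALA")
}

# total LJ+Coulomb energies split by component for a Protein + n SOL
# system, used by the scaling invariance tests
system_coords <- function(topo, seed = 1) {
  ffbalance:::.default_check_coords(topo, seed)
}
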