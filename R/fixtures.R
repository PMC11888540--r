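# Synthetic-data generators: chemically plausible toy topologies with
# generic parameters, ideal backbone geometries, Gaussian chains, and
# tumbling/wobble trajectories. Toy parameters are deliberately NOT the
# published force-field values: tests built on these fixtures assert
# relations (ratios, deltas, conservation laws), never absolute energies.

# Sidechain atom templates: "ATOM:PARENT" within the residue (parents
# must precede children). Ring-closure bonds listed separately.
.SIDECHAINS <- list(
  ALA = c("CB:CA", "HB1:CB", "HB2:CB", "HB3:CB"),
  ARG = c("CB:CA", "HB2:CB", "HB3:CB", "CG:CB", "HG2:CG", "HG3:CG", "CD:CG",
          "HD2:CD", "HD3:CD", "NE:CD", "HE:NE", "CZ:NE", "NH1:CZ", "HH11:NH1",
          "HH12:NH1", "NH2:CZ", "HH21:NH2", "HH22:NH2"),
  ASN = c("CB:CA", "HB2:CB", "HB3:CB", "CG:CB", "OD1:CG", "ND2:CG",
          "HD21:ND2", "HD22:ND2"),
  ASP = c("CB:CA", "HB2:CB", "HB3:CB", "CG:CB", "OD1:CG", "OD2:CG"),
  CYS = c("CB:CA", "HB2:CB", "HB3:CB", "SG:CB", "HG:SG"),
  GLN = c("CB:CA", "HB2:CB", "HB3:CB", "CG:CB", "HG2:CG", "HG3:CG", "CD:CG",
          "OE1:CD", "NE2:CD", "HE21:NE2", "HE22:NE2"),
  GLU = c("CB:CA", "HB2:CB", "HB3:CB", "CG:CB", "HG2:CG", "HG3:CG", "CD:CG",
          "OE1:CD", "OE2:CD"),
  GLY = character(0),
  HIS = c("CB:CA", "HB2:CB", "HB3:CB", "CG:CB", "ND1:CG", "CD2:CG", "HD2:CD2",
          "CE1:ND1", "HE1:CE1", "NE2:CE1", "HE2:NE2"),
  ILE = c("CB:CA", "HB:CB", "CG1:CB", "HG12:CG1", "HG13:CG1", "CG2:CB",
          "HG21:CG2", "HG22:CG2", "HG23:CG2", "CD1:CG1", "HD11:CD1",
          "HD12:CD1", "HD13:CD1"),
  LEU = c("CB:CA", "HB2:CB", "HB3:CB", "CG:CB", "HG:CG", "CD1:CG", "HD11:CD1",
          "HD12:CD1", "HD13:CD1", "CD2:CG", "HD21:CD2", "HD22:CD2", "HD23:CD2"),
  LYS = c("CB:CA", "HB2:CB", "HB3:CB", "CG:CB", "HG2:CG", "HG3:CG", "CD:CG",
          "HD2:CD", "HD3:CD", "CE:CD", "HE2:CE", "HE3:CE", "NZ:CE", "HZ1:NZ",
          "HZ2:NZ", "HZ3:NZ"),
  MET = c("CB:CA", "HB2:CB", "HB3:CB", "CG:CB", "HG2:CG", "HG3:CG", "SD:CG",
          "CE:SD", "HE1:CE", "HE2:CE", "HE3:CE"),
  PHE = c("CB:CA", "HB2:CB", "HB3:CB", "CG:CB", "CD1:CG", "HD1:CD1", "CD2:CG",
          "HD2:CD2", "CE1:CD1", "HE1:CE1", "CE2:CD2", "HE2:CE2", "CZ:CE1",
          "HZ:CZ"),
  PRO = c("CB:CA", "HB2:CB", "HB3:CB", "CG:CB", "HG2:CG", "HG3:CG", "CD:CG",
          "HD2:CD", "HD3:CD"),
  SER = c("CB:CA", "HB2:CB", "HB3:CB", "OG:CB", "HG:OG"),
  THR = c("CB:CA", "HB:CB", "OG1:CB", "HG1:OG1", "CG2:CB", "HG21:CG2",
          "HG22:CG2", "HG23:CG2"),
  TRP = c("CB:CA", "HB2:CB", "HB3:CB", "CG:CB", "CD1:CG", "HD1:CD1", "CD2:CG",
          "NE1:CD1", "HE1:NE1", "CE2:NE1", "CE3:CD2", "HE3:CE3", "CZ2:CE2",
          "HZ2:CZ2", "CZ3:CE3", "HZ3:CZ3", "CH2:CZ2", "HH2:CH2"),
  TYR = c("CB:CA", "HB2:CB", "HB3:CB", "CG:CB", "CD1:CG", "HD1:CD1", "CD2:CG",
          "HD2:CD2", "CE1:CD1", "HE1:CE1", "CE2:CD2", "HE2:CE2", "CZ:CE1",
          "OH:CZ", "HH:OH"),
  VAL = c("CB:CA", "HB:CB", "CG1:CB", "HG11:CG1", "HG12:CG1", "HG13:CG1",
          "CG2:CB", "HG21:CG2", "HG22:CG2", "HG23:CG2"))

.RING_CLOSURES <- list(
  HIS = list(c("NE2", "CD2")), PHE = list(c("CZ", "CE2")),
  TYR = list(c("CZ", "CE2")), PRO = list(c("CD", "N")),
  TRP = list(c("CE2", "CD2"), c("CH2", "CZ3")))

# charged sidechain groups of the toy parameter set (integers per residue)
.TOY_SIDECHAIN_CHARGES <- list(
  ASP = c(OD1 = -0.5, OD2 = -0.5), GLU = c(OE1 = -0.5, OE2 = -0.5),
  LYS = c(NZ = 1.0), ARG = c(CZ = 1.0))

.ELEMENT_MASS <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, H = 1.008)
.TOY_TYPES <- data.frame(
  name = c("Ctoy", "Ntoy", "Otoy", "Stoy", "Htoy", "OWtoy", "HWtoy", "MWtoy"),
  mass = c(12.011, 14.007, 15.999, 32.06, 1.008, 15.999, 1.008, 0),
  charge = 0,
  sigma = c(0.340, 0.325, 0.296, 0.356, 0.107, 0.3159, 0.0, 0.0),
  epsilon = c(0.360, 0.711, 0.880, 1.046, 0.0657, 0.7749, 0.0, 0.0),
  stringsAsFactors = FALSE)

.element_of <- function(atomname) {
  first <- substr(sub("^[0-9]+", "", toupper(atomname)), 1, 1)
  if (!first %in% names(.ELEMENT_MASS)) stop("cannot infer element of ", atomname)
  first
}

#' Build a chemically plausible toy topology from a sequence
#'
#' One protein molecule with correct atom names and connectivity for the
#' 20 standard residues (neutral termini), generic element-based
#' Lennard-Jones types, small backbone partial charges summing to the
#' residue's integer charge, and an n = 1 psi correction dihedral with
#' k = 2.0 kJ/mol on every non-C-terminal residue (mimicking the base
#' force field's correction term). A four-site water molecule (LJ on
#' oxygen only) is included, plus a `[ system ]`/`[ molecules ]` block.
#'
#' @param sequence 1-letter amino-acid string, e.g. `"AQA"`.
#' @param n_water Number of water copies declared in `[ molecules ]`.
#' @return An `ff_topology` that passes [validate_topology()].
#' @export
make_toy_topology <- function(sequence, n_water = 1) {
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  if (!length(letters1)) stop("sequence must be non-empty")
  res3 <- .AA3[letters1]
  if (anyNA(res3)) stop("unknown residue letter(s): ",
                        paste(unique(letters1[is.na(res3)]), collapse = ", "))

  topo <- ff_topology()
  topo$atomtypes <- .TOY_TYPES

  atoms <- list(); bonds <- list()
  idx <- 0L
  name2idx <- list()   # per-residue atom name -> global index
  add_atom <- function(resnr, resname, atomname, charge) {
    idx <<- idx + 1L
    el <- .element_of(atomname)
    atoms[[idx]] <<- data.frame(
      index = idx, type = paste0(el, "toy"), resnr = resnr, resname = resname,
      atomname = atomname, cgnr = resnr, charge = charge,
      mass = unname(.ELEMENT_MASS[el]), stringsAsFactors = FALSE)
    name2idx[[resnr]][[atomname]] <<- idx
    idx
  }
  add_bond <- function(i, j) bonds[[length(bonds) + 1L]] <<- c(i, j)

  prev_c <- NA_integer_
  for (r in seq_along(res3)) {
    rn <- res3[r]
    name2idx[[r]] <- list()
    scq <- .TOY_SIDECHAIN_CHARGES[[rn]]
    qn <- if (rn == "PRO") 0.0 else -0.4
    iN <- add_atom(r, rn, "N", qn)
    if (!is.na(prev_c)) add_bond(prev_c, iN)
    if (rn != "PRO") { iH <- add_atom(r, rn, "H", 0.4); add_bond(iN, iH) }
    iCA <- add_atom(r, rn, "CA", 0.1); add_bond(iN, iCA)
    if (rn == "GLY") {
      add_bond(iCA, add_atom(r, rn, "HA2", -0.05))
      add_bond(iCA, add_atom(r, rn, "HA3", -0.05))
    } else {
      add_bond(iCA, add_atom(r, rn, "HA", -0.1))
    }
    for (spec in .SIDECHAINS[[rn]]) {
      parts <- strsplit(spec, ":")[[1]]
      q <- if (!is.null(scq) && parts[1] %in% names(scq)) scq[[parts[1]]] else 0
      ia <- add_atom(r, rn, parts[1], q)
      add_bond(name2idx[[r]][[parts[2]]], ia)
    }
    for (cl in .RING_CLOSURES[[rn]])
      add_bond(name2idx[[r]][[cl[1]]], name2idx[[r]][[cl[2]]])
    iC <- add_atom(r, rn, "C", 0.5); add_bond(iCA, iC)
    iO <- add_atom(r, rn, "O", -0.5); add_bond(iC, iO)
    prev_c <- iC
  }

  mol <- .new_molecule("Protein", 3L)
  mol$atoms <- do.call(rbind, c(atoms, make.row.names = FALSE))
  bm <- do.call(rbind, bonds)
  mol$bonds <- data.frame(ai = bm[, 1], aj = bm[, 2], funct = 1L,
                          params_raw = NA_character_, stringsAsFactors = FALSE)
  # psi correction term (n = 1, k = 2.0 kJ/mol) on every non-terminal residue
  dh <- list()
  for (r in seq_len(length(res3) - 1)) {
    dh[[r]] <- data.frame(
      ai = name2idx[[r]][["N"]], aj = name2idx[[r]][["CA"]],
      ak = name2idx[[r]][["C"]], al = name2idx[[r + 1]][["N"]],
      funct = 1L, phase = 0.0, k = 2.0, mult = 1L, params_raw = NA_character_,
      stringsAsFactors = FALSE)
  }
  if (length(dh)) mol$dihedrals <- do.call(rbind, c(dh, make.row.names = FALSE))
  topo$molecules[["Protein"]] <- mol

  # four-site water: LJ on oxygen only, charges on H and the virtual site
  wat <- .new_molecule("SOL", 2L)
  wat$atoms <- data.frame(
    index = 1:4, type = c("OWtoy", "HWtoy", "HWtoy", "MWtoy"),
    resnr = 1L, resname = "SOL", atomname = c("OW", "HW1", "HW2", "MW"),
    cgnr = 1L, charge = c(0, 0.5564, 0.5564, -1.1128),
    mass = c(15.999, 1.008, 1.008, 0), stringsAsFactors = FALSE)
  wat$bonds <- data.frame(ai = c(1L, 1L, 1L), aj = c(2L, 3L, 4L), funct = 1L,
                          params_raw = NA_character_, stringsAsFactors = FALSE)
  topo$molecules[["SOL"]] <- wat

  topo$system_name <- "toy system"
  topo$system_molecules <- data.frame(name = c("Protein", "SOL"),
                                      count = c(1L, as.integer(n_water)),
                                      stringsAsFactors = FALSE)
  topo
}

#' Deterministic placeholder coordinates for a topology molecule
#'
#' Grows coordinates along the bond graph (each atom 0.12 nm from its
#' first-seen bonded parent in a pseudo-random direction), giving a
#' clash-free, reproducible configuration for energy-oracle checks. Not
#' a physical structure.
#'
#' @param topo An `ff_topology`. @param molecule Molecule name.
#' @param seed RNG seed.
#' @return N x 3 coordinate matrix (nm).
#' @export
toy_coords <- function(topo, molecule = "Protein", seed = 1) {
  mol <- topo$molecules[[molecule]]
  if (is.null(mol)) stop("unknown molecule: ", molecule)
  n <- nrow(mol$atoms)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  xyz <- matrix(NA_real_, n, 3)
  parent <- rep(NA_integer_, n)
  for (i in seq_len(nrow(mol$bonds))) {
    ai <- mol$bonds$ai[i]; aj <- mol$bonds$aj[i]
    if (is.na(parent[aj]) && aj != 1) parent[aj] <- ai
    if (is.na(parent[ai]) && ai != 1) parent[ai] <- aj
  }
  for (i in seq_len(n)) {
    if (i == 1 || is.na(parent[i]) || any(is.na(xyz[parent[i], ]))) {
      xyz[i, ] <- stats::runif(3, 0, 0.5) + (i - 1) * c(0.15, 0, 0)
    } else {
      repeat {
        d <- .unit3(stats::rnorm(3)) * 0.12
        cand <- xyz[parent[i], ] + d
        ok <- all(sqrt(rowSums(sweep(xyz[seq_len(i - 1), , drop = FALSE],
                                     2, cand)^2)) > 0.06)
        if (ok) { xyz[i, ] <- cand; break }
      }
    }
  }
  xyz
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

.BB_GEOM <- list(b_NCA = 0.1458, b_CAC = 0.1525, b_CN = 0.1329, b_CO = 0.1231,
                 a_CNCA = 121.7, a_NCAC = 111.2, a_CACN = 116.2, a_CACO = 120.8)

# Backbone chain growth at fixed (phi, psi, omega); N, CA, C, O per residue.
.build_backbone <- function(n_res, phi, psi, omega = 180) {
  g <- .BB_GEOM
  coords <- list(); meta <- list()
  add <- function(resid, name, p) {
    coords[[length(coords) + 1]] <<- p
    meta[[length(meta) + 1]] <<- c(resid, name)
  }
  N <- c(0, 0, 0)
  CA <- N + c(g$b_NCA, 0, 0)
  ang <- g$a_NCAC * pi / 180
  C <- CA + g$b_CAC * c(-cos(ang), sin(ang), 0)
  add(1, "N", N); add(1, "CA", CA); add(1, "C", C)
  prev <- list(N = N, CA = CA, C = C)
  for (r in seq_len(n_res)) {
    if (r < n_res) {
      Nn <- .place_atom(prev$N, prev$CA, prev$C, g$b_CN, g$a_CACN, psi)
      O <- .place_atom(Nn, prev$CA, prev$C, g$b_CO, g$a_CACO, 180)
      add(r, "O", O); add(r + 1, "N", Nn)
      CAn <- .place_atom(prev$CA, prev$C, Nn, g$b_NCA, g$a_CNCA, omega)
      add(r + 1, "CA", CAn)
      Cn <- .place_atom(prev$C, Nn, CAn, g$b_CAC, g$a_NCAC, phi)
      add(r + 1, "C", Cn)
      prev <- list(N = Nn, CA = CAn, C = Cn)
    } else {
      O <- .place_atom(prev$N, prev$CA, prev$C, g$b_CO, g$a_CACO, psi + 180)
      add(r, "O", O)
    }
  }
  m <- do.call(rbind, meta)
  ord <- order(as.integer(m[, 1]), match(m[, 2], c("N", "CA", "C", "O")))
  ff_frame(do.call(rbind, coords)[ord, ], m[ord, 2], as.integer(m[ord, 1]), "ALA")
}

#' Ideal alpha-helix backbone coordinates
#'
#' Backbone (N, CA, C, O) built by internal-coordinate chain growth at
#' phi = -57, psi = -47, omega = 180 degrees with ideal bond lengths and
#' angles.
#'
#' @param n_res Number of residues (>= 4).
#' @return An [ff_frame()].
#' @export
ideal_helix_coords <- function(n_res) {
  stopifnot(n_res >= 4)
  .build_backbone(n_res, phi = -57, psi = -47)
}

#' Fully extended backbone coordinates
#'
#' As [ideal_helix_coords()] but at phi = psi = 180 degrees.
#'
#' @param n_res Number of residues (>= 4).
#' @return An [ff_frame()].
#' @export
extended_coords <- function(n_res) {
  stopifnot(n_res >= 4)
  .build_backbone(n_res, phi = 180, psi = 180)
}

#' Freely jointed (Gaussian) chain ensembles
#'
#' Beads connected by fixed-length bonds in i.i.d. uniform random
#' directions; the ensemble mean squared radius of gyration approaches
#' `n b^2 / 6` for long chains.
#'
#' @param n_beads Beads per chain (>= 2).
#' @param bond_length Bond length b in nm.
#' @param n_chains Number of independent chains.
#' @param seed RNG seed (deterministic output).
#' @return An `ff_trajectory` with one frame per chain.
#' @export
gaussian_chain <- function(n_beads, bond_length, n_chains = 1, seed = 1) {
  stopifnot(n_beads >= 2)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  frames <- lapply(seq_len(n_chains), function(k) {
    z <- stats::runif(n_beads - 1, -1, 1)
    phi <- stats::runif(n_beads - 1, 0, 2 * pi)
    s <- sqrt(1 - z^2)
    steps <- bond_length * cbind(s * cos(phi), s * sin(phi), z)
    rbind(c(0, 0, 0), apply(steps, 2, cumsum))
  })
  ff_trajectory(frames, atomname = "CA", resid = seq_len(n_beads), resname = "GLY")
}

#' Rigid-body tumbling trajectory
#'
#' Applies an independent uniform (Haar) random rotation to the whole
#' frame in every trajectory frame: no internal motion, only global
#' reorientation.
#'
#' @param frame An [ff_frame()].
#' @param n_frames Number of frames (>= 10).
#' @param seed RNG seed.
#' @return An `ff_trajectory`.
#' @export
rigid_tumbling_trajectory <- function(frame, n_frames, seed = 1) {
  stopifnot(inherits(frame, "ff_frame"), n_frames >= 10)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ctr <- colMeans(frame$xyz)
  base <- sweep(frame$xyz, 2, ctr)
  frames <- lapply(seq_len(n_frames), function(f) base %*% t(.random_rotation()))
  ff_trajectory(frames, frame$atomname, frame$resid, frame$resname, frame$mass)
}

#' Tumbling trajectory with per-residue N-H wobble in a cone
#'
#' As [rigid_tumbling_trajectory()], but in every frame each residue's
#' amide hydrogen is additionally repositioned so the N-H vector is
#' drawn uniformly within a cone of the given semi-angle about its
#' reference direction (the equilibrium distribution of
#' diffusion-in-cone, for which `S = cos(theta)(1+cos(theta))/2`).
#'
#' @param frame An [ff_frame()] containing N and H atoms per residue.
#' @param cone_semiangle_deg Cone semi-angle in degrees (0 = pure
#'   tumbling).
#' @param n_frames Number of frames (>= 10).
#' @param seed RNG seed.
#' @return An `ff_trajectory`.
#' @export
wobble_trajectory <- function(frame, cone_semiangle_deg, n_frames, seed = 1) {
  stopifnot(inherits(frame, "ff_frame"), n_frames >= 10)
  theta <- cone_semiangle_deg * pi / 180
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ctr <- colMeans(frame$xyz)
  base <- sweep(frame$xyz, 2, ctr)
  resids <- unique(frame$resid)
  iN <- iH <- integer(0)
  for (r in resids) {
    jn <- which(frame$resid == r & toupper(frame$atomname) == "N")
    jh <- which(frame$resid == r & toupper(frame$atomname) %in% c("H", "HN"))
    if (length(jn) == 1 && length(jh) == 1) { iN <- c(iN, jn); iH <- c(iH, jh) }
  }
  refdir <- lapply(seq_along(iN), function(k)
    .unit3(base[iH[k], ] - base[iN[k], ]))
  blen <- vapply(seq_along(iN), function(k)
    .norm3(base[iH[k], ] - base[iN[k], ]), 0)
  frames <- lapply(seq_len(n_frames), function(f) {
    x <- base
    if (theta > 0) {
      for (k in seq_along(iN)) {
        v <- .sample_in_cone(refdir[[k]], theta)
        x[iH[k], ] <- x[iN[k], ] + blen[k] * v
      }
    }
    x %*% t(.random_rotation())
  })
  ff_trajectory(frames, frame$atomname, frame$resid, frame$resname, frame$mass)
}
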