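# Cutoff-free single-point energy oracle. This is a verifier for
# topology transformations, not a simulation engine: direct double sums,
# no periodic boundary conditions, no cutoffs, no PME.

# Coulomb prefactor 1/(4 pi eps0) in kJ mol^-1 nm e^-2
.KE <- 138.935458

#' Lennard-Jones 12-6 pair energy
#'
#' `4 * epsilon * ((sigma/r)^12 - (sigma/r)^6)`; zero at `r = sigma`,
#' minimum `-epsilon` at `r = 2^(1/6) sigma`.
#'
#' @param sigma nm. @param epsilon kJ/mol. @param r Separation in nm (> 0).
#' @return Energy in kJ/mol (vectorized over `r`).
#' @export
lj_pair_energy <- function(sigma, epsilon, r) {
  if (any(r <= 0)) stop("lj_pair_energy: r must be > 0")
  sr6 <- (sigma / r)^6
  4 * epsilon * (sr6 * sr6 - sr6)
}

#' Proper-dihedral (cosine) energy
#'
#' `k * (1 + cos(n * phi - delta))`.
#'
#' @param k Force constant, kJ/mol.
#' @param n Multiplicity (integer >= 1).
#' @param delta_deg Phase, degrees.
#' @param phi_deg Torsion angle, degrees.
#' @return Energy in kJ/mol (vectorized over `phi_deg`).
#' @export
dihedral_energy <- function(k, n, delta_deg, phi_deg) {
  if (any(n < 1)) stop("dihedral multiplicity must be >= 1")
  k * (1 + cos((n * phi_deg - delta_deg) * pi / 180))
}

#' Build a configuration: coordinates bound to topology molecules
#'
#' Expands the per-molecule atom tables into one flat atom list in the
#' order given by `counts`, and attaches Cartesian coordinates.
#'
#' @param topo An `ff_topology`.
#' @param counts Named integer vector: molecule name -> number of copies,
#'   in system order (defaults to the topology's `[ molecules ]` section).
#' @param coords N x 3 matrix (nm), N = total atoms over all copies.
#' @return An object of class `ff_configuration`.
#' @export
make_configuration <- function(topo, counts = NULL, coords) {
  stopifnot(inherits(topo, "ff_topology"))
  if (is.null(counts)) {
    if (is.null(topo$system_molecules))
      stop("no counts given and topology has no [ molecules ] section")
    counts <- setNames(topo$system_molecules$count, topo$system_molecules$name)
  }
  rows <- list()
  inst <- 0L
  for (i in seq_along(counts)) {
    mn <- names(counts)[i]
    mol <- topo$molecules[[mn]]
    if (is.null(mol)) stop("unknown molecule in counts: ", mn)
    for (k in seq_len(counts[i])) {
      inst <- inst + 1L
      a <- mol$atoms
      rows[[inst]] <- data.frame(
        molecule = mn, instance = inst, local_index = a$index,
        type = a$type, atomname = a$atomname, resname = a$resname,
        resnr = a$resnr, charge = .atom_charges(topo, mol),
        mass = .atom_masses(topo, mol), stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, c(rows, make.row.names = FALSE))
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 3 || nrow(coords) != nrow(atoms))
    stop("coords must be a numeric ", nrow(atoms), " x 3 matrix")
  if (any(!is.finite(coords))) stop("non-finite coordinates")
  structure(list(topo = topo, atoms = atoms, coords = coords),
            class = "ff_configuration")
}

# Bond-graph distances up to 3 within one molecule: returns list with
# excl (matrix of i,j pairs at graph distance 1 or 2) and pairs14
# (distance exactly 3), local indices.
.bonded_neighborhoods <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  for (i in seq_len(nrow(mol$bonds))) {
    ai <- mol$bonds$ai[i]; aj <- mol$bonds$aj[i]
    adj[[ai]] <- c(adj[[ai]], aj); adj[[aj]] <- c(adj[[aj]], ai)
  }
  d12 <- list(); d13 <- list(); d14 <- list()
  for (i in seq_len(n)) {
    n1 <- unique(adj[[i]])
    n2 <- setdiff(unique(unlist(adj[n1])), c(i, n1))
    n3 <- setdiff(unique(unlist(adj[n2])), c(i, n1, n2))
    d12[[i]] <- n1[n1 > i]; d13[[i]] <- n2[n2 > i]; d14[[i]] <- n3[n3 > i]
  }
  mk <- function(lst) {
    if (!length(unlist(lst))) return(matrix(integer(0), ncol = 2))
    cbind(rep(seq_len(n), lengths(lst)), unlist(lst))
  }
  list(excl = rbind(mk(d12), mk(d13)), pairs14 = mk(d14))
}

#' Cutoff-free single-point energy
#'
#' Direct double sum over all atom pairs. Intramolecular 1-2 and 1-3
#' pairs (from the bond graph) are excluded; 1-4 pairs are scaled by the
#' fudge factors of the `[ defaults ]` directive. Coulomb uses
#' `q_i q_j / (4 pi eps0 r_ij)`; dihedral energy sums the explicit
#' proper terms (funct 1, 4, 9).
#'
#' @param topo An `ff_topology` (must match the configuration's).
#' @param config An [make_configuration()] object.
#' @param terms Subset of `c("lj", "coulomb", "dihedral")`.
#' @return Named numeric vector of the requested term energies plus
#'   `total`, in kJ/mol.
#' @export
total_energy <- function(topo, config,
                         terms = c("lj", "coulomb", "dihedral")) {
  stopifnot(inherits(config, "ff_configuration"))
  terms <- match.arg(terms, several.ok = TRUE)
  atoms <- config$atoms
  xyz <- config$coords
  n <- nrow(atoms)
  at <- topo$atomtypes
  ti <- match(atoms$type, at$name)
  if (anyNA(ti)) stop("configuration references atom types absent from topology")
  sig <- at$sigma[ti]; eps <- at$epsilon[ti]; q <- atoms$charge

  # pair scale matrix: 1 = full, 0 = excluded, fudge = 1-4
  scale_lj <- matrix(1, n, n)
  scale_qq <- matrix(1, n, n)
  for (inst in unique(atoms$instance)) {
    sel <- which(atoms$instance == inst)
    mol <- topo$molecules[[atoms$molecule[sel[1]]]]
    nh <- .bonded_neighborhoods(mol)
    if (nrow(nh$excl)) {
      ij <- cbind(sel[nh$excl[, 1]], sel[nh$excl[, 2]])
      scale_lj[ij] <- 0; scale_lj[ij[, 2:1, drop = FALSE]] <- 0
      scale_qq[ij] <- 0; scale_qq[ij[, 2:1, drop = FALSE]] <- 0
    }
    if (nrow(nh$pairs14)) {
      ij <- cbind(sel[nh$pairs14[, 1]], sel[nh$pairs14[, 2]])
      scale_lj[ij] <- topo$defaults$fudge_lj
      scale_lj[ij[, 2:1, drop = FALSE]] <- topo$defaults$fudge_lj
      scale_qq[ij] <- topo$defaults$fudge_qq
      scale_qq[ij[, 2:1, drop = FALSE]] <- topo$defaults$fudge_qq
    }
  }

  # pairwise LJ parameters, honouring nonbonded overrides
  rule <- topo$defaults$comb_rule
  SIG <- if (rule == "lorentz_berthelot") outer(sig, sig, "+") / 2
         else sqrt(outer(sig, sig))
  EPS <- sqrt(outer(eps, eps))
  nb <- topo$nonbond_params
  if (!is.null(nb) && nrow(nb)) {
    for (k in seq_len(nrow(nb))) {
      ia <- which(atoms$type == nb$type_a[k])
      ib <- which(atoms$type == nb$type_b[k])
      if (length(ia) && length(ib)) {
        SIG[ia, ib] <- nb$sigma[k]; SIG[ib, ia] <- nb$sigma[k]
        EPS[ia, ib] <- nb$epsilon[k]; EPS[ib, ia] <- nb$epsilon[k]
      }
    }
  }

  D <- as.matrix(stats::dist(xyz))
  up <- upper.tri(D)
  active <- up & (scale_lj > 0 | scale_qq > 0)
  if (any(D[active] < 1e-6))
    stop("overlapping atoms (separation < 1e-6 nm) in configuration")

  out <- c()
  if ("lj" %in% terms) {
    sr6 <- (SIG[up] / D[up])^6
    elj <- 4 * EPS[up] * (sr6 * sr6 - sr6) * scale_lj[up]
    elj[scale_lj[up] == 0] <- 0
    out["lj"] <- sum(elj)
  }
  if ("coulomb" %in% terms) {
    eqq <- .KE * outer(q, q)[up] / D[up] * scale_qq[up]
    eqq[scale_qq[up] == 0] <- 0
    out["coulomb"] <- sum(eqq)
  }
  if ("dihedral" %in% terms) {
    e <- 0
    for (inst in unique(atoms$instance)) {
      sel <- which(atoms$instance == inst)
      mol <- topo$molecules[[atoms$molecule[sel[1]]]]
      dh <- mol$dihedrals
      prop <- which(dh$funct %in% c(1L, 4L, 9L) & !is.na(dh$k))
      for (i in prop) {
        p <- xyz[sel[c(dh$ai[i], dh$aj[i], dh$ak[i], dh$al[i])], , drop = FALSE]
        phi <- dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ])
        e <- e + dihedral_energy(dh$k[i], dh$mult[i], dh$phase[i], phi)
      }
    }
    out["dihedral"] <- e
  }
  out["total"] <- sum(out)
  out
}
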