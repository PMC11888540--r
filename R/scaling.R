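#' Define a protein-water Lennard-Jones scaling scheme
#'
#' Which protein atoms get strengthened interactions with the water
#' oxygen, and by how much. Modes:
#' \describe{
#'   \item{ALL}{every protein atom (the original uniform scaling).}
#'   \item{BACKBONE}{backbone heavy atoms only (no hydrogens).}
#'   \item{SIDECHAIN_ALL}{all sidechain atoms of every residue except
#'     glycine (which has no sidechain).}
#'   \item{SIDECHAIN_UNCHARGED}{sidechain atoms of residues that are not
#'     glycine and not in `charged_residues`.}
#' }
#' `gamma` multiplies the combination-rule epsilon of each selected
#' protein-atom / water-oxygen pair; `gamma = 1.10` is the canonical
#' "10 percent" strengthening of protein hydration.
#'
#' @param mode One of `"ALL"`, `"BACKBONE"`, `"SIDECHAIN_ALL"`,
#'   `"SIDECHAIN_UNCHARGED"`.
#' @param gamma Dimensionless factor on epsilon, > 0.
#' @param water_oxygen_type Atom-type token of the water oxygen; `NULL`
#'   to auto-detect (the type of an atom named OW in a water residue).
#' @param charged_residues Residue names whose sidechains are excluded in
#'   `SIDECHAIN_UNCHARGED` mode.
#' @param clone_suffix Suffix appended to atom-type names cloned to
#'   realize selective scaling.
#' @return An object of class `scaling_scheme`.
#' @export
scaling_scheme <- function(mode = c("ALL", "BACKBONE", "SIDECHAIN_ALL",
                                    "SIDECHAIN_UNCHARGED"),
                           gamma = 1.10, water_oxygen_type = NULL,
                           charged_residues = .CHARGED_RESIDUES,
                           clone_suffix = "_sc") {
  mode <- match.arg(mode)
  stopifnot(is.numeric(gamma), length(gamma) == 1, gamma > 0)
  structure(list(mode = mode, gamma = gamma,
                 water_oxygen_type = water_oxygen_type,
                 charged_residues = toupper(charged_residues),
                 clone_suffix = clone_suffix),
            class = "scaling_scheme")
}

#' @export
print.scaling_scheme <- function(x, ...) {
  cat(sprintf("<scaling_scheme> mode=%s gamma=%.4f\n", x$mode, x$gamma))
  invisible(x)
}

# Molecules containing at least one protein residue.
.protein_molecules <- function(topo) {
  names(topo$molecules)[vapply(topo$molecules, function(m)
    any(.is_protein_residue(m$atoms$resname)), logical(1))]
}

#' Select the atoms targeted by a scaling scheme
#'
#' @param topo An `ff_topology` containing at least one protein molecule.
#' @param scheme A [scaling_scheme()].
#' @return data.frame with columns `molecule`, `index`, `atomname`,
#'   `resname`, `resnr`, `type` listing every targeted atom. May have
#'   zero rows (e.g. sidechain scaling of a pure-glycine chain).
#' @export
select_scaling_targets <- function(topo, scheme) {
  stopifnot(inherits(topo, "ff_topology"), inherits(scheme, "scaling_scheme"))
  prot <- .protein_molecules(topo)
  if (!length(prot)) stop("topology contains no protein molecule to scale")
  out <- list()
  for (mn in prot) {
    a <- topo$molecules[[mn]]$atoms
    cls <- classify_atom(a$atomname, a$resname)
    canon <- .canonical_residue(a$resname)
    sel <- switch(scheme$mode,
      ALL = cls %in% c("BACKBONE", "SIDECHAIN"),
      BACKBONE = cls == "BACKBONE" & toupper(a$atomname) %in% .BACKBONE_HEAVY,
      SIDECHAIN_ALL = cls == "SIDECHAIN" & canon != "GLY",
      SIDECHAIN_UNCHARGED = cls == "SIDECHAIN" & canon != "GLY" &
        !(toupper(a$resname) %in% scheme$charged_residues))
    if (any(sel))
      out[[mn]] <- data.frame(molecule = mn, index = a$index[sel],
                              atomname = a$atomname[sel], resname = a$resname[sel],
                              resnr = a$resnr[sel], type = a$type[sel],
                              stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, c(out, make.row.names = FALSE))
  else data.frame(molecule = character(0), index = integer(0),
                  atomname = character(0), resname = character(0),
                  resnr = integer(0), type = character(0), stringsAsFactors = FALSE)
}

#' Combine Lennard-Jones parameters for an atom-type pair
#'
#' Lorentz-Berthelot: sigma is the arithmetic mean, epsilon the geometric
#' mean. Geometric: both are geometric means.
#'
#' @param sigma_a,epsilon_a,sigma_b,epsilon_b Per-type parameters
#'   (nm, kJ/mol); must be non-negative.
#' @param rule `"lorentz_berthelot"` or `"geometric"`.
#' @return Named numeric vector `c(sigma=, epsilon=)`.
#' @export
combine_lj <- function(sigma_a, epsilon_a, sigma_b, epsilon_b,
                       rule = c("lorentz_berthelot", "geometric")) {
  rule <- match.arg(rule)
  if (any(c(sigma_a, sigma_b, epsilon_a, epsilon_b) < 0))
    stop("negative sigma or epsilon in combination rule")
  if (rule == "lorentz_berthelot")
    c(sigma = (sigma_a + sigma_b) / 2, epsilon = sqrt(epsilon_a * epsilon_b))
  else
    c(sigma = sqrt(sigma_a * sigma_b), epsilon = sqrt(epsilon_a * epsilon_b))
}

# Find the water oxygen atom type (atom named OW/O in a water residue).
.find_water_oxygen_type <- function(topo) {
  for (mol in topo$molecules) {
    a <- mol$atoms
    w <- .is_water_residue(a$resname) & toupper(a$atomname) %in% c("OW", "O")
    if (any(w)) return(a$type[which(w)[1]])
  }
  stop("no recognized water molecule (atom OW in a water residue) in topology")
}

#' Apply selective protein-water Lennard-Jones scaling
#'
#' Realizes a [scaling_scheme()] on a topology. For every targeted atom
#' whose atom type is shared with non-targeted atoms, a cloned atom type
#' (identical mass, charge, sigma, epsilon; name suffixed) is created and
#' the targeted atoms re-typed. For every distinct targeted type T a
#' `[ nonbond_params ]` override (T, water oxygen) is emitted with the
#' combination-rule sigma and epsilon multiplied by `gamma`. No other
#' interaction is touched: protein-protein, water-water and
#' non-targeted-protein-water pairs evaluate identically before and
#' after (charges are never modified, so Coulomb terms are invariant).
#'
#' @param topo An `ff_topology`.
#' @param scheme A [scaling_scheme()].
#' @param force Replace a pre-existing override on a targeted
#'   (type, water-oxygen) pair instead of failing.
#' @return A new `ff_topology`; attribute `"scaling_log"` carries a list
#'   with `cloned_types` (named character, clone -> parent) and
#'   `overrides` (data.frame of pairs written).
#' @export
apply_water_scaling <- function(topo, scheme, force = FALSE) {
  stopifnot(inherits(topo, "ff_topology"), inherits(scheme, "scaling_scheme"))
  ow <- scheme$water_oxygen_type
  if (is.null(ow)) ow <- .find_water_oxygen_type(topo)
  if (!ow %in% topo$atomtypes$name)
    stop("water oxygen type '", ow, "' not found in [ atomtypes ]")

  targets <- select_scaling_targets(topo, scheme)
  if (!nrow(targets))
    stop("scaling scheme ", scheme$mode, " selects no atoms in this topology")

  # which types are shared with non-targeted atoms anywhere in the system
  target_key <- paste(targets$molecule, targets$index)
  type_has_nontarget <- setNames(logical(nrow(topo$atomtypes)), topo$atomtypes$name)
  for (mn in names(topo$molecules)) {
    a <- topo$molecules[[mn]]$atoms
    non <- !(paste(mn, a$index) %in% target_key)
    for (tp in unique(a$type[non])) type_has_nontarget[tp] <- TRUE
  }

  cloned <- character(0)   # clone name -> parent name
  at <- topo$atomtypes
  for (tp in unique(targets$type)) {
    if (!type_has_nontarget[tp]) next
    clone <- paste0(tp, scheme$clone_suffix)
    if (clone %in% at$name || clone %in% names(cloned))
      stop("clone type name collision: ", clone)
    row <- at[at$name == tp, , drop = FALSE]
    row$name <- clone
    at <- rbind(at, row)
    cloned[clone] <- tp
  }
  topo$atomtypes <- at

  # re-type targeted atoms whose type was cloned
  retype <- if (length(cloned)) setNames(names(cloned), unname(cloned))
            else setNames(character(0), character(0))  # parent -> clone
  for (mn in unique(targets$molecule)) {
    a <- topo$molecules[[mn]]$atoms
    sel <- paste(mn, a$index) %in% target_key & a$type %in% names(retype)
    a$type[sel] <- retype[a$type[sel]]
    topo$molecules[[mn]]$atoms <- a
  }

  # emit one override per distinct (possibly cloned) targeted type
  final_types <- unique(ifelse(targets$type %in% names(retype),
                               retype[targets$type], targets$type))
  owrow <- at[at$name == ow, ]
  written <- list()
  for (tp in final_types) {
    trow <- at[at$name == tp, ]
    cmb <- combine_lj(trow$sigma, trow$epsilon, owrow$sigma, owrow$epsilon,
                      topo$defaults$comb_rule)
    existing <- .lookup_override(topo, tp, ow)
    if (!is.null(existing)) {
      if (!force)
        stop("pre-existing nonbonded override on (", tp, ", ", ow,
             "); use force = TRUE to replace it")
      keys <- .pair_key(topo$nonbond_params$type_a, topo$nonbond_params$type_b)
      topo$nonbond_params <- topo$nonbond_params[keys != .pair_key(tp, ow), ]
      message("replaced existing override on (", tp, ", ", ow, ")")
    }
    topo$nonbond_params <- rbind(topo$nonbond_params, data.frame(
      type_a = tp, type_b = ow, sigma = unname(cmb["sigma"]),
      epsilon = scheme$gamma * unname(cmb["epsilon"]), stringsAsFactors = FALSE))
    written[[tp]] <- data.frame(type = tp, water_type = ow,
                                sigma = unname(cmb["sigma"]),
                                epsilon = scheme$gamma * unname(cmb["epsilon"]),
                                stringsAsFactors = FALSE)
  }
  rownames(topo$atomtypes) <- NULL
  rownames(topo$nonbond_params) <- NULL
  attr(topo, "scaling_log") <- list(
    scheme = scheme, cloned_types = cloned,
    overrides = do.call(rbind, c(written, make.row.names = FALSE)),
    n_targets = nrow(targets))
  topo
}

#' Repartition hydrogen masses onto bonded heavy atoms
#'
#' Sets every protein hydrogen's mass to `h_mass` and subtracts the
#' difference from the single heavy atom it is bonded to, so each
#' molecule's total mass is conserved exactly. Water (and any
#' non-protein molecule) is untouched. Hydrogens are identified by atom
#' name (leading H, ignoring digits) and a mass below 3.5 amu.
#'
#' @param topo An `ff_topology`.
#' @param h_mass Target hydrogen mass in amu (> 0); 1.5 amu supports a
#'   4 fs integration timestep.
#' @return A new `ff_topology` with explicit per-atom masses on modified
#'   molecules.
#' @export
repartition_hydrogen_masses <- function(topo, h_mass = 1.5) {
  stopifnot(inherits(topo, "ff_topology"), h_mass > 0)
  for (mn in .protein_molecules(topo)) {
    mol <- topo$molecules[[mn]]
    a <- mol$atoms
    mass <- .atom_masses(topo, mol)
    nm <- toupper(sub("^[0-9]+", "", a$atomname))
    is_h <- startsWith(nm, "H") & mass < 3.5 & mass > 0
    if (!any(is_h)) next
    # adjacency from bonds
    nb <- vector("list", nrow(a))
    for (i in seq_len(nrow(mol$bonds))) {
      ai <- mol$bonds$ai[i]; aj <- mol$bonds$aj[i]
      nb[[ai]] <- c(nb[[ai]], aj); nb[[aj]] <- c(nb[[aj]], ai)
    }
    for (h in which(is_h)) {
      heavy <- setdiff(nb[[a$index[h]]], a$index[is_h])
      if (length(nb[[a$index[h]]]) != 1 || length(heavy) != 1)
        stop("hydrogen ", a$atomname[h], " (index ", a$index[h], ") in ", mn,
             " is not bonded to exactly one heavy atom")
      hi <- match(heavy, a$index)
      delta <- h_mass - mass[h]
      if (mass[hi] - delta <= 0)
        stop("repartitioning would make heavy atom ", a$atomname[hi],
             " mass non-positive")
      mass[h] <- h_mass
      mass[hi] <- mass[hi] - delta
    }
    a$mass <- mass
    mol$atoms <- a
    topo$molecules[[mn]] <- mol
  }
  topo
}
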