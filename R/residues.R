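# Residue and atom-name knowledge shared by classification, scaling and
# the fixture generators.

.AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
          E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
          M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
          Y = "TYR", V = "VAL")

# protonation / naming variants mapped to a canonical parent
.RESIDUE_ALIASES <- c(
  HID = "HIS", HIE = "HIS", HIP = "HIS", HSD = "HIS", HSE = "HIS", HSP = "HIS",
  CYX = "CYS", CYM = "CYS", ASH = "ASP", GLH = "GLU", LYN = "LYS", TYM = "TYR",
  NLE = "LEU")

.PROTEIN_RESIDUES <- c(unname(.AA3), names(.RESIDUE_ALIASES))
.WATER_RESIDUES <- c("SOL", "HOH", "WAT", "TIP3", "TIP4", "T4P", "SPC", "T3P")
.ION_RESIDUES <- c("NA", "CL", "K", "MG", "CA2", "ZN", "NA+", "CL-",
                   "SOD", "CLA", "POT", "CAL")

# Default set of charged residues: Asp/Glu carboxylates, Lys/Arg, the
# doubly protonated His forms, and deprotonated Cys/Tyr variants.
# Neutral His tautomers and protonated Asp/Glu (ASH/GLH) are uncharged.
.CHARGED_RESIDUES <- c("ASP", "GLU", "LYS", "ARG", "HIP", "HSP", "CYM", "TYM")

.BACKBONE_ATOMS <- c("N", "H", "HN", "H1", "H2", "H3", "CA", "HA", "HA1",
                     "HA2", "HA3", "C", "O", "OXT", "OC1", "OC2", "OT1", "OT2")
.BACKBONE_HEAVY <- c("N", "CA", "C", "O", "OXT", "OC1", "OC2", "OT1", "OT2")

.canonical_residue <- function(resname) {
  resname <- toupper(resname)
  hit <- .RESIDUE_ALIASES[resname]
  ifelse(is.na(hit), resname, hit)
}

.is_protein_residue <- function(resname) toupper(resname) %in% .PROTEIN_RESIDUES
.is_water_residue <- function(resname) toupper(resname) %in% .WATER_RESIDUES
.is_ion_residue <- function(resname) toupper(resname) %in% .ION_RESIDUES

#' Classify an atom as backbone, sidechain, water, ion or other
#'
#' Protein atoms partition exactly into backbone and sidechain. The
#' backbone set is the peptide unit N, H (incl. terminal H1-H3), CA, HA
#' (HA2/HA3 for glycine), C, O and terminal carboxylate oxygens; every
#' other atom of a protein residue is sidechain. Water and common
#' monatomic ions are classified as such; an unrecognized residue yields
#' `"OTHER"` with a warning so it can never be scaled silently.
#'
#' @param atom_name Atom name(s), e.g. `"CA"`.
#' @param residue_name Residue name(s), 3-letter, recycled against
#'   `atom_name`.
#' @return Character vector in
#'   `c("BACKBONE","SIDECHAIN","WATER","ION","OTHER")`.
#' @examples
#' classify_atom("CA", "ALA")   # BACKBONE
#' classify_atom("CB", "GLN")   # SIDECHAIN
#' classify_atom("OW", "SOL")   # WATER
#' @export
classify_atom <- function(atom_name, residue_name) {
  n <- max(length(atom_name), length(residue_name))
  atom_name <- rep_len(toupper(atom_name), n)
  residue_name <- rep_len(toupper(residue_name), n)
  out <- character(n)
  water <- .is_water_residue(residue_name)
  ion <- .is_ion_residue(residue_name)
  prot <- .is_protein_residue(residue_name)
  out[water] <- "WATER"
  out[ion & !water] <- "ION"
  bb <- prot & atom_name %in% .BACKBONE_ATOMS
  out[bb] <- "BACKBONE"
  out[prot & !bb] <- "SIDECHAIN"
  unknown <- !water & !ion & !prot
  if (any(unknown)) {
    warning("unrecognized residue(s) classified as OTHER: ",
            paste(unique(residue_name[unknown]), collapse = ", "))
    out[unknown] <- "OTHER"
  }
  out
}
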