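#' Residue-specific psi force-constant presets
#'
#' A preset maps residue names to the force constant (kJ/mol) of the
#' n = 1 psi-torsion correction term. Built-in presets:
#' \describe{
#'   \item{BASE}{Ser, Thr, Gln at 2.0 kJ/mol (the unmodified correction).}
#'   \item{STQ}{Ser, Thr, Gln reduced to 1.0 kJ/mol, weakening the
#'     helical bias of the base parameterization.}
#'   \item{STQ_PRIME}{Ser and Thr at 1.0 kJ/mol, Gln at 1.5 kJ/mol — the
#'     intermediate glutamine value that balances helicity in
#'     polyglutamine stretches.}
#' }
#'
#' @param name `"BASE"`, `"STQ"`, `"STQ_PRIME"`, or `"custom"` with an
#'   explicit `k_map`.
#' @param k_map Named numeric vector, residue 3-letter token -> k_psi in
#'   kJ/mol (all > 0). Overrides/extends the named preset.
#' @return An object of class `torsion_preset`.
#' @export
torsion_preset <- function(name = c("BASE", "STQ", "STQ_PRIME", "custom"),
                           k_map = NULL) {
  name <- match.arg(name)
  base <- switch(name,
    BASE = c(SER = 2.0, THR = 2.0, GLN = 2.0),
    STQ = c(SER = 1.0, THR = 1.0, GLN = 1.0),
    STQ_PRIME = c(SER = 1.0, THR = 1.0, GLN = 1.5),
    custom = c())
  if (!is.null(k_map)) {
    stopifnot(is.numeric(k_map), !is.null(names(k_map)))
    base[toupper(names(k_map))] <- k_map
  }
  if (!length(base)) stop("custom preset requires a k_map")
  if (any(base <= 0)) stop("k_psi values must be > 0")
  structure(list(name = name, k_map = base), class = "torsion_preset")
}

#' @export
print.torsion_preset <- function(x, ...) {
  cat(sprintf("<torsion_preset> %s: %s\n", x$name,
              paste(sprintf("%s=%.2f", names(x$k_map), x$k_map), collapse = " ")))
  invisible(x)
}

#' Locate psi backbone dihedrals for chosen residue types
#'
#' The psi torsion of residue i is N(i)-CA(i)-C(i)-N(i+1); C-terminal
#' residues have no psi. Matching is by atom name across consecutive
#' residues (alias-aware residue names), independent of the order of
#' dihedral lines in the file.
#'
#' @param topo An `ff_topology`.
#' @param residues Residue 3-letter tokens to match (e.g. `c("GLN")`).
#' @return data.frame with columns `molecule`, `resnr`, `resname`,
#'   `dihedral_row` (row number in that molecule's dihedral table),
#'   `ai,aj,ak,al`. Rows only for psi quadruples present in the dihedral
#'   table; a requested residue with a missing backbone atom is an error.
#' @export
find_psi_dihedrals <- function(topo, residues) {
  stopifnot(inherits(topo, "ff_topology"))
  residues <- toupper(residues)
  out <- list()
  for (mn in .protein_molecules(topo)) {
    mol <- topo$molecules[[mn]]
    a <- mol$atoms
    resnrs <- sort(unique(a$resnr[.is_protein_residue(a$resname)]))
    for (r in resnrs) {
      rname <- a$resname[a$resnr == r][1]
      if (!(.canonical_residue(rname) %in% .canonical_residue(residues) |
            toupper(rname) %in% residues)) next
      if (!(r + 1) %in% resnrs) next  # C-terminal: no following N
      pick <- function(resnr, name) {
        i <- a$index[a$resnr == resnr & toupper(a$atomname) == name]
        if (length(i) != 1)
          stop("residue ", rname, " ", r, " in ", mn,
               ": backbone atom ", name, " of residue ", resnr,
               " missing or duplicated")
        i
      }
      q <- c(pick(r, "N"), pick(r, "CA"), pick(r, "C"), pick(r + 1, "N"))
      dh <- mol$dihedrals
      hit <- which((dh$ai == q[1] & dh$aj == q[2] & dh$ak == q[3] & dh$al == q[4]) |
                   (dh$ai == q[4] & dh$aj == q[3] & dh$ak == q[2] & dh$al == q[1]))
      for (h in hit)
        out[[length(out) + 1]] <- data.frame(
          molecule = mn, resnr = r, resname = rname, dihedral_row = h,
          ai = q[1], aj = q[2], ak = q[3], al = q[4], stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, c(out, make.row.names = FALSE))
  else data.frame(molecule = character(0), resnr = integer(0),
                  resname = character(0), dihedral_row = integer(0),
                  ai = integer(0), aj = integer(0), ak = integer(0),
                  al = integer(0), stringsAsFactors = FALSE)
}

#' Set psi force constants according to a preset
#'
#' For every matched psi quadruple of a residue type in the preset, the
#' n = 1 proper term's force constant is replaced by the preset value;
#' phase and multiplicity are preserved exactly, and every other
#' dihedral term — including other multiplicities on the same quadruple —
#' is untouched. The transformation is idempotent.
#'
#' A residue of a requested type whose psi quadruple carries no explicit
#' n = 1 proper term is a hard error: the correction term being refined
#' must exist in the base topology (shared `[ dihedraltypes ]`-only
#' parameters cannot be modified per residue).
#'
#' @param topo An `ff_topology`.
#' @param preset A [torsion_preset()].
#' @return A new `ff_topology`; attribute `"torsion_log"` lists the
#'   modified terms (`molecule`, `resnr`, `resname`, `k_old`, `k_new`).
#' @export
set_psi_force_constant <- function(topo, preset) {
  stopifnot(inherits(topo, "ff_topology"), inherits(preset, "torsion_preset"))
  hits <- find_psi_dihedrals(topo, names(preset$k_map))
  log <- list()
  # every requested residue type present must have a matched n=1 term
  matched_res <- character(0)
  for (mn in unique(hits$molecule)) {
    mol <- topo$molecules[[mn]]
    h <- hits[hits$molecule == mn, ]
    for (r in unique(h$resnr)) {
      rows <- h$dihedral_row[h$resnr == r]
      dh <- mol$dihedrals[rows, ]
      n1 <- rows[dh$funct %in% c(1L, 4L, 9L) & !is.na(dh$mult) & dh$mult == 1L]
      if (!length(n1))
        stop("residue ", h$resname[h$resnr == r][1], " ", r, " in ", mn,
             ": psi quadruple has no explicit n=1 proper term to refine")
      rname <- h$resname[h$resnr == r][1]
      key <- .canonical_residue(rname)
      k_new <- preset$k_map[[if (toupper(rname) %in% names(preset$k_map))
        toupper(rname) else key]]
      for (row in n1) {
        log[[length(log) + 1]] <- data.frame(
          molecule = mn, resnr = r, resname = rname,
          k_old = mol$dihedrals$k[row], k_new = k_new, stringsAsFactors = FALSE)
        mol$dihedrals$k[row] <- k_new
      }
      matched_res <- c(matched_res, key)
    }
    topo$molecules[[mn]] <- mol
  }
  attr(topo, "torsion_log") <- if (length(log))
    do.call(rbind, c(log, make.row.names = FALSE))
  else data.frame(molecule = character(0), resnr = integer(0),
                  resname = character(0), k_old = numeric(0), k_new = numeric(0))
  topo
}

#' Tabulate dihedral terms that differ between two topologies
#'
#' Both topologies must have the same molecules with identical atom
#' counts and dihedral tables apart from parameter values.
#'
#' @param topo_a,topo_b Structurally identical `ff_topology` objects.
#' @return data.frame of changed terms: `molecule`, `row`, `ai..al`,
#'   `funct`, `resnr`, `resname` (residue owning the second atom),
#'   `k_a`, `k_b`, `phase_a`, `phase_b`, `mult_a`, `mult_b`.
#' @export
diff_torsions <- function(topo_a, topo_b) {
  if (!identical(sort(names(topo_a$molecules)), sort(names(topo_b$molecules))))
    stop("topologies have different molecule sets")
  out <- list()
  for (mn in names(topo_a$molecules)) {
    ma <- topo_a$molecules[[mn]]; mb <- topo_b$molecules[[mn]]
    if (nrow(ma$atoms) != nrow(mb$atoms) || nrow(ma$dihedrals) != nrow(mb$dihedrals))
      stop("molecule '", mn, "' differs structurally between topologies")
    da <- ma$dihedrals; db <- mb$dihedrals
    if (!all(da$ai == db$ai & da$aj == db$aj & da$ak == db$ak & da$al == db$al))
      stop("molecule '", mn, "' has different dihedral quadruples")
    same <- function(x, y) (is.na(x) & is.na(y)) | (!is.na(x) & !is.na(y) & x == y)
    changed <- which(!(same(da$k, db$k) & same(da$phase, db$phase) &
                       same(da$mult, db$mult)))
    for (i in changed) {
      res_at <- match(da$aj[i], ma$atoms$index)
      out[[length(out) + 1]] <- data.frame(
        molecule = mn, row = i, ai = da$ai[i], aj = da$aj[i], ak = da$ak[i],
        al = da$al[i], funct = da$funct[i],
        resnr = ma$atoms$resnr[res_at], resname = ma$atoms$resname[res_at],
        k_a = da$k[i], k_b = db$k[i], phase_a = da$phase[i], phase_b = db$phase[i],
        mult_a = da$mult[i], mult_b = db$mult[i], stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, c(out, make.row.names = FALSE))
  else data.frame(molecule = character(0), row = integer(0), ai = integer(0),
                  aj = integer(0), ak = integer(0), al = integer(0),
                  funct = integer(0), resnr = integer(0), resname = character(0),
                  k_a = numeric(0), k_b = numeric(0), phase_a = numeric(0),
                  phase_b = numeric(0), mult_a = integer(0), mult_b = integer(0),
                  stringsAsFactors = FALSE)
}
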