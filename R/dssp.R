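# Kabsch-Sander secondary-structure assignment. Backbone amide
# hydrogens are reconstructed from the preceding peptide C=O, the H-bond
# energy is the standard electrostatic estimate with a -0.5 kcal/mol
# cutoff, and helices require two consecutive n-turns (the minimal-helix
# rule). Covers H (alpha), G (3-10), I (pi), E/B (strand/bridge), T
# (turn), C (coil).

.HB_CUTOFF <- -0.5  # kcal/mol

# hbond matrix: [acceptor residue a, donor residue d] TRUE if CO(a)...HN(d)
# satisfies the Kabsch-Sander energy criterion.
.ks_hbonds <- function(N, CA, C, O, resname) {
  nres <- nrow(N)
  # reconstruct amide H: 1.0 A from N along the previous C=O direction
  H <- matrix(NA_real_, nres, 3)
  for (i in 2:nres)
    H[i, ] <- N[i, ] + 0.1 * .unit3(C[i - 1, ] - O[i - 1, ])
  hb <- matrix(FALSE, nres, nres)
  for (a in seq_len(nres)) {
    for (d in seq_len(nres)) {
      if (abs(a - d) < 2) next            # no bond to self/adjacent
      if (toupper(resname[d]) == "PRO") next  # proline has no amide H
      if (any(is.na(H[d, ]))) next
      if (sum((CA[a, ] - CA[d, ])^2) > 0.81) next  # 9 A prefilter
      rON <- 10 * sqrt(sum((O[a, ] - N[d, ])^2))
      rCH <- 10 * sqrt(sum((C[a, ] - H[d, ])^2))
      rOH <- 10 * sqrt(sum((O[a, ] - H[d, ])^2))
      rCN <- 10 * sqrt(sum((C[a, ] - N[d, ])^2))
      if (min(rON, rCH, rOH, rCN) < 0.5) { hb[a, d] <- TRUE; next }
      E <- 0.084 * 332 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
      hb[a, d] <- E < .HB_CUTOFF
    }
  }
  hb
}

#' DSSP secondary-structure assignment for one frame
#'
#' Requires backbone N, CA, C, O per residue; the amide hydrogen is
#' reconstructed geometrically. Returns one letter per residue:
#' H (alpha helix), G (3-10 helix), I (pi helix), E (extended strand),
#' B (isolated bridge), T (turn), C (coil). Priority H > E > B > G > I > T.
#'
#' @param frame An [ff_frame()] with backbone atoms named N, CA, C, O.
#' @return Character vector, one code per residue (in residue order).
#' @export
dssp_assign <- function(frame) {
  stopifnot(inherits(frame, "ff_frame"))
  resids <- unique(frame$resid)
  nres <- length(resids)
  get_bb <- function(name) {
    m <- matrix(NA_real_, nres, 3)
    for (i in seq_len(nres)) {
      j <- which(frame$resid == resids[i] & toupper(frame$atomname) == name)
      if (length(j) == 1) m[i, ] <- frame$xyz[j, ]
    }
    m
  }
  N <- get_bb("N"); CA <- get_bb("CA"); C <- get_bb("C"); O <- get_bb("O")
  if (anyNA(N) || anyNA(CA) || anyNA(C) || anyNA(O))
    stop("missing backbone atom(s); DSSP needs N, CA, C, O for every residue")
  resname <- vapply(resids, function(r) frame$resname[frame$resid == r][1], "")

  hb <- .ks_hbonds(N, CA, C, O, resname)
  turn <- function(n) {
    t <- logical(nres)
    for (i in seq_len(max(0, nres - n))) t[i] <- hb[i, i + n]
    t
  }
  t3 <- turn(3); t4 <- turn(4); t5 <- turn(5)

  ss <- rep("C", nres)
  mark <- function(ss, tt, n, code) {
    if (nres - n >= 2)
      for (i in 2:(nres - n))
        if (tt[i - 1] && tt[i])
          for (j in i:(i + n - 1)) if (ss[j] == "C") ss[j] <- code
    ss
  }
  # bridges for E/B
  bridge <- matrix(FALSE, nres, nres)
  if (nres >= 5) {
    for (i in 2:(nres - 1)) {
      for (j in 2:(nres - 1)) {
        if (abs(i - j) < 3) next
        para <- (hb[i - 1, j] && hb[j, i + 1]) || (hb[j - 1, i] && hb[i, j + 1])
        anti <- (hb[i, j] && hb[j, i]) ||
          (j + 1 <= nres && i + 1 <= nres && hb[i - 1, j + 1] && hb[j - 1, i + 1])
        if (para || anti) bridge[i, j] <- TRUE
      }
    }
  }
  is_bridge <- apply(bridge, 1, any)
  # ladder: consecutive bridge residues -> E, isolated -> B
  ss_e <- rep("", nres)
  for (i in which(is_bridge)) {
    neighbors <- is_bridge[max(1, i - 1)] || is_bridge[min(nres, i + 1)]
    ss_e[i] <- if (neighbors && nres > 1) "E" else "B"
  }

  ss <- mark(ss, t4, 4, "H")
  for (i in seq_len(nres)) if (ss[i] == "C" && ss_e[i] != "") ss[i] <- ss_e[i]
  ss <- mark(ss, t3, 3, "G")
  ss <- mark(ss, t5, 5, "I")
  # turns: residues covered by any single n-turn
  for (n in c(3, 4, 5)) {
    tt <- turn(n)
    for (i in which(tt)) for (j in (i + 1):(i + n - 1))
      if (j <= nres && ss[j] == "C") ss[j] <- "T"
  }
  names(ss) <- resids
  ss
}

#' Per-residue helix fraction over a trajectory
#'
#' Assigns DSSP states to every frame and reports, per residue, the
#' fraction of frames in the alpha-helical state H (optionally counting
#' 3-10 helix G as helical).
#'
#' @param traj An `ff_trajectory` with backbone N, CA, C, O atoms.
#' @param include_310 Count G as helix too (default FALSE).
#' @return data.frame `resid`, `fraction`; attribute `"per_frame"` holds
#'   the fraction of helical residues in each frame, attribute
#'   `"assignments"` the frames x residues state matrix.
#' @export
helix_fraction <- function(traj, include_310 = FALSE) {
  stopifnot(inherits(traj, "ff_trajectory"))
  nf <- n_frames(traj)
  states <- NULL
  for (f in seq_len(nf)) {
    ss <- dssp_assign(get_frame(traj, f))
    if (is.null(states)) states <- matrix("", nf, length(ss))
    states[f, ] <- ss
  }
  helical <- states == "H"
  if (include_310) helical <- helical | states == "G"
  out <- data.frame(resid = unique(traj$resid), fraction = colMeans(helical))
  attr(out, "per_frame") <- rowMeans(helical)
  attr(out, "assignments") <- states
  out
}
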