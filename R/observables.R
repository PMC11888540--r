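#' Radius of gyration of one frame
#'
#' Mass-weighted RMS distance from the center of mass:
#' `sqrt(sum(m_i |r_i - r_cm|^2) / sum(m_i))`.
#'
#' @param xyz N x 3 coordinates (nm) or an [ff_frame()].
#' @param masses Optional per-atom masses; unit masses if omitted.
#' @return R_g in nm.
#' @export
radius_of_gyration <- function(xyz, masses = NULL) {
  if (inherits(xyz, "ff_frame")) {
    if (is.null(masses)) masses <- xyz$mass
    xyz <- xyz$xyz
  }
  xyz <- as.matrix(xyz)
  if (!nrow(xyz)) stop("empty selection")
  if (is.null(masses)) masses <- rep(1, nrow(xyz))
  if (sum(masses) <= 0) stop("total mass must be > 0")
  com <- colSums(xyz * masses) / sum(masses)
  sqrt(sum(masses * rowSums(sweep(xyz, 2, com)^2)) / sum(masses))
}

#' Optimal (Kabsch) superposition of one coordinate set onto another
#'
#' Least-squares rigid-body fit with a proper rotation (det = +1).
#'
#' @param mobile,ref N x 3 matrices.
#' @return List with `xyz` (superposed mobile), `rotation`, `rmsd` (nm).
#' @export
kabsch_superpose <- function(mobile, ref) {
  mobile <- as.matrix(mobile); ref <- as.matrix(ref)
  stopifnot(nrow(mobile) == nrow(ref), nrow(mobile) >= 3)
  cm <- colMeans(mobile); cr <- colMeans(ref)
  A <- sweep(mobile, 2, cm); B <- sweep(ref, 2, cr)
  s <- svd(crossprod(A, B))
  if (s$d[2] <= 1e-10 * max(s$d[1], .Machine$double.eps))
    stop("degenerate (collinear) selection: rotation undefined")
  d <- sign(det(s$u %*% t(s$v)))
  Dm <- diag(c(1, 1, d))
  R <- s$u %*% Dm %*% t(s$v)
  fitted <- sweep(A %*% R, 2, cr, "+")
  list(xyz = fitted, rotation = R,
       rmsd = sqrt(mean(rowSums((fitted - ref)^2))))
}

#' Kabsch RMSD between two frames
#'
#' Root-mean-square deviation after optimal rigid-body superposition
#' (or without superposition when `superpose = FALSE`).
#'
#' @param frame_a,frame_b N x 3 matrices or [ff_frame()]s.
#' @param selection Optional integer atom selection applied to both.
#' @param superpose Superpose before measuring (default TRUE).
#' @return RMSD in nm.
#' @export
kabsch_rmsd <- function(frame_a, frame_b, selection = NULL, superpose = TRUE) {
  xa <- if (inherits(frame_a, "ff_frame")) frame_a$xyz else as.matrix(frame_a)
  xb <- if (inherits(frame_b, "ff_frame")) frame_b$xyz else as.matrix(frame_b)
  if (!is.null(selection)) { xa <- xa[selection, , drop = FALSE]
                             xb <- xb[selection, , drop = FALSE] }
  if (!superpose) return(sqrt(mean(rowSums((xa - xb)^2))))
  kabsch_superpose(xa, xb)$rmsd
}

#' Root-mean-square fluctuations about the mean structure
#'
#' Each frame is superposed onto the mean structure (two refinement
#' passes starting from the first frame), then per-atom RMSFs are taken
#' about the converged mean.
#'
#' @param traj An `ff_trajectory`.
#' @param selection Optional integer atom selection.
#' @return Numeric vector of per-atom RMSF (nm).
#' @export
rmsf <- function(traj, selection = NULL) {
  stopifnot(inherits(traj, "ff_trajectory"))
  nf <- n_frames(traj)
  sel <- if (is.null(selection)) seq_len(dim(traj$coords)[2]) else selection
  frames <- lapply(seq_len(nf), function(i) traj$coords[i, sel, , drop = TRUE])
  ref <- frames[[1]]
  for (pass in 1:2) {
    fitted <- lapply(frames, function(f) kabsch_superpose(f, ref)$xyz)
    ref <- Reduce(`+`, fitted) / nf
  }
  dev <- vapply(fitted, function(f) rowSums((f - ref)^2), numeric(length(sel)))
  sqrt(rowMeans(matrix(dev, nrow = length(sel))))
}

#' Agreement RMSD between simulated and experimental series
#'
#' `sqrt(sum((x_sim - x_exp)^2) / N)` over N matched points; the
#' standard summary of simulation-experiment agreement for per-residue
#' observables.
#'
#' @param sim,exp Numeric vectors, or data.frames with columns
#'   `label`/`resid` and `value`.
#' @param labels Optional explicit labels for plain vectors; both series
#'   must agree on them.
#' @return Scalar RMSD in the units of the inputs.
#' @export
agreement_rmsd <- function(sim, exp, labels = NULL) {
  getv <- function(x) {
    if (is.data.frame(x)) {
      lab <- if ("label" %in% names(x)) x$label else x$resid
      list(lab = lab, val = x$value)
    } else list(lab = if (!is.null(names(x))) names(x) else labels, val = as.numeric(x))
  }
  a <- getv(sim); b <- getv(exp)
  if (!is.null(a$lab) && !is.null(b$lab) && !identical(a$lab, b$lab))
    stop("label mismatch between simulated and experimental series")
  if (length(a$val) != length(b$val)) stop("series lengths differ")
  sqrt(sum((a$val - b$val)^2) / length(a$val))
}
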