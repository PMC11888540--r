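# iRED order parameters: isotropic reorientational eigenmode dynamics.
# The covariance matrix <P2(u_i . u_j)> over frames is eigendecomposed;
# its five largest eigenmodes carry the overall reorientation of the
# molecule, and the remaining (internal) modes measure the loss of
# orientational order, so S2_i = 1 - sum over internal modes of
# lambda_m |m_i|^2.

#' Extract N-H unit-vector series from a trajectory
#'
#' @param traj An `ff_trajectory` whose residues carry atoms named N and
#'   H (or HN).
#' @return frames x residues x 3 array of unit vectors; residue ids in
#'   `dimnames[[2]]`.
#' @export
nh_vectors <- function(traj) {
  stopifnot(inherits(traj, "ff_trajectory"))
  resids <- unique(traj$resid)
  iN <- iH <- integer(0)
  keep <- integer(0)
  for (r in resids) {
    jn <- which(traj$resid == r & toupper(traj$atomname) == "N")
    jh <- which(traj$resid == r & toupper(traj$atomname) %in% c("H", "HN"))
    if (length(jn) == 1 && length(jh) == 1) {
      iN <- c(iN, jn); iH <- c(iH, jh); keep <- c(keep, r)
    }
  }
  if (!length(keep)) stop("no residues with both N and H atoms")
  nf <- n_frames(traj)
  out <- array(NA_real_, c(nf, length(keep), 3),
               dimnames = list(NULL, keep, NULL))
  for (f in seq_len(nf)) {
    v <- traj$coords[f, iH, , drop = TRUE] - traj$coords[f, iN, , drop = TRUE]
    v <- matrix(v, ncol = 3)
    out[f, , ] <- v / sqrt(rowSums(v^2))
  }
  out
}

#' iRED S2 order parameters from a unit-vector series
#'
#' @param vectors frames x M x 3 array of (near-)unit vectors, or an
#'   `ff_trajectory` (N-H vectors are extracted).
#' @param n_modes Number of reorientational modes removed (default 5,
#'   the rank of the rigid-body P2 covariance).
#' @param blocks Optionally split the frames into this many contiguous
#'   blocks and report the mean S2 across blocks (with an `"sd"`
#'   attribute).
#' @return data.frame `index` (residue label), `s2` in [0, 1].
#' @export
ired_s2 <- function(vectors, n_modes = 5, blocks = 1) {
  if (inherits(vectors, "ff_trajectory")) vectors <- nh_vectors(vectors)
  stopifnot(length(dim(vectors)) == 3, dim(vectors)[3] == 3)
  nf <- dim(vectors)[1]; M <- dim(vectors)[2]
  if (nf < 10) stop("need at least 10 frames")
  if (M < 2) stop("need at least 2 vector sites")
  if (M < n_modes + 1)
    warning("fewer than ", n_modes + 1,
            " sites: separating reorientational modes is ill-defined")
  if (any(!is.finite(vectors))) stop("non-finite vectors")
  nrm <- sqrt(vectors[, , 1]^2 + vectors[, , 2]^2 + vectors[, , 3]^2)
  if (any(abs(nrm - 1) > 1e-6)) {
    vectors <- vectors / array(rep(nrm, 3), dim(vectors))
  }
  labels <- dimnames(vectors)[[2]]
  if (is.null(labels)) labels <- seq_len(M)

  one_block <- function(sel) {
    n <- length(sel)
    # Q[[i]]: n x 9 flattened outer products u u^T per frame
    Q <- vector("list", M)
    for (i in seq_len(M)) {
      u <- vectors[sel, i, , drop = TRUE]
      u <- matrix(u, ncol = 3)
      Q[[i]] <- cbind(u[, 1] * u, u[, 2] * u, u[, 3] * u)
    }
    G <- matrix(0, M, M)
    for (i in seq_len(M)) for (j in i:M) {
      g <- sum(Q[[i]] * Q[[j]]) / n       # <(u_i . u_j)^2>
      G[i, j] <- G[j, i] <- 1.5 * g - 0.5  # <P2(u_i . u_j)>
    }
    e <- eigen(G, symmetric = TRUE)       # eigenvalues descending
    internal <- seq_len(M) > n_modes
    s2 <- 1 - colSums((e$values[internal] * t(e$vectors[, internal, drop = FALSE]^2)))
    pmin(pmax(s2, 0), 1)
  }

  if (blocks <= 1) {
    s2 <- one_block(seq_len(nf))
    return(data.frame(index = labels, s2 = s2, stringsAsFactors = FALSE))
  }
  bounds <- floor(seq(0, nf, length.out = blocks + 1))
  vals <- sapply(seq_len(blocks), function(b)
    one_block((bounds[b] + 1):bounds[b + 1]))
  out <- data.frame(index = labels, s2 = rowMeans(vals), stringsAsFactors = FALSE)
  attr(out, "sd") <- apply(vals, 1, stats::sd)
  out
}

#' Equilibrium diffusion-in-cone order parameter
#'
#' Closed form for a vector uniformly distributed within a cone of
#' semi-angle theta: `S = cos(theta) (1 + cos(theta)) / 2`, `S2 = S^2`.
#'
#' @param theta_deg Cone semi-angle in degrees.
#' @return S2 (dimensionless).
#' @export
cone_order_parameter <- function(theta_deg) {
  ct <- cos(theta_deg * pi / 180)
  (ct * (1 + ct) / 2)^2
}
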