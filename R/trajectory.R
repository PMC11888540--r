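#' Construct a single structure frame
#'
#' A frame is a coordinate matrix plus per-atom metadata; the common
#' currency of the observable functions.
#'
#' @param xyz N x 3 numeric matrix, nm.
#' @param atomname,resid,resname Per-atom metadata vectors (length N).
#' @param mass Optional per-atom masses (amu).
#' @return Object of class `ff_frame`.
#' @export
ff_frame <- function(xyz, atomname, resid, resname, mass = NULL) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, all(is.finite(xyz)))
  n <- nrow(xyz)
  structure(list(xyz = xyz, atomname = rep_len(atomname, n),
                 resid = rep_len(as.integer(resid), n),
                 resname = rep_len(resname, n),
                 mass = if (is.null(mass)) NULL else rep_len(mass, n)),
            class = "ff_frame")
}

#' Construct a trajectory from frames
#'
#' @param frames List of N x 3 coordinate matrices (all the same N), or a
#'   single `ff_frame` repeated metadata applies to.
#' @param atomname,resid,resname,mass Per-atom metadata (as in
#'   [ff_frame()]).
#' @return Object of class `ff_trajectory` holding a
#'   frames x atoms x 3 array plus metadata.
#' @export
ff_trajectory <- function(frames, atomname = NULL, resid = NULL,
                          resname = NULL, mass = NULL) {
  stopifnot(length(frames) >= 1)
  n <- nrow(frames[[1]])
  arr <- array(NA_real_, c(length(frames), n, 3))
  for (i in seq_along(frames)) {
    f <- as.matrix(frames[[i]])
    if (nrow(f) != n) stop("all frames must have the same atom count")
    arr[i, , ] <- f
  }
  if (any(!is.finite(arr))) stop("non-finite coordinates in trajectory")
  structure(list(coords = arr,
                 atomname = if (is.null(atomname)) rep("X", n) else rep_len(atomname, n),
                 resid = if (is.null(resid)) seq_len(n) else rep_len(as.integer(resid), n),
                 resname = if (is.null(resname)) rep("UNK", n) else rep_len(resname, n),
                 mass = if (is.null(mass)) NULL else rep_len(mass, n)),
            class = "ff_trajectory")
}

#' @export
print.ff_trajectory <- function(x, ...) {
  cat(sprintf("<ff_trajectory> %d frames x %d atoms (%d residues)\n",
              dim(x$coords)[1], dim(x$coords)[2], length(unique(x$resid))))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj An `ff_trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Extract one frame of a trajectory
#' @param traj An `ff_trajectory`. @param i Frame number.
#' @return An [ff_frame()].
#' @export
get_frame <- function(traj, i) {
  ff_frame(traj$coords[i, , ], traj$atomname, traj$resid, traj$resname, traj$mass)
}

#' Read a PDB file into a frame
#'
#' Delegates parsing to `bio3d::read.pdb`; PDB coordinates (Angstrom)
#' are converted to nm.
#'
#' @param path PDB file.
#' @return An [ff_frame()].
#' @export
read_pdb_frame <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading PDB files requires the bio3d package")
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  ff_frame(cbind(a$x, a$y, a$z) / 10, a$elety, a$resno, a$resid)
}

#' Write a frame to a PDB file
#'
#' @param frame An [ff_frame()] (nm; written in Angstrom).
#' @param path Output path.
#' @export
write_pdb_frame <- function(frame, path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("writing PDB files requires the bio3d package")
  xyz <- as.vector(t(frame$xyz * 10))
  bio3d::write.pdb(file = path, xyz = xyz, resno = frame$resid,
                   resid = frame$resname, elety = frame$atomname)
  invisible(path)
}

#' Read a multi-frame XYZ file as a trajectory
#'
#' Plain XYZ: atom count line, comment line, then `name x y z` rows,
#' repeated per frame. Units default to Angstrom (converted to nm).
#'
#' @param path XYZ file.
#' @param unit `"angstrom"` or `"nm"`.
#' @param resid Optional residue assignment per atom.
#' @return An `ff_trajectory`.
#' @export
read_xyz <- function(path, unit = c("angstrom", "nm"), resid = NULL) {
  unit <- match.arg(unit)
  lines <- readLines(path, warn = FALSE)
  frames <- list(); names_at <- NULL
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- as.integer(trimws(lines[i]))
    block <- lines[(i + 2):(i + 1 + n)]
    f <- do.call(rbind, strsplit(trimws(block), "[ \t]+"))
    names_at <- f[, 1]
    m <- matrix(as.numeric(f[, 2:4]), ncol = 3)
    if (unit == "angstrom") m <- m / 10
    frames[[length(frames) + 1]] <- m
    i <- i + 2 + n
  }
  ff_trajectory(frames, atomname = names_at, resid = resid)
}

#' Write a trajectory to a multi-frame XYZ file
#'
#' @param traj An `ff_trajectory` (nm).
#' @param path Output path.
#' @param unit `"angstrom"` or `"nm"` for the written values.
#' @export
write_xyz <- function(traj, path, unit = c("angstrom", "nm")) {
  unit <- match.arg(unit)
  k <- if (unit == "angstrom") 10 else 1
  con <- file(path, "w")
  on.exit(close(con))
  n <- dim(traj$coords)[2]
  for (f in seq_len(n_frames(traj))) {
    writeLines(c(as.character(n), sprintf("frame %d", f)), con)
    xyz <- traj$coords[f, , ] * k
    writeLines(sprintf("%-4s %14.6f %14.6f %14.6f", traj$atomname,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}
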