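# Trajectory container: an atom table plus a coordinate array over frames.

#' Construct a trajectory
#'
#' A claypep trajectory is an ordered set of frames sharing one atom table.
#' Coordinates are stored in Angstrom in a `n_atoms x 3 x n_frames` array;
#' the box is orthorhombic and periodic, one `(Lx, Ly, Lz)` row per frame.
#'
#' @param atoms data.frame with columns `atom_id` (integer), `name`
#'   (character), `role` (one of [atom_roles()]), `molecule_id` (integer),
#'   `residue_id` (integer index of the residue within its molecule) and
#'   `residue_type` (3-letter amino-acid code, or `LDH`/`SOL`/`ION`).
#' @param coords numeric array `n_atoms x 3 x n_frames` (Angstrom); a plain
#'   `n x 3` matrix is promoted to a single frame.
#' @param box numeric `n_frames x 3` matrix of box edge lengths (Angstrom);
#'   a length-3 vector is recycled across frames.
#' @param time numeric vector of frame times in ns (default `0, dt, ...`
#'   with `dt = 1`).
#' @return An object of class `claypep_traj`.
#' @export
trajectory <- function(atoms, coords, box, time = NULL) {
  if (is.matrix(coords)) coords <- array(coords, c(nrow(coords), 3L, 1L))
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  n_at <- dim(coords)[1]
  n_fr <- dim(coords)[3]
  need <- c("atom_id", "name", "role", "molecule_id", "residue_id",
            "residue_type")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms table lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) != n_at) stop("atoms table and coords disagree on atom count")
  bad <- setdiff(unique(atoms$role), atom_roles())
  if (length(bad)) stop("unknown roles: ", paste(bad, collapse = ", "))
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  if (is.null(dim(box))) box <- matrix(box, n_fr, 3L, byrow = TRUE)
  if (nrow(box) == 1L && n_fr > 1L) box <- box[rep(1L, n_fr), , drop = FALSE]
  if (nrow(box) != n_fr || ncol(box) != 3L) stop("box must be n_frames x 3")
  if (any(box <= 0)) stop("box lengths must be positive")
  if (is.null(time)) time <- seq_len(n_fr) - 1
  if (length(time) != n_fr) stop("time must have one value per frame")
  structure(list(atoms = atoms, coords = coords, box = box,
                 time = as.numeric(time)),
            class = "claypep_traj")
}

#' @export
print.claypep_traj <- function(x, ...) {
  cat(sprintf("claypep trajectory: %d atoms, %d frames, box %.1f x %.1f x %.1f A\n",
              n_atoms(x), n_frames(x), x$box[1, 1], x$box[1, 2], x$box[1, 3]))
  tab <- table(x$atoms$role)
  cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Number of frames / atoms in a trajectory
#' @param traj A [trajectory()].
#' @return Integer count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' @rdname n_frames
#' @export
n_atoms <- function(traj) dim(traj$coords)[1]

#' Extract frames of a trajectory
#'
#' @param traj A [trajectory()].
#' @param frames Integer vector of frame indices.
#' @return A `claypep_traj` restricted to the requested frames.
#' @export
subset_frames <- function(traj, frames) {
  trajectory(traj$atoms, traj$coords[, , frames, drop = FALSE],
             traj$box[frames, , drop = FALSE], traj$time[frames])
}

# Coordinates of one frame as an n x 3 matrix.
frame_coords <- function(traj, frame = 1L) {
  traj$coords[, , frame, drop = TRUE]
}

# Minimum-image displacement component-wise for a periodic dimension.
min_image <- function(d, L) d - L * round(d / L)

# Minimum-image pairwise distances between rows of a (m x 3) and b (k x 3).
# `periodic` flags which of x, y, z wrap.
pair_dists <- function(a, b, box, periodic = c(TRUE, TRUE, TRUE)) {
  m <- nrow(a); k <- nrow(b)
  dd <- matrix(0, m, k)
  for (j in 1:3) {
    d <- outer(a[, j], b[, j], "-")
    if (periodic[j]) d <- min_image(d, box[j])
    dd <- dd + d * d
  }
  sqrt(dd)
}
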