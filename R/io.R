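# Trajectory readers and writers: GRO (nm), multi-model PDB (A), XYZ (A).
#
# The atom table is reconstructed from atom/residue names through the
# role-map table (see role_map()). Molecules are encoded in the residue
# number (one residue id per molecule); residues inside a peptide are
# recovered by splitting the molecule's atom sequence at each backbone N,
# which is the first atom of every residue in the writer's ordering.

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gro", "pdb", "xyz")) ext else
    stop("cannot guess trajectory format from extension: ", path)
}

#' Read a trajectory file
#'
#' Supports GRO (nm, converted to A), multi-model PDB (A) and XYZ (A with a
#' `box=` comment). Roles are derived from atom names via the mapping table.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"gro"`, `"pdb"` or `"xyz"`.
#' @param map Role mapping data.frame from [role_map()].
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, format = "auto", map = role_map()) {
  if (format == "auto") format <- guess_format(path)
  switch(format,
         gro = read_gro(path, map),
         pdb = read_pdb_traj(path, map),
         xyz = read_xyz(path, map),
         stop("unknown format: ", format))
}

#' Write a trajectory file
#'
#' @param traj A [trajectory()].
#' @param path Output file; format guessed from the extension unless given.
#' @param format `"auto"`, `"gro"`, `"pdb"` or `"xyz"`.
#' @return Invisibly, `path`.
#' @export
write_trajectory <- function(traj, path, format = "auto") {
  if (format == "auto") format <- guess_format(path)
  switch(format,
         gro = write_gro(traj, path),
         pdb = write_pdb_traj(traj, path),
         xyz = write_xyz(traj, path),
         stop("unknown format: ", format))
  invisible(path)
}

# ---- molecule / residue reconstruction ------------------------------------

# given per-atom molecule ids, names, roles and residue names, rebuild
# residue_id by splitting each organic molecule at its backbone N atoms
rebuild_residues <- function(molecule_id, role) {
  residue_id <- rep(1L, length(role))
  for (m in unique(molecule_id)) {
    rows <- which(molecule_id == m)
    if (!any(role[rows] %in% c("BACKBONE_N", "C_TERM_C"))) next
    r <- cumsum(role[rows] == "BACKBONE_N")
    r[r == 0L] <- 1L
    residue_id[rows] <- r
  }
  residue_id
}

build_atoms <- function(name, resname, molecule_id, map) {
  role <- names_to_roles(name, map)
  data.frame(atom_id = seq_along(name), name = name, role = role,
             molecule_id = as.integer(molecule_id),
             residue_id = rebuild_residues(molecule_id, role),
             residue_type = resname, stringsAsFactors = FALSE)
}

# ---- GRO -------------------------------------------------------------------

write_gro <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  at <- traj$atoms
  for (t in seq_len(n_frames(traj))) {
    writeLines(sprintf("claypep trajectory t= %.6f ns", traj$time[t]), con)
    writeLines(sprintf("%5d", n_atoms(traj)), con)
    xyz <- traj$coords[, , t, drop = TRUE] / 10  # A -> nm
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       at$molecule_id %% 100000L, at$residue_type, at$name,
                       at$atom_id %% 100000L, xyz[, 1], xyz[, 2], xyz[, 3]),
               con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", traj$box[t, 1] / 10,
                       traj$box[t, 2] / 10, traj$box[t, 3] / 10), con)
  }
  invisible(path)
}

read_gro <- function(path, map = role_map()) {
  lines <- readLines(path)
  i <- 1L
  frames <- list(); boxes <- list(); times <- numeric(0)
  atoms <- NULL
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    tm <- regmatches(lines[i], regexpr("t= *[-0-9.eE+]+", lines[i]))
    times <- c(times, if (length(tm)) as.numeric(sub("t= *", "", tm)) else length(times))
    n <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(n)) stop("parse error at line ", i + 1L, ": expected atom count")
    rec <- lines[(i + 2L):(i + 1L + n)]
    if (length(rec) != n || anyNA(rec)) stop("parse error: truncated frame at line ", i)
    xyz <- cbind(as.numeric(substr(rec, 21, 28)),
                 as.numeric(substr(rec, 29, 36)),
                 as.numeric(substr(rec, 37, 44))) * 10
    if (anyNA(xyz)) stop("parse error: bad coordinate field near line ", i + 2L)
    if (is.null(atoms)) {
      atoms <- build_atoms(trimws(substr(rec, 11, 15)),
                           trimws(substr(rec, 6, 10)),
                           as.integer(substr(rec, 1, 5)), map)
    } else if (nrow(atoms) != n) {
      stop("structural error: inconsistent atom count across frames")
    }
    bx <- as.numeric(strsplit(trimws(lines[i + 2L + n]), "\\s+")[[1]])[1:3] * 10
    frames[[length(frames) + 1L]] <- xyz
    boxes[[length(boxes) + 1L]] <- bx
    i <- i + 3L + n
  }
  assemble_traj(atoms, frames, boxes, times)
}

# ---- PDB -------------------------------------------------------------------

write_pdb_traj <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  at <- traj$atoms
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     traj$box[1, 1], traj$box[1, 2], traj$box[1, 3],
                     90, 90, 90), con)
  multi <- n_frames(traj) > 1L
  for (t in seq_len(n_frames(traj))) {
    if (multi) writeLines(sprintf("MODEL     %4d", t), con)
    writeLines(sprintf("REMARK   6 TIME %.6f NS", traj$time[t]), con)
    xyz <- traj$coords[, , t, drop = TRUE]
    dim(xyz) <- c(n_atoms(traj), 3L)
    writeLines(sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                       at$atom_id %% 100000L, at$name, at$residue_type,
                       at$molecule_id %% 10000L,
                       xyz[, 1], xyz[, 2], xyz[, 3], 1, 0), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

read_pdb_traj <- function(path, map = role_map()) {
  lines <- readLines(path)
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cr)) {
    stop("parse error: PDB lacks a CRYST1 record (periodic box required)")
  }
  bx <- c(as.numeric(substr(cr[1], 7, 15)), as.numeric(substr(cr[1], 16, 24)),
          as.numeric(substr(cr[1], 25, 33)))
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  blocks <- if (length(starts)) {
    mapply(function(s, e) lines[(s + 1L):(e - 1L)], starts, ends,
           SIMPLIFY = FALSE)
  } else list(lines)
  atoms <- NULL; frames <- list(); boxes <- list(); times <- numeric(0)
  for (b in blocks) {
    tm <- grep("^REMARK   6 TIME", b, value = TRUE)
    times <- c(times, if (length(tm)) as.numeric(strsplit(trimws(tm[1]), "\\s+")[[1]][4])
               else length(times))
    rec <- grep("^(ATOM|HETATM)", b, value = TRUE)
    if (!length(rec)) stop("parse error: PDB frame without ATOM records")
    xyz <- cbind(as.numeric(substr(rec, 31, 38)),
                 as.numeric(substr(rec, 39, 46)),
                 as.numeric(substr(rec, 47, 54)))
    if (anyNA(xyz)) stop("parse error: bad ATOM coordinate field")
    if (is.null(atoms)) {
      atoms <- build_atoms(trimws(substr(rec, 13, 16)),
                           trimws(substr(rec, 18, 20)),
                           as.integer(substr(rec, 23, 26)), map)
    } else if (nrow(atoms) != nrow(xyz)) {
      stop("structural error: inconsistent atom count across frames")
    }
    frames[[length(frames) + 1L]] <- xyz
    boxes[[length(boxes) + 1L]] <- bx
  }
  assemble_traj(atoms, frames, boxes, times)
}

# ---- XYZ -------------------------------------------------------------------

write_xyz <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  at <- traj$atoms
  for (t in seq_len(n_frames(traj))) {
    writeLines(sprintf("%d", n_atoms(traj)), con)
    writeLines(sprintf("t= %.6f ns box= %.4f %.4f %.4f", traj$time[t],
                       traj$box[t, 1], traj$box[t, 2], traj$box[t, 3]), con)
    xyz <- traj$coords[, , t, drop = TRUE]
    dim(xyz) <- c(n_atoms(traj), 3L)
    writeLines(sprintf("%-5s %12.6f %12.6f %12.6f", at$name,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}

read_xyz <- function(path, map = role_map()) {
  lines <- readLines(path)
  i <- 1L
  atoms <- NULL; frames <- list(); boxes <- list(); times <- numeric(0)
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- as.integer(trimws(lines[i]))
    cm <- lines[i + 1L]
    bm <- regmatches(cm, regexpr("box= *([-0-9.eE+ ]+)", cm))
    if (!length(bm)) stop("parse error: XYZ comment lacks a box= record")
    bx <- as.numeric(strsplit(trimws(sub("box= *", "", bm)), "\\s+")[[1]])[1:3]
    tm <- regmatches(cm, regexpr("t= *[-0-9.eE+]+", cm))
    times <- c(times, if (length(tm)) as.numeric(sub("t= *", "", tm)) else length(times))
    rec <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "\\s+")
    name <- vapply(rec, `[`, "", 1L)
    xyz <- t(vapply(rec, function(r) as.numeric(r[2:4]), numeric(3)))
    if (is.null(atoms)) {
      role <- names_to_roles(name, map)
      molecule_id <- xyz_molecules(role)
      restype <- ifelse(role %in% c("LDH_METAL_MG", "LDH_METAL_AL",
                                    "LDH_HYDROXYL_O", "LDH_HYDROXYL_H"), "LDH",
                        ifelse(role %in% c("WATER_O", "WATER_H"), "SOL",
                               ifelse(role == "COUNTERION", "ION", "UNK")))
      atoms <- data.frame(atom_id = seq_along(name), name = name, role = role,
                          molecule_id = molecule_id,
                          residue_id = rebuild_residues(molecule_id, role),
                          residue_type = restype, stringsAsFactors = FALSE)
    } else if (nrow(atoms) != n) {
      stop("structural error: inconsistent atom count across frames")
    }
    frames[[length(frames) + 1L]] <- xyz
    boxes[[length(boxes) + 1L]] <- bx
    i <- i + 2L + n
  }
  assemble_traj(atoms, frames, boxes, times)
}

# XYZ carries no residue numbers: group mineral atoms into one molecule,
# every water/ion bead into its own, and split organic atoms into molecules
# at each backbone N that follows a completed C-terminus.
xyz_molecules <- function(role) {
  mol <- integer(length(role))
  cur <- 1L
  seen_ct <- FALSE
  prev_class <- ""
  for (i in seq_along(role)) {
    class <- if (role[i] %in% c("LDH_METAL_MG", "LDH_METAL_AL",
                                "LDH_HYDROXYL_O", "LDH_HYDROXYL_H")) "ldh"
    else if (role[i] %in% c("WATER_O", "WATER_H", "COUNTERION")) "bead"
    else "org"
    if (i > 1L && (class != prev_class || class == "bead" ||
                   (class == "org" && role[i] == "BACKBONE_N" && seen_ct))) {
      cur <- cur + 1L
      seen_ct <- FALSE
    }
    if (role[i] == "C_TERM_C") seen_ct <- TRUE
    mol[i] <- cur
    prev_class <- class
  }
  mol
}

assemble_traj <- function(atoms, frames, boxes, times) {
  coords <- array(unlist(frames), c(nrow(atoms), 3L, length(frames)))
  trajectory(atoms, coords, do.call(rbind, boxes), times)
}
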