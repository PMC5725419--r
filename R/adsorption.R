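# Adsorption state, RDF templating signal, backbone orientation and
# reactive-pair counting.

#' Per-frame, per-site adsorption state
#'
#' A site (a molecule's C-terminal carboxylate, or an aspartate side-chain
#' carboxylate) is adsorbed in a frame when the minimum distance from either
#' of its oxygens to the LDH surface (hydroxyl O and H atoms by default) is
#' at most `cutoff`. Distances use the minimum image in the periodic xy
#' plane; the slab is open along z.
#'
#' @param traj A [trajectory()] with role annotations.
#' @param cutoff Distance cutoff in A (default 2.5, the first hydration
#'   layer of the LDH surface).
#' @param surface Which surface atoms count: `"both"` hydroxyl O and H
#'   (default), `"O"` or `"H"` only.
#' @return Object of class `claypep_adsorption`: `sites` (data.frame
#'   site/molecule_id/residue_id/class), `adsorbed` (logical matrix,
#'   frames x sites), `cutoff`, `time`.
#' @export
adsorption_series <- function(traj, cutoff = 2.5,
                              surface = c("both", "O", "H")) {
  surface <- match.arg(surface)
  roles <- switch(surface,
                  both = c("LDH_HYDROXYL_O", "LDH_HYDROXYL_H"),
                  O = "LDH_HYDROXYL_O", H = "LDH_HYDROXYL_H")
  surf <- which(traj$atoms$role %in% roles)
  if (!length(surf)) stop("input error: no LDH surface atoms in trajectory")

  at <- traj$atoms
  mols <- unique(at$molecule_id[at$role == "C_TERM_C" | at$role == "SIDECHAIN_O"])
  sites <- NULL
  ox_rows <- list()
  for (m in mols) {
    rows <- which(at$molecule_id == m)
    ot <- rows[at$role[rows] == "C_TERM_O"]
    if (length(ot) == 0L) {
      if (any(at$role[rows] == "C_TERM_C")) {
        warning(sprintf("molecule %d lacks C-terminal oxygens; skipped", m))
      }
    } else {
      sites <- rbind(sites, data.frame(molecule_id = m, residue_id = NA_integer_,
                                       class = "backbone"))
      ox_rows[[length(ox_rows) + 1L]] <- ot
    }
    sc <- rows[at$role[rows] == "SIDECHAIN_O"]
    if (length(sc)) {
      for (r in unique(at$residue_id[sc])) {
        sites <- rbind(sites, data.frame(molecule_id = m, residue_id = r,
                                         class = "sidechain"))
        ox_rows[[length(ox_rows) + 1L]] <- sc[at$residue_id[sc] == r]
      }
    }
  }
  if (is.null(sites)) stop("input error: no adsorption sites (no molecules with OT/OD oxygens)")
  sites$site <- seq_len(nrow(sites))
  n_s <- nrow(sites)
  nf <- n_frames(traj)
  ads <- matrix(FALSE, nf, n_s)

  for (t in seq_len(nf)) {
    box <- traj$box[t, ]
    sx <- traj$coords[surf, 1, t]; sy <- traj$coords[surf, 2, t]
    sz <- traj$coords[surf, 3, t]
    ord <- order(sz)
    sx <- sx[ord]; sy <- sy[ord]; sz <- sz[ord]
    for (s in seq_len(n_s)) {
      rows <- ox_rows[[s]]
      hit <- FALSE
      for (o in rows) {
        zo <- traj$coords[o, 3, t]
        lo <- findInterval(zo - cutoff, sz) + 1L
        hi <- findInterval(zo + cutoff, sz)
        if (hi < lo) next
        idx <- lo:hi
        dx <- min_image(sx[idx] - traj$coords[o, 1, t], box[1])
        dy <- min_image(sy[idx] - traj$coords[o, 2, t], box[2])
        dz <- sz[idx] - zo
        if (min(dx * dx + dy * dy + dz * dz) <= cutoff^2) { hit <- TRUE; break }
      }
      ads[t, s] <- hit
    }
  }
  structure(list(sites = sites[, c("site", "molecule_id", "residue_id", "class")],
                 adsorbed = ads, cutoff = cutoff, time = traj$time),
            class = "claypep_adsorption")
}

#' @export
print.claypep_adsorption <- function(x, ...) {
  cat(sprintf("claypep adsorption series: %d frames x %d sites (cutoff %.2f A)\n",
              nrow(x$adsorbed), ncol(x$adsorbed), x$cutoff))
  cat(sprintf("  overall adsorbed fraction: %.3f\n", mean(x$adsorbed)))
  invisible(x)
}

# molecule-level adsorption matrices derived from a series
mol_adsorbed <- function(adsorption, class = c("backbone", "any")) {
  class <- match.arg(class)
  s <- adsorption$sites
  mols <- sort(unique(s$molecule_id))
  out <- matrix(FALSE, nrow(adsorption$adsorbed), length(mols),
                dimnames = list(NULL, mols))
  for (i in seq_along(mols)) {
    cols <- if (class == "backbone") {
      s$site[s$molecule_id == mols[i] & s$class == "backbone"]
    } else s$site[s$molecule_id == mols[i]]
    if (length(cols)) {
      out[, i] <- rowSums(adsorption$adsorbed[, cols, drop = FALSE]) > 0
    }
  }
  out
}

#' Adsorption fractions
#'
#' Percentage of molecules adsorbed via their C-terminal carboxylate, and
#' percentage of adsorbed side-chain carboxylate sites, per frame and
#' averaged over the equilibrated tail of the trajectory. Side-chain
#' percentages are computed per site, which scales peptide side-chain counts
#' by the number of residues per C-terminus (2x for di-, 6x for
#' hexa-peptides).
#'
#' @param traj A [trajectory()].
#' @param adsorption Optional precomputed [adsorption_series()].
#' @param cutoff Cutoff in A if the series must be computed (default 2.5).
#' @param equil_fraction Fraction of frames, from the end, regarded as
#'   equilibrated and used for the summary (default 0.5).
#' @return Object of class `claypep_ads_fraction`: `series` (per-frame
#'   percentages) and `summary` (means over the equilibrated window).
#' @export
adsorption_fraction <- function(traj, adsorption = NULL, cutoff = 2.5,
                                equil_fraction = 0.5) {
  if (is.null(adsorption)) adsorption <- adsorption_series(traj, cutoff)
  bb <- mol_adsorbed(adsorption, "backbone")
  sc_cols <- adsorption$sites$site[adsorption$sites$class == "sidechain"]
  nf <- nrow(adsorption$adsorbed)
  series <- data.frame(
    frame = seq_len(nf),
    pct_backbone = 100 * rowMeans(bb),
    pct_sidechain = if (length(sc_cols)) {
      100 * rowMeans(adsorption$adsorbed[, sc_cols, drop = FALSE])
    } else NA_real_)
  eq <- seq.int(max(1L, floor(nf * (1 - equil_fraction)) + 1L), nf)
  structure(list(series = series,
                 summary = c(pct_backbone = mean(series$pct_backbone[eq]),
                             pct_sidechain = mean(series$pct_sidechain[eq])),
                 cutoff = adsorption$cutoff, equil_frames = eq),
            class = "claypep_ads_fraction")
}

#' @export
print.claypep_ads_fraction <- function(x, ...) {
  cat(sprintf("claypep adsorption: %.1f%% backbone", x$summary["pct_backbone"]))
  if (is.finite(x$summary["pct_sidechain"])) {
    cat(sprintf(", %.1f%% side-chain sites", x$summary["pct_sidechain"]))
  }
  cat(sprintf(" (cutoff %.2f A, %d equilibrated frames)\n",
              x$cutoff, length(x$equil_frames)))
  invisible(x)
}

#' Radial distribution function
#'
#' Pair-distribution function g(r) between two atom roles under periodic
#' minimum-image distances, normalised against the ideal-gas density of the
#' second role. With `lateral = TRUE` distances and densities are taken in
#' the xy plane only (surface templating signal).
#'
#' @param traj A [trajectory()].
#' @param role_a,role_b Roles of the reference and distributed atoms (see
#'   [atom_roles()]); e.g. `"C_TERM_O"` vs `"LDH_METAL_AL"`, or
#'   `"LDH_METAL_AL"` twice for the Al-Al self-RDF.
#' @param r_max Histogram range, A; must be below half the smallest
#'   periodic box edge considered.
#' @param bin Bin width, A (default 0.1, resolving first-shell peaks).
#' @param lateral Use xy-projected distances and area normalisation.
#' @param frames Frames to accumulate (default all).
#' @return Object of class `claypep_rdf`: data.frame `table` with `r` (bin
#'   centres), `g` and raw `counts`, plus metadata.
#' @export
rdf <- function(traj, role_a, role_b, r_max = 12, bin = 0.1,
                lateral = FALSE, frames = NULL) {
  ia <- which(traj$atoms$role == role_a)
  ib <- which(traj$atoms$role == role_b)
  if (!length(ia) || !length(ib)) stop("input error: both roles must be present")
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  box_min <- min(traj$box[frames, if (lateral) 1:2 else 1:3])
  if (r_max >= box_min / 2) {
    stop("input error: r_max must be below half the smallest box edge")
  }
  same <- role_a == role_b
  breaks <- seq(0, r_max, by = bin)
  counts <- numeric(length(breaks) - 1L)
  for (t in frames) {
    box <- traj$box[t, ]
    a <- traj$coords[ia, , t, drop = FALSE]; dim(a) <- c(length(ia), 3L)
    b <- traj$coords[ib, , t, drop = FALSE]; dim(b) <- c(length(ib), 3L)
    if (lateral) { a[, 3] <- 0; b[, 3] <- 0 }
    d <- pair_dists(a, b, box, periodic = c(TRUE, TRUE, !lateral))
    if (same) diag(d) <- Inf
    d <- d[d < r_max]
    counts <- counts + tabulate(pmin(floor(d / bin) + 1L, length(counts)),
                                nbins = length(counts))
  }
  r_lo <- breaks[-length(breaks)]
  r_hi <- breaks[-1]
  vol <- traj$box[frames[1], 1] * traj$box[frames[1], 2] *
    (if (lateral) 1 else traj$box[frames[1], 3])
  shell <- if (lateral) pi * (r_hi^2 - r_lo^2) else (4 / 3) * pi * (r_hi^3 - r_lo^3)
  rho <- (length(ib) - as.integer(same)) / vol
  g <- counts / (length(frames) * length(ia) * rho * shell)
  structure(list(table = data.frame(r = (r_lo + r_hi) / 2, g = g, counts = counts),
                 pair = paste(role_a, role_b, sep = "-"), bin = bin,
                 lateral = lateral, n_frames = length(frames),
                 n_a = length(ia), n_b = length(ib)),
            class = "claypep_rdf")
}

#' @export
print.claypep_rdf <- function(x, ...) {
  pk <- x$table[which.max(x$table$g), ]
  cat(sprintf("claypep %sRDF %s: %d bins of %.2f A, first max g=%.2f at r=%.2f A\n",
              if (x$lateral) "lateral " else "", x$pair, nrow(x$table), x$bin,
              pk$g, pk$r))
  invisible(x)
}

#' Backbone orientation histogram
#'
#' Elevation angle of the C-to-N backbone vector of the terminal residue,
#' in the spherical convention where 0 deg is perpendicular to the surface
#' plane and 90 deg parallel; up/down symmetry folds the angle into
#' `[0, 90]`. Binned at 1 degree. If an adsorption series is supplied, only
#' molecules adsorbed (backbone) in a frame contribute.
#'
#' @param traj A [trajectory()].
#' @param adsorption Optional [adsorption_series()]; when given, restricts
#'   the histogram to adsorbed (molecule, frame) observations.
#' @return Object of class `claypep_orientation`: `counts` (90 bins,
#'   `[i-1, i)` degrees), `n_obs`, `n_skipped` (zero-length vectors).
#' @export
orientation_histogram <- function(traj, adsorption = NULL) {
  at <- traj$atoms
  ct <- which(at$role == "C_TERM_C")
  if (!length(ct)) stop("input error: no C-terminal carbons in trajectory")
  nv <- integer(length(ct))
  for (i in seq_along(ct)) {
    m <- at$molecule_id[ct[i]]; r <- at$residue_id[ct[i]]
    n <- which(at$molecule_id == m & at$residue_id == r & at$role == "BACKBONE_N")
    if (length(n) != 1L) stop("terminal residue must carry exactly one backbone N")
    nv[i] <- n
  }
  mols <- at$molecule_id[ct]
  ads <- if (!is.null(adsorption)) mol_adsorbed(adsorption, "backbone") else NULL

  counts <- integer(90)
  n_skip <- 0L
  for (t in seq_len(n_frames(traj))) {
    box <- traj$box[t, ]
    v <- traj$coords[nv, , t, drop = FALSE] - traj$coords[ct, , t, drop = FALSE]
    dim(v) <- c(length(ct), 3L)
    v[, 1] <- min_image(v[, 1], box[1])
    v[, 2] <- min_image(v[, 2], box[2])
    keep <- rep(TRUE, length(ct))
    if (!is.null(ads)) keep <- ads[t, as.character(mols)]
    len <- sqrt(rowSums(v^2))
    zero <- len < 1e-12
    if (any(zero & keep)) n_skip <- n_skip + sum(zero & keep)
    keep <- keep & !zero
    if (!any(keep)) next
    # rounding guards against representation error placing exact angles
    # (45, 90, ...) into the neighbouring bin
    theta <- round(acos(pmin(1, abs(v[keep, 3]) / len[keep])) * 180 / pi, 6)
    bins <- pmin(floor(theta) + 1L, 90L)
    counts <- counts + tabulate(bins, nbins = 90L)
  }
  if (n_skip) warning(sprintf("%d zero-length C-N vectors skipped", n_skip))
  structure(list(counts = counts, breaks = 0:90, n_obs = sum(counts),
                 n_skipped = n_skip),
            class = "claypep_orientation")
}

#' @export
print.claypep_orientation <- function(x, ...) {
  cat(sprintf("claypep orientation histogram: %d observations, mode at %d-%d deg\n",
              x$n_obs, which.max(x$counts) - 1L, which.max(x$counts)))
  invisible(x)
}

#' Reactive pair count
#'
#' A reactive pair is an adsorbed C-terminus and an adsorbed molecule's
#' N-terminus closer than `cutoff` (default 4 A). Pairs are counted as a
#' greedy nearest-first matching so each terminus participates at most
#' once. For aspartate the adsorbed side-chain carboxylate is an additional
#' donor (beta-peptide geometry); pairings within one molecule (cyclic) are
#' excluded, and the report sums alpha and beta counts.
#'
#' @param traj A [trajectory()].
#' @param adsorption An [adsorption_series()] for the same trajectory
#'   (required: both members of a pair must be adsorbed).
#' @param cutoff Distance cutoff in A, strict inequality (default 4).
#' @param equil_fraction Tail fraction of frames used for the summary.
#' @return Object of class `claypep_pairs`: per-frame data.frame `series`
#'   (`n_pairs`, `n_alpha`, `n_beta`, `pct_molecules`) and `summary`.
#' @export
reactive_pairs <- function(traj, adsorption, cutoff = 4, equil_fraction = 0.5) {
  if (missing(adsorption) || is.null(adsorption)) {
    stop("dependency error: reactive_pairs requires an adsorption series")
  }
  at <- traj$atoms
  ct <- which(at$role == "C_TERM_C")
  mols <- at$molecule_id[ct]
  n_mol <- length(mols)
  nterm <- vapply(mols, function(m) {
    which(at$molecule_id == m & at$residue_id == 1L & at$role == "BACKBONE_N")[1]
  }, integer(1))
  # aspartate side-chain donors: the side-chain carbon of each ASP residue
  scd <- which(at$role == "SIDECHAIN_OTHER" & at$residue_type == "ASP")
  bb <- mol_adsorbed(adsorption, "backbone")
  any_ads <- mol_adsorbed(adsorption, "any")
  s <- adsorption$sites

  nf <- n_frames(traj)
  series <- data.frame(frame = seq_len(nf), n_pairs = 0L, n_alpha = 0L,
                       n_beta = 0L, pct_molecules = 0)
  for (t in seq_len(nf)) {
    box <- traj$box[t, ]
    # donors: (row index, molecule, type)
    don_rows <- ct[bb[t, as.character(mols)]]
    don_mol <- at$molecule_id[don_rows]
    don_type <- rep("alpha", length(don_rows))
    if (length(scd)) {
      for (d in scd) {
        m <- at$molecule_id[d]; r <- at$residue_id[d]
        col <- s$site[s$molecule_id == m & !is.na(s$residue_id) &
                        s$residue_id == r & s$class == "sidechain"]
        if (length(col) && adsorption$adsorbed[t, col]) {
          don_rows <- c(don_rows, d)
          don_mol <- c(don_mol, m)
          don_type <- c(don_type, "beta")
        }
      }
    }
    acc_keep <- any_ads[t, as.character(mols)]
    acc_rows <- nterm[acc_keep]
    acc_mol <- mols[acc_keep]
    if (!length(don_rows) || !length(acc_rows)) next
    a <- traj$coords[don_rows, , t, drop = FALSE]; dim(a) <- c(length(don_rows), 3L)
    b <- traj$coords[acc_rows, , t, drop = FALSE]; dim(b) <- c(length(acc_rows), 3L)
    d <- pair_dists(a, b, box, periodic = c(TRUE, TRUE, FALSE))
    # exclusions: intramolecular (covers the aspartate cyclic geometry)
    d[outer(don_mol, acc_mol, "==")] <- Inf
    cand <- which(d < cutoff, arr.ind = TRUE)
    if (!nrow(cand)) next
    cand <- cand[order(d[cand]), , drop = FALSE]
    used_d <- logical(length(don_rows)); used_a <- logical(length(acc_rows))
    n_a <- 0L; n_b <- 0L; part <- integer(0)
    for (i in seq_len(nrow(cand))) {
      di <- cand[i, 1]; ai <- cand[i, 2]
      if (used_d[di] || used_a[ai]) next
      used_d[di] <- TRUE; used_a[ai] <- TRUE
      if (don_type[di] == "alpha") n_a <- n_a + 1L else n_b <- n_b + 1L
      part <- union(part, c(don_mol[di], acc_mol[ai]))
    }
    series$n_alpha[t] <- n_a
    series$n_beta[t] <- n_b
    series$n_pairs[t] <- n_a + n_b
    series$pct_molecules[t] <- 100 * length(part) / n_mol
  }
  eq <- seq.int(max(1L, floor(nf * (1 - equil_fraction)) + 1L), nf)
  structure(list(series = series,
                 summary = c(mean_pairs = mean(series$n_pairs[eq]),
                             pct_molecules = mean(series$pct_molecules[eq])),
                 cutoff = cutoff),
            class = "claypep_pairs")
}

#' @export
print.claypep_pairs <- function(x, ...) {
  cat(sprintf("claypep reactive pairs: mean %.2f pairs/frame, %.1f%% of molecules (cutoff %.1f A)\n",
              x$summary["mean_pairs"], x$summary["pct_molecules"], x$cutoff))
  invisible(x)
}
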