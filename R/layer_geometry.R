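# Layer assignment by density clustering, d-spacing profiles and
# undulation statistics of the mineral layers.

# Exact DBSCAN on a coordinate matrix. Follows the usual convention that
# min_samples counts the point itself. Returns integer cluster labels,
# NA for noise. Small n (metal atoms), so the O(n^2) distance matrix is fine.
dbscan_labels <- function(xyz, eps, min_samples) {
  n <- nrow(xyz)
  d2 <- as.matrix(stats::dist(xyz))
  nb <- lapply(seq_len(n), function(i) which(d2[i, ] <= eps))
  core <- lengths(nb) >= min_samples
  labels <- rep(NA_integer_, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || !is.na(labels[i])) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      j <- queue[[1]]
      queue <- queue[-1]
      for (k in nb[[j]]) {
        if (is.na(labels[k])) {
          labels[k] <- cl
          if (core[k]) queue <- c(queue, k)
        }
      }
    }
  }
  labels
}

#' Assign LDH metal atoms to layers
#'
#' Density-based clustering (DBSCAN) of the metal-atom coordinates: a layer
#' is a set of metal atoms connected through neighbours at most `eps` apart
#' (3D distance). Clusters are ordered by their mean z. Noise points are
#' reported, not silently dropped.
#'
#' @param frame A [trajectory()] (first frame is used unless `frame_idx`
#'   says otherwise).
#' @param eps Neighbourhood radius in A (default 5, i.e. atoms of one layer
#'   are apart by at most 5 A).
#' @param min_samples DBSCAN core-point threshold, counting the point
#'   itself (default 4).
#' @param expected Optional expected layer count; a mismatch raises a
#'   warning.
#' @param frame_idx Frame to cluster (default 1).
#' @return Object of class `claypep_layers`: list with `layer` (per metal
#'   atom, NA = noise), `atom_idx` (row indices of the metal atoms in the
#'   atom table), `mean_z` (per layer, ascending), `n_noise`, `eps`.
#' @export
assign_layers <- function(frame, eps = 5, min_samples = 4L, expected = NULL,
                          frame_idx = 1L) {
  metal <- which(frame$atoms$role %in% c("LDH_METAL_MG", "LDH_METAL_AL"))
  if (!length(metal)) stop("input error: frame contains no LDH metal atoms")
  xyz <- frame$coords[metal, , frame_idx, drop = FALSE]
  dim(xyz) <- c(length(metal), 3L)
  labels <- dbscan_labels(xyz, eps, min_samples)
  keep <- !is.na(labels)
  mean_z <- tapply(xyz[keep, 3], labels[keep], mean)
  ord <- order(mean_z)
  if (length(mean_z) > 1 && min(diff(sort(mean_z))) < 1e-9) {
    stop("input error: degenerate layers with equal mean z")
  }
  relabel <- integer(length(mean_z))
  relabel[ord] <- seq_along(ord)
  labels[keep] <- relabel[labels[keep]]
  mean_z <- as.numeric(sort(mean_z))
  if (!is.null(expected) && length(mean_z) != expected) {
    warning(sprintf("found %d layers where %d were expected",
                    length(mean_z), expected))
  }
  structure(list(layer = labels, atom_idx = metal, mean_z = mean_z,
                 n_noise = sum(!keep), eps = eps),
            class = "claypep_layers")
}

#' @export
print.claypep_layers <- function(x, ...) {
  cat(sprintf("claypep layer assignment: %d layers, %d metal atoms, %d noise\n",
              length(x$mean_z), length(x$layer), x$n_noise))
  cat("  mean z (A):", paste(sprintf("%.2f", x$mean_z), collapse = ", "), "\n")
  invisible(x)
}

#' d-spacing between adjacent layers
#'
#' Global and local d-spacing between every pair of adjacent layers. The
#' local map slides a `window x window` A window over the xy-plane in
#' `step`-A steps; the local d-spacing is the difference of the mean z of
#' the metal atoms of the two layers inside the window. Windows where
#' either layer has no atoms are `NA` and excluded from the statistics.
#'
#' @param assignment A [assign_layers()] result.
#' @param frame The [trajectory()] the assignment was computed on.
#' @param window Window edge, A (default 5).
#' @param step Window step, A (default 1).
#' @param periodic Wrap windows across the periodic xy box edges
#'   (default TRUE); with `FALSE` only fully interior windows are used.
#' @param frame_idx Frame to analyse (default 1).
#' @return Object of class `claypep_dspacing`: `pairs` (data.frame with
#'   per-pair mean/sd of the local values and the plain mean-z difference)
#'   and `local` (list of matrices of local d-spacing, window origins along
#'   x in rows, y in columns).
#' @export
d_spacing <- function(assignment, frame, window = 5, step = 1,
                      periodic = TRUE, frame_idx = 1L) {
  K <- length(assignment$mean_z)
  if (K < 2) stop("input error: need at least two layers for d-spacing")
  xyz <- frame$coords[assignment$atom_idx, , frame_idx, drop = FALSE]
  dim(xyz) <- c(length(assignment$atom_idx), 3L)
  Lx <- frame$box[frame_idx, 1]; Ly <- frame$box[frame_idx, 2]
  x0 <- if (periodic) seq(0, Lx - step / 2, by = step) else seq(0, Lx - window, by = step)
  y0 <- if (periodic) seq(0, Ly - step / 2, by = step) else seq(0, Ly - window, by = step)

  # per-layer mean z inside each window, via per-window atom masks
  win_mean <- function(layer) {
    sel <- which(!is.na(assignment$layer) & assignment$layer == layer)
    x <- xyz[sel, 1]; y <- xyz[sel, 2]; z <- xyz[sel, 3]
    out <- matrix(NA_real_, length(x0), length(y0))
    for (i in seq_along(x0)) {
      inx <- if (periodic) ((x - x0[i]) %% Lx) < window else x >= x0[i] & x < x0[i] + window
      if (!any(inx)) next
      yy <- y[inx]; zz <- z[inx]
      for (j in seq_along(y0)) {
        iny <- if (periodic) ((yy - y0[j]) %% Ly) < window else yy >= y0[j] & yy < y0[j] + window
        if (any(iny)) out[i, j] <- mean(zz[iny])
      }
    }
    out
  }
  means <- lapply(seq_len(K), win_mean)
  local <- vector("list", K - 1L)
  pairs <- data.frame(pair = character(K - 1L), mean = NA_real_, sd = NA_real_,
                      mean_z_diff = NA_real_, n_windows = NA_integer_,
                      stringsAsFactors = FALSE)
  for (k in seq_len(K - 1L)) {
    m <- means[[k + 1L]] - means[[k]]
    local[[k]] <- m
    v <- m[!is.na(m)]
    if (any(v <= 0)) warning("non-positive local d-spacing values found")
    pairs$pair[k] <- sprintf("%d-%d", k, k + 1L)
    pairs$mean[k] <- mean(v)
    pairs$sd[k] <- if (length(v) > 1) stats::sd(v) else 0
    pairs$mean_z_diff[k] <- assignment$mean_z[k + 1L] - assignment$mean_z[k]
    pairs$n_windows[k] <- length(v)
  }
  all_v <- unlist(lapply(local, function(m) m[!is.na(m)]))
  structure(list(pairs = pairs, local = local, x0 = x0, y0 = y0,
                 window = window, step = step, periodic = periodic,
                 mean = mean(all_v),
                 sd = if (length(all_v) > 1) stats::sd(all_v) else 0),
            class = "claypep_dspacing")
}

#' @export
print.claypep_dspacing <- function(x, ...) {
  cat(sprintf("claypep d-spacing: %.3f +/- %.3f A over %d adjacent pairs (%dx%d A windows)\n",
              x$mean, x$sd, nrow(x$pairs), x$window, x$window))
  print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' Layer undulation statistics
#'
#' Centres every layer (per frame) on its mean z, accumulates the metal-atom
#' z deviations across frames, and reports the standard deviation per layer
#' and pooled over all layers.
#'
#' @param assignment A [assign_layers()] result valid for every frame.
#' @param traj The [trajectory()].
#' @return Object of class `claypep_undulation`: `per_layer` (data.frame
#'   layer/sd/n) and `pooled` (overall z standard deviation, A).
#' @export
undulation <- function(assignment, traj) {
  keep <- !is.na(assignment$layer)
  idx <- assignment$atom_idx[keep]
  lab <- assignment$layer[keep]
  K <- length(assignment$mean_z)
  dev <- lapply(seq_len(K), function(k) vector("list", n_frames(traj)))
  for (t in seq_len(n_frames(traj))) {
    z <- traj$coords[idx, 3, t]
    for (k in seq_len(K)) {
      zk <- z[lab == k]
      dev[[k]][[t]] <- zk - mean(zk)
    }
  }
  dev <- lapply(dev, unlist)
  per_layer <- data.frame(layer = seq_len(K),
                          sd = vapply(dev, stats::sd, numeric(1)),
                          n = lengths(dev))
  pooled <- stats::sd(unlist(dev))
  structure(list(per_layer = per_layer, pooled = pooled),
            class = "claypep_undulation")
}

#' @export
print.claypep_undulation <- function(x, ...) {
  cat(sprintf("claypep undulation: pooled z std %.4f A\n", x$pooled))
  print(x$per_layer, row.names = FALSE)
  invisible(x)
}
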