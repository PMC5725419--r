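# Lateral mobility of adsorbed species: per-step velocities and directions,
# six-fold templating test on the direction histogram, residence statistics.

#' Lateral diffusion velocities of adsorbed C-terminal carbons
#'
#' For every molecule adsorbed (C-terminal site) in two consecutive frames,
#' the xy displacement of its C-terminal carbon (periodic minimum image) is
#' converted to a drift velocity in A/ns and a direction in polar
#' coordinates on the xy plane.
#'
#' @param traj A [trajectory()] with at least two frames for a non-empty
#'   result.
#' @param adsorption An [adsorption_series()] aligned with `traj`.
#' @return Object of class `claypep_diffusion`: data.frame `steps` with
#'   `molecule_id`, `frame` (the later frame of the pair), `velocity`
#'   (A/ns) and `direction` (degrees in `[0, 360)`).
#' @export
track_velocities <- function(traj, adsorption) {
  nf <- n_frames(traj)
  if (nf < 2L) {
    warning("single-frame trajectory: no diffusion steps")
    return(structure(list(steps = data.frame(molecule_id = integer(0),
                                             frame = integer(0),
                                             velocity = numeric(0),
                                             direction = numeric(0))),
                     class = "claypep_diffusion"))
  }
  at <- traj$atoms
  ct <- which(at$role == "C_TERM_C")
  mols <- at$molecule_id[ct]
  bb <- mol_adsorbed(adsorption, "backbone")[, as.character(mols), drop = FALSE]
  dt <- diff(traj$time)
  if (any(dt <= 0)) stop("input error: frame times must increase")
  steps <- vector("list", nf - 1L)
  for (t in seq_len(nf - 1L)) {
    ok <- bb[t, ] & bb[t + 1L, ]
    if (!any(ok)) next
    box <- traj$box[t, ]
    dx <- min_image(traj$coords[ct[ok], 1, t + 1L] - traj$coords[ct[ok], 1, t], box[1])
    dy <- min_image(traj$coords[ct[ok], 2, t + 1L] - traj$coords[ct[ok], 2, t], box[2])
    v <- sqrt(dx^2 + dy^2) / dt[t]
    # round to fight atan2 representation error so lattice steps land in
    # their exact degree bin
    dir <- round(atan2(dy, dx) * 180 / pi, 6) %% 360
    steps[[t]] <- data.frame(molecule_id = mols[ok], frame = t + 1L,
                             velocity = v, direction = dir)
  }
  steps <- do.call(rbind, steps)
  if (is.null(steps)) steps <- data.frame(molecule_id = integer(0), frame = integer(0),
                                          velocity = numeric(0), direction = numeric(0))
  structure(list(steps = steps), class = "claypep_diffusion")
}

#' @export
print.claypep_diffusion <- function(x, ...) {
  if (!nrow(x$steps)) {
    cat("claypep diffusion: no qualifying steps\n")
  } else {
    cat(sprintf("claypep diffusion: %d steps, mean velocity %.2f A/ns (sd %.2f)\n",
                nrow(x$steps), mean(x$steps$velocity), stats::sd(x$steps$velocity)))
  }
  invisible(x)
}

# circular autocorrelation of a (mean-subtracted) histogram, normalised to 1
# at lag 0; FFT-based
circ_autocorr <- function(counts) {
  h <- counts - mean(counts)
  if (sum(h^2) == 0) return(rep(NA_real_, length(counts)))
  ac <- Re(stats::fft(Mod(stats::fft(h))^2, inverse = TRUE))
  ac / ac[1]
}

# Score the six-fold signature on the uniquely hexagonal lags 60, 120, 240
# and 300 deg. Lag 180 is deliberately not scored: any centrosymmetric step
# distribution (including a four-fold lattice walk) peaks there, so it
# carries no six-fold information. The off-peak baseline likewise excludes
# windows around all multiples of 60 and around 90/180/270, so four-fold
# controls score ~0.
six_fold_from_counts <- function(counts, peak_halfwidth = 5L) {
  ac <- circ_autocorr(counts)
  lags <- seq_along(ac) - 1L
  peaks <- c(60L, 120L, 240L, 300L)
  excl <- c(seq(0L, 360L, by = 60L), 90L, 180L, 270L)
  near_excl <- vapply(lags, function(l) {
    any(abs((l - excl + 180L) %% 360L - 180L) <= peak_halfwidth)
  }, logical(1))
  list(ac = ac,
       score = mean(ac[lags %in% peaks]) - mean(ac[!near_excl]))
}

#' Six-fold symmetry of the diffusion-direction distribution
#'
#' Bins step directions at 1 degree, computes the circular autocorrelation
#' of the mean-subtracted histogram (normalised to 1 at lag 0), and scores
#' six-fold lattice templating as the mean autocorrelation at lags 60, 120,
#' 180, 240 and 300 degrees minus the mean over off-peak lags (lags within
#' `peak_halfwidth` of a multiple of 60, including 0, are excluded from the
#' off-peak set). Significance is assessed against an isotropy null:
#' `n_null` seeded resamples of the same number of uniform directions.
#'
#' @param stats A [track_velocities()] result, or a numeric vector of
#'   directions in degrees.
#' @param peak_halfwidth Halfwidth (deg) of the exclusion window around
#'   multiples of 60 when forming the off-peak baseline (default 5).
#' @param n_null Number of null resamples (default 1000).
#' @param seed Seed for the null resampling (default 1).
#' @return Object of class `claypep_sixfold`: `lags`, `autocorrelation`,
#'   `six_fold_score`, `p_value` (one-sided), `null_band` (central 95%
#'   interval of the null scores), `n_steps`. All-NA null result when there
#'   are no steps.
#' @export
direction_autocorrelation <- function(stats, peak_halfwidth = 5L,
                                      n_null = 1000L, seed = 1L) {
  dirs <- if (inherits(stats, "claypep_diffusion")) stats$steps$direction else stats
  lags <- 0:359
  if (!length(dirs)) {
    return(structure(list(lags = lags, autocorrelation = rep(NA_real_, 360),
                          six_fold_score = NA_real_, p_value = NA_real_,
                          null_band = c(NA_real_, NA_real_), n_steps = 0L),
                     class = "claypep_sixfold"))
  }
  bin_dirs <- function(d) tabulate(pmin(floor(d %% 360) + 1L, 360L), nbins = 360L)
  obs <- six_fold_from_counts(bin_dirs(dirs), peak_halfwidth)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  null_scores <- vapply(seq_len(n_null), function(i) {
    six_fold_from_counts(bin_dirs(stats::runif(length(dirs), 0, 360)),
                         peak_halfwidth)$score
  }, numeric(1))
  p <- (1 + sum(null_scores >= obs$score)) / (n_null + 1)
  structure(list(lags = lags, autocorrelation = obs$ac,
                 six_fold_score = obs$score, p_value = p,
                 null_band = stats::quantile(null_scores, c(0.025, 0.975),
                                             names = FALSE),
                 null_scores = null_scores, n_steps = length(dirs)),
            class = "claypep_sixfold")
}

# save/restore the global RNG state so seeded sub-analyses do not disturb
# the caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' @export
print.claypep_sixfold <- function(x, ...) {
  cat(sprintf("claypep six-fold test: score %.4f (p = %.4g, null 95%% band [%.4f, %.4f], %d steps)\n",
              x$six_fold_score, x$p_value, x$null_band[1], x$null_band[2],
              x$n_steps))
  invisible(x)
}

#' Post-first-binding residence statistics
#'
#' Fraction of frames each molecule spends adsorbed (C-terminal site)
#' counting from its first adsorption event onwards. Molecules never
#' adsorbed are excluded from the fractions and counted separately.
#'
#' @param adsorption An [adsorption_series()].
#' @return Object of class `claypep_residence`: `per_molecule` (data.frame
#'   `molecule_id`, `first_frame`, `fraction`), `mean`, `sd`,
#'   `n_never_adsorbed`.
#' @export
residence <- function(adsorption) {
  bb <- mol_adsorbed(adsorption, "backbone")
  mols <- as.integer(colnames(bb))
  nf <- nrow(bb)
  first <- apply(bb, 2, function(s) if (any(s)) which(s)[1] else NA_integer_)
  frac <- vapply(seq_along(mols), function(i) {
    if (is.na(first[i])) NA_real_ else mean(bb[first[i]:nf, i])
  }, numeric(1))
  per <- data.frame(molecule_id = mols, first_frame = first, fraction = frac)
  ok <- !is.na(frac)
  structure(list(per_molecule = per,
                 mean = mean(frac[ok]),
                 sd = if (sum(ok) > 1) stats::sd(frac[ok]) else NA_real_,
                 n_never_adsorbed = sum(!ok)),
            class = "claypep_residence")
}

#' @export
print.claypep_residence <- function(x, ...) {
  cat(sprintf("claypep residence: mean fraction %.3f (sd %.3f), %d molecules never adsorbed\n",
              x$mean, x$sd, x$n_never_adsorbed))
  invisible(x)
}
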