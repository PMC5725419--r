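# Interlayer hydration energetics: per-water hydration energy relative to
# the dry system, compared against the bulk-water reference.

#' Potential-energy series
#'
#' @param energy Numeric vector, per-frame potential energy in kJ/mol.
#' @param n_water Integer water count of the system.
#' @param time Optional frame times, ns.
#' @return Object of class `claypep_energy`.
#' @export
energy_series <- function(energy, n_water, time = NULL) {
  if (!length(energy)) stop("input error: empty energy series")
  if (n_water < 0) stop("input error: negative water count")
  if (!is.null(time) && length(time) != length(energy)) {
    stop("time and energy lengths differ")
  }
  structure(list(energy = as.numeric(energy), n_water = as.integer(n_water),
                 time = time),
            class = "claypep_energy")
}

#' @export
print.claypep_energy <- function(x, ...) {
  cat(sprintf("claypep energy series: %d frames, N = %d waters, mean %.2f kJ/mol\n",
              length(x$energy), x$n_water, mean(x$energy)))
  invisible(x)
}

#' Read / write a two-column energy CSV
#'
#' Plain CSV with columns `frame` and `energy` (kJ/mol).
#'
#' @param path File path.
#' @param n_water Water count of the system the series belongs to.
#' @return [energy_series()] for the reader; invisible path for the writer.
#' @export
read_energy_csv <- function(path, n_water) {
  df <- utils::read.csv(path)
  if (!all(c("frame", "energy") %in% names(df))) {
    stop("energy CSV must have columns 'frame' and 'energy'")
  }
  energy_series(df$energy[order(df$frame)], n_water)
}

#' @rdname read_energy_csv
#' @param series An [energy_series()] to write.
#' @export
write_energy_csv <- function(series, path) {
  utils::write.csv(data.frame(frame = seq_along(series$energy),
                              energy = series$energy),
                   path, row.names = FALSE)
  invisible(path)
}

# block-averaged standard error of the mean
block_se <- function(x, n_blocks = 5L) {
  n <- length(x)
  if (n < n_blocks) return(stats::sd(x) / sqrt(n))
  idx <- cut(seq_len(n), n_blocks, labels = FALSE)
  bm <- tapply(x, idx, mean)
  stats::sd(bm) / sqrt(n_blocks)
}

#' Hydration energy per water molecule
#'
#' The per-water hydration energy is the difference between the mean
#' potential energy of the hydrated system (N waters) and of the fully
#' dehydrated system, divided by N. If it lies strictly below the mean
#' energy of bulk water (-33.25 kJ/mol by default) the interlayer is prone
#' to rehydrate (swell). Uncertainty is propagated from block-averaged
#' standard errors of the two series.
#'
#' @param series_n [energy_series()] of the hydrated system (N > 0 waters).
#' @param series_0 [energy_series()] of the dry system (N = 0).
#' @param reference Bulk-water mean potential energy, kJ/mol (default
#'   -33.25).
#' @param n_blocks Blocks for the block-averaged standard error (default 5).
#' @return Object of class `claypep_hydration`: `delta_u` (kJ/mol per
#'   water), `se`, `n_water`, `u_n_mean`, `u_0_mean`, `reference`,
#'   `will_rehydrate` (`delta_u < reference`, strict).
#' @export
hydration_energy <- function(series_n, series_0, reference = -33.25,
                             n_blocks = 5L) {
  stopifnot(inherits(series_n, "claypep_energy"),
            inherits(series_0, "claypep_energy"))
  if (series_0$n_water != 0L) stop("input error: series_0 must have N = 0 waters")
  if (series_n$n_water <= 0L) stop("input error: series_n must have N > 0 waters")
  u_n <- mean(series_n$energy)
  u_0 <- mean(series_0$energy)
  N <- series_n$n_water
  delta <- (u_n - u_0) / N
  se <- sqrt(block_se(series_n$energy, n_blocks)^2 +
               block_se(series_0$energy, n_blocks)^2) / N
  structure(list(delta_u = delta, se = se, n_water = N,
                 u_n_mean = u_n, u_0_mean = u_0, reference = reference,
                 will_rehydrate = delta < reference),
            class = "claypep_hydration")
}

#' @export
print.claypep_hydration <- function(x, ...) {
  cat(sprintf("claypep hydration energy: %.3f +/- %.3f kJ/mol per water (N = %d)\n",
              x$delta_u, x$se, x$n_water))
  cat(sprintf("  reference %.2f kJ/mol -> %s\n", x$reference,
              if (x$will_rehydrate) "prone to rehydrate (swell)" else "stays dehydrated"))
  invisible(x)
}
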