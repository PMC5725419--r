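# Base-graphics plot methods for the main result objects.

#' @export
plot.claypep_rdf <- function(x, ...) {
  graphics::plot(x$table$r, x$table$g, type = "l", xlab = "r (A)",
                 ylab = "g(r)", main = paste("RDF", x$pair), ...)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

#' @export
plot.claypep_orientation <- function(x, ...) {
  graphics::plot(0:89 + 0.5, x$counts, type = "h", xlab = expression(Theta (deg)),
                 ylab = "count", main = "Backbone C-N elevation", ...)
  invisible(x)
}

#' @export
plot.claypep_sixfold <- function(x, ...) {
  graphics::plot(x$lags, x$autocorrelation, type = "l", xlab = "lag (deg)",
                 ylab = "autocorrelation",
                 main = sprintf("Direction autocorrelation (score %.3f)",
                                x$six_fold_score), ...)
  graphics::abline(v = seq(60, 300, by = 60), lty = 3)
  invisible(x)
}

#' Plot per-cycle chain-length distributions
#'
#' Converged surface concentration per chain length, one curve per selected
#' cycle — the standard view of peptide growth across wetting-drying cycles.
#'
#' @param x A [run_cycles()] result.
#' @param cycles Cycles to draw (default: up to 6, evenly spaced).
#' @param n_show Longest chain length shown (default 20).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.claypep_cycles <- function(x, cycles = NULL,
                                n_show = min(20L, x$params$n_max), ...) {
  nc <- nrow(x$surface)
  if (is.null(cycles)) cycles <- unique(round(seq(1, nc, length.out = min(6, nc))))
  graphics::matplot(seq_len(n_show), t(x$surface[cycles, seq_len(n_show), drop = FALSE]),
                    type = "b", pch = 16, lty = 1, xlab = "chain length n",
                    ylab = "surface concentration X[n]", ...)
  graphics::abline(h = x$params$theta, lty = 3)
  graphics::legend("topright", legend = paste("cycle", cycles), lty = 1,
                   col = seq_along(cycles), pch = 16, bty = "n")
  invisible(x)
}
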