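# Kinetic model of surface-activated peptide growth under wetting-drying
# cycles.
#
# During a dehydration phase adsorbed monomers X1 extend adsorbed chains,
#   X1 + Xn -> Xn+1  (all rate constants equal, k = 1),
# until the monomer pool is exhausted. A wetting step releases a fixed
# fraction of every chain (length >= 2) into solution and repopulates the
# surface with monomers from an infinite amino-acid bath up to full
# capacity.
#
# Two variants of the monomer balance are provided:
#  * "published": d[X1]/dt = -k [X1] sum_{n>=2} [Xn]; the monomer loss
#    counts only chain extension, so total monomer-unit mass grows during a
#    phase. This is the as-printed form of the model and the default, since
#    it is the variant that reproduces the reported chain-length outcomes
#    (dimers through hexamers after a single dehydration, 10-mers after
#    more than 10 cycles).
#  * "conserving": d[X1]/dt = -k [X1] (2 [X1] + sum_{n>=2} [Xn]); the
#    factor-2 dimerization loss makes sum n [Xn] exactly conserved, which is
#    the closed-surface reading and the one matched by the stochastic
#    (Gillespie) twin.
# In both variants d[Xn]/dt = k [X1]([Xn-1] - [Xn]) for n >= 2.

#' Kinetic model parameters
#'
#' @param capacity Total surface population restored at each wetting
#'   (default 100).
#' @param k Rate constant shared by all reactions (default 1).
#' @param desorb_fraction Fraction of every chain (length >= 2) released at
#'   each wetting (default 0.05).
#' @param n_max Chain-length truncation of the ODE hierarchy (default 64);
#'   mass reaching the last length is monitored.
#' @param theta Significance threshold used when reporting the first cycle
#'   at which a length is "observed" (default 1% of capacity).
#' @param tol Convergence criterion on the monomer concentration: a
#'   dehydration phase stops when `X1 < tol` (default 1e-6).
#' @param rtol,atol Integrator tolerances (default 1e-9, 1e-12).
#' @param mode `"published"` (as-printed monomer equation, default) or
#'   `"conserving"` (factor-2 dimerization loss, exact mass conservation).
#' @return Object of class `claypep_kinpar`.
#' @export
kinetic_params <- function(capacity = 100, k = 1, desorb_fraction = 0.05,
                           n_max = 64L, theta = 0.01 * capacity, tol = 1e-6,
                           rtol = 1e-9, atol = 1e-12,
                           mode = c("published", "conserving")) {
  mode <- match.arg(mode)
  stopifnot(capacity > 0, k > 0, desorb_fraction >= 0, desorb_fraction <= 1,
            n_max >= 2, theta >= 0, tol > 0)
  structure(list(capacity = capacity, k = k, desorb_fraction = desorb_fraction,
                 n_max = as.integer(n_max), theta = theta, tol = tol,
                 rtol = rtol, atol = atol, mode = mode),
            class = "claypep_kinpar")
}

#' Initial kinetic state
#'
#' Fully monomer-populated surface: `X1 = capacity`, all longer chains
#' empty, nothing released yet.
#'
#' @param params A [kinetic_params()].
#' @return Object of class `claypep_kinstate`: `X` (length `n_max`
#'   concentration vector), `released` (cumulative desorbed amounts per
#'   length), `input` (cumulative monomers supplied by the bath),
#'   `cycle` (completed wetting-drying cycles).
#' @export
kinetic_state <- function(params = kinetic_params()) {
  structure(list(X = c(params$capacity, numeric(params$n_max - 1L)),
                 released = numeric(params$n_max), input = params$capacity,
                 cycle = 0L),
            class = "claypep_kinstate")
}

#' @export
print.claypep_kinstate <- function(x, ...) {
  occ <- which(x$X >= 1e-3)
  cat(sprintf("claypep kinetic state after %d cycle(s): surface mass %.2f, released %.2f\n",
              x$cycle, sum(seq_along(x$X) * x$X), sum(seq_along(x$X) * x$released)))
  if (length(occ)) {
    cat("  X[n] >= 1e-3 at n =", paste(occ, collapse = ", "), "\n")
  }
  invisible(x)
}

kin_deriv <- function(t, X, p) {
  s2 <- sum(X[-1])
  d <- numeric(p$n_max)
  d[-1] <- p$k * X[1] * (X[-p$n_max] - X[-1])
  d[1] <- if (p$mode == "conserving") {
    -p$k * X[1] * (2 * X[1] + s2)
  } else {
    -p$k * X[1] * s2
  }
  list(d)
}

#' Integrate one dehydration phase
#'
#' Integrates the polymerization ODE hierarchy until the monomer pool is
#' exhausted (`X1 < tol`), using a stiff-safe adaptive integrator with a
#' root-stop. A state with `X1` already below `tol` is an absorbing state
#' and returned unchanged. In `"conserving"` mode the total monomer-unit
#' mass `sum n X[n]` is conserved to integrator tolerance.
#'
#' @param state A [kinetic_state()].
#' @param params A [kinetic_params()].
#' @param t_max Step budget for the integrator (default 1e6 time units);
#'   failure to exhaust the monomers within it raises an error carrying the
#'   final state.
#' @return The converged `claypep_kinstate`.
#' @export
dehydration_phase <- function(state, params = kinetic_params(), t_max = 1e6) {
  X <- state$X
  if (X[1] < params$tol) return(state)
  # In published mode a pure-monomer surface needs a seed: dX1/dt = 0 while
  # X2 grows as k X1^2, so integration proceeds; no special-casing needed.
  root <- function(t, X, p) X[1] - p$tol
  out <- deSolve::lsodar(X, times = c(0, t_max), func = kin_deriv,
                         parms = params, rtol = params$rtol,
                         atol = params$atol, rootfunc = root)
  Xf <- pmax(as.numeric(out[nrow(out), -1]), 0)
  if (Xf[1] >= params$tol * 1.0001 && out[nrow(out), 1] >= t_max) {
    st <- state; st$X <- Xf
    stop(paste0("dehydration phase did not converge within the step budget; ",
                "X1 = ", signif(Xf[1], 6), " at t = ", t_max,
                " (state: ", paste(signif(Xf[seq_len(min(10, length(Xf)))], 4),
                                   collapse = ", "), " ...)"))
  }
  overflow <- Xf[params$n_max] * params$n_max
  if (overflow > 1e-9 * params$capacity) {
    warning(sprintf("mass at the n_max = %d truncation boundary: %.3g; increase n_max",
                    params$n_max, overflow))
  }
  state$X <- Xf
  state
}

#' Apply one wetting step
#'
#' Releases `desorb_fraction` of every chain of length >= 2 into solution
#' (added to the cumulative `released` ledger) and repopulates the surface
#' with monomers from the bath up to `capacity`.
#'
#' @inheritParams dehydration_phase
#' @return The updated `claypep_kinstate` with `cycle` incremented.
#' @export
wetting_step <- function(state, params = kinetic_params()) {
  f <- params$desorb_fraction
  rel <- c(0, f * state$X[-1])
  state$released <- state$released + rel
  state$X <- state$X - rel
  topup <- params$capacity - sum(state$X)
  state$X[1] <- state$X[1] + topup
  state$input <- state$input + topup
  state$cycle <- state$cycle + 1L
  state
}

#' Run wetting-drying cycles
#'
#' Alternates [dehydration_phase()] and [wetting_step()] for `n_cycles`
#' cycles, recording the converged surface distribution, the per-cycle
#' released amounts and their cumulant, and the first cycle at which each
#' chain length reaches the significance threshold `theta`.
#'
#' @param n_cycles Number of wetting-drying cycles (>= 1).
#' @param params A [kinetic_params()].
#' @return Object of class `claypep_cycles`: matrices `surface`, `released`
#'   and `cumulative` (cycles x lengths; `surface` is the converged
#'   distribution before the wetting step), `first_reach` (first cycle at
#'   which each length's converged concentration is >= theta, NA if never),
#'   `state` (final), `params`.
#' @export
run_cycles <- function(n_cycles, params = kinetic_params()) {
  stopifnot(n_cycles >= 1)
  st <- kinetic_state(params)
  nm <- params$n_max
  surface <- released <- cumulative <- matrix(0, n_cycles, nm)
  first_reach <- rep(NA_integer_, nm)
  for (cy in seq_len(n_cycles)) {
    st <- dehydration_phase(st, params)
    surface[cy, ] <- st$X
    hit <- which(is.na(first_reach) & st$X >= params$theta)
    first_reach[hit] <- cy
    rel0 <- st$released
    st <- wetting_step(st, params)
    released[cy, ] <- st$released - rel0
    cumulative[cy, ] <- st$released
  }
  structure(list(surface = surface, released = released,
                 cumulative = cumulative, first_reach = first_reach,
                 state = st, params = params),
            class = "claypep_cycles")
}

#' @export
print.claypep_cycles <- function(x, ...) {
  nc <- nrow(x$surface)
  longest <- max(which(x$surface[nc, ] >= x$params$theta))
  cat(sprintf("claypep wetting-drying run: %d cycles (mode '%s', theta = %.2g)\n",
              nc, x$params$mode, x$params$theta))
  cat(sprintf("  longest chain >= theta after cycle %d: %d-mer\n", nc, longest))
  fr <- x$first_reach[!is.na(x$first_reach)]
  cat("  first cycle reaching theta, by length:",
      paste(sprintf("%d:%d", which(!is.na(x$first_reach)), fr), collapse = " "),
      "\n")
  invisible(x)
}

#' Stochastic (Gillespie) twin of the dehydration phase
#'
#' Exact stochastic simulation of the reaction set `X1 + Xn -> Xn+1`
#' starting from an integer population, run until no reaction is possible.
#' The dimerization propensity is `k X1 (X1 - 1)` (ordered pairs), matching
#' the deterministic `"conserving"` equations, whose solution is the
#' ensemble mean in the large-population limit.
#'
#' @param X0 Integer initial populations (length `n_max`, or a single
#'   monomer count).
#' @param params A [kinetic_params()].
#' @return Integer population vector at exhaustion.
#' @export
gillespie_dehydration <- function(X0, params = kinetic_params()) {
  nm <- params$n_max
  X <- if (length(X0) == 1L) c(as.integer(X0), integer(nm - 1L)) else as.integer(X0)
  repeat {
    a <- params$k * X[1] * X
    a[1] <- params$k * X[1] * max(X[1] - 1L, 0L)
    a[nm] <- 0
    if (sum(a) <= 0) break
    j <- sample.int(nm, 1L, prob = a)
    if (j == 1L) {
      X[1] <- X[1] - 2L; X[2] <- X[2] + 1L
    } else {
      X[1] <- X[1] - 1L; X[j] <- X[j] - 1L; X[j + 1L] <- X[j + 1L] + 1L
    }
  }
  X
}

#' Gillespie ensemble of dehydration phases
#'
#' @param n_runs Number of seeded realizations.
#' @param params A [kinetic_params()].
#' @param seed Integer seed.
#' @return Object of class `claypep_gillespie`: `mean`, `se` (Monte-Carlo
#'   standard error of the mean) and the raw `runs` matrix (runs x lengths).
#' @export
gillespie_ensemble <- function(n_runs = 1000L, params = kinetic_params(),
                               seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  runs <- t(vapply(seq_len(n_runs), function(i) {
    gillespie_dehydration(params$capacity, params)
  }, integer(params$n_max)))
  structure(list(mean = colMeans(runs),
                 se = apply(runs, 2, stats::sd) / sqrt(n_runs),
                 runs = runs, n_runs = n_runs),
            class = "claypep_gillespie")
}

#' @export
print.claypep_gillespie <- function(x, ...) {
  occ <- which(x$mean > 0)
  cat(sprintf("claypep Gillespie ensemble: %d runs, occupied lengths up to %d\n",
              x$n_runs, max(occ)))
  invisible(x)
}
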