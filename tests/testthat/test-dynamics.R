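# fixture: one monomer bead molecule over a hydroxyl sheet, scripted motion
scripted_traj <- function(ct_x, ct_z, dt = 0.1, box = c(40, 40, 40)) {
  nf <- length(ct_x)
  xs <- seq(0, box[1] - 1e-9, by = 2)
  g <- expand.grid(x = xs, y = xs)
  ns <- nrow(g)
  atoms <- data.frame(atom_id = seq_len(ns + 4L),
                      name = c(rep("OH", ns), "CT", "OT1", "OT2", "N"),
                      role = c(rep("LDH_HYDROXYL_O", ns), "C_TERM_C",
                               "C_TERM_O", "C_TERM_O", "BACKBONE_N"),
                      molecule_id = c(rep(1L, ns), rep(2L, 4L)),
                      residue_id = 1L,
                      residue_type = c(rep("LDH", ns), rep("ALA", 4L)))
  coords <- array(0, c(ns + 4L, 3L, nf))
  for (t in seq_len(nf)) {
    coords[1:ns, 1, t] <- g$x; coords[1:ns, 2, t] <- g$y
    ct <- c(ct_x[t], 10, ct_z[t])
    coords[ns + 1L, , t] <- ct
    coords[ns + 2L, , t] <- ct + c(0, 0, -0.5)
    coords[ns + 3L, , t] <- ct + c(0.5, 0, -0.5)
    coords[ns + 4L, , t] <- ct + c(-1.4, 0, 0)
  }
  trajectory(atoms, coords, box, time = (seq_len(nf) - 1) * dt)
}

test_that("stationary and uniformly drifting adsorbed particles give exact velocities", {
  stat <- scripted_traj(rep(10, 6), rep(2, 6))
  ads <- adsorption_series(stat)
  dv <- track_velocities(stat, ads)
  expect_identical(nrow(dv$steps), 5L)
  expect_true(all(dv$steps$velocity == 0))

  # 1 A per 0.1 ns along +x -> 10 A/ns at direction 0
  drift <- scripted_traj(10 + 0:5, rep(2, 6))
  dv2 <- track_velocities(drift, adsorption_series(drift))
  expect_equal(dv2$steps$velocity, rep(10, 5))
  expect_equal(dv2$steps$direction, rep(0, 5))
})

test_that("desorbing on alternate frames leaves no qualifying steps", {
  z <- rep(c(2, 9), 4)  # adsorbed on odd frames only
  traj <- scripted_traj(rep(10, 8) + 0.2 * (0:7), z)
  ads <- adsorption_series(traj)
  dv <- track_velocities(traj, ads)
  expect_identical(nrow(dv$steps), 0L)
  sf <- direction_autocorrelation(dv)
  expect_true(is.na(sf$six_fold_score))
  expect_identical(sf$n_steps, 0L)
})

test_that("single-frame trajectories warn and return an empty result", {
  traj <- scripted_traj(10, 2)
  ads <- adsorption_series(traj)
  expect_warning(dv <- track_velocities(traj, ads), "single-frame")
  expect_identical(nrow(dv$steps), 0L)
})

test_that("velocities are invariant under rigid xy translation", {
  set.seed(31)
  x <- cumsum(c(12, rnorm(9)))
  traj <- scripted_traj(x, rep(2, 10))
  v1 <- track_velocities(traj, adsorption_series(traj))$steps$velocity
  shifted <- traj
  shifted$coords[, 1, ] <- (shifted$coords[, 1, ] + 5) %% 40
  shifted$coords[, 2, ] <- (shifted$coords[, 2, ] + 3) %% 40
  v2 <- track_velocities(shifted, adsorption_series(shifted))$steps$velocity
  expect_equal(v1, v2)
})

test_that("uniform directions give a flat autocorrelation and a null-band score", {
  set.seed(8)
  dirs <- runif(5000, 0, 360)
  sf <- direction_autocorrelation(dirs)
  expect_lt(abs(sf$six_fold_score), 0.05)
  expect_gte(sf$six_fold_score, sf$null_band[1])
  expect_lte(sf$six_fold_score, sf$null_band[2])
  expect_gt(sf$p_value, 0.01)
})

test_that("six-fold biased directions peak at exact 60 deg multiples", {
  set.seed(9)
  dirs <- 60 * sample(0:5, 4000, replace = TRUE)
  sf <- direction_autocorrelation(dirs)
  ac <- sf$autocorrelation
  peaks <- which(ac > 0.5) - 1L
  expect_identical(peaks, seq(0L, 300L, by = 60L))
  expect_gt(sf$six_fold_score, 0.5)
  expect_lt(sf$p_value, 0.01)
})

test_that("a four-fold walk is not mistaken for six-fold templating", {
  set.seed(10)
  dirs <- 90 * sample(0:3, 4000, replace = TRUE) + rnorm(4000, 0, 0.3)
  sf <- direction_autocorrelation(dirs)
  expect_lt(abs(sf$six_fold_score), 0.05)
  expect_gt(sf$p_value, 0.01)
})

test_that("rotating all directions leaves the six-fold score unchanged", {
  set.seed(12)
  dirs <- 60 * sample(0:5, 3000, replace = TRUE)
  s0 <- direction_autocorrelation(dirs)$six_fold_score
  s17 <- direction_autocorrelation((dirs + 17) %% 360)$six_fold_score
  expect_equal(s0, s17)
})

test_that("residence fractions follow the post-first-binding definition", {
  mk_ads <- function(states) {
    # minimal adsorption object: one backbone site
    structure(list(sites = data.frame(site = 1L, molecule_id = 1L,
                                      residue_id = NA_integer_,
                                      class = "backbone"),
                   adsorbed = matrix(states, ncol = 1), cutoff = 2.5,
                   time = seq_along(states)),
              class = "claypep_adsorption")
  }
  # adsorbed from frame 3 of 10 onwards -> 1.0
  r1 <- residence(mk_ads(c(FALSE, FALSE, rep(TRUE, 8))))
  expect_equal(r1$per_molecule$fraction, 1)
  expect_identical(r1$per_molecule$first_frame, 3L)
  # adsorbed frames {3,4,5,8,9,10} -> 6/8
  s <- rep(FALSE, 10); s[c(3, 4, 5, 8, 9, 10)] <- TRUE
  expect_equal(residence(mk_ads(s))$per_molecule$fraction, 0.75)
  # never adsorbed -> excluded
  r3 <- residence(mk_ads(rep(FALSE, 10)))
  expect_identical(r3$n_never_adsorbed, 1L)
  expect_true(is.na(r3$per_molecule$fraction))
  # always adsorbed -> exactly 1
  expect_equal(residence(mk_ads(rep(TRUE, 10)))$mean, 1)
})
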