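test_that("adsorption respects the 2.5 A cutoff boundary", {
  # OT oxygens directly above surface atoms at 2.4 and 2.6 A
  traj <- mol_surface_traj(ot_xy = rbind(c(10, 10), c(20, 20)),
                           ot_z = c(2.4, 2.6))
  ads <- adsorption_series(traj)
  bb <- ads$adsorbed[1, ads$sites$class == "backbone"]
  expect_identical(unname(bb), c(TRUE, FALSE))
})

test_that("adsorption fraction matches a brute-force distance oracle", {
  set.seed(42)
  M <- 10
  xy <- cbind(runif(M, 2, 38), runif(M, 2, 38))
  # 7 adsorbed (even at the worst lateral offset to the surface grid), 3 not
  z <- c(runif(7, 1.0, 2.0), runif(3, 4, 8))
  traj <- mol_surface_traj(xy, z)
  fr <- adsorption_fraction(traj, equil_fraction = 1)
  expect_equal(unname(fr$summary["pct_backbone"]), 70)

  # oracle: all-pairs minimum-image distances, no z-window shortcut
  at <- traj$atoms
  surf <- traj$coords[at$role == "LDH_HYDROXYL_O", , 1]
  box <- traj$box[1, ]
  oracle <- vapply(unique(at$molecule_id[at$role == "C_TERM_O"]), function(m) {
    ot <- traj$coords[at$molecule_id == m & at$role == "C_TERM_O", , 1]
    dmin <- Inf
    for (i in 1:2) for (j in seq_len(nrow(surf))) {
      d <- ot[i, ] - surf[j, ]
      d[1:2] <- d[1:2] - box[1:2] * round(d[1:2] / box[1:2])
      dmin <- min(dmin, sqrt(sum(d^2)))
    }
    dmin <= 2.5
  }, logical(1))
  ads <- adsorption_series(traj)
  expect_identical(unname(ads$adsorbed[1, ads$sites$class == "backbone"]),
                   unname(oracle))
})

test_that("peptide side-chain percentages are scaled per residue", {
  # two hexa-ASP chains built by hand from the generator
  cfg <- generator_config(n_layers = 2, nx = 10, ny = 10, hydration = 0,
                          rng_seed = 8)
  f0 <- populate_interlayer(build_ldh_slab(cfg),
                            list(list(residue = "ASP", length = 6, count = 2)))
  ads <- adsorption_series(f0)
  expect_identical(sum(ads$sites$class == "sidechain"), 12L)
  k <- sum(ads$adsorbed[1, ads$sites$class == "sidechain"])
  fr <- adsorption_fraction(f0, ads, equil_fraction = 1)
  # per-site percentage = raw adsorbed-site count over chains, divided by 6
  expect_equal(unname(fr$summary["pct_sidechain"]), 100 * k / (2 * 6))
})

test_that("enlarging the cutoff never unmarks an adsorbed site", {
  set.seed(7)
  traj <- mol_surface_traj(cbind(runif(8, 2, 38), runif(8, 2, 38)),
                           runif(8, 1, 6))
  prev <- NULL
  for (cutoff in c(1, 2, 2.5, 3, 4, 6)) {
    cur <- adsorption_series(traj, cutoff = cutoff)$adsorbed
    if (!is.null(prev)) expect_true(all(cur[prev]))
    prev <- cur
  }
})

test_that("RDF of ideal-gas points is flat at 1", {
  set.seed(1)
  box <- c(20, 20, 20)
  nA <- 300; nB <- 400; nf <- 5
  coords <- array(runif(3 * (nA + nB) * nf, 0, 20), c(nA + nB, 3, nf))
  atoms <- data.frame(atom_id = seq_len(nA + nB),
                      name = c(rep("CT", nA), rep("AL", nB)),
                      role = c(rep("C_TERM_C", nA), rep("LDH_METAL_AL", nB)),
                      molecule_id = seq_len(nA + nB), residue_id = 1L,
                      residue_type = c(rep("ALA", nA), rep("LDH", nB)))
  traj <- trajectory(atoms, coords, box)
  r <- rdf(traj, "C_TERM_C", "LDH_METAL_AL", r_max = 9, bin = 0.25)
  sel <- r$table$r > 2
  expect_equal(mean(r$table$g[sel]), 1, tolerance = 0.02)
  expect_true(all(abs(r$table$g[sel] - 1) < 0.2))
})

test_that("RDF equals a brute-force pair enumeration on a 10-atom fixture", {
  set.seed(3)
  box <- c(12, 10, 14)
  n <- 10
  xyz <- cbind(runif(n, 0, 12), runif(n, 0, 10), runif(n, 0, 14))
  atoms <- data.frame(atom_id = 1:n, name = "AL", role = "LDH_METAL_AL",
                      molecule_id = 1:n, residue_id = 1L, residue_type = "LDH")
  traj <- trajectory(atoms, xyz, box)
  r_max <- 4.9; bin <- 0.1
  res <- rdf(traj, "LDH_METAL_AL", "LDH_METAL_AL", r_max = r_max, bin = bin)

  # oracle: O(n^2) loop, explicit shell counting and normalisation
  counts <- numeric(r_max / bin)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    d <- xyz[i, ] - xyz[j, ]
    d <- d - box * round(d / box)
    dd <- sqrt(sum(d^2))
    if (dd < r_max) {
      k <- floor(dd / bin) + 1
      counts[k] <- counts[k] + 1
    }
  }
  expect_identical(res$table$counts, counts)
  edges <- seq(0, r_max, by = bin)
  shell <- (4 / 3) * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  g_oracle <- counts / (n * ((n - 1) / prod(box)) * shell)
  expect_equal(res$table$g, g_oracle, tolerance = 1e-12)

  # normalisation conservation: histogram total equals the pair count in range
  expect_identical(sum(res$table$counts), sum(counts))
})

test_that("templated C-termini reproduce the Al lattice RDF peaks", {
  cfg <- generator_config(n_layers = 2, nx = 8, ny = 8, hydration = 0,
                          templated = TRUE, undulation_amplitude = 0,
                          rng_seed = 13)
  f0 <- populate_interlayer(build_ldh_slab(cfg),
                            list(list(residue = "ALA", length = 1, count = 12)))
  sim <- evolve(f0, 5)
  first_peak <- function(r) {
    tb <- r$table[r$table$r > 1.5, ]
    tb$r[which(tb$g > 0)[1]]
  }
  ct_al <- rdf(sim$trajectory, "C_TERM_C", "LDH_METAL_AL", r_max = 9, lateral = TRUE)
  al_al <- rdf(sim$trajectory, "LDH_METAL_AL", "LDH_METAL_AL", r_max = 9, lateral = TRUE)
  expect_equal(first_peak(ct_al), first_peak(al_al))
  # the Al sublattice nearest-neighbour spacing is a*sqrt(3)
  expect_equal(first_peak(al_al), 3.05 * sqrt(3), tolerance = 0.05)
})

test_that("rdf validates its range against the box", {
  traj <- metal_layers_traj(c(0, 12), Lx = 20, Ly = 20, box_z = 30)
  expect_error(rdf(traj, "LDH_METAL_MG", "LDH_METAL_MG", r_max = 15),
               "half the smallest box edge")
  expect_error(rdf(traj, "LDH_METAL_MG", "C_TERM_O", r_max = 5),
               "both roles")
})

test_that("orientation histogram follows the spherical elevation convention", {
  mk <- function(nvec) {
    atoms <- data.frame(atom_id = 1:2, name = c("CT", "N"),
                        role = c("C_TERM_C", "BACKBONE_N"), molecule_id = 1L,
                        residue_id = 1L, residue_type = "ALA")
    trajectory(atoms, rbind(c(10, 10, 10), c(10, 10, 10) + nvec), c(40, 40, 40))
  }
  expect_identical(which(orientation_histogram(mk(c(0, 0, 1)))$counts == 1L), 1L)   # 0 deg
  expect_identical(which(orientation_histogram(mk(c(1, 0, 0)))$counts == 1L), 90L)  # 90 deg
  expect_identical(which(orientation_histogram(mk(c(1, 0, 1)))$counts == 1L), 46L)  # 45 deg
  expect_identical(which(orientation_histogram(mk(c(0, 0, -1)))$counts == 1L), 1L)  # folded
})

test_that("orientation counts sum to the adsorbed observations", {
  sim <- small_sim()
  ads <- adsorption_series(sim$trajectory)
  h1 <- orientation_histogram(sim$trajectory, ads)
  expect_identical(h1$n_obs, sum(ads$adsorbed[, ads$sites$class == "backbone"]))
})

test_that("orientation histogram is invariant under rigid rotation about z", {
  set.seed(23)
  traj <- mol_surface_traj(cbind(runif(12, 12, 28), runif(12, 12, 28)),
                           runif(12, 1, 3), n_offset = c(1.0, 0.6, 0.8))
  h1 <- orientation_histogram(traj)
  rot <- traj
  th <- 30 * pi / 180
  x <- rot$coords[, 1, ] - 20; y <- rot$coords[, 2, ] - 20
  rot$coords[, 1, ] <- 20 + cos(th) * x - sin(th) * y
  rot$coords[, 2, ] <- 20 + sin(th) * x + cos(th) * y
  h2 <- orientation_histogram(rot)
  expect_identical(h1$counts, h2$counts)
  expect_identical(h1$n_obs, 12L)
})

test_that("reactive pairs respect the 4 A boundary and adsorption gating", {
  # two molecules, both adsorbed; the exact C-N distance is measured from
  # the fixture and the cutoff probed just above and below it
  traj <- mol_surface_traj(rbind(c(10, 10), c(14.5, 10)), c(2, 2),
                           n_offset = c(1.4, 0, 0))
  at <- traj$atoms
  cn <- function(i, j) {
    ct <- traj$coords[at$molecule_id == i & at$role == "C_TERM_C", , 1]
    nn <- traj$coords[at$molecule_id == j & at$role == "BACKBONE_N", , 1]
    sqrt(sum((ct - nn)^2))
  }
  d_near <- min(cn(2, 3), cn(3, 2))   # closest C-N arrangement
  d_far <- max(cn(2, 3), cn(3, 2))
  ads <- adsorption_series(traj)
  rp <- reactive_pairs(traj, ads, cutoff = min(d_near + 0.05, d_far - 0.05))
  expect_identical(rp$series$n_pairs[1], 1L)
  rp0 <- reactive_pairs(traj, ads, cutoff = d_near - 0.05)
  expect_identical(rp0$series$n_pairs[1], 0L)
  expect_identical(reactive_pairs(traj, ads, cutoff = 0)$series$n_pairs[1], 0L)
  expect_error(reactive_pairs(traj, NULL), "dependency")

  # desorbed partner breaks the pair even within range
  traj2 <- mol_surface_traj(rbind(c(10, 10), c(12, 10)), c(2, 9),
                            n_offset = c(1.4, 0, 0))
  ads2 <- adsorption_series(traj2)
  expect_identical(reactive_pairs(traj2, ads2, cutoff = 6)$series$n_pairs[1], 0L)
})

test_that("reactive pair count matches an enumeration + matching oracle", {
  set.seed(19)
  M <- 20
  traj <- mol_surface_traj(cbind(runif(M, 2, 38), runif(M, 2, 38)),
                           runif(M, 1.5, 4.5), n_offset = c(1.4, 0.3, 0))
  ads <- adsorption_series(traj)
  rp <- reactive_pairs(traj, ads, cutoff = 4)

  at <- traj$atoms
  box <- traj$box[1, ]
  mols <- sort(unique(at$molecule_id[at$role == "C_TERM_C"]))
  adsb <- ads$adsorbed[1, ads$sites$class == "backbone"]
  ct <- t(vapply(mols, function(m) traj$coords[at$molecule_id == m & at$role == "C_TERM_C", , 1], numeric(3)))
  nn <- t(vapply(mols, function(m) traj$coords[at$molecule_id == m & at$role == "BACKBONE_N", , 1], numeric(3)))
  cand <- NULL
  for (i in seq_along(mols)) for (j in seq_along(mols)) {
    if (i == j || !adsb[i] || !adsb[j]) next
    d <- ct[i, ] - nn[j, ]
    d[1:2] <- d[1:2] - box[1:2] * round(d[1:2] / box[1:2])
    dd <- sqrt(sum(d^2))
    if (dd < 4) cand <- rbind(cand, c(i, j, dd))
  }
  n_oracle <- 0L
  if (!is.null(cand)) {
    cand <- cand[order(cand[, 3]), , drop = FALSE]
    used_c <- used_n <- rep(FALSE, M)
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      if (!used_c[i] && !used_n[j]) {
        used_c[i] <- used_n[j] <- TRUE
        n_oracle <- n_oracle + 1L
      }
    }
  }
  expect_identical(rp$series$n_pairs[1], n_oracle)
  expect_lte(rp$series$n_pairs[1], M)
})

test_that("aspartate side-chain donors count as beta pairs, cyclic excluded", {
  # ASP with side-chain carboxylate adsorbed near the surface, its own N far,
  # and a second molecule whose N is close to the ASP side-chain carbon
  od <- list(rbind(c(10.3, 10, 2.0), c(10.9, 10, 2.0)))
  traj <- mol_surface_traj(rbind(c(10, 10)), ot_z = 8, asp = TRUE, od_xyz = od,
                           n_offset = c(0.5, 0, 0))
  # append a partner molecule adsorbed via OT with N near the ASP CG
  at <- traj$atoms
  xyz <- traj$coords[, , 1]
  part <- rbind(c(13, 10, 2), c(13, 10.5, 2), c(13.5, 10, 2), c(11.5, 10, 2))
  at <- rbind(at, data.frame(atom_id = nrow(at) + 1:4,
                             name = c("CT", "OT1", "OT2", "N"),
                             role = c("C_TERM_C", "C_TERM_O", "C_TERM_O", "BACKBONE_N"),
                             molecule_id = 99L, residue_id = 1L, residue_type = "ALA"))
  traj <- trajectory(at, rbind(xyz, part), traj$box[1, ])
  ads <- adsorption_series(traj)
  s <- ads$sites
  expect_false(ads$adsorbed[1, s$class == "backbone" & s$molecule_id == 2])  # ASP OT far
  expect_true(ads$adsorbed[1, s$class == "sidechain"][1])                    # ASP OD close
  rp <- reactive_pairs(traj, ads, cutoff = 4)
  expect_identical(rp$series$n_beta[1], 1L)
  expect_identical(rp$series$n_alpha[1], 0L)
  expect_identical(rp$series$n_pairs[1], 1L)
  # the ASP's own N (intramolecular, cyclic geometry) is never a partner:
  # with the partner molecule removed there is no pair at any distance
  traj_solo <- mol_surface_traj(rbind(c(10, 10)), ot_z = 8, asp = TRUE,
                                od_xyz = od, n_offset = c(0.5, 0, 0))
  ads_solo <- adsorption_series(traj_solo)
  expect_identical(reactive_pairs(traj_solo, ads_solo, cutoff = 10)$series$n_pairs[1], 0L)
})
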