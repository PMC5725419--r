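test_that("slab has exact stoichiometry, layer thickness and stacking", {
  cfg <- generator_config(n_layers = 5, nx = 8, ny = 8)
  slab <- build_ldh_slab(cfg)
  al <- sum(slab$atoms$role == "LDH_METAL_AL")
  mg <- sum(slab$atoms$role == "LDH_METAL_MG")
  expect_identical(al * 3L, mg)

  # hydroxyl z-extent of each layer equals the configured thickness
  hyd <- slab$atoms$role %in% c("LDH_HYDROXYL_O", "LDH_HYDROXYL_H")
  z <- frame_z <- slab$coords[, 3, 1]
  for (l in 1:5) {
    sel <- hyd & slab$atoms$molecule_id == l
    expect_equal(max(z[sel]) - min(z[sel]), 5.3)
  }

  # metal planes separated by thickness + gap
  met <- slab$atoms$role %in% c("LDH_METAL_MG", "LDH_METAL_AL")
  mz <- sort(unique(round(z[met], 9)))
  expect_length(mz, 5)
  expect_equal(diff(mz), rep(cfg$layer_thickness + cfg$interlayer_gap, 4))
})

test_that("metal sublattice is hexagonal: six nearest neighbours at 60 deg spacing", {
  cfg <- generator_config(n_layers = 1, nx = 6, ny = 6)
  slab <- build_ldh_slab(cfg)
  met <- which(slab$atoms$role %in% c("LDH_METAL_MG", "LDH_METAL_AL"))
  xy <- slab$coords[met, 1:2, 1]
  box <- slab$box[1, ]
  a <- cfg$lattice_a
  dx <- outer(xy[, 1], xy[, 1], "-"); dx <- dx - box[1] * round(dx / box[1])
  dy <- outer(xy[, 2], xy[, 2], "-"); dy <- dy - box[2] * round(dy / box[2])
  d <- sqrt(dx^2 + dy^2); diag(d) <- Inf
  nn <- abs(d - a) < 1e-6
  expect_true(all(rowSums(nn) == 6))
  # neighbour directions of the first atom are 60 deg apart
  ang <- sort(atan2(dy[1, nn[1, ]], dx[1, nn[1, ]]) * 180 / pi %% 360)
  expect_equal(diff(ang), rep(60, 5), tolerance = 1e-9)
})

test_that("populate places molecules, waters and labelled sites correctly", {
  cfg <- generator_config(n_layers = 3, nx = 8, ny = 8, hydration = 20)
  slab <- build_ldh_slab(cfg)
  f0 <- populate_interlayer(slab, list(list(residue = "ALA", length = 1, count = 10)))
  expect_identical(sum(f0$atoms$role == "WATER_O"), 200L)

  # aspartate carries both carboxylate pairs
  fa <- populate_interlayer(slab, list(list(residue = "ASP", length = 1, count = 1)))
  m <- fa$atoms[fa$atoms$residue_type == "ASP", ]
  expect_identical(sum(m$role == "C_TERM_O"), 2L)
  expect_identical(sum(m$role == "SIDECHAIN_O"), 2L)

  # hexa-peptide: 6 residues, one C-terminus, six side-chain beads,
  # and the terminal residue holds both the C and its backbone N
  fh <- populate_interlayer(slab, list(list(residue = "LEU", length = 6, count = 2)))
  for (mol in unique(fh$atoms$molecule_id[fh$atoms$residue_type == "LEU"])) {
    mm <- fh$atoms[fh$atoms$molecule_id == mol, ]
    expect_identical(length(unique(mm$residue_id)), 6L)
    expect_identical(sum(mm$role == "C_TERM_C"), 1L)
    expect_identical(sum(mm$role == "SIDECHAIN_OTHER"), 6L)
    term <- mm$residue_id[mm$role == "C_TERM_C"]
    expect_identical(sum(mm$residue_id == term & mm$role == "BACKBONE_N"), 1L)
  }

  # overfilled interlayer is rejected
  expect_error(populate_interlayer(slab, list(list(residue = "ALA", length = 1,
                                                   count = 2000))),
               "insufficient")
})

test_that("generator config validation rejects bad parameters", {
  expect_error(generator_config(mg_al_ratio = 2), "stoichiometry")
  expect_error(generator_config(hex_bias = 1.5), "hex_bias")
  expect_error(generator_config(hydration = -1), "hydration")
  expect_error(generator_config(residence_fraction = 1.2), "residence_fraction")
  expect_error(generator_config(nx = 7), "even")
  cfg1 <- generator_config(n_layers = 1)
  expect_error(populate_interlayer(build_ldh_slab(cfg1),
                                   list(list(residue = "ALA", length = 1, count = 1))),
               "no interlayer")
})

test_that("evolution is bit-reproducible from the seed", {
  cfg <- generator_config(n_layers = 2, nx = 6, ny = 6, hydration = 2,
                          rng_seed = 99)
  f0 <- populate_interlayer(build_ldh_slab(cfg),
                            list(list(residue = "ALA", length = 1, count = 5)))
  s1 <- evolve(f0, 20)
  s2 <- evolve(f0, 20)
  expect_identical(s1$trajectory$coords, s2$trajectory$coords)
  expect_identical(s1$states, s2$states)
  expect_identical(s1$energy$energy, s2$energy$energy)
})

test_that("hex_bias = 1 restricts steps to the six lattice directions", {
  cfg <- generator_config(n_layers = 2, nx = 8, ny = 8, hydration = 0,
                          hex_bias = 1, rng_seed = 3)
  f0 <- populate_interlayer(build_ldh_slab(cfg),
                            list(list(residue = "ALA", length = 1, count = 10)))
  sim <- evolve(f0, 50)
  ct <- which(sim$trajectory$atoms$role == "C_TERM_C")
  box <- sim$trajectory$box[1, ]
  for (t in 1:49) {
    dx <- sim$trajectory$coords[ct, 1, t + 1] - sim$trajectory$coords[ct, 1, t]
    dy <- sim$trajectory$coords[ct, 2, t + 1] - sim$trajectory$coords[ct, 2, t]
    dx <- dx - box[1] * round(dx / box[1])
    dy <- dy - box[2] * round(dy / box[2])
    ang <- atan2(dy, dx) * 180 / pi
    expect_true(all(abs(((ang %% 60) + 30) %% 60 - 30) < 1e-6))
  }
})

test_that("generated adsorption states are recovered by the geometric analysis", {
  sim <- small_sim()
  ads <- adsorption_series(sim$trajectory)
  bb <- ads$adsorbed[, ads$sites$class == "backbone"]
  expect_identical(unname(bb), unname(sim$states))
})

test_that("stationary adsorbed fraction tracks residence_fraction", {
  cfg <- generator_config(n_layers = 2, nx = 6, ny = 6, hydration = 0,
                          residence_fraction = 0.7, rng_seed = 21)
  f0 <- populate_interlayer(build_ldh_slab(cfg),
                            list(list(residue = "ALA", length = 1, count = 30)))
  sim <- evolve(f0, 400)
  # ~ binomial tolerance with autocorrelation inflation
  expect_equal(mean(sim$states), 0.7, tolerance = 0.05)
})
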