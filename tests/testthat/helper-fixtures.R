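# Shared fixtures, built in code.

# metal-only trajectory: layers of metal atoms on an x-y grid at given z
# values (z may be a function of (x, y) per layer)
metal_layers_traj <- function(z_layers, Lx = 30, Ly = 20, spacing = 1,
                              box_z = 60) {
  xs <- seq(0, Lx - spacing / 2, by = spacing)
  ys <- seq(0, Ly - spacing / 2, by = spacing)
  g <- expand.grid(x = xs, y = ys)
  xyz <- NULL
  for (z in z_layers) {
    zz <- if (is.function(z)) z(g$x, g$y) else rep(z, nrow(g))
    xyz <- rbind(xyz, cbind(g$x, g$y, zz))
  }
  n <- nrow(xyz)
  atoms <- data.frame(atom_id = seq_len(n), name = "MG", role = "LDH_METAL_MG",
                      molecule_id = rep(seq_along(z_layers), each = nrow(g)),
                      residue_id = 1L, residue_type = "LDH")
  trajectory(atoms, xyz, c(Lx, Ly, box_z))
}

# minimal molecule+surface trajectory builder: a sheet of hydroxyl O atoms
# at z = 0 plus monomer bead molecules at given C-terminal positions.
# `ot_z` gives the OT oxygen height per molecule; N is offset along +x.
mol_surface_traj <- function(ot_xy, ot_z, box = c(40, 40, 40),
                             n_offset = c(-1.4, 0, 0), asp = FALSE,
                             od_xyz = NULL, surface_spacing = 2) {
  xs <- seq(0, box[1] - 1e-9, by = surface_spacing)
  ys <- seq(0, box[2] - 1e-9, by = surface_spacing)
  g <- expand.grid(x = xs, y = ys)
  atoms <- data.frame(atom_id = seq_len(nrow(g)), name = "OH",
                      role = "LDH_HYDROXYL_O", molecule_id = 1L,
                      residue_id = 1L, residue_type = "LDH")
  xyz <- cbind(g$x, g$y, 0)
  M <- nrow(ot_xy)
  for (m in seq_len(M)) {
    ct <- c(ot_xy[m, 1], ot_xy[m, 2], ot_z[m] + 0.5)
    pos <- rbind(CT = ct,
                 OT1 = c(ot_xy[m, 1], ot_xy[m, 2], ot_z[m]),
                 OT2 = c(ot_xy[m, 1] + 0.5, ot_xy[m, 2], ot_z[m]),
                 N = ct + n_offset)
    names_ <- c("CT", "OT1", "OT2", "N")
    roles_ <- c("C_TERM_C", "C_TERM_O", "C_TERM_O", "BACKBONE_N")
    if (asp) {
      od <- if (is.null(od_xyz)) rbind(ct + c(0.8, 0.8, 1), ct + c(1.2, 0.8, 1)) else od_xyz[[m]]
      pos <- rbind(pos, CG = colMeans(od), OD1 = od[1, ], OD2 = od[2, ])
      names_ <- c(names_, "CG", "OD1", "OD2")
      roles_ <- c(roles_, "SIDECHAIN_OTHER", "SIDECHAIN_O", "SIDECHAIN_O")
    }
    atoms <- rbind(atoms, data.frame(atom_id = nrow(atoms) + seq_len(nrow(pos)),
                                     name = names_, role = roles_,
                                     molecule_id = m + 1L, residue_id = 1L,
                                     residue_type = if (asp) "ASP" else "ALA"))
    xyz <- rbind(xyz, pos)
  }
  trajectory(atoms, xyz, box)
}

# small generated simulation, cached across tests
.sim_cache <- new.env()
cached_sim <- function(key, maker) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- maker()
  .sim_cache[[key]]
}

small_sim <- function() cached_sim("small", function() {
  cfg <- generator_config(n_layers = 3, nx = 8, ny = 8, hydration = 3,
                          rng_seed = 11)
  f0 <- populate_interlayer(build_ldh_slab(cfg),
                            list(list(residue = "ALA", length = 1, count = 12)))
  evolve(f0, 60)
})
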