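# Synthetic LDH-interlayer trajectory generator.
#
# The generator builds a bead-level emulation of a hydrated Mg3Al(OH)8
# interlayer: a stack of hexagonal metal layers decorated with hydroxyls,
# intercalated amino-acid/peptide bead molecules, water beads and
# counterions. Molecules perform lateral random walks with an optional
# six-fold directional bias and toggle between adsorbed and desorbed states
# as a two-state Markov chain, so every downstream statistic has a known
# ground truth.

#' Generator configuration
#'
#' Collects the geometric and kinetic parameters of the synthetic
#' interlayer. Defaults encode the reference study conditions: a 5-layer
#' Mg3Al(OH)8 slab of 5.3 A layer thickness, a hydrated interlayer
#' (d-spacing 12.6 A), a ~95% post-binding residence fraction and a ~10 A/ns
#' lateral drift at a 0.1 ns frame interval.
#'
#' @param n_layers Number of mineral layers (default 5).
#' @param layer_thickness Hydroxyl-to-hydroxyl z-extent of one layer, A
#'   (default 5.3).
#' @param interlayer_gap Gap between facing hydroxyl sheets, A (default 7.3,
#'   i.e. a 12.6 A d-spacing).
#' @param lattice_a Metal-metal nearest-neighbour distance, A (default 3.05).
#' @param nx,ny Number of lattice cells along x and y; both must be even so
#'   that the Al sublattice tiles periodically (defaults 12).
#' @param mg_al_ratio Mg per Al; only the stoichiometric value 3 is
#'   supported (one charge site per 4 metals).
#' @param hydration Waters per amino acid; the reference ladder is
#'   20, 15, 10, 7, 5, 3, 2, 0 but any non-negative value is accepted.
#' @param waters_per `"amino_acid"` (count waters per residue) or `"anion"`
#'   (per anion, i.e. charged molecules plus counterions).
#' @param residence_fraction Stationary adsorbed fraction of the two-state
#'   adsorption Markov chain, in `[0, 1]` (default 0.95).
#' @param switch_rate Relaxation rate of the Markov chain per frame
#'   (default 0.2; mean adsorbed bout `1/(switch_rate * (1 -
#'   residence_fraction))` frames).
#' @param hex_bias Probability that a step follows one of the six lattice
#'   directions exactly, in `[0, 1]` (default 0 = isotropic walk).
#' @param hex_offset Orientation of the six lattice directions, degrees.
#' @param step_scale Mean lateral step length per frame, A (default 1).
#' @param dt Frame interval, ns (default 0.1).
#' @param undulation_amplitude Amplitude of the sinusoidal layer
#'   undulation, A (default 0.5).
#' @param undulation_wavelength Wavelength of the undulation, A (default:
#'   the box length `nx * lattice_a`).
#' @param undulation_phases Per-layer phases, radians (default all 0:
#'   correlated undulations, constant local gap).
#' @param templated If `TRUE`, molecule anchors are seated on Al lattice
#'   columns and do not diffuse (used to emulate lattice templating).
#' @param energy_profile Function of the water count giving the mean
#'   potential energy, kJ/mol. The default, `-450 - 40 * N`, is monotone
#'   decreasing with hydration so the per-water hydration energy (-40
#'   kJ/mol) lies below the bulk-water reference.
#' @param energy_noise_sd Gaussian noise on the per-frame energy, kJ/mol.
#' @param rng_seed Integer seed controlling all generator randomness.
#' @return An object of class `claypep_config` (a validated list).
#' @export
generator_config <- function(n_layers = 5L, layer_thickness = 5.3,
                             interlayer_gap = 7.3, lattice_a = 3.05,
                             nx = 12L, ny = 12L, mg_al_ratio = 3,
                             hydration = 20, waters_per = c("amino_acid", "anion"),
                             residence_fraction = 0.95, switch_rate = 0.2,
                             hex_bias = 0, hex_offset = 0, step_scale = 1,
                             dt = 0.1, undulation_amplitude = 0.5,
                             undulation_wavelength = NULL,
                             undulation_phases = NULL, templated = FALSE,
                             energy_profile = function(n) -450 - 40 * n,
                             energy_noise_sd = 5, rng_seed = 1L) {
  waters_per <- match.arg(waters_per)
  if (mg_al_ratio != 3) {
    stop("configuration error: only the Mg3Al stoichiometry (mg_al_ratio = 3) is supported")
  }
  if (n_layers < 1 || layer_thickness <= 0 || interlayer_gap <= 0 ||
      lattice_a <= 0 || nx < 2 || ny < 2) {
    stop("configuration error: non-positive geometry")
  }
  if (nx %% 2L || ny %% 2L) {
    stop("configuration error: nx and ny must be even for a periodic Al sublattice")
  }
  if (hydration < 0) stop("configuration error: hydration must be non-negative")
  if (residence_fraction < 0 || residence_fraction > 1) {
    stop("configuration error: residence_fraction must lie in [0, 1]")
  }
  if (hex_bias < 0 || hex_bias > 1) {
    stop("configuration error: hex_bias must lie in [0, 1]")
  }
  if (switch_rate <= 0 || switch_rate > 1) {
    stop("configuration error: switch_rate must lie in (0, 1]")
  }
  cfg <- list(n_layers = as.integer(n_layers), layer_thickness = layer_thickness,
              interlayer_gap = interlayer_gap, lattice_a = lattice_a,
              nx = as.integer(nx), ny = as.integer(ny),
              mg_al_ratio = mg_al_ratio, hydration = hydration,
              waters_per = waters_per, residence_fraction = residence_fraction,
              switch_rate = switch_rate, hex_bias = hex_bias,
              hex_offset = hex_offset, step_scale = step_scale, dt = dt,
              undulation_amplitude = undulation_amplitude,
              undulation_wavelength = undulation_wavelength,
              undulation_phases = undulation_phases, templated = templated,
              energy_profile = energy_profile,
              energy_noise_sd = energy_noise_sd,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "claypep_config"
  cfg
}

# Derived slab geometry shared by build/populate/evolve.
slab_geometry <- function(config) {
  a <- config$lattice_a
  h <- a * sqrt(3) / 2
  d <- config$layer_thickness + config$interlayer_gap
  half <- config$layer_thickness / 2
  list(a = a, h = h, d = d,
       Lx = config$nx * a, Ly = config$ny * h,
       Lz = config$n_layers * d,
       z_center = half + (seq_len(config$n_layers) - 1) * d,
       z_oh_o = half - 0.6,   # hydroxyl O offset from the metal plane
       z_oh_h = half)         # hydroxyl H offset (defines layer thickness)
}

#' Build a flat LDH slab
#'
#' Constructs `n_layers` flat layers of hexagonally arranged metal atoms
#' (exactly 1 Al per 3 Mg, with Al dispersed on a periodic sublattice),
#' each decorated on both faces by hydroxyl O and H sheets, stacked along z
#' with the configured interlayer gap.
#'
#' @param config A [generator_config()].
#' @return A single-frame [trajectory()] of the mineral slab.
#' @export
#' @examples
#' slab <- build_ldh_slab(generator_config(n_layers = 2, nx = 4, ny = 4))
#' table(slab$atoms$role)
build_ldh_slab <- function(config) {
  stopifnot(inherits(config, "claypep_config"))
  g <- slab_geometry(config)
  ij <- expand.grid(i = 0:(config$nx - 1L), j = 0:(config$ny - 1L))
  x <- (ij$i + 0.5 * (ij$j %% 2)) * g$a
  y <- ij$j * g$h
  is_al <- (ij$i %% 2L == 0L) & (ij$j %% 2L == 0L)
  n_site <- length(x)

  per_layer <- function(l) {
    zc <- g$z_center[l]
    name <- c(ifelse(is_al, "AL", "MG"), rep(c("OH", "HO", "OH", "HO"), each = n_site))
    role <- c(ifelse(is_al, "LDH_METAL_AL", "LDH_METAL_MG"),
              rep(c("LDH_HYDROXYL_O", "LDH_HYDROXYL_H",
                    "LDH_HYDROXYL_O", "LDH_HYDROXYL_H"), each = n_site))
    xs <- rep(x, 5L); ys <- rep(y, 5L)
    zs <- c(rep(zc, n_site),
            rep(zc + g$z_oh_o, n_site), rep(zc + g$z_oh_h, n_site),
            rep(zc - g$z_oh_o, n_site), rep(zc - g$z_oh_h, n_site))
    list(name = name, role = role, xyz = cbind(xs, ys, zs))
  }
  parts <- lapply(seq_len(config$n_layers), per_layer)
  xyz <- do.call(rbind, lapply(parts, `[[`, "xyz"))
  n_per <- 5L * n_site
  atoms <- data.frame(
    atom_id = seq_len(nrow(xyz)),
    name = unlist(lapply(parts, `[[`, "name")),
    role = unlist(lapply(parts, `[[`, "role")),
    molecule_id = rep(seq_len(config$n_layers), each = n_per),
    residue_id = 1L,
    residue_type = "LDH",
    stringsAsFactors = FALSE)
  traj <- trajectory(atoms, xyz, c(g$Lx, g$Ly, g$Lz), time = 0)
  attr(traj, "config") <- config
  traj
}

# Normalise a species spec into a list of molecules: per molecule a character
# vector of residue codes (N- to C-terminal order).
normalize_species <- function(species) {
  if (is.data.frame(species)) {
    species <- lapply(seq_len(nrow(species)), function(i) as.list(species[i, ]))
  }
  out <- list()
  for (sp in species) {
    res <- sp$residue
    len <- if (!is.null(sp$length)) sp$length else length(res)
    count <- if (!is.null(sp$count)) sp$count else 1L
    chain <- if (length(res) == 1L) rep(res, len) else res
    if (length(chain) != len) stop("species length does not match composition")
    out <- c(out, rep(list(toupper(chain)), count))
  }
  out
}

# Side-chain charge at pH 9.5 (backbone C-terminus contributes -1 on top).
side_charge <- c(ALA = 0, ASP = -1, LEU = 0, LYS = 1, HIS = 0, TYR = 0)

# Bead template for one molecule (face = +1 geometry, z >= 0 away from the
# surface, anchor = the OT plane). Returns name/role/residue_id/offsets.
molecule_template <- function(chain) {
  name <- character(); role <- character(); resid <- integer()
  off <- NULL
  L <- length(chain)
  for (r in seq_len(L)) {
    bx <- (r - 1) * 3.0
    name <- c(name, "N"); role <- c(role, "BACKBONE_N"); resid <- c(resid, r)
    off <- rbind(off, c(bx, 0, 0.8))
    if (chain[r] == "ASP") {
      name <- c(name, "CG", "OD1", "OD2")
      role <- c(role, "SIDECHAIN_OTHER", "SIDECHAIN_O", "SIDECHAIN_O")
      resid <- c(resid, r, r, r)
      off <- rbind(off, c(bx + 0.7, 0.7, 1.2), c(bx + 0.4, 1.4, 1.2),
                   c(bx + 1.3, 1.1, 1.2))
    } else {
      name <- c(name, "CB"); role <- c(role, "SIDECHAIN_OTHER")
      resid <- c(resid, r)
      off <- rbind(off, c(bx + 0.7, 0.7, 1.2))
    }
  }
  bx <- (L - 1) * 3.0
  name <- c(name, "CT", "OT1", "OT2")
  role <- c(role, "C_TERM_C", "C_TERM_O", "C_TERM_O")
  resid <- c(resid, L, L, L)
  off <- rbind(off, c(bx + 1.4, 0, 0.8),
               c(bx + 1.85, 0.45, 0), c(bx + 0.95, -0.45, 0))
  # centre the lateral offsets on the OT midpoint (= CT column), so the
  # molecule anchor is the C-terminal carboxylate position
  off[, 1] <- off[, 1] - (bx + 1.4)
  list(name = name, role = role, residue_id = resid, offsets = off)
}

#' Populate the interlayer gaps with molecules, water and counterions
#'
#' Inserts bead amino acids/peptides, `hydration x N` water beads and
#' charge-balancing counterions into the gaps of a slab built by
#' [build_ldh_slab()]. Molecules are assigned round-robin to gaps and
#' randomly to the lower or upper face of their gap.
#'
#' @param slab Single-frame slab from [build_ldh_slab()].
#' @param species Molecule specification: a list of entries
#'   `list(residue = "ALA", length = 1, count = 10)`; `residue` may also be
#'   a vector of residue codes giving an explicit composition.
#' @param hydration Waters per amino acid (overrides the slab config if
#'   given).
#' @param counterions Number of counterions; by default charge balance
#'   against the Al count at pH 9.5 is used.
#' @param seed Integer seed for placement randomness (defaults to the slab
#'   config's `rng_seed`).
#' @return A single-frame [trajectory()] carrying the molecule metadata
#'   needed by [evolve()].
#' @export
populate_interlayer <- function(slab, species, hydration = NULL,
                                counterions = NULL, seed = NULL) {
  config <- attr(slab, "config")
  if (is.null(config)) stop("slab must come from build_ldh_slab()")
  if (config$n_layers < 2L) stop("generation error: no interlayer gap (n_layers < 2)")
  if (!is.null(hydration)) config$hydration <- hydration
  if (!is.null(seed)) config$rng_seed <- as.integer(seed)
  set.seed(config$rng_seed)
  g <- slab_geometry(config)
  chains <- normalize_species(species)
  n_mol <- length(chains)
  n_gaps <- config$n_layers - 1L
  n_res <- sum(lengths(chains))

  mol_charge <- vapply(chains, function(ch) -1 + sum(side_charge[ch]), numeric(1))
  n_al <- sum(slab$atoms$role == "LDH_METAL_AL")
  n_cl <- if (is.null(counterions)) max(0L, n_al + as.integer(sum(mol_charge))) else as.integer(counterions)
  n_wat <- switch(config$waters_per,
                  amino_acid = round(config$hydration * n_res),
                  anion = round(config$hydration * (n_mol + n_cl)))

  # crude volumetric capacity check: ~8 A^3 per bead in the gaps
  n_beads <- sum(vapply(chains, function(ch) 3L + sum(ifelse(ch == "ASP", 4L, 2L)), integer(1))) +
    n_wat + n_cl
  if (n_beads * 8 > n_gaps * g$Lx * g$Ly * config$interlayer_gap) {
    stop("generation error: interlayer volume insufficient at requested density")
  }

  # Al column xy positions, for templated placement
  al_xy <- frame_coords(slab)[slab$atoms$role == "LDH_METAL_AL" &
                                slab$atoms$molecule_id == 1L, 1:2, drop = FALSE]

  atoms <- slab$atoms
  xyz <- frame_coords(slab)
  mol0 <- max(atoms$molecule_id)
  templates <- vector("list", n_mol)
  info <- data.frame(molecule_id = integer(n_mol), gap = integer(n_mol),
                     face = integer(n_mol))
  if (config$templated && n_mol > nrow(al_xy)) {
    stop("generation error: more molecules than Al template sites")
  }
  al_pick <- if (config$templated) sample.int(nrow(al_xy), n_mol) else integer(0)

  for (m in seq_len(n_mol)) {
    tpl <- molecule_template(chains[[m]])
    gap <- ((m - 1L) %% n_gaps) + 1L
    face <- sample(c(1L, -1L), 1L)
    anchor_xy <- if (config$templated) al_xy[al_pick[m], ] else
      c(stats::runif(1, 0, g$Lx), stats::runif(1, 0, g$Ly))
    sheet <- if (face == 1L) g$z_center[gap] + g$z_oh_h else g$z_center[gap + 1L] - g$z_oh_h
    anchor_z <- sheet + face * 3.0   # desorbed start; evolve() sets the state
    pos <- cbind(anchor_xy[1] + tpl$offsets[, 1],
                 anchor_xy[2] + tpl$offsets[, 2],
                 anchor_z + face * tpl$offsets[, 3])
    pos[, 1] <- pos[, 1] %% g$Lx
    pos[, 2] <- pos[, 2] %% g$Ly
    k <- length(tpl$name)
    atoms <- rbind(atoms, data.frame(
      atom_id = nrow(atoms) + seq_len(k), name = tpl$name, role = tpl$role,
      molecule_id = mol0 + m, residue_id = tpl$residue_id,
      residue_type = chains[[m]][tpl$residue_id], stringsAsFactors = FALSE))
    xyz <- rbind(xyz, pos)
    templates[[m]] <- tpl
    info[m, ] <- c(mol0 + m, gap, face)
  }

  place_beads <- function(n, name, role, restype) {
    if (n == 0L) return(NULL)
    gap <- ((seq_len(n) - 1L) %% n_gaps) + 1L
    zlow <- g$z_center[gap] + g$z_oh_h + 2
    zhigh <- g$z_center[gap + 1L] - g$z_oh_h - 2
    data.frame(name = name, role = role, restype = restype,
               x = stats::runif(n, 0, g$Lx), y = stats::runif(n, 0, g$Ly),
               z = stats::runif(n, zlow, zhigh), stringsAsFactors = FALSE)
  }
  extra <- rbind(place_beads(n_wat, "OW", "WATER_O", "SOL"),
                 place_beads(n_cl, "CL", "COUNTERION", "ION"))
  if (!is.null(extra)) {
    atoms <- rbind(atoms, data.frame(
      atom_id = nrow(atoms) + seq_len(nrow(extra)), name = extra$name,
      role = extra$role,
      molecule_id = mol0 + n_mol + seq_len(nrow(extra)),
      residue_id = 1L, residue_type = extra$restype, stringsAsFactors = FALSE))
    xyz <- rbind(xyz, as.matrix(extra[, c("x", "y", "z")]))
  }

  traj <- trajectory(atoms, xyz, slab$box[1, ], time = 0)
  attr(traj, "config") <- config
  attr(traj, "mol_info") <- info
  attr(traj, "mol_templates") <- templates
  traj
}

#' Evolve a populated interlayer into a trajectory
#'
#' Molecules perform lateral random walks (optionally biased along the six
#' lattice directions), toggle adsorption as a two-state Markov chain whose
#' stationary adsorbed fraction equals `residence_fraction`, and ride the
#' sinusoidal layer undulation. Mineral, water and counterion beads are
#' static apart from the undulation. A per-frame potential-energy series is
#' drawn around `energy_profile(n_water)`. Fully reproducible from
#' `rng_seed`.
#'
#' @param frame0 A populated frame from [populate_interlayer()].
#' @param n_frames Number of frames to generate.
#' @param config Optional [generator_config()] overriding the one attached
#'   to `frame0`.
#' @return An object of class `claypep_sim`: list with elements
#'   `trajectory`, `energy` (an [energy_series()]), `states` (ground-truth
#'   adsorption matrix, frames x molecules) and `config`.
#' @export
evolve <- function(frame0, n_frames, config = NULL) {
  if (is.null(config)) config <- attr(frame0, "config")
  info <- attr(frame0, "mol_info")
  templates <- attr(frame0, "mol_templates")
  if (is.null(config) || is.null(info)) {
    stop("frame0 must come from populate_interlayer()")
  }
  set.seed(config$rng_seed)
  g <- slab_geometry(config)
  lambda <- if (is.null(config$undulation_wavelength)) g$Lx else config$undulation_wavelength
  phases <- if (is.null(config$undulation_phases)) rep(0, config$n_layers) else config$undulation_phases
  A <- config$undulation_amplitude
  undu <- function(x, layer) A * sin(2 * pi * x / lambda + phases[layer])

  atoms <- frame0$atoms
  base <- frame_coords(frame0)
  n_at <- nrow(base)
  M <- nrow(info)
  coords <- array(NA_real_, c(n_at, 3L, n_frames))

  # static background (mineral + solvent) with undulation applied once
  bg <- base
  ldh <- atoms$residue_type == "LDH"
  layer_of <- atoms$molecule_id[ldh]
  bg[ldh, 3] <- bg[ldh, 3] + undu(bg[ldh, 1], layer_of)

  f <- config$residence_fraction
  rho <- config$switch_rate
  q_ads <- f * rho          # desorbed -> adsorbed
  q_des <- (1 - f) * rho    # adsorbed -> desorbed
  states <- matrix(FALSE, n_frames, M)
  state <- stats::runif(M) < f
  # anchors: xy of the OT midpoint per molecule
  anchor <- matrix(0, M, 2)
  mol_rows <- vector("list", M)
  for (m in seq_len(M)) {
    rows <- which(atoms$molecule_id == info$molecule_id[m])
    mol_rows[[m]] <- rows
    ot <- rows[atoms$role[rows] == "C_TERM_O"]
    anchor[m, ] <- colMeans(base[ot, 1:2, drop = FALSE])
  }
  hexdirs <- config$hex_offset + 60 * (0:5)

  for (t in seq_len(n_frames)) {
    # Markov update (frame 1 keeps the stationary draw)
    if (t > 1L) {
      u <- stats::runif(M)
      state <- ifelse(state, u >= q_des, u < q_ads)
    }
    states[t, ] <- state
    # lateral step
    if (!config$templated && config$step_scale > 0) {
      use_hex <- stats::runif(M) < config$hex_bias
      theta <- ifelse(use_hex, sample(hexdirs, M, replace = TRUE),
                      stats::runif(M, 0, 360))
      mag <- stats::rexp(M, 1 / config$step_scale)
      if (t > 1L) {
        anchor[, 1] <- (anchor[, 1] + mag * cospi(theta / 180)) %% g$Lx
        anchor[, 2] <- (anchor[, 2] + mag * sinpi(theta / 180)) %% g$Ly
      }
    }
    fr <- bg
    for (m in seq_len(M)) {
      tpl <- templates[[m]]
      rows <- mol_rows[[m]]
      face <- info$face[m]
      gap <- info$gap[m]
      layer <- if (face == 1L) gap else gap + 1L
      phi <- stats::runif(1, 0, 2 * pi)
      R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
      xy <- tpl$offsets[, 1:2, drop = FALSE] %*% R
      x <- (anchor[m, 1] + xy[, 1]) %% g$Lx
      y <- (anchor[m, 2] + xy[, 2]) %% g$Ly
      sheet <- if (face == 1L) g$z_center[gap] + g$z_oh_h else g$z_center[gap + 1L] - g$z_oh_h
      zoff <- if (state[m]) 1.5 else 3.0
      anchor_z <- sheet + face * zoff + undu(anchor[m, 1], layer)
      fr[rows, 1] <- x
      fr[rows, 2] <- y
      fr[rows, 3] <- anchor_z + face * tpl$offsets[, 3]
    }
    coords[, , t] <- fr
  }

  n_wat <- sum(atoms$role == "WATER_O")
  energy <- config$energy_profile(n_wat) +
    stats::rnorm(n_frames, 0, config$energy_noise_sd)
  time <- (seq_len(n_frames) - 1) * config$dt
  traj <- trajectory(atoms, coords, frame0$box[1, ], time)
  colnames(states) <- info$molecule_id
  out <- list(trajectory = traj,
              energy = energy_series(energy, n_wat, time = time),
              states = states, config = config)
  class(out) <- "claypep_sim"
  out
}

#' @export
print.claypep_sim <- function(x, ...) {
  cat(sprintf("claypep simulation: %d frames, %d molecules, %d waters (%.0f W/AA)\n",
              n_frames(x$trajectory), ncol(x$states), x$energy$n_water,
              x$config$hydration))
  invisible(x)
}
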