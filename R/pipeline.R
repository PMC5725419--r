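# Pipeline orchestration: one configured run from generation through
# analysis to a report bundle on disk.

#' Run a configured analysis pipeline
#'
#' Executes the requested stages in dependency order and writes CSV/JSON
#' reports plus a provenance record into `outdir`. Stages:
#' `generate` (synthetic trajectory + energy series), `layers` (layer
#' assignment, d-spacing, undulation), `adsorption`, `rdf`, `orient`,
#' `pairs`, `diffusion`, `residence`, `energy`, `kinetics`. Stages that
#' need the adsorption series pull it in automatically (noted in the log).
#' A stage failure is recorded, dependent stages are skipped, independent
#' stages continue; the returned bundle lists all failures.
#'
#' @param config A list, or path to a YAML file, with entries `seed`,
#'   `outdir`, `stages` (character vector), and optional parameter blocks
#'   `generator` (arguments of [generator_config()]), `species`,
#'   `n_frames`, `analysis` (cutoffs etc.), `kinetics` (arguments of
#'   [kinetic_params()] plus `n_cycles`). Unknown top-level keys are
#'   rejected.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the stage results, the paths written and
#'   any failures. Nonzero `length(result$failures)` signals failure.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("seed", "outdir", "stages", "generator", "species", "n_frames",
             "analysis", "kinetics")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  outdir <- if (is.null(config$outdir)) stop("config needs an outdir") else config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  if (is.null(stages)) stages <- c("generate", "layers", "adsorption")
  needs_ads <- c("pairs", "diffusion", "residence", "orient")
  if (any(stages %in% needs_ads) && !"adsorption" %in% stages) {
    stages <- append(stages, "adsorption", after = which(stages == "generate")[1])
    if (!quiet) message("dependency: adsorption stage auto-inserted")
  }
  log <- function(...) if (!quiet) message(sprintf(...))
  res <- list(); paths <- character(0); failures <- character(0)
  ana <- config$analysis

  run_stage <- function(name, fun) {
    out <- tryCatch(fun(), error = function(e) {
      failures <<- c(failures, sprintf("%s: %s", name, conditionMessage(e)))
      log("stage %s FAILED: %s", name, conditionMessage(e))
      NULL
    })
    res[[name]] <<- out
    invisible(out)
  }

  if ("generate" %in% stages) {
    run_stage("generate", function() {
      gen_args <- config$generator
      gen_args$rng_seed <- seed
      cfg <- do.call(generator_config, as.list(gen_args))
      species <- config$species
      if (is.null(species)) species <- list(list(residue = "ALA", length = 1, count = 10))
      nf <- if (is.null(config$n_frames)) 100L else as.integer(config$n_frames)
      slab <- build_ldh_slab(cfg)
      frame0 <- populate_interlayer(slab, species)
      sim <- evolve(frame0, nf)
      p1 <- file.path(outdir, "trajectory.pdb")
      p2 <- file.path(outdir, "energies.csv")
      write_trajectory(sim$trajectory, p1)
      write_energy_csv(sim$energy, p2)
      paths <<- c(paths, p1, p2)
      log("generate: %d frames, %d atoms", nf, n_atoms(sim$trajectory))
      sim
    })
  }
  traj <- res$generate$trajectory

  if ("layers" %in% stages && !is.null(traj)) {
    run_stage("layers", function() {
      eps <- if (is.null(ana$eps)) 5 else ana$eps
      la <- assign_layers(traj, eps = eps)
      ds <- d_spacing(la, traj)
      un <- undulation(la, traj)
      p <- file.path(outdir, "layers.json")
      jsonlite::write_json(list(mean_z = la$mean_z, n_noise = la$n_noise,
                                d_spacing = ds$pairs,
                                undulation = un$per_layer,
                                pooled_undulation_sd = un$pooled),
                           p, auto_unbox = TRUE, digits = NA)
      paths <<- c(paths, p)
      list(assignment = la, d_spacing = ds, undulation = un)
    })
  }

  if ("adsorption" %in% stages && !is.null(traj)) {
    run_stage("adsorption", function() {
      cutoff <- if (is.null(ana$cutoff)) 2.5 else ana$cutoff
      ads <- adsorption_series(traj, cutoff = cutoff)
      fr <- adsorption_fraction(traj, ads)
      p <- file.path(outdir, "adsorption.csv")
      utils::write.csv(fr$series, p, row.names = FALSE)
      paths <<- c(paths, p)
      list(series = ads, fraction = fr)
    })
  }
  ads <- res$adsorption$series

  if ("rdf" %in% stages && !is.null(traj)) {
    run_stage("rdf", function() {
      r_max <- if (is.null(ana$r_max)) 12 else ana$r_max
      ot_al <- rdf(traj, "C_TERM_O", "LDH_METAL_AL", r_max = r_max)
      al_al <- rdf(traj, "LDH_METAL_AL", "LDH_METAL_AL", r_max = r_max)
      p <- file.path(outdir, "rdf.csv")
      utils::write.csv(data.frame(r = ot_al$table$r, g_ot_al = ot_al$table$g,
                                  g_al_al = al_al$table$g), p, row.names = FALSE)
      paths <<- c(paths, p)
      list(ot_al = ot_al, al_al = al_al)
    })
  }

  if ("orient" %in% stages && !is.null(traj) && !is.null(ads)) {
    run_stage("orient", function() {
      oh <- orientation_histogram(traj, ads)
      p <- file.path(outdir, "orientation.csv")
      utils::write.csv(data.frame(theta = 0:89 + 0.5, count = oh$counts),
                       p, row.names = FALSE)
      paths <<- c(paths, p)
      oh
    })
  }

  if ("pairs" %in% stages && !is.null(traj) && !is.null(ads)) {
    run_stage("pairs", function() {
      pr <- reactive_pairs(traj, ads,
                           cutoff = if (is.null(ana$pair_cutoff)) 4 else ana$pair_cutoff)
      p <- file.path(outdir, "reactive_pairs.csv")
      utils::write.csv(pr$series, p, row.names = FALSE)
      paths <<- c(paths, p)
      pr
    })
  }

  if ("diffusion" %in% stages && !is.null(traj) && !is.null(ads)) {
    run_stage("diffusion", function() {
      dv <- track_velocities(traj, ads)
      sf <- direction_autocorrelation(dv, seed = seed)
      p <- file.path(outdir, "diffusion.csv")
      utils::write.csv(dv$steps, p, row.names = FALSE)
      paths <<- c(paths, p)
      list(velocities = dv, sixfold = sf)
    })
  }

  if ("residence" %in% stages && !is.null(ads)) {
    run_stage("residence", function() residence(ads))
  }

  if ("energy" %in% stages && !is.null(res$generate)) {
    run_stage("energy", function() {
      # reference dry system: same generator, hydration 0
      gen_args <- config$generator
      gen_args$rng_seed <- seed + 1L
      gen_args$hydration <- 0
      cfg <- do.call(generator_config, as.list(gen_args))
      species <- config$species
      if (is.null(species)) species <- list(list(residue = "ALA", length = 1, count = 10))
      dry <- evolve(populate_interlayer(build_ldh_slab(cfg), species),
                    n_frames(res$generate$trajectory))
      if (res$generate$energy$n_water == 0L) {
        stop("hydrated run has zero waters; no hydration energy defined")
      }
      hydration_energy(res$generate$energy, dry$energy)
    })
  }

  if ("kinetics" %in% stages) {
    run_stage("kinetics", function() {
      kin <- config$kinetics
      n_cycles <- if (is.null(kin$n_cycles)) 20L else as.integer(kin$n_cycles)
      kin$n_cycles <- NULL
      params <- do.call(kinetic_params, as.list(kin))
      cyc <- run_cycles(n_cycles, params)
      p <- file.path(outdir, "kinetics_surface.csv")
      m <- as.data.frame(cyc$surface)
      names(m) <- paste0("X", seq_len(ncol(m)))
      utils::write.csv(cbind(cycle = seq_len(nrow(m)), m), p, row.names = FALSE)
      p2 <- file.path(outdir, "kinetics_summary.json")
      jsonlite::write_json(list(first_reach = cyc$first_reach,
                                theta = params$theta, mode = params$mode),
                           p2, auto_unbox = TRUE, digits = NA)
      paths <<- c(paths, p, p2)
      cyc
    })
  }

  # provenance: enough to reproduce every output (no timestamp, so repeated
  # runs of the same config are bit-identical)
  cfg_json <- file.path(outdir, "config_used.json")
  cfg_out <- config
  cfg_out$generator$energy_profile <- NULL  # closures are not serialisable
  jsonlite::write_json(cfg_out, cfg_json, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  prov <- list(seed = seed, stages = stages,
               config_md5 = unname(tools::md5sum(cfg_json)),
               package = "claypep",
               version = as.character(utils::packageVersion("claypep")),
               r_version = paste(R.version$major, R.version$minor, sep = "."),
               failures = failures)
  jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  paths <- c(paths, cfg_json, file.path(outdir, "provenance.json"))
  invisible(list(results = res, paths = paths, failures = failures,
                 stages = stages))
}
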