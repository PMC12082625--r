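#' Default pipeline configuration
#'
#' Returns the full configuration list for [run_pipeline()], with every
#' stage parameter at its documented default. Supply a YAML file or a
#' named list to override entries; unknown keys are rejected.
#'
#' @param ... Named overrides (e.g. `alpha = 0.5`, `seed = 7`).
#' @return Named list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    # inputs: either a fixture directory or explicit files
    fixture_dir = NULL,
    dark_model = NULL, fo_dark = NULL, fo_mix = NULL,
    # simulate stage (used when no inputs are given)
    size_class = "tiny", n_true = 0.3, noise_frac = 0.03, noise_floor = 0,
    d_min = 1.8, seed = 1,
    cluster_shift = 0.6, fe_s_bond = 3.0, bend = c(5, 7),
    # stage toggles
    stages = c("simulate", "scale", "diffmap", "extrapolate", "bend",
               "geometry"),
    # scaling / weighting / maps
    alpha = 1, n_shells = 20, low_cut = 10, contour = 3.5,
    # occupancy scan (alpha = 0 for the scan: the outlier term shrinks
    # exactly the strong differences the vacancy signal lives in)
    scan_alpha = 0, roi_selection = "SF4", roi_radius = 1.5,
    threshold_sigma = 3,
    # bending refinement
    flavin_selection = "FLV", scan_bound = 12, scan_step = 0.5,
    mask_radius = 2.5,
    out_dir = NULL)
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over))) {
    over <- over[[1]]
  }
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = c("run_config", "list"))
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are [default_config()] entries.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  default_config(yaml::read_yaml(path))
}

validate_config <- function(cfg) {
  for (f in c("dark_model", "fo_dark", "fo_mix")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      stop("config input does not exist: ", f, " = ", cfg[[f]])
    }
  }
  stopifnot(cfg$alpha >= 0, cfg$n_shells >= 1, cfg$low_cut > 0,
            cfg$scan_step > 0, cfg$roi_radius > 0,
            cfg$n_true >= 0, cfg$n_true <= 1)
  invisible(cfg)
}

#' Write the packaged demo fixture
#'
#' Generates the documented demonstration scenario at toy scale: a
#' two-state crystal with the 4Fe-4S cluster shifted 0.6 Angstrom, the
#' Fe4-SG4 bond elongated from 2.3 to 3.0 Angstrom, a (5, 7) degree
#' flavin butterfly bend, mixed at occupancy 0.3 with 3% amplitude
#' noise.
#'
#' @param dir Output directory.
#' @param seed RNG seed.
#' @param n_true,noise_frac,bend Scenario overrides.
#' @return The `two_state_fixture`, invisibly; files under `dir`.
#' @export
generate_demo <- function(dir, seed = 1, n_true = 0.3, noise_frac = 0.03,
                          bend = c(5, 7)) {
  fx <- demo_fixture(seed = seed, n_true = n_true, noise_frac = noise_frac,
                     bend = bend)
  write_fixture(fx, dir)
  invisible(fx)
}

demo_fixture <- function(seed = 1, n_true = 0.3, noise_frac = 0.03,
                         bend = c(5, 7), size_class = "tiny", d_min = 1.8,
                         cluster_shift = 0.6, fe_s_bond = 3.0) {
  spec <- perturbation_spec(
    displacement = list(selection = "SF4",
                        vector = c(cluster_shift, 0, 0)),
    elongate_bond = list(from = list(name = "SG4"), to = list(name = "FE4"),
                         length = fe_s_bond),
    bend = bend)
  two_state_fixture(size_class = size_class, n_true = n_true,
                    perturbation = spec, noise_frac = noise_frac,
                    d_min = d_min, seed = seed)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order -- simulate (or load inputs),
#' scale, difference map, occupancy scan, bending refinement, geometry
#' report -- and returns a manifest with every parameter, seed and
#' headline number. A stage failure is recorded and its dependents are
#' skipped. The run is deterministic for a fixed config.
#'
#' @param config A `run_config` (see [default_config()]), a named list
#'   of overrides, or a YAML path.
#' @return List of class `pipeline_run`: `manifest` (parameters,
#'   headline numbers, per-stage status), plus the stage objects
#'   (`fixture`, `scale`, `ded`, `scan`, `bending`, `geometry`).
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- read_config(config)
  if (!inherits(config, "run_config")) config <- default_config(config)
  validate_config(config)
  run <- list(config = config)
  status <- list()
  headline <- list()
  fail <- function(stage, err) {
    status[[stage]] <<- paste("failed:", conditionMessage(err))
  }
  stages <- config$stages

  # --- inputs -------------------------------------------------------
  if ("simulate" %in% stages && is.null(config$fixture_dir) &&
      is.null(config$dark_model)) {
    fx <- demo_fixture(seed = config$seed, n_true = config$n_true,
                       noise_frac = config$noise_frac, bend = config$bend,
                       size_class = config$size_class, d_min = config$d_min,
                       cluster_shift = config$cluster_shift,
                       fe_s_bond = config$fe_s_bond)
    status$simulate <- "ok"
  } else if (!is.null(config$fixture_dir)) {
    fx <- read_fixture(config$fixture_dir)
    status$simulate <- "loaded"
  } else {
    dark <- read_model(config$dark_model)
    fx <- list(ground = dark, excited = NULL,
               fo_dark = read_reflections_tsv(config$fo_dark),
               fo_mix = read_reflections_tsv(config$fo_mix),
               fc_dark = calc_structure_factors(dark, config$d_min),
               n_true = NA_real_)
    status$simulate <- "loaded"
  }
  run$fixture <- fx
  headline$n_true <- fx$n_true

  # --- scaling ------------------------------------------------------
  diffs <- NULL
  if ("scale" %in% stages) {
    sc <- tryCatch({
      sc_dark <- scale_to_reference(fx$fo_dark, fx$fc_dark)
      sc_mix <- scale_to_reference(fx$fo_mix, fx$fc_dark)
      diffs <- qweight_differences(sc_mix$scaled, sc_dark$scaled,
                                   alpha = config$alpha,
                                   n_shells = config$n_shells)
      status$scale <- "ok"
      list(dark = sc_dark, mix = sc_mix)
    }, error = function(e) { fail("scale", e); diffs <<- NULL; NULL })
    run$scale <- sc
    if (!is.null(sc)) {
      headline$scale_k_dark <- sc$dark$result$k
      headline$scale_k_mix <- sc$mix$result$k
    }
  }

  # --- difference map ----------------------------------------------
  if ("diffmap" %in% stages) {
    ded <- if (is.null(diffs)) {
      status$diffmap <- "skipped (no scaled differences)"; NULL
    } else {
      tryCatch({
        d <- fofo_map(diffs, fx$fc_dark, low_cut = config$low_cut,
                      contour = config$contour, model = fx$ground)
        status$diffmap <- "ok"
        d
      }, error = function(e) { fail("diffmap", e); NULL })
    }
    run$ded <- ded
    if (!is.null(ded) && nrow(ded$peaks)) {
      headline$top_peak_sigma <- ded$peaks$height_sigma[1]
      headline$top_peak_atom <- ded$peaks$nearest_atom[1]
    }
  }

  # --- occupancy scan ----------------------------------------------
  if ("extrapolate" %in% stages) {
    scan <- if (is.null(diffs) || is.null(run$ded)) {
      status$extrapolate <- "skipped (needs diffmap stage)"; NULL
    } else {
      tryCatch({
        roi <- make_region_mask(run$ded$map, fx$ground, config$roi_selection,
                                config$roi_radius)
        scan_diffs <- qweight_differences(run$scale$mix$scaled,
                                          run$scale$dark$scaled,
                                          alpha = config$scan_alpha,
                                          n_shells = config$n_shells)
        s <- occupancy_scan(fx$fc_dark, scan_diffs, roi,
                            threshold_sigma = config$threshold_sigma)
        status$extrapolate <- "ok"
        s
      }, error = function(e) { fail("extrapolate", e); NULL })
    }
    run$scan <- scan
    if (!is.null(scan)) headline$n_est <- scan$n_est
  }

  # --- bending refinement ------------------------------------------
  if ("bend" %in% stages) {
    bending <- if (is.null(diffs)) {
      status$bend <- "skipped (no scaled differences)"; NULL
    } else {
      tryCatch({
        # quantitative refinement runs on sigma-only weighted differences
        # (the outlier term would shrink the bend signal itself)
        qdiffs <- qweight_differences(run$scale$mix$scaled,
                                      run$scale$dark$scaled,
                                      alpha = config$scan_alpha,
                                      n_shells = config$n_shells)
        ded_q <- fofo_map(qdiffs, fx$fc_dark, low_cut = config$low_cut,
                          contour = config$contour)
        frame <- flavin_frame(fx$ground, config$flavin_selection)
        b <- dfocc_refine(ded_q, fx$ground, frame,
                          scan_bound = config$scan_bound,
                          step = config$scan_step,
                          mask_radius = config$mask_radius,
                          d_min = config$d_min)
        status$bend <- "ok"
        b
      }, error = function(e) { fail("bend", e); NULL })
    }
    run$bending <- bending
    if (!is.null(bending)) {
      headline$rho_c <- bending$rho_c
      headline$rho_n <- bending$rho_n
      headline$dfocc <- bending$dfocc
    }
  }

  # --- geometry report ---------------------------------------------
  if ("geometry" %in% stages) {
    geom <- tryCatch({
      g <- geometry_report(fx)
      status$geometry <- "ok"
      g
    }, error = function(e) { fail("geometry", e); NULL })
    run$geometry <- geom
    if (!is.null(geom)) {
      headline$fe_sg_distance <- geom$fe_sg_distance
      headline$mean_cluster_displacement <- geom$mean_cluster_displacement
      headline$bfactor_pearson <- geom$bfactor_pearson
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("redoxmap")),
    parameters = unclass(config),
    stages = status,
    headline = headline)
  run$manifest <- manifest
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(run$ded)) {
      write_ccp4(run$ded$map, file.path(config$out_dir, "ded.ccp4"))
      utils::write.table(run$ded$peaks, file.path(config$out_dir, "peaks.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  }
  structure(run, class = "pipeline_run")
}

geometry_report <- function(fx) {
  g <- list()
  if (!is.null(fx$excited)) {
    g$fe_sg_distance <- min_edge_distance(
      fx$excited, list(name = "FE4"), list(name = "SG4"))
    disp <- displacement_profile(fx$ground, fx$excited, selection = "SF4")
    g$mean_cluster_displacement <- mean(disp$displacement)
    g$displacements <- displacement_profile(fx$ground, fx$excited)
    bf <- tryCatch(bfactor_profiles(fx$ground, fx$excited),
                   error = function(e) NULL)
    g$bfactor_pearson <- if (is.null(bf)) NA_real_ else bf$r
    g$flavin_cluster_edge <- min_edge_distance(fx$ground, "FLV",
                                               c("SF4", "CYS"))
    g$adp <- adp_eigen(fx$ground, "SF4")
    frame <- tryCatch(flavin_frame(fx$excited, "FLV"), error = function(e) NULL)
    if (!is.null(frame)) {
      ba <- butterfly_angles(fx$excited, frame)
      g$excited_rho_c <- unname(ba["rho_c"])
      g$excited_rho_n <- unname(ba["rho_n"])
    }
  }
  g
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>\n stages:\n")
  for (s in names(x$manifest$stages)) {
    cat(sprintf("  %-12s %s\n", s, x$manifest$stages[[s]]))
  }
  cat(" headline:\n")
  h <- x$manifest$headline
  for (s in names(h)) {
    v <- h[[s]]
    cat(sprintf("  %-26s %s\n", s,
                if (is.numeric(v)) signif(v, 5) else as.character(v)))
  }
  invisible(x)
}

#' Read a fixture bundle written by [write_fixture()]
#'
#' @param dir Fixture directory.
#' @return A `two_state_fixture` (manifest parameters restored).
#' @export
read_fixture <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  ground <- read_model(file.path(dir, "ground.pdb"))
  excited <- read_model(file.path(dir, "excited.pdb"))
  structure(list(ground = ground, excited = excited,
                 n_true = man$n_true, noise_frac = man$noise_frac,
                 noise_floor = man$noise_floor, seed = man$seed,
                 d_min = man$d_min,
                 fo_dark = read_reflections_tsv(file.path(dir, "fo_dark.tsv")),
                 fo_mix = read_reflections_tsv(file.path(dir, "fo_mix.tsv")),
                 fc_dark = read_reflections_tsv(file.path(dir, "fc_dark.tsv")),
                 manifest = man),
            class = "two_state_fixture")
}
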