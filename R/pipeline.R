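#' Assemble a pipeline configuration
#'
#' Central configuration for the end-to-end pipeline. Values may come
#' from a YAML file, an R list, or both (explicit arguments override the
#' file). Unknown keys are rejected with their location.
#'
#' @param path Optional YAML config file.
#' @param overrides Named list overriding file values.
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    paths = list(bundle = "bundle", output = "output"),
    visual = list(system = "trichromat_visible", egg_system = "bluetit_uvs",
                  weber_reference_e = 0.05, receptor_manifest = NULL),
    metrics = list(jnd_radius = 2.0, n_luminance_bins = 32,
                   n_pattern_scales = 33, pixel_budget = 2000,
                   downsample = "subsample"),
    stats = list(alpha = 0.05,
                 protected = list(plumage = "taxon_group",
                                  behaviour = "model_type")),
    simulate = list(grid_dim = 44, n_specimens = 8,
                    arms = list(female_cuckoo_finch = 17, female_bishop = 16,
                                male_bishop = 18),
                    arm_rejection_probs = list(female_cuckoo_finch = 0.582,
                                               female_bishop = 0.625,
                                               male_bishop = 0.389),
                    colour_jnd_effect = 0.29, n_pairs = 15),
    seed = 1L)
  cfg <- defaults
  merge_into <- function(base, extra, where) {
    for (k in names(extra)) {
      if (!k %in% names(base))
        stop(sprintf("invalid config key '%s' at %s", k, where))
      if (is.list(base[[k]]) && is.list(extra[[k]]) &&
          !is.null(names(base[[k]])))
        base[[k]] <- merge_into(base[[k]], extra[[k]],
                                paste0(where, "$", k))
      else base[[k]] <- extra[[k]]
    }
    base
  }
  if (!is.null(path)) cfg <- merge_into(cfg, yaml::read_yaml(path), "config")
  if (length(overrides)) cfg <- merge_into(cfg, overrides, "overrides")
  stopifnot(cfg$metrics$jnd_radius > 0, cfg$metrics$pixel_budget >= 1,
            cfg$stats$alpha > 0, cfg$stats$alpha < 1)
  structure(cfg, class = "pipeline_config")
}

write_manifest <- function(cfg, out_dir, stage) {
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(cfg), f)
  yaml::write_yaml(list(
    stage = stage, seed = cfg$seed,
    config_md5 = unname(tools::md5sum(f)),
    package_version = as.character(utils::packageVersion("mimicspec")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    file.path(out_dir, paste0("manifest_", stage, ".yaml")))
  unlink(f)
}

#' Write a complete synthetic input bundle
#'
#' Runs the generators and serializes everything the analysis stages
#' read: per-specimen-region float TIFF images (three chromatic channels
#' plus a double-cone luminance channel, scaled by a random gain so the
#' normalization step is exercised) with patch and grey-standard masks
#' and a manifest CSV; long-format egg spectra, outlines and nest checks;
#' the aggression trial table; and ground-truth files.
#'
#' @param cfg A [pipeline_config()].
#' @return The bundle directory, invisibly.
#' @export
pipeline_simulate <- function(cfg) {
  dir.create(cfg$paths$bundle, recursive = TRUE, showWarnings = FALSE)
  bd <- cfg$paths$bundle
  gd <- cfg$simulate$grid_dim
  spec_set <- generate_specimens(
    default_taxa(n_specimens = cfg$simulate$n_specimens),
    seed = child_seed(cfg$seed, "bundle/specimens"), grid_dim = gd)
  img_dir <- file.path(bd, "images"); dir.create(img_dir, showWarnings = FALSE)
  man <- list()
  std_cols <- 8L
  write_specimen <- function(sp, taxon_group) {
    gain <- withr::with_seed(child_seed(cfg$seed, paste0("gain/", sp$id)),
                             stats::runif(1, 0.5, 4))
    for (rg in names(sp$patches)) {
      p <- sp$patches[[rg]]
      px <- array(0, c(gd, gd + std_cols, 4))
      for (ch in 1:3) px[, 1:gd, ch] <- matrix(p$catches[, ch], gd, gd)
      px[, 1:gd, 4] <- p$grid
      px[, gd + seq_len(std_cols), ] <- 0.40
      img <- file.path(img_dir, sprintf("%s_%s.tif", sp$id, rg))
      tiff::writeTIFF(pmin(px * gain / 4, 1), img, bits.per.sample = 32)
      pm <- matrix(0, gd, gd + std_cols); pm[, 1:gd] <- 1
      sm <- matrix(0, gd, gd + std_cols); sm[, gd + seq_len(std_cols)] <- 1
      mask_p <- file.path(img_dir, sprintf("%s_%s_mask.png", sp$id, rg))
      mask_s <- file.path(img_dir, sprintf("%s_%s_std.png", sp$id, rg))
      png::writePNG(pm, mask_p); png::writePNG(sm, mask_s)
      man[[length(man) + 1L]] <<- data.frame(
        specimen_id = sp$id, taxon_group = taxon_group, region = rg,
        image_path = basename(img), mask_path = basename(mask_p),
        standard_mask_path = basename(mask_s), stringsAsFactors = FALSE)
    }
  }
  for (sp in spec_set$focal) write_specimen(sp, "focal")
  for (grp in names(spec_set$others))
    for (sp in spec_set$others[[grp]]) write_specimen(sp, grp)
  utils::write.csv(do.call(rbind, man), file.path(bd, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(spec_set$ground_truth,
                   file.path(bd, "ground_truth_specimens.csv"),
                   row.names = FALSE)

  es <- experiment_spec(
    arms = unlist(cfg$simulate$arms),
    arm_rejection_probs = unlist(cfg$simulate$arm_rejection_probs),
    colour_jnd_effect = cfg$simulate$colour_jnd_effect,
    n_pairs = cfg$simulate$n_pairs,
    seed = child_seed(cfg$seed, "bundle/eggs"))
  eg <- generate_egg_experiment(es)
  spec_rows <- list(); out_rows <- list(); patt <- list()
  for (pid in names(eg$eggs)) for (egrec in eg$eggs[[pid]]) {
    for (k in seq_along(egrec$spectra)) {
      s <- egrec$spectra[[k]]
      spec_rows[[length(spec_rows) + 1L]] <- data.frame(
        clutch_id = pid, egg_id = egrec$egg_id, role = egrec$role,
        replicate = k, wavelength_nm = s$wavelength_nm,
        reflectance = s$value)
    }
    out_rows[[length(out_rows) + 1L]] <- data.frame(
      clutch_id = pid, egg_id = egrec$egg_id, role = egrec$role,
      x_mm = egrec$outline[, 1], y_mm = egrec$outline[, 2])
    patt[[length(patt) + 1L]] <- data.frame(
      egg_id = egrec$egg_id,
      t(as.vector(egrec$pattern_patch)))
  }
  utils::write.csv(do.call(rbind, spec_rows),
                   file.path(bd, "egg_spectra.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, out_rows),
                   file.path(bd, "egg_outlines.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, patt),
                   file.path(bd, "egg_patterns.csv"), row.names = FALSE)
  utils::write.csv(eg$nest_checks, file.path(bd, "nest_checks.csv"),
                   row.names = FALSE)
  arm_tab <- unique(eg$rejection_table[, c("pair_id", "model_type")])
  utils::write.csv(arm_tab, file.path(bd, "egg_arms.csv"), row.names = FALSE)
  utils::write.csv(eg$rejection_table, file.path(bd, "ground_truth_eggs.csv"),
                   row.names = FALSE)

  trials <- generate_aggression_trials(es, seed = child_seed(cfg$seed, "bundle/trials"))
  utils::write.csv(trials, file.path(bd, "trials.csv"), row.names = FALSE)
  write_manifest(cfg, bd, "simulate")
  invisible(bd)
}

# Read one manifest row back into a cone-catch patch.
read_specimen_patch <- function(row, img_dir, cfg) {
  img <- read_linear_image(file.path(img_dir, row$image_path),
                           c("SWS", "MWS", "LWS", "DBL"))
  std <- grey_standard(read_mask(file.path(img_dir, row$standard_mask_path)),
                       reflectance = 0.40)
  img <- normalize_to_standard(img, std)
  patch <- extract_patch(img, read_mask(file.path(img_dir, row$mask_path)),
                         row$region)
  patch <- downsample_patch(patch, budget = cfg$metrics$pixel_budget,
                            seed = child_seed(cfg$seed, row$image_path),
                            method = cfg$metrics$downsample)
  lumgrid <- if (!is.null(patch$coords))
    patch_luminance_grid(patch$coords, pmax(patch$values[, "DBL"], 1e-6))
  else NULL
  cone_catch_patch(pmax(patch$values[, c("SWS", "MWS", "LWS")], 1e-6),
                   pmax(patch$values[, "DBL"], 1e-6), row$region,
                   grid = lumgrid$grid, grid_mask = lumgrid$mask)
}

#' Compare plumage across the bundle's specimens
#'
#' Reads the image bundle back through calibration (grey-standard
#' normalization, patch extraction, downsampling), rebuilds cone-catch
#' patches and writes the specimen-pair comparison table and its
#' group-by-region summary.
#'
#' @param cfg A [pipeline_config()].
#' @return The comparison table, invisibly.
#' @export
pipeline_plumage_compare <- function(cfg) {
  bd <- cfg$paths$bundle
  dir.create(cfg$paths$output, recursive = TRUE, showWarnings = FALSE)
  man <- utils::read.csv(file.path(bd, "manifest.csv"),
                         stringsAsFactors = FALSE)
  img_dir <- file.path(bd, "images")
  load_group <- function(rows) {
    lapply(split(rows, rows$specimen_id), function(rr) {
      patches <- list()
      for (i in seq_len(nrow(rr)))
        patches[[rr$region[i]]] <- read_specimen_patch(rr[i, ], img_dir, cfg)
      list(id = rr$specimen_id[1], patches = patches)
    })
  }
  focal <- load_group(man[man$taxon_group == "focal", ])
  others <- lapply(split(man[man$taxon_group != "focal", ],
                         man$taxon_group[man$taxon_group != "focal"]),
                   load_group)
  e <- weber_from_abundances(c(SWS = 0.70, MWS = 0.99, LWS = 1.00),
                             list("LWS", cfg$visual$weber_reference_e))
  tab <- build_comparison_table(focal, others, e,
                                e_D = cfg$visual$weber_reference_e,
                                radius_jnd = cfg$metrics$jnd_radius)
  utils::write.csv(tab, file.path(cfg$paths$output, "plumage_comparisons.csv"),
                   row.names = FALSE)
  utils::write.csv(attr(tab, "summary"),
                   file.path(cfg$paths$output, "plumage_summary.csv"),
                   row.names = FALSE)
  write_manifest(cfg, cfg$paths$output, "plumage-compare")
  invisible(tab)
}

#' Quantify egg differences and classify outcomes
#'
#' Reads egg spectra, outlines, shell patterns and nest checks from the
#' bundle, computes per-pair host-vs-experimental differences (colour and
#' luminance JNDs from spectra, pattern via the granularity pipeline,
#' shape and volume from outlines), classifies rejection outcomes from
#' the nest checks, and writes the rejection analysis table.
#'
#' @param cfg A [pipeline_config()].
#' @return The rejection table, invisibly.
#' @export
pipeline_egg_analysis <- function(cfg) {
  bd <- cfg$paths$bundle
  dir.create(cfg$paths$output, recursive = TRUE, showWarnings = FALSE)
  spectra <- utils::read.csv(file.path(bd, "egg_spectra.csv"),
                             stringsAsFactors = FALSE)
  outlines <- utils::read.csv(file.path(bd, "egg_outlines.csv"),
                              stringsAsFactors = FALSE)
  patterns <- utils::read.csv(file.path(bd, "egg_patterns.csv"),
                              stringsAsFactors = FALSE)
  checks <- utils::read.csv(file.path(bd, "nest_checks.csv"),
                            stringsAsFactors = FALSE)
  arms <- utils::read.csv(file.path(bd, "egg_arms.csv"),
                          stringsAsFactors = FALSE)
  receptors <- switch(cfg$visual$egg_system,
                      bluetit_uvs = bluetit_uvs(),
                      peafowl_vs = peafowl_vs(),
                      stop("unknown egg visual system: ", cfg$visual$egg_system))
  rows <- list()
  for (pid in unique(spectra$clutch_id)) {
    sp <- spectra[spectra$clutch_id == pid, ]
    mk_rec <- function(eid) {
      se <- sp[sp$egg_id == eid, ]
      reps <- lapply(split(se, se$replicate), function(d)
        spectrum(d$wavelength_nm, d$reflectance))
      ol <- outlines[outlines$egg_id == eid, c("x_mm", "y_mm")]
      pat <- as.numeric(patterns[patterns$egg_id == eid, -1])
      dimp <- as.integer(sqrt(length(pat)))
      egg_record(pid, eid, unique(se$role), unname(reps), ol,
                 matrix(pat, dimp, dimp), n_replicates = length(reps))
    }
    eggs <- lapply(unique(sp$egg_id), mk_rec)
    roles <- vapply(eggs, `[[`, character(1), "role")
    clutch <- eggs[roles == "host"]; forn <- eggs[roles == "experimental"][[1]]
    jnds <- egg_colour_luminance_jnd(clutch, forn, receptors)
    pat_host <- Reduce(`+`, lapply(clutch, `[[`, "pattern_patch")) / length(clutch)
    vs_host <- lapply(clutch, function(eg) egg_volume_shape(eg$outline))
    vs_forn <- egg_volume_shape(forn$outline)
    ck <- checks[checks$clutch_id == pid, ]
    outc <- classify_outcome(ck, initial_count = length(eggs))
    rows[[length(rows) + 1L]] <- data.frame(
      pair_id = pid,
      model_type = arms$model_type[arms$pair_id == pid][1],
      colour_jnd = jnds[["colour_jnd"]],
      luminance_jnd = jnds[["luminance_jnd"]],
      pattern_diff = egg_pattern_diff(pat_host, forn$pattern_patch),
      shape_diff = egg_shape_diff(
        vs_forn, Reduce(`+`, vs_host) / length(vs_host), scale = c(0.2, 0.05)),
      volume_diff = abs(vs_forn[["volume_mm3"]] -
                          mean(vapply(vs_host, `[[`, numeric(1), "volume_mm3"))),
      outcome_class = as.character(outc),
      outcome = as.integer(outc == "rejected"),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, file.path(cfg$paths$output, "egg_differences.csv"),
                   row.names = FALSE)
  write_manifest(cfg, cfg$paths$output, "egg-analysis")
  invisible(tab)
}

#' Run the inference stage on pipeline outputs
#'
#' Loads whichever analysis tables exist in the output directory (plumage
#' comparisons, aggression trials from the bundle, egg differences), runs
#' [run_study_models()] and writes tidy coefficient tables (full and
#' final), elimination traces and pairwise contrast tables.
#'
#' @param cfg A [pipeline_config()].
#' @return The model bundle, invisibly.
#' @export
pipeline_behaviour_stats <- function(cfg) {
  od <- cfg$paths$output
  dir.create(od, recursive = TRUE, showWarnings = FALSE)
  read_if <- function(p) if (file.exists(p))
    utils::read.csv(p, stringsAsFactors = FALSE) else NULL
  plum <- read_if(file.path(od, "plumage_comparisons.csv"))
  trials <- read_if(file.path(cfg$paths$bundle, "trials.csv"))
  eggs <- read_if(file.path(od, "egg_differences.csv"))
  if (!is.null(eggs))
    eggs <- eggs[eggs$outcome_class %in% c("rejected", "accepted"), ]
  res <- run_study_models(plum, trials, eggs, alpha = cfg$stats$alpha)
  dump_fit <- function(el, name) {
    for (stage in c("full", "final"))
      utils::write.csv(el[[stage]]$coefficients,
                       file.path(od, sprintf("%s_%s_coefficients.csv", name, stage)),
                       row.names = FALSE)
    utils::write.csv(el$trace, file.path(od, sprintf("%s_elimination.csv", name)),
                     row.names = FALSE)
    if (!is.null(el$contrasts))
      utils::write.csv(el$contrasts,
                       file.path(od, sprintf("%s_contrasts.csv", name)),
                       row.names = FALSE)
  }
  if (!is.null(res$plumage))
    for (nm in names(res$plumage)) dump_fit(res$plumage[[nm]], paste0("plumage_", nm))
  if (!is.null(res$aggression))
    for (nm in names(res$aggression)) dump_fit(res$aggression[[nm]], paste0("aggression_", nm))
  if (!is.null(res$rejection)) dump_fit(res$rejection, "rejection")
  write_manifest(cfg, od, "behaviour-stats")
  invisible(res)
}

#' Assemble the summary report tables
#'
#' Collects the group-by-region plumage means and each analysis's final
#' contrast tables into a single `report/` directory.
#'
#' @param cfg A [pipeline_config()].
#' @return The report directory, invisibly.
#' @export
pipeline_report <- function(cfg) {
  od <- cfg$paths$output
  rd <- file.path(od, "report")
  dir.create(rd, recursive = TRUE, showWarnings = FALSE)
  for (f in list.files(od, pattern = "summary|contrasts", full.names = TRUE))
    file.copy(f, file.path(rd, basename(f)), overwrite = TRUE)
  write_manifest(cfg, rd, "report")
  invisible(rd)
}

#' Run pipeline stages
#'
#' @param stages Character vector of stages, in order, from
#'   `c("simulate", "plumage-compare", "egg-analysis", "behaviour-stats",
#'   "report")`.
#' @param cfg A [pipeline_config()].
#' @return Named list of stage results, invisibly.
#' @export
run_pipeline <- function(stages = c("simulate", "plumage-compare",
                                    "egg-analysis", "behaviour-stats",
                                    "report"),
                         cfg = pipeline_config()) {
  out <- list()
  for (st in stages)
    out[[st]] <- switch(st,
      "simulate" = pipeline_simulate(cfg),
      "plumage-compare" = pipeline_plumage_compare(cfg),
      "egg-analysis" = pipeline_egg_analysis(cfg),
      "behaviour-stats" = pipeline_behaviour_stats(cfg),
      "report" = pipeline_report(cfg),
      stop("unknown stage: ", st))
  invisible(out)
}
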