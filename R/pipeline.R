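# Reproducible pipeline runs: one entry point dispatching to the package's
# stages, with JSON config, a recorded seed, structured logs to stderr and
# a manifest (parameters, seed, versions, output checksums) written next to
# the outputs.

pipeline_stages <- c("synth", "register", "analyze-clusters",
                     "simulate-placement", "simulate-walk",
                     "average-particles", "surface", "predict-current")

log_msg <- function(level, run_level, ...) {
  levels <- c(debug = 1, info = 2, warn = 3, quiet = 4)
  if (levels[[level]] >= levels[[run_level]]) {
    message(sprintf("[%s] %s", level, sprintf(...)))
  }
}

#' Run a pipeline stage
#'
#' Executes one named stage with the given parameters, writes its outputs
#' and a manifest into `outdir`, and returns the manifest. Identical
#' config and seed produce identical summaries.
#'
#' @param config Named list (or path to a JSON file) with elements
#'   `subcommand` (one of `synth`, `register`, `analyze-clusters`,
#'   `simulate-placement`, `simulate-walk`, `average-particles`,
#'   `surface`, `predict-current`) and `params` (stage parameters).
#' @param outdir Output directory (created if missing).
#' @param seed Integer seed recorded in the manifest and driving all
#'   randomness; overrides `config$seed`.
#' @param log_level `"debug"`, `"info"`, `"warn"` or `"quiet"`.
#' @return The manifest (invisibly): subcommand, parameters, seed, package
#'   version, outputs with md5 checksums, and the stage summary.
#' @export
run_pipeline <- function(config, outdir = tempfile("idnodes_run_"),
                         seed = NULL, log_level = "info") {
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config$subcommand)) {
    abort("config$subcommand is missing")
  }
  if (!config$subcommand %in% pipeline_stages) {
    abort(sprintf("unknown subcommand '%s' (expected one of: %s)",
                  config$subcommand, paste(pipeline_stages, collapse = ", ")))
  }
  params <- config$params %||% list()
  seed <- seed %||% config$seed
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_msg("info", log_level, "stage %s -> %s (seed %s)", config$subcommand,
          outdir, seed %||% "none")
  stage_fun <- switch(config$subcommand,
    "synth" = stage_synth,
    "register" = stage_register,
    "analyze-clusters" = stage_analyze_clusters,
    "simulate-placement" = stage_simulate_placement,
    "simulate-walk" = stage_simulate_walk,
    "average-particles" = stage_average_particles,
    "surface" = stage_surface,
    "predict-current" = stage_predict_current)
  res <- stage_fun(params, outdir, seed)
  manifest <- list(
    subcommand = config$subcommand,
    parameters = params,
    seed = seed,
    package_version = as.character(utils::packageVersion("idnodes")),
    outputs = lapply(res$outputs, function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    }),
    summary = res$summary)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(res$summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_msg("info", log_level, "stage %s done (%d outputs)", config$subcommand,
          length(res$outputs))
  invisible(manifest)
}

p_get <- function(params, name, default) params[[name]] %||% default

stage_synth <- function(params, outdir, seed) {
  field <- gen_ellipse_field(
    box_length = p_get(params, "box_length", 8000),
    n_ref = p_get(params, "n_ref", 6),
    n_query = p_get(params, "n_query", 12),
    attraction_f = p_get(params, "attraction_f", 1),
    halfwidth_nm = p_get(params, "halfwidth_nm", 500),
    seed = seed)
  f_ell <- file.path(outdir, "ellipses.csv")
  f_mem <- file.path(outdir, "membrane.csv")
  write.csv(field$ellipses, f_ell, row.names = FALSE)
  write.csv(field$membrane_line, f_mem, row.names = FALSE)
  outputs <- c(f_ell, f_mem)
  if (isTRUE(p_get(params, "render", FALSE))) {
    img <- render_localization_image(
      field, pixel_nm = p_get(params, "pixel_nm", 20),
      density = p_get(params, "density", 0.01),
      precision_nm = p_get(params, "precision_nm", 20),
      seed = derive_seed(seed, 2))
    f_img <- file.path(outdir, "image.tif")
    write_image_tiff(img, f_img)
    outputs <- c(outputs, f_img, paste0(f_img, ".json"))
  }
  list(outputs = outputs,
       summary = list(n_ref = sum(field$ellipses$channel == "reference"),
                      n_query = sum(field$ellipses$channel == "query"),
                      attraction_f = field$attraction_f))
}

stage_register <- function(params, outdir, seed) {
  pairs <- read_fiducials_csv(params$fiducials)
  tr <- estimate_affine(pairs, trim_worst = p_get(params, "trim_worst", 0))
  err <- registration_error(pairs, tr,
                            threshold_nm = p_get(params, "threshold_nm", 20))
  f_tr <- file.path(outdir, "transform.json")
  write_transform_json(tr, f_tr)
  list(outputs = f_tr,
       summary = list(rmse_nm = err$rmse_nm, flagged = err$flagged,
                      n_pairs = nrow(pairs)))
}

stage_analyze_clusters <- function(params, outdir, seed) {
  image <- read_image_tiff(params$image)
  clusters <- analyze_image(
    image,
    smooth_radius_px = p_get(params, "smooth_radius_px", 0),
    threshold = p_get(params, "threshold", "otsu"),
    min_size = p_get(params, "min_size", 4))
  if (!is.null(params$membrane)) {
    membrane <- as_tibble(read.csv(params$membrane))
    clusters <- filter_by_membrane(clusters, membrane,
                                   p_get(params, "halfwidth_nm", 500))
  }
  qry <- clusters[clusters$channel == "query", ]
  ref <- clusters[clusters$channel == "reference", ]
  attr(qry, "pixel_nm") <- attr(clusters, "pixel_nm")
  attr(ref, "pixel_nm") <- attr(clusters, "pixel_nm")
  f_cl <- file.path(outdir, "clusters.csv")
  write_clusters_csv(clusters, f_cl)
  outputs <- f_cl
  summary <- list(n_reference = nrow(ref), n_query = nrow(qry))
  if (nrow(qry) && nrow(ref)) {
    rec <- nn_distances(qry, ref)
    smry <- distance_summary(rec, bin_nm = p_get(params, "bin_nm", 100))
    f_d <- file.path(outdir, "distances.csv")
    write.csv(rec, f_d, row.names = FALSE)
    outputs <- c(outputs, f_d)
    summary$contact_fraction <- attr(smry, "contact_fraction")
    summary$histogram <- as.list(setNames(smry$fraction, smry$bin))
  }
  list(outputs = outputs, summary = summary)
}

stage_simulate_placement <- function(params, outdir, seed) {
  boxes <- if (!is.null(params$boxes)) as_tibble(params$boxes) else
    tibble(length_nm = 8000, n_ref = 6, n_query = 12)
  cfg <- placement_config(
    boxes, size_source = lognormal_size_sampler(),
    attraction_f = p_get(params, "attraction_f", 1),
    n_reps = p_get(params, "n_reps", 1000),
    halfwidth_nm = p_get(params, "halfwidth_nm", 500),
    bin_nm = p_get(params, "bin_nm", 100), seed = seed)
  res <- run_placement_experiment(cfg)
  f_rep <- file.path(outdir, "placement_reps.csv")
  write.csv(res$per_rep, f_rep, row.names = FALSE)
  list(outputs = f_rep,
       summary = list(contact_mean = res$contact_mean,
                      contact_sd = res$contact_sd,
                      attraction_f = cfg$attraction_f,
                      n_reps = cfg$n_reps,
                      histogram = as.list(setNames(
                        res$mean_histogram$fraction,
                        res$mean_histogram$bin))))
}

stage_simulate_walk <- function(params, outdir, seed) {
  cfg <- walk_config(
    arrangement = p_get(params, "arrangement", "clustered"),
    p_bind = p_get(params, "p_bind", 0.5),
    p_unbind = p_get(params, "p_unbind", 0.002),
    attraction = p_get(params, "attraction", 1),
    n_steps = p_get(params, "n_steps", 500),
    n_ligate = p_get(params, "n_ligate", 2127),
    n_channels = p_get(params, "n_channels", 44),
    n_reps = p_get(params, "n_reps", 1000), seed = seed)
  reps <- run_walk_reps(cfg, n_reps = p_get(params, "n_reps", 10),
                        seed = seed)
  f_kd <- file.path(outdir, "kd_reps.csv")
  write.csv(reps, f_kd, row.names = FALSE)
  list(outputs = f_kd,
       summary = list(kd_mean_nM = mean(reps$kd_nM),
                      kd_sd_nM = sd(reps$kd_nM),
                      bound_fraction = mean(reps$bound_fraction),
                      arrangement = cfg$arrangement))
}

stage_average_particles <- function(params, outdir, seed) {
  truth <- gen_particle_stack(
    n = p_get(params, "n", 50),
    max_shift_px = p_get(params, "max_shift_px", 10),
    max_rot_deg = p_get(params, "max_rot_deg", 30),
    noise_level = p_get(params, "noise_level", 0.1),
    box_px = p_get(params, "box_px", 100), seed = seed)
  poses <- align_two_stage(
    truth$stack,
    rot_range_deg = p_get(params, "rot_range_deg",
                          p_get(params, "max_rot_deg", 30) + 6),
    rot_step_deg = p_get(params, "rot_step_deg", 2),
    max_shift_px = p_get(params, "max_shift_px", 10) + 4)
  avg <- average_stack(truth$stack, poses)
  f_poses <- file.path(outdir, "poses.csv")
  write.csv(as.data.frame(poses), f_poses, row.names = FALSE)
  f_avg <- file.path(outdir, "average.tif")
  write_image_tiff(recon_image(avg, pixel_nm = truth$stack$pixel_nm), f_avg)
  corr <- stats::cor(as.vector(avg[, , 1]), as.vector(truth$template[, , 1]))
  list(outputs = c(f_poses, f_avg, paste0(f_avg, ".json")),
       summary = list(n_particles = nrow(poses),
                      template_correlation = corr,
                      final_score = tail(attr(poses, "score_trace"), 1)))
}

stage_surface <- function(params, outdir, seed) {
  surface <- if (!is.null(params$heightmap)) {
    read_height_map_csv(params$heightmap)
  } else {
    gen_height_map(kind = p_get(params, "kind", "bump_lattice"),
                   amplitude = p_get(params, "amplitude", 100),
                   period = p_get(params, "period", 500),
                   extent = p_get(params, "extent", 4000),
                   spacing = p_get(params, "spacing", 20))
  }
  amp <- amplification_factor(surface)
  peaks <- detect_peaks(surface,
                        min_distance_nm = params$min_distance_nm,
                        min_prominence_nm = params$min_prominence_nm)
  outputs <- character(0)
  summary <- list(amplification = amp, n_peaks = nrow(peaks))
  if (nrow(peaks) >= 2) {
    sp <- peak_spacing_stats(peaks, mode = "3d")
    spec <- periodicity_spectrum(peaks)
    f_pk <- file.path(outdir, "peaks.csv")
    write.csv(as.data.frame(peaks), f_pk, row.names = FALSE)
    f_sp <- file.path(outdir, "peak_spacing.csv")
    write.csv(sp, f_sp, row.names = FALSE)
    outputs <- c(f_pk, f_sp)
    summary$median_spacing_nm <- stats::median(sp$distance_nm)
    summary$dominant_period_nm <- spec$dominant_period_nm
  }
  list(outputs = outputs, summary = summary)
}

stage_predict_current <- function(params, outdir, seed) {
  br <- patch_current_breakdown(
    patch_diameter_um = p_get(params, "patch_diameter_um", 2),
    amplification = p_get(params, "amplification", 6.5),
    cluster_spacing_um = p_get(params, "cluster_spacing_um", 1),
    packing = p_get(params, "packing", "square"),
    channels_per_cluster = p_get(params, "channels_per_cluster", 44),
    g_pS = p_get(params, "g_pS", 10),
    v_mV = p_get(params, "v_mV", 60),
    round_clusters = p_get(params, "round_clusters", TRUE))
  f_br <- file.path(outdir, "current.json")
  jsonlite::write_json(as.list(br), f_br, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  list(outputs = f_br, summary = as.list(br))
}
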