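#' Deterministic per-stage seed derivation
#'
#' Every stochastic stage derives its own seed from the master seed and a
#' stage tag, so stages are independent yet the whole run is reproducible.
#'
#' @param master master seed (integer).
#' @param tag character stage tag.
#' @return integer seed in \[0, 2^31).
#' @export
stage_seed <- function(master, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(master) * 48271 + h * 16807) %% 2147483647)
}

#' Default run configuration
#'
#' Nested parameter list for an end-to-end experiment.  Simulation defaults
#' are the parameter-table conditions (all in pre-expansion units): NA 1.15,
#' M 40, physical pixel pitch 4.8 um (so xy pitch = 4800000/40/20 = 6 nm),
#' z step 120 nm, expansion 20, membrane 4000-10000 puncta/um^2, cytosol
#' 2000-4000 /um^3, background 1000-2000 /um^3, localization SD 20 nm,
#' cluster SD 1-48 nm, Poisson SNR 7-12, read SNR 50-100, H-minima 0.01,
#' agglomeration thresholds 0.1..0.9, 30 nm barcode exclusion, barcode
#' densities 5-300 /um^3.
#'
#' The `ci` preset runs the identical physics at a reduced problem size
#' (1.2 um cube, compact net, fewer SGD steps); the `full` preset uses
#' 3 um volumes and the nine-conv-layer net.
#'
#' @param preset "ci" or "full".
#' @param seed master seed.
#' @return a nested list of class `run_config`.
#' @export
default_config <- function(preset = c("ci", "full"), seed = 1) {
  preset <- match.arg(preset)
  ci <- preset == "ci"
  cfg <- list(
    preset = preset,
    seed = as.integer(seed),
    volume = list(
      shape_vox = if (ci) c(200, 200, 200) else c(500, 500, 500),
      voxel_size = 6,
      neurite = list(count = if (ci) 16 else 80,
                     radius_range = c(50, 400),
                     tortuosity = 0.25, soma_fraction = 0.1)),
    optics = list(na = 1.15, wavelength_ex = 561, wavelength_em = 590,
                  n_immersion = 1.33, expansion_factor = 20,
                  magnification = 40, physical_pixel_pitch_um = 4.8),
    simulate = list(membrane_density = c(4000, 10000),
                    cytosol_density = c(2000, 4000),
                    background_density = c(1000, 2000),
                    jitter_sd = 20, cluster_sd = c(1, 48),
                    snr_poisson = c(7, 12), snr_read = c(50, 100),
                    xy_pitch = 6, z_step = 120),
    net = list(preset = if (ci) "small" else "full",
               iterations_2d = if (ci) 800 else 3000,
               iterations_3d = if (ci) 800 else 3000,
               lr = 0.001, momentum = 0.9, batch = 100,
               orientations = TRUE, median_filter = 3),
    segmentation = list(h_min = 0.01,
                        thresholds = seq(0.1, 0.9, by = 0.1),
                        h_sweep = 10^seq(-3, -0.5, length.out = 6),
                        ntree = 100),
    barcodes = list(densities = c(5, 10, 30, 100, 300),
                    trials = if (ci) 5 else 10,
                    headline_density = 30, exclusion_nm = 30),
    experiment = list(n_train_volumes = if (ci) 2 else 3,
                      images_per_train_volume = if (ci) 2 else 4,
                      n_test_images = 3))
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Read / write a run configuration (YAML, lossless round-trip)
#' @param config a `run_config`.
#' @param path `.yaml` file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # yaml reads numeric vectors as lists; restore
  relist <- function(x) {
    if (is.list(x) && length(x) && all(vapply(x, function(e) is.numeric(e) && length(e) == 1, logical(1))) &&
        is.null(names(x))) return(unlist(x))
    if (is.list(x)) return(lapply(x, relist))
    x
  }
  cfg <- relist(cfg)
  class(cfg) <- c("run_config", "list")
  cfg
}

# scaled, expansion-adjusted PSF on the simulation grid
config_psf <- function(config) {
  o <- config$optics
  vs <- config$volume$voxel_size
  psf <- make_confocal_psf(na = o$na, wavelength_ex = o$wavelength_ex,
                           wavelength_em = o$wavelength_em,
                           pitch_nm = rep(vs * o$expansion_factor, 3),
                           n_immersion = o$n_immersion)
  scale_psf(psf, o$expansion_factor)
}

# simulate one image (membrane + cytosol + background channels summed) from a
# ground truth volume
simulate_image <- function(gt, psf, config, seed) {
  s <- config$simulate
  memb <- extract_membrane(gt)
  f1 <- label_membranes(memb, s$membrane_density, s$jitter_sd,
                        per_neuron = TRUE, seed = stage_seed(seed, "membrane"))
  f2 <- label_volume_compartment(gt, NULL, s$background_density,
                                 seed = stage_seed(seed, "background"))
  field <- apply_puncta(bind_fields(f1, f2), s$cluster_sd,
                        seed = stage_seed(seed, "puncta"))
  render_stack(field, psf, shape_vox = dim(gt$labels),
               voxel_size = gt$voxel_size[1],
               xy_pitch = s$xy_pitch, z_step = s$z_step,
               snr_poisson_range = s$snr_poisson, snr_read_range = s$snr_read,
               seed = stage_seed(seed, "render"))
}

#' Run the full simulation + reconstruction experiment
#'
#' Orchestrates the end-to-end protocol: several ground-truth volumes are
#' generated; training images are simulated from the training volumes and a
#' held-out volume provides the test images (the train/test volumes never
#' mix).  The boundary detector is trained (2D then 3D, two orientations),
#' BPMs are inferred, a merge policy is trained on the training images, and
#' for every test image three score curves are produced: (a) plain watershed
#' across an H-minima sweep, (b) the hierarchical agglomeration levels
#' without barcodes, (c) barcode consolidation across a density grid.
#'
#' @param config a `run_config` (see [default_config()]).
#' @param out_dir optional directory; when given, score CSVs
#'   (`watershed_sweep.csv`, `tree_levels.csv`, `barcode_sweep.csv`),
#'   artifacts and a provenance YAML are written there.
#' @param verbose print stage progress.
#' @return list with the three score data.frames (`watershed`, `levels`,
#'   `barcodes`), the per-test-image pipeline state, and the trained nets.
#' @export
run_experiment <- function(config = default_config(), out_dir = NULL,
                           verbose = interactive()) {
  seed <- config$seed
  say <- function(...) if (verbose) message(sprintf(...))
  nvol <- config$experiment$n_train_volumes
  say("generating %d training + 1 test ground-truth volumes", nvol)
  gts <- lapply(seq_len(nvol + 1), function(i)
    generate_ground_truth(config$volume$shape_vox, config$volume$voxel_size,
                          config$volume$neurite,
                          seed = stage_seed(seed, paste0("gt", i))))
  gt_test <- gts[[nvol + 1]]
  psf <- config_psf(config)
  say("simulating training images")
  train_stacks <- list(); train_gts <- list()
  for (vi in seq_len(nvol))
    for (im in seq_len(config$experiment$images_per_train_volume)) {
      train_stacks[[length(train_stacks) + 1]] <-
        simulate_image(gts[[vi]], psf, config,
                       stage_seed(seed, sprintf("train_img_%d_%d", vi, im)))
      train_gts[[length(train_gts) + 1]] <- gts[[vi]]
    }
  say("training boundary detector (2D -> 3D, two orientations)")
  config_fn <- if (config$net$preset == "small") net_config_small else net_config_full
  nets <- train_2d_then_3d(train_stacks, train_gts, config_fn,
                           iterations_2d = config$net$iterations_2d,
                           iterations_3d = config$net$iterations_3d,
                           lr = config$net$lr, momentum = config$net$momentum,
                           batch = config$net$batch,
                           seed = stage_seed(seed, "net"),
                           orientations = config$net$orientations)
  say("training merge policy on training images")
  z_step <- config$simulate$z_step
  train_sub <- seq_along(train_stacks)                 # GALA training images
  tr_bpms <- lapply(train_sub, function(i)
    infer_bpm(train_stacks[[i]], nets, config$net$median_filter))
  tr_svs <- lapply(train_sub, function(i)
    oversegment(tr_bpms[[i]], config$segmentation$h_min,
                c(rep(config$simulate$xy_pitch, 2), z_step)))
  tr_gimg <- lapply(train_sub, function(i) project_to_image_grid(train_gts[[i]], z_step))
  policy <- train_merge_policy(tr_svs, tr_bpms,
                               lapply(train_sub, function(i) train_stacks[[i]]$data),
                               tr_gimg, ntree = config$segmentation$ntree,
                               seed = stage_seed(seed, "policy"))
  gt_img <- project_to_image_grid(gt_test, z_step)
  watershed_rows <- list(); level_rows <- list(); barcode_rows <- list()
  states <- list()
  for (ti in seq_len(config$experiment$n_test_images)) {
    say("test image %d", ti)
    stack <- simulate_image(gt_test, psf, config,
                            stage_seed(seed, paste0("test_img_", ti)))
    bpm <- infer_bpm(stack, nets, config$net$median_filter)
    vs_img <- c(rep(config$simulate$xy_pitch, 2), z_step)
    # (a) plain watershed sweep over H-minima depth
    for (h in config$segmentation$h_sweep) {
      svh <- oversegment(bpm, h, vs_img)
      sc <- safe_scores(label_volume(svh$labels, vs_img), gt_img)
      watershed_rows[[length(watershed_rows) + 1]] <-
        cbind(data.frame(image = ti, h_min = h, n_segments = svh$count), sc)
    }
    sv <- oversegment(bpm, config$segmentation$h_min, vs_img)
    tree <- build_hierarchy(sv, policy, bpm, stack$data,
                            config$segmentation$thresholds)
    # (b) tree levels without barcodes
    for (t in config$segmentation$thresholds) {
      lev <- tree_level(tree, t)
      sc <- safe_scores(relabel_supervoxels(sv, lev), gt_img)
      level_rows[[length(level_rows) + 1]] <-
        cbind(data.frame(image = ti, threshold = t,
                         n_segments = length(unique(lev))), sc)
    }
    # (c) barcode consolidation across the density grid
    sw <- density_sweep(tree, sv, gt_test, gt_img,
                        config$barcodes$densities, config$barcodes$trials,
                        config$barcodes$exclusion_nm,
                        seed = stage_seed(seed, paste0("sweep", ti)))
    barcode_rows[[length(barcode_rows) + 1]] <- cbind(data.frame(image = ti), sw)
    states[[ti]] <- list(stack = stack, bpm = bpm, sv = sv, tree = tree)
  }
  res <- list(watershed = do.call(rbind, watershed_rows),
              levels = do.call(rbind, level_rows),
              barcodes = do.call(rbind, barcode_rows),
              states = states, nets = nets, policy = policy,
              gt_test = gt_test, gt_img = gt_img, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res$watershed, file.path(out_dir, "watershed_sweep.csv"), row.names = FALSE)
    utils::write.csv(res$levels, file.path(out_dir, "tree_levels.csv"), row.names = FALSE)
    utils::write.csv(res$barcodes, file.path(out_dir, "barcode_sweep.csv"), row.names = FALSE)
    prov <- list(config = unclass(config),
                 config_hash = rlang::hash(unclass(config)),
                 stage_seeds = list(net = stage_seed(seed, "net"),
                                    policy = stage_seed(seed, "policy")),
                 timestamp = format(Sys.time(), tz = "UTC"))
    yaml::write_yaml(prov, file.path(out_dir, "provenance.yaml"))
    write_config(config, file.path(out_dir, "config.yaml"))
  }
  res
}

safe_scores <- function(pred, gt) {
  sc <- tryCatch(score_report(pred, gt), error = function(e) NULL)
  if (is.null(sc))
    data.frame(rand_split = NA, rand_merge = NA, rand_f = NA,
               vi_split = NA, vi_merge = NA, vi_f = NA)
  else as.data.frame(unclass(sc))
}
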