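# Pipeline orchestration: a YAML-configured, stage-wise, resumable driver
# covering simulate -> register -> prepare -> train -> enhance -> evaluate.
# One global seed fans out to per-stage seeds (stage name hashed with the
# global seed) so stages are individually reproducible without collisions.
# Each stage writes a JSON report embedding the resolved parameters and a
# digest; a rerun with unchanged parameters and existing outputs is skipped.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    out_dir = "semsr_run",
    verbosity = 1L,
    simulate = list(
      n_images = 4L, n_test_images = 2L, n_particles = 16L,
      fov_nm = 1420, pixel_size_nm = 7.1, near_pair_fraction = 0.75,
      gap_range_nm = c(8, 40), pair_radius_range_nm = c(20, 45),
      psf_sigma_nm = 10, downsample_factor = 2L,
      noise_poisson_scale = 0.001, noise_gaussian_sigma = 0.01,
      autocontrast = TRUE, damage_magnitude_px = 0, damage_smoothness_px = 32
    ),
    register = list(levels = 3L, min_block_px = 24L, elastic = TRUE,
                    enabled = FALSE),
    prepare = list(size = 32L, stride = 32L, threshold = 0.5),
    train = list(iterations = 300L, d_update_period = 4L, batch_size = 8L,
                 learning_rate = 1e-3, alpha = "auto", beta = "auto",
                 g_depth = 2L, g_channels = 8L, d_blocks = 2L, d_channels = 8L,
                 tile = 128L, overlap = 16L),
    evaluate = list(exist_frac = 0.6, width_frac = 0.8,
                    peak_policy = "min-peak", n_bins = 15L, spectrum_bins = 48L)
  )
}

merge_validate <- function(user, defaults, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(defaults)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown config key%s: %s",
                 if (length(unknown) > 1) "s" else "",
                 paste0(path, unknown, collapse = ", ")), call. = FALSE)
  for (nm in names(user))
    defaults[[nm]] <- merge_validate(user[[nm]], defaults[[nm]],
                                     paste0(path, nm, "."))
  defaults
}

#' Load and validate a pipeline configuration
#'
#' YAML file with sections `simulate`, `register`, `prepare`, `train`,
#' `evaluate` plus globals `seed`, `out_dir`, `verbosity`. Missing keys take
#' defaults; unknown keys are rejected.
#'
#' @param path YAML file, or `NULL` for the defaults.
#' @param overrides named list merged on top (e.g. `list(seed = 7)`).
#' @return a validated `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, overrides = NULL) {
  user <- if (!is.null(path)) yaml::read_yaml(path) else list()
  cfg <- merge_validate(user, pipeline_defaults())
  if (!is.null(overrides)) cfg <- merge_validate(overrides, cfg)
  structure(cfg, class = "pipeline_config")
}

#' Per-stage seed derived from the global seed
#'
#' Stage name is hashed (CRC32) and combined with the global seed modulo
#' 2^31 - 1, giving distinct, stable streams per stage.
#'
#' @param global_seed integer.
#' @param stage stage name.
#' @return integer seed.
#' @export
stage_seed <- function(global_seed, stage) {
  h <- strtoi(substr(digest::digest(stage, algo = "crc32"), 1, 7), 16L)
  as.integer((as.numeric(global_seed) * 48271 + h) %% 2147483647)
}

stage_report_path <- function(cfg, stage)
  file.path(cfg$out_dir, sprintf("report_%s.json", stage))

write_report <- function(cfg, stage, params, metrics, t0) {
  rep <- list(stage = stage, params = params, metrics = metrics,
              digest = digest::digest(params),
              wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(rep, stage_report_path(cfg, stage),
                       auto_unbox = TRUE, digits = NA, null = "null")
  rep
}

stage_cached <- function(cfg, stage, params) {
  p <- stage_report_path(cfg, stage)
  if (!file.exists(p)) return(FALSE)
  rep <- tryCatch(jsonlite::read_json(p), error = function(e) NULL)
  !is.null(rep) && identical(rep$digest, digest::digest(params))
}

#' Run one pipeline stage
#'
#' Stages: `simulate`, `register`, `prepare`, `train`, `enhance`, `evaluate`.
#' Outputs land under `config$out_dir`; each stage writes
#' `report_<stage>.json`. When the report already matches the stage
#' parameters and `force` is FALSE, the stage is skipped (`cached = TRUE` in
#' the return). Missing upstream outputs give an error naming the stage to
#' run first.
#'
#' @param stage stage name.
#' @param config a [pipeline_config()].
#' @param force rerun even when cached.
#' @return the stage report (list), invisibly.
#' @export
run_stage <- function(stage, config, force = FALSE) {
  stage <- match.arg(stage, c("simulate", "register", "prepare", "train",
                              "enhance", "evaluate"))
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- cfg[[if (stage == "enhance") "train" else stage]]
  if (is.null(params)) params <- list()
  params$global_seed <- cfg$seed
  params$stage <- stage
  if (!force && stage_cached(cfg, stage, params)) {
    rep <- jsonlite::read_json(stage_report_path(cfg, stage))
    rep$cached <- TRUE
    if (cfg$verbosity > 0) message(sprintf("[%s] cached, skipping", stage))
    return(invisible(rep))
  }
  t0 <- Sys.time()
  need <- function(path, upstream) {
    if (!file.exists(path))
      stop(sprintf("missing %s - run stage '%s' first", path, upstream),
           call. = FALSE)
    path
  }
  sdir <- file.path(cfg$out_dir, "images")
  metrics <- switch(
    stage,
    simulate = {
      dir.create(sdir, showWarnings = FALSE)
      sc <- cfg$simulate
      n_all <- sc$n_images + sc$n_test_images
      seeds <- stage_seed(cfg$seed, "simulate") + seq_len(n_all)
      manifest <- list()
      for (i in seq_len(n_all)) {
        field <- generate_particle_field(
          sc$n_particles, fov_nm = sc$fov_nm,
          near_pair_fraction = sc$near_pair_fraction,
          gap_range_nm = sc$gap_range_nm,
          pair_radius_range_nm = sc$pair_radius_range_nm, seed = seeds[i])
        high <- render_highres(field, sc$pixel_size_nm)
        dmg <- high
        if (sc$damage_magnitude_px > 0)
          dmg <- apply_damage_warp(high, sc$damage_magnitude_px,
                                   sc$damage_smoothness_px, seeds[i] + 1000L)
        low <- degrade(dmg, degradation_config(
          psf_sigma_nm = sc$psf_sigma_nm,
          downsample_factor = sc$downsample_factor,
          noise_poisson_scale = sc$noise_poisson_scale,
          noise_gaussian_sigma = sc$noise_gaussian_sigma,
          autocontrast = sc$autocontrast, seed = seeds[i] + 2000L))
        role <- if (i <= sc$n_images) "train" else "test"
        base <- sprintf("%s_%03d", role, i)
        write_sem_image(high, file.path(sdir, paste0(base, "_high.png")))
        write_sem_image(low, file.path(sdir, paste0(base, "_low.png")))
        write_particle_field(field, file.path(sdir, paste0(base, "_particles.csv")))
        segs <- pair_gap_segments(field)
        utils::write.csv(segs, file.path(sdir, paste0(base, "_gaps.csv")),
                         row.names = FALSE)
        manifest[[i]] <- data.frame(id = base, role = role,
                                    n_particles = nrow(field$particles),
                                    n_gaps = NROW(segs))
      }
      manifest <- do.call(rbind, manifest)
      utils::write.csv(manifest, file.path(cfg$out_dir, "manifest.csv"),
                       row.names = FALSE)
      list(n_images = n_all, n_gaps = sum(manifest$n_gaps))
    },
    register = {
      man <- utils::read.csv(need(file.path(cfg$out_dir, "manifest.csv"),
                                  "simulate"))
      rdir <- file.path(cfg$out_dir, "registered")
      dir.create(rdir, showWarnings = FALSE)
      cors <- numeric(0)
      for (id in man$id) {
        low <- read_sem_image(file.path(sdir, paste0(id, "_low.png")))
        high <- read_sem_image(file.path(sdir, paste0(id, "_high.png")))
        if (isTRUE(cfg$register$enabled)) {
          rp <- register_pair(low, high, levels = cfg$register$levels,
                              min_block_px = cfg$register$min_block_px,
                              elastic = cfg$register$elastic)
          x <- rp$x; z <- rp$z
          cors <- c(cors, rp$correlation["elastic"])
          jsonlite::write_json(list(matrix = rp$transform$matrix),
                               file.path(rdir, paste0(id, "_affine.json")),
                               digits = NA)
        } else {
          # simulated pairs share a grid by construction; plain upsample
          x <- lanczos_upsample(low, 2L)
          nr <- min(nrow(x$pixels), nrow(high$pixels))
          nc <- min(ncol(x$pixels), ncol(high$pixels))
          x$pixels <- x$pixels[1:nr, 1:nc]
          z <- high; z$pixels <- z$pixels[1:nr, 1:nc]
          cors <- c(cors, zncc(x, z))
        }
        write_sem_image(x, file.path(rdir, paste0(id, "_x.png")))
        write_sem_image(z, file.path(rdir, paste0(id, "_z.png")))
      }
      list(mean_correlation = mean(cors))
    },
    prepare = {
      man <- utils::read.csv(need(file.path(cfg$out_dir, "manifest.csv"),
                                  "simulate"))
      rdir <- file.path(cfg$out_dir, "registered")
      ids <- man$id[man$role == "train"]
      need(file.path(rdir, paste0(ids[1], "_x.png")), "register")
      pairs <- lapply(ids, function(id) {
        list(x = read_sem_image(file.path(rdir, paste0(id, "_x.png"))),
             z = read_sem_image(file.path(rdir, paste0(id, "_z.png"))))
      })
      built <- build_patch_dataset(pairs, size = cfg$prepare$size,
                                   stride = cfg$prepare$stride,
                                   threshold = cfg$prepare$threshold)
      saveRDS(built$dataset, file.path(cfg$out_dir, "patches.rds"))
      mani <- data.frame(
        kept = length(built$dataset$pairs),
        removed = length(built$removed$pairs),
        threshold = cfg$prepare$threshold)
      utils::write.csv(mani, file.path(cfg$out_dir, "patch_manifest.csv"),
                       row.names = FALSE)
      list(n_kept = length(built$dataset$pairs),
           n_removed = length(built$removed$pairs))
    },
    train = {
      ds <- readRDS(need(file.path(cfg$out_dir, "patches.rds"), "prepare"))
      tc <- cfg$train
      w <- if (identical(tc$alpha, "auto") || identical(tc$beta, "auto"))
        "auto" else loss_weights(tc$alpha, tc$beta)
      res <- train_gan(
        ds, generator_spec(tc$g_depth, tc$g_channels),
        discriminator_spec(tc$d_blocks, tc$d_channels),
        train_config(iterations = tc$iterations,
                     d_update_period = tc$d_update_period,
                     batch_size = tc$batch_size,
                     learning_rate = tc$learning_rate,
                     seed = stage_seed(cfg$seed, "train"), weights = w),
        verbose = cfg$verbosity > 1)
      write_generator(res$generator, file.path(cfg$out_dir, "generator.json"))
      utils::write.csv(res$history, file.path(cfg$out_dir, "train_metrics.csv"),
                       row.names = FALSE)
      list(final_l1 = utils::tail(res$history$l1, 1),
           alpha = res$weights$alpha, beta = res$weights$beta,
           d_updates = sum(res$history$d_updated))
    },
    enhance = {
      gen <- read_generator(need(file.path(cfg$out_dir, "generator.json"),
                                 "train"))
      man <- utils::read.csv(need(file.path(cfg$out_dir, "manifest.csv"),
                                  "simulate"))
      edir <- file.path(cfg$out_dir, "enhanced")
      dir.create(edir, showWarnings = FALSE)
      for (id in man$id) {
        low <- read_sem_image(file.path(sdir, paste0(id, "_low.png")))
        out <- infer_image(gen, low, tile = cfg$train$tile,
                           overlap = cfg$train$overlap)
        write_sem_image(out, file.path(edir, paste0(id, "_sr.png")))
      }
      list(n_enhanced = nrow(man))
    },
    evaluate = {
      man <- utils::read.csv(need(file.path(cfg$out_dir, "manifest.csv"),
                                  "simulate"))
      edir <- file.path(cfg$out_dir, "enhanced")
      ids <- man$id[man$role == "test"]
      if (!length(ids)) ids <- man$id
      ev <- cfg$evaluate
      studies <- list(); per_class_acc <- NULL
      cls_imgs <- list(input = list(), output = list(), ground_truth = list())
      for (id in ids) {
        low <- read_sem_image(file.path(sdir, paste0(id, "_low.png")))
        high <- read_sem_image(file.path(sdir, paste0(id, "_high.png")))
        sr <- read_sem_image(need(file.path(edir, paste0(id, "_sr.png")),
                                  "enhance"))
        x <- lanczos_upsample(low, 2L)
        nr <- min(nrow(x$pixels), nrow(high$pixels), nrow(sr$pixels))
        nc <- min(ncol(x$pixels), ncol(high$pixels), ncol(sr$pixels))
        crop <- function(im) { im$pixels <- im$pixels[1:nr, 1:nc]; im }
        triple <- list(input = crop(x), output = crop(sr),
                       ground_truth = crop(high))
        segs <- utils::read.csv(file.path(sdir, paste0(id, "_gaps.csv")))
        st <- gap_study(triple, segs, exist_frac = ev$exist_frac,
                        width_frac = ev$width_frac,
                        peak_policy = ev$peak_policy, n_bins = ev$n_bins)
        studies[[id]] <- st$measurements
        for (cl in names(cls_imgs))
          cls_imgs[[cl]] <- c(cls_imgs[[cl]], list(triple[[cl]]))
      }
      all_meas <- do.call(rbind, studies)
      gt <- all_meas[all_meas$class == "ground_truth", ]
      summary <- do.call(rbind, lapply(unique(all_meas$class), function(cl) {
        mc <- all_meas[all_meas$class == cl, ]
        both <- mc$exists & is.finite(mc$width_nm) &
          gt$exists & is.finite(gt$width_nm)
        data.frame(class = cl,
                   undetected_fraction = mean(!mc$exists),
                   mean_abs_diff_nm =
                     if (any(both)) mean(abs(mc$width_nm[both] -
                                               gt$width_nm[both])) else NA)
      }))
      spec <- spectrum_study(cls_imgs, n_bins = ev$spectrum_bins)
      out <- list(per_class = summary,
                  spectra = lapply(spec, function(s) as.list(s)))
      jsonlite::write_json(out, file.path(cfg$out_dir, "evaluation.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
      utils::write.csv(all_meas, file.path(cfg$out_dir, "gap_table.csv"),
                       row.names = FALSE)
      list(undetected_input =
             summary$undetected_fraction[summary$class == "input"],
           undetected_output =
             summary$undetected_fraction[summary$class == "output"])
    })
  rep <- write_report(cfg, stage, params, metrics, t0)
  if (cfg$verbosity > 0)
    message(sprintf("[%s] done in %.1fs", stage, rep$wall_time_s))
  invisible(rep)
}

#' Run the full pipeline
#'
#' @param config a [pipeline_config()].
#' @param force rerun cached stages.
#' @return named list of stage reports, invisibly.
#' @export
run_all <- function(config, force = FALSE) {
  stages <- c("simulate", "register", "prepare", "train", "enhance", "evaluate")
  reps <- lapply(stages, run_stage, config = config, force = force)
  names(reps) <- stages
  invisible(reps)
}

#' Command-line entry point
#'
#' `semsr <verb> --config <file> [--force] [--seed N] [--out DIR]` with verbs
#' `simulate`, `register`, `prepare`, `train`, `enhance`, `evaluate`,
#' `run-all`.
#'
#' @param args character vector of command-line arguments.
#' @return exit status 0 on success, invisibly.
#' @export
semsr_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  spec <- list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--force", action = "store_true", default = FALSE),
    optparse::make_option("--seed", type = "integer", default = NULL),
    optparse::make_option("--out", type = "character", default = NULL))
  parser <- optparse::OptionParser(
    usage = "semsr <stage|run-all> [options]", option_list = spec)
  parsed <- optparse::parse_args(parser, args = args, positional_arguments = 1)
  verb <- parsed$args
  overrides <- list()
  if (!is.null(parsed$options$seed)) overrides$seed <- parsed$options$seed
  if (!is.null(parsed$options$out)) overrides$out_dir <- parsed$options$out
  cfg <- pipeline_config(parsed$options$config, overrides)
  if (verb == "run-all") run_all(cfg, force = parsed$options$force)
  else run_stage(verb, cfg, force = parsed$options$force)
  invisible(0L)
}
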