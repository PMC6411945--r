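#' Default pipeline configuration
#'
#' Every analysis parameter of the package has a documented default here;
#' a YAML config file may override any subset.  The configuration (plus the
#' package version and seed) is serialized into each run's manifest so that
#' a run is reproducible from its manifest alone.
#'
#' @return nested list of parameter blocks
#' @export
default_config <- function() {
  list(
    version = 1,
    seed = 1,
    calibration = list(pixel_size = 1, frame_interval = NULL),
    comets = list(upscale_factor = 3, rolling_ball_radius = 15,
                  min_cell_area = 50, min_area = 4,
                  threshold_method = "otsu", threshold_value = NULL,
                  exclude_border_cells = FALSE),
    mtdensity = list(rolling_ball_radius = 50, sigma = 1.8,
                     upper_threshold = 2, lower_threshold = 0.66,
                     min_length = 8, line_width = 1),
    track = list(sigma = 1.5, min_prominence = 10, border = 3,
                 max_displacement = 6, min_frames = 3),
    kymo = list(stabilize = TRUE, window = 50, stride = 1,
                trace_sigma = 2, regions = list()),
    islands = list(min_cells = 5),
    qpcr = list(per_replicate = TRUE),
    simulate = list(kind = "filaments", args = list())
  )
}

#' Read a YAML pipeline configuration
#'
#' Values present in the file override the defaults; everything else keeps
#' its default, so a config file only needs the parameters that differ.
#'
#' @param path YAML file (or `NULL` for pure defaults)
#' @return configuration list
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  merge_cfg <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]]) &&
          !is.null(names(base[[nm]])))
        base[[nm]] <- merge_cfg(base[[nm]], over[[nm]])
      else base[[nm]] <- over[[nm]]
    }
    base
  }
  merge_cfg(cfg, user)
}

write_manifest <- function(out_dir, command, inputs, config, outputs) {
  manifest <- list(
    command = command,
    inputs = inputs,
    config = config,
    outputs = outputs,
    package = "cytoquant",
    package_version = as.character(utils::packageVersion("cytoquant")),
    r_version = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
}

write_table <- function(df, out_dir, name, log) {
  p <- file.path(out_dir, paste0(name, ".csv"))
  utils::write.csv(df, p, row.names = FALSE)
  log(sprintf("wrote %s (%d rows)", basename(p), nrow(df)))
  p
}

#' Run a quantification pipeline end to end
#'
#' Ties the package's modules together behind a single entry point: reads
#' inputs, runs the requested pipeline with the supplied configuration, and
#' writes tidy CSV result tables (one row per particle / track / trace /
#' cell / island / gene plus a summary table), a JSON run manifest (command,
#' inputs, full configuration, package version) and a human-readable log
#' that reports the count of objects surviving each filter.
#'
#' Commands: `"comets"` (inputs: `junction`, `comet` TIFFs), `"mtdensity"`
#' (input: `image`, 2-D or z-stack TIFF), `"track"` (input: `movie` TIFF),
#' `"kymo"` (input: `movie` TIFF; regions from config), `"islands"` (input:
#' `annotations` CSV/JSON), `"qpcr"` (input: `ct` CSV with columns `gene`,
#' `condition`, `replicate`, `ct`, `is_reference`), `"simulate"` (writes
#' TIFFs and ground-truth JSON per `config$simulate`).
#'
#' @param command one of the pipeline names above
#' @param inputs named list of input file paths
#' @param config configuration list from [read_config()] /
#'   [default_config()]
#' @param out_dir output directory (created if missing)
#' @return named list of written file paths, invisibly
#' @export
run_pipeline <- function(command = c("comets", "mtdensity", "track", "kymo",
                                     "islands", "qpcr", "simulate"),
                         inputs = list(), config = default_config(),
                         out_dir = ".") {
  command <- match.arg(command)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character(0)
  log <- function(msg) {
    log_lines <<- c(log_lines, msg)
  }
  for (nm in names(inputs))
    if (!file.exists(inputs[[nm]]))
      stop(sprintf("input '%s' not found: %s", nm, inputs[[nm]]))
  cal <- config$calibration
  outputs <- list()

  if (command == "comets") {
    jn <- read_stack(inputs$junction, pixel_size = cal$pixel_size)
    cm <- read_stack(inputs$comet, pixel_size = cal$pixel_size)
    if (has_axis(jn, "z")) jn <- max_project(jn)
    if (has_axis(cm, "z")) cm <- max_project(cm)
    cc <- config$comets
    res <- comet_morphometry(jn, cm, upscale_factor = cc$upscale_factor,
                             rolling_ball_radius = cc$rolling_ball_radius,
                             min_cell_area = cc$min_cell_area,
                             min_area = cc$min_area,
                             threshold_method = cc$threshold_method,
                             threshold_value = cc$threshold_value,
                             exclude_border_cells = cc$exclude_border_cells)
    log(sprintf("cells segmented: %d", res$cells$n_cells))
    log(sprintf("particles kept (area >= %g): %d", cc$min_area,
                nrow(res$particles)))
    log(sprintf("cells with >= 1 comet: %d", nrow(res$per_cell)))
    outputs$particles <- write_table(res$particles, out_dir, "particles", log)
    outputs$cells <- write_table(res$per_cell, out_dir, "cells", log)
    summ <- if (nrow(res$per_cell) >= 2)
      condition_summary(res$per_cell$mean_ar, "comets") else
      data.frame(condition = "comets", mean = NA_real_, sem = NA_real_,
                 n = nrow(res$per_cell))
    outputs$summary <- write_table(summ, out_dir, "summary", log)
  } else if (command == "mtdensity") {
    st <- read_stack(inputs$image, pixel_size = cal$pixel_size)
    if (has_axis(st, "z")) st <- max_project(st)
    mc <- config$mtdensity
    pr <- ridge_params(mc$sigma, mc$upper_threshold, mc$lower_threshold,
                       mc$min_length)
    res <- mt_density(st, pr, rolling_ball_radius = mc$rolling_ball_radius,
                      line_width = mc$line_width)
    log(sprintf("polylines: %d", length(res$ridges$polylines)))
    log(sprintf("density: %.4f a.u.", res$density))
    tab <- data.frame(image = inputs$image, n_polylines =
                        length(res$ridges$polylines),
                      total_ridge_length_px = sum(ridge_lengths(res$ridges)),
                      density_au = res$density)
    outputs$density <- write_table(tab, out_dir, "density", log)
  } else if (command == "track") {
    st <- read_stack(inputs$movie, pixel_size = cal$pixel_size,
                     frame_interval = cal$frame_interval)
    tc <- config$track
    res <- track_movie(st, sigma = tc$sigma,
                       min_prominence = tc$min_prominence,
                       border = tc$border,
                       max_displacement = tc$max_displacement,
                       min_frames = tc$min_frames)
    log(sprintf("tracks kept (>= %d frames): %d", tc$min_frames,
                length(res$tracks)))
    outputs$tracks <- write_table(res$metrics, out_dir, "tracks", log)
    summ <- data.frame(
      condition = "track",
      mean_speed_um_s = mean(res$metrics$mean_speed_um_s),
      sem_speed = stats::sd(res$metrics$mean_speed_um_s) /
        sqrt(max(nrow(res$metrics), 1)),
      mean_duration_s = mean(res$metrics$duration_s),
      mean_displacement_um = mean(res$metrics$displacement_um),
      n_tracks = nrow(res$metrics))
    outputs$summary <- write_table(summ, out_dir, "summary", log)
  } else if (command == "kymo") {
    st <- read_stack(inputs$movie, pixel_size = cal$pixel_size,
                     frame_interval = cal$frame_interval)
    kc <- config$kymo
    regions <- kc$regions
    # accept a list of rectangles, a single rectangle, or the row-matrix a
    # JSON manifest round-trip produces
    if (is.matrix(regions)) {
      regions <- lapply(seq_len(nrow(regions)), function(i)
        as.numeric(regions[i, ]))
    } else if (is.numeric(regions) && length(regions) == 4) {
      regions <- list(as.numeric(regions))
    } else {
      regions <- lapply(regions, function(r) as.numeric(unlist(r)))
    }
    if (length(regions) == 0)
      stop("kymo requires at least one region in config$kymo$regions")
    res <- region_motility(st, regions, stabilize_movie = kc$stabilize,
                           window = kc$window, stride = kc$stride,
                           trace_sigma = kc$trace_sigma)
    log(sprintf("regions: %d; traces: %s", nrow(res),
                paste(res$n_traces, collapse = ",")))
    outputs$regions <- write_table(res, out_dir, "regions", log)
    ok <- is.finite(res$mean_deviation)
    summ <- data.frame(condition = "kymo",
                       mean_deviation_deg = mean(res$mean_deviation[ok]),
                       n_regions = sum(ok))
    outputs$summary <- write_table(summ, out_dir, "summary", log)
  } else if (command == "islands") {
    ann <- read_annotations(inputs$annotations)
    ic <- config$islands
    res <- mesenchymal_fraction(ann, min_cells = ic$min_cells)
    log(sprintf("islands: %d total, %d included (>= %d cells)",
                nrow(res$per_island), sum(res$per_island$included),
                ic$min_cells))
    outputs$islands <- write_table(res$per_island, out_dir, "islands", log)
    outputs$summary <- write_table(res$summary, out_dir, "summary", log)
  } else if (command == "qpcr") {
    tab <- utils::read.csv(inputs$ct, stringsAsFactors = FALSE)
    ct <- ct_table(tab$gene, tab$condition, tab$replicate, tab$ct,
                   tab$is_reference)
    res <- ddct_fold_change(ct, per_replicate = config$qpcr$per_replicate)
    log(sprintf("genes of interest: %d", nrow(res)))
    outputs$folds <- write_table(res, out_dir, "folds", log)
  } else if (command == "simulate") {
    sc <- config$simulate
    args <- sc$args
    args$seed <- config$seed
    gen <- switch(sc$kind,
                  filaments = gen_filaments,
                  comet_field = gen_comet_field,
                  comet_movie = gen_comet_movie,
                  drift_movie = gen_drift_movie,
                  stop(sprintf("unknown simulation kind '%s'", sc$kind)))
    sim <- do.call(gen, args)
    stacks <- sim[vapply(sim, inherits, logical(1), "ImageStack")]
    for (nm in names(stacks)) {
      p <- file.path(out_dir, paste0(nm, ".tif"))
      mx <- max(stacks[[nm]]$pixels)
      sc16 <- with_pixels(stacks[[nm]],
                          round(stacks[[nm]]$pixels / max(mx, 1e-12) *
                                  65535))
      write_stack(sc16, p, bits = 16)
      outputs[[nm]] <- p
      log(sprintf("wrote %s", basename(p)))
    }
    tp <- file.path(out_dir, "truth.json")
    write_ground_truth(sim$truth, tp)
    outputs$truth <- tp
    log("wrote truth.json")
  }

  write_manifest(out_dir, command, inputs, config, outputs)
  outputs$manifest <- file.path(out_dir, "manifest.json")
  writeLines(log_lines, log_path)
  outputs$log <- log_path
  invisible(outputs)
}

#' Re-run a pipeline from its manifest
#'
#' Reads a `manifest.json` written by [run_pipeline()] and repeats the run
#' with the identical command, inputs and configuration; with the same
#' installed package version the output tables are reproduced
#' bit-identically.
#'
#' @param manifest_path path to a `manifest.json`
#' @param out_dir output directory for the re-run
#' @return named list of written file paths, invisibly
#' @export
rerun_from_manifest <- function(manifest_path, out_dir) {
  m <- jsonlite::fromJSON(manifest_path, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE)
  cfg <- default_config()
  over <- m$config
  merge_cfg <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]]) &&
          !is.null(names(base[[nm]])))
        base[[nm]] <- merge_cfg(base[[nm]], over[[nm]])
      else base[[nm]] <- over[[nm]]
    }
    base
  }
  cfg <- merge_cfg(cfg, over)
  run_pipeline(m$command, inputs = m$inputs, config = cfg,
               out_dir = out_dir)
}
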