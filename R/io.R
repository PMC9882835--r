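#' Thickness pipeline configuration
#'
#' Calibration and gating parameters of the thickness-mapping pipeline.
#'
#' @param pixel_size_nm pixel pitch (nm).
#' @param chromatic_shift_nm calibrated channel-2 shift (nm, 2-vector).
#' @param psf_sigma_nm PSF sigma per channel (nm).
#' @param smoothing_scale_nm along-surface smoothing scale (nm).
#' @param quality_min minimum peak-fit quality.
#' @param width_range acceptable fitted width in PSF multiples.
#' @param segment_sigma_px contour pre-smoothing (pixels).
#' @param seed integer seed recorded in outputs.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(pixel_size_nm = 65,
                            chromatic_shift_nm = c(30, -20),
                            psf_sigma_nm = c(200, 200),
                            smoothing_scale_nm = 500,
                            quality_min = 0.8, width_range = c(0.5, 3),
                            segment_sigma_px = 1.5, seed = 1L) {
  if (pixel_size_nm <= 0) stop("config field pixel_size_nm must be positive")
  if (length(psf_sigma_nm) == 1) psf_sigma_nm <- rep(psf_sigma_nm, 2)
  if (any(psf_sigma_nm <= 0)) stop("config field psf_sigma_nm must be positive")
  if (smoothing_scale_nm <= 0)
    stop("config field smoothing_scale_nm must be positive")
  if (length(chromatic_shift_nm) != 2)
    stop("config field chromatic_shift_nm must have length 2")
  structure(list(pixel_size_nm = pixel_size_nm,
                 chromatic_shift_nm = chromatic_shift_nm,
                 psf_sigma_nm = psf_sigma_nm,
                 smoothing_scale_nm = smoothing_scale_nm,
                 quality_min = quality_min, width_range = width_range,
                 segment_sigma_px = segment_sigma_px,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read or write a pipeline configuration
#'
#' JSON or YAML, decided by the file extension.
#'
#' @param path file path (.json, .yaml or .yml).
#' @param config a `pipeline_config` (for writing).
#' @return `read_config` returns a `pipeline_config`.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lst <- if (ext == "json") jsonlite::fromJSON(path)
    else if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
    else stop("unsupported config format: .", ext)
  do.call(pipeline_config, lst[intersect(names(lst),
                                         names(formals(pipeline_config)))])
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  lst <- unclass(config)
  if (ext == "json")
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  else if (ext %in% c("yaml", "yml")) yaml::write_yaml(lst, path)
  else stop("unsupported config format: .", ext)
  invisible(path)
}

#' Hash of a configuration
#'
#' MD5 of the canonical JSON serialization; stamped into output metadata so
#' artifacts can be traced to the configuration that produced them.
#'
#' @param config any serializable list.
#' @return hex string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Write a thickness map as CSV
#'
#' Columns `s_um, sprime_um, h_nm, quality, flag`; the seed and config hash
#' go into a commented header line.
#'
#' @param map a `thickness_map`.
#' @param path output path.
#' @param config optional `pipeline_config` recorded in the header.
#' @return the path, invisibly.
#' @export
write_thickness_map <- function(map, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config))
    writeLines(sprintf("# config_hash %s seed %d", config_hash(config),
                       config$seed), con)
  utils::write.csv(map[, c("s_um", "sprime_um", "h_nm", "quality", "flag")],
                   con, row.names = FALSE)
  invisible(path)
}

#' Read a thickness map CSV
#' @param path CSV path written by [write_thickness_map()].
#' @return data.frame.
#' @export
read_thickness_map <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Write or read a model trajectory as CSV
#'
#' Columns `t_min, h_nm, EV_au, G_per_min, c_au, P_MPa`.
#' @param traj a `tip_trajectory`.
#' @param path CSV path.
#' @return the path / the data.frame.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) utils::read.csv(path)

#' Write a time lapse as a multi-page TIFF plus truth CSV
#'
#' One 16-bit page per channel per frame, channel-major within frame
#' (page = (frame - 1) * n_channels + channel); the ground truth table and a
#' JSON echo of the imaging spec are written alongside.
#'
#' @param timelapse a `tip_timelapse`.
#' @param path TIFF path; truth CSV and spec JSON take derived names.
#' @param max_count count mapped to the 16-bit ceiling.
#' @return list of written paths.
#' @export
write_timelapse_tiff <- function(timelapse, path, max_count = 4096) {
  pages <- list()
  for (fr in timelapse$frames)
    for (ch in fr$channels)
      pages[[length(pages) + 1]] <- pmin(pmax(ch / max_count, 0), 1)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  truth_path <- sub("\\.tiff?$", "_truth.csv", path, ignore.case = TRUE)
  tr <- timelapse$truth
  utils::write.csv(data.frame(t_min = tr$t_min, s_um = 0, h_nm = tr$h_nm,
                              EV_au = tr$EV_au, G_per_min = tr$G_per_min),
                   truth_path, row.names = FALSE)
  spec_path <- sub("\\.tiff?$", "_spec.json", path, ignore.case = TRUE)
  jsonlite::write_json(unclass(timelapse$spec), spec_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(tiff = path, truth = truth_path, spec = spec_path))
}

#' Read a multi-page TIFF stack
#' @param path TIFF path.
#' @param n_channels channels per frame.
#' @param max_count count ceiling used at write time.
#' @return list of frames, each a list of channel matrices.
#' @export
read_timelapse_tiff <- function(path, n_channels = 3, max_count = 4096) {
  pages <- tiff::readTIFF(path, all = TRUE)
  nf <- length(pages) / n_channels
  lapply(seq_len(nf), function(i) {
    lapply(seq_len(n_channels), function(k) {
      pages[[(i - 1) * n_channels + k]] * max_count
    })
  })
}

#' Thickness-map overlay figure
#'
#' Writes a PNG of the membrane channel with the contour colored by local
#' wall thickness.
#'
#' @param map a `thickness_map`.
#' @param image the segmented `synthetic_image`.
#' @param path PNG path.
#' @return the path, invisibly.
#' @export
overlay_png <- function(map, image, path) {
  ct <- attr(map, "contour")
  grDevices::png(path, width = 800, height = 500)
  on.exit(grDevices::dev.off())
  m <- image$channels[[1]]
  graphics::image(x = image$x0_um + (seq_len(ncol(m)) - 1) * image$pixel_um,
                  y = image$y0_um + (seq_len(nrow(m)) - 1) * image$pixel_um,
                  z = t(m), col = grDevices::gray.colors(128),
                  xlab = "x (um)", ylab = "y (um)", asp = 1)
  ok <- map$flag == "ok"
  pal <- grDevices::hcl.colors(64, "viridis")
  hcl <- cut(map$h_nm, breaks = 64, labels = FALSE)
  graphics::points(ct$x_um[ok], ct$y_um[ok], col = pal[hcl[ok]], pch = 16,
                   cex = 0.6)
  invisible(path)
}

#' Run one pipeline command
#'
#' Small dispatcher tying the package stages together under a single
#' configuration: each command reads and writes only the documented formats,
#' logs the seed and config hash, and is deterministic for a fixed
#' configuration.
#'
#' @param config a `pipeline_config`.
#' @param command one of `make-phantom`, `map-thickness`, `estimate-modulus`,
#'   `estimate-turgor`, `simulate-model`, `analyze-timelapse`.
#' @param out_dir output directory, created if needed.
#' @param ... command-specific inputs: `geometry`/`spec` (make-phantom),
#'   `image` (map-thickness), `before`/`after`/`h_side_nm`/`h_tip_nm`/`P_MPa`
#'   (estimate-modulus), `c0_tilde_M`/`c_media_M`/`volume_ratio`/`beta_osm`
#'   (estimate-turgor), `scenario`/`params` (simulate-model), `timelapse`
#'   (analyze-timelapse).
#' @return list of artifact paths and results, invisibly.
#' @export
run_pipeline <- function(config, command, out_dir = ".", ...) {
  cmds <- c("make-phantom", "map-thickness", "estimate-modulus",
            "estimate-turgor", "simulate-model", "analyze-timelapse")
  if (!command %in% cmds)
    stop("unknown command '", command, "'; expected one of: ",
         paste(cmds, collapse = ", "))
  if (!inherits(config, "pipeline_config")) stop("config: not a pipeline_config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  args <- list(...)
  log <- function(...) message(sprintf("[hyphoshell %s seed=%d hash=%s] ",
                                       command, config$seed,
                                       substr(config_hash(config), 1, 8)),
                               sprintf(...))
  res <- switch(command,
    `make-phantom` = {
      geom <- if (!is.null(args$geometry)) args$geometry else
        make_phantom(radius_um = 1.2, length_um = 4, thickness_nm = 80)
      spec <- if (!is.null(args$spec)) args$spec else
        imaging_spec(pixel_size_nm = config$pixel_size_nm,
                     psf_sigma_nm = config$psf_sigma_nm,
                     chromatic_shift_nm = config$chromatic_shift_nm,
                     seed = config$seed)
      img <- render_image(geom, spec)
      tl <- structure(list(frames = list(img),
                           truth = data.frame(t_min = 0,
                                              h_nm = geom$thickness_fun(0),
                                              EV_au = NA, G_per_min = NA,
                                              tip_x_um = geom$tip_um[1]),
                           spec = spec),
                      class = "tip_timelapse")
      paths <- write_timelapse_tiff(tl, file.path(out_dir, "phantom.tif"))
      log("rendered phantom -> %s", paths$tiff)
      list(image = img, paths = paths)
    },
    `map-thickness` = {
      if (is.null(args$image)) stop("map-thickness: missing input 'image'")
      map <- map_thickness(args$image, config)
      p <- file.path(out_dir, "thickness_map.csv")
      write_thickness_map(map, p, config)
      log("thickness map (%d points) -> %s", nrow(map), p)
      list(map = map, paths = list(csv = p))
    },
    `estimate-modulus` = {
      need <- c("before", "after", "h_side_nm", "h_tip_nm")
      miss <- setdiff(need, names(args))
      if (length(miss)) stop("estimate-modulus: missing ",
                             paste(miss, collapse = ", "))
      st <- elastic_strain(args$before, args$after)
      side <- modulus_ratio_side(args$before$R_um, args$h_side_nm, st$radial,
                                 args$P_MPa)
      tip <- modulus_ratio_tip(args$before$Rt_um, args$h_tip_nm, st$tip,
                               args$P_MPa)
      rep <- list(strains = st,
                  anisotropy = anisotropy_ratio(st$radial, st$longitudinal),
                  side = side, tip = tip,
                  sigma_tip_N_m = if (is.finite(tip$Y_MPa))
                    surface_modulus(args$h_tip_nm, tip$Y_MPa) else NA,
                  config_hash = config_hash(config), seed = config$seed)
      p <- file.path(out_dir, "modulus.json")
      jsonlite::write_json(rep, p, auto_unbox = TRUE, digits = NA)
      log("modulus report -> %s", p)
      list(report = rep, paths = list(json = p))
    },
    `estimate-turgor` = {
      need <- c("c0_tilde_M", "c_media_M", "volume_ratio")
      miss <- setdiff(need, names(args))
      if (length(miss)) stop("estimate-turgor: missing ",
                             paste(miss, collapse = ", "))
      est <- turgor_from_osmotics(args$c0_tilde_M, args$c_media_M,
                                  args$volume_ratio,
                                  beta_osm = if (is.null(args$beta_osm)) 0.22
                                    else args$beta_osm)
      rep <- c(unclass(est), list(config_hash = config_hash(config)))
      p <- file.path(out_dir, "turgor.json")
      jsonlite::write_json(rep, p, auto_unbox = TRUE, digits = NA)
      log("turgor P = %.2f MPa -> %s", est$P_MPa, p)
      list(estimate = est, paths = list(json = p))
    },
    `simulate-model` = {
      params <- if (!is.null(args$params)) args$params else default_params()
      sc <- if (!is.null(args$scenario)) {
        if (inherits(args$scenario, "tip_scenario")) args$scenario
        else make_scenario(args$scenario, params)
      } else make_scenario("steady", params)
      traj <- integrate_model(params, sc)
      p <- file.path(out_dir, paste0("trajectory_", sc$kind, ".csv"))
      write_trajectory(traj, p)
      stab <- stability(params)
      ps <- file.path(out_dir, "stability.json")
      jsonlite::write_json(list(eigenvalues_re = Re(stab$eigenvalues),
                                eigenvalues_im = Im(stab$eigenvalues),
                                stable = stab$stable,
                                config_hash = config_hash(config)),
                           ps, auto_unbox = TRUE, digits = NA)
      log("%s trajectory (%d steps) -> %s", sc$kind, nrow(traj), p)
      list(trajectory = traj, stability = stab,
           paths = list(csv = p, stability = ps))
    },
    `analyze-timelapse` = {
      if (is.null(args$timelapse)) stop("analyze-timelapse: missing 'timelapse'")
      tr <- args$timelapse$truth
      summ <- data.frame(
        quantity = c("tip_speed", "h_tip", "EV"),
        relative_std = c(relative_std(tip_speed(tr$G_per_min,
                                                args$timelapse$params$R)),
                         relative_std(tr$h_nm), relative_std(tr$EV_au)))
      ccf_hE <- cross_correlation(tr$h_nm, tr$EV_au)
      p1 <- file.path(out_dir, "relative_std.csv")
      p2 <- file.path(out_dir, "cross_correlation.csv")
      utils::write.csv(summ, p1, row.names = FALSE)
      utils::write.csv(ccf_hE, p2, row.names = FALSE)
      log("time-lapse summary -> %s, %s", p1, p2)
      list(relative_std = summ, cross_correlation = ccf_hE,
           paths = list(relative_std = p1, cross_correlation = p2))
    })
  invisible(res)
}
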