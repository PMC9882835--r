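#' Simulate a model-driven imaging time lapse
#'
#' Integrates a scenario, advances a phantom tip at the model speed
#' `v = G R / (2 pi)`, renders the two wall channels at the model thickness
#' `h(t)`, and adds a third channel with an apical vesicle spot whose
#' amplitude is proportional to `EV(t)`. All frames share one raster sized
#' for the final tip position; per-frame noise seeds derive from the spec
#' seed, so the stack is reproducible.
#'
#' @param params `model_params`.
#' @param scenario `tip_scenario` (or NULL for steady growth).
#' @param spec `imaging_spec`.
#' @param frame_interval_min time between frames (min).
#' @param n_frames number of frames; frames start at t = 0.
#' @param tube_length_um initial midline length.
#' @param radius_um tube radius; defaults to the model tip radius.
#' @param spot_sigma_nm size of the apical vesicle spot.
#' @return a `tip_timelapse`: list(frames, truth, spec, params, scenario)
#'   where `truth` is data.frame(t_min, h_nm, EV_au, G_per_min, tip_x_um).
#' @export
simulate_timelapse <- function(params = default_params(),
                               scenario = make_scenario("steady", params),
                               spec = imaging_spec(),
                               frame_interval_min = 1, n_frames = 11,
                               tube_length_um = 3, radius_um = params$R,
                               spot_sigma_nm = 350) {
  if (frame_interval_min <= 0) stop("frame_interval_min must be positive")
  t_end <- frame_interval_min * (n_frames - 1)
  fine <- seq(0, t_end, by = min(0.05, frame_interval_min / 4))
  traj <- integrate_model(params, scenario, t_grid = fine)
  v <- tip_speed(traj$G_per_min, radius_um)
  adv <- c(0, cumsum((v[-1] + v[-length(v)]) / 2 * diff(fine)))
  ft <- seq(0, t_end, by = frame_interval_min)
  fidx <- vapply(ft, function(t) which.min(abs(fine - t)), integer(1))
  truth <- data.frame(t_min = ft, h_nm = traj$h_nm[fidx],
                      EV_au = traj$EV_au[fidx],
                      G_per_min = traj$G_per_min[fidx],
                      tip_x_um = tube_length_um + radius_um + adv[fidx])
  # one raster fits every frame: size it for the final geometry
  glast <- make_phantom(radius_um, tube_length_um + adv[length(adv)],
                        thickness_nm = max(truth$h_nm))
  ref <- render_image(glast, within_spec_nonoise(spec))
  raster <- list(x0_um = ref$x0_um, y0_um = ref$y0_um, nx = ref$nx,
                 ny = ref$ny)
  frames <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    gi <- make_phantom(radius_um, tube_length_um + adv[fidx[i]],
                       thickness_nm = truth$h_nm[i])
    si <- spec
    si$seed <- spec$seed + i - 1L
    img <- render_image(gi, si, raster = raster)
    # vesicle channel: apical spot, amplitude tracking EV(t)
    xg <- img$x0_um + (seq_len(img$nx) - 1) * img$pixel_um
    yg <- img$y0_um + (seq_len(img$ny) - 1) * img$pixel_um
    G <- expand.grid(x = xg, y = yg)
    d2 <- (G$x - gi$tip_um[1])^2 + (G$y - gi$tip_um[2])^2
    ss0 <- steady_state(params)
    amp <- spec$photon_scale * truth$EV_au[i] / ss0$EV_star
    rad <- amp * exp(-d2 / (2 * (spot_sigma_nm * 1e-3)^2)) +
      0.05 * spec$photon_scale
    spot <- matrix(rad, nrow = img$ny, ncol = img$nx, byrow = TRUE)
    if (spec$noise) {
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      set.seed(si$seed + 7919L)
      spot <- matrix(stats::rpois(length(spot), spot), nrow = img$ny) +
        matrix(stats::rnorm(length(spot), 0, spec$read_noise_sd),
               nrow = img$ny)
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }
    img$channels[[3]] <- spot
    frames[[i]] <- img
  }
  structure(list(frames = frames, truth = truth, spec = spec,
                 params = params, scenario = scenario),
            class = "tip_timelapse")
}

within_spec_nonoise <- function(spec) {
  spec$noise <- FALSE
  spec
}

#' @export
print.tip_timelapse <- function(x, ...) {
  cat("tip-growth time lapse:", nrow(x$truth), "frames,",
      x$scenario$kind, "scenario\n")
  invisible(x)
}

#' Thickness kymograph of a simulated time lapse
#'
#' Builds the `h(s, t)` kymograph of a time lapse from its ground truth,
#' optionally stamping a persistent fiducial thickness mark at a fixed lab
#' position (for advection checks the mark stays where the wall was laid
#' down; an `advect_um_min` value moves it backwards relative to the lab
#' frame).
#'
#' @param timelapse a `tip_timelapse` (only its truth table is used).
#' @param s_max_um arclength range behind the tip.
#' @param ds_um arclength step.
#' @param mark_lab_um lab-frame position of a thickness mark (NULL for none).
#' @param mark_amp_nm,mark_sigma_um amplitude and width of the mark.
#' @param advect_um_min drift speed of the mark in the lab frame.
#' @return kymograph list(t_min, s_um, h, tip_position_um).
#' @export
truth_kymograph <- function(timelapse, s_max_um = 6, ds_um = 0.05,
                            mark_lab_um = NULL, mark_amp_nm = 15,
                            mark_sigma_um = 0.3, advect_um_min = 0) {
  tr <- timelapse$truth
  s <- seq(0, s_max_um, by = ds_um)
  h <- matrix(rep(tr$h_nm, each = length(s)), nrow = nrow(tr),
              ncol = length(s), byrow = TRUE)
  if (!is.null(mark_lab_um)) {
    for (i in seq_len(nrow(tr))) {
      lab <- mark_lab_um + advect_um_min * tr$t_min[i]
      sm <- tr$tip_x_um[i] - lab   # arclength of the mark behind the tip
      h[i, ] <- h[i, ] + mark_amp_nm * exp(-(s - sm)^2 / (2 * mark_sigma_um^2))
    }
  }
  list(t_min = tr$t_min, s_um = s, h = h, tip_position_um = tr$tip_x_um)
}
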