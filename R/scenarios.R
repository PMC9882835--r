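#' Build a perturbation scenario
#'
#' Returns the schedules and initial state of the model perturbation
#' experiments:
#' \describe{
#'   \item{steady}{constant parameters, started at the fixed point.}
#'   \item{branching}{de-novo tip growth: reference thickness, vesicle level
#'     and remodeler load at `init_frac` (default 10\%) of their steady
#'     values, so growth starts near zero and builds up.}
#'   \item{osmotic_shock}{a step turgor drop of `delta_P` at `t_onset`,
#'     recovering exponentially with time constant `recovery_tau` (osmotic
#'     adaptation; growth restarts within 10-15 min).}
#'   \item{secretion_block}{vesicle source and sink ramped down over
#'     `ramp_min` to `source_mult` and `sink_mult` of their values
#'     (microtubule-depolymerization / ER-exit block); the sink is reduced
#'     harder than the source, see the methods vignette.}
#'   \item{obstacle}{a progressive partial turgor drop of fraction `depth`
#'     (ramp down, hold, ramp back), the effective load change of pushing
#'     against an elastic obstacle and escaping it.}
#' }
#'
#' @param kind scenario name.
#' @param params `model_params` used for the reference fixed point.
#' @param duration_min total simulated time.
#' @param t_onset perturbation onset (min).
#' @param dt output grid step (min).
#' @param init_frac branching: initial fraction of EV* and w*.
#' @param delta_P shock: turgor drop (MPa); default the 0.2 M sorbitol
#'   equivalent.
#' @param recovery_tau shock: adaptation time constant (min).
#' @param source_mult,sink_mult secretion block: terminal multipliers of
#'   `phi` and `alpha`.
#' @param ramp_min secretion block: ramp duration.
#' @param depth obstacle: fractional turgor drop.
#' @param ramp_down,hold,ramp_up obstacle: phase durations (min).
#' @return a `tip_scenario` list: kind, P_fun, phi_mult, alpha_mult,
#'   initial_state, t_grid, duration.
#' @export
make_scenario <- function(kind = c("steady", "branching", "osmotic_shock",
                                   "secretion_block", "obstacle"),
                          params = default_params(), duration_min = NULL,
                          t_onset = 5, dt = 0.1, init_frac = 0.1,
                          delta_P = vant_hoff_pressure(0.2),
                          recovery_tau = 6,
                          source_mult = 0.2, sink_mult = 0.1, ramp_min = 3,
                          depth = 0.22, ramp_down = 10, hold = 5,
                          ramp_up = 10) {
  kind <- match.arg(kind)
  ss <- steady_state(params)
  at_ss <- c(h = ss$h_star, EV = ss$EV_star, w = ss$h_star * ss$c_star)
  one <- function(t) 1
  Pconst <- function(t) params$P
  sc <- switch(kind,
    steady = list(duration = 120, P_fun = Pconst, phi_mult = one,
                  alpha_mult = one, initial_state = at_ss),
    branching = list(duration = 40, P_fun = Pconst, phi_mult = one,
                     alpha_mult = one,
                     initial_state = c(h = ss$h_star,
                                       EV = init_frac * ss$EV_star,
                                       w = init_frac * ss$h_star * ss$c_star)),
    osmotic_shock = list(
      duration = 60,
      P_fun = function(t) if (t < t_onset) params$P else
        params$P - delta_P * exp(-(t - t_onset) / recovery_tau),
      phi_mult = one, alpha_mult = one, initial_state = at_ss),
    secretion_block = local({
      ramp <- function(m) function(t)
        if (t < t_onset) 1 else if (t < t_onset + ramp_min)
          1 - (1 - m) * (t - t_onset) / ramp_min else m
      list(duration = 60, P_fun = Pconst, phi_mult = ramp(source_mult),
           alpha_mult = ramp(sink_mult), initial_state = at_ss)
    }),
    obstacle = local({
      t1 <- t_onset; t2 <- t1 + ramp_down; t3 <- t2 + hold; t4 <- t3 + ramp_up
      list(duration = t4 + 40,
           P_fun = function(t) {
             f <- if (t < t1) 0 else if (t < t2) (t - t1) / ramp_down
               else if (t < t3) 1 else if (t < t4) (t4 - t) / ramp_up else 0
             params$P * (1 - depth * f)
           },
           phi_mult = one, alpha_mult = one, initial_state = at_ss)
    }))
  if (!is.null(duration_min)) sc$duration <- duration_min
  sc$t_grid <- seq(0, sc$duration, by = dt)
  sc$kind <- kind
  class(sc) <- "tip_scenario"
  sc
}

#' @export
print.tip_scenario <- function(x, ...) {
  cat("tip-growth scenario:", x$kind, "-", x$duration, "min\n")
  invisible(x)
}
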