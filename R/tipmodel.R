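#' Tip-growth model parameters
#'
#' Parameters of the vesicle/wall/growth feedback model. The state couples
#' tip wall thickness `h` (nm), apical exocytic-vesicle level `EV`
#' (arbitrary units), and the areal load of wall-remodeling factors `w = h c`
#' through
#' \deqn{dh/dt = \gamma EV - G h}
#' \deqn{dEV/dt = \phi G - \alpha EV}
#' \deqn{d(hc)/dt = \beta EV - G h c}
#' with the wall strain rate `G = mu c (P R / (Y h) - epsilon)`, clamped at
#' zero below the yield strain (plastic flow is irreversible). Derived
#' quantities: `tau = 1000 P R / Y` (nm, the thickness at unit elastic
#' strain), `theta = epsilon / tau` (1/nm), `eta = beta mu tau`.
#'
#' @param gamma wall deposition per vesicle unit (nm per EV per min).
#' @param phi strain-rate feedback gain on vesicle recruitment (EV min).
#' @param alpha vesicle consumption/turnover rate (1/min).
#' @param beta remodeler incorporation coefficient (per EV per min).
#' @param mu strain-rate coefficient per remodeler unit (1/min).
#' @param epsilon dimensionless plastic yield strain.
#' @param P turgor pressure (MPa).
#' @param R tip radius of curvature (um).
#' @param Y wall Young's modulus (MPa).
#' @return a `model_params` object with a `derived` element.
#' @export
model_params <- function(gamma, phi, alpha, beta, mu, epsilon, P, R, Y) {
  v <- c(gamma = gamma, phi = phi, alpha = alpha, beta = beta, mu = mu,
         epsilon = epsilon, P = P, R = R, Y = Y)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all model parameters must be positive, got: ",
         paste(names(v)[!(is.finite(v) & v > 0)], collapse = ", "))
  p <- as.list(v)
  class(p) <- "model_params"
  p
}

# derived scales, never stored (always recomputed from the base parameters)
.tau_nm <- function(p, P = p$P) 1000 * P * p$R / p$Y
.theta <- function(p, P = p$P) p$epsilon / .tau_nm(p, P)
.eta <- function(p, P = p$P) p$beta * p$mu * .tau_nm(p, P)

#' @export
print.model_params <- function(x, ...) {
  cat("tip-growth model parameters:\n")
  cat(sprintf("  gamma %.4g  phi %.4g  alpha %.4g  beta %.4g  mu %.4g\n",
              x$gamma, x$phi, x$alpha, x$beta, x$mu))
  cat(sprintf("  epsilon %.4g  P %.4g MPa  R %.4g um  Y %.4g MPa\n",
              x$epsilon, x$P, x$R, x$Y))
  cat(sprintf("  derived: tau %.4g nm  theta %.4g /nm  eta %.4g\n",
              .tau_nm(x), .theta(x), .eta(x)))
  invisible(x)
}

#' Elastic strain of the tip wall
#'
#' `P R / (Y h)`, the dimensionless elastic strain of a thin pressurized
#' shell of thickness `h` (the factor 1000 reconciles MPa um / (MPa nm)).
#'
#' @param params `model_params`.
#' @param h_nm wall thickness (nm), > 0.
#' @param P_MPa optional pressure override (scenario schedules).
#' @return dimensionless elastic strain.
#' @export
elastic_strain_tip <- function(params, h_nm, P_MPa = params$P) {
  if (any(h_nm <= 0)) stop("h must be positive")
  .tau_nm(params, P_MPa) / h_nm
}

#' Wall strain rate
#'
#' `G = mu c (P R / (Y h) - epsilon)`, clamped at zero below yield.
#'
#' @param params `model_params`.
#' @param c_au remodeler concentration (>= 0).
#' @param h_nm wall thickness (nm).
#' @param P_MPa optional pressure override.
#' @return strain rate (1/min).
#' @export
growth_rate <- function(params, c_au, h_nm, P_MPa = params$P) {
  if (any(c_au < 0)) stop("c must be >= 0")
  params$mu * c_au * pmax(0, elastic_strain_tip(params, h_nm, P_MPa) -
                            params$epsilon)
}

#' Growing steady state of the model
#'
#' Closed forms: `h* = gamma phi / alpha`, `c* = beta / gamma`,
#' `G* = eta phi (1 - theta h*) / (alpha h*^2)`, `EV* = phi G* / alpha`.
#' A growing fixed point exists only if `theta h* < 1` (the yield strain is
#' exceeded at the homeostatic thickness).
#'
#' @param params `model_params`.
#' @return a `steady_state` list: h_star, EV_star, G_star, c_star, theta_h.
#' @export
steady_state <- function(params) {
  h <- params$gamma * params$phi / params$alpha
  th <- .theta(params) * h
  if (th >= 1)
    stop("no growing fixed point: theta * h_star = ", signif(th, 4), " >= 1")
  G <- .eta(params) * params$phi * (1 - th) / (params$alpha * h^2)
  structure(list(h_star = h, EV_star = params$phi * G / params$alpha,
                 G_star = G, c_star = params$beta / params$gamma,
                 theta_h = th),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("steady state: h* %.3g nm, EV* %.3g, G* %.3g /min, c* %.3g (theta h* = %.3g)\n",
              x$h_star, x$EV_star, x$G_star, x$c_star, x$theta_h))
  invisible(x)
}

#' Model right-hand side
#'
#' Exact time derivatives of the model state, in one of two formulations:
#' `algebraic_G` evolves `(h, EV, w = h c)` with `G` computed algebraically
#' from the yield law (the reference formulation; handles the `G = 0` clamp),
#' while `eq5` evolves `(h, EV, G)` using the derived strain-rate equation
#' \deqn{dG/dt = \eta EV (1-\theta h)/h^2 - \gamma \frac{2-\theta h}{(1-\theta h) h} G\,EV + \frac{G^2}{1-\theta h},}
#' valid only while `theta h < 1` and `G > 0`.
#'
#' @param state named vector: `h, EV, w` (algebraic_G) or `h, EV, G` (eq5).
#' @param params `model_params`.
#' @param t time (min), used for scenario schedules.
#' @param scenario optional `tip_scenario` providing `P(t)` and source/sink
#'   multiplier schedules.
#' @param formulation `"algebraic_G"` or `"eq5"`.
#' @return list(deriv = named derivative vector, G = strain rate).
#' @export
tip_derivatives <- function(state, params, t = 0, scenario = NULL,
                            formulation = c("algebraic_G", "eq5")) {
  formulation <- match.arg(formulation)
  P <- if (is.null(scenario)) params$P else scenario$P_fun(t)
  mphi <- if (is.null(scenario)) 1 else scenario$phi_mult(t)
  malp <- if (is.null(scenario)) 1 else scenario$alpha_mult(t)
  h <- state[["h"]]; EV <- state[["EV"]]
  if (formulation == "algebraic_G") {
    w <- state[["w"]]
    G <- growth_rate(params, w / h, h, P)
    d <- c(h = params$gamma * EV - G * h,
           EV = mphi * params$phi * G - malp * params$alpha * EV,
           w = params$beta * EV - G * w)
  } else {
    G <- state[["G"]]
    th <- .theta(params, P) * h
    if (th >= 1)
      stop("eq5 formulation invalid at theta*h >= 1; use algebraic_G")
    eta <- .eta(params, P)
    d <- c(h = params$gamma * EV - G * h,
           EV = mphi * params$phi * G - malp * params$alpha * EV,
           G = eta * EV * (1 - th) / h^2 -
             params$gamma * (2 - th) / ((1 - th) * h) * G * EV +
             G^2 / (1 - th))
  }
  list(deriv = d, G = unname(G))
}

#' Integrate the model
#'
#' Adaptive stiff-capable integration (lsoda) of the model on a time grid,
#' under an optional perturbation scenario. State invariants are enforced:
#' the run aborts with a diagnostic if thickness leaves (0, Inf) or the
#' solver fails (expected for unstable model variants). The first time `G`
#' reaches zero, if any, is recorded in the `t_G_zero` attribute.
#'
#' @param params `model_params`.
#' @param scenario optional `tip_scenario`; its initial state and duration
#'   are used unless overridden.
#' @param t_grid output times (min); defaults to the scenario grid.
#' @param formulation see [tip_derivatives()]; `eq5` requires a scenario with
#'   constant pressure.
#' @param initial_state optional named state vector override.
#' @param rtol,atol solver tolerances.
#' @return a `tip_trajectory` data.frame: t_min, h_nm, EV_au, G_per_min,
#'   c_au, P_MPa.
#' @export
integrate_model <- function(params, scenario = NULL, t_grid = NULL,
                            formulation = c("algebraic_G", "eq5"),
                            initial_state = NULL, rtol = 1e-8, atol = 1e-10) {
  formulation <- match.arg(formulation)
  if (is.null(t_grid))
    t_grid <- if (!is.null(scenario)) scenario$t_grid else seq(0, 120, 0.5)
  if (is.null(initial_state)) {
    initial_state <- if (!is.null(scenario) && !is.null(scenario$initial_state))
      scenario$initial_state else {
        ss <- steady_state(params)
        c(h = ss$h_star, EV = ss$EV_star, G = ss$G_star,
          w = ss$h_star * ss$c_star)
      }
  }
  y0 <- if (formulation == "algebraic_G") {
    st <- initial_state
    if (!("w" %in% names(st)))
      st[["w"]] <- st[["h"]] * 0  # G=0 start maps to zero remodeler load
    st[c("h", "EV", "w")]
  } else {
    st <- initial_state
    if (!("G" %in% names(st)))
      st[["G"]] <- growth_rate(params, st[["w"]] / st[["h"]], st[["h"]])
    st[c("h", "EV", "G")]
  }
  rhs <- function(t, y, parms) {
    list(tip_derivatives(y, params, t, scenario, formulation)$deriv)
  }
  sol <- deSolve::ode(y = y0, times = t_grid, func = rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  sol <- as.data.frame(sol)
  if (anyNA(sol) || nrow(sol) < length(t_grid) || any(sol$h <= 0))
    stop("integration aborted: state left the physical domain ",
         "(h <= 0 or solver failure) at t ~ ",
         signif(sol$time[which(!is.finite(sol$h) | sol$h <= 0)[1]], 4),
         " min")
  P_t <- if (is.null(scenario)) rep(params$P, nrow(sol)) else
    vapply(sol$time, scenario$P_fun, numeric(1))
  if (formulation == "algebraic_G") {
    G <- mapply(function(w, h, P) growth_rate(params, w / h, h, P),
                sol$w, sol$h, P_t)
    c_au <- sol$w / sol$h
  } else {
    G <- pmax(sol$G, 0)
    c_au <- G / pmax(params$mu * pmax(elastic_strain_tip(params, sol$h, P_t) -
                                        params$epsilon, 1e-300), 1e-300)
  }
  out <- data.frame(t_min = sol$time, h_nm = sol$h, EV_au = sol$EV,
                    G_per_min = G, c_au = c_au, P_MPa = P_t)
  iz <- which(out$G_per_min <= 1e-12)
  structure(out, t_G_zero = if (length(iz)) out$t_min[iz[1]] else NA_real_,
            formulation = formulation, class = c("tip_trajectory", "data.frame"))
}

#' Linear stability of the growing fixed point
#'
#' Numerical Jacobian (central differences, relative step 1e-6) of the
#' three-variable system `(h, EV, w)` at the growing fixed point, for the
#' reference model or a feedback variant: `"none"` replaces the vesicle
#' source by a constant (no mechanical feedback), `"elastic_strain"` makes it
#' proportional to the elastic strain `P R / (Y h)` instead of the strain
#' rate. Variant sources are scaled so the reference fixed point remains an
#' equilibrium, which is the point whose stability is probed.
#'
#' @param params `model_params`.
#' @param variant `"strain_rate"`, `"none"`, or `"elastic_strain"`.
#' @param point optional candidate fixed point list (h_star, EV_star,
#'   c_star); defaults to [steady_state()].
#' @return list(eigenvalues, stable, jacobian, variant).
#' @export
stability <- function(params, variant = c("strain_rate", "none",
                                          "elastic_strain"),
                      point = NULL) {
  variant <- match.arg(variant)
  ss <- if (is.null(point)) steady_state(params) else point
  y0 <- c(h = ss$h_star, EV = ss$EV_star, w = ss$h_star * ss$c_star)
  src <- switch(variant,
    strain_rate = function(G, h) params$phi * G,
    none = local({
      S <- params$alpha * ss$EV_star
      function(G, h) S
    }),
    elastic_strain = local({
      k <- params$alpha * ss$EV_star / elastic_strain_tip(params, ss$h_star)
      function(G, h) k * elastic_strain_tip(params, h)
    }))
  f <- function(y) {
    h <- y[["h"]]; EV <- y[["EV"]]; w <- y[["w"]]
    G <- growth_rate(params, w / h, h)
    c(params$gamma * EV - G * h,
      src(G, h) - params$alpha * EV,
      params$beta * EV - G * w)
  }
  n <- length(y0)
  J <- matrix(0, n, n, dimnames = list(names(y0), names(y0)))
  for (j in seq_len(n)) {
    d <- max(abs(y0[j]), 1e-6) * 1e-6
    yp <- y0; ym <- y0
    yp[j] <- y0[j] + d; ym[j] <- y0[j] - d
    J[, j] <- (f(yp) - f(ym)) / (2 * d)
  }
  ev <- eigen(J, only.values = TRUE)$values
  list(eigenvalues = ev, stable = all(Re(ev) < 0), jacobian = J,
       variant = variant)
}

#' Count growing equilibria
#'
#' Counts equilibria with `G > 0` and `EV > 0` by reducing the equilibrium
#' conditions to one residual in `h` (using `EV = phi G / alpha` and
#' `c = beta phi / (alpha h)` at equilibrium), scanning a wide logarithmic
#' grid for sign changes, polishing each bracket with uniroot, and validating
#' the full derivative vector at each candidate.
#'
#' @param params `model_params`.
#' @param h_range scan range for thickness (nm).
#' @param n_grid grid size.
#' @return integer count of distinct growing equilibria.
#' @export
count_fixed_points <- function(params, h_range = c(1e-2, 1e4), n_grid = 4000) {
  cc <- function(h) params$beta * params$phi / (params$alpha * h)
  Gf <- function(h) growth_rate(params, cc(h), h)
  resid <- function(h) Gf(h) * (params$gamma * params$phi / params$alpha - h)
  hs <- exp(seq(log(h_range[1]), log(h_range[2]), length.out = n_grid))
  r <- vapply(hs, resid, numeric(1))
  pos <- vapply(hs, Gf, numeric(1)) > 0
  roots <- c()
  for (i in seq_len(n_grid - 1)) {
    if (!pos[i] && !pos[i + 1]) next
    if (r[i] == 0 && pos[i]) roots <- c(roots, hs[i])
    if (r[i] * r[i + 1] < 0) {
      rt <- stats::uniroot(resid, c(hs[i], hs[i + 1]), tol = 1e-12)$root
      roots <- c(roots, rt)
    }
  }
  if (length(roots) == 0) return(0L)
  roots <- roots[!duplicated(round(log(roots), 6))]
  ok <- vapply(roots, function(h) {
    G <- Gf(h); EV <- params$phi * G / params$alpha
    if (G <= 0 || EV <= 0) return(FALSE)
    st <- c(h = h, EV = EV, w = h * cc(h))
    max(abs(tip_derivatives(st, params)$deriv)) <
      1e-6 * max(1, G * h)
  }, logical(1))
  sum(ok)
}

#' Calibrate the model from steady-state observables
#'
#' Builds a parameter set whose growing fixed point reproduces the observed
#' tip thickness, strain rate, and vesicle level exactly. The yield strain is
#' set by the smallest pressure drop that arrests growth: `epsilon =
#' (P - deltaP_stop) R / (Y h*)` (yield is reached exactly at the stopping
#' pressure). `alpha` (vesicle turnover) and `mu` are gauge choices; `phi`,
#' `gamma`, `beta` then follow from the closed-form fixed point.
#'
#' @param h_star observed tip wall thickness (nm).
#' @param G_star observed tip strain rate (1/min).
#' @param EV_star vesicle level scale (au); the wild-type default normalizes
#'   EV* to 1.
#' @param P turgor (MPa).
#' @param R tip radius (um).
#' @param Y tip wall Young's modulus (MPa).
#' @param deltaP_stop pressure drop that stops growth (MPa), in (0, P).
#' @param alpha vesicle turnover rate (1/min).
#' @param mu strain-rate coefficient.
#' @return `model_params` with `steady_state()` equal to the observables.
#' @export
calibrate <- function(h_star, G_star, EV_star = 1, P = 1.1, R = 1.2, Y = 64,
                      deltaP_stop = vant_hoff_pressure(0.2), alpha = 1,
                      mu = 1) {
  if (deltaP_stop <= 0 || deltaP_stop >= P)
    stop("deltaP_stop must lie strictly between 0 and P ",
         "(deltaP_stop = 0 means growth never stops: G* undefined)")
  if (any(c(h_star, G_star, EV_star) <= 0))
    stop("observables must be positive")
  epsilon <- 1000 * (P - deltaP_stop) * R / (Y * h_star)
  tau <- 1000 * P * R / Y
  phi <- alpha * EV_star / G_star
  gamma <- alpha * h_star / phi
  c_star <- G_star / (mu * (tau / h_star - epsilon))
  model_params(gamma = gamma, phi = phi, alpha = alpha,
               beta = gamma * c_star, mu = mu, epsilon = epsilon,
               P = P, R = R, Y = Y)
}

#' Canonical wild-type calibration
#'
#' The package's reference parameter set, generated by [calibrate()] from
#' tip observables of mature wild-type hyphae: `h* = 65` nm, `G* = 0.25`
#' per min, `EV* = 1` (normalization), `P = 1.1` MPa, `R = 1.2` um, `Y = 64`
#' MPa, growth arrest at 0.2 M sorbitol (`deltaP_stop ~ 0.496` MPa), vesicle
#' turnover `alpha = 1` per min. See the methods vignette for why these
#' choices place the model in its stable, experimentally consistent regime.
#'
#' @return `model_params`.
#' @export
default_params <- function() {
  calibrate(h_star = 65, G_star = 0.25, EV_star = 1, P = 1.1, R = 1.2,
            Y = 64, deltaP_stop = vant_hoff_pressure(0.2), alpha = 1, mu = 1)
}

#' Tip elongation speed from the strain rate
#'
#' The strain rate is the surface growth speed divided by the tip radius
#' squared; for a hemispherical cap advancing at speed `v` the surface
#' creation rate is `2 pi R v`, so `v = G R / (2 pi)`.
#'
#' @param G_per_min strain rate (1/min).
#' @param R_um tip radius (um).
#' @return tip speed (um/min).
#' @export
tip_speed <- function(G_per_min, R_um) G_per_min * R_um / (2 * pi)
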