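#' Temperature-dependent rate factor of a metabolic reaction
#'
#' Multiplier of a Boltzmann-limited rate at temperature `temp_c` (degrees C)
#' relative to the rate at 0 C. Expanding the Boltzmann factor
#' \eqn{e^{-E/(K T_k)}} about the freezing point \eqn{T_a} gives the exact
#' exponent \eqn{\frac{E}{K T_a^2}\,\frac{T}{1 + T/T_a}}; because
#' developmental temperatures stay below about 32 C (\eqn{T/T_a \lesssim 0.1})
#' the linearised exponent \eqn{\frac{E}{K T_a^2} T} is used throughout the
#' fold-change laws, and the exact form is kept for quantifying the
#' approximation error.
#'
#' @param temp_c Temperature in degrees Celsius (vectorised).
#' @param activation_energy Activation energy `E`, eV.
#' @param constants [thermal_constants()].
#' @param mode `"linearized"` (default; matches the fitted scaling factors)
#'   or `"exact"`.
#' @return Dimensionless rate multiplier `exp(exponent)`, same length as
#'   `temp_c`.
#' @examples
#' rate_factor(25, 0.822)
#' rate_factor(25, 0.822, mode = "exact")
#' @export
rate_factor <- function(temp_c, activation_energy,
                        constants = thermal_constants(),
                        mode = c("linearized", "exact")) {
  mode <- match.arg(mode)
  if (!is.numeric(temp_c) || !all(is.finite(temp_c)))
    stop("temp_c must be finite numeric", call. = FALSE)
  if (!is.numeric(activation_energy) || !all(is.finite(activation_energy)) ||
      any(activation_energy <= 0))
    stop("activation_energy must be finite and positive", call. = FALSE)
  slope <- activation_energy / (constants$boltzmann_k * constants$t_a^2)
  expo <- switch(mode,
                 linearized = slope * temp_c,
                 exact = slope * temp_c / (1 + temp_c / constants$t_a))
  exp(expo)
}

#' Integrate the ontogenetic growth equation
#'
#' Solves \eqn{dm/dt = a(T)\, m^{z} [1 - (m/M)^{1-z}]} at a fixed
#' temperature, where the rate coefficient is
#' `params$base_rate * rate_factor(temp_c, params$activation_energy)`.
#' Integration is performed on the substituted variable
#' \eqn{u = (m/M)^{1-z}}, whose equation
#' \eqn{du/dt = (1-z)\, a\, M^{z-1} (1 - u)} is regular at `m = 0` (the mass
#' equation itself has a degenerate equilibrium there), with an adaptive
#' solver at relative tolerance 1e-8.
#'
#' @param params [growth_params()].
#' @param temp_c Rearing temperature, degrees C.
#' @param t_end End of the integration window (> 0), in the time unit of
#'   `base_rate`.
#' @param n_steps Number of output intervals on the uniform time grid.
#' @param constants [thermal_constants()].
#' @param mode Rate-factor mode, `"linearized"` or `"exact"`.
#' @return Data frame with columns `time` and `mass` (`n_steps + 1` rows).
#' @examples
#' gp <- growth_params(base_rate = 1, activation_energy = 0.822,
#'                     asymptotic_mass = 1)
#' tail(solve_growth(gp, temp_c = 25, t_end = 5), 3)
#' @export
solve_growth <- function(params, temp_c, t_end, n_steps = 200L,
                         constants = thermal_constants(),
                         mode = c("linearized", "exact")) {
  stopifnot(inherits(params, "growth_params"), is.finite(t_end), t_end > 0,
            n_steps >= 1L)
  mode <- match.arg(mode)
  a_T <- params$base_rate *
    rate_factor(temp_c, params$activation_energy, constants, mode)
  z <- params$exponent
  M <- params$asymptotic_mass
  u0 <- (params$initial_mass / M)^(1 - z)
  k <- (1 - z) * a_T * M^(z - 1)
  times <- seq(0, t_end, length.out = n_steps + 1L)
  sol <- deSolve::lsoda(
    y = c(u = u0), times = times,
    func = function(t, y, p) list(k * (1 - y)),
    rtol = 1e-8, atol = 1e-16)
  if (attr(sol, "istate")[1L] < 0)
    stop("growth ODE solver failed to converge; istate = ",
         attr(sol, "istate")[1L], ", steps taken = ",
         attr(sol, "istate")[15L], call. = FALSE)
  u <- pmin(pmax(sol[, "u"], 0), 1)
  data.frame(time = sol[, "time"], mass = M * u^(1 / (1 - z)))
}

#' Closed-form solution of the growth equation
#'
#' For exponent `z = 3/4` the growth curve admits the closed form
#' \eqn{(m/M)^{1/4} = 1 - [1 - (m_0/M)^{1/4}]\, e^{-a t/(4 M^{1/4})}}
#' (and the analogous form for general `z`). Used as the regression oracle
#' for [solve_growth()] and to convert growth into developmental time.
#'
#' @inheritParams solve_growth
#' @param times Numeric vector of times.
#' @return Mass at `times`.
#' @export
growth_closed_form <- function(params, temp_c, times,
                               constants = thermal_constants(),
                               mode = c("linearized", "exact")) {
  mode <- match.arg(mode)
  a_T <- params$base_rate *
    rate_factor(temp_c, params$activation_energy, constants, mode)
  z <- params$exponent
  M <- params$asymptotic_mass
  u0 <- (params$initial_mass / M)^(1 - z)
  k <- (1 - z) * a_T * M^(z - 1)
  u <- 1 - (1 - u0) * exp(-k * times)
  M * u^(1 / (1 - z))
}

#' Time to grow to a target mass
#'
#' Inverts the closed-form growth curve: the developmental time at a given
#' temperature is the time at which the mass reaches `target_mass`
#' (identical across temperatures, since eclosion mass is assumed
#' temperature-independent). The default target operationalises the
#' small-mass regime `m << M` as `1e-3 * M`.
#'
#' @inheritParams solve_growth
#' @param target_mass Mass defining developmental completion; default
#'   `1e-3 * asymptotic_mass`.
#' @return Time (same unit as `1/base_rate`).
#' @export
time_to_mass <- function(params, temp_c, target_mass = NULL,
                         constants = thermal_constants(),
                         mode = c("linearized", "exact")) {
  mode <- match.arg(mode)
  M <- params$asymptotic_mass
  if (is.null(target_mass)) target_mass <- 1e-3 * M
  stopifnot(target_mass > params$initial_mass, target_mass < M)
  a_T <- params$base_rate *
    rate_factor(temp_c, params$activation_energy, constants, mode)
  z <- params$exponent
  u0 <- (params$initial_mass / M)^(1 - z)
  u1 <- (target_mass / M)^(1 - z)
  k <- (1 - z) * a_T * M^(z - 1)
  log((1 - u0) / (1 - u1)) / k
}

#' Fold change in developmental time with temperature
#'
#' \eqn{t/t_0 = e^{-\alpha (T - T_0)}}: development is faster (the ratio is
#' below 1) above the reference temperature when `alpha > 0`.
#'
#' @param temp_c Temperature, degrees C (vectorised).
#' @param scaling [scaling_params()].
#' @return Dimensionless ratio `t/t0`.
#' @examples
#' devtime_fold_change(18, scaling_params(0.128, 0.133))
#' @export
devtime_fold_change <- function(temp_c, scaling) {
  stopifnot(inherits(scaling, "scaling_params"))
  if (!is.numeric(temp_c) || !all(is.finite(temp_c)))
    stop("temp_c must be finite numeric", call. = FALSE)
  exp(-scaling$alpha * (temp_c - scaling$ref_temp))
}

#' Fold change in synaptic connectivity with temperature
#'
#' \eqn{n/n_0 = e^{-\beta (T - T_0)}}. When the brain's rate-limiting
#' reaction has the same activation energy as the body's (`beta = 0`) the
#' ratio is identically 1: the same connectivity is reached at every
#' temperature.
#'
#' @inheritParams devtime_fold_change
#' @return Dimensionless ratio `n/n0`.
#' @examples
#' connectivity_fold_change(18, scaling_params(0.128, 0.133))
#' @export
connectivity_fold_change <- function(temp_c, scaling) {
  stopifnot(inherits(scaling, "scaling_params"))
  if (!is.numeric(temp_c) || !all(is.finite(temp_c)))
    stop("temp_c must be finite numeric", call. = FALSE)
  exp(-scaling$beta * (temp_c - scaling$ref_temp))
}

#' Activation energies implied by the fitted scaling factors
#'
#' Converts the macroscopic per-degree scaling factors into activation
#' energies via \eqn{E = \alpha K T_a^2} (whole-body development),
#' \eqn{\Delta E = \beta K T_a^2 / 4} and \eqn{E' = E - \Delta E} (the
#' rate-limiting reaction for brain development).
#'
#' @param scaling [scaling_params()].
#' @param constants [thermal_constants()]; defaults to those stored in
#'   `scaling`.
#' @return Named list with `e` (body, eV), `delta_e` (eV), `e_prime`
#'   (brain, eV).
#' @examples
#' activation_energies(scaling_params(0.128, 0.133))
#' @export
activation_energies <- function(scaling, constants = NULL) {
  stopifnot(inherits(scaling, "scaling_params"))
  constants <- constants %||% scaling$constants
  stopifnot(scaling$alpha > 0, scaling$beta >= 0)
  kta2 <- constants$boltzmann_k * constants$t_a^2
  e <- scaling$alpha * kta2
  delta_e <- scaling$beta * kta2 / 4
  if (delta_e >= e)
    warning("beta >= 4 * alpha implies a negative brain activation energy",
            call. = FALSE)
  list(e = e, delta_e = delta_e, e_prime = e - delta_e)
}

#' Relative developmental advancement of the brain at matched ontogenetic
#' fraction
#'
#' Compares brain state (synapse count `n`) at the same fraction of
#' ontogenesis across temperatures. In the small-mass regime both body and
#' brain grow as a power of `a * t`, so the advancement at any fixed
#' fraction of development equals \eqn{e^{-\beta (T - T_0)}} independently of
#' the fraction: at lower rearing temperature the brain at, say, half of
#' pupal development is in a more advanced state than at higher temperature.
#'
#' @inheritParams devtime_fold_change
#' @param fraction Ontogenetic fraction in (0, 1]; the result does not
#'   depend on it (argument kept to make the matched-stage comparison
#'   explicit).
#' @return Fold advancement (> 1 below `ref_temp` when `beta > 0`).
#' @examples
#' relative_brain_stage(18, scaling_params(0.128, 0.133))
#' @export
relative_brain_stage <- function(temp_c, scaling, fraction = 0.5) {
  stopifnot(inherits(scaling, "scaling_params"),
            is.numeric(fraction), all(fraction > 0), all(fraction <= 1))
  connectivity_fold_change(temp_c, scaling)
}
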