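#' Two-level temperature cycle specification
#'
#' A step cycle alternating between a low dwell `t_low` (T1) and a high
#' dwell `t_high` (T2) with equal time at each level, summarised by its mean
#' \eqn{\bar T = (T_1 + T_2)/2} and half-amplitude
#' \eqn{\Delta T = (T_2 - T_1)/2}.
#'
#' @param t_low,t_high Low and high temperature, degrees C.
#' @return An object of class `cycle_spec` with fields `t_low`, `t_high`,
#'   `mean_temp`, `half_amplitude`.
#' @examples
#' cycle_spec(18, 30)
#' @export
cycle_spec <- function(t_low, t_high) {
  stopifnot(is.numeric(t_low), is.numeric(t_high), is.finite(t_low),
            is.finite(t_high), t_high >= t_low)
  structure(list(t_low = t_low, t_high = t_high,
                 mean_temp = (t_low + t_high) / 2,
                 half_amplitude = (t_high - t_low) / 2),
            class = "cycle_spec")
}

#' Periodic temperature profile (piecewise linear)
#'
#' An arbitrary periodic temperature waveform given by knots
#' (phase time within one period, temperature) interpolated piecewise
#' linearly and wrapped around the period, e.g. the experimental protocol of
#' 8-hour holds at the extremes connected by 4-hour linear ramps.
#'
#' @param phase_hours Knot times, strictly increasing within `[0, period)`.
#' @param temp_c Knot temperatures, degrees C, within `[10, 35]`.
#' @param period Cycle period, hours (default 24).
#' @return An object of class `temperature_profile`.
#' @examples
#' # 8 h at 30 C, 4 h ramp down, 8 h at 18 C, 4 h ramp up
#' trapezoid_profile(cycle_spec(18, 30))
#' @export
temperature_profile <- function(phase_hours, temp_c, period = 24) {
  stopifnot(is.numeric(phase_hours), is.numeric(temp_c),
            length(phase_hours) == length(temp_c), length(temp_c) >= 1L,
            all(is.finite(phase_hours)), all(is.finite(temp_c)),
            is.finite(period), period > 0)
  if (any(phase_hours < 0) || any(phase_hours >= period))
    stop("knot times must lie within [0, period)", call. = FALSE)
  if (any(diff(phase_hours) <= 0))
    stop("knot times must be strictly increasing", call. = FALSE)
  if (any(temp_c < 10) || any(temp_c > 35))
    stop("knot temperatures must lie within [10, 35] C", call. = FALSE)
  structure(list(phase_hours = phase_hours, temp_c = temp_c,
                 period = period),
            class = "temperature_profile")
}

#' @rdname temperature_profile
#' @param cycle A [cycle_spec()].
#' @param ramp_hours Duration of each linear transition between levels; use
#'   a small value (default in [square_profile()] is 1e-6 h) for an
#'   effectively instantaneous step.
#' @export
square_profile <- function(cycle, period = 24, ramp_hours = 1e-6) {
  trapezoid_profile(cycle, period = period, ramp_hours = ramp_hours)
}

#' @rdname temperature_profile
#' @export
trapezoid_profile <- function(cycle, period = 24, ramp_hours = 4) {
  stopifnot(inherits(cycle, "cycle_spec"), ramp_hours >= 0,
            2 * ramp_hours < period)
  hold <- (period - 2 * ramp_hours) / 2
  temperature_profile(
    phase_hours = c(0, hold, hold + ramp_hours, 2 * hold + ramp_hours),
    temp_c = c(cycle$t_high, cycle$t_high, cycle$t_low, cycle$t_low),
    period = period)
}

#' Evaluate a periodic profile at arbitrary times
#'
#' @param profile A [temperature_profile()].
#' @param hours Times in hours (any real values; the profile is periodic).
#' @return Temperatures, degrees C.
#' @export
profile_temperature <- function(profile, hours) {
  stopifnot(inherits(profile, "temperature_profile"))
  ph <- profile$phase_hours
  tc <- profile$temp_c
  # close the period: the last segment wraps to the first knot
  x <- c(ph, ph[1L] + profile$period)
  y <- c(tc, tc[1L])
  phase <- hours %% profile$period
  # phases below the first knot belong to the wrapped final segment
  phase <- ifelse(phase < ph[1L], phase + profile$period, phase)
  stats::approx(x, y, xout = phase, method = "linear", rule = 2)$y
}

#' Fold change in developmental time on a step temperature cycle
#'
#' For a two-level cycle with equal dwell at \eqn{\bar T \pm \Delta T},
#' developmental time relative to constant development at the mean
#' temperature is \eqn{\tilde t / \bar t = 1 / \cosh(\alpha \Delta T)}:
#' cycling always shortens development, increasingly so with amplitude,
#' because the high-temperature phase contributes disproportionately.
#'
#' @param scaling [scaling_params()].
#' @param half_amplitude Cycle half-amplitude \eqn{\Delta T} in degrees C
#'   (vectorised, non-negative).
#' @return Ratio \eqn{\tilde t / \bar t \le 1}.
#' @examples
#' step_cycle_time_fold(scaling_params(0.128, 0.133), half_amplitude = 4)
#' @export
step_cycle_time_fold <- function(scaling, half_amplitude) {
  stopifnot(inherits(scaling, "scaling_params"))
  if (!is.numeric(half_amplitude) || !all(is.finite(half_amplitude)) ||
      any(half_amplitude < 0))
    stop("half_amplitude must be non-negative and finite", call. = FALSE)
  1 / cosh(scaling$alpha * half_amplitude)
}

#' Fold change in connectivity on a step temperature cycle
#'
#' \eqn{\tilde n / \bar n = [\cosh(\gamma \Delta T) / \cosh(\alpha \Delta
#' T)]^4} with \eqn{\gamma = \alpha - \beta/4}. Since \eqn{\gamma < \alpha}
#' whenever `beta > 0`, fluctuating temperatures always produce fewer
#' synaptic partners than constant development at the mean temperature.
#'
#' @inheritParams step_cycle_time_fold
#' @return Ratio \eqn{\tilde n / \bar n \le 1}.
#' @examples
#' step_cycle_connectivity_fold(scaling_params(0.128, 0.133),
#'                              half_amplitude = 8)
#' @export
step_cycle_connectivity_fold <- function(scaling, half_amplitude) {
  stopifnot(inherits(scaling, "scaling_params"))
  if (!is.numeric(half_amplitude) || !all(is.finite(half_amplitude)) ||
      any(half_amplitude < 0))
    stop("half_amplitude must be non-negative and finite", call. = FALSE)
  (cosh(scaling$gamma * half_amplitude) /
     cosh(scaling$alpha * half_amplitude))^4
}

# Period averages of the linearised rate factors e^{s T(tau)} over one
# period, by composite trapezoid on each linear segment (endpoints always
# sampled, >= n_per_period points spread over the period).
profile_rate_means <- function(profile, slopes, n_per_period = 8000L) {
  ph <- c(profile$phase_hours, profile$phase_hours[1L] + profile$period)
  tc <- c(profile$temp_c, profile$temp_c[1L])
  total <- numeric(length(slopes))
  mean_temp_num <- 0
  for (i in seq_len(length(ph) - 1L)) {
    len <- ph[i + 1L] - ph[i]
    if (len <= 0) next
    npts <- max(2L, ceiling(n_per_period * len / profile$period) + 1L)
    tau <- seq(ph[i], ph[i + 1L], length.out = npts)
    temp <- tc[i] + (tc[i + 1L] - tc[i]) * (tau - ph[i]) / len
    h <- len / (npts - 1L)
    w <- c(h / 2, rep(h, npts - 2L), h / 2)
    for (j in seq_along(slopes))
      total[j] <- total[j] + sum(w * exp(slopes[j] * temp))
    mean_temp_num <- mean_temp_num + sum(w * temp)
  }
  list(means = total / profile$period,
       mean_temp = mean_temp_num / profile$period)
}

#' Fold change under an arbitrary periodic temperature program
#'
#' Generalises the step-cycle closed forms to any piecewise-linear periodic
#' waveform. Development under cycling satisfies
#' \eqn{\int_0^{\tilde t} a(T(\tau), E)\, d\tau = 4\, m^{1/4}} and the
#' wiring integral uses the brain rate \eqn{a(T(\tau), E')}; with many
#' cycles per development the integrals are governed by the period averages
#' \eqn{\langle e^{\alpha T} \rangle} and \eqn{\langle e^{\gamma T}
#' \rangle}, giving
#' \deqn{\tilde t/\bar t = e^{\alpha \bar T} / \langle e^{\alpha T}
#' \rangle, \qquad \tilde n/\bar n = \left[ (\tilde t/\bar t)\, \langle
#' e^{\gamma T} \rangle / e^{\gamma \bar T} \right]^4,}
#' where \eqn{\bar T} is the time-average temperature. These are the
#' many-period limits (exactly phase-invariant); on a two-level equal-dwell
#' profile they reduce to the \eqn{\cosh} laws. A doubled-resolution
#' quadrature check guards the numerical period averages.
#'
#' @param profile A [temperature_profile()].
#' @param scaling [scaling_params()].
#' @param quantity `"time"` or `"connectivity"`.
#' @param n_per_period Quadrature points per period (>= 100; the default is
#'   dense enough that the doubled-resolution check passes at 1e-6 even on
#'   steep ramps).
#' @param n_periods Number of cycles completed during development, used only
#'   to warn when the averaging assumption (>= 20 periods) is doubtful.
#' @return Dimensionless ratio relative to constant development at the
#'   profile's mean temperature.
#' @examples
#' sc <- scaling_params(0.128, 0.133)
#' general_cycle_fold(trapezoid_profile(cycle_spec(16, 32)), sc,
#'                    "connectivity")
#' @export
general_cycle_fold <- function(profile, scaling,
                               quantity = c("time", "connectivity"),
                               n_per_period = 8000L, n_periods = 20) {
  stopifnot(inherits(profile, "temperature_profile"),
            inherits(scaling, "scaling_params"))
  quantity <- match.arg(quantity)
  if (n_per_period < 100L)
    stop("n_per_period must be at least 100", call. = FALSE)
  if (n_periods < 20)
    warning("fewer than 20 cycles per development: phase dependence may ",
            "not have averaged out", call. = FALSE)
  pm <- profile_rate_means(profile, c(scaling$alpha, scaling$gamma),
                           n_per_period = n_per_period)
  pm2 <- profile_rate_means(profile, c(scaling$alpha, scaling$gamma),
                            n_per_period = 2L * n_per_period)
  rel <- abs(pm$means - pm2$means) / abs(pm2$means)
  if (any(rel > 1e-6))
    warning(sprintf(
      "quadrature not converged (relative change %.2e on doubling)",
      max(rel)), call. = FALSE)
  tbar <- pm2$mean_temp
  time_fold <- exp(scaling$alpha * tbar) / pm2$means[1L]
  if (quantity == "time") return(time_fold)
  (time_fold * pm2$means[2L] / exp(scaling$gamma * tbar))^4
}

#' Temperature-cycle predictions for a set of amplitudes
#'
#' Convenience table of the step-cycle predictions across half-amplitudes,
#' e.g. the four experimental regimes 20-28, 18-30, 16-32, 14-34 C
#' (half-amplitudes 4, 6, 8, 10 about a 24 C mean).
#'
#' @param scaling [scaling_params()].
#' @param half_amplitudes Numeric vector of \eqn{\Delta T} values.
#' @return Data frame with columns `half_amplitude`, `time_fold`,
#'   `connectivity_fold`.
#' @export
cycle_prediction_table <- function(scaling, half_amplitudes = c(4, 6, 8, 10)) {
  data.frame(
    half_amplitude = half_amplitudes,
    time_fold = step_cycle_time_fold(scaling, half_amplitudes),
    connectivity_fold = step_cycle_connectivity_fold(scaling,
                                                     half_amplitudes))
}

#' Read a periodic profile from CSV
#'
#' Expects columns `phase_hours` and `temp_c`; the period may be given as an
#' argument or defaults to 24 h.
#'
#' @param path CSV path.
#' @param period Period, hours.
#' @return A [temperature_profile()].
#' @export
read_profile_csv <- function(path, period = 24) {
  df <- utils::read.csv(path)
  need <- c("phase_hours", "temp_c")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("profile CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  temperature_profile(df$phase_hours, df$temp_c, period = period)
}
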