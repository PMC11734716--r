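#' Construct a trajectory set
#'
#' Positions of freely walking flies in a circular arena at a fixed frame
#' rate, with the arena geometry and odor-source position attached.
#'
#' @param flies Data frame with columns `fly`, `t_s`, `x_cm`, `y_cm`; time
#'   strictly increasing within each fly.
#' @param arena_radius Arena radius, cm (default 20.1, a 40.2-cm diameter
#'   arena).
#' @param source Numeric length-2 odor-source position, cm.
#' @param frame_rate Frames per second.
#' @param tol Allowed excursion beyond the wall, cm (tracking slack).
#' @return An object of class `trajectory_set`.
#' @export
trajectory_set <- function(flies, arena_radius = 20.1, source = c(10, 0),
                           frame_rate = 20, tol = 0.5) {
  need <- c("fly", "t_s", "x_cm", "y_cm")
  miss <- setdiff(need, names(flies))
  if (length(miss))
    stop("trajectories missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  stopifnot(arena_radius > 0, length(source) == 2L, frame_rate > 0)
  if (sqrt(sum(source^2)) >= arena_radius)
    stop("odor source must lie inside the arena", call. = FALSE)
  r <- sqrt(flies$x_cm^2 + flies$y_cm^2)
  if (any(r > arena_radius + tol))
    stop("positions outside the arena (radius ", arena_radius, " cm)",
         call. = FALSE)
  bad <- vapply(split(flies$t_s, flies$fly),
                function(t) any(diff(t) <= 0), logical(1))
  if (any(bad))
    stop("time must be strictly increasing within each fly", call. = FALSE)
  structure(list(flies = flies, arena_radius = arena_radius,
                 source = source, frame_rate = frame_rate),
            class = "trajectory_set")
}

#' Read trajectories from CSV with a YAML header
#'
#' The CSV holds columns `fly`, `t_s`, `x_cm`, `y_cm`; arena geometry may
#' come from a YAML sidecar (fields `arena_radius`, `source_x`, `source_y`,
#' `frame_rate`) or from the arguments.
#'
#' @param path Trajectory CSV.
#' @param meta Optional YAML path with the arena metadata.
#' @inheritParams trajectory_set
#' @return A [trajectory_set()].
#' @export
read_trajectory_csv <- function(path, meta = NULL, arena_radius = 20.1,
                                source = c(10, 0), frame_rate = 20) {
  df <- utils::read.csv(path)
  if (!is.null(meta)) {
    m <- yaml::read_yaml(meta)
    arena_radius <- m$arena_radius %||% arena_radius
    source <- c(m$source_x %||% source[1L], m$source_y %||% source[2L])
    frame_rate <- m$frame_rate %||% frame_rate
  }
  trajectory_set(df, arena_radius = arena_radius, source = source,
                 frame_rate = frame_rate)
}

#' Odor-evoked change in walking speed on a spherical treadmill
#'
#' For each stimulus presentation, the basal speed is the mean over the
#' `basal_window` seconds before onset and the response is the mean change
#' (speed minus basal) over the first `response_window` seconds of
#' stimulation. Flies whose session-average basal speed is below
#' `min_basal` are flagged and excluded from the per-fly summary (a fly
#' that is not walking cannot show a speed increase). Trials whose windows
#' extend past the recorded series are skipped with a warning.
#'
#' @param speeds List of per-fly numeric speed series, mm/s, sampled at
#'   `frame_rate` (or a single numeric vector for one fly).
#' @param onsets Stimulus onset times, seconds, sorted.
#' @param frame_rate Frames per second.
#' @param basal_window Seconds before onset used for the basal speed.
#' @param response_window Seconds after onset used for the response.
#' @param min_basal Exclusion threshold on the session-average basal speed,
#'   mm/s.
#' @return List with `trials` (data frame `fly`, `trial`, `basal`,
#'   `delta_speed`) and `per_fly` (data frame `fly`, `mean_basal`,
#'   `mean_delta`, `excluded`).
#' @export
treadmill_response <- function(speeds, onsets, frame_rate = 20,
                               basal_window = 3, response_window = 2,
                               min_basal = 2) {
  if (is.numeric(speeds)) speeds <- list(speeds)
  stopifnot(length(onsets) >= 1L, !is.unsorted(onsets))
  trials <- do.call(rbind, lapply(seq_along(speeds), function(f) {
    v <- speeds[[f]]
    n <- length(v)
    rows <- lapply(seq_along(onsets), function(k) {
      i_on <- round(onsets[k] * frame_rate) + 1L
      i0 <- i_on - round(basal_window * frame_rate)
      i1 <- i_on + round(response_window * frame_rate) - 1L
      if (i0 < 1L || i1 > n) {
        warning("trial ", k, " of fly ", f,
                " extends past the recorded series; skipped", call. = FALSE)
        return(NULL)
      }
      basal <- mean(v[i0:(i_on - 1L)])
      data.frame(fly = f, trial = k, basal = basal,
                 delta_speed = mean(v[i_on:i1]) - basal)
    })
    do.call(rbind, rows)
  }))
  per_fly <- do.call(rbind, lapply(split(trials, trials$fly), function(d) {
    mb <- mean(d$basal)
    data.frame(fly = d$fly[1L], mean_basal = mb,
               mean_delta = mean(d$delta_speed),
               excluded = mb < min_basal)
  }))
  per_fly$mean_delta[per_fly$excluded] <- NA_real_
  rownames(per_fly) <- NULL
  list(trials = trials, per_fly = per_fly)
}

#' Fraction of flies near the odor source over time
#'
#' Per frame, the fraction of flies whose distance to the source is at most
#' `threshold` (5 cm operationalises "has located the odor source").
#' Trajectories are aligned on their common frame grid.
#'
#' @param trajs A [trajectory_set()].
#' @param threshold Distance threshold, cm.
#' @return Data frame with columns `t_s` and `fraction` in `[0, 1]`; empty
#'   when the set contains no flies.
#' @export
at_source_fraction <- function(trajs, threshold = 5) {
  stopifnot(inherits(trajs, "trajectory_set"), threshold >= 0)
  df <- trajs$flies
  if (nrow(df) == 0L)
    return(data.frame(t_s = numeric(), fraction = numeric()))
  d <- sqrt((df$x_cm - trajs$source[1L])^2 +
            (df$y_cm - trajs$source[2L])^2)
  near <- d <= threshold
  agg <- stats::aggregate(list(fraction = near),
                          by = list(t_s = round(df$t_s, 6)), FUN = mean)
  agg[order(agg$t_s), ]
}

#' Odor occupancy over the first minutes of the assay
#'
#' Time-normalised integral (trapezoid rule) of [at_source_fraction()] over
#' the first `window` seconds: 1 if all flies spend all of that time within
#' the source threshold, 0 if none ever do.
#'
#' @param trajs A [trajectory_set()].
#' @param threshold Distance threshold, cm.
#' @param window Integration window, seconds (default 420 s = 7 min).
#' @return Scalar in `[0, 1]`.
#' @export
odor_occupancy <- function(trajs, threshold = 5, window = 420) {
  stopifnot(inherits(trajs, "trajectory_set"), window > 0)
  frac <- at_source_fraction(trajs, threshold = threshold)
  if (nrow(frac) == 0L || max(frac$t_s) < window)
    stop("recording shorter than the ", window,
         "-s occupancy window (have ",
         if (nrow(frac)) max(frac$t_s) else 0, " s)", call. = FALSE)
  keep <- frac$t_s <= window
  t <- frac$t_s[keep]
  y <- frac$fraction[keep]
  # close the window end by linear interpolation if no frame lands on it
  if (max(t) < window) {
    y_end <- stats::approx(frac$t_s, frac$fraction, xout = window)$y
    t <- c(t, window)
    y <- c(y, y_end)
  }
  sum(diff(t) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2) /
    (window - t[1L])
}

#' Walking speeds from trajectory positions
#'
#' Central-difference speed at the native frame rate, mm/s.
#'
#' @param trajs A [trajectory_set()].
#' @return Numeric vector of speeds pooled over flies and time.
#' @export
trajectory_speeds <- function(trajs) {
  stopifnot(inherits(trajs, "trajectory_set"))
  unlist(lapply(split(trajs$flies, trajs$flies$fly), function(d) {
    n <- nrow(d)
    if (n < 3L) return(numeric())
    dx <- d$x_cm[3:n] - d$x_cm[1:(n - 2L)]
    dy <- d$y_cm[3:n] - d$y_cm[1:(n - 2L)]
    dt <- d$t_s[3:n] - d$t_s[1:(n - 2L)]
    10 * sqrt(dx^2 + dy^2) / dt            # cm -> mm
  }), use.names = FALSE)
}

#' Decompose the walking-speed distribution into inactive and active modes
#'
#' Walking speed pooled over flies and time is bimodal: a peak at zero
#' (inactive flies) and an active mode. This computes the binned speed
#' distribution, the zero-peak mass (samples below `active_cut`), and fits
#' a single Gaussian \eqn{a\, e^{-((x-b)/c)^2}} to the binned probabilities
#' of the active mode: `a` estimates the activity level, `b` the mean
#' active walking speed (mm/s). Confidence intervals come from the fit's
#' parameter covariance.
#'
#' @param speeds Numeric vector of speeds, mm/s (>= 1000 samples
#'   recommended).
#' @param active_cut Speeds below this (mm/s) count as the zero peak and
#'   are excluded from the Gaussian fit.
#' @param bin_width Histogram bin width, mm/s.
#' @return List with `distribution` (data frame `speed`, `probability`),
#'   `zero_peak_mass`, and `fit` (data frame with rows `a`, `b`, `c` and
#'   columns `estimate`, `ci_low`, `ci_high`).
#' @export
fit_speed_modes <- function(speeds, active_cut = 1, bin_width = 1) {
  stopifnot(is.numeric(speeds), length(speeds) > 0, all(is.finite(speeds)),
            all(speeds >= 0))
  zero_mass <- mean(speeds < active_cut)
  breaks <- seq(0, max(speeds, active_cut) + bin_width, by = bin_width)
  h <- graphics::hist(speeds, breaks = breaks, plot = FALSE)
  dist <- data.frame(speed = h$mids,
                     probability = h$counts / sum(h$counts))
  active <- dist[dist$speed >= active_cut & dist$probability > 0, ]
  if (nrow(active) < 4L || stats::sd(speeds[speeds >= active_cut]) == 0)
    stop("active-speed mode is degenerate (", nrow(active),
         " informative bins): cannot fit a Gaussian", call. = FALSE)
  start <- list(a = max(active$probability),
                b = stats::weighted.mean(active$speed, active$probability),
                c = max(bin_width,
                        sqrt(2) * stats::sd(speeds[speeds >= active_cut])))
  fit <- tryCatch(
    minpack.lm::nlsLM(probability ~ a * exp(-((speed - b) / c)^2),
                      data = active, start = start,
                      lower = c(a = 0, b = 0, c = 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("Gaussian fit to the active mode failed: ",
           conditionMessage(e), call. = FALSE))
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  ci <- cbind(est - stats::qnorm(0.975) * se,
              est + stats::qnorm(0.975) * se)
  list(distribution = dist,
       zero_peak_mass = zero_mass,
       fit = data.frame(parameter = c("a", "b", "c"),
                        estimate = unname(est),
                        ci_low = unname(ci[, 1L]),
                        ci_high = unname(ci[, 2L])))
}
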