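#' Configuration for the synthetic fold-change generators
#'
#' Describes the simulated study: the exponential scaling laws, the absolute
#' scales at the reference temperature, the noise model, and the sampling
#' design. Defaults emulate the fixed-temperature experiments: rearing
#' temperatures 12, 18, 25 and 31 C with about 30 individuals each,
#' scaling factors 0.128 (time) and 0.133 (connectivity) per degree C,
#' negative-binomial partner counts and lognormal developmental times.
#' The absolute scales `n0` (20 partners) and `t0` (10 days) are free
#' placeholders, not measured values.
#'
#' @param seed Integer seed; identical configs generate identical data.
#' @param alpha,beta Generating scaling factors, per degree C.
#' @param ref_temp Reference temperature `T0`, degrees C.
#' @param n0 Mean partner count at `ref_temp`.
#' @param t0 Developmental time at `ref_temp` (days).
#' @param dispersion Negative-binomial size parameter for counts (larger is
#'   closer to Poisson; `Inf` gives exactly Poisson noise).
#' @param cv Lognormal coefficient of variation for developmental times
#'   (0 gives noise-free law values).
#' @param design List with `temperatures` (degrees C, including `ref_temp`)
#'   and `n_per_temp` (single number or one per temperature).
#' @return An object of class `generator_config`.
#' @examples
#' cfg <- generator_config(seed = 42)
#' head(gen_partner_counts(cfg)$records)
#' @export
generator_config <- function(seed = 20250115L, alpha = 0.128, beta = 0.133,
                             ref_temp = 25, n0 = 20, t0 = 10,
                             dispersion = 15, cv = 0.08,
                             design = list(
                               temperatures = c(12, 18, 25, 31),
                               n_per_temp = 30L)) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            n0 > 0, t0 > 0, dispersion > 0, cv >= 0,
            is.list(design), !is.null(design$temperatures),
            !is.null(design$n_per_temp))
  n_per <- design$n_per_temp
  if (length(n_per) == 1L)
    n_per <- rep(n_per, length(design$temperatures))
  stopifnot(length(n_per) == length(design$temperatures), all(n_per >= 1))
  if (!any(abs(design$temperatures - ref_temp) < 1e-9))
    stop("design temperatures must include ref_temp", call. = FALSE)
  structure(list(seed = as.integer(seed), alpha = alpha, beta = beta,
                 ref_temp = ref_temp, n0 = n0, t0 = t0,
                 dispersion = dispersion, cv = cv,
                 temperatures = design$temperatures,
                 n_per_temp = n_per),
            class = "generator_config")
}

#' Simulate per-individual synaptic-partner counts across temperatures
#'
#' Counts are drawn from a negative binomial with mean
#' \eqn{n_0 e^{-\beta (T - T_0)}} and size `dispersion` (overdispersed
#' counts of labeled cells across hemibrains; `dispersion = Inf` gives
#' Poisson noise). The output is a [fold_change_dataset()] of kind
#' `"partners"`.
#'
#' @param config A [generator_config()].
#' @return A [fold_change_dataset()].
#' @export
gen_partner_counts <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, {
    rec <- do.call(rbind, lapply(seq_along(config$temperatures), function(i) {
      temp <- config$temperatures[i]
      n <- config$n_per_temp[i]
      mu <- config$n0 * exp(-config$beta * (temp - config$ref_temp))
      counts <- if (is.infinite(config$dispersion)) {
        stats::rpois(n, lambda = mu)
      } else {
        stats::rnbinom(n, size = config$dispersion, mu = mu)
      }
      data.frame(temperature_c = temp,
                 individual = sprintf("T%g_i%03d", temp, seq_len(n)),
                 value = counts, condition = "synthetic")
    }))
    fold_change_dataset(rec, ref_temp = config$ref_temp,
                        value_kind = "partners")
  })
}

#' Simulate per-individual developmental times across temperatures
#'
#' Times are lognormal with mean \eqn{t_0 e^{-\alpha (T - T_0)}} and
#' coefficient of variation `cv` (`cv = 0` returns the law values exactly).
#'
#' @param config A [generator_config()].
#' @return A [fold_change_dataset()] of kind `"devtime"`.
#' @export
gen_devtimes <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, {
    sdlog <- sqrt(log(1 + config$cv^2))
    rec <- do.call(rbind, lapply(seq_along(config$temperatures), function(i) {
      temp <- config$temperatures[i]
      n <- config$n_per_temp[i]
      mu <- config$t0 * exp(-config$alpha * (temp - config$ref_temp))
      times <- if (config$cv == 0) rep(mu, n) else
        stats::rlnorm(n, meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
      data.frame(temperature_c = temp,
                 individual = sprintf("T%g_i%03d", temp, seq_len(n)),
                 value = times, condition = "synthetic")
    }))
    fold_change_dataset(rec, ref_temp = config$ref_temp,
                        value_kind = "devtime")
  })
}

#' Simulate a synapse table with planted partner structure
#'
#' Builds a synapse table (one row per synapse) from an explicit
#' specification of per-partner, per-presynaptic-neuron synapse counts, with
#' glomeruli planted as 3D Gaussian blobs whose centres are separated by a
#' configurable number of within-blob spreads. Running the planted table
#' through [allocate_partners()] with filters disabled reproduces the
#' specification exactly.
#'
#' @param partner_spec Data frame with columns `glomerulus` (integer or
#'   label), `pre_id`, `pre_type`, `post_id`, `n_synapses`, and optionally
#'   `post_class` (`uPN`, `mPN`, `LN`, `other`).
#' @param spread Within-glomerulus coordinate standard deviation (same
#'   units as the coordinates).
#' @param separation Distance between glomerulus centres in units of
#'   `spread`.
#' @param seed Integer seed.
#' @return A data frame of class `synapse_table` with columns `pre_id`,
#'   `pre_type`, `post_id`, `x`, `y`, `z`, `post_class`, and the planted
#'   `glomerulus` label (ground truth for clustering checks).
#' @export
gen_synapse_table <- function(partner_spec, spread = 1, separation = 8,
                              seed = 20250115L) {
  need <- c("glomerulus", "pre_id", "pre_type", "post_id", "n_synapses")
  miss <- setdiff(need, names(partner_spec))
  if (length(miss))
    stop("partner_spec missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"post_class" %in% names(partner_spec))
    partner_spec$post_class <- "other"
  stopifnot(all(partner_spec$n_synapses >= 1), spread >= 0, separation >= 0)
  gloms <- unique(partner_spec$glomerulus)
  # centres on a widely spaced 3D diagonal lattice
  centres <- cbind(x = seq_along(gloms), y = 2 * seq_along(gloms),
                   z = -seq_along(gloms)) * separation * max(spread, 1e-12)
  rownames(centres) <- as.character(gloms)
  withr::with_seed(seed, {
    rows <- lapply(seq_len(nrow(partner_spec)), function(i) {
      sp <- partner_spec[i, ]
      k <- sp$n_synapses
      ctr <- centres[as.character(sp$glomerulus), ]
      data.frame(pre_id = sp$pre_id, pre_type = sp$pre_type,
                 post_id = sp$post_id,
                 x = ctr[1L] + stats::rnorm(k, sd = spread),
                 y = ctr[2L] + stats::rnorm(k, sd = spread),
                 z = ctr[3L] + stats::rnorm(k, sd = spread),
                 post_class = sp$post_class,
                 glomerulus = sp$glomerulus)
    })
    tab <- do.call(rbind, rows)
    class(tab) <- c("synapse_table", "data.frame")
    tab
  })
}

#' Simulate free-walking arena trajectories
#'
#' Generates stop-and-go biased random walks in a circular arena: each fly
#' alternates between an inactive state (speed 0) and an active state with
#' Gaussian-distributed speed, switching with fixed per-second rates; while
#' active the heading persists with angular noise and is biased toward the
#' odor source with weight `attraction`; flies reflect off the arena wall.
#' With `attraction = 0` the long-run occupancy of the 5-cm source disc
#' approaches its area fraction of the arena.
#'
#' @param n_flies Number of flies.
#' @param arena_radius Arena radius, cm.
#' @param source Numeric length-2 source position (cm), inside the arena.
#' @param attraction Drift weight toward the source in `[0, 1]` (0 =
#'   unbiased walk; near 1 = heading locked onto the source).
#' @param stop_rate,go_rate Per-second switching rates active->inactive and
#'   inactive->active.
#' @param speed_mean,speed_sd Active-speed Gaussian, mm/s.
#' @param duration_s Recording length, seconds.
#' @param frame_rate Frames per second.
#' @param heading_sd Angular noise per step, radians.
#' @param start_at_source Start all flies at the source (otherwise uniform
#'   over the arena).
#' @param seed Integer seed.
#' @return An object of class `trajectory_set`: list with `flies` (data
#'   frame `fly`, `t_s`, `x_cm`, `y_cm`), `arena_radius`, `source`,
#'   `frame_rate`.
#' @export
gen_trajectories <- function(n_flies = 10L, arena_radius = 20.1,
                             source = c(10, 0), attraction = 0.3,
                             stop_rate = 0.2, go_rate = 0.3,
                             speed_mean = 8, speed_sd = 3,
                             duration_s = 900, frame_rate = 20,
                             heading_sd = 0.4,
                             start_at_source = FALSE,
                             seed = 20250115L) {
  stopifnot(n_flies >= 1L, arena_radius > 0, length(source) == 2L,
            sqrt(sum(source^2)) < arena_radius,
            attraction >= 0, attraction <= 1,
            stop_rate >= 0, go_rate >= 0, speed_mean > 0, speed_sd >= 0,
            duration_s > 0, frame_rate > 0)
  dt <- 1 / frame_rate
  n_frames <- floor(duration_s * frame_rate) + 1L
  p_stop <- 1 - exp(-stop_rate * dt)
  p_go <- 1 - exp(-go_rate * dt)
  withr::with_seed(seed, {
    flies <- lapply(seq_len(n_flies), function(f) {
      if (start_at_source) {
        pos <- source
      } else {
        repeat {
          pos <- stats::runif(2, -arena_radius, arena_radius)
          if (sum(pos^2) < arena_radius^2) break
        }
      }
      heading <- stats::runif(1, 0, 2 * pi)
      active <- stats::runif(1) < go_rate / max(go_rate + stop_rate, 1e-12)
      xy <- matrix(0, n_frames, 2L)
      xy[1L, ] <- pos
      for (i in seq_len(n_frames - 1L)) {
        active <- if (active) stats::runif(1) >= p_stop
                  else stats::runif(1) < p_go
        if (active) {
          to_src <- atan2(source[2L] - pos[2L], source[1L] - pos[1L])
          # circular mixture: rotate heading toward the source, then jitter
          dhead <- atan2(sin(to_src - heading), cos(to_src - heading))
          heading <- heading + attraction * dhead +
            stats::rnorm(1, sd = heading_sd)
          sp <- max(0, stats::rnorm(1, speed_mean, speed_sd)) / 10  # cm/s
          cand <- pos + sp * dt * c(cos(heading), sin(heading))
          r <- sqrt(sum(cand^2))
          if (r > arena_radius) {       # reflect across the wall tangent
            cand <- cand * (2 * arena_radius - r) / r
            heading <- atan2(cand[2L] - pos[2L], cand[1L] - pos[1L])
          }
          pos <- cand
        }
        xy[i + 1L, ] <- pos
      }
      data.frame(fly = f, t_s = (seq_len(n_frames) - 1L) * dt,
                 x_cm = xy[, 1L], y_cm = xy[, 2L])
    })
    trajectory_set(do.call(rbind, flies), arena_radius = arena_radius,
                   source = source, frame_rate = frame_rate)
  })
}

#' Write a fold-change dataset to CSV
#'
#' Columns `temperature_c`, `individual`, `value`, `kind`, `condition`,
#' matching [read_fold_change_csv()].
#'
#' @param data A [fold_change_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fold_change_csv <- function(data, path) {
  stopifnot(inherits(data, "fold_change_dataset"))
  out <- data$records
  out$kind <- data$value_kind
  out <- out[, c("temperature_c", "individual", "value", "kind", "condition")]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
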