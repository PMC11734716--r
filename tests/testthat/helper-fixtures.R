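# Fixtures shared across test files; everything is built in code.

# Printed scaling factors of the fixed-temperature experiments.
ref_scaling <- function() scaling_params(alpha = 0.128, beta = 0.133)

# Hand-built toy synapse table: one glomerulus, one ORN type, two ORNs
# (A, B) and three postsynaptic partners with per-connection counts
# A->P1: 12, B->P1: 2, A->P2: 5, B->P2: 6, A->P3: 4.
toy_synapse_table <- function() {
  counts <- c(12L, 2L, 5L, 6L, 4L)
  pre <- rep(c("A", "B", "A", "B", "A"), counts)
  post <- rep(c("P1", "P1", "P2", "P2", "P3"), counts)
  synapse_table(data.frame(
    pre_id = pre, pre_type = "ORNa", post_id = post,
    x = seq_along(pre), y = 0, z = 0))
}

# Matching generator specification for gen_synapse_table.
toy_partner_spec <- function() {
  data.frame(glomerulus = 1L,
             pre_id = c("A", "B", "A", "B", "A"),
             pre_type = "ORNa",
             post_id = c("P1", "P1", "P2", "P2", "P3"),
             n_synapses = c(12L, 2L, 5L, 6L, 4L),
             post_class = c("uPN", "uPN", "mPN", "mPN", "LN"))
}

# Stop-and-go speed mixture sampled directly (not via trajectories):
# a fraction of exact zeros plus active speeds with density
# proportional to exp(-((x - b)/c)^2), truncated at zero.
speed_mixture <- function(n, active_frac = 0.4, b = 8, c = 3, seed = 1) {
  withr::with_seed(seed, {
    n_active <- rbinom(1, n, active_frac)
    active <- rnorm(n_active, mean = b, sd = c / sqrt(2))
    active <- active[active > 0]
    sample(c(rep(0, n - n_active), active))
  })
}

# Expected Gaussian amplitude of the binned probability for speed_mixture.
mixture_amplitude <- function(active_frac = 0.4, c = 3, bin_width = 1) {
  active_frac * bin_width / (c * sqrt(pi))
}

# Trajectory set with all flies parked at fixed positions.
parked_trajectories <- function(positions, duration_s = 450,
                                frame_rate = 20, source = c(10, 0),
                                arena_radius = 20.1) {
  t_s <- seq(0, duration_s, by = 1 / frame_rate)
  flies <- do.call(rbind, lapply(seq_len(nrow(positions)), function(f)
    data.frame(fly = f, t_s = t_s,
               x_cm = positions[f, 1L], y_cm = positions[f, 2L])))
  trajectory_set(flies, arena_radius = arena_radius, source = source,
                 frame_rate = frame_rate)
}

# Best-permutation agreement between two flat cluster labelings.
label_agreement <- function(truth, labels) {
  truth <- as.integer(factor(truth))
  labels <- as.integer(factor(labels))
  k <- max(labels)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- 0
  for (p in perms(seq_len(k)))
    best <- max(best, mean(p[labels] == truth))
  best
}
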