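#!/usr/bin/env Rscript
# Simulate the study's inputs: per-hemibrain synaptic-partner counts and
# developmental times across rearing temperatures (12-31 C), a synapse
# table with planted glomeruli, and free-walking arena trajectories.
# Outputs land under results/.

suppressPackageStartupMessages(library(thermowire))
dir.create("results", showWarnings = FALSE)
seed <- 20250115L

cfg <- generator_config(
  seed = seed, alpha = 0.128, beta = 0.133, ref_temp = 25,
  n0 = 20, t0 = 10,
  design = list(temperatures = c(12, 18, 25, 31),
                n_per_temp = c(20L, 38L, 31L, 24L)))

partners <- gen_partner_counts(cfg)
write_fold_change_csv(partners, "results/partner_counts.csv")
devtimes <- gen_devtimes(cfg)
write_fold_change_csv(devtimes, "results/devtimes.csv")
cat("Simulated", nrow(partners$records), "partner counts and",
    nrow(devtimes$records), "developmental times across",
    length(cfg$temperatures), "temperatures.\n")

# Synapse table: three glomeruli, each innervated by a few ORNs converging
# onto a handful of partners of mixed classes.
spec <- do.call(rbind, lapply(1:3, function(g) {
  partners_g <- data.frame(
    post_id = sprintf("G%d_P%d", g, 1:6),
    post_class = c("uPN", "uPN", "mPN", "mPN", "LN", "other"),
    base = c(40L, 25L, 12L, 8L, 5L, 2L))
  do.call(rbind, lapply(1:3, function(orn)
    data.frame(glomerulus = g, pre_id = sprintf("G%d_orn%d", g, orn),
               pre_type = sprintf("ORN_type%d", g),
               post_id = partners_g$post_id,
               n_synapses = pmax(1L, partners_g$base - 3L * (orn - 1L)),
               post_class = partners_g$post_class)))
}))
syn <- gen_synapse_table(spec, spread = 1, separation = 8, seed = seed)
utils::write.csv(as.data.frame(syn), "results/synapse_table.csv",
                 row.names = FALSE)
cat("Simulated synapse table:", nrow(syn), "synapses,",
    length(unique(syn$glomerulus)), "glomeruli.\n")

# Arena trajectories: odor-attracted flies emulating the two rearing
# conditions through different activity levels.
for (cond in list(list(tag = "18C", attraction = 0.30, stop_rate = 0.15),
                  list(tag = "25C", attraction = 0.12, stop_rate = 0.25))) {
  trajs <- gen_trajectories(
    n_flies = 20L, attraction = cond$attraction, stop_rate = cond$stop_rate,
    duration_s = 900, seed = seed + match(cond$tag, c("18C", "25C")))
  utils::write.csv(trajs$flies,
                   sprintf("results/trajectories_%s.csv", cond$tag),
                   row.names = FALSE)
  cat(sprintf("Simulated %d trajectories for the %s-reared condition.\n",
              20L, cond$tag))
}
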