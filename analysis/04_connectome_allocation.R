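#!/usr/bin/env Rscript
# Reduce the simulated synapse table: assign synapses to glomeruli by 3D
# clustering, allocate each ORN type's output onto partners with the
# per-connection (>= 3) and per-partner (>= 10) filters, estimate the
# labeling detection threshold, and tabulate partner classes.
# Requires results/ from 01_simulate.R.

suppressPackageStartupMessages(library(thermowire))
seed <- 20250115L

syn <- read_synapse_csv("results/synapse_table.csv")
labeled <- assign_glomerulus(syn, n_clusters = 3, seed = seed)
agree <- mean(vapply(split(labeled$glomerulus, labeled$cluster),
                     function(g) max(table(g)) / length(g), numeric(1)))
cat(sprintf("Clustered %d synapses into 3 glomeruli (purity %.3f).\n",
            nrow(labeled), agree))

allocs <- lapply(split(as.data.frame(labeled), labeled$cluster),
                 function(d) {
  d <- d[d$pre_type == names(sort(table(d$pre_type), decreasing = TRUE))[1], ]
  allocate_partners(synapse_table(d))
})
for (k in names(allocs)) {
  al <- allocs[[k]]
  cat(sprintf("Glomerulus cluster %s: %d retained partners, top fraction %.2f\n",
              k, nrow(al), if (nrow(al)) al$fraction[1] else NA))
  write_allocation_csv(al, sprintf("results/allocation_cluster%s.csv", k))
}

al1 <- allocs[[1]]
thr <- estimate_report_threshold(al1, observed_partner_count = 3)
cat(sprintf(
  "A labeling method reporting 3 partners implies a detection threshold of > %d synapses.\n",
  thr))

classes <- unique(as.data.frame(syn)[, c("post_id", "post_class")])
comp <- class_composition(al1, classes)
print(comp)
utils::write.csv(comp, "results/class_composition.csv", row.names = FALSE)

# left-right innervation symmetry of simulated paired volumes
withr::with_seed(seed, {
  vol_l <- rlnorm(12, log(300), 0.4)
  vol_r <- vol_l * rlnorm(12, 0, 0.3)
})
sym <- innervation_symmetry(vol_l, vol_r)
cat(sprintf("Symmetry index over 12 simulated hemisphere pairs: mean %.1f%%, range [%.1f, %.1f]\n",
            mean(sym), min(sym), max(sym)))
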