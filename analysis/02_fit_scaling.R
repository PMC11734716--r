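#!/usr/bin/env Rscript
# Fit the exponential scaling factors alpha (developmental time) and beta
# (synaptic connectivity) from the simulated fold-change datasets, with
# bootstrap uncertainty, and convert them to activation energies.
# Requires results/ from 01_simulate.R.

suppressPackageStartupMessages(library(thermowire))
seed <- 20250115L

partners <- read_fold_change_csv("results/partner_counts.csv")
devtimes <- read_fold_change_csv("results/devtimes.csv")

fit_beta <- fit_scaling_factor(partners, method = "nls", seed = seed)
fit_alpha <- fit_scaling_factor(devtimes, method = "nls", seed = seed)
cat("Connectivity scaling factor beta:\n"); print(fit_beta)
cat("Developmental-time scaling factor alpha:\n"); print(fit_alpha)

write_fit_json(fit_beta, "results/fit_beta.json")
write_fit_json(fit_alpha, "results/fit_alpha.json")

sc <- scaling_params(alpha = fit_alpha$estimate, beta = fit_beta$estimate)
en <- activation_energies(sc)
cat(sprintf(
  "Implied activation energies: E = %.3f eV (body), E' = %.3f eV (brain)\n",
  en$e, en$e_prime))
write_result_json(en, sc, "results/activation_energies.json")

# cross-check: the log-linear fit agrees within one bootstrap SE
ll <- fit_scaling_factor(partners, method = "loglinear", n_boot = 0)
cat(sprintf("Log-linear cross-check for beta: %.4f (nls %.4f, SE %.4f)\n",
            ll$estimate, fit_beta$estimate, fit_beta$stderr))
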