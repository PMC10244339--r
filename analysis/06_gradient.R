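#!/usr/bin/env Rscript

# Places the culture Fe' requirement in the context of the coastal-to-
# ocean dissolved-iron gradient: how far short does offshore Fe' fall?

suppressPackageStartupMessages(library(kelpfe))

gt <- load_gradient(kelpfe_example_gradient())
cat("Gradient compilation:", nrow(gt), "records,",
    sum(gt$environment == "coastal"), "coastal /",
    sum(gt$environment == "oceanic"), "oceanic.\n")
cat(sprintf("dFe spans %.3g nM (near shore) down to %.3g nM offshore.\n",
            max(gt$dfe_nM), min(gt$dfe_nM)))

required <- parse_conc("45.2nM")  # lowest Fe' with healthy replicates

oceanic <- gt[gt$environment == "oceanic", ]
fe_avail <- as.numeric(ocean_dfe_to_fe_prime(oceanic$dfe))
folds <- fold_limitation(required, fe_avail)
out <- data.frame(
  distance_km = oceanic$distance_km,
  dfe_nM = oceanic$dfe_nM,
  fe_prime_pM = fe_avail * 1e12,
  fold_short_of_requirement = folds
)
write.csv(out, "results/gradient.csv", row.names = FALSE)
print(out, digits = 3)

window <- fold_limitation(required, c(1.49e-12, 0.11e-12))
cat(sprintf(
  "\nAcross the typical oceanic Fe' window (0.11-1.49 pM), the kelp\n"))
cat(sprintf(
  "requirement of 45.2 nM sits %.0f- to %.0f-fold above supply -\n",
  window[1], window[2]))
cat("well beyond the thousandfold threshold: open-ocean dFe cannot\n")
cat("sustain kelp growth without fertilisation.\n")
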