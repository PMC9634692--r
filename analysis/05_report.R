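#!/usr/bin/env Rscript
# Fold-change report across the fitted conditions: aminoacyl vs native
# extension at 0 mM Mg2+, 2MeI vs 2AI ligation activation, aminoacyl vs
# native ligation, and duplex protection of the internal bridge.

suppressMessages(library(glykin))

ext <- read.csv("results/extension_rates.csv")
lig <- read.csv("results/ligation_rates.csv")
hl <- read.csv("results/half_lives.csv")

rates <- rbind(
  ext[, c("condition", "estimate", "sd")],
  lig[, c("condition", "estimate", "sd")],
  data.frame(condition = "lig_native_RNA",
             estimate = lig$k3[lig$condition == "lig_2MeI"], sd = NA))

folds <- report_folds(rates, list(
  c("gly_0mM", "rna_0mM"),
  c("lig_2MeI", "lig_2AI"),
  c("lig_2MeI", "lig_native_RNA")))
folds$claim <- c("aminoacyl vs native extension, 0 mM Mg2+",
                 "2MeI vs 2AI ligation activation",
                 "aminoacyl vs native RNA ligation")

protection <- hl$half_life_h[hl$condition == "internal_ds_2.5mM"] /
  hl$half_life_h[hl$condition == "internal_ss_2.5mM"]
folds <- rbind(folds,
               data.frame(numerator = "internal_ds_2.5mM",
                          denominator = "internal_ss_2.5mM",
                          fold = protection, fold_sd = NA,
                          claim = "duplex protection of the internal bridge"))

write.csv(folds, "results/fold_changes.csv", row.names = FALSE)
for (i in seq_len(nrow(folds))) {
  cat(sprintf("%-45s %8.2f-fold\n", folds$claim[i], folds$fold[i]))
}
cat("wrote results/fold_changes.csv\n")
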