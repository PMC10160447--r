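#!/usr/bin/env Rscript
# Stage 1: genetic analysis of the synthetic cross.
#
# Simulates the mapping populations at the study sizes (F2 of 623, BC1 of 71
# backcrossed to the green parent) under a single fully penetrant dominant
# yellow-peel locus, and tests the observed phenotype counts against the
# Mendelian 3:1 and 1:1 expectations.

library(bsaqtl)
dir.create("results", showWarnings = FALSE)
seed <- 1

map <- genetic_map(c("LG10", "LG01"), c(5e6, 5e6), c(40, 40))
locus <- causal_locus("LG10", 2.5e6)

f2 <- simulate_population("F2", 623, map, locus, seed = derive_seed(seed, 1))
bc1 <- simulate_population("BC1", 71, map, locus, seed = derive_seed(seed, 2))

tests <- list(F2 = chi_square_gof(sum(f2$phenotype == "yellow"),
                                  sum(f2$phenotype == "green"), c(3, 1)),
              BC1 = chi_square_gof(sum(bc1$phenotype == "yellow"),
                                   sum(bc1$phenotype == "green"), c(1, 1)))

tab <- do.call(rbind, lapply(names(tests), function(k) {
  t <- tests[[k]]
  data.frame(population = k, total = t$n_yellow + t$n_green,
             n_yellow = t$n_yellow, n_green = t$n_green,
             ratio = paste0(t$ratio[1], ":", t$ratio[2]),
             chi2 = round(t$chi2, 4), p = round(t$p, 4),
             verdict = t$verdict)
}))
write.table(tab, "results/segregation.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("Synthetic genetic analysis (seed", seed, ")\n")
for (k in names(tests)) print(tests[[k]])
cat("Both populations fit their Mendelian expectations:",
    all(tab$verdict == "fits"),
    "- consistent with a single dominant nuclear locus.\n")
cat("Written: results/segregation.tsv\n")
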