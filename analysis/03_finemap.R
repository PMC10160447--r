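#!/usr/bin/env Rscript
# Stage 3: fine mapping with co-dominant markers.
#
# Emulates the marker walk: a large screening population is genotyped at
# twelve co-dominant markers across the candidate chromosome (one marker
# sits inside the causal gene, as the final diagnostic marker did), the
# causal interval is narrowed from the recombinants' breakpoints, candidate
# gel-resolvable InDel markers are pulled from the variant set inside the
# interval, and the best marker is checked for phenotype concordance in a
# 37-accession panel.

library(bsaqtl)
dir.create("results", showWarnings = FALSE)
seed <- 1

pos <- round(seq(2e5, 4.8e6, length.out = 12))
causal <- pos[6]
map <- genetic_map("LG10", 5e6, 40)  # informative sites every 10 kb
locus <- causal_locus("LG10", causal)

# screening population (the study screened 1,132 plants with flanking markers)
pop <- simulate_population("F2", 1132, map, locus, seed = derive_seed(seed, 1))
calls <- population_marker_calls(pop, "LG10", pos)
tab <- recombinant_table(sprintf("Id%02d", seq_along(pos)), pos, calls,
                         pop$phenotype)
interval <- narrow_interval(tab, "F2")
print(interval)
cat("Interval length:", round(interval_length_kb(interval), 1), "kb;",
    "contains the causal position:",
    interval$start <= causal && causal <= interval$end, "\n")

# co-dominant InDel marker development in the primary candidate region
# (markers are developed from parental InDels before narrowing refines it)
bulks <- build_bulks(pop, 33, seed = derive_seed(seed, 2))
sites <- simulate_read_counts(bulks$freq,
                              seq_sim_params(seed = derive_seed(seed, 3)))
indels <- select_codominant_indels(sites, "LG10", 1e6, 4e6, min_size_diff = 3)
cat(nrow(indels), "gel-resolvable InDel marker candidate(s) in the primary",
    "region,", sum(indels$pos >= interval$start & indels$pos <= interval$end),
    "inside the final interval\n")

# diagnostic-marker concordance in a small natural panel: the marker at the
# causal position is genotyped in 37 accessions
panel <- simulate_population("F2", 37, map, locus, seed = derive_seed(seed, 4))
panel_calls <- population_marker_calls(panel, "LG10", causal)[, 1]
conc <- marker_concordance(panel_calls, panel$phenotype)
cat(sprintf("Diagnostic marker concordance in the panel: %d/%d (%.3f)\n",
            round(conc$concordance * conc$n_used), conc$n_used,
            conc$concordance))

out <- data.frame(start = interval$start, end = interval$end,
                  length_kb = interval_length_kb(interval),
                  left_marker = interval$left_marker,
                  right_marker = interval$right_marker,
                  n_indel_candidates = nrow(indels),
                  panel_concordance = conc$concordance)
write.table(out, "results/finemap_interval.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Written: results/finemap_interval.tsv\n")
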