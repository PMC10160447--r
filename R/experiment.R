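# Convenience wrapper for the study design point: an F2 BSA with 33+33
# bulks at ~30x pooled depth on a genome of 5 Mb chromosomes with one
# informative site per 10 kb and the dominant locus mid-chromosome.

#' Simulate a bulked-segregant experiment at the study design point
#'
#' Runs population simulation, bulk construction, pooled read-count
#' simulation and windowed SNP-index computation in one call. All
#' randomness derives from `seed` via [derive_seed()].
#'
#' @param seed Master integer seed.
#' @param map Genetic map (default: causal chromosome LG10 plus one neutral
#'   chromosome, 5 Mb / 40 cM each, one site per 10 kb).
#' @param locus Causal locus (default mid-LG10).
#' @param n_f2 F2 population size (default 623).
#' @param bulk_size Plants per bulk (default 33).
#' @param params Sequencing parameters; default [seq_sim_params()] (30x,
#'   0.5% error) with a derived seed.
#' @param wcfg Window configuration (default 1 Mb / 100 kb / 10 sites).
#' @return List with `population`, `bulks`, `sites`, `track`, `windows`.
#' @export
simulate_bsa_experiment <- function(seed,
                                    map = genetic_map(c("LG10", "LG01"),
                                                      c(5e6, 5e6), c(40, 40)),
                                    locus = causal_locus("LG10", 2.5e6),
                                    n_f2 = 623, bulk_size = 33,
                                    params = NULL,
                                    wcfg = window_config()) {
  if (is.null(params))
    params <- seq_sim_params(seed = derive_seed(seed, 3))
  pop <- simulate_population("F2", n_f2, map, locus,
                             seed = derive_seed(seed, 1))
  bulks <- build_bulks(pop, bulk_size, seed = derive_seed(seed, 2))
  sites <- simulate_read_counts(bulks$freq, params)
  track <- snp_index_table(sites)
  windows <- sliding_window_means(track, wcfg,
                                  stats::setNames(map$chrom$length_bp,
                                                  map$chrom$name))
  list(population = pop, bulks = bulks, sites = sites, track = track,
       windows = windows)
}

#' The window containing a position
#'
#' Among eligible windows overlapping `pos` on `chrom`, returns the one whose
#' midpoint is closest to `pos` (sliding windows overlap, so several contain
#' any given position).
#'
#' @param windows Output of [sliding_window_means()].
#' @param chrom Chromosome name.
#' @param pos Position in bp.
#' @return A single-row data frame.
#' @export
window_at <- function(windows, chrom, pos) {
  w <- windows[windows$chrom == chrom & windows$start <= pos &
                 windows$end >= pos & windows$eligible, , drop = FALSE]
  if (nrow(w) == 0L) stop("no eligible window contains ", chrom, ":", pos)
  w[which.min(abs((w$start + w$end) / 2 - pos)), , drop = FALSE]
}
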