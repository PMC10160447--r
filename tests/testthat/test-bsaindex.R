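# SNP-index arithmetic, sliding windows, region calling and null calibration.

test_that("snp_index and delta follow their definitions and bounds", {
  expect_equal(snp_index(7, 8), 0.875)
  expect_equal(snp_index(0, 20), 0)
  expect_true(is.na(snp_index(0, 0)))
  expect_error(snp_index(10, 0), "exceed")
  expect_error(snp_index(-1, 5), "non-negative")
  expect_equal(delta_snp_index(1.0, 1/3), 2/3, tolerance = 1e-12)
  x <- runif(50)
  expect_equal(delta_snp_index(x, x), rep(0, 50))
  expect_equal(delta_snp_index(0, 1), -1)
  expect_true(is.na(delta_snp_index(NA_real_, 0.5)))
  # bounds over a random fixture
  set.seed(31)
  tot <- rpois(500, 30)
  alt <- rbinom(500, tot, runif(500))
  i <- snp_index(alt, tot)
  expect_true(all(i >= 0 & i <= 1, na.rm = TRUE))
  expect_true(all(abs(delta_snp_index(i, rev(i))) <= 1, na.rm = TRUE))
})

test_that("window means equal brute-force recomputation", {
  expect_equal(mean(c(0.8, 0.9, 1.0)), 0.9)  # single-window arithmetic case
  set.seed(32)
  n <- 400
  track <- data.frame(chrom = "LG10", pos = sort(sample(1:3e6, n)),
                      index_G = runif(n), index_Y = runif(n))
  track$delta <- track$index_G - track$index_Y
  cfg <- window_config(5e5, 1e5, min_sites = 10)
  w <- sliding_window_means(track, cfg, chrom_lengths = c(LG10 = 3e6))
  for (k in seq_len(nrow(w))) {
    inside <- track$pos >= w$start[k] & track$pos < w$start[k] + cfg$window_size_bp
    expect_equal(w$n_sites[k], sum(inside))
    if (w$n_sites[k] > 0) {
      expect_equal(w$mean_index_G[k], mean(track$index_G[inside]),
                   tolerance = 1e-12)
      expect_equal(w$mean_delta[k], mean(track$delta[inside]),
                   tolerance = 1e-12)
    }
  }
  # windows with fewer than min_sites sites are flagged ineligible
  expect_identical(w$eligible, w$n_sites >= 10)
  # zero-depth (NA) sites are excluded, not imputed
  track2 <- track
  track2$index_G[1:50] <- NA
  w2 <- sliding_window_means(track2, cfg, chrom_lengths = c(LG10 = 3e6))
  expect_true(all(w2$n_sites <= w$n_sites))
  expect_error(sliding_window_means(track[order(track$index_G), ], cfg),
               "sorted")
})

test_that("region calling finds maximal runs under strict thresholds", {
  mk <- function(idx, delta, n = 50) {
    k <- length(idx)
    data.frame(chrom = "LG10", start = seq(1, by = 1e5, length.out = k),
               end = seq(1e6, by = 1e5, length.out = k), n_sites = n,
               mean_index_G = idx, mean_index_Y = idx - delta,
               mean_delta = delta, eligible = n >= 10)
  }
  # all below thresholds -> nothing
  expect_equal(nrow(call_candidate_regions(mk(rep(0.5, 10), rep(0, 10)))), 0)
  # exactly at threshold does not qualify (strict >)
  expect_equal(nrow(call_candidate_regions(mk(rep(0.9, 5), rep(0.5, 5)))), 0)
  expect_equal(nrow(call_candidate_regions(mk(rep(0.875, 5), rep(0.6, 5)))), 0)
  # a qualifying block is called and spans its windows
  idx <- c(rep(0.5, 5), rep(0.95, 4), rep(0.5, 3))
  dlt <- c(rep(0.0, 5), rep(0.66, 4), rep(0.0, 3))
  r <- call_candidate_regions(mk(idx, dlt))
  expect_equal(nrow(r), 1)
  expect_equal(r$start, 1 + 5 * 1e5)
  expect_equal(r$end, 1e6 + 8 * 1e5)
  expect_equal(r$n_windows, 4L)
  # two runs separated by one failing window are not merged
  idx2 <- c(rep(0.95, 3), 0.5, rep(0.95, 3))
  dlt2 <- c(rep(0.6, 3), 0.0, rep(0.6, 3))
  expect_equal(nrow(call_candidate_regions(mk(idx2, dlt2))), 2)
  # runs shorter than min_consecutive_windows are dropped
  expect_equal(nrow(call_candidate_regions(
    mk(idx2, dlt2), region_call_config(min_consecutive_windows = 4))), 0)
  # ineligible windows cannot qualify
  w <- mk(rep(0.95, 5), rep(0.6, 5), n = 5)
  expect_equal(nrow(call_candidate_regions(w)), 0)
})

test_that("a simulated distal high block is recovered by a brute-force scan", {
  # construct an LG10-like track: distal third linked (index_G ~ 0.97,
  # delta ~ 0.65), rest at the null
  set.seed(33)
  pos <- seq(1e4, 5e6, by = 1e4)
  linked <- pos > 3.3e6
  index_G <- ifelse(linked, rbeta(length(pos), 40, 1.5), rbeta(length(pos), 15, 15))
  index_Y <- ifelse(linked, rbeta(length(pos), 10, 20), rbeta(length(pos), 15, 15))
  track <- data.frame(chrom = "LG10", pos = pos, index_G = index_G,
                      index_Y = index_Y, delta = index_G - index_Y)
  w <- sliding_window_means(track, window_config(), c(LG10 = 5e6))
  r <- call_candidate_regions(w)
  expect_equal(nrow(r), 1)
  expect_true(r$start <= 4e6 && r$end >= 4.5e6)  # contains the high block
  # brute-force: every window fully inside the called region qualifies
  cfg <- region_call_config()
  inside <- w$start >= r$start & w$end <= r$end
  expect_true(all(w$mean_index_G[inside] > cfg$snp_index_threshold &
                    w$mean_delta[inside] > cfg$delta_threshold))
})

test_that("the null calibration holds at genuinely unlinked markers", {
  # 200 single-marker chromosomes unlinked to the causal one; 33+33 bulks,
  # depth 30x: mean per-site SNP-index ~ 0.5 and mean delta ~ 0
  map <- unlinked_marker_map(200)
  pop <- simulate_population("F2", 200, map, causal_locus("LG10", 2.5e6),
                             seed = 1)
  bulks <- build_bulks(pop, 33, seed = 1)
  sites <- simulate_read_counts(bulks$freq, seq_sim_params(seed = 1))
  track <- snp_index_table(sites)
  null_track <- track[track$chrom != "LG10", ]
  expect_equal(nrow(null_track), 200)
  expect_lt(abs(mean(c(null_track$index_G, null_track$index_Y),
                     na.rm = TRUE) - 0.5), 0.02)
  expect_lt(abs(mean(null_track$delta, na.rm = TRUE)), 0.02)
})
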