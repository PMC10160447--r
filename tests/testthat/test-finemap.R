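# Interval narrowing from recombinants, marker selection, concordance.

expect_matches_oracle <- function(tab, design) {
  res <- narrow_interval(tab, design)
  orc <- oracle_interval(tab, design)
  lo <- min(tab$positions_bp)
  expect_equal(res$start, if (orc[1] == lo) lo else orc[1] - 0.5)
  expect_equal(res$end, orc[2])
  invisible(res)
}

test_that("phenotypes map to the dominance-consistent genotype sets", {
  expect_identical(genotype_constraint("green", "F2"), "A")
  expect_identical(genotype_constraint("green", "BC1"), "A")
  expect_identical(genotype_constraint("yellow", "F2"), c("H", "B"))
  expect_identical(genotype_constraint("yellow", "BC1"), "H")
  expect_error(genotype_constraint("striped", "F2"), "unknown phenotype")
})

test_that("a single green recombinant places the locus past the breakpoint midpoint", {
  pos <- seq(100, 600, by = 100)
  calls <- matrix(c("H", "H", "H", "A", "A", "A"), nrow = 1)
  tab <- recombinant_table(paste0("M", 1:6), pos, calls, "green")
  res <- expect_matches_oracle(tab, "F2")
  expect_equal(res$start, 350)  # midpoint of M3 (300) and M4 (400)
  expect_equal(res$end, 600)
  expect_equal(res$left_marker, "M3")
  expect_equal(res$right_marker, "M6")
})

test_that("non-recombinant panels keep the full spanned region", {
  pos <- c(1000, 2000, 5000)
  calls <- rbind(rep("A", 3), rep("H", 3), rep("B", 3))
  tab <- recombinant_table(paste0("M", 1:3), pos, calls,
                           c("green", "yellow", "yellow"))
  res <- expect_matches_oracle(tab, "F2")
  expect_equal(c(res$start, res$end), c(1000, 5000))
})

test_that("opposing recombinants bracket the interior marker between their breakpoints", {
  pos <- seq(100, 900, by = 100)
  calls <- rbind(c("H", "H", "H", "H", "A", "A", "A", "A", "A"),
                 c("A", "A", "A", "A", "A", "H", "H", "H", "H"))
  tab <- recombinant_table(paste0("M", 1:9), pos, calls, c("green", "green"))
  res <- expect_matches_oracle(tab, "F2")
  expect_equal(res$start, 450)
  expect_equal(res$end, 550)
  expect_true(res$start < 500 && 500 < res$end)  # contains M5
  expect_equal(res$left_marker, "M4")
  expect_equal(res$right_marker, "M6")
})

test_that("missing calls are uninformative and yellow F2 constraints are {H,B}", {
  pos <- seq(100, 600, by = 100)
  # same recombinant as above but the discordant flank is masked: the
  # breakpoint midpoint moves to the nearest observed markers
  calls <- matrix(c("H", "H", NA, "A", "A", "A"), nrow = 1)
  tab <- recombinant_table(paste0("M", 1:6), pos, calls, "green")
  res <- expect_matches_oracle(tab, "F2")
  expect_equal(res$start, 300)  # midpoint of M2 (200) and M4 (400)
  # a yellow F2 individual excludes only its homozygous-green stretch
  calls2 <- rbind(c("H", "H", NA, "A", "A", "A"),
                  c("B", "B", "H", "H", "A", "A"))
  tab2 <- recombinant_table(paste0("M", 1:6), pos, calls2,
                            c("green", "yellow"))
  res2 <- expect_matches_oracle(tab2, "F2")
  expect_equal(res2$start, 300)
  expect_equal(res2$end, 450)  # yellow individual: A from mid(M4,M5) on
})

test_that("marker-bounded narrowing is conservative and keeps the true locus", {
  # the conservative mode extends each genotype stretch to the discordant
  # markers themselves: the single-recombinant interval starts at M3, not
  # at the M3/M4 midpoint
  pos <- seq(100, 600, by = 100)
  calls <- matrix(c("H", "H", "H", "A", "A", "A"), nrow = 1)
  tab <- recombinant_table(paste0("M", 1:6), pos, calls, "green")
  res <- narrow_interval(tab, "F2", boundary = "marker")
  expect_equal(c(res$start, res$end), c(300, 600))
  mid <- narrow_interval(tab, "F2")
  expect_lte(mid$end - mid$start, res$end - res$start)
  # at population scale, opposing recombinants in one marker interval make
  # midpoint constraints contradictory, while marker bounds stay consistent
  # and bracket the causal position in nearly every run
  pos <- round(seq(2e5, 4.8e6, length.out = 12))  # causal not at a marker
  fm_map <- genetic_map("LG10", 5e6, 40, marker_positions = list(LG10 = pos))
  contained <- vapply(1:10, function(s) {
    pop <- simulate_population("F2", 623, fm_map, causal_locus("LG10", 2.5e6),
                               seed = 100 + s)
    calls <- population_marker_calls(pop, "LG10", pos)
    tab <- recombinant_table(paste0("M", 1:12), pos, calls, pop$phenotype)
    tab <- suppressMessages(screen_recombinants(tab, "F2"))
    res <- suppressWarnings(narrow_interval(tab, "F2",
                                            drop_conflicting = TRUE,
                                            boundary = "marker"))
    res$start <= 2.5e6 && 2.5e6 <= res$end
  }, logical(1))
  expect_gte(sum(contained), 9)
})

test_that("adding individuals never widens the interval", {
  set.seed(41)
  pos <- seq(1000, 12000, by = 1000)
  map <- genetic_map("LG10", 2e4, 50,
                     marker_positions = list(LG10 = pos))
  locus <- causal_locus("LG10", 6000)
  pop <- simulate_population("F2", 60, map, locus, seed = 42)
  calls <- population_marker_calls(pop, "LG10", pos)
  widths <- vapply(c(5, 15, 30, 60), function(k) {
    tab <- recombinant_table(paste0("M", seq_along(pos)), pos,
                             calls[1:k, , drop = FALSE], pop$phenotype[1:k])
    res <- narrow_interval(tab, "F2")
    res$end - res$start
  }, numeric(1))
  expect_true(all(diff(widths) <= 0))
})

test_that("phenotype/genotype conflicts error or drop the offender on request", {
  pos <- seq(100, 400, by = 100)
  calls <- rbind(rep("A", 4),      # green, consistent
                 rep("H", 4))      # green but heterozygous everywhere
  tab <- recombinant_table(paste0("M", 1:4), pos, calls,
                           c("green", "green"))
  expect_error(narrow_interval(tab, "F2"),
               "phenotype/genotype inconsistency.*ind")
  expect_warning(res <- narrow_interval(tab, "F2", drop_conflicting = TRUE),
                 "dropping individual")
  expect_equal(c(res$start, res$end), c(100, 400))
})

test_that("interval length arithmetic matches the printed coordinates", {
  expect_equal(interval_length_kb(mapped_interval(8812267, 8983006)), 170.739)
  expect_equal(interval_length_kb(mapped_interval(5000, 6000)), 1)
  expect_equal(interval_length_kb(mapped_interval(1, 1000001)), 1000)
  expect_error(mapped_interval(10, 10), "smaller")
})

test_that("co-dominant InDel selection keeps gel-resolvable markers in the region", {
  sites <- data.frame(
    chrom = "LG10",
    pos = c(8820000L, 8850000L, 8900000L, 8950000L, 9100000L),
    ref = c("A", "T", "G", "ATT", "C"),
    alt = c(paste0("A", strrep("TG", 27), "T"),  # 55 bp insertion
            "TA",                                 # 1 bp InDel
            "C",                                  # SNP
            "A",                                  # 2 bp deletion
            paste0("C", strrep("A", 10))),        # outside region
    stringsAsFactors = FALSE)
  sites$type <- ifelse(nchar(sites$ref) != nchar(sites$alt), "InDel", "SNP")
  sel <- select_codominant_indels(sites, "LG10", 8812267, 8983006,
                                  min_size_diff = 3)
  expect_equal(sel$pos, 8820000L)
  expect_equal(sel$size_diff, 55)
  # region with no InDels -> empty
  expect_equal(nrow(select_codominant_indels(sites, "LG10", 8890000, 8910000)), 0)
})

test_that("marker concordance counts phenotype predictions correctly", {
  # perfectly linked marker in an F2-like panel
  calls <- c(rep("B", 9), rep("H", 19), rep("A", 9))
  phen <- c(rep("yellow", 28), rep("green", 9))
  expect_equal(marker_concordance(calls, phen)$concordance, 1.0)
  # one discordant of 37
  phen2 <- phen; phen2[1] <- "green"
  expect_equal(marker_concordance(calls, phen2)$concordance, 36 / 37)
  # independent marker in a 3:1 panel: expected concordance
  # 0.75 * 0.75 + 0.25 * 0.25 = 0.625
  set.seed(43)
  n <- 20000
  calls3 <- sample(c("A", "H", "B"), n, TRUE, prob = c(0.25, 0.5, 0.25))
  phen3 <- sample(c("yellow", "green"), n, TRUE, prob = c(0.75, 0.25))
  expect_lt(abs(marker_concordance(calls3, phen3)$concordance - 0.625), 0.02)
  # missing calls are excluded but counted
  res <- marker_concordance(c("A", NA, "B"), c("green", "green", "yellow"))
  expect_equal(res$n_used, 2)
  expect_equal(res$n_missing, 1)
  expect_error(marker_concordance(c(NA, NA), c("green", "green")), "missing")
})
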