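# Fixtures built in code: hand-written VCF text, hand-built site tables and
# a brute-force compatibility oracle for interval narrowing.

fixture_vcf_lines <- function(samples = c("parentG", "parentY", "G_pool", "Y_pool")) {
  c("##fileformat=VCFv4.2",
    "##contig=<ID=LG10>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

# 5 data rows, one of them multiallelic (row 3).
write_fixture_vcf <- function(path) {
  rows <- c(
    "LG10\t100\t.\tA\tG\t.\tPASS\t.\tGT:AD:DP\t1/1:0,20:20\t0/0:18,0:18\t1/1:1,19:20\t0/1:12,8:20",
    "LG10\t200\t.\tC\tT\t.\tPASS\t.\tGT:AD:DP\t1/1:0,22:22\t0/0:25,0:25\t1/1:0,30:30\t0/1:20,10:30",
    "LG10\t300\t.\tG\tA,T\t.\tPASS\t.\tGT:AD:DP\t1/1:0,10:10\t0/0:10,0:10\t0/1:5,5:10\t0/1:5,5:10",
    "LG10\t400\t.\tT\tTACG\t.\tPASS\t.\tGT:AD:DP\t1/1:0,15:15\t0/0:16,0:16\t1/1:2,14:16\t0/1:9,6:15",
    "LG10\t500\t.\tAC\tA\t.\tPASS\t.\tGT:AD:DP\t1/1:0,12:12\t0/0:14,0:14\t1/1:0,18:18\t0/1:11,7:18")
  writeLines(c(fixture_vcf_lines(), rows), path)
  path
}

# Hand-built variant_sites table: 10 sites, exactly 6 passing the default
# informative filter (parents opposite homozygotes, both bulks depth >= 8).
fixture_filter_sites <- function() {
  df <- data.frame(
    chrom = "LG10", pos = seq(1000, 10000, by = 1000),
    ref = "A", alt = "G", type = "SNP",
    parentG_gt = c("1/1", "1/1", "0/0", "0/1", "1/1",
                   "1/1", "1/1", "1/1", NA, "1/1"),
    parentY_gt = c("0/0", "0/0", "1/1", "0/0", "1/1",
                   "0/0", "0/0", "0/0", "0/0", "0/0"),
    parentG_ref = 0L, parentG_alt = 20L,
    parentY_ref = 20L, parentY_alt = 0L,
    G_pool_ref = c(5L, 6L, 7L, 5L, 5L, 4L, 3L, 5L, 6L, 5L),
    G_pool_alt = c(5L, 6L, 7L, 5L, 5L, 4L, 4L, 5L, 6L, 5L),
    Y_pool_ref = c(4L, 5L, 6L, 4L, 4L, 5L, 5L, 4L, 5L, 4L),
    Y_pool_alt = c(6L, 5L, 4L, 6L, 6L, 5L, 3L, 6L, 5L, 4L),
    stringsAsFactors = FALSE)
  # passing rows: 1, 2, 3, 6, 8, 10 (4 het parent, 5 identical parents,
  # 7 bulk depth 7, 9 missing parent call)
  class(df) <- c("variant_sites", "data.frame")
  df
}

# Brute-force position-by-position compatibility scan (independent oracle for
# narrow_interval): genotype at a grid point is the call of the nearest
# non-missing marker (ties to the left), compatibility per individual from
# genotype_constraint, intersection by logical AND over the grid.
oracle_interval <- function(tab, design, grid_by = 0.5) {
  pos <- tab$positions_bp
  grid <- seq(min(pos), max(pos), by = grid_by)
  ok <- rep(TRUE, length(grid))
  for (i in seq_len(nrow(tab$calls))) {
    allowed <- genotype_constraint(tab$phenotypes[i], design)
    obs <- !is.na(tab$calls[i, ])
    if (!any(obs)) next
    p <- pos[obs]; g <- tab$calls[i, obs]
    geno <- vapply(grid, function(x) {
      d <- abs(p - x)
      j <- which(d == min(d))
      g[j[1L]]  # tie -> left marker
    }, "")
    ok <- ok & geno %in% allowed
  }
  if (!any(ok)) return(NULL)
  r <- rle(ok)
  hi <- cumsum(r$lengths); lo <- hi - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  c(grid[lo[best]], grid[hi[best]])
}

# Map with a causal chromosome plus n_unlinked single-marker chromosomes that
# never recombine: their markers are genuinely unlinked to everything.
unlinked_marker_map <- function(n_unlinked, causal_len_bp = 5e6,
                                causal_cM = 40, spacing = 1e4) {
  chrom <- c("LG10", sprintf("U%03d", seq_len(n_unlinked)))
  mp <- c(list(LG10 = seq(spacing, causal_len_bp, by = spacing)),
          stats::setNames(rep(list(5000), n_unlinked), chrom[-1]))
  genetic_map(chrom, c(causal_len_bp, rep(1e4, n_unlinked)),
              c(causal_cM, rep(0, n_unlinked)), marker_positions = mp)
}
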