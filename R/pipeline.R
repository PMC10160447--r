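# End-to-end orchestration: simulate -> VCF -> index -> call -> fine-map,
# with plain-text config, per-stage logging and track export.

#' Derive a deterministic sub-seed for a pipeline stage
#'
#' All stages of a run draw from sub-seeds derived from one master seed, so
#' a single integer reproduces the whole run.
#'
#' @param seed Master integer seed.
#' @param stage Stage index (small integer).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  as.integer(((as.numeric(seed) %% 2147483647) * 1000003 + stage * 7919) %%
               2147483646) + 1L
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
}

#' Full run configuration
#'
#' Defaults reproduce the study design: an F2 of 623 plants and a BC1 of 71
#' backcrossed to the green parent, 33-plant bulks, ~30x pooled depth, one
#' informative site per 10 kb, a 5 Mb causal chromosome (40 cM) with the
#' dominant locus mid-chromosome plus one neutral chromosome, 1 Mb / 100 kb
#' windows and the 0.875 / 0.5 calling thresholds.
#'
#' @param seed Master seed.
#' @param n_f2,n_bc1 Population sizes.
#' @param bulk_size Plants per bulk.
#' @param chrom_names,chrom_length_bp,chrom_length_cM Map specification.
#' @param marker_spacing_bp Informative-site spacing.
#' @param causal_chrom,causal_pos Causal locus.
#' @param mean_depth,base_error_rate,indel_fraction Sequencing simulation.
#' @param min_depth Bulk depth filter.
#' @param window_size_bp,step_bp,min_sites Windowing.
#' @param snp_index_threshold,delta_threshold,min_consecutive Region calling.
#' @param n_fine_markers Markers used for interval narrowing.
#' @param out_dir Output directory.
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(seed = 1, n_f2 = 623, n_bc1 = 71, bulk_size = 33,
                       chrom_names = c("LG10", "LG01"),
                       chrom_length_bp = c(5e6, 5e6),
                       chrom_length_cM = c(40, 40),
                       marker_spacing_bp = 1e4,
                       causal_chrom = "LG10", causal_pos = 2.5e6,
                       mean_depth = 30, base_error_rate = 0.005,
                       indel_fraction = 0.05, min_depth = 8,
                       window_size_bp = 1e6, step_bp = 1e5, min_sites = 10,
                       snp_index_threshold = 0.875, delta_threshold = 0.5,
                       min_consecutive = 3, n_fine_markers = 12,
                       out_dir = tempfile("bsaqtl_run_")) {
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

#' Serialize a run configuration to a key=value text file
#'
#' @param config A [run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  keys <- names(config)
  vals <- vapply(config, function(v) paste(format(v, scientific = FALSE),
                                           collapse = ","), "")
  writeLines(paste0(keys, "=", vals), path)
  invisible(path)
}

#' Read a run configuration back from a key=value text file
#'
#' @param path File written by [write_run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- lapply(kv, function(p) {
    v <- strsplit(p[2], ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(v))
    if (!anyNA(num)) num else v
  })
  names(vals) <- vapply(kv, `[`, "", 1)
  do.call(run_config, vals)
}

#' Run the whole mapping workflow on synthetic data
#'
#' Chains all stages: population simulation, segregation tests, bulk
#' construction, pooled read simulation, VCF round-trip, informative-site
#' filtering, SNP-index and windowed tracks, candidate-region calling and
#' recombinant-based interval narrowing. Persists the VCF, the TSV/BED
#' tracks, the recombinant table, the config and a JSON report under
#' `config$out_dir`. Identical seed and config give byte-identical outputs.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage messages.
#' @return An object of class `bsa_run_report` (a named list), invisibly the
#'   same as what is persisted to `report.json`.
#' @export
run_full <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  log <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  map <- with_stage("map", genetic_map(config$chrom_names,
                                       config$chrom_length_bp,
                                       config$chrom_length_cM,
                                       config$marker_spacing_bp))
  locus <- causal_locus(config$causal_chrom, config$causal_pos)

  log("[simulate] F2 n=%d, BC1 n=%d", config$n_f2, config$n_bc1)
  pop_f2 <- with_stage("simulate", simulate_population(
    "F2", config$n_f2, map, locus, seed = derive_seed(seed, 1)))
  pop_bc1 <- with_stage("simulate", simulate_population(
    "BC1", config$n_bc1, map, locus, seed = derive_seed(seed, 2)))

  seg <- list(
    F2 = chi_square_gof(sum(pop_f2$phenotype == "yellow"),
                        sum(pop_f2$phenotype == "green"), c(3, 1)),
    BC1 = chi_square_gof(sum(pop_bc1$phenotype == "yellow"),
                         sum(pop_bc1$phenotype == "green"), c(1, 1)))
  log("[segtest] F2 %d:%d chi2=%.4f P=%.4f; BC1 %d:%d chi2=%.4f P=%.4f",
      seg$F2$n_yellow, seg$F2$n_green, seg$F2$chi2, seg$F2$p,
      seg$BC1$n_yellow, seg$BC1$n_green, seg$BC1$chi2, seg$BC1$p)

  bulks <- with_stage("bulks", build_bulks(pop_f2, config$bulk_size,
                                           seed = derive_seed(seed, 3)))
  sites <- with_stage("simulate_reads", simulate_read_counts(
    bulks$freq, seq_sim_params(config$mean_depth, config$base_error_rate,
                               config$indel_fraction,
                               seed = derive_seed(seed, 4))))
  vcf_path <- file.path(config$out_dir, "sites.vcf")
  with_stage("write_vcf", write_bsa_vcf(sites, vcf_path))
  log("[simulate_reads] %d sites written to %s", nrow(sites), vcf_path)

  sites_in <- with_stage("read_variants", read_variants(vcf_path))
  informative <- with_stage("filter", filter_informative(
    sites_in, filter_config(config$min_depth)))
  stopifnot(nrow(informative) <= nrow(sites_in))
  log("[filter] %d sites in, %d kept, %d removed", nrow(sites_in),
      nrow(informative), nrow(sites_in) - nrow(informative))

  track <- with_stage("snp_index", snp_index_table(informative))
  chrom_lengths <- stats::setNames(config$chrom_length_bp, config$chrom_names)
  windows <- with_stage("windows", sliding_window_means(
    track, window_config(config$window_size_bp, config$step_bp,
                         config$min_sites), chrom_lengths))
  regions <- with_stage("call", call_candidate_regions(
    windows, region_call_config(config$snp_index_threshold,
                                config$delta_threshold,
                                config$min_consecutive)))
  log("[call] %d candidate region(s)", nrow(regions))

  fine <- with_stage("finemap", {
    on_causal <- regions[regions$chrom == config$causal_chrom, , drop = FALSE]
    span <- if (nrow(on_causal)) {
      r <- on_causal[which.max(on_causal$mean_delta), ]
      c(r$start, min(r$end, chrom_lengths[[config$causal_chrom]]))
    } else c(1, chrom_lengths[[config$causal_chrom]])
    fpos <- unique(round(seq(span[1], span[2],
                             length.out = config$n_fine_markers)))
    calls <- population_marker_calls(pop_f2, config$causal_chrom, fpos)
    tab <- recombinant_table(sprintf("M%02d", seq_along(fpos)), fpos, calls,
                             pop_f2$phenotype)
    tab <- suppressMessages(screen_recombinants(tab, "F2"))
    # conservative flanking-marker bounds: breakpoint positions between
    # discordant markers are unknown, so never exclude the true locus
    list(table = tab,
         interval = suppressWarnings(narrow_interval(tab, "F2",
                                                     drop_conflicting = TRUE,
                                                     boundary = "marker")))
  })
  log("[finemap] interval %.0f-%.0f bp (%.1f kb)", fine$interval$start,
      fine$interval$end, interval_length_kb(fine$interval))

  with_stage("export", {
    export_tracks(track, windows, regions, config$out_dir)
    rec <- data.frame(individual = rownames(fine$table$calls),
                      phenotype = fine$table$phenotypes,
                      fine$table$calls, check.names = FALSE,
                      stringsAsFactors = FALSE)
    utils::write.table(rec, file.path(config$out_dir, "recombinants.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  cfg_path <- file.path(config$out_dir, "config.txt")
  write_run_config(config, cfg_path)
  # fingerprint over everything except the output location, so identical
  # seed+parameters give identical reports regardless of where they land
  fp_file <- tempfile()
  fp_cfg <- config
  fp_cfg$out_dir <- "."
  write_run_config(fp_cfg, fp_file)
  fingerprint <- unname(tools::md5sum(fp_file))
  unlink(fp_file)
  report <- list(
    package_version = as.character(utils::packageVersion("bsaqtl")),
    config_md5 = fingerprint,
    seed = seed,
    counts = list(n_f2 = config$n_f2, n_bc1 = config$n_bc1,
                  sites_simulated = nrow(sites), sites_read = nrow(sites_in),
                  sites_informative = nrow(informative),
                  sites_filtered = nrow(sites_in) - nrow(informative),
                  windows = nrow(windows)),
    segregation = list(
      F2 = seg$F2[c("n_yellow", "n_green", "chi2", "p", "verdict")],
      BC1 = seg$BC1[c("n_yellow", "n_green", "chi2", "p", "verdict")]),
    regions = regions,
    interval = fine$interval[c("start", "end", "length_bp", "left_marker",
                               "right_marker")])
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  class(report) <- "bsa_run_report"
  invisible(report)
}

#' Export per-site, windowed and region tracks
#'
#' Writes `snp_index.tsv` and `windows.tsv` (1-based inclusive coordinates,
#' stated in their comment headers) and `regions.bed` (0-based half-open BED
#' converted from the internal convention). An empty region set yields a
#' valid BED with no data lines.
#'
#' @param records A `snp_index_track`.
#' @param windows Output of [sliding_window_means()].
#' @param regions Output of [call_candidate_regions()].
#' @param dir Destination directory (must be writable).
#' @return Character vector of the three file paths, invisibly.
#' @export
export_tracks <- function(records, windows, regions, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create destination directory: ", dir)
  write_tsv <- function(df, path, comments) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(comments, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  p1 <- file.path(dir, "snp_index.tsv")
  write_tsv(records, p1, c("# per-site SNP-index track",
                           "# coordinates: 1-based inclusive"))
  p2 <- file.path(dir, "windows.tsv")
  write_tsv(windows, p2,
            c("# sliding-window mean SNP-index / delta",
              "# coordinates: 1-based inclusive; windows half-open in bp"))
  p3 <- file.path(dir, "regions.bed")
  con <- file(p3, "w")
  writeLines("# candidate regions; BED: 0-based half-open", con)
  if (nrow(regions))
    writeLines(sprintf("%s\t%d\t%d\tregion_%d\t%d\t.", regions$chrom,
                       as.integer(regions$start) - 1L,
                       as.integer(regions$end), seq_len(nrow(regions)),
                       pmin(1000L, as.integer(round(1000 * regions$mean_delta)))),
               con)
  close(con)
  invisible(c(p1, p2, p3))
}

#' Read back a TSV track written by [export_tracks()]
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_track_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
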