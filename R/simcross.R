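# Cross simulation: haplotype mosaics, meiosis, populations and bulks.
#
# Haplotypes are run-length encodings of parental origin along a chromosome:
# `breaks` are the bp positions where origin switches (position p belongs to
# the segment left of the first break >= p) and `origins` has one entry per
# segment, 0 = green parent, 1 = yellow parent.

#' Construct a haplotype mosaic
#'
#' @param breaks Strictly increasing numeric vector of origin switch points
#'   (bp); empty for a non-recombinant haplotype.
#' @param origins Integer vector of parental origins (0 green, 1 yellow), one
#'   per segment, i.e. `length(breaks) + 1` entries.
#' @return A list with elements `breaks` and `origins`.
#' @export
haplotype <- function(breaks = numeric(0), origins = 0L) {
  breaks <- as.numeric(breaks)
  origins <- as.integer(origins)
  if (length(origins) != length(breaks) + 1L)
    stop("origins must have one entry per segment (length(breaks) + 1)")
  if (length(breaks) && is.unsorted(breaks, strictly = TRUE))
    stop("breaks must be strictly increasing")
  if (!all(origins %in% c(0L, 1L))) stop("origins must be 0 or 1")
  list(breaks = breaks, origins = origins)
}

#' Parental origin of a haplotype at given positions
#'
#' @param hap A [haplotype()].
#' @param pos Numeric vector of bp positions.
#' @return Integer vector of origins (0 green, 1 yellow).
#' @export
hap_origin_at <- function(hap, pos) {
  hap$origins[findInterval(pos, hap$breaks) + 1L]
}

#' A fully inbred founder individual
#'
#' @param origin 0 for the green parent, 1 for the yellow parent.
#' @param map A [genetic_map()].
#' @return An individual: a list with element `haps`, one `list(h1, h2)` pair
#'   of haplotypes per chromosome (named as in the map).
#' @export
founder_individual <- function(origin, map) {
  h <- haplotype(numeric(0), as.integer(origin))
  haps <- rep(list(list(h, h)), nrow(map$chrom))
  names(haps) <- map$chrom$name
  list(haps = haps)
}

# Combine two parental haplotypes given crossover positions. `start_hap` is
# the haplotype transmitted left of the first crossover.
recombine_haplotypes <- function(h1, h2, xo, start_hap, length_bp) {
  if (length(xo) == 0L) return(if (start_hap == 1L) h1 else h2)
  breaks <- sort(unique(c(h1$breaks, h2$breaks, xo)))
  ends <- c(breaks, length_bp)
  mids <- (c(0, breaks) + ends) / 2
  on_start <- findInterval(mids, xo) %% 2L == 0L
  use_first <- on_start == (start_hap == 1L)
  o1 <- h1$origins[findInterval(mids, h1$breaks) + 1L]
  o2 <- h2$origins[findInterval(mids, h2$breaks) + 1L]
  orig <- ifelse(use_first, o1, o2)
  r <- rle(orig)
  k <- cumsum(r$lengths)
  haplotype(breaks[k[-length(k)]], as.integer(r$values))
}

#' Simulate one meiosis
#'
#' Crossovers follow a no-interference model: the count per chromosome is
#' Poisson with mean `length_cM / 100` and positions are uniform on the
#' genetic map (hence, with linear interpolation, uniform in bp). Uses the
#' current RNG state.
#'
#' @param parent An individual (see [founder_individual()]).
#' @param map A [genetic_map()].
#' @return One recombinant haplotype per chromosome (named list).
#' @examples
#' map <- genetic_map("LG10", 1e6, 100)
#' f1 <- list(haps = list(LG10 = list(haplotype(origins = 0L),
#'                                    haplotype(origins = 1L))))
#' g <- simulate_gamete(f1, map)
#' @export
simulate_gamete <- function(parent, map) {
  nchr <- nrow(map$chrom)
  if (is.null(nchr) || nchr == 0L) stop("empty genetic map")
  out <- vector("list", nchr)
  for (i in seq_len(nchr)) {
    len_bp <- map$chrom$length_bp[i]
    morgans <- map$chrom$length_cM[i] / 100
    pair <- parent$haps[[i]]
    n_xo <- stats::rpois(1L, morgans)
    xo <- if (n_xo > 0L) sort(stats::runif(n_xo, 0, len_bp)) else numeric(0)
    out[[i]] <- recombine_haplotypes(pair[[1L]], pair[[2L]], xo,
                                     sample.int(2L, 1L), len_bp)
  }
  names(out) <- map$chrom$name
  out
}

#' Simulate a segregating population from a biparental cross
#'
#' The green (recessive) and yellow (dominant) parents are fully inbred.
#' F1 individuals carry one intact haplotype from each parent; F2 individuals
#' arise from two independent F1 gametes; BC1 individuals from one F1 gamete
#' and one green-parent gamete. Phenotype is yellow iff the individual carries
#' at least one dominant allele at the causal locus (full penetrance), then
#' flipped independently with probability `misphenotyping_rate`.
#'
#' @param design One of `"F1"`, `"F2"`, `"BC1"`.
#' @param n Number of individuals (>= 1).
#' @param map A [genetic_map()].
#' @param locus A [causal_locus()].
#' @param misphenotyping_rate Probability that a recorded phenotype is wrong.
#' @param seed Optional integer seed (set once at entry).
#' @return An object of class `bsa_population`: list with `individuals`,
#'   `phenotype` (character vector `"yellow"`/`"green"`), `design`, `map`,
#'   `locus`.
#' @examples
#' map <- genetic_map("LG10", 5e6, 40)
#' pop <- simulate_population("F2", 200, map, causal_locus("LG10", 2.5e6),
#'                            seed = 1)
#' table(pop$phenotype)
#' @export
simulate_population <- function(design = c("F1", "F2", "BC1"), n, map, locus,
                                misphenotyping_rate = 0, seed = NULL) {
  design <- match.arg(design)
  stopifnot(n >= 1, misphenotyping_rate >= 0, misphenotyping_rate <= 1)
  ichr <- check_locus(locus, map)
  if (!is.null(seed)) set.seed(seed)
  green <- founder_individual(0L, map)
  yellow <- founder_individual(1L, map)
  f1 <- list(haps = Map(function(g, y) list(g[[1L]], y[[1L]]),
                        green$haps, yellow$haps))
  inds <- vector("list", n)
  for (j in seq_len(n)) {
    haps <- switch(design,
      F1 = f1$haps,
      F2 = Map(list, simulate_gamete(f1, map), simulate_gamete(f1, map)),
      BC1 = Map(list, simulate_gamete(f1, map), simulate_gamete(green, map)))
    inds[[j]] <- list(haps = haps)
  }
  pos <- locus$position_bp
  n_dom <- vapply(inds, function(ind) {
    pr <- ind$haps[[ichr]]
    sum(hap_origin_at(pr[[1L]], pos) == 1L, hap_origin_at(pr[[2L]], pos) == 1L)
  }, numeric(1))
  phenotype <- ifelse(n_dom >= 1, "yellow", "green")
  if (misphenotyping_rate > 0) {
    flip <- stats::runif(n) < misphenotyping_rate
    phenotype[flip] <- ifelse(phenotype[flip] == "yellow", "green", "yellow")
  }
  structure(list(individuals = inds, phenotype = phenotype, design = design,
                 map = map, locus = locus),
            class = "bsa_population")
}

#' Genotype at the causal locus
#'
#' @param population A `bsa_population`.
#' @return Integer vector: number of dominant (yellow-parent) alleles (0/1/2)
#'   per individual.
#' @export
causal_genotype <- function(population) {
  ichr <- match(population$locus$chromosome, population$map$chrom$name)
  pos <- population$locus$position_bp
  vapply(population$individuals, function(ind) {
    pr <- ind$haps[[ichr]]
    sum(hap_origin_at(pr[[1L]], pos) == 1L, hap_origin_at(pr[[2L]], pos) == 1L)
  }, numeric(1))
}

#' Build phenotype-selected bulks and their true allele frequencies
#'
#' Draws disjoint random samples of the requested size from the yellow and
#' green phenotype classes and computes, at every marker of the map, the
#' frequency of the green-parent allele among the `2 * size_per_bulk`
#' haplotypes of each bulk.
#'
#' @param population A `bsa_population`.
#' @param size_per_bulk Plants per bulk (default 33).
#' @param seed Optional integer seed.
#' @return An object of class `bsa_bulks`: list with `yellow`/`green` member
#'   indices and `freq`, a data frame with columns `chrom`, `pos`,
#'   `freq_G_pool`, `freq_Y_pool` (green-parent allele frequency in the green
#'   and yellow bulk respectively).
#' @export
build_bulks <- function(population, size_per_bulk = 33, seed = NULL) {
  stopifnot(size_per_bulk >= 1)
  if (!is.null(seed)) set.seed(seed)
  phen <- population$phenotype
  for (ph in c("yellow", "green")) {
    avail <- sum(phen == ph)
    if (avail < size_per_bulk)
      stop(sprintf("cannot form %s bulk: need %d plants but only %d available",
                   ph, size_per_bulk, avail))
  }
  members_y <- sample(which(phen == "yellow"), size_per_bulk)
  members_g <- sample(which(phen == "green"), size_per_bulk)
  map <- population$map
  freq <- do.call(rbind, lapply(seq_len(nrow(map$chrom)), function(i) {
    pos <- map$markers[[i]]
    if (!length(pos)) return(NULL)
    data.frame(chrom = map$chrom$name[i], pos = as.integer(pos),
               freq_G_pool = bulk_green_freq(population, members_g, i, pos),
               freq_Y_pool = bulk_green_freq(population, members_y, i, pos),
               stringsAsFactors = FALSE)
  }))
  rownames(freq) <- NULL
  structure(list(yellow = members_y, green = members_g,
                 size_per_bulk = size_per_bulk, freq = freq),
            class = "bsa_bulks")
}

bulk_green_freq <- function(population, members, ichr, pos) {
  acc <- numeric(length(pos))
  for (j in members) {
    pr <- population$individuals[[j]]$haps[[ichr]]
    acc <- acc + (hap_origin_at(pr[[1L]], pos) == 0L) +
      (hap_origin_at(pr[[2L]], pos) == 0L)
  }
  acc / (2 * length(members))
}

#' Pooled-sequencing simulation parameters
#'
#' @param mean_depth Mean reads per site per sample; per-site depth is
#'   Poisson with this mean (default 30, the order of the study design's
#'   pooled coverage).
#' @param base_error_rate Probability that a read reports the wrong allele
#'   (must lie in `[0, 0.5)`; default 0.005).
#' @param indel_fraction Fraction of simulated sites emitted as InDels rather
#'   than SNPs (default 0.05); InDel length differences are uniform on 1-12 bp.
#' @param seed Optional integer seed.
#' @return An object of class `seq_sim_params`.
#' @export
seq_sim_params <- function(mean_depth = 30, base_error_rate = 0.005,
                           indel_fraction = 0.05, seed = NULL) {
  if (!is.finite(mean_depth) || mean_depth <= 0)
    stop("mean_depth must be positive")
  if (!is.finite(base_error_rate) || base_error_rate < 0 ||
      base_error_rate >= 0.5)
    stop("base_error_rate must lie in [0, 0.5)")
  stopifnot(indel_fraction >= 0, indel_fraction <= 1)
  structure(list(mean_depth = mean_depth, base_error_rate = base_error_rate,
                 indel_fraction = indel_fraction, seed = seed),
            class = "seq_sim_params")
}

#' Simulate pooled read counts at informative sites
#'
#' The simulated reference genome carries the yellow-parent allele at every
#' informative site, so REF is the yellow-parent allele and ALT the
#' green-parent allele: the green bulk's SNP-index (ALT fraction) is high in
#' the region linked to a dominant yellow locus. Per site and bulk, total
#' depth is Poisson(`mean_depth`) and the green-allele read count is
#' Binomial(depth, `f * (1 - e) + (1 - f) * e`) where `f` is the bulk's true
#' green-allele frequency and `e` the base error rate. Parents are emitted as
#' fixed homozygotes with error-free reads.
#'
#' @param freq Data frame with columns `chrom`, `pos`, `freq_G_pool`,
#'   `freq_Y_pool` (see [build_bulks()]).
#' @param params A [seq_sim_params()].
#' @return A `variant_sites` data frame: `chrom`, `pos`, `ref`, `alt`, `type`,
#'   parent genotypes and per-sample ref/alt depths.
#' @export
simulate_read_counts <- function(freq, params = seq_sim_params()) {
  stopifnot(is.data.frame(freq),
            all(c("chrom", "pos", "freq_G_pool", "freq_Y_pool") %in%
                  names(freq)))
  f <- cbind(freq$freq_G_pool, freq$freq_Y_pool)
  if (any(!is.finite(f)) || any(f < 0) || any(f > 1))
    stop("allele frequencies must lie in [0, 1]")
  if (!inherits(params, "seq_sim_params")) stop("params must be seq_sim_params")
  if (!is.null(params$seed)) set.seed(params$seed)
  m <- nrow(freq)
  e <- params$base_error_rate
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "",
                USE.NAMES = FALSE)
  if (params$indel_fraction > 0 && m > 0) {
    is_indel <- stats::runif(m) < params$indel_fraction
    len <- sample(1:12, m, replace = TRUE)
    extra <- vapply(len, function(k)
      paste(sample(bases, k, replace = TRUE), collapse = ""), "")
    grow_alt <- stats::runif(m) < 0.5
    ins <- is_indel & grow_alt
    del <- is_indel & !grow_alt
    alt[ins] <- paste0(ref[ins], extra[ins])
    alt[del] <- ref[del]
    ref[del] <- paste0(ref[del], extra[del])
  }
  dp_G <- stats::rpois(m, params$mean_depth)
  dp_Y <- stats::rpois(m, params$mean_depth)
  alt_G <- stats::rbinom(m, dp_G, freq$freq_G_pool * (1 - e) +
                           (1 - freq$freq_G_pool) * e)
  alt_Y <- stats::rbinom(m, dp_Y, freq$freq_Y_pool * (1 - e) +
                           (1 - freq$freq_Y_pool) * e)
  dp_pg <- stats::rpois(m, params$mean_depth)
  dp_py <- stats::rpois(m, params$mean_depth)
  out <- data.frame(
    chrom = freq$chrom, pos = as.integer(freq$pos), ref = ref, alt = alt,
    type = ifelse(nchar(ref) != nchar(alt), "InDel", "SNP"),
    parentG_gt = "1/1", parentY_gt = "0/0",
    parentG_ref = 0L, parentG_alt = dp_pg,
    parentY_ref = dp_py, parentY_alt = 0L,
    G_pool_ref = dp_G - alt_G, G_pool_alt = alt_G,
    Y_pool_ref = dp_Y - alt_Y, Y_pool_alt = alt_Y,
    stringsAsFactors = FALSE)
  class(out) <- c("variant_sites", "data.frame")
  out
}
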