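#' Define a genetic map for cross simulation
#'
#' A genetic map lists chromosomes with their physical (bp) and genetic (cM)
#' lengths plus the positions of parent-informative marker sites. Genetic
#' positions are obtained from physical positions by linear interpolation, so
#' recombination is uniform along each chromosome.
#'
#' @param chrom Character vector of chromosome names.
#' @param length_bp Numeric vector of physical lengths in bp (1-based
#'   coordinates span `[1, length_bp]`).
#' @param length_cM Numeric vector of genetic lengths in centimorgan. A length
#'   of 0 gives a chromosome that never recombines.
#' @param marker_spacing_bp Spacing used to lay out informative marker sites
#'   when `marker_positions` is not supplied (default one site per 10 kb).
#' @param marker_positions Optional named list (one element per chromosome) of
#'   strictly increasing integer bp positions.
#' @return An object of class `genetic_map` with elements `chrom` (data frame
#'   of name/length_bp/length_cM) and `markers` (list of bp positions).
#' @examples
#' map <- genetic_map("LG10", 5e6, 40)
#' head(map$markers$LG10)
#' @export
genetic_map <- function(chrom, length_bp, length_cM,
                        marker_spacing_bp = 10000, marker_positions = NULL) {
  chrom <- as.character(chrom)
  if (length(chrom) < 1L) stop("a genetic map needs at least one chromosome")
  if (anyDuplicated(chrom)) stop("duplicated chromosome names")
  length_bp <- as.numeric(length_bp)
  length_cM <- as.numeric(length_cM)
  if (length(length_bp) != length(chrom) || length(length_cM) != length(chrom))
    stop("chrom, length_bp and length_cM must have the same length")
  if (any(!is.finite(length_bp)) || any(length_bp < 1))
    stop("length_bp must be positive")
  if (any(!is.finite(length_cM)) || any(length_cM < 0))
    stop("length_cM must be non-negative")
  if (is.null(marker_positions)) {
    stopifnot(marker_spacing_bp >= 1)
    marker_positions <- lapply(seq_along(chrom), function(i)
      seq(marker_spacing_bp, length_bp[i], by = marker_spacing_bp))
    names(marker_positions) <- chrom
  }
  if (!all(chrom %in% names(marker_positions)))
    stop("marker_positions must be a named list covering every chromosome")
  marker_positions <- marker_positions[chrom]
  for (i in seq_along(chrom)) {
    p <- marker_positions[[i]]
    if (length(p) && is.unsorted(p, strictly = TRUE))
      stop("marker positions must be strictly increasing on ", chrom[i])
    if (length(p) && (min(p) < 1 || max(p) > length_bp[i]))
      stop("marker positions outside [1, length_bp] on ", chrom[i])
  }
  structure(
    list(chrom = data.frame(name = chrom, length_bp = length_bp,
                            length_cM = length_cM, stringsAsFactors = FALSE),
         markers = marker_positions),
    class = "genetic_map")
}

#' Genetic positions of the markers of one chromosome
#'
#' @param map A [genetic_map()].
#' @param chrom Chromosome name.
#' @return Numeric vector of cM positions (linear interpolation along bp).
#' @export
marker_cm <- function(map, chrom) {
  i <- match(chrom, map$chrom$name)
  if (is.na(i)) stop("unknown chromosome: ", chrom)
  map$markers[[i]] * map$chrom$length_cM[i] / map$chrom$length_bp[i]
}

#' Describe the causal locus of a simulated cross
#'
#' @param chromosome Chromosome name carrying the locus.
#' @param position_bp 1-based bp position.
#' @param dominant_allele_origin Which parent carries the dominant allele;
#'   `"yellow"` (the default) matches a dominant yellow-peel locus.
#' @return An object of class `causal_locus`.
#' @export
causal_locus <- function(chromosome, position_bp,
                         dominant_allele_origin = "yellow") {
  stopifnot(length(chromosome) == 1L, length(position_bp) == 1L,
            position_bp >= 1)
  dominant_allele_origin <- match.arg(dominant_allele_origin,
                                      c("yellow", "green"))
  structure(list(chromosome = as.character(chromosome),
                 position_bp = as.numeric(position_bp),
                 dominant_allele_origin = dominant_allele_origin),
            class = "causal_locus")
}

check_locus <- function(locus, map) {
  i <- match(locus$chromosome, map$chrom$name)
  if (is.na(i)) stop("causal locus chromosome not in map: ", locus$chromosome)
  if (locus$position_bp > map$chrom$length_bp[i])
    stop("causal locus position outside chromosome bounds")
  i
}
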