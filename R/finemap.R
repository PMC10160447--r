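# Interval narrowing from recombinant marker genotypes, plus co-dominant
# marker selection and marker-phenotype concordance.
#
# Marker calls: "A" homozygous green-parent, "B" homozygous yellow-parent,
# "H" heterozygous, NA missing. An individual's genotype along the
# chromosome is taken as piecewise constant with switch points at the
# midpoints between adjacent discordant (non-missing) markers.

#' Genotypes compatible with a phenotype at the causal locus
#'
#' Under full-penetrance dominance: green individuals are homozygous for the
#' green-parent allele; yellow F2 individuals are heterozygous or homozygous
#' dominant; yellow BC1 individuals (backcross to the recessive parent) can
#' only be heterozygous.
#'
#' @param phenotype `"yellow"` or `"green"`.
#' @param design `"F2"` or `"BC1"`.
#' @return Character vector of allowed genotype codes among `"A"`, `"H"`,
#'   `"B"`.
#' @export
genotype_constraint <- function(phenotype, design = c("F2", "BC1")) {
  design <- match.arg(design)
  if (!phenotype %in% c("yellow", "green"))
    stop("unknown phenotype: ", phenotype)
  if (phenotype == "green") "A"
  else if (design == "F2") c("H", "B")
  else "H"
}

#' Ordered marker genotypes of a mapping panel
#'
#' @param marker_names Character vector of marker names (left to right).
#' @param positions_bp Strictly increasing bp positions, one per marker.
#' @param calls Character matrix (individuals x markers) of `"A"`, `"H"`,
#'   `"B"` or `NA`.
#' @param phenotypes Character vector (`"yellow"`/`"green"`), one per
#'   individual.
#' @return An object of class `recombinant_table`.
#' @export
recombinant_table <- function(marker_names, positions_bp, calls, phenotypes) {
  positions_bp <- as.numeric(positions_bp)
  calls <- as.matrix(calls)
  if (length(marker_names) != length(positions_bp) ||
      ncol(calls) != length(marker_names))
    stop("marker_names, positions_bp and calls columns must agree")
  if (length(positions_bp) >= 2 && is.unsorted(positions_bp, strictly = TRUE))
    stop("marker positions must be strictly increasing")
  if (nrow(calls) != length(phenotypes))
    stop("one phenotype per individual is required")
  bad <- !is.na(calls) & !calls %in% c("A", "H", "B")
  if (any(bad)) stop("marker calls must be A, H, B or NA")
  if (is.null(rownames(calls)))
    rownames(calls) <- paste0("ind", seq_len(nrow(calls)))
  colnames(calls) <- marker_names
  structure(list(marker_names = as.character(marker_names),
                 positions_bp = positions_bp, calls = calls,
                 phenotypes = as.character(phenotypes)),
            class = "recombinant_table")
}

# --- closed-interval set helpers (matrices with columns start, end) ---------

merge_intervals <- function(m) {
  if (nrow(m) <= 1L) return(m)
  m <- m[order(m[, 1L]), , drop = FALSE]
  out <- m[1L, , drop = FALSE]
  for (i in 2:nrow(m)) {
    if (m[i, 1L] <= out[nrow(out), 2L])
      out[nrow(out), 2L] <- max(out[nrow(out), 2L], m[i, 2L])
    else out <- rbind(out, m[i, , drop = FALSE])
  }
  out
}

intersect_intervals <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(matrix(numeric(0), ncol = 2L))
  res <- matrix(numeric(0), ncol = 2L)
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    s <- max(a[i, 1L], b[j, 1L])
    e <- min(a[i, 2L], b[j, 2L])
    if (s < e) res <- rbind(res, c(s, e))
  }
  if (nrow(res)) merge_intervals(res) else res
}

# Positions compatible with one individual's marker calls and phenotype.
# boundary = "midpoint": the genotype switches at the midpoint between
# adjacent discordant markers (symmetric point estimate of the breakpoint).
# boundary = "marker": the switch may lie anywhere between the discordant
# markers, so each genotype stretch conservatively extends to the flanking
# markers themselves; with error-free data the true locus position is then
# never excluded.
compatible_intervals <- function(calls_i, positions, allowed, lo, hi,
                                 boundary = "midpoint") {
  obs <- !is.na(calls_i)
  full <- matrix(c(lo, hi), ncol = 2L)
  if (!any(obs)) return(full)
  p <- positions[obs]
  g <- calls_i[obs]
  r <- rle(g)
  k <- cumsum(r$lengths)
  last_of_group <- k[-length(k)]
  if (boundary == "midpoint") {
    bounds <- if (length(k) > 1L) (p[last_of_group] + p[last_of_group + 1L]) / 2
              else numeric(0)
    starts <- c(lo, bounds)
    ends <- c(bounds, hi)
  } else {
    starts <- c(lo, p[last_of_group])
    ends <- c(p[last_of_group + 1L], hi)
  }
  keep <- r$values %in% allowed
  m <- cbind(starts, ends, deparse.level = 0)[keep, , drop = FALSE]
  dimnames(m) <- NULL
  if (nrow(m)) merge_intervals(m) else m
}

#' Drop individuals whose genotypes fit their phenotype nowhere
#'
#' An individual whose marker calls are incompatible with its phenotype at
#' every position in the spanned region (e.g. a phenotyping error, or a
#' double recombinant whose matching stretch falls between markers) cannot
#' constrain the locus and would otherwise abort the intersection. This
#' screen removes such individuals with a message; in a real mapping study
#' they would be re-genotyped.
#'
#' @param table A [recombinant_table()].
#' @param design `"F2"` or `"BC1"`.
#' @return A `recombinant_table` containing the informative individuals.
#' @export
screen_recombinants <- function(table, design = c("F2", "BC1")) {
  design <- match.arg(design)
  lo <- min(table$positions_bp)
  hi <- max(table$positions_bp)
  ok <- vapply(seq_len(nrow(table$calls)), function(i)
    nrow(compatible_intervals(table$calls[i, ], table$positions_bp,
                              genotype_constraint(table$phenotypes[i], design),
                              lo, hi)) > 0L, logical(1))
  if (!all(ok))
    message(sum(!ok), " individual(s) nowhere compatible with their ",
            "phenotype; dropped: ",
            paste(rownames(table$calls)[!ok], collapse = ", "))
  recombinant_table(table$marker_names, table$positions_bp,
                    table$calls[ok, , drop = FALSE], table$phenotypes[ok])
}

#' Narrow the causal interval from recombinant genotypes
#'
#' For each individual, the positions compatible with its phenotype are those
#' where its piecewise-constant genotype (switch points at midpoints between
#' adjacent discordant markers) falls in [genotype_constraint()]; missing
#' calls are uninformative at their marker. The mapped interval is the
#' largest component of the intersection of these compatible sets over the
#' region spanned by the markers, reported with its innermost flanking
#' markers.
#'
#' @param table A [recombinant_table()].
#' @param design `"F2"` or `"BC1"`.
#' @param drop_conflicting If `TRUE`, a single individual whose genotype is
#'   irreconcilable with the rest (e.g. a phenotyping error) is dropped with
#'   a warning instead of raising an error.
#' @param boundary `"midpoint"` places each breakpoint at the midpoint
#'   between adjacent discordant markers (symmetric point estimate);
#'   `"marker"` lets each genotype stretch extend conservatively to the
#'   discordant markers themselves, the classical flanking-marker logic
#'   that never excludes the true locus under error-free genotyping.
#' @return An object of class `mapped_interval`: `start`, `end`, `length_bp`,
#'   `left_marker`, `right_marker`.
#' @export
narrow_interval <- function(table, design = c("F2", "BC1"),
                            drop_conflicting = FALSE,
                            boundary = c("midpoint", "marker")) {
  design <- match.arg(design)
  boundary <- match.arg(boundary)
  if (!inherits(table, "recombinant_table"))
    stop("table must be a recombinant_table")
  if (nrow(table$calls) < 1L) stop("at least one individual is required")
  if (length(table$positions_bp) < 2L) stop("at least two markers are required")
  lo <- min(table$positions_bp)
  hi <- max(table$positions_bp)
  comp <- lapply(seq_len(nrow(table$calls)), function(i)
    compatible_intervals(table$calls[i, ], table$positions_bp,
                         genotype_constraint(table$phenotypes[i], design),
                         lo, hi, boundary))
  names(comp) <- rownames(table$calls)
  inter <- Reduce(intersect_intervals, comp)
  if (nrow(inter) == 0L) {
    restores <- vapply(seq_along(comp), function(i) {
      others <- Reduce(intersect_intervals, comp[-i])
      nrow(others) > 0L
    }, logical(1))
    offenders <- if (any(restores)) names(comp)[restores] else names(comp)
    if (drop_conflicting && any(restores)) {
      drop <- which(restores)[1L]
      warning("phenotype/genotype inconsistency: dropping individual ",
              names(comp)[drop])
      inter <- Reduce(intersect_intervals, comp[-drop])
    } else {
      stop("phenotype/genotype inconsistency; offending individuals: ",
           paste(offenders, collapse = ", "))
    }
  }
  best <- which.max(inter[, 2L] - inter[, 1L])
  start <- unname(inter[best, 1L])
  end <- unname(inter[best, 2L])
  left_i <- which(table$positions_bp <= start)
  right_i <- which(table$positions_bp >= end)
  mapped_interval(start, end,
                  left_marker = if (length(left_i))
                    table$marker_names[max(left_i)] else table$marker_names[1L],
                  right_marker = if (length(right_i))
                    table$marker_names[min(right_i)]
                  else table$marker_names[length(table$marker_names)])
}

#' A mapped interval between flanking markers
#'
#' @param start,end Interval bounds in bp (`start < end`).
#' @param left_marker,right_marker Flanking marker names (optional).
#' @return An object of class `mapped_interval`.
#' @examples
#' interval_length_kb(mapped_interval(8812267, 8983006))  # 170.739
#' @export
mapped_interval <- function(start, end, left_marker = NA_character_,
                            right_marker = NA_character_) {
  stopifnot(is.numeric(start), is.numeric(end))
  if (!(start < end)) stop("start must be smaller than end")
  structure(list(start = start, end = end, length_bp = end - start,
                 left_marker = left_marker, right_marker = right_marker),
            class = "mapped_interval")
}

#' @export
print.mapped_interval <- function(x, ...) {
  cat(sprintf("Mapped interval: %s-%s bp (%.1f kb), flanked by %s / %s\n",
              format(x$start, big.mark = ","), format(x$end, big.mark = ","),
              x$length_bp / 1000,
              x$left_marker, x$right_marker))
  invisible(x)
}

#' Interval length in kilobases
#'
#' @param interval A [mapped_interval()].
#' @return `(end - start) / 1000`.
#' @export
interval_length_kb <- function(interval) {
  if (!inherits(interval, "mapped_interval"))
    stop("interval must be a mapped_interval")
  (interval$end - interval$start) / 1000
}

#' Select gel-resolvable co-dominant InDel markers in a region
#'
#' Keeps InDel sites inside `[start, end]` whose parental allele-length
#' difference is at least `min_size_diff` bp (default 3 bp, resolvable on a
#' polyacrylamide gel so the heterozygote shows both bands).
#'
#' @param sites A `variant_sites` data frame (parent-informative).
#' @param chrom Chromosome name.
#' @param start,end Region bounds, 1-based inclusive.
#' @param min_size_diff Minimum ref/alt length difference in bp.
#' @return Subset of `sites` with an extra `size_diff` column, sorted by
#'   position.
#' @export
select_codominant_indels <- function(sites, chrom, start, end,
                                     min_size_diff = 3) {
  stopifnot(is.data.frame(sites), start <= end, min_size_diff >= 1)
  size_diff <- abs(nchar(sites$ref) - nchar(sites$alt))
  keep <- sites$type == "InDel" & sites$chrom == chrom &
    sites$pos >= start & sites$pos <= end & size_diff >= min_size_diff
  out <- sites[keep, , drop = FALSE]
  out$size_diff <- size_diff[keep]
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Marker-phenotype concordance in a panel
#'
#' Predicts yellow for individuals whose marker call carries at least one
#' dominant-parent allele (`"H"` or `"B"`), green otherwise, and reports the
#' fraction of non-missing individuals whose observed phenotype matches.
#'
#' @param calls Character vector of marker calls (`"A"`, `"H"`, `"B"`, `NA`).
#' @param phenotypes Character vector (`"yellow"`/`"green"`), same length.
#' @return List with `concordance`, `n_used`, `n_missing`.
#' @export
marker_concordance <- function(calls, phenotypes) {
  if (length(calls) != length(phenotypes))
    stop("calls and phenotypes must have the same length")
  use <- !is.na(calls)
  if (!any(use)) stop("all marker calls are missing")
  pred <- ifelse(calls[use] %in% c("H", "B"), "yellow", "green")
  list(concordance = mean(pred == phenotypes[use]),
       n_used = sum(use), n_missing = sum(!use))
}

#' Marker genotypes of simulated individuals
#'
#' Reads the simulated truth: the number of yellow-parent alleles carried at
#' each position is translated to co-dominant calls `"A"`/`"H"`/`"B"`.
#'
#' @param population A `bsa_population`.
#' @param chrom Chromosome name.
#' @param positions Marker bp positions.
#' @param individuals Optional indices (default: all).
#' @return Character matrix (individuals x markers).
#' @export
population_marker_calls <- function(population, chrom, positions,
                                    individuals = NULL) {
  ichr <- match(chrom, population$map$chrom$name)
  if (is.na(ichr)) stop("unknown chromosome: ", chrom)
  if (is.null(individuals)) individuals <- seq_along(population$individuals)
  calls <- matrix(NA_character_, nrow = length(individuals),
                  ncol = length(positions),
                  dimnames = list(paste0("ind", individuals), NULL))
  for (r in seq_along(individuals)) {
    pr <- population$individuals[[individuals[r]]]$haps[[ichr]]
    n_y <- (hap_origin_at(pr[[1L]], positions) == 1L) +
      (hap_origin_at(pr[[2L]], positions) == 1L)
    calls[r, ] <- c("A", "H", "B")[n_y + 1L]
  }
  calls
}
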