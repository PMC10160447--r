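# SNP-index / delta-SNP-index computation, sliding windows and region calling.

#' Per-site SNP-index
#'
#' The SNP-index of a bulk at a site is the fraction of its reads carrying
#' the alternate (here: green-parent) allele. Sites with zero depth get `NA`
#' and are excluded from windowed statistics downstream.
#'
#' @param alt_depth,total_depth Non-negative integer vectors (recycled).
#' @return Numeric vector in `[0, 1]`, `NA` where `total_depth` is 0.
#' @examples
#' snp_index(7, 8)   # 0.875
#' @export
snp_index <- function(alt_depth, total_depth) {
  if (any(alt_depth < 0, na.rm = TRUE) || any(total_depth < 0, na.rm = TRUE))
    stop("depths must be non-negative")
  if (any(alt_depth > total_depth, na.rm = TRUE))
    stop("alt_depth cannot exceed total_depth")
  out <- alt_depth / total_depth
  out[!is.na(total_depth) & total_depth == 0] <- NA_real_
  out
}

#' Delta SNP-index
#'
#' Difference of the green-bulk and yellow-bulk SNP-indices. Near 0 at
#' unlinked sites; approaches `1 - 1/3 = 2/3` at sites fully linked to a
#' dominant locus when the reference carries the dominant parent's allele.
#' Undefined (`NA`) whenever either index is undefined.
#'
#' @param index_G,index_Y Numeric vectors of per-bulk SNP-indices.
#' @return `index_G - index_Y`, in `[-1, 1]`.
#' @export
delta_snp_index <- function(index_G, index_Y) {
  index_G - index_Y
}

#' Per-site SNP-index track from filtered variant sites
#'
#' @param sites A `variant_sites` data frame (informative sites).
#' @return A `snp_index_track` data frame: `chrom`, `pos`, `index_G`,
#'   `index_Y`, `delta`.
#' @export
snp_index_table <- function(sites) {
  stopifnot(is.data.frame(sites))
  index_G <- snp_index(sites$G_pool_alt, sites$G_pool_ref + sites$G_pool_alt)
  index_Y <- snp_index(sites$Y_pool_alt, sites$Y_pool_ref + sites$Y_pool_alt)
  out <- data.frame(chrom = sites$chrom, pos = sites$pos,
                    index_G = index_G, index_Y = index_Y,
                    delta = delta_snp_index(index_G, index_Y),
                    stringsAsFactors = FALSE)
  class(out) <- c("snp_index_track", "data.frame")
  out
}

#' Sliding-window configuration
#'
#' Window and step defaults (1 Mb / 100 kb, at least 10 sites per window) are
#' configurable choices: the windowed track smooths per-site binomial noise
#' the way the usual averaged SNP-index curves do.
#'
#' @param window_size_bp Window width in bp (default 1e6).
#' @param step_bp Step between window starts (default 1e5; must not exceed
#'   the window size).
#' @param min_sites Minimum defined sites for a window to enter region
#'   calling (default 10).
#' @return An object of class `window_config`.
#' @export
window_config <- function(window_size_bp = 1e6, step_bp = 1e5,
                          min_sites = 10) {
  stopifnot(window_size_bp > 0, step_bp > 0, min_sites > 0)
  if (step_bp > window_size_bp) stop("step_bp must not exceed window_size_bp")
  structure(list(window_size_bp = window_size_bp, step_bp = step_bp,
                 min_sites = min_sites), class = "window_config")
}

#' Windowed mean SNP-index and delta
#'
#' Windows are half-open `[start, start + window)` in bp, advanced by
#' `step_bp` from position 1. Sites with undefined index (zero depth) are
#' dropped before averaging. Windows with fewer than `min_sites` sites are
#' kept in the output but flagged ineligible for region calling.
#'
#' @param records A `snp_index_track`, sorted by chromosome then position.
#' @param cfg A [window_config()].
#' @param chrom_lengths Optional named vector of chromosome lengths; windows
#'   then tile the full chromosome rather than stopping at the last site.
#' @return Data frame: `chrom`, `start`, `end` (1-based inclusive),
#'   `n_sites`, `mean_index_G`, `mean_index_Y`, `mean_delta`, `eligible`.
#' @export
sliding_window_means <- function(records, cfg = window_config(),
                                 chrom_lengths = NULL) {
  stopifnot(is.data.frame(records))
  if (!inherits(cfg, "window_config")) stop("cfg must be a window_config")
  chroms <- unique(records$chrom)
  if (anyDuplicated(rle(as.character(records$chrom))$values))
    stop("records must be sorted by chromosome and position")
  res <- lapply(chroms, function(ch) {
    r <- records[records$chrom == ch, , drop = FALSE]
    if (is.unsorted(r$pos))
      stop("records must be sorted by chromosome and position")
    ok <- !is.na(r$index_G) & !is.na(r$index_Y)
    r <- r[ok, , drop = FALSE]
    pos <- r$pos
    len <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths))
      chrom_lengths[[ch]] else if (length(pos)) max(pos) else 1
    starts <- seq(1, max(1, len), by = cfg$step_bp)
    cs_g <- c(0, cumsum(r$index_G))
    cs_y <- c(0, cumsum(r$index_Y))
    cs_d <- c(0, cumsum(r$delta))
    i_lo <- findInterval(starts - 1L, pos) + 1L
    i_hi <- findInterval(starts + cfg$window_size_bp - 1L, pos)
    n <- pmax(i_hi - i_lo + 1L, 0L)
    mean_at <- function(cs) ifelse(n > 0, (cs[i_hi + 1L] - cs[i_lo]) / n, NA_real_)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + cfg$window_size_bp - 1, len),
               n_sites = n,
               mean_index_G = mean_at(cs_g),
               mean_index_Y = mean_at(cs_y),
               mean_delta = mean_at(cs_d),
               eligible = n >= cfg$min_sites,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Candidate-region calling configuration
#'
#' The defaults reproduce the thresholds used to flag the linked region in a
#' dominant-locus BSA: bulk SNP-index above 0.875 and delta above 0.5, both
#' strict inequalities, sustained over at least 3 consecutive windows.
#'
#' @param snp_index_threshold Green-bulk windowed SNP-index threshold
#'   (default 0.875), in `(0, 1]`.
#' @param delta_threshold Windowed delta threshold (default 0.5), in `(0, 1]`.
#' @param min_consecutive_windows Minimum run length of qualifying windows
#'   (default 3).
#' @return An object of class `region_call_config`.
#' @export
region_call_config <- function(snp_index_threshold = 0.875,
                               delta_threshold = 0.5,
                               min_consecutive_windows = 3) {
  stopifnot(snp_index_threshold > 0, snp_index_threshold <= 1,
            delta_threshold > 0, delta_threshold <= 1,
            min_consecutive_windows >= 1)
  structure(list(snp_index_threshold = snp_index_threshold,
                 delta_threshold = delta_threshold,
                 min_consecutive_windows = min_consecutive_windows),
            class = "region_call_config")
}

#' Call candidate regions from windowed statistics
#'
#' A window qualifies when it is eligible (enough sites) and both criteria
#' fire: green-bulk mean SNP-index strictly above `snp_index_threshold` and
#' mean delta strictly above `delta_threshold`. A region is a maximal run of
#' at least `min_consecutive_windows` qualifying windows; runs separated by
#' even a single failing window stay separate regions. The region span is the
#' union of its windows.
#'
#' @param windows Output of [sliding_window_means()].
#' @param cfg A [region_call_config()].
#' @return A `candidate_regions` data frame: `chrom`, `start`, `end`,
#'   `n_windows`, `mean_index_G`, `mean_delta`, `criteria`.
#' @export
call_candidate_regions <- function(windows, cfg = region_call_config()) {
  stopifnot(is.data.frame(windows))
  if (!inherits(cfg, "region_call_config"))
    stop("cfg must be a region_call_config")
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_windows = integer(0),
                      mean_index_G = numeric(0), mean_delta = numeric(0),
                      criteria = character(0), stringsAsFactors = FALSE)
  class(empty) <- c("candidate_regions", "data.frame")
  if (nrow(windows) == 0L) return(empty)
  res <- list()
  for (ch in unique(windows$chrom)) {
    w <- windows[windows$chrom == ch, , drop = FALSE]
    qual <- w$eligible &
      !is.na(w$mean_index_G) & w$mean_index_G > cfg$snp_index_threshold &
      !is.na(w$mean_delta) & w$mean_delta > cfg$delta_threshold
    r <- rle(qual)
    hi <- cumsum(r$lengths)
    lo <- hi - r$lengths + 1L
    for (k in which(r$values & r$lengths >= cfg$min_consecutive_windows)) {
      idx <- lo[k]:hi[k]
      res[[length(res) + 1L]] <- data.frame(
        chrom = ch, start = min(w$start[idx]), end = max(w$end[idx]),
        n_windows = length(idx),
        mean_index_G = mean(w$mean_index_G[idx]),
        mean_delta = mean(w$mean_delta[idx]),
        criteria = "snp_index>thr & delta>thr",
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else empty
  rownames(out) <- NULL
  class(out) <- c("candidate_regions", "data.frame")
  out
}
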