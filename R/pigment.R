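# Spectrophotometric pigment quantification and the colorimetric index.

#' Chlorophyll a/b and carotenoid content from extract absorbances
#'
#' Applies the standard linear equations for a 96% ethanol extract read at
#' 470, 649 and 665 nm:
#' `C_a = 13.96 D665 - 6.88 D649`,
#' `C_b = 24.96 D649 - 7.32 D665`,
#' `C_xc = (1000 D470 - 2.05 C_a - 114.8 C_b) / 245`,
#' giving concentrations in mg/L of extract. The map is linear, so replicate
#' readings may equivalently be averaged before or after conversion.
#'
#' @param d470,d649,d665 Non-negative absorbance readings (vectors recycled
#'   to a common length).
#' @param volume_l_per_g Optional extract volume per gram of fresh tissue
#'   (L/g); when given, contents are additionally scaled to mg per g fresh
#'   weight (e.g. `0.015` for 1 g of peel in 15 mL).
#' @return Data frame with columns `C_a`, `C_b`, `C_xc`.
#' @examples
#' pigment_content(0.8, 0.25, 0.5)  # C_a 5.26, C_b 2.58, C_xc 2.0124
#' @export
pigment_content <- function(d470, d649, d665, volume_l_per_g = NULL) {
  n <- max(length(d470), length(d649), length(d665))
  d470 <- rep_len(d470, n); d649 <- rep_len(d649, n); d665 <- rep_len(d665, n)
  if (any(!is.finite(c(d470, d649, d665))))
    stop("absorbances must be finite")
  if (any(c(d470, d649, d665) < 0))
    stop("negative absorbance")
  c_a <- 13.96 * d665 - 6.88 * d649
  c_b <- 24.96 * d649 - 7.32 * d665
  c_xc <- (1000 * d470 - 2.05 * c_a - 114.8 * c_b) / 245
  out <- data.frame(C_a = c_a, C_b = c_b, C_xc = c_xc)
  if (!is.null(volume_l_per_g)) {
    stopifnot(volume_l_per_g > 0)
    out <- out * volume_l_per_g
  }
  out
}

#' Citrus colour index from CIELAB readings
#'
#' `CCI = 1000 * a / (L * b)`: positive for red/orange hues, negative for
#' green, near zero for yellow-neutral. Undefined (returned as `NA` with a
#' warning) when `L * b = 0`.
#'
#' @param L Lightness, 0-100.
#' @param a Red-green axis (positive red, negative green).
#' @param b Yellow-blue axis (positive yellow, negative blue).
#' @return Numeric vector of CCI values.
#' @examples
#' cci(50, 10, 20)  # 10
#' @export
cci <- function(L, a, b) {
  n <- max(length(L), length(a), length(b))
  L <- rep_len(L, n); a <- rep_len(a, n); b <- rep_len(b, n)
  if (any(L < 0 | L > 100)) stop("L must lie in [0, 100]")
  denom <- L * b
  out <- 1000 * a / denom
  if (any(denom == 0)) {
    warning("CCI undefined where L * b = 0; returning NA")
    out[denom == 0] <- NA_real_
  }
  out
}
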