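#' Standard normal variate (SNV) transform
#'
#' Per-spectrum centering and scaling to zero mean and unit standard
#' deviation (sample, n-1, convention). SNV removes additive baseline
#' offsets and multiplicative scatter, and is idempotent.
#'
#' @param x numeric vector (one spectrum) or matrix (observations in rows).
#' @return Same shape as `x`, each spectrum with mean 0 and sd 1.
#' @export
#'
#' @examples
#' snv(c(1, 2, 3))  # -1 0 1
snv <- function(x) {
  if (is.matrix(x)) return(t(apply(x, 1, snv)))
  s <- sd(x)
  if (!is.finite(s) || s == 0)
    stop("SNV undefined for a constant spectrum (sd = 0)", call. = FALSE)
  (x - mean(x)) / s
}

#' Savitzky-Golay second derivative of a spectrum
#'
#' Second derivative with respect to the (uniform) wavenumber grid, via a
#' Savitzky-Golay polynomial filter. Edge points are handled by the filter's
#' polynomial fits within the first/last window. Band minima of the second
#' derivative sharpen overlapping absorption bands, which is how the sugar
#' fingerprint region (1200-800 cm-1) is usually inspected.
#'
#' @param x numeric vector of absorbances, or matrix (spectra in rows).
#' @param window_points odd filter length (default 15 points).
#' @param poly_order polynomial order (default 3); must be >= 2 and less
#'   than `window_points`.
#' @param step grid spacing (cm-1 per point; default 1).
#' @return Second-derivative spectrum, same shape as `x`.
#' @export
second_derivative <- function(x, window_points = 15, poly_order = 3, step = 1) {
  if (is.matrix(x))
    return(t(apply(x, 1, second_derivative, window_points, poly_order, step)))
  if (window_points %% 2 != 1 || poly_order < 2 || window_points <= poly_order)
    stop("need odd window_points > poly_order >= 2", call. = FALSE)
  if (window_points > length(x))
    stop("filter window larger than the spectrum", call. = FALSE)
  signal::sgolayfilt(x, p = poly_order, n = window_points, m = 2, ts = step)
}

#' Report dominant bands of a PCA loading vector
#'
#' Finds local extrema of a loading (or any weight vector on the wavenumber
#' grid), ranks them by absolute value and returns the strongest `top_k`
#' with the sign of their association. Used to read which spectral bands
#' drive a principal component.
#'
#' @param loading numeric loading vector.
#' @param grid wavenumber grid, same length as `loading`.
#' @param top_k maximum number of bands to report.
#' @param min_prominence extrema with |value| below this fraction of the
#'   largest |extremum| are dropped (default 0.05).
#' @param min_separation minimum spacing (grid units) between reported
#'   centers; stronger extrema win (default 100, so a broad band reports once).
#' @param smooth_points odd moving-average window applied before extremum
#'   detection (default 21; 1 disables). Symmetric smoothing leaves the peak
#'   position of a symmetric band unchanged while suppressing spurious
#'   noise extrema on broad, flat-topped bands.
#' @return Data frame with `center` (grid units), `value` and `sign`
#'   (+1/-1); zero rows for a flat loading.
#' @export
band_report <- function(loading, grid, top_k = 5, min_prominence = 0.05,
                        min_separation = 100, smooth_points = 21) {
  stopifnot(length(loading) == length(grid))
  n <- length(loading)
  if (n < 3 || diff(range(loading)) == 0)
    return(data.frame(center = numeric(0), value = numeric(0),
                      sign = numeric(0)))
  if (smooth_points > 1 && n > smooth_points) {
    kern <- rep(1 / smooth_points, smooth_points)
    sm <- stats::filter(loading, kern, sides = 2)
    pad <- (smooth_points - 1L) / 2L
    sm[seq_len(pad)] <- loading[seq_len(pad)]
    sm[(n - pad + 1L):n] <- loading[(n - pad + 1L):n]
    loading <- as.numeric(sm)
  }
  d <- diff(loading)
  # local extrema: sign change of the first difference
  is_ext <- c(FALSE, d[-1] * d[-length(d)] < 0, FALSE) |
    c(FALSE, d[-length(d)] != 0 & d[-1] == 0, FALSE)
  idx <- which(is_ext)
  if (!length(idx))
    return(data.frame(center = numeric(0), value = numeric(0),
                      sign = numeric(0)))
  ord <- idx[order(abs(loading[idx]), decreasing = TRUE)]
  ord <- ord[abs(loading[ord]) >= min_prominence * abs(loading[ord[1]])]
  keep <- integer(0)
  for (i in ord) { # greedy: strongest extremum claims its neighbourhood
    if (length(keep) >= top_k) break
    if (!length(keep) || all(abs(grid[i] - grid[keep]) >= min_separation))
      keep <- c(keep, i)
  }
  data.frame(center = grid[keep], value = loading[keep],
             sign = sign(loading[keep]))
}
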