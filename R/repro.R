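# Scan-rescan reproducibility statistics.

#' Small-sample CoV bias-correction factor
#'
#' The sample coefficient of variation computed from n repeats is biased
#' low; the standard first-order correction multiplies it by
#' `1 + 1/(4n)`. For a scan-rescan pair (n = 2) the factor is 1.125.
#'
#' @param n Number of repeated scans (>= 2).
#' @return The correction factor.
#' @export
cov_bias_factor <- function(n = 2) {
  if (n < 2) stop("cov_bias_factor: need at least 2 repeats", call. = FALSE)
  1 + 1 / (4 * n)
}

#' Bias-corrected scan-rescan coefficient of variation
#'
#' Per ROI: `CoV = sd(scan, rescan) / mean(scan, rescan) * 1.125 * 100`
#' (percent), with the two-value sample standard deviation (n - 1
#' denominator, i.e. `|scan - rescan| / sqrt(2)`) and the factor 1.125 =
#' `1 + 1/(4*2)` correcting the small-sample downward bias of a
#' two-scan CoV.
#'
#' @param values_scan,values_rescan Paired finite numeric vectors (one
#'   entry per ROI or subject).
#' @return CoV per pair, percent.
#' @examples
#' scan_rescan_cov(23.0, 23.2)  # ~0.689 %
#' @export
scan_rescan_cov <- function(values_scan, values_rescan) {
  if (length(values_scan) != length(values_rescan))
    stop("scan_rescan_cov: inputs must be paired", call. = FALSE)
  if (!all(is.finite(values_scan)) || !all(is.finite(values_rescan)))
    stop("scan_rescan_cov: values must be finite", call. = FALSE)
  m <- (values_scan + values_rescan) / 2
  if (any(m == 0))
    stop("scan_rescan_cov: zero scan-rescan mean", call. = FALSE)
  s <- abs(values_scan - values_rescan) / sqrt(2)
  s / m * cov_bias_factor(2) * 100
}

#' Bland-Altman agreement analysis of paired measurements
#'
#' Bias is the mean scan - rescan difference; the 95% limits of agreement
#' are `bias +/- 1.96 * sd(differences)` (n - 1 denominator).
#'
#' @param scan,rescan Paired numeric vectors (>= 2 pairs), or `scan` may be
#'   a 2-column matrix/data.frame of pairs.
#' @return A `bland_altman` object: list with `bias`, `loa_low`,
#'   `loa_high`, `sd_diff`, `n`, and the per-pair `means`/`differences`
#'   used for plotting.
#' @examples
#' bland_altman(c(20, 22, 24), c(21, 21, 23))
#' @export
bland_altman <- function(scan, rescan = NULL) {
  if (is.null(rescan)) {
    scan <- as.matrix(scan)
    if (ncol(scan) != 2L) stop("bland_altman: need pairs", call. = FALSE)
    rescan <- scan[, 2]; scan <- scan[, 1]
  }
  if (length(scan) != length(rescan))
    stop("bland_altman: inputs must be paired", call. = FALSE)
  if (length(scan) < 2L)
    stop("bland_altman: need at least 2 pairs", call. = FALSE)
  d <- scan - rescan
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  structure(list(bias = bias,
                 loa_low = bias - 1.96 * sd_diff,
                 loa_high = bias + 1.96 * sd_diff,
                 sd_diff = sd_diff, n = length(d),
                 means = (scan + rescan) / 2, differences = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n = %d, bias = %.4g, 95%% LoA [%.4g, %.4g]\n",
              x$n, x$bias, x$loa_low, x$loa_high))
  invisible(x)
}
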