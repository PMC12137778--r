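# MTR maps, ROI statistics and histograms.

# Background noise scale estimated from a border shell of the volume, where
# no phantom/tissue signal is expected.
.estimate_background_sd <- function(img, border = 2L) {
  d <- dim(img)
  border <- min(border, floor(min(d[1:2]) / 4))
  if (border < 1L) return(0)
  shell <- c(img[c(seq_len(border), d[1] - seq_len(border) + 1L), , ],
             img[, c(seq_len(border), d[2] - seq_len(border) + 1L), ])
  stats::sd(shell)
}

#' Compute an MTR map from a low/high RF-energy image pair
#'
#' `MTR = (MT_low - MT_high) / MT_low * 100` (percent), computed only where
#' `MT_low` exceeds a validity threshold; everything else is marked missing
#' (`NA`), never silently zeroed. The high-flip-angle image sits close to
#' the noise floor at ultra-low field, so voxels whose `MT_low` is itself
#' noise-dominated would produce meaningless ratios. Values are not
#' clipped: negative noise-driven MTR values are retained so histograms
#' reflect the raw statistic.
#'
#' @param low,high 3D magnitude arrays of equal shape (`MT_low` acquired at
#'   the low flip angle, `MT_high` at the high one).
#' @param threshold Absolute validity threshold on `MT_low`; if `NULL`
#'   (default) it is `k_sd` times the background noise sd.
#' @param k_sd Multiplier for the automatic threshold (default 5).
#' @param background_sd Background noise sd; if `NULL`, estimated from the
#'   border shell of `low`.
#' @return An `mtr_result`: list with `mtr` (3D array, percent, `NA` where
#'   invalid), `valid_mask` (logical 3D array) and `provenance` (threshold
#'   actually applied, voxel counts).
#' @examples
#' low <- array(100, c(4, 4, 2)); high <- array(77, c(4, 4, 2))
#' r <- compute_mtr_map(low, high, threshold = 0)
#' r$mtr[1, 1, 1]  # 23
#' @export
compute_mtr_map <- function(low, high, threshold = NULL, k_sd = 5,
                            background_sd = NULL) {
  if (!identical(dim(low), dim(high)))
    stop("compute_mtr_map: 'low' and 'high' shapes differ", call. = FALSE)
  if (is.null(threshold)) {
    if (is.null(background_sd)) background_sd <- .estimate_background_sd(low)
    threshold <- k_sd * background_sd
  }
  valid <- is.finite(low) & is.finite(high) & (low > threshold)
  if (!any(valid))
    stop("compute_mtr_map: no voxel exceeds the MT_low validity threshold (",
         signif(threshold, 4), ")", call. = FALSE)
  mtr <- array(NA_real_, dim(low))
  mtr[valid] <- (low[valid] - high[valid]) / low[valid] * 100
  structure(list(mtr = mtr, valid_mask = valid,
                 provenance = list(threshold = threshold,
                                   n_valid = sum(valid),
                                   n_total = length(low))),
            class = "mtr_result")
}

#' @export
print.mtr_result <- function(x, ...) {
  cat(sprintf("<mtr_result> %d/%d valid voxels (MT_low > %.4g)\n",
              x$provenance$n_valid, x$provenance$n_total,
              x$provenance$threshold))
  v <- x$mtr[x$valid_mask]
  cat(sprintf("  MTR: mean %.2f%%, sd %.2f%%\n", mean(v), stats::sd(v)))
  invisible(x)
}

.as_mtr_array <- function(x) {
  if (inherits(x, "mtr_result")) x$mtr
  else if (is.array(x)) x
  else stop("expected an 'mtr_result' or a 3D array", call. = FALSE)
}

#' Per-ROI statistics of an MTR map
#'
#' Mean, sample standard deviation (n - 1 denominator) and valid-voxel
#' count per labelled region. Empty ROIs (no valid voxel) yield `NA`
#' statistics with a zero count — explicitly missing, not zero.
#'
#' @param result An `mtr_result` or a plain 3D array (NA = invalid).
#' @param labels Integer 3D label array aligned to the map (e.g.
#'   `parameter_maps$label`), or a `parameter_maps` object.
#' @param label_names Optional data.frame with columns `index`, `label`
#'   naming the ROIs (taken from `labels` when it is a `parameter_maps`).
#' @param include_background Include label 0 in the table (default FALSE).
#' @return data.frame with columns `index`, `label`, `mean`, `sd`,
#'   `n_voxels`.
#' @export
roi_statistics <- function(result, labels, label_names = NULL,
                           include_background = FALSE) {
  mtr <- .as_mtr_array(result)
  if (inherits(labels, "parameter_maps")) {
    if (is.null(label_names)) label_names <- labels$labels
    labels <- labels$label
  }
  if (!identical(dim(mtr), dim(labels)))
    stop("roi_statistics: label map shape does not match the MTR map",
         call. = FALSE)
  idx <- sort(unique(as.integer(labels)))
  if (!include_background) idx <- setdiff(idx, 0L)
  rows <- lapply(idx, function(i) {
    v <- mtr[labels == i]
    v <- v[is.finite(v)]
    nm <- if (!is.null(label_names) && i %in% label_names$index)
      label_names$label[match(i, label_names$index)] else as.character(i)
    if (length(v) == 0)
      data.frame(index = i, label = nm, mean = NA_real_, sd = NA_real_,
                 n_voxels = 0L, stringsAsFactors = FALSE)
    else
      data.frame(index = i, label = nm, mean = mean(v),
                 sd = if (length(v) > 1) stats::sd(v) else NA_real_,
                 n_voxels = length(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Histogram of MTR values
#'
#' Bins valid (optionally masked) MTR values at a fixed bin width. The
#' default 1-percentage-point bins span [-20, 60]; the range is widened
#' automatically so that every valid voxel is counted (counts always sum to
#' the number of valid masked voxels).
#'
#' @param result An `mtr_result` or 3D array.
#' @param mask Optional logical 3D array restricting the voxels.
#' @param bin_width Bin width in percentage points (> 0).
#' @param limits Nominal lower/upper histogram limits, percent.
#' @return data.frame with columns `bin_low`, `bin_high`, `mid`, `count`.
#' @export
mtr_histogram <- function(result, mask = NULL, bin_width = 1,
                          limits = c(-20, 60)) {
  if (bin_width <= 0) stop("mtr_histogram: 'bin_width' must be > 0",
                           call. = FALSE)
  mtr <- .as_mtr_array(result)
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(mtr)))
      stop("mtr_histogram: mask shape mismatch", call. = FALSE)
    mtr <- mtr[mask]
  }
  v <- mtr[is.finite(mtr)]
  if (length(v) == 0) stop("mtr_histogram: no valid voxels in mask",
                           call. = FALSE)
  lo <- min(limits[1], floor(min(v) / bin_width) * bin_width)
  hi <- max(limits[2], ceiling(max(v) / bin_width) * bin_width)
  breaks <- seq(lo, hi + bin_width / 2, by = bin_width)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = FALSE)
  data.frame(bin_low = utils::head(h$breaks, -1),
             bin_high = utils::tail(h$breaks, -1),
             mid = h$mids, count = h$counts)
}
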