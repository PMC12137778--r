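# Image-domain utilities: coil combination, non-local means denoising.

#' Root-sum-of-squares coil combination
#'
#' @param coils Per-coil complex (or real) images: a 4D array with coils on
#'   the last axis, or a list of equally shaped 3D arrays.
#' @return 3D array of non-negative magnitudes (voxel-size attribute
#'   preserved when present).
#' @examples
#' a <- array(3, c(2, 2, 1)); b <- array(4, c(2, 2, 1))
#' rss_combine(list(a, b))[1, 1, 1]  # 5
#' @export
rss_combine <- function(coils) {
  if (is.list(coils)) {
    dims <- dim(coils[[1]])
    for (x in coils)
      if (!identical(dim(x), dims))
        stop("rss_combine: coil image shapes differ", call. = FALSE)
    acc <- array(0, dims)
    for (x in coils) acc <- acc + Mod(x)^2
  } else {
    d <- dim(coils)
    if (is.null(d) || length(d) != 4L)
      stop("rss_combine: expected a 4D array (x, y, z, coil) or a list of ",
           "3D arrays", call. = FALSE)
    dims <- d[1:3]
    acc <- array(0, dims)
    for (cc in seq_len(d[4])) acc <- acc + Mod(coils[, , , cc, drop = TRUE])^2
    if (d[4] == 1L) acc <- array(acc, dims)
  }
  out <- sqrt(acc)
  vox <- attr(coils, "voxel")
  if (!is.null(vox)) attr(out, "voxel") <- vox
  out
}

# Replicate-pad a 3D array by r voxels on every side.
.pad_replicate <- function(a, r) {
  if (r == 0) return(a)
  d <- dim(a)
  ix <- pmin(pmax(seq_len(d[1] + 2 * r) - r, 1L), d[1])
  iy <- pmin(pmax(seq_len(d[2] + 2 * r) - r, 1L), d[2])
  iz <- pmin(pmax(seq_len(d[3] + 2 * r) - r, 1L), d[3])
  a[ix, iy, iz, drop = FALSE]
}

# Sliding-window box mean of half-width r along every axis, same-size
# output, replicate boundary handling; cumulative sums per axis.
.box_mean3d <- function(a, r) {
  if (r == 0) return(a)
  a <- .pad_replicate(a, r)
  w <- 2L * r + 1L
  for (ax in 1:3) {
    d <- dim(a)
    m <- matrix(aperm(a, c(ax, setdiff(1:3, ax))), nrow = d[ax])
    cs <- rbind(0, apply(m, 2, cumsum))
    sums <- cs[(w + 1):(d[ax] + 1), , drop = FALSE] -
            cs[1:(d[ax] - w + 1), , drop = FALSE]
    newd <- d; newd[ax] <- d[ax] - w + 1L
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(array(sums, newd[perm]), order(perm))
  }
  a / w^3
}

#' Non-local means denoising of a magnitude image
#'
#' Standard patch-based non-local means: each voxel is replaced by a
#' weighted mean over the voxels in its search window, weights
#' `exp(-ssd / h^2)` where `ssd` is the mean squared difference between the
#' two voxels' patches and `h` the smoothing strength. A constant image and
#' `smoothing = 0` are returned unchanged; the output is a convex
#' combination of input intensities, so it is non-negative whenever the
#' input is.
#'
#' Denoising is optional in the analysis pipeline: patch averaging of
#' magnitude images can leave MTR maps looking patchy, so quantitative
#' checks default to noise-free or pre-denoise data.
#'
#' @param img 3D array of non-negative intensities.
#' @param patch_radius Half-width of the comparison patch, voxels (>= 0).
#' @param search_radius Half-width of the search window, voxels (>= 0).
#' @param smoothing Weighting bandwidth `h` (a.u., same scale as the image
#'   intensities); `0` disables filtering.
#' @return Denoised 3D array, same shape.
#' @export
nlm_denoise <- function(img, patch_radius = 1, search_radius = 2,
                        smoothing = 0.1) {
  if (patch_radius < 0 || search_radius < 0)
    stop("nlm_denoise: radii must be >= 0", call. = FALSE)
  if (smoothing < 0) stop("nlm_denoise: 'smoothing' must be >= 0",
                          call. = FALSE)
  d <- dim(img)
  if (is.null(d) || length(d) != 3L)
    stop("nlm_denoise: 'img' must be a 3D array", call. = FALSE)
  if (smoothing == 0 || search_radius == 0) return(img)

  sr <- as.integer(search_radius)
  padded <- .pad_replicate(img, sr)
  num <- array(0, d)
  den <- array(0, d)
  ix <- (sr + 1):(sr + d[1]); iy <- (sr + 1):(sr + d[2])
  iz <- (sr + 1):(sr + d[3])
  for (dx in -sr:sr) for (dy in -sr:sr) for (dz in -sr:sr) {
    shifted <- padded[ix + dx, iy + dy, iz + dz, drop = FALSE]
    ssd <- .box_mean3d((img - shifted)^2, as.integer(patch_radius))
    w <- exp(-ssd / smoothing^2)
    num <- num + w * shifted
    den <- den + w
  }
  num / den
}
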