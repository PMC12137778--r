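#' Non-balanced SSFP acquisition protocol
#'
#' Parameters of a spoiled, non-balanced steady-state free precession
#' acquisition. The same protocol drives both observable pathways: the
#' post-pulse FID (`F0`, the FISP / SSFP-FID observable) and the refocusing
#' echo (`F-1`, the PSIF / SSFP-Echo observable sampled just before the next
#' pulse).
#'
#' @param tr Repetition time, ms.
#' @param flip_angle Nominal flip angle, degrees, in `[0, 420]` (0 means no
#'   excitation and yields zero signal). Angles above 360 degrees are
#'   legitimate at ultra-low field where RF deposition is not SAR-limited.
#' @param pulse_width Rectangular (hard) RF pulse duration, microseconds;
#'   must be shorter than `tr`.
#' @param sequence Which pathway is "the" signal of this protocol:
#'   `"psif_echo"` (default) or `"fid"`.
#' @param fov Field of view, 3 extents in mm (RL x AP x FH).
#' @param voxel Voxel size, 3 extents in mm. `fov / voxel` must be a whole
#'   number of voxels along every axis.
#' @param bandwidth Readout bandwidth, kHz (metadata only).
#' @param n_epg_states Number of retained configuration orders K in the EPG
#'   engine (>= 4). Truncation error can be probed by doubling it.
#'
#' @return An object of class `sequence_protocol`.
#' @examples
#' default_protocol()
#' @export
sequence_protocol <- function(tr = 12.03, flip_angle = 60, pulse_width = 220,
                              sequence = c("psif_echo", "fid"),
                              fov = c(180, 220, 200), voxel = c(2, 2, 5),
                              bandwidth = 18, n_epg_states = 40) {
  sequence <- match.arg(sequence)
  if (!is.numeric(tr) || tr <= 0) stop("sequence_protocol: 'tr' must be > 0",
                                       call. = FALSE)
  if (!is.numeric(flip_angle) || flip_angle < 0 || flip_angle > 420)
    stop("sequence_protocol: 'flip_angle' must lie in [0, 420] degrees",
         call. = FALSE)
  if (!is.numeric(pulse_width) || pulse_width <= 0)
    stop("sequence_protocol: 'pulse_width' must be > 0", call. = FALSE)
  if (pulse_width / 1000 >= tr)
    stop("sequence_protocol: 'pulse_width' (", pulse_width,
         " us) must be shorter than 'tr' (", tr, " ms)", call. = FALSE)
  if (length(fov) != 3L || length(voxel) != 3L || any(fov <= 0) ||
      any(voxel <= 0))
    stop("sequence_protocol: 'fov' and 'voxel' must be 3 positive extents",
         call. = FALSE)
  mat <- fov / voxel
  if (any(abs(mat - round(mat)) > 1e-8))
    stop("sequence_protocol: fov/voxel must be a whole number of voxels ",
         "per axis (got ", paste(signif(mat, 6), collapse = " x "), ")",
         call. = FALSE)
  if (!is.numeric(n_epg_states) || n_epg_states < 4)
    stop("sequence_protocol: 'n_epg_states' must be >= 4", call. = FALSE)
  structure(list(
    tr = as.numeric(tr), flip_angle = as.numeric(flip_angle),
    pulse_width = as.numeric(pulse_width), sequence = sequence,
    fov = as.numeric(fov), voxel = as.numeric(voxel),
    matrix_size = as.integer(round(mat)),
    bandwidth = as.numeric(bandwidth),
    n_epg_states = as.integer(n_epg_states)
  ), class = "sequence_protocol")
}

#' @rdname sequence_protocol
#' @details `default_protocol()` returns the in vivo acquisition protocol:
#'   PSIF echo, TR = 12.03 ms, 220 us hard pulse, 2 x 2 x 5 mm voxels over a
#'   180 x 220 x 200 mm FOV, 18 kHz bandwidth.
#' @export
default_protocol <- function() sequence_protocol()

#' @export
print.sequence_protocol <- function(x, ...) {
  cat("<sequence_protocol> ", x$sequence, "\n", sep = "")
  cat(sprintf("  TR %g ms | flip %g deg | pulse %g us | BW %g kHz\n",
              x$tr, x$flip_angle, x$pulse_width, x$bandwidth))
  cat(sprintf("  FOV %s mm | voxel %s mm | matrix %s | K = %d\n",
              paste(x$fov, collapse = "x"), paste(x$voxel, collapse = "x"),
              paste(x$matrix_size, collapse = "x"), x$n_epg_states))
  invisible(x)
}
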