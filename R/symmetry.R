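# Sweep-curve symmetry analysis and flip-angle-pair selection.

.curve_xy <- function(curve) {
  if (inherits(curve, "sweep_curve")) list(x = curve$x, y = curve$signal)
  else if (is.list(curve) && !is.null(curve$x) &&
           (!is.null(curve$signal) || !is.null(curve$y)))
    list(x = curve$x, y = curve$signal %||% curve$y)
  else stop("expected a sweep_curve or a list with x and signal",
            call. = FALSE)
}

.match_x <- function(x, value, eps) {
  hit <- which(abs(x - value) <= eps)
  if (length(hit) == 0) NA_integer_ else hit[1]
}

#' Locate the symmetry axis of a flip-angle response curve
#'
#' Scores every grid angle as a candidate mirror axis by the mean absolute
#' mismatch `|S(a* - d) - S(a* + d)|` over all offsets `d` for which both
#' mirrored angles lie on the grid, and returns the angle with the smallest
#' score (ties toward the smaller angle). Candidates supported by fewer
#' than `min_pairs` mirrored pairs are excluded, otherwise near-edge angles
#' with almost no constraints would win by default. For a single-pool
#' (no-MT) material the PSIF response is symmetric about 180 degrees; a
#' transmit miscalibration `b1_scale = s` moves the axis to the nominal
#' angle `180/s`.
#'
#' @param curve A `sweep_curve` (or list with `x`, `signal`).
#' @param min_pairs Minimum number of mirrored pairs a candidate needs.
#' @return The symmetry angle, degrees.
#' @export
find_symmetry_point <- function(curve, min_pairs = 3) {
  cv <- .curve_xy(curve)
  x <- cv$x; y <- cv$y
  n <- length(x)
  if (n < 2 * min_pairs + 1)
    stop("find_symmetry_point: curve span insufficient (need at least ",
         2 * min_pairs + 1, " grid points)", call. = FALSE)
  eps <- 1e-6 * max(1, max(abs(x)))
  cand <- rep(NA_real_, n); score <- rep(Inf, n)
  for (j in seq_len(n)) {
    a <- x[j]
    left <- which(x < a - eps)
    if (length(left) < min_pairs) next
    mirror <- vapply(2 * a - x[left], .match_x, integer(1), x = x, eps = eps)
    ok <- !is.na(mirror)
    if (sum(ok) < min_pairs) next
    cand[j] <- a
    score[j] <- mean(abs(y[left[ok]] - y[mirror[ok]]))
  }
  if (!any(is.finite(score)))
    stop("find_symmetry_point: no candidate axis has ", min_pairs,
         " mirrored pairs on the grid", call. = FALSE)
  # a curve can have several exact mirror axes (e.g. both 180 and 360
  # degrees for an ideal single-pool response swept past one full turn);
  # numerically tied scores resolve toward the smaller angle
  tie_tol <- 1e-9 * max(abs(y), 1e-300)
  eligible <- which(score <= min(score) + tie_tol)
  cand[eligible[1]]
}

#' Signal asymmetry at a mirrored flip-angle pair
#'
#' `[S(a* - d) - S(a* + d)] / [S(a* - d) + S(a* + d)]`: zero for a material
#' with no bound pool (mirror-symmetric response) and positive when MT
#' saturation — which grows quadratically with flip angle — depresses the
#' high-flip-angle side.
#'
#' @param curve A `sweep_curve`.
#' @param symmetry_point Mirror axis, degrees (e.g. from
#'   [find_symmetry_point()]).
#' @param delta Offset from the axis, degrees; both `symmetry_point +/-
#'   delta` must be on the curve's grid.
#' @return Dimensionless asymmetry index.
#' @export
asymmetry_index <- function(curve, symmetry_point, delta) {
  cv <- .curve_xy(curve)
  eps <- 1e-6 * max(1, max(abs(cv$x)))
  i_lo <- .match_x(cv$x, symmetry_point - delta, eps)
  i_hi <- .match_x(cv$x, symmetry_point + delta, eps)
  if (is.na(i_lo) || is.na(i_hi))
    stop("asymmetry_index: ", symmetry_point, " +/- ", delta,
         " degrees not on the curve's grid", call. = FALSE)
  s_lo <- cv$y[i_lo]; s_hi <- cv$y[i_hi]
  if (s_lo + s_hi == 0)
    stop("asymmetry_index: zero denominator", call. = FALSE)
  (s_lo - s_hi) / (s_lo + s_hi)
}

#' Choose the differential-MT flip-angle pair from two sweep curves
#'
#' Enumerates all pairs mirrored about the symmetry axis of the no-MT
#' reference curve, keeps those whose reference signals match within
#' `signal_match_tol` (relative to the curve maximum — equal water signal
#' in both images means the ratio cancels everything but MT) and exceed
#' `min_signal_frac` of the maximum (both images must stay well above the
#' noise floor), and among those returns the pair with the largest
#' predicted MTR on the MT curve. Ties prefer the higher reference signal,
#' then the smaller low angle.
#'
#' @param curve_no_mt Reference `sweep_curve` of a material without a bound
#'   pool (e.g. water).
#' @param curve_mt `sweep_curve` of the MT material of interest, on the
#'   same grid.
#' @param signal_match_tol Maximum allowed relative mismatch of the two
#'   reference signals, in (0, 1].
#' @param min_signal_frac Minimum reference signal as a fraction of the
#'   curve maximum, in (0, 1].
#' @param symmetry_point Mirror axis; found from `curve_no_mt` when `NULL`.
#' @return A `flip_angle_pair`: list with `pair` (low, high; degrees),
#'   `symmetry_point`, `predicted_mtr` (percent), and the table of all
#'   `feasible` pairs.
#' @export
choose_flip_angle_pair <- function(curve_no_mt, curve_mt,
                                   signal_match_tol = 0.05,
                                   min_signal_frac = 0.9,
                                   symmetry_point = NULL) {
  c0 <- .curve_xy(curve_no_mt)
  c1 <- .curve_xy(curve_mt)
  if (length(c0$x) != length(c1$x) || any(abs(c0$x - c1$x) > 1e-6))
    stop("choose_flip_angle_pair: the two curves must share one grid",
         call. = FALSE)
  if (signal_match_tol <= 0 || signal_match_tol > 1 ||
      min_signal_frac <= 0 || min_signal_frac > 1)
    stop("choose_flip_angle_pair: tolerances must lie in (0, 1]",
         call. = FALSE)
  if (is.null(symmetry_point))
    symmetry_point <- find_symmetry_point(curve_no_mt)
  x <- c0$x; s0 <- c0$y; s1 <- c1$y
  eps <- 1e-6 * max(1, max(abs(x)))
  smax <- max(s0)
  rows <- list()
  for (i in seq_along(x)) {
    if (x[i] >= symmetry_point - eps) break
    j <- .match_x(x, 2 * symmetry_point - x[i], eps)
    if (is.na(j)) next
    match_ok <- abs(s0[i] - s0[j]) / smax <= signal_match_tol
    frac_ok <- s0[i] >= min_signal_frac * smax
    if (!match_ok || !frac_ok || s1[i] <= 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      low = x[i], high = x[j], s_ref_low = s0[i], s_ref_high = s0[j],
      mtr = (s1[i] - s1[j]) / s1[i] * 100)
  }
  if (length(rows) == 0)
    stop("choose_flip_angle_pair: no feasible symmetric pair under the ",
         "given tolerances", call. = FALSE)
  feas <- do.call(rbind, rows)
  o <- order(-feas$mtr, -feas$s_ref_low, feas$low)
  best <- feas[o[1], ]
  structure(list(pair = c(low = best$low, high = best$high),
                 symmetry_point = symmetry_point,
                 predicted_mtr = best$mtr,
                 feasible = feas),
            class = "flip_angle_pair")
}

#' @export
print.flip_angle_pair <- function(x, ...) {
  cat(sprintf("<flip_angle_pair> %g / %g degrees (axis %g), predicted MTR %.2f%% (%d feasible pairs)\n",
              x$pair["low"], x$pair["high"], x$symmetry_point,
              x$predicted_mtr, nrow(x$feasible)))
  invisible(x)
}
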