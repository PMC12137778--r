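#' Default flip-angle sweep grid
#'
#' The flip-angle experiment grid: 1 degree plus 10..420 degrees in steps of
#' 10, i.e. 43 acquisitions.
#'
#' @return Numeric vector of 43 angles, degrees.
#' @export
default_flip_angles <- function() c(1, seq(10, 420, by = 10))

#' Default pulse-width sweep grid
#'
#' 40 to 220 microseconds in 20 us steps (10 values) at fixed flip angle.
#'
#' @return Numeric vector of pulse widths, microseconds.
#' @export
default_pulse_widths <- function() seq(40, 220, by = 20)

.sweep_curve <- function(x, signals, sweep_kind, protocol, tissue) {
  o <- order(x)
  structure(list(x = x[o], signal = signals[o], sweep_kind = sweep_kind,
                 protocol = protocol,
                 tissue_label = tissue$label, tissue = tissue),
            class = "sweep_curve")
}

#' @export
print.sweep_curve <- function(x, ...) {
  cat(sprintf("<sweep_curve> %s, %d points, tissue '%s' (%s pathway)\n",
              x$sweep_kind, length(x$x),
              if (is.na(x$tissue_label)) "?" else x$tissue_label,
              x$protocol$sequence))
  invisible(x)
}

#' @export
as.data.frame.sweep_curve <- function(x, ...) {
  data.frame(x = x$x, signal = x$signal, sweep_kind = x$sweep_kind,
             tissue_label = if (is.na(x$tissue_label)) "" else x$tissue_label,
             stringsAsFactors = FALSE)
}

.signal_for <- function(protocol, sig) {
  if (protocol$sequence == "psif_echo") sig$s_echo else sig$s_fid
}

#' Steady-state signal versus flip angle
#'
#' Runs the steady-state simulator once per flip angle at fixed TR and pulse
#' width and collects the observable of `protocol$sequence` (echo for PSIF,
#' FID for FISP). This is the sweep from which the MT symmetry analysis and
#' the flip-angle-pair choice are made: without a bound pool the echo
#' response is mirror-symmetric about 180 degrees, and bound-pool saturation
#' (growing with the square of the flip angle) breaks that symmetry.
#'
#' @param angles Flip angles in degrees; default [default_flip_angles()].
#' @param protocol,tissue,field See [ssfp_steady_state()].
#' @return A `sweep_curve` (ascending angles).
#' @examples
#' \donttest{
#' fa <- flip_angle_sweep(seq(10, 350, 10), default_protocol(),
#'                        tissue_presets("water"))
#' find_symmetry_point(fa)
#' }
#' @export
flip_angle_sweep <- function(angles = default_flip_angles(),
                             protocol = default_protocol(),
                             tissue, field = field_conditions()) {
  if (length(angles) == 0) stop("flip_angle_sweep: empty angle list",
                                call. = FALSE)
  sig <- vapply(angles, function(a) {
    p <- protocol
    p$flip_angle <- a
    res <- tryCatch(ssfp_steady_state(p, tissue, field),
                    ulfmt_convergence_error = function(e)
                      stop("flip_angle_sweep: solver failed at flip angle ",
                           a, " deg: ", conditionMessage(e), call. = FALSE))
    .signal_for(protocol, res)
  }, numeric(1))
  .sweep_curve(angles, sig, "flip_angle", protocol, tissue)
}

#' Steady-state signal versus RF pulse width
#'
#' Sweeps the hard-pulse duration at fixed flip angle and TR. At fixed flip
#' angle the mean RF amplitude scales as `1/tau`, so the bound-pool
#' saturation rate integrates to `W * tau ~ 1/tau`: MT materials gain signal
#' as the pulse lengthens, single-pool materials are unaffected.
#'
#' @param widths Pulse widths in microseconds; default
#'   [default_pulse_widths()]. All must be shorter than TR.
#' @param protocol,tissue,field See [ssfp_steady_state()]; the protocol's
#'   `flip_angle` (60 degrees in [default_protocol()]) is held fixed.
#' @return A `sweep_curve` (ascending widths).
#' @export
pulse_width_sweep <- function(widths = default_pulse_widths(),
                              protocol = default_protocol(),
                              tissue, field = field_conditions()) {
  if (length(widths) == 0) stop("pulse_width_sweep: empty width list",
                                call. = FALSE)
  if (any(widths / 1000 >= protocol$tr))
    stop("pulse_width_sweep: widths ",
         paste(widths[widths / 1000 >= protocol$tr], collapse = ", "),
         " us are not shorter than TR = ", protocol$tr, " ms", call. = FALSE)
  sig <- vapply(widths, function(w) {
    p <- protocol
    p$pulse_width <- w
    res <- tryCatch(ssfp_steady_state(p, tissue, field),
                    ulfmt_convergence_error = function(e)
                      stop("pulse_width_sweep: solver failed at width ",
                           w, " us: ", conditionMessage(e), call. = FALSE))
    .signal_for(protocol, res)
  }, numeric(1))
  .sweep_curve(widths, sig, "pulse_width", protocol, tissue)
}

#' Predicted MTR of a flip-angle pair
#'
#' Simulates the steady-state signal at the low and high flip angles of a
#' differential MT acquisition and returns
#' `MTR = (S_low - S_high) / S_low * 100` in percent.
#'
#' @param pair Numeric length-2: `(low_angle, high_angle)` in degrees.
#' @param protocol,tissue,field See [ssfp_steady_state()].
#' @return MTR in percent.
#' @examples
#' \donttest{
#' predict_mtr(c(60, 300), default_protocol(),
#'             tissue_presets("conditioner_like"))
#' }
#' @export
predict_mtr <- function(pair, protocol = default_protocol(), tissue,
                        field = field_conditions()) {
  if (length(pair) != 2L) stop("predict_mtr: 'pair' must be (low, high)",
                               call. = FALSE)
  s <- vapply(pair, function(a) {
    p <- protocol
    p$flip_angle <- a
    .signal_for(protocol, ssfp_steady_state(p, tissue, field))
  }, numeric(1))
  if (s[1] <= 0)
    stop("predict_mtr: signal at the low flip angle is not positive",
         call. = FALSE)
  (s[1] - s[2]) / s[1] * 100
}
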