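# Steady-state solvers: EPG fixed-point iteration and the brute-force
# isochromat oracle used to validate it.

.convergence_error <- function(msg, n_iter, s_fid, s_echo) {
  stop(structure(class = c("ulfmt_convergence_error", "error", "condition"),
                 list(message = paste0(msg, " (", n_iter, " iterations; ",
                                       "last s_fid = ", signif(s_fid, 6),
                                       ", s_echo = ", signif(s_echo, 6), ")"),
                      call = NULL)))
}

# Geometric-extrapolation stopping rule. Successive signal changes of a
# linearly contracting fixed point shrink by the contraction ratio r; the
# remaining error is ~ d * r / (1 - r), which for slowly converging tissues
# (T1 >> TR) is much larger than the last change d itself. We therefore stop
# on the projected remaining error, not on d.
.projected_error <- function(d, d_prev) {
  if (d == 0) return(0)
  if (!is.finite(d_prev) || d_prev <= 0 || d >= d_prev) return(Inf)
  r <- d / d_prev
  d * r / (1 - r)
}

#' Two-pool non-balanced SSFP steady state (EPG engine)
#'
#' Iterates one spoiled TR — bound-pool saturation + instantaneous RF
#' rotation of the free pool, relaxation/exchange over the TR, ideal
#' spoiler shift — from thermal equilibrium (or a supplied state) until both
#' observable signals reach a fixed point. The FID observable is `|F_0|`
#' sampled right after the pulse (FISP / SSFP-FID); the echo observable is
#' the `|F_-1|` refocusing pathway sampled just before the next pulse
#' (PSIF / SSFP-Echo).
#'
#' @param protocol A [sequence_protocol()].
#' @param tissue A [tissue_params()].
#' @param field A [field_conditions()]; the effective flip angle is
#'   `b1_scale * flip_angle` and also scales the saturation amplitude.
#' @param init_state Optional starting `epg_state` (the steady state is
#'   independent of it; exposed to allow verifying exactly that).
#' @param tol Relative tolerance on the projected remaining error of both
#'   signals.
#' @param max_iter Iteration cap; exceeding it raises a
#'   `ulfmt_convergence_error` with diagnostics.
#' @return An object of class `steady_state_signal`: list with `s_fid`,
#'   `s_echo` (magnitudes, a.u.), `converged`, `n_iterations`.
#' @examples
#' sig <- ssfp_steady_state(default_protocol(), tissue_presets("water"))
#' sig$s_echo
#' @export
ssfp_steady_state <- function(protocol, tissue, field = field_conditions(),
                              init_state = NULL, tol = 1e-10,
                              max_iter = 10000) {
  alpha_eff <- field$b1_scale * protocol$flip_angle
  # the hard pulse is instantaneous for the free pool: relaxation spans the
  # full TR; the pulse width only modulates the bound-pool saturation
  dt <- protocol$tr
  sat <- if (tissue$bound_fraction > 0)
    bound_pool_saturation_factor(alpha_eff, protocol$pulse_width, tissue)
  else 1
  prop <- .relax_propagator(tissue, dt)
  state <- if (is.null(init_state)) epg_init(tissue, protocol$n_epg_states)
           else init_state

  s_prev <- c(NA_real_, NA_real_)
  d_prev <- NA_real_
  ok_runs <- 0L
  for (it in seq_len(max_iter)) {
    state$zb <- state$zb * sat
    state <- epg_rf_rotation(state, alpha_eff)
    s_fid <- Mod(state$fp[1])
    state <- relax_exchange_interval(state, dt, tissue, prop = prop)
    s_echo <- Mod(state$fm[2])
    state <- epg_spoiler_shift(state)

    s <- c(s_fid, s_echo)
    if (!all(is.finite(s)))
      .convergence_error("ssfp_steady_state: signal diverged", it,
                         s_fid, s_echo)
    if (!anyNA(s_prev)) {
      scale <- max(s, 1e-30)
      d <- max(abs(s - s_prev)) / scale
      proj <- .projected_error(d, d_prev)
      ok_runs <- if (proj <= tol) ok_runs + 1L else 0L
      if (ok_runs >= 2L)
        return(structure(list(s_fid = s_fid, s_echo = s_echo,
                              converged = TRUE, n_iterations = it),
                         class = "steady_state_signal"))
      d_prev <- d
    }
    s_prev <- s
  }
  .convergence_error("ssfp_steady_state: no convergence", max_iter,
                     s_prev[1], s_prev[2])
}

#' Brute-force isochromat steady-state oracle
#'
#' Independent validation of the EPG engine: `n_isochromats` spins uniformly
#' spanning one full cycle (2*pi) of spoiler dephasing per TR are evolved
#' with the full two-pool Bloch-McConnell longitudinal dynamics and
#' per-isochromat precession, using the same hard-pulse model. The FID
#' signal is the magnitude of the complex mean transverse magnetization just
#' after the pulse; the echo is the mean just before the next pulse. As the
#' isochromat count grows, this converges to the exact ensemble signal the
#' EPG configuration states represent.
#'
#' @inheritParams ssfp_steady_state
#' @param n_isochromats Number of isochromats (>= 500 recommended).
#' @return A `steady_state_signal`.
#' @export
isochromat_oracle <- function(protocol, tissue, field = field_conditions(),
                              n_isochromats = 2000, tol = 1e-10,
                              max_iter = 10000) {
  n <- as.integer(n_isochromats)
  if (n < 2) stop("isochromat_oracle: need at least 2 isochromats",
                  call. = FALSE)
  alpha_eff <- field$b1_scale * protocol$flip_angle
  a <- alpha_eff * pi / 180
  ca <- cos(a); sa <- sin(a)
  dt <- protocol$tr  # same pulse model as the EPG engine
  sat <- if (tissue$bound_fraction > 0)
    bound_pool_saturation_factor(alpha_eff, protocol$pulse_width, tissue)
  else 1
  prop <- .relax_propagator(tissue, dt)
  theta <- 2 * pi * (seq_len(n) - 0.5) / n
  deph <- exp(1i * theta)

  f <- tissue$bound_fraction
  pd <- tissue$proton_density
  mxy <- complex(n)
  mz <- rep((1 - f) * pd, n)
  mzb <- rep(f * pd, n)

  s_prev <- c(NA_real_, NA_real_)
  d_prev <- NA_real_
  ok_runs <- 0L
  for (it in seq_len(max_iter)) {
    mzb <- mzb * sat
    # rotation about the x-axis (matches the EPG RF operator phase)
    my <- Im(mxy); mz_old <- mz
    mxy <- complex(real = Re(mxy), imaginary = ca * my - sa * mz_old)
    mz <- sa * my + ca * mz_old
    s_fid <- Mod(mean(mxy))
    # free interval: T2 decay + spoiler dephasing; two-pool longitudinal
    mxy <- mxy * (prop$e2 * deph)
    if (prop$single_pool) {
      mz <- prop$m0f + (mz - prop$m0f) * prop$e1
    } else {
      mz_new <- prop$E[1, 1] * mz + prop$E[1, 2] * mzb + prop$c[1]
      mzb <- prop$E[2, 1] * mz + prop$E[2, 2] * mzb + prop$c[2]
      mz <- mz_new
    }
    s_echo <- Mod(mean(mxy))

    s <- c(s_fid, s_echo)
    if (!all(is.finite(s)))
      .convergence_error("isochromat_oracle: signal diverged", it,
                         s_fid, s_echo)
    if (!anyNA(s_prev)) {
      scale <- max(s, 1e-30)
      d <- max(abs(s - s_prev)) / scale
      proj <- .projected_error(d, d_prev)
      ok_runs <- if (proj <= tol) ok_runs + 1L else 0L
      if (ok_runs >= 2L)
        return(structure(list(s_fid = s_fid, s_echo = s_echo,
                              converged = TRUE, n_iterations = it),
                         class = "steady_state_signal"))
      d_prev <- d
    }
    s_prev <- s
  }
  .convergence_error("isochromat_oracle: no convergence", max_iter,
                     s_prev[1], s_prev[2])
}

#' @export
print.steady_state_signal <- function(x, ...) {
  cat(sprintf("<steady_state_signal> s_fid = %.6g, s_echo = %.6g (%s, %d iterations)\n",
              x$s_fid, x$s_echo,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  invisible(x)
}
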