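# Extended phase graph engine with a coupled bound pool.
#
# State representation: configuration orders k = 0..K-1.
#   fp[j] = F_{+(j-1)}   transverse, dephasing order +(j-1)
#   fm[j] = F_{-(j-1)}   transverse, order -(j-1); fm[1] == fp[1] (both F_0)
#   z[j]  = Z_{j-1}      free-pool longitudinal configurations
#   zb[j] = Zb_{j-1}     bound-pool longitudinal configurations. The bound
#                        pool has no transverse coherence, but exchange with
#                        the order-resolved free Z_k populates longitudinal
#                        bound configurations of every order, and the return
#                        flow is not negligible — dropping it biases the
#                        two-pool echo signal by several percent.
# RF mixing uses the conjugate representation (F_k, F_{-k}*, Z_k).

#' Initialize an EPG state at thermal equilibrium
#'
#' @param tissue A [tissue_params()] object; sets the equilibrium split
#'   `Z_0 = (1 - f) * PD` (free) and `Z_b = f * PD` (bound).
#' @param n_states Number of configuration orders K to carry.
#' @return An object of class `epg_state` with complex fields `fp`, `fm`,
#'   `z` and `zb` (all length K). At equilibrium `z[1] = (1 - f) * PD`,
#'   `zb[1] = f * PD` and everything else is zero.
#' @export
epg_init <- function(tissue, n_states = 40) {
  K <- as.integer(n_states)
  if (K < 4) stop("epg_init: need at least 4 configuration states",
                  call. = FALSE)
  pd <- tissue$proton_density
  f <- tissue$bound_fraction
  z <- complex(K)
  z[1] <- complex(real = (1 - f) * pd)
  zb <- complex(K)
  zb[1] <- complex(real = f * pd)
  structure(list(fp = complex(K), fm = complex(K), z = z,
                 zb = zb, n_states = K),
            class = "epg_state")
}

#' Apply an RF pulse to the free pool of an EPG state
#'
#' Mixes each configuration triple (F_k, F_-k*, Z_k) by the standard unitary
#' RF operator for a rotation by `alpha_eff` about a fixed phase axis. The
#' bound pool has no transverse magnetization and is untouched by rotation
#' (its response to RF is pure saturation, see
#' [bound_pool_saturation_factor()]).
#'
#' @param state An `epg_state`.
#' @param alpha_eff Effective flip angle in degrees (nominal angle times any
#'   B1 scale).
#' @return The rotated `epg_state`.
#' @export
epg_rf_rotation <- function(state, alpha_eff) {
  if (!is.finite(alpha_eff)) stop("epg_rf_rotation: non-finite flip angle",
                                  call. = FALSE)
  a <- alpha_eff * pi / 180
  ca2 <- cos(a / 2)^2; sa2 <- sin(a / 2)^2; sa <- sin(a); ca <- cos(a)
  Tm <- matrix(c(ca2,            sa2,            -1i * sa,
                 sa2,            ca2,             1i * sa,
                 -0.5i * sa,     0.5i * sa,       ca),
               nrow = 3, byrow = TRUE)
  v <- rbind(state$fp, Conj(state$fm), state$z)
  v <- Tm %*% v
  state$fp <- v[1, ]
  state$fm <- Conj(v[2, ])
  state$z <- v[3, ]
  state
}

#' On-resonance bound-pool absorption lineshape value G(0)
#'
#' Returns the value of the bound-pool absorption lineshape used in the
#' saturation rate `W = pi * omega1^2 * G(0)`. The Gaussian lineshape is
#' finite on resonance, `G(0) = T2b / sqrt(2*pi)`. The super-Lorentzian
#' diverges at zero offset, so when it is selected G(0) is taken as the
#' lineshape evaluated at a cutoff offset (default 1 kHz), the usual
#' regularization in quantitative MT work.
#'
#' @param tissue A [tissue_params()] object (uses `t2_bound`, microseconds,
#'   and `lineshape`).
#' @param cutoff_hz Offset (Hz) at which the super-Lorentzian is evaluated
#'   in place of the divergent on-resonance value.
#' @return Lineshape amplitude in seconds.
#' @export
lineshape_g0 <- function(tissue, cutoff_hz = 1000) {
  t2b <- tissue$t2_bound * 1e-6  # us -> s
  if (t2b <= 0) stop("lineshape_g0: t2_bound must be positive", call. = FALSE)
  if (tissue$lineshape == "gaussian") return(t2b / sqrt(2 * pi))
  # super-Lorentzian at the cutoff offset
  integrand <- function(theta) {
    u <- abs(3 * cos(theta)^2 - 1)
    sin(theta) * sqrt(2 / pi) * (t2b / u) *
      exp(-2 * (2 * pi * cutoff_hz * t2b / u)^2)
  }
  stats::integrate(integrand, 0, pi / 2, rel.tol = 1e-9)$value
}

#' Bound-pool saturation factor of one rectangular RF pulse
#'
#' A hard pulse of flip angle `alpha` and width `tau` has mean amplitude
#' `omega1 = alpha_rad / tau` and saturates the bound pool at rate
#' `W = pi * omega1^2 * G(0)`; over the pulse the bound longitudinal
#' magnetization is multiplied by `exp(-W * tau)`. Varying `alpha` (or
#' `tau`) therefore modulates the RF energy deposited and with it the MT
#' weighting — the handle the on-resonance MT method turns.
#'
#' @param flip_angle Effective flip angle, degrees (>= 0).
#' @param pulse_width Pulse duration, microseconds (> 0).
#' @param tissue A [tissue_params()] object.
#' @param cutoff_hz Passed to [lineshape_g0()].
#' @return Dimensionless factor in (0, 1].
#' @examples
#' cond <- tissue_params(600, 120, 0.12, 30, 600, 12)
#' bound_pool_saturation_factor(300, 220, cond)  # strong saturation
#' bound_pool_saturation_factor(60, 220, cond)   # mild saturation
#' @export
bound_pool_saturation_factor <- function(flip_angle, pulse_width, tissue,
                                         cutoff_hz = 1000) {
  if (pulse_width <= 0) stop("bound_pool_saturation_factor: pulse_width ",
                             "must be > 0", call. = FALSE)
  if (flip_angle < 0) stop("bound_pool_saturation_factor: flip_angle must ",
                           "be >= 0", call. = FALSE)
  tau <- pulse_width * 1e-6           # s
  omega1 <- (flip_angle * pi / 180) / tau  # rad/s
  w <- pi * omega1^2 * lineshape_g0(tissue, cutoff_hz)
  exp(-w * tau)
}

# Closed-form expm for the 2x2 two-pool longitudinal evolution matrix.
# The off-diagonal entries are both non-negative, so the discriminant
# (a11 - a22)^2 + 4 a12 a21 >= 0 and the eigenvalues are real.
.expm2 <- function(M) {
  tr <- M[1, 1] + M[2, 2]
  disc <- (M[1, 1] - M[2, 2])^2 + 4 * M[1, 2] * M[2, 1]
  disc <- max(disc, 0)
  s <- sqrt(disc)
  l1 <- (tr + s) / 2
  l2 <- (tr - s) / 2
  I2 <- diag(2)
  if (s > 1e-12 * max(1, abs(tr))) {
    (exp(l1) * (M - l2 * I2) - exp(l2) * (M - l1 * I2)) / (l1 - l2)
  } else {
    exp(l1) * (I2 + (M - l1 * I2))  # (near-)defective: first-order Jordan
  }
}

# Precompute the relaxation/exchange propagator over an interval dt (ms):
# transverse decay e2 and the longitudinal affine map (E, c). E applies to
# every configuration order; the recovery offset c only to order 0.
.relax_propagator <- function(tissue, dt) {
  e2 <- exp(-dt / tissue$t2_free)
  f <- tissue$bound_fraction
  pd <- tissue$proton_density
  if (f == 0 && tissue$exchange_rate == 0) {
    e1 <- exp(-dt / tissue$t1_free)
    return(list(e2 = e2, single_pool = TRUE, e1 = e1, m0f = pd))
  }
  kf <- tissue$exchange_rate * f / 1000        # /ms
  kb <- tissue$exchange_rate * (1 - f) / 1000  # /ms
  m0f <- (1 - f) * pd
  m0b <- f * pd
  A <- matrix(c(-(1 / tissue$t1_free + kf), kb,
                kf, -(1 / tissue$t1_bound + kb)),
              nrow = 2, byrow = TRUE)
  E <- .expm2(A * dt)
  b <- c(m0f / tissue$t1_free, m0b / tissue$t1_bound)
  cc <- solve(A, (E - diag(2)) %*% b)
  list(e2 = e2, single_pool = FALSE, E = E, c = as.numeric(cc))
}

#' Relaxation and exchange over a free interval
#'
#' Propagates an EPG state over `dt` milliseconds with no RF: transverse
#' configurations decay by `exp(-dt/T2f)`; the order-0 longitudinal pair
#' `(Z_0, Zb_0)` follows the exact matrix-exponential solution of the
#' two-pool longitudinal Bloch-McConnell equations with recovery toward
#' `(M0f, M0b)`; higher-order pairs `(Z_k, Zb_k)` decay and exchange by the
#' homogeneous part of the same propagator, without a recovery source
#' (thermal recovery is spatially uniform and only feeds order 0).
#'
#' @param state An `epg_state`.
#' @param dt Interval in ms (>= 0).
#' @param tissue A [tissue_params()] object.
#' @param prop Optional precomputed propagator (internal use; the
#'   steady-state solver caches it across iterations).
#' @return The propagated `epg_state`.
#' @export
relax_exchange_interval <- function(state, dt, tissue, prop = NULL) {
  if (is.null(prop)) {
    if (!is.numeric(dt) || dt < 0)
      stop("relax_exchange_interval: 'dt' must be >= 0", call. = FALSE)
    if (dt == 0) return(state)
    prop <- .relax_propagator(tissue, dt)
  }
  state$fp <- state$fp * prop$e2
  state$fm <- state$fm * prop$e2
  if (prop$single_pool) {
    state$z <- state$z * prop$e1
    state$z[1] <- state$z[1] + prop$m0f * (1 - prop$e1)
  } else {
    z <- state$z; zb <- state$zb
    state$z <- prop$E[1, 1] * z + prop$E[1, 2] * zb
    state$zb <- prop$E[2, 1] * z + prop$E[2, 2] * zb
    state$z[1] <- state$z[1] + prop$c[1]
    state$zb[1] <- state$zb[1] + prop$c[2]
  }
  state
}

#' Ideal gradient spoiler: shift configuration orders by one
#'
#' One fully spoiled TR advances every transverse configuration by one
#' dephasing order: `F_k -> F_{k+1}`. The former `F_{-1}` becomes the new
#' `F_0` — this refocusing pathway is the PSIF echo. Longitudinal orders are
#' unaffected. The highest positive order is truncated.
#'
#' @param state An `epg_state`.
#' @return The shifted `epg_state`.
#' @export
epg_spoiler_shift <- function(state) {
  K <- state$n_states
  new_f0 <- state$fm[2]                      # old F_{-1}
  state$fp <- c(new_f0, state$fp[-K])
  state$fm <- c(state$fm[-1], 0 + 0i)
  state$fm[1] <- new_f0                      # F_{-0} and F_{+0} are both F_0
  state
}
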