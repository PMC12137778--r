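# Multi-coil, noisy magnitude acquisition simulation on parameter maps.

# Run expr with a private, seeded RNG stream; the caller's RNG state is
# untouched. All randomized paths in the simulator go through this.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Acquisition/noise settings for the simulator
#'
#' @param n_coils Number of receive channels (>= 1); the reference head coil
#'   has eight.
#' @param noise_sigma Standard deviation of the i.i.d. complex Gaussian
#'   noise added per channel (real and imaginary parts each), a.u.
#' @param seed Integer seed; identical seed + configuration gives
#'   bit-identical output.
#' @param coil_mode `"gaussian"` (smooth lobes around the FOV perimeter) or
#'   `"uniform"` (all-ones sensitivities).
#' @return An `acquisition_sim` object.
#' @export
acquisition_sim <- function(n_coils = 8, noise_sigma = 0, seed = 1,
                            coil_mode = c("gaussian", "uniform")) {
  coil_mode <- match.arg(coil_mode)
  if (n_coils < 1) stop("acquisition_sim: 'n_coils' must be >= 1",
                        call. = FALSE)
  if (noise_sigma < 0) stop("acquisition_sim: 'noise_sigma' must be >= 0",
                            call. = FALSE)
  structure(list(n_coils = as.integer(n_coils),
                 noise_sigma = as.numeric(noise_sigma),
                 seed = as.integer(seed), coil_mode = coil_mode),
            class = "acquisition_sim")
}

#' Simulate smooth complex coil sensitivity profiles
#'
#' Gaussian-lobe magnitude profiles centered around the FOV perimeter in
#' the RL-AP plane (one lobe per coil, equally spaced with a small seeded
#' jitter) on a strictly positive floor, with a smooth seeded linear phase
#' per coil. The root-sum-of-squares magnitude is therefore bounded away
#' from zero everywhere. `"uniform"` mode returns all-ones maps.
#'
#' @param grid Integer length-3 matrix dimensions.
#' @param n_coils Number of coils.
#' @param seed Integer seed (profiles are deterministic given it).
#' @param mode `"gaussian"` or `"uniform"`.
#' @return Complex 4D array `grid x n_coils`.
#' @export
simulate_coil_sensitivities <- function(grid, n_coils, seed = 1,
                                        mode = c("gaussian", "uniform")) {
  mode <- match.arg(mode)
  grid <- as.integer(grid)
  if (length(grid) != 3L) stop("simulate_coil_sensitivities: 'grid' must ",
                               "have 3 dimensions", call. = FALSE)
  if (n_coils < 1) stop("simulate_coil_sensitivities: 'n_coils' must be ",
                        ">= 1", call. = FALSE)
  sens <- array(0 + 0i, c(grid, n_coils))
  if (mode == "uniform") {
    sens[] <- 1 + 0i
    return(sens)
  }
  # normalized coordinates in [-1, 1]
  nx <- (seq_len(grid[1]) - 0.5) / grid[1] * 2 - 1
  ny <- (seq_len(grid[2]) - 0.5) / grid[2] * 2 - 1
  nz <- (seq_len(grid[3]) - 0.5) / grid[3] * 2 - 1
  X <- array(nx, grid)
  Y <- array(rep(ny, each = grid[1]), grid)
  Z <- array(rep(nz, each = grid[1] * grid[2]), grid)
  .with_seed(seed, {
    jitter_ang <- stats::runif(n_coils, -0.1, 0.1)
    widths <- stats::runif(n_coils, 0.55, 0.75)
    phase_coef <- matrix(stats::runif(3 * n_coils, -0.5, 0.5), nrow = 3)
    for (cc in seq_len(n_coils)) {
      ang <- 2 * pi * (cc - 1) / n_coils + jitter_ang[cc]
      cxy <- 1.1 * c(cos(ang), sin(ang))
      d2 <- (X - cxy[1])^2 + (Y - cxy[2])^2 + 0.25 * Z^2
      mag <- 0.05 + exp(-d2 / (2 * widths[cc]^2))
      ph <- pi * (phase_coef[1, cc] * X + phase_coef[2, cc] * Y +
                  phase_coef[3, cc] * Z)
      sens[, , , cc] <- mag * exp(1i * ph)
    }
  })
  sens
}

# Per-label steady-state signal lookup for a parameter map set.
.label_signals <- function(maps, protocol, field) {
  idx <- maps$labels$index
  vapply(seq_along(idx), function(i) {
    if (idx[i] == 0L) return(0)  # background, zero proton density
    tis <- maps$tissues[[maps$labels$label[i]]]
    if (tis$proton_density == 0) return(0)
    res <- tryCatch(ssfp_steady_state(protocol, tis, field),
                    ulfmt_convergence_error = function(e)
                      stop("simulate_acquisition: solver failed for tissue '",
                           maps$labels$label[i], "': ", conditionMessage(e),
                           call. = FALSE))
    if (protocol$sequence == "psif_echo") res$s_echo else res$s_fid
  }, numeric(1))
}

#' Simulate one multi-coil acquisition of a phantom
#'
#' The steady-state signal is computed once per compartment (parameters are
#' constant within a compartment) and broadcast over the label map, then
#' multiplied by each coil's complex sensitivity; i.i.d. complex Gaussian
#' noise is added per channel in the image domain, which for this noise
#' model is equivalent to adding it in k-space.
#'
#' @param maps A `parameter_maps` object (see [build_vial_phantom()]).
#' @param protocol A [sequence_protocol()].
#' @param field A [field_conditions()].
#' @param acq An [acquisition_sim()].
#' @param sens Optional precomputed sensitivity array (as returned by
#'   [simulate_coil_sensitivities()]); computed from `acq` if missing.
#' @param noise_seed Seed of the noise stream; defaults to `acq$seed + 1`
#'   so that the coil-profile and noise draws are independent.
#' @return A complex 4D array `grid x n_coils` of class `coil_images`, with
#'   attributes `voxel` and `signal_map` (the noise-free signal volume).
#' @export
simulate_acquisition <- function(maps, protocol, field = field_conditions(),
                                 acq = acquisition_sim(), sens = NULL,
                                 noise_seed = acq$seed + 1L) {
  dims <- dim(maps$label)
  sig_by_label <- .label_signals(maps, protocol, field)
  signal_map <- array(sig_by_label[maps$label + 1L], dims)
  if (is.null(sens))
    sens <- simulate_coil_sensitivities(dims, acq$n_coils, seed = acq$seed,
                                        mode = acq$coil_mode)
  out <- array(0 + 0i, c(dims, acq$n_coils))
  for (cc in seq_len(acq$n_coils)) out[, , , cc] <- sens[, , , cc] * signal_map
  if (acq$noise_sigma > 0) {
    n <- length(out)
    noise <- .with_seed(noise_seed,
      complex(real = stats::rnorm(n, 0, acq$noise_sigma),
              imaginary = stats::rnorm(n, 0, acq$noise_sigma)))
    out <- out + array(noise, dim(out))
  }
  structure(out, class = "coil_images", voxel = maps$voxel,
            signal_map = signal_map)
}

#' Simulate a full sweep acquisition as a 4D magnitude stack
#'
#' Runs [simulate_acquisition()] once per flip angle, combines coils by
#' root-sum-of-squares and stacks the magnitude volumes along a 4th axis in
#' ascending-angle order. The order in which a scanner would actually play
#' the acquisitions out (low/high interleave, see
#' [make_interleaved_order()]) is retained as provenance metadata.
#'
#' Coil sensitivities are identical across angles (same hardware); the
#' noise realization differs per angle but is fully determined by the seed.
#'
#' @param maps A `parameter_maps` object.
#' @param protocol A [sequence_protocol()]; its `flip_angle` is replaced by
#'   each sweep angle in turn.
#' @param angles Flip angles, degrees (default [default_flip_angles()]).
#' @param acq An [acquisition_sim()].
#' @param field A [field_conditions()].
#' @return A `sweep_dataset`: list with `data` (4D magnitude array,
#'   ascending angles), `angles`, `voxel` and `provenance` (seed, protocol,
#'   acquisition order, tissue labels).
#' @export
simulate_sweep_dataset <- function(maps, protocol = default_protocol(),
                                   angles = default_flip_angles(),
                                   acq = acquisition_sim(),
                                   field = field_conditions()) {
  angles <- sort(angles)
  dims <- dim(maps$label)
  sens <- simulate_coil_sensitivities(dims, acq$n_coils, seed = acq$seed,
                                      mode = acq$coil_mode)
  data <- array(0, c(dims, length(angles)))
  for (i in seq_along(angles)) {
    p <- protocol
    p$flip_angle <- angles[i]
    vol <- simulate_acquisition(maps, p, field, acq, sens = sens,
                                noise_seed = acq$seed + 7919L * i)
    data[, , , i] <- rss_combine(vol)
  }
  structure(list(
    data = data, angles = angles, voxel = maps$voxel,
    provenance = list(seed = acq$seed, n_coils = acq$n_coils,
                      noise_sigma = acq$noise_sigma,
                      coil_mode = acq$coil_mode,
                      angles = angles,
                      acquisition_order = make_interleaved_order(angles),
                      protocol = unclass(protocol),
                      tissue_labels = maps$labels$label)),
    class = "sweep_dataset")
}
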