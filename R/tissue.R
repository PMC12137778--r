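#' Two-pool tissue parameters
#'
#' Describes one material as a free water pool (directly observable) coupled
#' to a macromolecular bound pool (very short T2, saturable but invisible).
#' The bound fraction `f` is the share of the total equilibrium magnetization
#' held by the bound pool; exchange follows detailed balance with forward
#' rate `k_f = k * f` (free to bound) and reverse rate `k_b = k * (1 - f)`,
#' where `k` is the fundamental exchange rate.
#'
#' @param t1_free Longitudinal relaxation time of the free pool, ms.
#' @param t2_free Transverse relaxation time of the free pool, ms.
#' @param bound_fraction Dimensionless bound-pool fraction `f` in `[0, 1)`.
#'   `0` selects a pure single-pool computation path.
#' @param exchange_rate Fundamental exchange rate `k`, 1/s.
#' @param t1_bound Longitudinal relaxation time of the bound pool, ms.
#' @param t2_bound Transverse relaxation time of the bound pool, microseconds.
#'   Sets the on-resonance absorption lineshape amplitude G(0).
#' @param lineshape Bound-pool absorption lineshape, `"gaussian"` (default)
#'   or `"super_lorentzian"`.
#' @param proton_density Equilibrium magnetization scale, arbitrary units,
#'   `>= 0`.
#' @param label Optional character label carried through phantoms and sweep
#'   provenance.
#'
#' @return An object of class `tissue_params`.
#' @examples
#' wm <- tissue_params(t1_free = 350, t2_free = 90, bound_fraction = 0.13,
#'                     exchange_rate = 35, t1_bound = 350, t2_bound = 11)
#' water <- tissue_params(t1_free = 3000, t2_free = 2000)
#' @export
tissue_params <- function(t1_free, t2_free, bound_fraction = 0,
                          exchange_rate = 0, t1_bound = t1_free,
                          t2_bound = 11, lineshape = c("gaussian",
                          "super_lorentzian"), proton_density = 1,
                          label = NULL) {
  lineshape <- match.arg(lineshape)
  for (nm in c("t1_free", "t2_free", "t1_bound", "t2_bound")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("tissue_params: '", nm, "' must be a single positive number",
           call. = FALSE)
  }
  if (!is.numeric(bound_fraction) || bound_fraction < 0 || bound_fraction >= 1)
    stop("tissue_params: 'bound_fraction' must lie in [0, 1)", call. = FALSE)
  if (!is.numeric(exchange_rate) || exchange_rate < 0)
    stop("tissue_params: 'exchange_rate' must be >= 0", call. = FALSE)
  if (!is.numeric(proton_density) || proton_density < 0)
    stop("tissue_params: 'proton_density' must be >= 0", call. = FALSE)
  structure(list(
    t1_free = as.numeric(t1_free),
    t2_free = as.numeric(t2_free),
    bound_fraction = as.numeric(bound_fraction),
    exchange_rate = as.numeric(exchange_rate),
    t1_bound = as.numeric(t1_bound),
    t2_bound = as.numeric(t2_bound),
    lineshape = lineshape,
    proton_density = as.numeric(proton_density),
    label = if (is.null(label)) NA_character_ else as.character(label)
  ), class = "tissue_params")
}

#' @export
print.tissue_params <- function(x, ...) {
  cat("<tissue_params>",
      if (!is.na(x$label)) paste0(" '", x$label, "'") else "", "\n", sep = "")
  cat(sprintf("  free pool : T1 = %g ms, T2 = %g ms, PD = %g\n",
              x$t1_free, x$t2_free, x$proton_density))
  if (x$bound_fraction > 0)
    cat(sprintf("  bound pool: f = %g, k = %g /s, T1b = %g ms, T2b = %g us (%s)\n",
                x$bound_fraction, x$exchange_rate, x$t1_bound, x$t2_bound,
                x$lineshape))
  else cat("  bound pool: none (single-pool)\n")
  invisible(x)
}

#' Transmit/static field conditions
#'
#' @param b1_scale Multiplicative transmit-field (B1) error: the flip angle
#'   actually played out is `b1_scale * nominal`. `1` is an ideal transmitter.
#' @param b0 Static field strength in mT, carried as metadata only (field
#'   strength enters the physics through the tissue parameters chosen for it).
#'
#' @return An object of class `field_conditions`.
#' @export
field_conditions <- function(b1_scale = 1, b0 = 64) {
  if (!is.numeric(b1_scale) || length(b1_scale) != 1L || b1_scale <= 0)
    stop("field_conditions: 'b1_scale' must be a single positive number",
         call. = FALSE)
  structure(list(b1_scale = as.numeric(b1_scale), b0 = as.numeric(b0)),
            class = "field_conditions")
}

#' Built-in 64 mT tissue presets
#'
#' Returns the preset table shipped with the package
#' (`inst/extdata/tissue_presets.yaml`): water, CSF-like, white-matter-like,
#' dairy-cream-like and hair-conditioner-like materials. All values are
#' literature-informed estimates for ultra-low field (64 mT), not measured
#' reference values; override any of them via [load_config()] or by editing
#' a copy of the YAML file.
#'
#' @param name Optional preset name; if given, the single `tissue_params`
#'   object is returned instead of the whole list.
#' @param file Alternative YAML preset file.
#' @return A named list of `tissue_params`, or a single `tissue_params`.
#' @examples
#' names(tissue_presets())
#' tissue_presets("conditioner_like")
#' @export
tissue_presets <- function(name = NULL, file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "tissue_presets.yaml", package = "ulfmt",
                        mustWork = TRUE)
  raw <- yaml::read_yaml(file)
  presets <- lapply(names(raw), function(nm) {
    p <- raw[[nm]]
    tissue_params(
      t1_free = p$t1_free, t2_free = p$t2_free,
      bound_fraction = p$bound_fraction %||% 0,
      exchange_rate = p$exchange_rate %||% 0,
      t1_bound = p$t1_bound %||% p$t1_free,
      t2_bound = p$t2_bound %||% 11,
      lineshape = p$lineshape %||% "gaussian",
      proton_density = p$proton_density %||% 1,
      label = nm)
  })
  names(presets) <- names(raw)
  if (!is.null(name)) {
    if (!name %in% names(presets))
      stop("unknown tissue preset '", name, "'; available: ",
           paste(names(presets), collapse = ", "), call. = FALSE)
    return(presets[[name]])
  }
  presets
}

`%||%` <- function(a, b) if (is.null(a)) b else a
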