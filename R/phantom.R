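# Digital phantoms: compartment geometry, rasterization to parameter maps.

#' Define one phantom compartment
#'
#' @param label Unique compartment name.
#' @param tissue A [tissue_params()] describing the material.
#' @param geometry Geometry type: `"cylinder"` (axis along FH, the 3rd
#'   axis), `"sphere"` or `"box"`.
#' @param center Center in mm, world coordinates (origin at the FOV center,
#'   axes RL x AP x FH).
#' @param radius Radius in mm (cylinder, sphere).
#' @param height Extent along FH in mm (cylinder).
#' @param size Length-3 extents in mm (box).
#' @return A `phantom_compartment`.
#' @export
phantom_compartment <- function(label, tissue,
                                geometry = c("cylinder", "sphere", "box"),
                                center = c(0, 0, 0), radius = NULL,
                                height = NULL, size = NULL) {
  geometry <- match.arg(geometry)
  if (length(center) != 3L) stop("phantom_compartment: 'center' must have ",
                                 "3 components (mm)", call. = FALSE)
  if (geometry %in% c("cylinder", "sphere") &&
      (is.null(radius) || radius <= 0))
    stop("phantom_compartment: '", geometry, "' needs a positive 'radius'",
         call. = FALSE)
  if (geometry == "cylinder" && (is.null(height) || height <= 0))
    stop("phantom_compartment: 'cylinder' needs a positive 'height'",
         call. = FALSE)
  if (geometry == "box" && (is.null(size) || length(size) != 3L ||
                            any(size <= 0)))
    stop("phantom_compartment: 'box' needs 3 positive 'size' extents",
         call. = FALSE)
  structure(list(label = as.character(label), tissue = tissue,
                 geometry = geometry, center = as.numeric(center),
                 radius = radius, height = height, size = size),
            class = "phantom_compartment")
}

.compartment_extent <- function(comp) {
  # half-extents of the bounding box, mm
  switch(comp$geometry,
         cylinder = c(comp$radius, comp$radius, comp$height / 2),
         sphere = rep(comp$radius, 3),
         box = comp$size / 2)
}

#' Define a digital phantom
#'
#' @param compartments List of [phantom_compartment()] objects with unique
#'   labels; may be empty (all-background phantom).
#' @param fov,voxel FOV and voxel size in mm (3 extents each); `fov/voxel`
#'   must be whole numbers (the matrix size).
#' @param background_label Label of everything outside the compartments
#'   (zero proton density).
#' @return A `phantom_definition`.
#' @export
phantom_definition <- function(compartments, fov = c(180, 220, 200),
                               voxel = c(2, 2, 5),
                               background_label = "background") {
  mat <- fov / voxel
  if (any(abs(mat - round(mat)) > 1e-8))
    stop("phantom_definition: fov/voxel must be whole voxel counts",
         call. = FALSE)
  labels <- vapply(compartments, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop("phantom_definition: compartment labels must be unique",
         call. = FALSE)
  if (background_label %in% labels)
    stop("phantom_definition: background label collides with a compartment",
         call. = FALSE)
  for (comp in compartments) {
    he <- .compartment_extent(comp)
    if (any(abs(comp$center) + he > fov / 2 + 1e-9))
      stop("phantom_definition: compartment '", comp$label,
           "' extends outside the field of view", call. = FALSE)
  }
  structure(list(compartments = compartments, fov = as.numeric(fov),
                 voxel = as.numeric(voxel),
                 grid = as.integer(round(mat)),
                 background_label = background_label),
            class = "phantom_definition")
}

.voxel_centers <- function(n, vox, extent) {
  (seq_len(n) - 0.5) * vox - extent / 2
}

#' Rasterize a phantom into voxelwise parameter maps
#'
#' A voxel belongs to a compartment iff its center lies inside the geometry
#' (no partial-volume mixing), which keeps compartment means exactly equal
#' to the tissue value. Overlapping compartments are an error. Background
#' voxels get zero proton density.
#'
#' @param spec A [phantom_definition()].
#' @return A `parameter_maps` object: one 3D array per tissue parameter
#'   (`t1_free`, `t2_free`, `bound_fraction`, `exchange_rate`, `t1_bound`,
#'   `t2_bound`, `proton_density`), an integer `label` array (0 =
#'   background), a `labels` table mapping indices to names, and the list of
#'   per-compartment `tissue_params`.
#' @examples
#' maps <- build_vial_phantom(default_vial_phantom(fov = c(60, 60, 20)))
#' table(maps$label)
#' @export
build_vial_phantom <- function(spec) {
  if (!inherits(spec, "phantom_definition"))
    stop("build_vial_phantom: 'spec' must be a phantom_definition",
         call. = FALSE)
  dims <- spec$grid
  cx <- .voxel_centers(dims[1], spec$voxel[1], spec$fov[1])
  cy <- .voxel_centers(dims[2], spec$voxel[2], spec$fov[2])
  cz <- .voxel_centers(dims[3], spec$voxel[3], spec$fov[3])

  label <- array(0L, dims)
  par_names <- c("t1_free", "t2_free", "bound_fraction", "exchange_rate",
                 "t1_bound", "t2_bound", "proton_density")
  maps <- lapply(par_names, function(nm) array(0, dims))
  names(maps) <- par_names
  # background: inert but positive relaxation times, zero proton density
  maps$t1_free[] <- 1; maps$t2_free[] <- 1
  maps$t1_bound[] <- 1; maps$t2_bound[] <- 1

  X <- array(cx, dims)
  Y <- array(rep(cy, each = dims[1]), dims)
  Z <- array(rep(cz, each = dims[1] * dims[2]), dims)

  for (i in seq_along(spec$compartments)) {
    comp <- spec$compartments[[i]]
    ctr <- comp$center
    inside <- switch(comp$geometry,
      cylinder = ((X - ctr[1])^2 + (Y - ctr[2])^2 <= comp$radius^2) &
                 (abs(Z - ctr[3]) <= comp$height / 2),
      sphere = (X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2 <=
               comp$radius^2,
      box = (abs(X - ctr[1]) <= comp$size[1] / 2) &
            (abs(Y - ctr[2]) <= comp$size[2] / 2) &
            (abs(Z - ctr[3]) <= comp$size[3] / 2))
    if (any(label[inside] != 0L))
      stop("build_vial_phantom: compartment '", comp$label,
           "' overlaps another compartment", call. = FALSE)
    label[inside] <- i
    tis <- comp$tissue
    for (nm in par_names) maps[[nm]][inside] <- tis[[nm]]
  }

  tissues <- lapply(spec$compartments, `[[`, "tissue")
  names(tissues) <- vapply(spec$compartments, `[[`, character(1), "label")
  structure(c(maps, list(
    label = label,
    labels = data.frame(
      index = c(0L, seq_along(spec$compartments)),
      label = c(spec$background_label,
                vapply(spec$compartments, `[[`, character(1), "label")),
      stringsAsFactors = FALSE),
    tissues = tissues,
    voxel = spec$voxel, fov = spec$fov)),
    class = "parameter_maps")
}

#' @export
print.parameter_maps <- function(x, ...) {
  cat("<parameter_maps> grid ", paste(dim(x$label), collapse = "x"),
      ", voxel ", paste(x$voxel, collapse = "x"), " mm, ",
      nrow(x$labels), " labels\n", sep = "")
  invisible(x)
}

#' Default six-vial MT phantom
#'
#' Two vials of water, two of a dairy-cream-like material and two of a
#' hair-conditioner-like material (tissue presets, see [tissue_presets()]),
#' as parallel cylinders along FH in a 2 x 3 arrangement. Defaults to the
#' full acquisition FOV (180 x 220 x 200 mm at 2 x 2 x 5 mm voxels, i.e. a
#' 90 x 110 x 40 grid); pass a smaller `fov` for quick tests.
#'
#' @param fov,voxel FOV and voxel size, mm.
#' @param radius,height Vial radius and length, mm; scaled down
#'   automatically for small FOVs.
#' @return A `phantom_definition`.
#' @export
default_vial_phantom <- function(fov = c(180, 220, 200), voxel = c(2, 2, 5),
                                 radius = NULL, height = NULL) {
  presets <- tissue_presets()
  mats <- c("water", "water", "cream_like", "cream_like",
            "conditioner_like", "conditioner_like")
  if (is.null(radius)) radius <- 0.2 * min(fov[1:2]) / 2
  if (is.null(height)) height <- 0.6 * fov[3]
  dx <- fov[1] / 4
  dy <- fov[2] / 3.2
  centers <- rbind(c(-dx, -dy, 0), c(dx, -dy, 0),
                   c(-dx, 0, 0), c(dx, 0, 0),
                   c(-dx, dy, 0), c(dx, dy, 0))
  comps <- lapply(seq_along(mats), function(i) {
    phantom_compartment(paste0(mats[i], "_", 1 + (i - 1) %% 2),
                        presets[[mats[i]]], "cylinder",
                        center = centers[i, ], radius = radius,
                        height = height)
  })
  phantom_definition(comps, fov = fov, voxel = voxel)
}

#' Default relaxometry-array T1/T2 pairs
#'
#' Fourteen synthetic (T1, T2) pairs spanning roughly 30-2500 ms T1 and
#' 10-1500 ms T2, emulating the spread of a commercial relaxometry array
#' phantom at ultra-low field. These are documented placeholders, not
#' measured vendor values; supply your own lists to
#' [build_relaxometry_array()] to match a specific phantom.
#'
#' @return A data.frame with columns `t1` and `t2` (ms).
#' @export
default_relaxometry_pairs <- function() {
  data.frame(
    t1 = c(2500, 2000, 1500, 1100, 800, 600, 450, 330, 240, 180, 130, 90,
           60, 30),
    t2 = c(1500, 900, 500, 300, 200, 140, 100, 70, 50, 35, 25, 18, 14, 10))
}

#' Relaxometry-array phantom (no bound pool)
#'
#' One cylindrical vial per (T1, T2) pair, arranged on a circle, up to
#' `n_per_layer` vials per layer with layers stacked along FH. Every vial is
#' a pure single-pool material (`bound_fraction = 0`), so its flip-angle
#' response must be mirror-symmetric and its MTR zero — the control
#' demonstrating that T1/T2 variation alone does not masquerade as an MT
#' effect.
#'
#' @param t1_list,t2_list Matching vectors of relaxation times, ms.
#' @param fov,voxel FOV and voxel size, mm.
#' @param n_per_layer Vials per circular layer (default 14).
#' @param radius Vial radius, mm.
#' @return A `parameter_maps` object (rasterized).
#' @examples
#' p <- default_relaxometry_pairs()
#' maps <- build_relaxometry_array(p$t1[1:4], p$t2[1:4], fov = c(80, 80, 20))
#' @export
build_relaxometry_array <- function(t1_list, t2_list,
                                    fov = c(180, 180, 40),
                                    voxel = c(2, 2, 5),
                                    n_per_layer = 14, radius = NULL) {
  if (length(t1_list) == 0 || length(t1_list) != length(t2_list))
    stop("build_relaxometry_array: t1_list and t2_list must be non-empty ",
         "and the same length", call. = FALSE)
  if (any(t1_list <= 0) || any(t2_list <= 0))
    stop("build_relaxometry_array: relaxation times must be positive",
         call. = FALSE)
  n <- length(t1_list)
  n_layers <- ceiling(n / n_per_layer)
  ring <- 0.35 * min(fov[1:2])
  if (is.null(radius))
    radius <- min(0.4 * 2 * pi * ring / n_per_layer, 0.1 * min(fov[1:2]))
  layer_h <- fov[3] / n_layers
  comps <- lapply(seq_len(n), function(i) {
    layer <- (i - 1) %/% n_per_layer
    j <- (i - 1) %% n_per_layer
    ang <- 2 * pi * j / min(n_per_layer, n - layer * n_per_layer)
    zc <- -fov[3] / 2 + (layer + 0.5) * layer_h
    tis <- tissue_params(t1_free = t1_list[i], t2_free = t2_list[i],
                         bound_fraction = 0,
                         label = sprintf("vial_%02d", i))
    phantom_compartment(sprintf("vial_%02d", i), tis, "cylinder",
                        center = c(ring * cos(ang), ring * sin(ang), zc),
                        radius = radius, height = 0.8 * layer_h)
  })
  build_vial_phantom(phantom_definition(comps, fov = fov, voxel = voxel))
}
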