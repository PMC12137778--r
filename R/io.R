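# File I/O: NIfTI volumes, YAML/JSON configs, CSV tables, provenance.

#' Interleaved acquisition order for a sweep
#'
#' Scanner acquisition order alternating the lowest and highest remaining
#' values (1, 420, 10, 410, ... for the default flip-angle grid), which
#' spreads any slow drift evenly over the low- and high-energy ends of the
#' sweep. The output is a permutation of the input.
#'
#' @param angles Sorted (or sortable) numeric vector.
#' @return The same values in interleaved acquisition order.
#' @examples
#' make_interleaved_order(default_flip_angles())[1:4]  # 1 420 10 410
#' @export
make_interleaved_order <- function(angles) {
  if (length(angles) == 0) stop("make_interleaved_order: empty input",
                                call. = FALSE)
  s <- sort(angles)
  lo <- 1L; hi <- length(s)
  out <- numeric(length(s))
  for (i in seq_along(s)) {
    if (i %% 2L == 1L) { out[i] <- s[lo]; lo <- lo + 1L }
    else { out[i] <- s[hi]; hi <- hi - 1L }
  }
  out
}

#' Read / write NIfTI volumes
#'
#' Thin wrappers over RNifti preserving voxel sizes (mm) in the header.
#' `write_nifti` accepts 3D or 4D arrays; `read_nifti` returns a plain
#' array with a `voxel` attribute.
#'
#' @param img Numeric 3D/4D array (a `voxel` attribute, if present, is used
#'   unless `voxel` is given).
#' @param path File path (`.nii` or `.nii.gz`).
#' @param voxel Voxel sizes in mm (length 3).
#' @return `read_nifti`: the array with `voxel` attribute;
#'   `write_nifti`: `path`, invisibly.
#' @export
write_nifti <- function(img, path, voxel = NULL) {
  if (is.null(voxel)) voxel <- attr(img, "voxel") %||% c(1, 1, 1)
  arr <- array(as.numeric(img), dim(img))
  nii <- RNifti::asNifti(arr)
  RNifti::pixdim(nii) <- c(voxel, rep(1, max(0, length(dim(arr)) - 3L)))
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  nii <- RNifti::readNifti(path)
  out <- array(as.numeric(nii), dim(nii))
  attr(out, "voxel") <- RNifti::pixdim(nii)[1:3]
  out
}

#' Write / read a parameter-map set as NIfTI volumes
#'
#' One float volume per tissue parameter plus an integer label volume, all
#' sharing the grid and voxel sizes, written as `<prefix>_<name>.nii.gz`.
#'
#' @param maps A `parameter_maps` object.
#' @param prefix Output path prefix.
#' @return `write_parameter_maps`: named vector of file paths, invisibly.
#'   `read_parameter_maps`: the reassembled map list (arrays + voxel; the
#'   tissue objects themselves are not stored in NIfTI and are not
#'   recovered).
#' @export
write_parameter_maps <- function(maps, prefix) {
  nms <- c("t1_free", "t2_free", "bound_fraction", "exchange_rate",
           "t1_bound", "t2_bound", "proton_density", "label")
  paths <- vapply(nms, function(nm) {
    p <- paste0(prefix, "_", nm, ".nii.gz")
    write_nifti(maps[[nm]], p, voxel = maps$voxel)
    p
  }, character(1))
  invisible(paths)
}

#' @rdname write_parameter_maps
#' @export
read_parameter_maps <- function(prefix) {
  nms <- c("t1_free", "t2_free", "bound_fraction", "exchange_rate",
           "t1_bound", "t2_bound", "proton_density", "label")
  out <- lapply(nms, function(nm)
    read_nifti(paste0(prefix, "_", nm, ".nii.gz")))
  names(out) <- nms
  out$voxel <- attr(out$t1_free, "voxel")
  out$label <- array(as.integer(round(out$label)), dim(out$label))
  out
}

#' Export a sweep curve as CSV
#'
#' Stable schema: columns `x`, `signal`, `sweep_kind`, `tissue_label`.
#'
#' @param curve A `sweep_curve` (or list coercible by
#'   `as.data.frame.sweep_curve`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sweep_csv
#' @export
read_sweep_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "signal", "sweep_kind", "tissue_label")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_sweep_csv: missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  df
}

.check_positive <- function(cfg, section, fields) {
  for (f in fields) {
    v <- cfg[[f]]
    if (!is.null(v) && (!is.numeric(v) || v <= 0))
      stop("load_config: field '", section, "$", f,
           "' must be a positive number (got ", deparse(v), ")",
           call. = FALSE)
  }
}

#' Load a run configuration (YAML or JSON)
#'
#' Reads a configuration with optional sections `tissues` (named two-pool
#' parameter sets), `protocol`, `acquisition` and `field`, validates the
#' obviously physical constraints, and resolves defaults. The resolved
#' configuration round-trips losslessly through [write_provenance()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `run_config`: list with `tissues` (list of [tissue_params()]),
#'   `protocol` ([sequence_protocol()]), `acquisition`
#'   ([acquisition_sim()]), `field` ([field_conditions()]) and the `raw`
#'   list as read.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: no such file: ", path,
                               call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)

  tissues <- list()
  if (!is.null(raw$tissues)) {
    for (nm in names(raw$tissues)) {
      tc <- raw$tissues[[nm]]
      .check_positive(tc, paste0("tissues$", nm),
                      c("t1_free", "t2_free", "t1_bound", "t2_bound"))
      tissues[[nm]] <- tryCatch(
        tissue_params(t1_free = tc$t1_free, t2_free = tc$t2_free,
                      bound_fraction = tc$bound_fraction %||% 0,
                      exchange_rate = tc$exchange_rate %||% 0,
                      t1_bound = tc$t1_bound %||% tc$t1_free,
                      t2_bound = tc$t2_bound %||% 11,
                      lineshape = tc$lineshape %||% "gaussian",
                      proton_density = tc$proton_density %||% 1,
                      label = nm),
        error = function(e) stop("load_config: tissues$", nm, ": ",
                                 conditionMessage(e), call. = FALSE))
    }
  }
  pc <- raw$protocol %||% list()
  protocol <- tryCatch(
    sequence_protocol(tr = pc$tr %||% 12.03,
                      flip_angle = pc$flip_angle %||% 60,
                      pulse_width = pc$pulse_width %||% 220,
                      sequence = pc$sequence %||% "psif_echo",
                      fov = unlist(pc$fov %||% c(180, 220, 200)),
                      voxel = unlist(pc$voxel %||% c(2, 2, 5)),
                      bandwidth = pc$bandwidth %||% 18,
                      n_epg_states = pc$n_epg_states %||% 40),
    error = function(e) stop("load_config: protocol: ",
                             conditionMessage(e), call. = FALSE))
  ac <- raw$acquisition %||% list()
  acquisition <- tryCatch(
    acquisition_sim(n_coils = ac$n_coils %||% 8,
                    noise_sigma = ac$noise_sigma %||% 0,
                    seed = ac$seed %||% 1,
                    coil_mode = ac$coil_mode %||% "gaussian"),
    error = function(e) stop("load_config: acquisition: ",
                             conditionMessage(e), call. = FALSE))
  fc <- raw$field %||% list()
  field <- tryCatch(
    field_conditions(b1_scale = fc$b1_scale %||% 1, b0 = fc$b0 %||% 64),
    error = function(e) stop("load_config: field: ",
                             conditionMessage(e), call. = FALSE))
  structure(list(tissues = tissues, protocol = protocol,
                 acquisition = acquisition, field = field, raw = raw),
            class = "run_config")
}

#' Write a provenance sidecar for a run
#'
#' Echoes the resolved configuration (seed, protocol, tissue parameters,
#' field and acquisition settings) as JSON next to the outputs, so a run
#' can be reproduced bit-exactly from its sidecar.
#'
#' @param x A list (e.g. the `provenance` element of a `sweep_dataset`, or
#'   a `run_config`).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(x, path) {
  if (inherits(x, "run_config"))
    x <- list(tissues = lapply(x$tissues, unclass),
              protocol = unclass(x$protocol),
              acquisition = unclass(x$acquisition),
              field = unclass(x$field))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}
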